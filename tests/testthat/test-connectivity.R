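test_that("DTF is row-normalized with diagonal 1 for an uncoupled system", {
  m <- list(coeffs = list(diag(c(0.5, -0.3, 0.2))), fs = 100)
  g <- dtf(transfer_matrix(m, seq(0.5, 45, 0.5)))
  # diagonal H: gamma_ii = 1, off-diagonal 0
  expect_equal(max(abs(g$values[1, 1, ] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$values[1, 2, ])), 0)
  # normalization identity at every frequency
  expect_lt(max(abs(apply(g$values^2, c(1, 3), sum) - 1)), 1e-12)
})

test_that("DTF normalization holds for random stable models", {
  set.seed(10)
  for (rep in 1:10) {
    M <- sample(2:6, 1)
    repeat {
      A <- list(matrix(rnorm(M * M, sd = 0.3), M),
                matrix(rnorm(M * M, sd = 0.15), M))
      if (companion_spectral_radius(A) < 0.95) break
    }
    g <- dtf(transfer_matrix(list(coeffs = A, fs = 128), seq(0.5, 45, 0.5)))
    expect_lt(max(abs(apply(g$values^2, c(1, 3), sum) - 1)), 1e-8)
    expect_true(all(g$values >= 0 & g$values <= 1))
  }
})

test_that("unidirectional coupling produces asymmetric DTF", {
  tr <- var_ground_truth(list(matrix(c(0.5, 0.4, 0, 0.5), 2)))
  rec <- simulate_var(tr, 1e5, seed = 12, fs = 128)
  m <- fit_var(rec, 1)
  g <- dtf(transfer_matrix(m, seq(0.5, 45, 0.5)))
  expect_lt(max(g$values[1, 2, ]), 0.05)   # no influence 2 -> 1
  expect_gt(max(g$values[2, 1, ]), 0.05)   # influence 1 -> 2 at resonance
})

test_that("DTF is invariant to per-channel rescaling given variance normalization", {
  tr <- var_ground_truth(list(matrix(c(0.5, 0.4, 0, 0.5), 2)))
  rec <- simulate_var(tr, 5e4, seed = 13, fs = 128)
  fr <- seq(0.5, 45, 0.5)
  g1 <- dtf(transfer_matrix(fit_var(rec$data, 1, scale = TRUE, fs = 128), fr))
  g2 <- dtf(transfer_matrix(fit_var(rec$data * c(10, 0.1), 1, scale = TRUE,
                                    fs = 128), fr))
  expect_lt(max(abs(g1$values - g2$values)), 1e-10)
})

test_that("a 1->2->3 chain shows cascade DTF influence 1->3", {
  A <- diag(0.5, 3); A[2, 1] <- 0.4; A[3, 2] <- 0.4
  tr <- var_ground_truth(list(A))
  fr <- seq(0.5, 45, 0.5)
  # noise floor from null (uncoupled) simulations of the same size
  null_floor <- max(vapply(1:5, function(s) {
    rec0 <- simulate_var(var_ground_truth(list(diag(0.5, 3))), 1e5,
                         seed = 600 + s, fs = 128)
    max(dtf(transfer_matrix(fit_var(rec0, 1), fr))$values[3, 1, ])
  }, numeric(1)))
  rec <- simulate_var(tr, 1e5, seed = 14, fs = 128)
  g <- dtf(transfer_matrix(fit_var(rec, 1), fr))
  expect_gt(max(g$values[3, 1, ]), null_floor)
})

test_that("cross-spectra are Hermitian with expected degenerate cases", {
  set.seed(15)
  x <- rnorm(2^14)
  rec <- recording(rbind(x, x), fs = 256)
  S <- cross_spectrum(rec, window_s = 2)
  # identical channels: S12 = S11 = S22
  expect_lt(max(Mod(S$S[1, 2, ] - S$S[1, 1, ])), 1e-10)
  expect_lt(max(Mod(S$S[1, 2, ] - Conj(S$S[2, 1, ]))), 1e-12) # Hermitian
  expect_true(all(Re(diag(S$S[, , 10])) >= 0))
})

test_that("independent channels have near-zero normalized cross-spectra", {
  set.seed(16)
  rec <- recording(matrix(rnorm(2 * 1e6), 2), fs = 512)
  S <- cross_spectrum(rec, window_s = 2)
  num <- Mod(S$S[1, 2, ])
  den <- sqrt(Re(S$S[1, 1, ]) * Re(S$S[2, 2, ]))
  expect_lt(mean(num / den), 0.05)
})

test_that("a pure sinusoid concentrates its auto-spectrum in one bin", {
  fs <- 256
  tt <- seq_len(fs * 32) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 17 * tt)),
                   fs = fs)
  S <- cross_spectrum(rec, window_s = 2)
  p <- Re(S$S[1, 1, ])
  expect_gt(sum(p[abs(S$freqs - 10) <= 0.5]) / sum(p), 0.99)
  expect_error(cross_spectrum(rec, window_s = 100), "longer")
})

test_that("coherency magnitude behaves at its limits", {
  set.seed(17)
  x <- rnorm(2^15)
  fs <- 256
  same <- coherence(cross_spectrum(recording(rbind(x, x), fs = fs), 2))
  expect_lt(max(abs(Mod(same$values[1, 2, ]) - 1)), 1e-10)
  indep <- coherence(cross_spectrum(
    recording(matrix(rnorm(2 * 2^18), 2), fs = fs), 2))
  K <- 2^18 / 256 * 2 - 1
  expect_lt(mean(Mod(indep$values[1, 2, ])), 2 / sqrt(K))
  expect_true(all(Mod(indep$values) <= 1 + 1e-12))
})

test_that("iCoh cancels zero-lag mixing but detects a pure delay", {
  set.seed(18)
  fs <- 200
  n <- 1e6
  s1 <- rnorm(n); s2 <- rnorm(n)
  # instantaneous mixtures of the same sources: |C| high, iCoh ~ 0
  mixed <- recording(rbind(s1 + 0.7 * s2, 0.8 * s1 + s2), fs = fs)
  C <- coherence(cross_spectrum(mixed, 2))
  expect_gt(mean(Mod(C$values[1, 2, ])), 0.9)
  ic <- icoh(C)
  expect_lt(mean(abs(ic$values[1, 2, ])), 0.05)
  # 25 ms delay on a 10 Hz narrowband source: quarter cycle, iCoh -> 1
  a <- eegconn:::ar2_resonator(10, 0.5, fs)
  src <- as.numeric(stats::filter(rnorm(2^16 + fs), a, method = "recursive"))
  lag <- round(0.025 * fs)
  x1 <- src[(lag + 1):(lag + 2^16)]
  x2 <- src[1:2^16]
  icd <- icoh(coherence(cross_spectrum(recording(rbind(x1, x2), fs = fs), 2)))
  expect_gt(abs(icd$values[1, 2, which.min(abs(icd$freqs - 10))]), 0.8)
})

test_that("iCoh is antisymmetric with a zero diagonal", {
  set.seed(19)
  rec <- recording(matrix(rnorm(3 * 2^14), 3), fs = 128)
  ic <- icoh(coherence(cross_spectrum(rec, 2)))
  expect_equal(max(abs(ic$values[1, 1, ])), 0)
  for (i in 1:3) for (j in 1:3)
    expect_equal(ic$values[i, j, ], -ic$values[j, i, ], tolerance = 1e-12)
})

const_tensor <- function(c, M = 4, freqs = seq(0.5, 45, 0.5)) {
  eegconn:::conn_tensor("dtf", array(c, c(M, M, length(freqs))), freqs, TRUE)
}

test_that("band averages reproduce constants and indicators", {
  tens <- const_tensor(0.37)
  b <- band_average(tens)
  for (bm in b) expect_equal(max(abs(bm$values - 0.37)), 0)
  # indicator: 1 exactly on the alpha bins
  fr <- seq(0.5, 45, 0.5)
  v <- array(0, c(3, 3, length(fr)))
  v[, , fr >= 8 & fr < 13] <- 1
  ind <- eegconn:::conn_tensor("dtf", v, fr, TRUE)
  bi <- band_average(ind)
  expect_equal(max(abs(bi$alpha$values - 1)), 0)
  expect_equal(max(abs(bi$delta$values)), 0)
  expect_error(band_average(tens, bands = list(bad = c(50, 60))), "no frequency")
})

test_that("the total band is the bin-weighted mean of the sub-bands", {
  set.seed(20)
  fr <- seq(0.5, 45, 0.5)
  v <- array(runif(2 * 2 * length(fr)), c(2, 2, length(fr)))
  tens <- eegconn:::conn_tensor("dtf", v, fr, TRUE)
  b <- band_average(tens)
  sub <- c("delta", "theta", "alpha", "beta", "gamma")
  nb <- vapply(sub, function(s)
    sum(eegconn:::band_bins(fr, b[[s]]$lo, b[[s]]$hi)), numeric(1))
  weighted <- Reduce(`+`, Map(function(s, w) b[[s]]$values * w, sub, nb)) /
    sum(nb)
  expect_equal(b$total$values, weighted, tolerance = 1e-12)
})

test_that("window-averaged tensors equal the mean of their inputs", {
  t1 <- const_tensor(0.2); t2 <- const_tensor(0.6)
  avg <- average_tensors(list(t1, t2))
  expect_equal(max(abs(avg$values - 0.4)), 0)
})
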