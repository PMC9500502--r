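sine_rec <- function(f, fs, n_s, amp = 1, M = 2) {
  tt <- seq_len(fs * n_s) / fs
  recording(matrix(rep(amp * sin(2 * pi * f * tt), each = M), M,
                   byrow = FALSE), fs = fs)
}

test_that("high-pass FIR removes DC after edge trimming", {
  rec <- recording(matrix(100, 2, 4096), fs = 512)
  out <- trim_edges(highpass_fir(rec, 0.5, 826))
  expect_lt(max(abs(out$data)), 0.1)
})

test_that("designed filter response matches passband/stopband contract", {
  fs <- 512
  # rebuild the package's taps (spectral inversion of a unit-DC low-pass)
  # and evaluate the response independently
  hlp <- signal::fir1(826, 0.5 / (fs / 2), type = "low")
  hlp <- hlp / sum(hlp)
  h <- -hlp; h[414] <- h[414] + 1
  # passband: 10 Hz within 1% of unity
  expect_lt(abs(Mod(oracle_fir_response(h, 10, fs)) - 1), 0.01)
  # stopband: 0.1 Hz attenuated by >= 20 dB; DC nulled
  expect_lt(20 * log10(Mod(oracle_fir_response(h, 0.1, fs))), -20)
  expect_lt(Mod(oracle_fir_response(h, 0, fs)), 1e-12)
  # and the applied filter reproduces the response on a 10 Hz sinusoid
  tt <- seq_len(fs * 8) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 10 * tt)),
                   fs = fs)
  out <- trim_edges(highpass_fir(rec, 0.5, 826))
  amp <- sqrt(2 * mean(out$data[1, ]^2))
  expect_lt(abs(amp - 1), 0.01)
})

test_that("filtering is linear and rejects bad settings", {
  fs <- 256
  set.seed(2)
  x <- recording(matrix(rnorm(2 * 2048), 2), fs = fs)
  y <- recording(matrix(rnorm(2 * 2048), 2), fs = fs)
  z <- recording(3 * x$data - 2 * y$data, fs = fs)
  fx <- highpass_fir(x, 1, 200)$data
  fy <- highpass_fir(y, 1, 200)$data
  fz <- highpass_fir(z, 1, 200)$data
  expect_lt(max(abs(fz - (3 * fx - 2 * fy))), 1e-9)
  expect_error(highpass_fir(x, 200, 200), "Nyquist")
  expect_error(highpass_fir(x, 1, 201), "even")
})

test_that("line-noise removal restores the white floor at 50 Hz", {
  fs <- 512
  set.seed(8)
  tt <- seq_len(fs * 20) / fs
  noise <- matrix(rnorm(2 * length(tt)), 2)
  line <- 10 * sin(2 * pi * 50 * tt)
  rec <- recording(noise + rep(line, each = 2), fs = fs)
  out <- remove_line_noise(rec, 50, 4)
  ps <- welch_psd(out, window_s = 4)
  at <- ps$freqs >= 49.5 & ps$freqs <= 50.5
  nb <- ps$freqs >= 40 & ps$freqs <= 60 & !at
  excess_db <- 10 * (log10(mean(ps$psd[, at])) - log10(median(ps$psd[, nb])))
  expect_lt(excess_db, 3)
})

test_that("line-noise removal is a near no-op without a line component", {
  fs <- 256
  set.seed(12)
  rec <- recording(matrix(rnorm(2 * fs * 10), 2), fs = fs)
  out <- remove_line_noise(rec, 50, 4)
  rms_in <- sqrt(rowMeans(rec$data^2))
  rms_out <- sqrt(rowMeans(out$data^2))
  expect_true(all(abs(rms_out / rms_in - 1) < 0.01))
})

test_that("amplitude-modulated line noise is attenuated by >= 10 dB", {
  fs <- 512
  set.seed(13)
  tt <- seq_len(fs * 32) / fs
  am <- (1 + 0.5 * sin(2 * pi * 0.05 * tt))
  line <- 5 * am * sin(2 * pi * 50 * tt)
  rec <- recording(rbind(line, line) + matrix(rnorm(2 * length(tt)), 2),
                   fs = fs)
  out <- remove_line_noise(rec, 50, 4)
  p50 <- function(r) {
    ps <- welch_psd(r, window_s = 4)
    mean(ps$psd[, ps$freqs >= 49.5 & ps$freqs <= 50.5])
  }
  expect_gt(10 * log10(p50(rec) / p50(out)), 10)
})

laplace <- function(n) { s <- sample(c(-1, 1), n, TRUE); s * rexp(n) }

test_that("FastICA recovers non-Gaussian sources up to sign and order", {
  set.seed(3)
  n <- 8000
  S <- rbind(laplace(n), laplace(n), rnorm(n))
  A <- matrix(c(1, .5, .3, .4, 1, -.6, .2, -.3, 1), 3)
  rec <- recording(A %*% S, fs = 100)
  dec <- ica_decompose(rec, seed = 9)
  cors <- abs(cor(t(dec$activations), t(S[1:2, ])))
  expect_true(all(apply(cors, 2, max) > 0.95))
})

test_that("already-independent channels give a scaled permutation unmixing", {
  set.seed(4)
  n <- 8000
  S <- rbind(2 * laplace(n), 0.5 * laplace(n), laplace(n))
  dec <- ica_decompose(recording(S, fs = 100), seed = 2)
  W <- abs(dec$unmixing %*% diag(apply(S, 1, sd)))
  dominance <- apply(W, 1, max) / sqrt(rowSums(W^2))
  expect_true(all(dominance > 0.95))
})

test_that("ICA is deterministic for a fixed seed", {
  set.seed(5)
  rec <- recording(matrix(rnorm(3 * 4000), 3), fs = 100)
  expect_identical(ica_decompose(rec, seed = 7)$unmixing,
                   ica_decompose(rec, seed = 7)$unmixing)
})

# hand-built decomposition: identity mixing, chosen activations
fake_dec <- function(acts, fs, labels = NULL) {
  K <- nrow(acts)
  if (is.null(labels)) labels <- paste0("C", seq_len(K))
  structure(list(unmixing = diag(K), mixing = diag(K), activations = acts,
                 center = rep(0, K), component_flags = NULL, fs = fs,
                 channel_labels = labels, reference_note = "synthetic"),
            class = "ica_decomposition")
}

test_that("rule-based flags identify constructed artifact components", {
  fs <- 256
  n <- fs * 20
  tt <- seq_len(n) / fs
  set.seed(6)
  line_ic <- sin(2 * pi * 50 * tt)
  a <- eegconn:::ar2_resonator(10, 1, fs)
  brain_ic <- as.numeric(stats::filter(rnorm(n), a, method = "recursive")) +
    2 * eegconn:::pink_noise(n)
  spike_ic <- rt(n, df = 3)                       # flat spectrum, heavy tails
  dec <- fake_dec(rbind(line_ic, brain_ic, spike_ic), fs)
  dec <- flag_artifact_components(dec)
  expect_equal(dec$component_flags$flag, c("artifact", "brain", "artifact"))
  expect_match(dec$component_flags$reason[1], "line")
})

test_that("back projection reconstructs, removes, and ranks correctly", {
  fs <- 256
  n <- fs * 16
  tt <- seq_len(n) / fs
  set.seed(7)
  S <- rbind(laplace(n), laplace(n), 5 * sin(2 * pi * 50 * tt))
  A <- matrix(rnorm(9), 3)
  rec <- recording(A %*% S - rowMeans(A %*% S), fs = fs)
  dec <- ica_decompose(rec, seed = 3)
  # keep everything: identity map
  full <- back_project(dec, keep = 1:3)
  expect_lt(max(abs(full$data - rec$data)) / max(abs(rec$data)), 1e-6)
  # drop the line component: 50 Hz power falls by >= 20 dB
  cors <- abs(cor(t(dec$activations), S[3, ]))
  line_ic <- which.max(cors)
  cleaned <- back_project(dec, keep = setdiff(1:3, line_ic))
  p50 <- function(r) {
    ps <- welch_psd(r, window_s = 4)
    mean(ps$psd[, ps$freqs >= 49.5 & ps$freqs <= 50.5])
  }
  expect_gt(10 * log10(p50(rec) / p50(cleaned)), 20)
  # single component: rank-1 output
  one <- back_project(dec, keep = 2)
  expect_equal(qr(one$data)$rank, 1)
  expect_error(back_project(dec, keep = integer(0)), "at least one")
})

test_that("the full chain leaves a clean cohort's band powers intact", {
  sp <- cohort_spec(n_subjects_per_group = c(1, 1), n_channels = 8,
                    fs = 256, duration = 30, line_noise_amp = 0,
                    noise_seed = 41, mixing_matrix_seed = 42)
  rec <- make_cohort(sp)[[1]]$recording
  pp <- preprocess_recording(rec, cutoff_hz = 0.5, fir_order = 826,
                             line_hz = 50, seed = 1)
  band_power <- function(r) {
    ps <- welch_psd(r, window_s = 2)
    sel <- ps$freqs >= 1 & ps$freqs <= 45
    rowSums(ps$psd[, sel])
  }
  ratio <- band_power(pp$recording) / band_power(rec)
  expect_true(all(abs(ratio - 1) < 0.1))
})
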