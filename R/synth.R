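#' Ground-truth VAR process specification
#'
#' Describes an exact vector-autoregressive process used to generate
#' multichannel signals with fully known structure: the coefficient matrices,
#' the innovation covariance, and the boolean directed-coupling graph implied
#' by the nonzero coefficient pattern. Simulated data from such a process is
#' the oracle for every estimation stage (MVAR fit, transfer matrix, DTF).
#'
#' @param coeffs list of p square M x M coefficient matrices, one per lag.
#' @param noise_cov M x M symmetric positive-definite innovation covariance.
#'   Defaults to the identity.
#' @return Object of class `var_truth` with fields `order`, `coeffs`,
#'   `noise_cov`, `coupling_graph` (entry \[i, j\] is `TRUE` iff some lag's
#'   coefficient \[i, j\] is nonzero) and `spectral_radius` of the companion
#'   matrix.
#' @export
var_ground_truth <- function(coeffs, noise_cov = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  stopifnot(length(coeffs) >= 1)
  M <- nrow(coeffs[[1]])
  for (A in coeffs) stopifnot(is.matrix(A), nrow(A) == M, ncol(A) == M)
  if (is.null(noise_cov)) noise_cov <- diag(M)
  noise_cov <- as.matrix(noise_cov)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("noise_cov must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise_cov must be positive definite")
  rho <- companion_spectral_radius(coeffs)
  cg <- Reduce(`|`, lapply(coeffs, function(A) A != 0))
  structure(list(order = length(coeffs), coeffs = coeffs,
                 noise_cov = noise_cov, coupling_graph = cg,
                 spectral_radius = rho),
            class = "var_truth")
}

#' Spectral radius of the VAR companion matrix
#'
#' A VAR(p) process is stable iff this is strictly below 1.
#'
#' @param coeffs list of p M x M coefficient matrices.
#' @return Largest eigenvalue modulus of the (pM) x (pM) companion matrix.
#' @export
companion_spectral_radius <- function(coeffs) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  M <- nrow(coeffs[[1]]); p <- length(coeffs)
  C <- matrix(0, p * M, p * M)
  C[seq_len(M), ] <- do.call(cbind, coeffs)
  if (p > 1)
    C[(M + 1):(p * M), seq_len((p - 1) * M)] <- diag((p - 1) * M)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a VAR process
#'
#' Runs the VAR recursion with Gaussian innovations drawn from the truth's
#' noise covariance. A burn-in stretch is generated from zero initial
#' conditions and discarded so the returned samples are (numerically)
#' stationary. The same seed always yields bit-identical output.
#'
#' @param truth a [var_ground_truth()].
#' @param n_samples number of samples to return.
#' @param seed RNG seed for the innovations.
#' @param fs nominal sampling rate attached to the returned recording (Hz).
#' @param burnin samples generated and discarded before the kept stretch.
#' @param channel_labels optional labels; defaults to `S1..SM`.
#' @return A [recording()] with M channels and `n_samples` samples.
#' @export
simulate_var <- function(truth, n_samples, seed, fs = 512, burnin = 1000,
                         channel_labels = NULL) {
  stopifnot(inherits(truth, "var_truth"))
  if (truth$spectral_radius >= 1)
    stop(sprintf("unstable VAR process: companion spectral radius %.4f >= 1",
                 truth$spectral_radius))
  M <- nrow(truth$noise_cov)
  L <- t(chol(truth$noise_cov))
  set.seed(seed)
  innov <- L %*% matrix(rnorm(M * (burnin + n_samples)), M)
  stacked <- do.call(cbind, truth$coeffs)
  x <- var_recursion(stacked, innov, truth$order, burnin)
  if (is.null(channel_labels)) channel_labels <- paste0("S", seq_len(M))
  recording(x, fs = fs, channel_labels = channel_labels,
            reference_note = "simulated VAR process")
}

#' Two-group synthetic EEG cohort specification
#'
#' Defines an eyes-closed resting-state-like cohort of two groups with
#' group-dependent spectral power and coupling structure. Each subject is a
#' random instantaneous mixture of band-limited oscillatory sources — alpha
#' (8-13 Hz) sources with directed lagged couplings at the group's density,
#' and gamma (30-45 Hz) sources — plus 1/f background noise and an optional
#' line-frequency sinusoid. Instantaneous mixing emulates volume conduction,
#' which the imaginary part of coherency is designed to cancel.
#'
#' Defaults emulate a 32-channel, 512 Hz, 6-minute recording session of a
#' healthy group against a patient-like group with a lower alpha peak,
#' higher gamma power and denser alpha-band coupling.
#'
#' @param n_subjects_per_group integer vector of length 2 (or scalar,
#'   recycled): subjects per group.
#' @param n_channels channels per recording.
#' @param fs sampling rate, Hz; must exceed 90 Hz so the 45 Hz gamma edge is
#'   below Nyquist.
#' @param duration recording length, seconds.
#' @param alpha_peak_gain length-2 positive multipliers on alpha source
#'   amplitude per group.
#' @param gamma_gain length-2 positive multipliers on gamma source amplitude
#'   per group.
#' @param alpha_coupling_density length-2 fractions in \[0, 1\]: fraction of
#'   ordered alpha-source pairs with a directed lag-1 coupling.
#' @param mixing_matrix_seed,noise_seed integer seeds for the per-subject
#'   mixing matrices and source/noise realizations.
#' @param line_noise_amp amplitude (same units as sources) of an added 50 Hz
#'   sinusoid; 0 disables. Ignored (with a warning) when 50 Hz is at or above
#'   Nyquist.
#' @param subject_gain_sd log-normal sd of per-subject multiplicative jitter
#'   on the band gains (between-subject variability).
#' @param group_labels length-2 character labels.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = c(18, 20),
                        n_channels = 32, fs = 512, duration = 360,
                        alpha_peak_gain = c(1.0, 0.6),
                        gamma_gain = c(1.0, 1.6),
                        alpha_coupling_density = c(0.1, 0.4),
                        mixing_matrix_seed = 101, noise_seed = 202,
                        line_noise_amp = 0, subject_gain_sd = 0.15,
                        group_labels = c("healthy", "patient")) {
  n_subjects_per_group <- rep_len(as.integer(n_subjects_per_group), 2)
  alpha_peak_gain <- rep_len(alpha_peak_gain, 2)
  gamma_gain <- rep_len(gamma_gain, 2)
  alpha_coupling_density <- rep_len(alpha_coupling_density, 2)
  stopifnot(all(n_subjects_per_group >= 1), n_channels >= 2,
            fs > 2 * 45, duration > 0,
            all(alpha_peak_gain > 0), all(gamma_gain > 0),
            all(alpha_coupling_density >= 0),
            all(alpha_coupling_density <= 1),
            line_noise_amp >= 0, subject_gain_sd >= 0)
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 n_channels = n_channels, fs = fs, duration = duration,
                 alpha_peak_gain = alpha_peak_gain, gamma_gain = gamma_gain,
                 alpha_coupling_density = alpha_coupling_density,
                 mixing_matrix_seed = mixing_matrix_seed,
                 noise_seed = noise_seed, line_noise_amp = line_noise_amp,
                 subject_gain_sd = subject_gain_sd,
                 group_labels = group_labels),
            class = "cohort_spec")
}

# AR(2) resonator coefficients for a pole at f0 Hz with ~bw Hz bandwidth
ar2_resonator <- function(f0, bw, fs) {
  r <- exp(-pi * bw / fs)
  c(2 * r * cos(2 * pi * f0 / fs), -r^2)
}

# 1/f (pink-like) noise via spectral shaping of white Gaussian noise;
# unit variance, deterministic under the caller's RNG state.
pink_noise <- function(n) {
  w <- rnorm(n)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)          # two-sided frequency index, symmetric
  scale <- 1 / sqrt(pmax(f, 1))
  x <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
  x / sd(x)
}

# Build the alpha-band source VAR for one subject: AR(2) resonators at 10 Hz
# on the diagonal plus directed lag-1 couplings at the requested density.
# Couplings are shrunk if they push the companion spectral radius past 0.98.
alpha_source_var <- function(n_src, density, fs) {
  a <- ar2_resonator(10, 2, fs)
  A1 <- diag(a[1], n_src)
  A2 <- diag(a[2], n_src)
  pairs <- which(diag(n_src) == 0)
  n_cpl <- round(density * length(pairs))
  if (n_cpl > 0) {
    sel <- sample(pairs, n_cpl)
    cpl <- 0.15
    repeat {
      A1c <- A1; A1c[sel] <- cpl
      if (companion_spectral_radius(list(A1c, A2)) < 0.98 || cpl < 1e-3)
        break
      cpl <- cpl * 0.7
    }
    A1 <- A1c
  }
  var_ground_truth(list(A1, A2))
}

#' Generate a two-group synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort`; each element is a list with `recording`,
#'   `group`, and `subject_id`. The generating spec and the per-subject seeds
#'   are attached as attributes `spec` and `seeds` so downstream tests can
#'   verify recovery of the known group parameters.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- sum(spec$n_subjects_per_group)
  set.seed(spec$noise_seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1, n_tot)
  set.seed(spec$mixing_matrix_seed)
  mix_seeds <- sample.int(.Machine$integer.max - 1, n_tot)
  M <- spec$n_channels
  N <- round(spec$fs * spec$duration)
  n_alpha <- max(4L, round(M / 4))
  n_gamma <- max(2L, round(M / 8))
  labels <- if (M <= 32) montage_1020_32()[seq_len(M)] else
    paste0("Ch", seq_len(M))
  gam_coef <- ar2_resonator(38, 6, spec$fs)
  out <- vector("list", n_tot)
  idx <- 0L
  for (g in 1:2) {
    for (s in seq_len(spec$n_subjects_per_group[g])) {
      idx <- idx + 1L
      set.seed(subj_seeds[idx])
      jit <- exp(rnorm(2, 0, spec$subject_gain_sd))
      truth <- alpha_source_var(n_alpha, spec$alpha_coupling_density[g],
                                spec$fs)
      alpha_seed <- sample.int(.Machine$integer.max - 1, 1)
      alpha_src <- simulate_var(truth, N, seed = alpha_seed, fs = spec$fs)$data
      alpha_src <- alpha_src / apply(alpha_src, 1, sd) *
        (spec$alpha_peak_gain[g] * jit[1])
      set.seed(alpha_seed + 1L)
      gamma_src <- matrix(0, n_gamma, N)
      for (k in seq_len(n_gamma)) {
        e <- rnorm(N + 500)
        x <- as.numeric(stats::filter(e, gam_coef, method = "recursive"))
        x <- x[-seq_len(500)]
        gamma_src[k, ] <- x / sd(x) * (spec$gamma_gain[g] * jit[2])
      }
      src <- rbind(alpha_src, gamma_src)
      set.seed(mix_seeds[idx])
      B <- matrix(rnorm(M * nrow(src), sd = 1 / sqrt(nrow(src))), M)
      set.seed(subj_seeds[idx] + 1L)
      bg <- t(vapply(seq_len(M), function(i) pink_noise(N), numeric(N)))
      x <- B %*% src + 0.8 * bg
      if (spec$line_noise_amp > 0) {
        if (50 >= spec$fs / 2) {
          warning("line frequency at/above Nyquist; line noise not added")
        } else {
          tt <- seq_len(N) / spec$fs
          phase <- runif(M, 0, 2 * pi)
          x <- x + spec$line_noise_amp *
            sin(outer(phase, 2 * pi * 50 * tt, `+`))
        }
      }
      out[[idx]] <- list(
        recording = recording(x, fs = spec$fs, channel_labels = labels,
                              reference_note = "synthetic cohort subject"),
        group = spec$group_labels[g],
        subject_id = sprintf("%s_s%02d", spec$group_labels[g], s))
    }
  }
  structure(out, class = "cohort", spec = spec,
            seeds = list(subject = subj_seeds, mixing = mix_seeds))
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x, `[[`, "", "group")
  cat(sprintf("<cohort> %d subjects (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(grp)), table(grp)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk with a manifest
#'
#' Each subject's recording is written via [write_recording()] and a
#' `manifest.csv` (subject_id, group, file) is placed in `dir`.
#'
#' @param cohort a `cohort` from [make_cohort()].
#' @param dir output directory, created if needed.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(su) {
    write_recording(su$recording, file.path(dir, su$subject_id))
    data.frame(subject_id = su$subject_id, group = su$group,
               file = paste0(su$subject_id, ".tsv"))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
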