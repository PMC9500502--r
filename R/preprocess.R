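#' Zero-phase high-pass FIR filter
#'
#' Designs a linear-phase (type I) high-pass FIR filter with
#' [signal::fir1()] and applies it with group-delay compensation, so the
#' output is delay-free. Slow drifts and DC are removed without the phase
#' distortion that would bias lag-based connectivity estimates downstream.
#' The first and last `order/2` samples carry the edge transient of the
#' zero-padded convolution; [trim_edges()] drops them.
#'
#' @param rec a [recording()].
#' @param cutoff_hz high-pass cutoff (−6 dB point), Hz.
#' @param order filter order; must be even so the group delay is an integer
#'   number of samples.
#' @return The filtered [recording()], with the group delay (samples)
#'   attached as attribute `group_delay`.
#' @export
highpass_fir <- function(rec, cutoff_hz = 0.5, order = 826) {
  stopifnot(inherits(rec, "recording"))
  if (cutoff_hz >= rec$fs / 2) stop("cutoff must be below Nyquist")
  if (order %% 2 != 0) stop("order must be even (type-I linear phase)")
  # spectral inversion of a unit-DC-gain windowed-sinc low-pass: the
  # high-pass then has an exact null at DC, which a directly windowed
  # high-pass of this order would not achieve at so low a cutoff
  hlp <- signal::fir1(order, cutoff_hz / (rec$fs / 2), type = "low")
  hlp <- hlp / sum(hlp)
  gd <- order / 2
  h <- -hlp
  h[gd + 1] <- h[gd + 1] + 1
  N <- ncol(rec$data)
  filt <- function(x) {
    y <- stats::convolve(c(x, numeric(gd)), rev(h), type = "open")
    y[(gd + 1):(gd + N)]            # compensate the linear-phase delay
  }
  out <- t(apply(rec$data, 1, filt))
  res <- recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
                   reference_note = paste0(rec$reference_note,
                                           "; high-pass ", cutoff_hz, " Hz"))
  attr(res, "group_delay") <- gd
  res
}

#' Trim filter edge transients
#'
#' Drops `n` samples from each end of a recording (e.g. one group delay after
#' [highpass_fir()]) so MVAR fitting never sees the convolution edge.
#'
#' @param rec a [recording()].
#' @param n samples to drop from each end; defaults to the recording's
#'   `group_delay` attribute.
#' @return The shortened [recording()].
#' @export
trim_edges <- function(rec, n = NULL) {
  if (is.null(n)) n <- attr(rec, "group_delay")
  if (is.null(n) || n <= 0) return(rec)
  N <- ncol(rec$data)
  stopifnot(2 * n < N)
  recording(rec$data[, (n + 1):(N - n), drop = FALSE], fs = rec$fs,
            channel_labels = rec$channel_labels,
            reference_note = rec$reference_note)
}

#' Sliding-window line-noise removal
#'
#' In each window a sinusoid at the line frequency (amplitude and phase fit
#' by least squares per channel) is estimated and subtracted, following the
#' sliding-regression approach of line-noise cleaning tools. Fitting per
#' window tracks slow drifts of line amplitude; only two degrees of freedom
#' per window are removed, so non-line content is essentially untouched.
#'
#' @param rec a [recording()].
#' @param line_hz line frequency (Hz); must be below Nyquist.
#' @param window_s window length in seconds.
#' @return The cleaned [recording()].
#' @export
remove_line_noise <- function(rec, line_hz = 50, window_s = 4) {
  stopifnot(inherits(rec, "recording"))
  if (line_hz >= rec$fs / 2) stop("line frequency must be below Nyquist")
  N <- ncol(rec$data)
  nwin <- min(N, round(window_s * rec$fs))
  starts <- seq(1L, N, by = nwin)
  x <- rec$data
  for (s in starts) {
    e <- min(N, s + nwin - 1L)
    if (e - s + 1L < 8L && s > 1L) s2 <- e - nwin + 1L else s2 <- s
    idx <- s2:e
    tt <- idx / rec$fs
    C <- cbind(cos(2 * pi * line_hz * tt), sin(2 * pi * line_hz * tt))
    Y <- t(x[, idx, drop = FALSE])
    beta <- solve(crossprod(C), crossprod(C, Y))
    x[, s:e] <- x[, s:e, drop = FALSE] -
      t(C %*% beta)[, (s - s2 + 1):(e - s2 + 1), drop = FALSE]
  }
  recording(x, fs = rec$fs, channel_labels = rec$channel_labels,
            reference_note = paste0(rec$reference_note, "; line ", line_hz,
                                    " Hz removed"))
}

#' ICA decomposition of a recording
#'
#' Symmetric FastICA (logcosh contrast) on whitened, mean-removed channel
#' data. By default the number of extracted components equals the number of
#' channels; rank-deficient data reduce the component count to the numerical
#' rank with a warning. The decomposition is deterministic for a fixed seed.
#'
#' @param rec a [recording()].
#' @param seed RNG seed for the orthogonal initialization.
#' @param n_comp number of components (default: number of channels).
#' @param max_iter,tol FastICA iteration controls.
#' @return Object of class `ica_decomposition` with `unmixing` (K x M),
#'   `mixing` (M x K), `activations` (K x N), `center` (per-channel means
#'   removed before unmixing), `component_flags` (filled by
#'   [flag_artifact_components()]), plus `fs` and `channel_labels`.
#' @export
ica_decompose <- function(rec, seed = 1, n_comp = NULL, max_iter = 200,
                          tol = 1e-6) {
  stopifnot(inherits(rec, "recording"))
  X <- rec$data
  M <- nrow(X); N <- ncol(X)
  center <- rowMeans(X)
  Xc <- X - center
  cv <- tcrossprod(Xc) / N
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  K <- if (is.null(n_comp)) M else min(n_comp, M)
  if (rank < K) {
    warning(sprintf("rank-deficient data: reducing components %d -> %d",
                    K, rank))
    K <- rank
  }
  wh <- diag(1 / sqrt(eg$values[seq_len(K)]), K) %*%
    t(eg$vectors[, seq_len(K), drop = FALSE])
  Z <- wh %*% Xc
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(K * K), K)))
  sym_decorr <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), K) %*% t(s$vectors) %*% W
  }
  W <- sym_decorr(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- tcrossprod(G, Z) / N - diag(rowMeans(1 - G^2), K) %*% W
    W1 <- sym_decorr(W1)
    conv <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (conv < tol) break
  }
  unmixing <- W %*% wh
  mixing <- eg$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(K)]), K) %*% t(W)
  structure(list(unmixing = unmixing, mixing = mixing,
                 activations = unmixing %*% Xc, center = center,
                 component_flags = NULL, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 reference_note = rec$reference_note,
                 n_iter = it, converged = conv < tol),
            class = "ica_decomposition")
}

#' Default thresholds for rule-based artifact-component flagging
#'
#' @param line_hz line frequency inspected for line-dominated components.
#' @param line_ratio_db flag when line-band power exceeds the neighbouring
#'   floor by this many dB.
#' @param hf_slope_db_per_decade flag when the log-log PSD slope over
#'   25 Hz to min(95, 0.95 Nyquist) Hz is shallower (more positive) than
#'   this and high-frequency power dominates. Muscle spectra are flat or
#'   rising across that whole range, whereas narrowband gamma activity
#'   falls off again past its peak.
#' @param hf_power_frac minimum fraction of power above 20 Hz for the
#'   muscle rule.
#' @param lf_power_frac fraction of power below 4 Hz for the ocular rule.
#' @param frontal_ratio minimum ratio of frontal to global absolute mixing
#'   weight for the ocular rule.
#' @param kurtosis_excess excess-kurtosis threshold for spike-like
#'   components.
#' @return Named list of thresholds.
#' @export
artifact_config <- function(line_hz = 50, line_ratio_db = 10,
                            hf_slope_db_per_decade = -3,
                            hf_power_frac = 0.4,
                            lf_power_frac = 0.7, frontal_ratio = 0.8,
                            kurtosis_excess = 8) {
  list(line_hz = line_hz, line_ratio_db = line_ratio_db,
       hf_slope_db_per_decade = hf_slope_db_per_decade,
       hf_power_frac = hf_power_frac, lf_power_frac = lf_power_frac,
       frontal_ratio = frontal_ratio, kurtosis_excess = kurtosis_excess)
}

#' Flag artifact independent components by spectral and temporal rules
#'
#' Scores every component on documented features — line-frequency power
#' ratio, high-frequency spectral slope and power fraction (muscle),
#' low-frequency dominance with frontal channel loading (ocular), and excess
#' kurtosis of the activation (spikes) — and labels components exceeding the
#' configured thresholds as `artifact`, the rest as `brain`. This is a
#' transparent rule-based classifier, not a trained one; the per-component
#' feature record is retained so decisions can be audited.
#'
#' @param dec an [ica_decompose()] result.
#' @param fs sampling rate (defaults to the decomposition's).
#' @param config thresholds from [artifact_config()].
#' @return The decomposition with `component_flags` set: a data frame with
#'   one row per component (features, `flag` in brain/artifact, `reason`).
#' @export
flag_artifact_components <- function(dec, fs = dec$fs,
                                     config = artifact_config()) {
  stopifnot(inherits(dec, "ica_decomposition"))
  K <- nrow(dec$activations)
  ps <- welch_psd(dec$activations, fs = fs,
                  window_s = min(2, ncol(dec$activations) / fs / 2))
  f <- ps$freqs
  nyq <- fs / 2
  frontal <- grepl("^(Fp|AF)", dec$channel_labels)
  rows <- lapply(seq_len(K), function(k) {
    p <- ps$psd[k, ]
    tot <- sum(p[f > 0])
    line_ratio_db <- NA_real_
    if (config$line_hz + 2 < nyq) {
      in_line <- f >= config$line_hz - 1 & f <= config$line_hz + 1
      nb <- f >= config$line_hz - 10 & f <= config$line_hz + 10 &
        !(f >= config$line_hz - 2 & f <= config$line_hz + 2)
      if (any(in_line) && any(nb))
        line_ratio_db <- 10 * (log10(mean(p[in_line])) -
                                 log10(median(p[nb])))
    }
    hf_band <- f >= 25 & f <= min(95, 0.95 * nyq) &
      !(f >= config$line_hz - 2 & f <= config$line_hz + 2)
    hf_slope <- if (sum(hf_band) >= 3) {
      fit <- stats::lm.fit(cbind(1, log10(f[hf_band])),
                           10 * log10(pmax(p[hf_band], 1e-300)))
      fit$coefficients[2]
    } else NA_real_
    hf_frac <- sum(p[f > 20]) / tot
    lf_frac <- sum(p[f > 0 & f < 4]) / tot
    w <- abs(dec$mixing[, k])
    frontal_ratio <- if (any(frontal)) max(w[frontal]) / max(w) else NA_real_
    a <- dec$activations[k, ]
    kurt <- mean((a - mean(a))^4) / stats::var(a)^2 - 3
    reasons <- c(
      if (isTRUE(line_ratio_db > config$line_ratio_db)) "line",
      if (isTRUE(hf_slope > config$hf_slope_db_per_decade &&
                 hf_frac > config$hf_power_frac)) "muscle",
      if (isTRUE(lf_frac > config$lf_power_frac &&
                 (is.na(frontal_ratio) ||
                    frontal_ratio > config$frontal_ratio))) "ocular",
      if (isTRUE(kurt > config$kurtosis_excess)) "spike")
    data.frame(component = k, line_ratio_db = line_ratio_db,
               hf_slope = unname(hf_slope), hf_frac = hf_frac,
               lf_frac = lf_frac, frontal_ratio = frontal_ratio,
               kurtosis_excess = kurt,
               flag = if (length(reasons)) "artifact" else "brain",
               reason = paste(reasons, collapse = "+"))
  })
  dec$component_flags <- do.call(rbind, rows)
  dec
}

#' Back-project retained independent components to channel space
#'
#' Reconstructs channel data from a subset of components:
#' `mixing[, keep] %*% activations[keep, ] + center`. Keeping every
#' component reproduces the input (to numerical precision when the
#' decomposition is full rank).
#'
#' @param dec an [ica_decompose()] result.
#' @param keep integer indices of components to retain; defaults to the
#'   components flagged `brain` when flags are present.
#' @return A [recording()].
#' @export
back_project <- function(dec, keep = NULL) {
  stopifnot(inherits(dec, "ica_decomposition"))
  if (is.null(keep)) {
    if (is.null(dec$component_flags))
      stop("no `keep` given and no component flags present")
    keep <- dec$component_flags$component[dec$component_flags$flag == "brain"]
  }
  K <- nrow(dec$activations)
  keep <- unique(as.integer(keep))
  if (length(keep) == 0) stop("`keep` must name at least one component")
  if (any(keep < 1 | keep > K)) stop("`keep` out of range")
  x <- dec$mixing[, keep, drop = FALSE] %*%
    dec$activations[keep, , drop = FALSE] + dec$center
  recording(x, fs = dec$fs, channel_labels = dec$channel_labels,
            reference_note = paste0(dec$reference_note, "; ICA back-projected (",
                                    length(keep), "/", K, " ICs)"))
}

#' Full preprocessing chain
#'
#' High-pass FIR, edge trimming, optional line-noise removal, ICA, rule-based
#' artifact flagging, and back projection of the brain components.
#'
#' @param rec a [recording()].
#' @param cutoff_hz,fir_order high-pass settings ([highpass_fir()]).
#' @param line_hz line frequency, or `NULL` to skip line removal.
#' @param seed ICA seed.
#' @param artifact thresholds from [artifact_config()].
#' @param run_ica set `FALSE` to stop after filtering (for pipelines on
#'   artifact-free synthetic data).
#' @return List with `recording` (cleaned) and `ic_report` (the per-component
#'   feature/decision table, `NULL` when ICA was skipped).
#' @export
preprocess_recording <- function(rec, cutoff_hz = 0.5, fir_order = 826,
                                 line_hz = 50, seed = 1,
                                 artifact = artifact_config(line_hz =
                                                              if (is.null(line_hz)) 50 else line_hz),
                                 run_ica = TRUE) {
  out <- trim_edges(highpass_fir(rec, cutoff_hz, fir_order))
  if (!is.null(line_hz) && line_hz < rec$fs / 2)
    out <- remove_line_noise(out, line_hz)
  if (!run_ica) return(list(recording = out, ic_report = NULL))
  dec <- flag_artifact_components(ica_decompose(out, seed = seed),
                                  config = artifact)
  keep <- dec$component_flags$component[dec$component_flags$flag == "brain"]
  if (length(keep) == 0) keep <- seq_len(nrow(dec$activations))
  list(recording = back_project(dec, keep), ic_report = dec$component_flags)
}
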