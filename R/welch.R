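# Welch-averaged spectral estimators shared by the connectivity and
# preprocessing modules. Windows are Hamming-tapered with configurable
# overlap; the scaling constant is immaterial for coherence (it cancels) and
# consistent across channels for PSD comparisons.

welch_segments <- function(n, nwin, step) {
  if (nwin > n) stop("window longer than the data")
  starts <- seq(1L, n - nwin + 1L, by = step)
  lapply(starts, function(s) s:(s + nwin - 1L))
}

#' Welch power spectral density
#'
#' Average modified periodogram over Hamming-tapered, overlapping windows,
#' per channel.
#'
#' @param x a [recording()] or a channels-by-samples numeric matrix.
#' @param fs sampling rate (taken from the recording when omitted).
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap in \[0, 1).
#' @return List with `freqs` (Hz, 0..Nyquist) and `psd` (M x F matrix,
#'   power per Hz).
#' @export
welch_psd <- function(x, fs = NULL, window_s = 2, overlap = 0.5) {
  if (inherits(x, "recording")) { fs <- x$fs; x <- x$data }
  if (is.null(fs)) stop("fs required for matrix input")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  cs <- welch_cross_spectrum_mat(x, fs, window_s, overlap, diag_only = TRUE)
  list(freqs = cs$freqs, psd = cs$psd, n_windows = cs$n_windows)
}

# Core Welch estimator. With diag_only the auto-spectra are returned as an
# M x F real matrix; otherwise the full Hermitian M x M x F complex array.
welch_cross_spectrum_mat <- function(x, fs, window_s, overlap,
                                     diag_only = FALSE) {
  M <- nrow(x); n <- ncol(x)
  nwin <- round(window_s * fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  segs <- welch_segments(n, nwin, step)
  K <- length(segs)
  taper <- 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  U <- sum(taper^2) * fs
  nf <- nwin %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nwin
  if (diag_only) {
    acc <- matrix(0, nf, M)
    for (seg in segs) {
      X <- mvfft(t(x[, seg, drop = FALSE]) * taper)[seq_len(nf), ,
                                                    drop = FALSE]
      acc <- acc + Re(X * Conj(X))
    }
    return(list(freqs = freqs, psd = t(acc) / (K * U), n_windows = K))
  }
  ii <- rep(seq_len(M), times = M)
  jj <- rep(seq_len(M), each = M)
  acc <- matrix(0 + 0i, nf, M * M)
  for (seg in segs) {
    X <- mvfft(t(x[, seg, drop = FALSE]) * taper)[seq_len(nf), ,
                                                  drop = FALSE]
    acc <- acc + X[, ii, drop = FALSE] * Conj(X[, jj, drop = FALSE])
  }
  S <- array(t(acc) / (K * U), dim = c(M, M, nf))
  list(freqs = freqs, S = S, n_windows = K)
}
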