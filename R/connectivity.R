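#' Connectivity tensor container
#'
#' Internal constructor for an M x M x F array of pairwise couplings on a
#' frequency grid. `dtf` is directed (entry \[i, j, f\] = influence of j on
#' i); `coherence` (complex coherency) and `icoh` are undirected.
#'
#' @keywords internal
conn_tensor <- function(measure, values, freqs, directed, labels = NULL) {
  structure(list(measure = measure, values = values, freqs = freqs,
                 directed = directed, labels = labels),
            class = "connectivity_tensor")
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<connectivity_tensor> %s (%s), %d x %d channels, %d frequencies (%g-%g Hz)\n",
              x$measure, if (x$directed) "directed" else "undirected",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Directed transfer function
#'
#' Normalized DTF from a transfer matrix:
#' `gamma_ij(f) = |H_ij(f)| / sqrt(sum_k |H_ik(f)|^2)` — the inflow from
#' channel j to channel i as a fraction of all inflows to i, so for every
#' target i and frequency the squared entries sum to 1 across sources. DTF
#' reflects both direct and cascade (mediated) influence.
#'
#' @param H a [transfer_matrix()].
#' @param labels optional channel labels.
#' @return A `connectivity_tensor` with measure `"dtf"`, values in \[0, 1\].
#' @export
dtf <- function(H, labels = NULL) {
  stopifnot(inherits(H, "transfer_matrix"))
  a <- Mod(H$H)
  dn <- sqrt(apply(a^2, c(1, 3), sum))        # M x F row norms
  if (any(dn == 0)) stop("all-zero row in H: cannot normalize DTF")
  g <- a
  for (fi in seq_along(H$freqs)) g[, , fi] <- a[, , fi] / dn[, fi]
  conn_tensor("dtf", g, H$freqs, directed = TRUE, labels = labels)
}

#' Welch cross-spectral matrix of a recording
#'
#' Hermitian M x M cross-spectral density at each frequency, estimated by
#' averaging tapered windowed Fourier cross-products (Welch). Auto-spectra
#' are real and non-negative.
#'
#' @param rec a [recording()] (or matrix with `fs`).
#' @param window_s,overlap Welch window length (s) and fractional overlap.
#' @param fs sampling rate for matrix input.
#' @return Object of class `cross_spectrum`: `freqs`, complex `S`
#'   (M x M x F), `n_windows`, `labels`.
#' @export
cross_spectrum <- function(rec, window_s = 2, overlap = 0.5, fs = NULL) {
  labels <- NULL
  if (inherits(rec, "recording")) {
    fs <- rec$fs; labels <- rec$channel_labels; x <- rec$data
  } else x <- as.matrix(rec)
  if (is.null(fs)) stop("fs required for matrix input")
  if (round(window_s * fs) > ncol(x))
    stop("Welch window longer than the recording")
  cs <- welch_cross_spectrum_mat(x, fs, window_s, overlap)
  structure(list(freqs = cs$freqs, S = cs$S, n_windows = cs$n_windows,
                 fs = fs, labels = labels), class = "cross_spectrum")
}

#' Complex coherency from cross-spectra
#'
#' `C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`; `|C| <= 1` by
#' Cauchy-Schwarz. Frequencies with a zero auto-spectrum are masked (`NA`)
#' with a warning.
#'
#' @param S a [cross_spectrum()].
#' @return A `connectivity_tensor` with measure `"coherence"` holding the
#'   complex coherency (take `Mod()` for the coherence magnitude, or pass to
#'   [icoh()]).
#' @export
coherence <- function(S) {
  stopifnot(inherits(S, "cross_spectrum"))
  M <- dim(S$S)[1]; FF <- dim(S$S)[3]
  auto <- vapply(seq_len(FF), function(fi) Re(diag(S$S[, , fi])),
                 numeric(M))                 # M x F
  C <- S$S
  bad <- FALSE
  for (fi in seq_len(FF)) {
    d <- sqrt(auto[, fi])
    if (any(d == 0)) { bad <- TRUE; C[, , fi] <- NA_complex_; next }
    C[, , fi] <- S$S[, , fi] / tcrossprod(d)
  }
  if (bad) warning("zero auto-spectrum bin(s) masked")
  conn_tensor("coherence", C, S$freqs, directed = FALSE, labels = S$labels)
}

#' Imaginary part of coherency
#'
#' `iCoh_ij(f) = Im(C_ij(f))`. Purely instantaneous (zero-lag) coupling —
#' e.g. volume conduction of a common source — contributes only to the real
#' part, so iCoh isolates lagged interactions. Values are stored signed
#' (antisymmetric in i, j); use the absolute value as an undirected edge
#' weight.
#'
#' @param C complex coherency from [coherence()] (a [cross_spectrum()] is
#'   accepted and converted).
#' @return A `connectivity_tensor` with measure `"icoh"`, values in
#'   \[-1, 1\], zero on the diagonal.
#' @export
icoh <- function(C) {
  if (inherits(C, "cross_spectrum")) C <- coherence(C)
  stopifnot(inherits(C, "connectivity_tensor"), C$measure == "coherence")
  v <- Im(C$values)
  for (fi in seq_len(dim(v)[3])) {
    vf <- v[, , fi]; diag(vf) <- 0; v[, , fi] <- vf
  }
  conn_tensor("icoh", v, C$freqs, directed = FALSE, labels = C$labels)
}

#' Conventional EEG frequency bands
#'
#' Band limits in Hz: delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 30-45, plus `total` spanning 0.5-45 Hz. Bands are half-open
#' `[lo, hi)` except that an upper limit of 45 Hz is inclusive, so the five
#' sub-bands exactly partition `total`.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
eeg_bands <- function() {
  list(total = c(0.5, 45), delta = c(0.5, 4), theta = c(4, 8),
       alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
}

band_bins <- function(freqs, lo, hi) {
  if (hi >= 45) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
}

#' Average a connectivity tensor over frequency bands
#'
#' Arithmetic mean of the tensor over the frequency bins falling in each
#' band.
#'
#' @param tensor a `connectivity_tensor` with real values ([dtf()] output,
#'   `Mod()` of coherency, or [icoh()]; see `abs_values`).
#' @param bands named list of `c(lo, hi)` Hz pairs, as [eeg_bands()].
#' @param abs_values take `abs()` of the tensor first (the conventional
#'   non-negative edge weight for signed iCoh).
#' @return Named list of `band_matrix` objects (`measure`, `band`, `lo`,
#'   `hi`, M x M `values`, `directed`).
#' @export
band_average <- function(tensor, bands = eeg_bands(), abs_values = FALSE) {
  stopifnot(inherits(tensor, "connectivity_tensor"))
  v <- tensor$values
  if (is.complex(v)) stop("band_average needs real values; take Mod() or Im() first")
  if (abs_values) v <- abs(v)
  out <- lapply(names(bands), function(nm) {
    sel <- band_bins(tensor$freqs, bands[[nm]][1], bands[[nm]][2])
    if (!any(sel)) stop(sprintf("band '%s' contains no frequency bins", nm))
    bm <- apply(v[, , sel, drop = FALSE], c(1, 2), mean)
    dimnames(bm) <- list(tensor$labels, tensor$labels)
    structure(list(measure = tensor$measure, band = nm,
                   lo = bands[[nm]][1], hi = bands[[nm]][2], values = bm,
                   directed = tensor$directed), class = "band_matrix")
  })
  names(out) <- names(bands)
  out
}

#' Average connectivity tensors across windows
#'
#' Element-wise mean of tensors computed on successive analysis windows
#' (same measure and frequency grid), e.g. per-window DTF from
#' [windowed_fit()].
#'
#' @param tensors list of `connectivity_tensor`s.
#' @return A single `connectivity_tensor`.
#' @export
average_tensors <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  t1 <- tensors[[1]]
  acc <- t1$values
  if (length(tensors) > 1)
    for (k in 2:length(tensors)) acc <- acc + tensors[[k]]$values
  conn_tensor(t1$measure, acc / length(tensors), t1$freqs, t1$directed,
              t1$labels)
}

#' Write band matrices as CSV with a JSON index
#'
#' One CSV per (measure, band) matrix plus an `index.json` describing the
#' files.
#'
#' @param band_list list of `band_matrix` objects.
#' @param dir output directory.
#' @param subject subject identifier recorded in the index.
#' @return The index path, invisibly.
#' @export
write_band_matrices <- function(band_list, dir, subject = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- lapply(band_list, function(bm) {
    fn <- sprintf("%s_%s_%s.csv", subject, bm$measure, bm$band)
    write.csv(bm$values, file.path(dir, fn), row.names = FALSE)
    list(subject = subject, measure = bm$measure, band = bm$band,
         lo = bm$lo, hi = bm$hi, file = fn)
  })
  path <- file.path(dir, sprintf("%s_index.json", subject))
  jsonlite::write_json(idx, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
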