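#' Fit a multivariate autoregressive (MVAR) model
#'
#' Multichannel least-squares estimation of a VAR(p) model
#' `x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t`. Channels are mean-removed
#' internally; set `scale = TRUE` to also variance-normalize them (the
#' pipeline does this before connectivity estimation, keeping DTF invariant
#' to per-channel gain). The residual covariance is estimated with the
#' fitted degrees of freedom removed.
#'
#' @param rec a [recording()] or channels-by-samples matrix.
#' @param p model order (number of lags).
#' @param scale variance-normalize channels before fitting.
#' @param fs sampling rate for matrix input.
#' @return Object of class `var_model`: `order`, `coeffs` (list of p M x M
#'   matrices), `noise_cov`, `n_samples_used` (regression rows T̂),
#'   `residuals` (T̂ x M), `spectral_radius`, `stable`, `fs`, `window_meta`.
#' @export
fit_var <- function(rec, p, scale = FALSE, fs = NULL) {
  if (inherits(rec, "recording")) { fs <- rec$fs; x <- rec$data }
  else { x <- as.matrix(rec); if (is.null(fs)) fs <- NA_real_ }
  M <- nrow(x); N <- ncol(x)
  stopifnot(p >= 1)
  if (N - p <= 10 * p * M)
    stop(sprintf("insufficient samples: need N > %d for p = %d, M = %d (have %d)",
                 10 * p * M + p, p, M, N))
  x <- x - rowMeans(x)
  if (scale) x <- x / apply(x, 1, stats::sd)
  E <- stats::embed(t(x), p + 1)            # rows: [x_t, x_{t-1}, ..., x_{t-p}]
  Y <- E[, seq_len(M), drop = FALSE]
  X <- E[, -seq_len(M), drop = FALSE]
  B <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% B
  Teff <- nrow(Y)
  Sigma <- crossprod(resid) / max(1, Teff - p * M)
  coeffs <- lapply(seq_len(p), function(k)
    t(B[((k - 1) * M + 1):(k * M), , drop = FALSE]))
  rho <- companion_spectral_radius(coeffs)
  structure(list(order = p, coeffs = coeffs, noise_cov = Sigma,
                 n_samples_used = Teff, n_channels = M, fs = fs,
                 residuals = resid, spectral_radius = rho,
                 stable = rho < 1, scaled = scale, window_meta = NULL),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> order %d, %d channels, T = %d, spectral radius %.3f (%s)\n",
              x$order, x$n_channels, x$n_samples_used, x$spectral_radius,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' AIC of a VAR model (pure formula)
#'
#' `AIC(p) = ln|Sigma| + 2 p M^2 / T`, where `Sigma` is the residual noise
#' covariance, `M` the channel count and `T` the number of samples used in
#' the fit. A singular covariance yields `+Inf` with a warning (the model is
#' degenerate/overfit).
#'
#' @param noise_cov residual covariance matrix (M x M).
#' @param p model order.
#' @param t_used samples used in the fit.
#' @return The AIC value.
#' @export
aic_formula <- function(noise_cov, p, t_used) {
  M <- nrow(noise_cov)
  ld <- determinant(noise_cov, logarithm = TRUE)
  if (!is.finite(ld$modulus) || ld$sign <= 0) {
    warning("singular residual covariance: AIC is +Inf")
    return(Inf)
  }
  as.numeric(ld$modulus) + 2 * p * M^2 / t_used
}

#' @rdname aic_formula
#' @param model a fitted [fit_var()] model.
#' @export
var_aic <- function(model) {
  stopifnot(inherits(model, "var_model"))
  aic_formula(model$noise_cov, model$order, model$n_samples_used)
}

#' Select the MVAR model order by AIC
#'
#' Fits every order in `p_range` and returns the AIC minimizer; ties are
#' broken toward the smaller order (parsimony). The full AIC curve is
#' attached as attribute `aic_curve`.
#'
#' @inheritParams fit_var
#' @param p_range candidate orders (scanned in increasing order).
#' @return The selected order (integer) with attribute `aic_curve`
#'   (data frame of `p`, `aic`).
#' @export
select_order <- function(rec, p_range = 1:30, scale = FALSE, fs = NULL) {
  p_range <- sort(unique(as.integer(p_range)))
  M <- if (inherits(rec, "recording")) nrow(rec$data) else nrow(rec)
  N <- if (inherits(rec, "recording")) ncol(rec$data) else ncol(rec)
  feasible <- p_range[N - p_range > 10 * p_range * M]
  if (length(feasible) == 0)
    stop("no feasible model order in range for this data length")
  aics <- vapply(feasible, function(p)
    var_aic(fit_var(rec, p, scale = scale, fs = fs)), numeric(1))
  best <- feasible[which.min(aics)]       # first minimum = smallest p on ties
  structure(best, aic_curve = data.frame(p = feasible, aic = aics))
}

#' Validate a fitted MVAR model
#'
#' Three checks: (a) stability — companion-matrix spectral radius below 1;
#' (b) residual whiteness — Ljung-Box portmanteau test per channel, with the
#' fraction of channels passing at `alpha`; (c) consistency — the percentage
#' of the data's auto/cross-correlation structure (lags 0..`lags`)
#' reproduced by data simulated from the fitted model,
#' `100 (1 - ||R_data - R_model|| / ||R_data||)`.
#'
#' @param model a [fit_var()] result (carries its residuals).
#' @param rec the fitted data, needed for the consistency check; `NULL`
#'   skips it.
#' @param lags portmanteau/correlation lag depth.
#' @param alpha whiteness significance level.
#' @param seed seed for the consistency simulation.
#' @return Object of class `validation_report` with elements `stability`,
#'   `whiteness` (per-channel table + `pass_fraction`), `consistency`
#'   (percent, or `NA`). A failing report is a valid return.
#' @export
validate_model <- function(model, rec = NULL, lags = 20, alpha = 0.05,
                           seed = 1) {
  stopifnot(inherits(model, "var_model"))
  res <- model$residuals
  M <- ncol(res)
  fitdf <- min(model$order, lags - 1)
  wt <- lapply(seq_len(M), function(i) {
    bt <- Box.test(res[, i], lag = lags, type = "Ljung-Box", fitdf = fitdf)
    data.frame(channel = i, statistic = unname(bt$statistic),
               p_value = bt$p.value, pass = bt$p.value > alpha)
  })
  wt <- do.call(rbind, wt)
  consistency <- NA_real_
  if (!is.null(rec)) {
    x <- if (inherits(rec, "recording")) rec$data else as.matrix(rec)
    x <- x - rowMeans(x)
    if (isTRUE(model$scaled)) x <- x / apply(x, 1, stats::sd)
    truth <- var_ground_truth(model$coeffs,
                              (model$noise_cov + t(model$noise_cov)) / 2)
    sim <- simulate_var(truth, ncol(x), seed = seed,
                        fs = ifelse(is.na(model$fs), 1, model$fs))$data
    rd <- corr_structure(x, lags)
    rm_ <- corr_structure(sim, lags)
    consistency <- 100 * (1 - sqrt(sum((rd - rm_)^2)) / sqrt(sum(rd^2)))
  }
  structure(list(
    stability = list(spectral_radius = model$spectral_radius,
                     pass = model$stable),
    whiteness = list(per_channel = wt, pass_fraction = mean(wt$pass),
                     alpha = alpha, lags = lags),
    consistency = consistency), class = "validation_report")
}

# stacked auto/cross-covariance matrices, lags 0..L
corr_structure <- function(x, L) {
  N <- ncol(x)
  out <- lapply(0:L, function(k)
    tcrossprod(x[, 1:(N - k), drop = FALSE],
               x[, (1 + k):N, drop = FALSE]) / (N - k))
  do.call(rbind, out)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> stability: %s (rho = %.3f); whiteness pass: %.0f%%; consistency: %s\n",
              ifelse(x$stability$pass, "pass", "FAIL"),
              x$stability$spectral_radius,
              100 * x$whiteness$pass_fraction,
              ifelse(is.na(x$consistency), "n/a",
                     sprintf("%.1f%%", x$consistency))))
  invisible(x)
}

#' Frequency-domain transfer matrix of an MVAR model
#'
#' `H(f) = A(f)^{-1}` with `A(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`,
#' evaluated on the requested frequency grid. `H` maps innovations to
#' observed spectra and is the basis of the directed transfer function.
#'
#' @param model a [fit_var()] model (or [var_ground_truth()]).
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (defaults to the model's).
#' @return Object of class `transfer_matrix`: `freqs`, complex array `H`
#'   (M x M x F), `fs`.
#' @export
transfer_matrix <- function(model, freqs = seq(0.5, 45, by = 0.5),
                            fs = NULL) {
  coeffs <- model$coeffs
  if (is.null(fs)) fs <- if (!is.null(model$fs) && !is.na(model$fs)) model$fs
    else stop("fs required")
  M <- nrow(coeffs[[1]]); p <- length(coeffs)
  H <- array(0 + 0i, dim = c(M, M, length(freqs)))
  I <- diag(M)
  for (fi in seq_along(freqs)) {
    A <- I
    for (k in seq_len(p))
      A <- A - coeffs[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
    Hf <- tryCatch(solve(A), error = function(e)
      stop(sprintf("A(f) singular at f = %g Hz", freqs[fi]), call. = FALSE))
    H[, , fi] <- Hf
  }
  structure(list(freqs = freqs, H = H, fs = fs), class = "transfer_matrix")
}

#' Sliding-window MVAR fits
#'
#' Refits the model on overlapping windows — the sliding-window stand-in for
#' truly adaptive MVAR estimation. Downstream connectivity is averaged over
#' windows.
#'
#' @inheritParams fit_var
#' @param window_s window length (s).
#' @param step_s step between window starts (s).
#' @return List of `var_model`s, each with `window_meta = c(start, length)`
#'   in samples.
#' @export
windowed_fit <- function(rec, window_s, step_s, p, scale = FALSE,
                         fs = NULL) {
  if (inherits(rec, "recording")) { fs <- rec$fs; x <- rec$data }
  else { x <- as.matrix(rec); if (is.null(fs)) stop("fs required") }
  M <- nrow(x); N <- ncol(x)
  nwin <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  if (nwin - p <= 10 * p * M)
    stop(sprintf("window too short: need > %d samples for p = %d, M = %d",
                 10 * p * M + p, p, M))
  if (nwin > N) stop("window longer than the recording")
  starts <- seq(1L, N - nwin + 1L, by = step)
  lapply(starts, function(s) {
    m <- fit_var(x[, s:(s + nwin - 1L), drop = FALSE], p, scale = scale,
                 fs = fs)
    m$window_meta <- c(start = s, length = nwin)
    m
  })
}
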