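#' Shapiro-Wilk normality test
#'
#' Thin, precondition-checked wrapper around the standard Shapiro-Wilk test.
#'
#' @param x numeric sample, 3 <= n <= 5000, not constant.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop(sprintf("Shapiro-Wilk needs 3 <= n <= 5000 (have %d)", n))
  if (diff(range(x)) == 0) stop("sample is constant: normality undefined")
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with mid-ranks for ties. The exact null
#' distribution is used when the pooled sample has at most `exact_max`
#' observations and no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples, each with at least 3 observations.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   branch.
#' @param exact_max pooled-size limit for the automatic exact branch.
#' @return List with `statistic` (rank sum of `x`), `u` (Mann-Whitney U of
#'   `x`), `p_value`, and `exact` (logical, branch taken).
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs at least 3 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= exact_max) && !ties
  if (exact && ties) {
    warning("ties present: falling back to the corrected normal approximation")
    exact <- FALSE
  }
  if (diff(range(c(x, y))) == 0)           # fully tied pooled sample
    return(list(statistic = sum(rank(c(x, y))[seq_along(x)]),
                u = length(x) * length(y) / 2, p_value = 1, exact = FALSE))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  list(statistic = u + length(x) * (length(x) + 1) / 2, u = u,
       p_value = min(1, wt$p.value), exact = exact)
}

#' Group comparison of graph metrics
#'
#' The machine-readable group-comparison table: one two-sided Wilcoxon
#' rank-sum test per (measure, band, metric) cell, with the direction of the
#' median difference and per-group Shapiro-Wilk normality p-values reported
#' alongside. No multiple-testing correction is applied to the headline
#' significance marks (a Benjamini-Hochberg adjusted column is emitted in
#' addition).
#'
#' @param metrics tidy metrics table from [subject_metrics()] rows, with a
#'   `group` column containing exactly two levels.
#' @param metric_cols metric columns to test.
#' @param alpha significance level for the `significant` mark.
#' @return Data frame of class `comparison_table`: measure, band, metric,
#'   n per group, statistic, p_value, direction (group with the larger
#'   median), sw_p per group, significant, p_bh. Cells where a group has
#'   fewer than 3 subjects are `NA`.
#' @export
compare_groups <- function(metrics,
                           metric_cols = c("diameter", "global_efficiency",
                                           "transitivity"),
                           alpha = 0.05) {
  groups <- sort(unique(metrics$group))
  if (length(groups) != 2) stop("need exactly two groups")
  cells <- expand.grid(measure = unique(metrics$measure),
                       band = unique(metrics$band),
                       metric = metric_cols,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cl <- cells[r, ]
    sub <- metrics[metrics$measure == cl$measure & metrics$band == cl$band, ]
    x <- sub[sub$group == groups[1], cl$metric]
    y <- sub[sub$group == groups[2], cl$metric]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    sw <- function(v) tryCatch(shapiro_wilk(v)$p_value,
                               error = function(e) NA_real_)
    if (length(x) < 3 || length(y) < 3) {
      stat <- p <- NA_real_; dir <- NA_character_
    } else {
      w <- wilcoxon_rank_sum(x, y)
      stat <- w$statistic; p <- w$p_value
      dir <- if (median(x) == median(y)) "equal"
        else groups[which.max(c(median(x), median(y)))]
    }
    out <- data.frame(measure = cl$measure, band = cl$band,
                      metric = cl$metric, n_1 = length(x), n_2 = length(y),
                      statistic = stat, p_value = p, direction = dir,
                      sw_p_1 = sw(x), sw_p_2 = sw(y),
                      significant = !is.na(p) & p < alpha)
    out
  })
  tab <- do.call(rbind, rows)
  tab$p_bh <- p.adjust(tab$p_value, method = "BH")
  attr(tab, "groups") <- groups
  attr(tab, "alpha") <- alpha
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' Render a comparison table as banded Markdown
#'
#' One block per frequency band with a row per measure and a column per
#' metric, significant cells (uncorrected p below the table's alpha) in
#' bold.
#'
#' @param tab a [compare_groups()] result.
#' @return Character vector of Markdown lines, invisibly printed with
#'   `cat()` when interactive.
#' @export
format_comparison <- function(tab) {
  alpha <- attr(tab, "alpha") %||% 0.05
  bands <- unique(tab$band)
  metrics <- unique(tab$metric)
  lines <- c(sprintf("| Measure | %s |", paste(metrics, collapse = " | ")),
             paste0("|", paste(rep("---|", length(metrics) + 1),
                               collapse = "")))
  out <- character(0)
  for (b in bands) {
    out <- c(out, sprintf("**%s band**", b), lines)
    for (m in unique(tab$measure)) {
      cells <- vapply(metrics, function(mt) {
        p <- tab$p_value[tab$band == b & tab$measure == m & tab$metric == mt]
        if (length(p) == 0 || is.na(p)) "NA"
        else if (p < alpha) sprintf("**%.4g**", p) else sprintf("%.4g", p)
      }, character(1))
      out <- c(out, sprintf("| %s | %s |", m, paste(cells, collapse = " | ")))
    }
    out <- c(out, "")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral group contrast (alpha peak and gamma power)
#'
#' Per subject, Welch log-power is averaged over channels; the alpha-peak
#' power (maximum of the PSD in 8-13 Hz, in dB) and the mean gamma-band
#' (30-45 Hz) log-power are then compared between groups with the Wilcoxon
#' rank-sum test.
#'
#' @param cohort a `cohort` from [make_cohort()], or any list of elements
#'   with `recording` and `group`.
#' @param window_s Welch window length (s).
#' @return Data frame with one row per feature (`alpha_peak_db`,
#'   `gamma_mean_db`): group sizes, statistic, p_value, direction. `NA`
#'   when a group has fewer than 3 subjects.
#' @export
spectral_contrast <- function(cohort, window_s = 2) {
  grp <- vapply(cohort, `[[`, "", "group")
  groups <- sort(unique(grp))
  if (length(groups) != 2) stop("need exactly two groups")
  feats <- t(vapply(cohort, function(su) {
    ps <- welch_psd(su$recording, window_s = window_s)
    p <- colMeans(ps$psd)                  # mean over channels, per freq
    db <- 10 * log10(pmax(p, 1e-300))
    a <- ps$freqs >= 8 & ps$freqs <= 13
    g <- ps$freqs >= 30 & ps$freqs <= 45
    c(alpha_peak_db = max(db[a]), gamma_mean_db = mean(db[g]))
  }, numeric(2)))
  rows <- lapply(colnames(feats), function(fn) {
    x <- feats[grp == groups[1], fn]
    y <- feats[grp == groups[2], fn]
    if (length(x) < 3 || length(y) < 3)
      return(data.frame(feature = fn, n_1 = length(x), n_2 = length(y),
                        statistic = NA_real_, p_value = NA_real_,
                        direction = NA_character_))
    w <- wilcoxon_rank_sum(x, y)
    data.frame(feature = fn, n_1 = length(x), n_2 = length(y),
               statistic = w$statistic, p_value = w$p_value,
               direction = groups[which.max(c(median(x), median(y)))])
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}
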