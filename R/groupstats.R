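#' Two-tailed Student-t p value
#'
#' Computed through the regularized incomplete beta function:
#' `p = I_{df/(df+t^2)}(df/2, 1/2)`, which equals `2 * S(|t|; df)` with S
#' the t survival function. Vectorized over `t` and `df`.
#'
#' @param t t statistic(s), finite.
#' @param df degrees of freedom, >= 1.
#' @return two-tailed p in (0, 1].
#' @export
t_pvalue <- function(t, df) {
  if (any(!is.finite(t))) stop("t must be finite")
  if (any(df < 1)) stop("df must be >= 1")
  pbeta(df / (df + t^2), df / 2, 0.5)
}

#' Homoscedastic unpaired two-tailed t-test
#'
#' Pooled-variance Student t with `df = n_A + n_B - 2` and sample (n-1)
#' standard deviations for the group descriptives, matching the standard
#' two-sample homoscedastic test. Missing values are dropped pairwise with
#' the usable counts reported. A zero pooled variance with unequal means is
#' reported as the p -> 0 limit with a degeneracy flag.
#'
#' @param values_a,values_b numeric vectors (>= 2 usable values each).
#' @param roi,metric optional labels copied into the result row.
#' @param alpha significance level; the flag is inclusive (p <= alpha).
#' @return one-row data.frame of class `group_comparison`: roi, metric,
#'   n_A, n_B, mean_A, sd_A, mean_B, sd_B, t, df, p, significant, degenerate.
#' @export
unpaired_ttest <- function(values_a, values_b, roi = NA_character_,
                           metric = NA_character_, alpha = 0.05) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 usable values per group (got ",
         length(a), " and ", length(b), ")")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  degenerate <- FALSE
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(mean(a) - mean(b)) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- t_pvalue(tstat, df)
  }
  out <- data.frame(roi = roi, metric = metric, n_A = na, n_B = nb,
                    mean_A = mean(a), sd_A = sd(a),
                    mean_B = mean(b), sd_B = sd(b),
                    t = tstat, df = df, p = p,
                    significant = p <= alpha, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$p <- signif(y$p, digits)
  y$t <- signif(y$t, digits + 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-ROI two-group comparison over a cohort metric table
#'
#' Runs one homoscedastic unpaired two-tailed t-test per ROI for the chosen
#' metric, control vs mutant. No multiplicity correction is applied by
#' default (per-ROI raw p values are reported); optional Holm adjustment is
#' available and flagged in the output. Results are sorted by ROI name for
#' determinism.
#'
#' @param roi_table data.frame of per-subject ROI records (e.g. rbind-ed
#'   [roi_metrics_all()] rows) with columns `roi`, `group` and the metric.
#' @param metric column to compare, e.g. `"mean_supra_z"` or
#'   `"active_volume_mm3"`.
#' @param groups length-2 character: the two group labels, order defining
#'   the t sign (first minus second).
#' @param alpha significance level (inclusive flag).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return a `group_comparison` data.frame, one row per ROI, with attribute
#'   `p_adjust` recording the adjustment used.
#' @export
compare_cohort <- function(roi_table, metric = "mean_supra_z",
                           groups = c("control", "mutant"), alpha = 0.05,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!metric %in% names(roi_table)) stop("unknown metric: ", metric)
  if (!all(groups %in% roi_table$group))
    stop("both groups must be present in the table")
  rois <- sort(unique(roi_table$roi))
  rows <- lapply(rois, function(r) {
    sub <- roi_table[roi_table$roi == r, ]
    a <- sub[[metric]][sub$group == groups[1]]
    b <- sub[[metric]][sub$group == groups[2]]
    if (sum(is.finite(a)) < 2L || sum(is.finite(b)) < 2L) {
      # too few usable (non-missing) values: report an untestable row
      out <- data.frame(roi = r, metric = metric,
                        n_A = sum(is.finite(a)), n_B = sum(is.finite(b)),
                        mean_A = mean(a[is.finite(a)]),
                        sd_A = sd(a[is.finite(a)]),
                        mean_B = mean(b[is.finite(b)]),
                        sd_B = sd(b[is.finite(b)]),
                        t = NA_real_, df = NA_integer_, p = NA_real_,
                        significant = NA, degenerate = FALSE,
                        stringsAsFactors = FALSE)
      return(out)
    }
    unpaired_ttest(a, b, roi = r, metric = metric, alpha = alpha)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p, "holm")
    out$significant <- out$p_adjusted <= alpha
  }
  attr(out, "p_adjust") <- adjust
  class(out) <- c("group_comparison", "data.frame")
  out
}
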