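# Before/after and across-treatment statistics: modulation indices, paired
# Wilcoxon tests with Bonferroni correction, Kruskal-Wallis with a rank-based
# post-hoc against the saline control, and the gain-vs-kinetics correlation.

#' Modulation index
#'
#' `(a_after - a_before) / (a_after + a_before)` for a non-negative response
#' feature: bounded in `[-1, 1]`, antisymmetric under swapping the arguments
#' and invariant to a common positive rescaling.
#'
#' @param a_before,a_after Non-negative feature values (vectorized).
#' @return Modulation index; `NA` where both arguments are zero.
#' @export
modulation_index <- function(a_before, a_after) {
  stopifnot(length(a_before) == length(a_after))
  if (any(a_before < 0 | a_after < 0, na.rm = TRUE)) {
    stop("modulation_index requires non-negative features", call. = FALSE)
  }
  tot <- a_after + a_before
  ifelse(tot > 0, (a_after - a_before) / tot, NA_real_)
}

#' Paired before/after comparison (Wilcoxon signed-rank, Bonferroni)
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences, with the
#' p-value multiplied by `n_comparisons` (capped at 1) for multiple testing.
#'
#' @param before,after Equal-length numeric vectors (n >= 5).
#' @param n_comparisons Bonferroni factor, default 1.
#' @return List with `statistic` (V), `p` (corrected), `p_raw`, and
#'   `all_ties` (TRUE when every pair is identical; `p = 1` by convention).
#' @export
paired_compare <- function(before, after, n_comparisons = 1L) {
  stopifnot(length(before) == length(after), length(before) >= 5L)
  d <- after - before
  if (all(d == 0)) {
    return(list(statistic = 0, p = 1, p_raw = 1, all_ties = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(after, before, paired = TRUE))
  p <- min(1, wt$p.value * n_comparisons)
  list(statistic = unname(wt$statistic), p = p, p_raw = wt$p.value,
       all_ties = FALSE)
}

#' Across-treatment comparison vs the saline control
#'
#' Kruskal-Wallis omnibus test on modulation indices across treatment groups,
#' followed by a rank-based (Dunn) post-hoc of each treatment's average group
#' rank against the control group, with Holm (default) or Bonferroni
#' adjustment over treatments.
#'
#' @param mi_by_group Named list of numeric vectors, one per treatment; must
#'   include `control` as a name.
#' @param control Name of the control group, default `"saline"`.
#' @param adjust Multiplicity adjustment for the post-hoc p-values.
#' @return List with `omnibus_p`, `omnibus_stat`, and `posthoc` (data.frame:
#'   treatment, z, p_adj); `omnibus_p` is `NA` (flagged via `degenerate`) when
#'   all values are identical.
#' @export
treatment_vs_control <- function(mi_by_group, control = "saline",
                                 adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(mi_by_group), control %in% names(mi_by_group),
            length(mi_by_group) >= 2L)
  mi_by_group <- lapply(mi_by_group, function(x) x[!is.na(x)])
  if (any(vapply(mi_by_group, length, 0L) < 3L)) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  x <- unlist(mi_by_group, use.names = FALSE)
  g <- factor(rep(names(mi_by_group), vapply(mi_by_group, length, 0L)),
              levels = names(mi_by_group))
  if (length(unique(x)) == 1L) {
    return(list(omnibus_p = NA_real_, omnibus_stat = NA_real_,
                posthoc = NULL, degenerate = TRUE))
  }
  kw <- kruskal.test(x, g)

  # Dunn's test on average group ranks vs the control, with tie correction.
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  others <- setdiff(names(mi_by_group), control)
  z <- vapply(others, function(tr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n_g[[tr]] + 1 / n_g[[control]]))
    (rbar[[tr]] - rbar[[control]]) / se
  }, 0)
  p <- p.adjust(2 * pnorm(abs(z), lower.tail = FALSE), method = adjust)
  list(omnibus_p = kw$p.value, omnibus_stat = unname(kw$statistic),
       posthoc = data.frame(treatment = others, z = unname(z),
                            p_adj = unname(p), row.names = NULL),
       degenerate = FALSE)
}

#' Correlation between gain modulation and kinetics modulation
#'
#' Pearson correlation between the per-unit gain modulation index and a
#' kinetics (peak latency or peak frequency) modulation index, pooled across
#' cell types and conditions; incomplete pairs are dropped.
#'
#' @param gain_mi,kinetics_mi Numeric vectors, matched per unit.
#' @return List with `r`, `p`, `n`; `r` is `NA` when either variable has zero
#'   variance (flagged with a warning).
#' @export
gain_kinetics_correlation <- function(gain_mi, kinetics_mi) {
  stopifnot(length(gain_mi) == length(kinetics_mi))
  ok <- is.finite(gain_mi) & is.finite(kinetics_mi)
  x <- gain_mi[ok]
  y <- kinetics_mi[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
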