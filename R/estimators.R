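#' Anchor-based MID from group summaries
#'
#' The anchor-based minimally important difference of one scale: the
#' absolute difference between the small-level (satisfied/dissatisfied,
#' contiguous to neutral) group mean and the reference (neutral) group mean.
#'
#' @param summary A `group_summary` from [summarize_groups()] restricted to
#'   one scale, or the full table plus `scale`.
#' @param scale Scale name to extract when `summary` covers several scales.
#' @return The MID in standardised score points, full precision.
#' @export
anchor_mid <- function(summary, scale = NULL) {
  g <- pick_scale(summary, scale)
  ref <- g[g$level == "reference", ]
  sml <- g[g$level == "small", ]
  if (!nrow(ref) || ref$n < 1L || !nrow(sml) || sml$n < 1L)
    stop_midsat("MID not estimable for '", g$scale[1L],
                "': empty reference or small group",
                class = "midsat_not_estimable")
  abs(sml$mean - ref$mean)
}

#' Step differences vs the neutral reference
#'
#' Absolute per-level mean differences from the reference group for the
#' small, medium and large difference levels. Monotonicity across steps is
#' reported, not enforced: real satisfaction data can show a non-monotone
#' step (small large-level samples).
#'
#' @inheritParams anchor_mid
#' @return Named numeric vector `c(small=, medium=, large=)`; a step whose
#'   level is empty is `NA`.
#' @export
step_differences <- function(summary, scale = NULL) {
  g <- pick_scale(summary, scale)
  ref <- g[g$level == "reference", ]
  if (!nrow(ref) || ref$n < 1L)
    stop_midsat("reference group empty for '", g$scale[1L], "'",
                class = "midsat_not_estimable")
  out <- c(small = NA_real_, medium = NA_real_, large = NA_real_)
  for (lv in names(out)) {
    r <- g[g$level == lv, ]
    if (nrow(r) && r$n >= 1L) out[[lv]] <- abs(r$mean - ref$mean)
  }
  out
}

#' Kazis effect size
#'
#' A mean difference divided by the whole-sample standard deviation of the
#' scale. Labels follow the conventional bands: below 0.20 negligible,
#' 0.20 to below 0.50 small, 0.50 to below 0.80 moderate, 0.80 and above
#' large.
#'
#' @param mid Mean difference (score points), typically [anchor_mid()].
#' @param pooled_sd Whole-sample SD of the scale (n-1 denominator).
#' @return List with `effect_size` (full precision) and `es_label`.
#' @export
effect_size <- function(mid, pooled_sd) {
  if (!is.finite(pooled_sd) || pooled_sd <= 0)
    stop_midsat("effect size not estimable: pooled_sd must be positive",
                class = "midsat_not_estimable")
  es <- mid / pooled_sd
  lab <- if (es < 0.20) "negligible" else if (es < 0.50) "small"
         else if (es < 0.80) "moderate" else "large"
  list(effect_size = es, es_label = lab)
}

#' Standard error of measurement
#'
#' `SEM = sd * sqrt(1 - reliability)`: the score noise attributable to
#' measurement error, from the whole-sample SD and the scale's reliability
#' coefficient (e.g. Cronbach's alpha).
#'
#' @param whole_sample_sd Whole-sample SD of the scale (non-negative).
#' @param reliability Reliability coefficient, at most 1 (alpha can be
#'   negative for badly keyed scales).
#' @return SEM in score points.
#' @examples
#' sem(14.76, 0.84)  # 5.90
#' @export
sem <- function(whole_sample_sd, reliability) {
  if (is.na(reliability) || reliability > 1)
    stop_midsat("reliability must be <= 1 (got ", reliability, ")",
                class = "midsat_invalid_reliability")
  if (is.na(whole_sample_sd) || whole_sample_sd < 0)
    stop_midsat("whole_sample_sd must be non-negative",
                class = "midsat_invalid_input")
  whole_sample_sd * sqrt(1 - reliability)
}

#' One-half standard deviation benchmark
#'
#' @param whole_sample_sd Whole-sample SD of the scale (non-negative).
#' @return `whole_sample_sd / 2`.
#' @export
half_sd <- function(whole_sample_sd) {
  if (is.na(whole_sample_sd) || whole_sample_sd < 0)
    stop_midsat("whole_sample_sd must be non-negative",
                class = "midsat_invalid_input")
  whole_sample_sd / 2
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability from item variances and the variance of
#' the row sums: `(k/(k-1)) * (1 - sum(item variances) / var(row sums))`,
#' with n-1 variances and listwise deletion of incomplete rows.
#'
#' @param item_matrix Numeric matrix or data frame, respondents x items
#'   (already reverse-coded where applicable).
#' @return Alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L)
    stop_midsat("Cronbach's alpha needs at least 2 items",
                class = "midsat_invalid_input")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2L)
    stop_midsat("Cronbach's alpha needs at least 2 complete rows",
                class = "midsat_invalid_input")
  k <- ncol(x)
  vt <- stats::var(rowSums(x))
  if (vt <= 0)
    stop_midsat("total-score variance is zero; alpha undefined",
                class = "midsat_undefined_alpha")
  (k / (k - 1)) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

# extract one scale's rows from a group_summary (or pass through a
# single-scale table)
pick_scale <- function(summary, scale = NULL) {
  stopifnot(is.data.frame(summary))
  if (!is.null(scale)) summary <- summary[summary$scale == scale, ]
  if (!nrow(summary))
    stop_midsat("scale '", scale, "' not present in summary",
                class = "midsat_schema_mismatch")
  if (length(unique(summary$scale)) != 1L)
    stop_midsat("summary covers several scales; pass `scale`",
                class = "midsat_invalid_input")
  summary
}
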