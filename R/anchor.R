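#' Classify anchor responses into difference levels
#'
#' Maps each 7-point anchor response to its distance from the neutral
#' category, merging the satisfied and dissatisfied sides:
#' code 4 is `reference` (distance 0), codes 3 and 5 are `small`, 2 and 6
#' `medium`, 1 and 7 `large`. The small level is the pair of categories
#' contiguous to neutral; its mean score gap from the reference group is the
#' anchor-based MID.
#'
#' @param anchor_response Integer vector of raw anchor codes in 1..7 (`NA`
#'   allowed and propagated).
#' @param neutral Neutral category code (default 4).
#' @return An ordered factor with levels
#'   `reference < small < medium < large`.
#' @examples
#' classify_anchor(c(4, 3, 5, 1, 7))
#' @export
classify_anchor <- function(anchor_response, neutral = 4L) {
  x <- anchor_response
  bad <- !is.na(x) & (x < 1 | x > 7 | x != round(x))
  if (any(bad))
    stop_midsat("anchor response out of 1..7: ", x[bad][1L],
                class = "midsat_invalid_anchor")
  dist <- abs(x - neutral)
  factor(c("reference", "small", "medium", "large")[dist + 1L],
         levels = c("reference", "small", "medium", "large"), ordered = TRUE)
}

#' Per-level score summaries
#'
#' Computes n, mean and SD (n-1 denominator) of each scale within each
#' anchor difference level -- the group-summary table that drives the
#' anchor-based MID. Respondents with a missing level or a missing score for
#' a scale are excluded from that scale's summary. Empty levels are emitted
#' with `n = 0` and flagged, never dropped.
#'
#' @param scores A `score_matrix` from [score_responses()], or any data frame
#'   whose non-`respondent_id` columns are scores.
#' @param levels Per-respondent difference levels, aligned with the rows of
#'   `scores` (factor from [classify_anchor()] or raw anchor codes 1..7,
#'   which are classified first).
#' @return A long-format data frame of class `group_summary`: `scale`,
#'   `level`, `n`, `mean`, `sd`, `flag` (`""`, `"empty"` when `n = 0`, or
#'   `"sd_undefined"` when `n < 2`). Means and SDs are full precision.
#' @export
summarize_groups <- function(scores, levels) {
  if (!is.factor(levels)) levels <- classify_anchor(levels)
  if (length(levels) != nrow(scores))
    stop_midsat("levels must align with score rows (", length(levels),
                " vs ", nrow(scores), ")", class = "midsat_schema_mismatch")
  lvls <- c("reference", "small", "medium", "large")
  scales <- score_scales(scores)
  rows <- vector("list", length(scales) * length(lvls))
  i <- 0L
  for (sc in scales) {
    v <- scores[[sc]]
    for (lv in lvls) {
      x <- v[!is.na(levels) & levels == lv & !is.na(v)]
      n <- length(x)
      i <- i + 1L
      rows[[i]] <- data.frame(
        scale = sc, level = lv, n = n,
        mean = if (n) mean(x) else NA_real_,
        sd = if (n >= 2L) stats::sd(x) else NA_real_,
        flag = if (n == 0L) "empty" else if (n == 1L) "sd_undefined" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = lvls, ordered = TRUE)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Write group summaries to CSV
#'
#' Long-format layout (scale, level, n, mean, sd) mirroring a
#' scores-by-difference-magnitude table; means and SDs rounded half-up to
#' one decimal for presentation.
#'
#' @param groups A `group_summary` from [summarize_groups()].
#' @param path Output CSV path.
#' @param digits Decimals for mean/sd (default 1); `NULL` writes full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(groups, path, digits = 1) {
  out <- as.data.frame(groups)
  if (!is.null(digits)) {
    out$mean <- round_half_up(out$mean, digits)
    out$sd <- round_half_up(out$sd, digits)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
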