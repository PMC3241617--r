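#' Percentile bootstrap for the anchor-based MID
#'
#' Resamples the whole sample with replacement (group sizes vary from
#' replicate to replicate), recomputes the signed per-level mean difference
#' from the reference (neutral) group in every replicate, and summarises the
#' replicate distribution: its mean, its SD (reported as the bootstrap SE)
#' and the 2.5/97.5 percentiles as the 95% confidence limits. Replicates in
#' which the reference group or the level of interest comes up empty are
#' dropped and counted.
#'
#' Differences are signed (level mean minus reference mean), so a level
#' whose scores straddle the reference can produce an interval crossing
#' zero even when the absolute point estimate is positive.
#'
#' @param scores A `score_matrix` (or data frame of score columns).
#' @param levels Difference levels aligned with rows (factor from
#'   [classify_anchor()] or raw 1..7 anchor codes).
#' @param scales Score columns to bootstrap (default: all).
#' @param levels_of_interest Levels contrasted with the reference (default
#'   small, medium, large).
#' @param B Number of bootstrap replicates; at least 100 (default 1000).
#' @param seed Integer seed; the whole replicate stream is reproducible from
#'   it.
#' @param stratified If `TRUE`, resample within each difference level so
#'   group sizes stay fixed (sensitivity mode); default `FALSE`, whole-sample
#'   resampling.
#' @param conf_level Confidence level for the percentile interval (default
#'   0.95).
#' @return Data frame of class `bootstrap_mid`: `scale`, `level`, `B`,
#'   `mean_mid`, `se`, `ci_low`, `ci_high`, `n_dropped`, `seed`, `flag`
#'   (`"high_dropout"` when more than 10% of replicates were dropped).
#' @export
bootstrap_mid <- function(scores, levels, scales = NULL,
                          levels_of_interest = c("small", "medium", "large"),
                          B = 1000L, seed = 1L, stratified = FALSE,
                          conf_level = 0.95) {
  if (B < 100L)
    stop_midsat("B = ", B, " is too few replicates for a percentile CI ",
                "(minimum 100)", class = "midsat_invalid_input")
  if (!is.factor(levels)) levels <- classify_anchor(levels)
  scales <- scales %||% score_scales(scores)
  ok <- !is.na(levels)
  lev <- droplevels(factor(levels[ok], ordered = FALSE))
  if (!"reference" %in% levels(lev) || sum(lev == "reference") < 1L)
    stop_midsat("reference group empty; bootstrap not estimable",
                class = "midsat_not_estimable")
  sc_mat <- as.matrix(as.data.frame(scores)[ok, scales, drop = FALSE])
  n <- nrow(sc_mat)
  lev_int <- as.integer(lev)
  ref_code <- match("reference", levels(lev))
  want <- match(levels_of_interest, levels(lev))
  names(want) <- levels_of_interest

  set.seed(seed)
  strata <- if (stratified) split(seq_len(n), lev_int) else NULL
  # draws[[b]] = resample indices for replicate b; generated in one stream
  draws <- lapply(seq_len(B), function(b) {
    if (stratified) {
      unlist(lapply(strata, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
  })

  out <- vector("list", length(scales) * length(want))
  k <- 0L
  alpha <- (1 - conf_level) / 2
  for (j in seq_along(scales)) {
    x <- sc_mat[, j]
    reps <- matrix(NA_real_, B, length(want))
    for (b in seq_len(B)) {
      ix <- draws[[b]]
      gb <- lev_int[ix]
      xb <- x[ix]
      fin <- !is.na(xb)
      ref_vals <- xb[fin & gb == ref_code]
      if (!length(ref_vals)) next
      mref <- mean(ref_vals)
      for (q in seq_along(want)) {
        vals <- xb[fin & gb == want[q]]
        if (length(vals)) reps[b, q] <- mean(vals) - mref
      }
    }
    for (q in seq_along(want)) {
      r <- reps[, q]
      dropped <- sum(is.na(r))
      r <- r[!is.na(r)]
      qs <- stats::quantile(r, c(alpha, 1 - alpha), names = FALSE, type = 7)
      k <- k + 1L
      out[[k]] <- data.frame(
        scale = scales[j], level = names(want)[q], B = B,
        mean_mid = mean(r), se = stats::sd(r),
        ci_low = qs[1L], ci_high = qs[2L],
        n_dropped = dropped, seed = seed,
        flag = if (dropped > 0.1 * B) "high_dropout" else "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("bootstrap_mid", "data.frame")
  res
}
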