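#' One-way ANOVA from summary statistics
#'
#' Reconstructs the one-way ANOVA from per-group n, mean and SD, without raw
#' data. `classic` rebuilds the between/within sums of squares (identical to
#' a raw-data ANOVA on any dataset with these exact moments); `welch` is the
#' variance-weighted statistic with Welch-Satterthwaite denominator degrees
#' of freedom (identical to [stats::oneway.test()] with `var.equal = FALSE`).
#'
#' @param n,means,sds Numeric vectors of group sizes, means and SDs (n-1
#'   denominator), one entry per group. Groups need `n >= 2`.
#' @param method `"classic"` or `"welch"`.
#' @return List with `method`, `F`, `df1`, `df2` (fractional for Welch) and
#'   `p`.
#' @export
anova_from_summary <- function(n, means, sds, method = c("classic", "welch")) {
  method <- match.arg(method)
  keep <- !is.na(n) & n > 0L
  n <- n[keep]; means <- means[keep]; sds <- sds[keep]
  k <- length(n)
  if (k < 2L)
    stop_midsat("ANOVA needs at least 2 non-empty groups",
                class = "midsat_not_estimable")
  if (any(n >= 2L & is.na(sds)))
    stop_midsat("missing SD for a group with n >= 2",
                class = "midsat_invalid_input")
  if (any(n < 2L))
    stop_midsat("every group needs n >= 2 for ANOVA",
                class = "midsat_not_estimable")
  N <- sum(n)
  if (method == "classic") {
    gm <- sum(n * means) / N
    ssb <- sum(n * (means - gm)^2)
    ssw <- sum((n - 1) * sds^2)
    df1 <- k - 1
    df2 <- N - k
    f <- (ssb / df1) / (ssw / df2)
  } else {
    w <- n / sds^2
    sw <- sum(w)
    mw <- sum(w * means) / sw
    df1 <- k - 1
    tmp <- sum((1 - w / sw)^2 / (n - 1)) / (k^2 - 1)
    f <- (sum(w * (means - mw)^2) / df1) / (1 + 2 * (k - 2) * tmp)
    df2 <- 1 / (3 * tmp)
  }
  list(method = method, F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group centre (mean for the
#' classic test, median for the Brown-Forsythe variant). Needs raw scores;
#' summary moments do not determine it.
#'
#' @param scores Numeric vector of raw scores.
#' @param levels Group factor aligned with `scores`.
#' @param center `"mean"` (default, classic Levene) or `"median"`.
#' @return List with `W`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(scores, levels, center = c("mean", "median")) {
  center <- match.arg(center)
  ok <- !is.na(scores) & !is.na(levels)
  scores <- scores[ok]
  g <- factor(levels[ok])
  g <- droplevels(g)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop_midsat("Levene's test needs >= 2 groups with >= 2 observations each",
                class = "midsat_not_estimable")
  cen <- if (center == "mean") tapply(scores, g, mean) else
    tapply(scores, g, stats::median)
  z <- abs(scores - cen[as.integer(g)])
  fit <- stats::anova(stats::lm(z ~ g))
  list(W = fit$`F value`[1L], df1 = fit$Df[1L], df2 = fit$Df[2L],
       p = fit$`Pr(>F)`[1L])
}

#' Pairwise comparisons against the reference level, Bonferroni-adjusted
#'
#' Two-sided t-tests of each non-reference level against the reference
#' group, with `p_adjusted = min(1, p * m)` where `m` is the number of
#' comparisons actually performed.
#'
#' @param scores Numeric vector of raw scores.
#' @param levels Group factor; its first level (or `"reference"` when
#'   present) is the reference.
#' @param var_equal Pooled-variance t-tests if `TRUE`; Welch (default
#'   `FALSE`).
#' @return Data frame with `level`, `d` (mean difference vs reference),
#'   `se`, `p_raw`, `p_adjusted` and `flag` (`"empty"` when a level has no
#'   usable data).
#' @export
pairwise_bonferroni <- function(scores, levels, var_equal = FALSE) {
  ok <- !is.na(scores) & !is.na(levels)
  scores <- scores[ok]
  g <- factor(levels[ok])
  ref <- if ("reference" %in% levels(g)) "reference" else levels(g)[1L]
  others <- setdiff(levels(g), ref)
  if (!length(others))
    stop_midsat("need at least 2 groups", class = "midsat_not_estimable")
  x_ref <- scores[g == ref]
  rows <- lapply(others, function(lv) {
    x <- scores[g == lv]
    if (length(x) < 2L || length(x_ref) < 2L)
      return(data.frame(level = lv, d = NA_real_, se = NA_real_,
                        p_raw = NA_real_, p_adjusted = NA_real_,
                        flag = "empty", stringsAsFactors = FALSE))
    tt <- stats::t.test(x, x_ref, var.equal = var_equal)
    data.frame(level = lv, d = mean(x) - mean(x_ref),
               se = unname(tt$stderr), p_raw = tt$p.value,
               p_adjusted = NA_real_, flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(out$flag == "")
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out
}

#' Descriptive statistics per scale
#'
#' Mean, SD, median, range, moment skewness, and a Kolmogorov-Smirnov
#' comparison with a normal distribution parameterised by the sample's own
#' moments. Scales with fewer than 3 non-missing values are flagged.
#'
#' @param scores A `score_matrix` (or data frame of score columns).
#' @return Data frame with one row per scale: `scale`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, `skewness`, `ks_D`, `ks_p`, `flag`.
#' @export
exploratory_summary <- function(scores) {
  scales <- score_scales(scores)
  rows <- lapply(scales, function(sc) {
    x <- scores[[sc]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3L)
      return(data.frame(scale = sc, n = n, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, min = NA_real_, max = NA_real_,
                        skewness = NA_real_, ks_D = NA_real_, ks_p = NA_real_,
                        flag = "too_few", stringsAsFactors = FALSE))
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(scale = sc, n = n, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), min = min(x), max = max(x),
               skewness = sample_skewness(x),
               ks_D = unname(ks$statistic), ks_p = ks$p.value, flag = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clinician-rated effectiveness contrast
#'
#' External-validity check: signed mean differences of the
#' treatment-effectiveness score between each clinician rating group and the
#' `acceptable` reference group, with Welch standard errors and Bonferroni
#' adjustment over the three non-reference categories.
#'
#' @param effectiveness_scores Numeric vector of treatment-effectiveness
#'   scores.
#' @param clinician_ratings Character/factor vector with levels among
#'   `poor`, `acceptable`, `good`, `excellent`.
#' @return Data frame with `group`, `n`, `d`, `se`, `p_raw`, `p_adjusted`.
#'   Empty when no non-reference group has data.
#' @export
clinician_contrast <- function(effectiveness_scores, clinician_ratings) {
  ok <- !is.na(effectiveness_scores) & !is.na(clinician_ratings) &
    clinician_ratings != ""
  x <- effectiveness_scores[ok]
  g <- as.character(clinician_ratings)[ok]
  valid <- c("poor", "acceptable", "good", "excellent")
  if (!all(g %in% valid))
    stop_midsat("unknown clinician rating: ",
                setdiff(unique(g), valid)[1L], class = "midsat_invalid_input")
  x_ref <- x[g == "acceptable"]
  if (length(x_ref) < 2L)
    stop_midsat("clinician contrast needs an acceptable reference group",
                class = "midsat_not_estimable")
  others <- intersect(c("poor", "good", "excellent"), unique(g))
  m <- 3L  # fixed: the three non-reference categories of the rating scale
  rows <- lapply(others, function(lv) {
    xi <- x[g == lv]
    if (length(xi) < 2L) return(NULL)
    tt <- stats::t.test(xi, x_ref)
    data.frame(group = lv, n = length(xi), d = mean(xi) - mean(x_ref),
               se = unname(tt$stderr),
               p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(group = character(), n = integer(), d = numeric(),
                      se = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
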