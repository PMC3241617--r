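#' Triangulated MID estimation
#'
#' The package's central fit: for every scale (each domain and the total
#' composite) it triangulates the anchor-based MID with the three
#' distribution-based benchmarks, and attaches the group-difference
#' inference that justifies the anchor classification.
#'
#' Per scale it computes:
#' \itemize{
#'   \item anchor-based MID: |mean(small) - mean(reference)|, plus the
#'     medium and large step differences vs the neutral reference;
#'   \item Kazis effect size: MID divided by the whole-sample SD of the
#'     scale (n-1), with the conventional negligible/small/moderate/large
#'     label;
#'   \item one-half SD of the whole sample;
#'   \item SEM: whole-sample SD times `sqrt(1 - reliability)`, where the
#'     reliability is supplied per scale and/or computed as Cronbach's
#'     alpha from item-level data;
#'   \item classic and Welch one-way ANOVA across the four difference
#'     levels and Levene's test for homogeneity of variance.
#' }
#' Scales whose anchor groups make an estimate impossible are flagged, not
#' fatal.
#'
#' @param scores A `score_matrix` from [score_responses()], or a data frame
#'   whose non-`respondent_id` columns are 0-100 scores.
#' @param anchor Per-respondent anchor responses: raw 7-point codes (1..7,
#'   classified via [classify_anchor()]) or an already-classified factor.
#' @param neutral Neutral anchor code (default 4), used when `anchor` is
#'   numeric.
#' @param reliability Optional named vector of reliability coefficients per
#'   scale (names among the score columns); overrides any item-based alpha.
#'   SEM is reported only for scales with a known reliability.
#' @param item_data,spec Optional raw item responses and their
#'   [instrument_spec()]; when given, Cronbach's alpha is computed per
#'   domain (and over all items for `total`) on reverse-coded responses with
#'   listwise deletion.
#' @param levene_center Centre for Levene's test, `"mean"` or `"median"`.
#' @return An object of class `mid_estimate` with components `estimates`
#'   (one row per scale), `groups` (the [summarize_groups()] table), `anova`
#'   (classic and Welch F per scale plus Levene), `n`, `neutral`, `call`.
#'   Methods: [print()], [summary()], [coef()] (anchor MIDs), [confint()]
#'   (percentile bootstrap), [plot()] (step-difference profile).
#' @examples
#' study <- reconstruct_satmedq_study(seed = 1)
#' fit <- mid_estimate(study$scores, study$levels)
#' coef(fit)["total"]  # anchor-based MID of the composite score
#' @export
mid_estimate <- function(scores, anchor, neutral = 4L, reliability = NULL,
                         item_data = NULL, spec = NULL,
                         levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  levels <- if (is.factor(anchor)) anchor else classify_anchor(anchor, neutral)
  if (length(levels) != nrow(scores))
    stop_midsat("anchor vector must align with score rows",
                class = "midsat_schema_mismatch")
  scales <- score_scales(scores)
  groups <- summarize_groups(scores, levels)

  alpha_map <- c()
  if (!is.null(item_data)) {
    if (is.null(spec))
      stop_midsat("item_data needs its instrument spec",
                  class = "midsat_invalid_input")
    alpha_map <- item_alphas(item_data, spec)
  }

  est_rows <- vector("list", length(scales))
  an_rows <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    sc <- scales[i]
    g <- groups[groups$scale == sc, ]
    x <- scores[[sc]]
    xs <- x[!is.na(x)]
    pooled_sd <- sample_sd(xs)

    rel <- NA_real_
    rel_src <- "none"
    if (sc %in% names(alpha_map)) {
      rel <- alpha_map[[sc]]
      rel_src <- "cronbach_alpha"
    }
    if (!is.null(reliability) && sc %in% names(reliability)) {
      rel <- unname(reliability[[sc]])
      rel_src <- "supplied"
    }

    row <- data.frame(
      scale = sc, n = length(xs),
      mid_anchor = NA_real_, diff_small = NA_real_, diff_medium = NA_real_,
      diff_large = NA_real_, pooled_sd = pooled_sd, half_sd = NA_real_,
      effect_size = NA_real_, es_label = NA_character_,
      reliability = rel, reliability_source = rel_src, sem = NA_real_,
      flag = "", stringsAsFactors = FALSE)
    tryCatch({
      row$mid_anchor <- anchor_mid(g)
      steps <- step_differences(g)
      row$diff_small <- steps[["small"]]
      row$diff_medium <- steps[["medium"]]
      row$diff_large <- steps[["large"]]
    }, midsat_error = function(e) row$flag <<- conditionMessage(e))
    if (is.finite(pooled_sd) && pooled_sd > 0) {
      row$half_sd <- half_sd(pooled_sd)
      if (!is.na(row$mid_anchor)) {
        es <- effect_size(row$mid_anchor, pooled_sd)
        row$effect_size <- es$effect_size
        row$es_label <- es$es_label
      }
      if (!is.na(rel)) row$sem <- sem(pooled_sd, rel)
    } else if (identical(row$flag, "")) {
      row$flag <- "zero_variance"
    }
    est_rows[[i]] <- row

    an <- data.frame(scale = sc, method = c("classic", "welch"),
                     F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p = NA_real_, levene_W = NA_real_, levene_p = NA_real_,
                     stringsAsFactors = FALSE)
    gg <- g[g$n >= 2L, ]
    tryCatch({
      for (m in c("classic", "welch")) {
        a <- anova_from_summary(gg$n, gg$mean, gg$sd, method = m)
        an[an$method == m, c("F", "df1", "df2", "p")] <-
          a[c("F", "df1", "df2", "p")]
      }
      lv <- levene_test(x, levels, center = levene_center)
      an$levene_W <- lv$W
      an$levene_p <- lv$p
    }, midsat_error = function(e) NULL)
    an_rows[[i]] <- an
  }

  structure(
    list(estimates = do.call(rbind, est_rows),
         groups = groups,
         anova = do.call(rbind, an_rows),
         scores = scores, levels = levels,
         n = nrow(scores), neutral = neutral,
         call = match.call()),
    class = "mid_estimate")
}

# Cronbach's alpha per domain (+ total) from raw item responses
item_alphas <- function(item_data, spec) {
  resp <- as.matrix(item_data[, spec$items, drop = FALSE])
  storage.mode(resp) <- "double"
  rev_idx <- match(spec$reverse_items, spec$items)
  if (length(rev_idx))
    resp[, rev_idx] <- spec$response_min + spec$response_max -
      resp[, rev_idx]
  out <- c()
  for (d in names(spec$domains)) {
    cols <- match(spec$domains[[d]], spec$items)
    out[d] <- tryCatch(cronbach_alpha(resp[, cols, drop = FALSE]),
                       midsat_error = function(e) NA_real_)
  }
  out["total"] <- tryCatch(cronbach_alpha(resp),
                           midsat_error = function(e) NA_real_)
  out[!is.na(out)]
}

#' @export
print.mid_estimate <- function(x, digits = 1, ...) {
  cat("Triangulated MID estimates (n =", x$n, "respondents)\n\n")
  e <- x$estimates
  tab <- data.frame(
    scale = e$scale,
    MID = round_half_up(e$mid_anchor, digits),
    SEM = round_half_up(e$sem, digits),
    `half SD` = round_half_up(e$half_sd, digits),
    ES = round_half_up(e$effect_size, 2),
    label = e$es_label, check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mid_estimate <- function(object, ...) {
  stats::setNames(object$estimates$mid_anchor, object$estimates$scale)
}

#' @export
summary.mid_estimate <- function(object, ...) {
  structure(
    list(fit = object,
         descriptives = exploratory_summary(object$scores)),
    class = "summary.mid_estimate")
}

#' @export
print.summary.mid_estimate <- function(x, ...) {
  print(x$fit)
  cat("\nGroup summaries (mean (SD), n):\n")
  g <- x$fit$groups
  wide <- stats::reshape(
    data.frame(scale = g$scale, level = as.character(g$level),
               cell = sprintf("%s (%s), %d", round_half_up(g$mean, 1),
                              round_half_up(g$sd, 1), g$n)),
    idvar = "scale", timevar = "level", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  cat("\nANOVA across difference levels:\n")
  a <- x$fit$anova
  a$F <- round_half_up(a$F, 1)
  a$df2 <- round_half_up(a$df2, 1)
  a$p <- signif(a$p, 3)
  a$levene_W <- round_half_up(a$levene_W, 2)
  a$levene_p <- signif(a$levene_p, 3)
  print(a, row.names = FALSE)
  cat("\nDescriptives:\n")
  d <- x$descriptives
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round_half_up, digits = 2)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Percentile bootstrap intervals for a fitted MID estimate
#'
#' @param object A [mid_estimate()] fit.
#' @param parm Scales to bootstrap (default: all).
#' @param level Confidence level (default 0.95).
#' @param B Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param ... Passed to [bootstrap_mid()].
#' @return The [bootstrap_mid()] data frame.
#' @export
confint.mid_estimate <- function(object, parm = NULL, level = 0.95,
                                 B = 1000L, seed = 1L, ...) {
  bootstrap_mid(object$scores, object$levels,
                scales = parm %||% object$estimates$scale,
                B = B, seed = seed, conf_level = level, ...)
}

#' Step-difference profile plot
#'
#' Mean score difference from the neutral reference group at each
#' difference level (small, medium, large), one line per scale: the visual
#' check that perceived-difference steps scale with anchor distance.
#'
#' @param x A [mid_estimate()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mid_estimate <- function(x, ...) {
  e <- x$estimates
  mat <- t(as.matrix(e[, c("diff_small", "diff_medium", "diff_large")]))
  cols <- grDevices::hcl.colors(ncol(mat), "Dark 3")
  graphics::matplot(1:3, mat, type = "b", pch = 16, lty = 1, col = cols,
                    xaxt = "n", xlab = "difference level",
                    ylab = "mean difference vs neutral reference", ...)
  graphics::axis(1, at = 1:3, labels = c("small", "medium", "large"))
  graphics::legend("topleft", legend = e$scale, col = cols, lty = 1,
                   pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
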