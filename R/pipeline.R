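#' Run the full MID analysis pipeline
#'
#' One call from respondent-level data to the complete report bundle:
#' score, classify the anchor, triangulate the MID estimators, run the
#' group-difference inference, bootstrap the confidence intervals, and
#' write every table to disk. All randomness flows through `seed`, and the
#' written artefacts are byte-identical across reruns with the same inputs
#' and seed.
#'
#' Files written to `out_dir`:
#' \describe{
#'   \item{`group_summary.csv`}{per-scale difference-level n/mean/SD plus
#'     classic and Welch F -- the scores-by-difference-magnitude table;}
#'   \item{`mid_report.csv`}{per-scale neutral and small-group mean (SD),
#'     anchor MID, SEM, half-SD, effect size and label -- the triangulated
#'     MID table;}
#'   \item{`bootstrap_report.csv`}{per scale and level the bootstrap mean
#'     difference, SE and 2.5/97.5 percentiles;}
#'   \item{`descriptives.csv`}{whole-sample descriptives per scale;}
#'   \item{`clinician_contrast.csv`}{effectiveness contrasts vs the
#'     acceptable clinician rating (when ratings are present);}
#'   \item{`estimates.json`}{every estimate at full precision, plus run
#'     metadata (seed, config hash, package version);}
#'   \item{`run_log.txt`}{row counts, exclusions, dropped replicates.}
#' }
#'
#' @param responses Respondent data frame, or path to a CSV/TSV read via
#'   [read_responses()].
#' @param spec An [instrument_spec()] (default [satmedq_spec()]).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the bundle.
#' @param missing_policy Passed to [score_responses()].
#' @param anchor_col Anchor column name (default `"anchor"`).
#' @param neutral Neutral anchor code (default 4).
#' @param reliability Optional named reliability overrides per scale; scales
#'   without an override use Cronbach's alpha computed from the item data.
#' @param B,seed Bootstrap replicates (default 1000) and seed (default 1).
#' @param rounding Decimals for score-scale quantities in the CSV reports
#'   (default 1; effect sizes always 2).
#' @return Invisibly, a list with `fit` (the [mid_estimate()]),
#'   `bootstrap`, `descriptives`, `clinician`, `log` (character lines) and
#'   `paths` of the written files.
#' @export
run_mid_pipeline <- function(responses, spec = satmedq_spec(), out_dir = NULL,
                             missing_policy = c("complete_only",
                                                "prorate_half"),
                             anchor_col = "anchor", neutral = 4L,
                             reliability = NULL, B = 1000L, seed = 1L,
                             rounding = 1) {
  missing_policy <- match.arg(missing_policy)
  if (is.character(responses) && length(responses) == 1L)
    responses <- read_responses(responses, spec, anchor_col = anchor_col)
  validate_responses(responses, spec, anchor_col = anchor_col)
  if (!anchor_col %in% names(responses))
    stop_midsat("anchor column '", anchor_col, "' not found",
                class = "midsat_schema_mismatch")

  log <- c(sprintf("respondents read: %d", nrow(responses)))
  scores <- score_responses(responses, spec, missing_policy)
  prov <- attr(scores, "provenance")
  for (sc in colnames(prov))
    log <- c(log, sprintf("scale %s: %d complete, %d prorated, %d missing",
                          sc, sum(prov[, sc] == "complete"),
                          sum(prov[, sc] == "prorated"),
                          sum(prov[, sc] == "missing")))
  anchor <- responses[[anchor_col]]
  log <- c(log, sprintf("missing anchor: %d", sum(is.na(anchor))))

  fit <- mid_estimate(scores, anchor, neutral = neutral,
                      reliability = reliability,
                      item_data = responses, spec = spec)
  boot <- bootstrap_mid(scores, fit$levels, B = B, seed = seed)
  log <- c(log, sprintf("bootstrap: B = %d, dropped replicates max = %d",
                        B, max(boot$n_dropped)))
  desc <- exploratory_summary(scores)
  clin <- NULL
  if ("clinician_rating" %in% names(responses)) {
    clin <- tryCatch(
      clinician_contrast(scores$treatment_effectiveness,
                         responses$clinician_rating),
      midsat_error = function(e) {
        log <<- c(log, paste("clinician contrast skipped:",
                             conditionMessage(e)))
        NULL
      })
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_report_bundle(fit, boot, desc, clin, log, out_dir,
                                 seed = seed, rounding = rounding)
  }
  invisible(list(fit = fit, bootstrap = boot, descriptives = desc,
                 clinician = clin, log = log, paths = paths))
}

#' Write the MID report tables
#'
#' @param fit A [mid_estimate()] object.
#' @param boot A [bootstrap_mid()] result.
#' @param desc An [exploratory_summary()] result.
#' @param clin A [clinician_contrast()] result or `NULL`.
#' @param log Character vector of log lines.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the metadata.
#' @param rounding Decimals for score-scale quantities.
#' @return Named character vector of written paths, invisibly.
#' @keywords internal
write_report_bundle <- function(fit, boot, desc, clin, log, out_dir,
                                seed = 1L, rounding = 1) {
  r1 <- function(x) round_half_up(x, rounding)
  paths <- c()

  g <- as.data.frame(fit$groups)
  a <- fit$anova
  g$mean <- r1(g$mean); g$sd <- r1(g$sd)
  for (m in c("classic", "welch")) {
    ai <- a[a$method == m, c("scale", "F", "p")]
    names(ai) <- c("scale", paste0("F_", m), paste0("p_", m))
    ai[[2L]] <- r1(ai[[2L]])
    ai[[3L]] <- signif(ai[[3L]], 3)
    g <- merge(g, ai, by = "scale", sort = FALSE)
  }
  p <- file.path(out_dir, "group_summary.csv")
  utils::write.csv(g, p, row.names = FALSE)
  paths["group_summary"] <- p

  e <- fit$estimates
  gref <- fit$groups[fit$groups$level == "reference", ]
  gsml <- fit$groups[fit$groups$level == "small", ]
  mid_tab <- data.frame(
    scale = e$scale,
    neutral_mean_sd = sprintf("%s (%s)",
                              r1(gref$mean[match(e$scale, gref$scale)]),
                              r1(gref$sd[match(e$scale, gref$scale)])),
    small_mean_sd = sprintf("%s (%s)",
                            r1(gsml$mean[match(e$scale, gsml$scale)]),
                            r1(gsml$sd[match(e$scale, gsml$scale)])),
    mid_anchor = r1(e$mid_anchor), sem = r1(e$sem),
    half_sd = r1(e$half_sd), effect_size = round_half_up(e$effect_size, 2),
    es_label = e$es_label, reliability_source = e$reliability_source,
    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "mid_report.csv")
  utils::write.csv(mid_tab, p, row.names = FALSE)
  paths["mid_report"] <- p

  b <- as.data.frame(boot)
  b$mean_mid <- round_half_up(b$mean_mid, 2)
  b$se <- round_half_up(b$se, 2)
  b$ci_low <- round_half_up(b$ci_low, 2)
  b$ci_high <- round_half_up(b$ci_high, 2)
  p <- file.path(out_dir, "bootstrap_report.csv")
  utils::write.csv(b, p, row.names = FALSE)
  paths["bootstrap_report"] <- p

  d <- desc
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round_half_up, digits = 2)
  p <- file.path(out_dir, "descriptives.csv")
  utils::write.csv(d, p, row.names = FALSE)
  paths["descriptives"] <- p

  if (!is.null(clin) && nrow(clin)) {
    cc <- clin
    cc$d <- round_half_up(cc$d, 2); cc$se <- round_half_up(cc$se, 2)
    cc$p_raw <- signif(cc$p_raw, 3); cc$p_adjusted <- signif(cc$p_adjusted, 3)
    p <- file.path(out_dir, "clinician_contrast.csv")
    utils::write.csv(cc, p, row.names = FALSE)
    paths["clinician_contrast"] <- p
  }

  payload <- list(
    metadata = list(
      tool = "midsat",
      version = as.character(utils::packageVersion("midsat")),
      seed = seed, rounding = rounding,
      sd_convention = "n-1 whole-sample SD for ES, half-SD and SEM",
      mid_convention = "absolute small-vs-reference mean difference",
      config_hash = config_hash(list(seed = seed, rounding = rounding,
                                     n = fit$n))),
    estimates = fit$estimates,
    groups = as.data.frame(fit$groups),
    anova = fit$anova,
    bootstrap = as.data.frame(boot),
    descriptives = desc,
    clinician_contrast = clin)
  p <- file.path(out_dir, "estimates.json")
  # 17 significant digits: doubles survive the write/read round trip
  # bit-exactly
  jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  paths["estimates"] <- p

  p <- file.path(out_dir, "run_log.txt")
  writeLines(log, p)
  paths["log"] <- p
  invisible(paths)
}

# deterministic short hash of a config list (djb2 over its deparse)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Round-trip a written estimates file
#'
#' Reads `estimates.json` back into the list structure written by
#' [run_mid_pipeline()]; full-precision numbers survive the round trip
#' exactly.
#'
#' @param path Path to `estimates.json`.
#' @return The parsed list.
#' @export
read_mid_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
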