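#' Standardise a raw score to the 0-100 scale
#'
#' Linear transform of a raw sum onto 0-100:
#' `100 * (raw_sum - min_raw) / (max_raw - min_raw)`.
#'
#' @param raw_sum Raw score (vectorised).
#' @param min_raw,max_raw Attainable raw bounds; `max_raw > min_raw`.
#' @return Standardised score(s) in \[0, 100\].
#' @examples
#' standardize_score(6, 0, 12)  # 50
#' @export
standardize_score <- function(raw_sum, min_raw, max_raw) {
  if (max_raw <= min_raw)
    stop_midsat("degenerate raw range [", min_raw, ", ", max_raw, "]",
                class = "midsat_invalid_schema")
  bad <- !is.na(raw_sum) & (raw_sum < min_raw | raw_sum > max_raw)
  if (any(bad))
    stop_midsat("raw_sum out of range: ", raw_sum[bad][1L],
                " not in [", min_raw, ", ", max_raw, "]",
                class = "midsat_out_of_range")
  100 * (raw_sum - min_raw) / (max_raw - min_raw)
}

#' Score questionnaire responses
#'
#' Converts raw Likert responses to 0-100 standardised domain scores and the
#' total composite. Reverse-coded items are flipped
#' (`value -> response_min + response_max - value`) before summation. The
#' total standardises the raw sum over all items, not the mean of domain
#' scores, so items carry equal weight regardless of domain size.
#'
#' Missing data are handled per `missing_policy`:
#' \describe{
#'   \item{`complete_only`}{a domain is missing if any of its items is
#'     missing;}
#'   \item{`prorate_half`}{a domain with at least half of its items answered
#'     is scored from the mean of the answered items rescaled to the full
#'     raw range, else missing.}
#' }
#' The total score requires every domain to be non-missing (under
#' `prorate_half`, prorated domain raw scores feed the total).
#'
#' @param data Data frame with one row per respondent: a `respondent_id`
#'   column (created from row numbers if absent) and one column per item in
#'   `spec$items`. Extra columns are ignored.
#' @param spec An [instrument_spec()].
#' @param missing_policy `"complete_only"` (default) or `"prorate_half"`.
#' @return A data frame of class `score_matrix`: `respondent_id`, one column
#'   per domain, and `total`, with a `"provenance"` attribute (character
#'   matrix flagging each cell `complete`, `prorated` or `missing`) and a
#'   `"scales"` attribute naming the score columns.
#' @examples
#' spec <- satmedq_spec()
#' dat <- as.data.frame(setNames(as.list(rep(4L, 17)), spec$items))
#' score_responses(dat, spec)$total  # all items at max -> 100
#' @export
score_responses <- function(data, spec,
                            missing_policy = c("complete_only", "prorate_half")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(spec, "instrument_spec"))
  validate_responses(data, spec, anchor_col = "anchor")

  ids <- if ("respondent_id" %in% names(data)) {
    as.character(data$respondent_id)
  } else {
    sprintf("r%04d", seq_len(nrow(data)))
  }
  n <- nrow(data)
  rmin <- spec$response_min
  rmax <- spec$response_max
  step <- rmax - rmin

  # reverse-code, then work from one numeric matrix in item order
  resp <- as.matrix(data[spec$items])
  storage.mode(resp) <- "double"
  rev_idx <- match(spec$reverse_items, spec$items)
  if (length(rev_idx))
    resp[, rev_idx] <- rmin + rmax - resp[, rev_idx]

  scales <- c(names(spec$domains), "total")
  scores <- matrix(NA_real_, n, length(scales), dimnames = list(NULL, scales))
  prov <- matrix("missing", n, length(scales), dimnames = list(NULL, scales))

  dom_raw <- matrix(NA_real_, n, length(spec$domains))  # raw sums feeding total
  for (j in seq_along(spec$domains)) {
    dname <- names(spec$domains)[j]
    cols <- match(spec$domains[[j]], spec$items)
    k <- length(cols)
    sub <- resp[, cols, drop = FALSE]
    answered <- rowSums(!is.na(sub))
    complete <- answered == k
    raw <- rep(NA_real_, n)
    raw[complete] <- rowSums(sub, na.rm = FALSE)[complete]
    prov[complete, dname] <- "complete"
    if (missing_policy == "prorate_half") {
      prorate <- !complete & answered * 2L >= k
      if (any(prorate)) {
        raw[prorate] <- rowMeans(sub[prorate, , drop = FALSE], na.rm = TRUE) * k
        prov[prorate, dname] <- "prorated"
      }
    }
    dom_raw[, j] <- raw
    scores[, dname] <- standardize_score(raw, k * rmin, k * rmax)
  }

  total_raw <- rowSums(dom_raw)
  n_items <- length(spec$items)
  scores[, "total"] <- standardize_score(total_raw, n_items * rmin,
                                         n_items * rmax)
  ok <- !is.na(total_raw)
  prov[ok, "total"] <- ifelse(
    apply(prov[ok, scales != "total", drop = FALSE], 1L,
          function(p) any(p == "prorated")), "prorated", "complete")

  out <- data.frame(respondent_id = ids, scores, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "provenance") <- prov
  attr(out, "scales") <- scales
  class(out) <- c("score_matrix", "data.frame")
  out
}

# score column names of a score_matrix (domains + total)
score_scales <- function(scores) {
  attr(scores, "scales") %||% setdiff(names(scores), "respondent_id")
}

#' Write a score matrix to CSV
#'
#' One row per respondent with score columns and, for each score, a
#' `<scale>_provenance` sidecar column (`complete`/`prorated`/`missing`).
#'
#' @param scores A `score_matrix` from [score_responses()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  prov <- attr(scores, "provenance")
  out <- as.data.frame(scores)
  if (!is.null(prov)) {
    pv <- as.data.frame(prov, stringsAsFactors = FALSE)
    names(pv) <- paste0(names(pv), "_provenance")
    out <- cbind(out, pv)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
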