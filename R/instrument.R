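#' Define a questionnaire schema
#'
#' An instrument schema describes everything needed to turn raw Likert item
#' responses into 0-100 standardised domain and total scores: the item list,
#' the raw response range shared by all items, the partition of items into
#' domains, and which items are reverse-coded (answered in the direction
#' opposite to satisfaction).
#'
#' @param name Instrument name.
#' @param items Character vector of item identifiers (order defines the data
#'   column order).
#' @param response_min,response_max Integer bounds of the raw response codes
#'   (`response_max` must exceed `response_min`).
#' @param domains Named list mapping each domain name to the character vector
#'   of its item identifiers. The domains must partition `items`.
#' @param reverse_items Character vector (possibly empty) of reverse-coded
#'   items; must be a subset of `items`.
#' @param total_rule How the total score is formed. Only `"sum_of_items"` is
#'   defined: the total standardises the raw sum over all items (after
#'   reverse-coding), so items -- not domains -- carry equal weight.
#' @return An object of class `instrument_spec`.
#' @seealso [satmedq_spec()] for the shipped SATMED-Q default,
#'   [read_instrument_spec()] for loading a schema from JSON/YAML.
#' @export
instrument_spec <- function(name, items, response_min, response_max, domains,
                            reverse_items = character(),
                            total_rule = "sum_of_items") {
  items <- as.character(items)
  response_min <- as.integer(response_min)
  response_max <- as.integer(response_max)
  total_rule <- match.arg(total_rule, "sum_of_items")
  if (!is.list(domains) || is.null(names(domains)) || any(names(domains) == ""))
    stop_midsat("`domains` must be a named list of item vectors",
                class = "midsat_invalid_schema")
  domains <- lapply(domains, as.character)
  reverse_items <- as.character(reverse_items)

  if (anyDuplicated(items))
    stop_midsat("duplicated item identifiers", class = "midsat_invalid_schema")
  if (response_max <= response_min)
    stop_midsat("degenerate response range: response_max must exceed response_min",
                class = "midsat_invalid_schema")
  pooled <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(pooled))
    stop_midsat("an item appears in more than one domain",
                class = "midsat_invalid_schema")
  if (!setequal(pooled, items))
    stop_midsat("domains must partition the item list exactly",
                class = "midsat_invalid_schema")
  if (!all(reverse_items %in% items))
    stop_midsat("reverse_items contains unknown items: ",
                paste(setdiff(reverse_items, items), collapse = ", "),
                class = "midsat_invalid_schema")

  structure(
    list(name = name, items = items,
         response_min = response_min, response_max = response_max,
         domains = domains, reverse_items = reverse_items,
         total_rule = total_rule),
    class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("Instrument schema:", x$name, "\n")
  cat(sprintf("  %d items, raw responses %d..%d\n",
              length(x$items), x$response_min, x$response_max))
  for (d in names(x$domains))
    cat(sprintf("  %-26s %d item(s)\n", d, length(x$domains[[d]])))
  if (length(x$reverse_items))
    cat("  reverse-coded:", paste(x$reverse_items, collapse = ", "), "\n")
  invisible(x)
}

#' The default SATMED-Q schema
#'
#' Seventeen Likert items in six domains: treatment effectiveness,
#' convenience of use, impact on daily living, medical care (2 items; all
#' others have 3), undesirable side effects, and general satisfaction. Raw
#' responses default to a 5-point 0..4 coding, configurable because the
#' instrument's raw coding is not published unambiguously. The side-effects
#' items are reverse-coded by default: their raw responses concentrate at
#' "No, not at all" while the standardised side-effects satisfaction score is
#' high.
#'
#' @param response_min,response_max Raw response bounds (defaults 0 and 4).
#' @param reverse_items Reverse-coded items; defaults to the three
#'   side-effects items.
#' @return An [instrument_spec()] object.
#' @export
satmedq_spec <- function(response_min = 0L, response_max = 4L,
                         reverse_items = c("use1", "use2", "use3")) {
  domains <- list(
    treatment_effectiveness  = c("te1", "te2", "te3"),
    convenience_of_use       = c("conv1", "conv2", "conv3"),
    impact_daily_living      = c("idl1", "idl2", "idl3"),
    medical_care             = c("mc1", "mc2"),
    undesirable_side_effects = c("use1", "use2", "use3"),
    general_satisfaction     = c("gs1", "gs2", "gs3"))
  instrument_spec(
    name = "SATMED-Q",
    items = unlist(domains, use.names = FALSE),
    response_min = response_min, response_max = response_max,
    domains = domains, reverse_items = reverse_items)
}

#' The global-satisfaction anchor item descriptor
#'
#' Describes the single 7-category overall-satisfaction item (TSQM item #14)
#' used as the anchor: codes 1 (extremely dissatisfied) to 7 (extremely
#' satisfied) with the neutral category at 4. Only the neutral position
#' matters for anchor classification because the satisfied and dissatisfied
#' sides are merged by distance.
#'
#' @return A list with `name`, `column`, `response_min`, `response_max`,
#'   `neutral` and category `labels`.
#' @export
tsqm14_anchor <- function() {
  list(name = "TSQM item #14", column = "anchor",
       response_min = 1L, response_max = 7L, neutral = 4L,
       labels = c("extremely dissatisfied", "very dissatisfied",
                  "dissatisfied", "neither satisfied nor dissatisfied",
                  "satisfied", "very satisfied", "extremely satisfied"))
}

#' Read / write an instrument schema file
#'
#' Schemas are stored as JSON or YAML documents with fields mirroring
#' [instrument_spec()] (`name`, `items`, `response_min`, `response_max`,
#' `domains`, `reverse_items`, `total_rule`). The format is chosen from the
#' file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_instrument_spec()` returns an [instrument_spec()];
#'   `write_instrument_spec()` returns `path` invisibly.
#' @export
read_instrument_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  need <- c("name", "items", "response_min", "response_max", "domains")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_midsat("schema file missing fields: ", paste(miss, collapse = ", "),
                class = "midsat_invalid_schema")
  instrument_spec(
    name = raw$name, items = raw$items,
    response_min = raw$response_min, response_max = raw$response_max,
    domains = lapply(raw$domains, as.character),
    reverse_items = raw$reverse_items %||% character(),
    total_rule = raw$total_rule %||% "sum_of_items")
}

#' @rdname read_instrument_spec
#' @param spec An [instrument_spec()] object.
#' @export
write_instrument_spec <- function(spec, path) {
  stopifnot(inherits(spec, "instrument_spec"))
  obj <- unclass(spec)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read respondent-level questionnaire data
#'
#' Reads a delimited text file with a header row: one column per item
#' identifier, plus `respondent_id`, the anchor column, and optionally a
#' `clinician_rating` column. Missing cells are empty strings or `na`
#' sentinels.
#'
#' @param path CSV/TSV file path (delimiter inferred from extension; `.tsv`
#'   uses tab).
#' @param spec An [instrument_spec()]; used to check that all item columns
#'   are present and responses are in range.
#' @param anchor_col Name of the anchor-response column (default `"anchor"`).
#' @param na Strings interpreted as missing (default empty string and `"NA"`).
#' @return A data frame validated against the schema.
#' @export
read_responses <- function(path, spec = satmedq_spec(), anchor_col = "anchor",
                           na = c("", "NA")) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_responses(dat, spec, anchor_col = anchor_col)
  dat
}

# Check a respondent data frame against a schema; returns invisibly or stops
# with a named-column diagnostic.
validate_responses <- function(data, spec, anchor_col = "anchor") {
  if (!nrow(data))
    stop_midsat("empty respondent data", class = "midsat_empty_input")
  miss <- setdiff(spec$items, names(data))
  if (length(miss))
    stop_midsat("response data lacks item columns: ",
                paste(miss, collapse = ", "), class = "midsat_schema_mismatch")
  for (it in spec$items) {
    v <- data[[it]]
    bad <- !is.na(v) & (v < spec$response_min | v > spec$response_max |
                          v != round(v))
    if (any(bad))
      stop_midsat(sprintf("item %s has out-of-range responses (e.g. %s)",
                          it, v[bad][1L]), class = "midsat_out_of_range")
  }
  if (anchor_col %in% names(data)) {
    a <- data[[anchor_col]]
    bad <- !is.na(a) & (a < 1 | a > 7 | a != round(a))
    if (any(bad))
      stop_midsat("anchor responses must be integers in 1..7 (found ",
                  a[bad][1L], ")", class = "midsat_invalid_anchor")
  }
  invisible(data)
}
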