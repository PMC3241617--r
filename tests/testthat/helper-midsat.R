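# shared fixture builders (all data generated in code)

# a minimal 2-domain instrument on a 0..4 coding: one 3-item domain, one
# 2-item domain with a reverse-coded item
tiny_spec <- function(reverse = "b2") {
  instrument_spec(
    name = "tiny", items = c("a1", "a2", "a3", "b1", "b2"),
    response_min = 0L, response_max = 4L,
    domains = list(alpha = c("a1", "a2", "a3"), beta = c("b1", "b2")),
    reverse_items = reverse)
}

# random complete Likert responses for a spec
random_responses <- function(n, spec, seed = 1) {
  set.seed(seed)
  dat <- as.data.frame(lapply(spec$items, function(i)
    sample(spec$response_min:spec$response_max, n, replace = TRUE)))
  names(dat) <- spec$items
  dat$respondent_id <- sprintf("p%03d", seq_len(n))
  dat
}

# a plain score data frame (one scale) with anchor levels
toy_grouped_scores <- function(n_per = c(reference = 30, small = 40,
                                         medium = 20, large = 10),
                               means = c(reference = 55, small = 70,
                                         medium = 80, large = 90),
                               sds = c(reference = 12, small = 12,
                                       medium = 10, large = 8),
                               seed = 1) {
  set.seed(seed)
  lv <- rep(names(n_per), n_per)
  x <- stats::rnorm(sum(n_per), means[lv], sds[lv])
  sc <- data.frame(respondent_id = seq_along(x), score = x)
  attr(sc, "scales") <- "score"
  list(scores = sc,
       levels = factor(lv, levels = c("reference", "small", "medium",
                                      "large"), ordered = TRUE))
}
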