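test_that("the generator reproduces the configured cohort structure", {
  study <- generate_study(synthetic_config(seed = 3))
  expect_equal(nrow(study$records), 456L)
  expect_equal(as.vector(table(study$levels)[c("reference", "small",
                                               "medium", "large")]),
               c(68L, 213L, 136L, 39L))
  # the large level splits 35 extremely satisfied / 4 extremely dissatisfied
  a_large <- study$records$anchor[study$levels == "large"]
  expect_equal(sum(a_large == 7L), 35L)
  expect_equal(sum(a_large == 1L), 4L)
  # anchor codes reclassify to the generated levels
  expect_equal(classify_anchor(study$records$anchor), study$levels)
  # item responses are in range and rescore to the latent tier up to
  # quantisation
  spec <- satmedq_spec()
  expect_true(all(as.matrix(study$records[spec$items]) %in% 0:4))
})

test_that("generation is deterministic under the config seed", {
  s1 <- generate_study(synthetic_config(seed = 17))
  s2 <- generate_study(synthetic_config(seed = 17))
  expect_identical(s1$records, s2$records)
  expect_identical(as.data.frame(s1$scores), as.data.frame(s2$scores))
  s3 <- generate_study(synthetic_config(seed = 18))
  expect_false(identical(as.data.frame(s1$scores), as.data.frame(s3$scores)))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_total = 400),
               class = "midsat_invalid_config")  # sizes don't sum
  expect_error(synthetic_config(side_split = list(
    large = c(satisfied = 30L, dissatisfied = 4L),
    small = c(satisfied = 160L, dissatisfied = 53L),
    medium = c(satisfied = 102L, dissatisfied = 34L))),
    class = "midsat_invalid_config")  # large split != 39
  tg <- satmedq_group_targets()
  tg$sd[1L] <- 0
  expect_error(synthetic_config(scale_targets = tg),
               class = "midsat_invalid_config")
  tg2 <- satmedq_group_targets()
  tg2$mean[1L] <- 120
  expect_error(synthetic_config(scale_targets = tg2),
               class = "midsat_invalid_config")
  # infeasible truncation: an enormous sd leaves almost no probability
  # mass inside the score bounds
  tg3 <- satmedq_group_targets()
  tg3$sd[tg3$scale == "total"][1L] <- 2000
  expect_error(synthetic_config(scale_targets = tg3),
               class = "midsat_invalid_config")
})

test_that("moment matching hits targets exactly and is idempotent", {
  set.seed(8)
  g <- rep(c("a", "b"), c(25, 35))
  x <- stats::rnorm(60, 50, 20)
  tm <- c(a = 60, b = 80)
  ts <- c(a = 10, b = 5)
  y <- moment_match(x, g, tm, ts)
  for (l in c("a", "b")) {
    expect_equal(mean(y[g == l]), tm[[l]], tolerance = 1e-9)
    expect_equal(stats::sd(y[g == l]), ts[[l]], tolerance = 1e-9)
  }
  y2 <- moment_match(as.numeric(y), g, tm, ts)
  expect_equal(as.numeric(y2), as.numeric(y), tolerance = 1e-12)
  # group membership and sizes untouched
  expect_length(y, length(x))
  # two-point group: the closed-form pair m +/- s/sqrt(2)
  z <- moment_match(c(1, 2), c("g", "g"), c(g = 10), c(g = 4))
  expect_equal(sort(as.numeric(z)), c(10 - 4 / sqrt(2), 10 + 4 / sqrt(2)))
  expect_error(moment_match(c(3, 3, 3), rep("g", 3), c(g = 1), c(g = 1)),
               class = "midsat_not_matchable")
})

test_that("out-of-bounds values are flagged, never clipped", {
  x <- c(10, 20, 30, 40)
  y <- moment_match(x, rep("g", 4), c(g = 95), c(g = 20), bounds = c(0, 100))
  expect_equal(mean(as.numeric(y)), 95, tolerance = 1e-9)
  expect_true(any(attr(y, "out_of_bounds")))
  expect_gt(max(y), 100)  # exactness preserved over the bound
})

test_that("item discretisation round-trips within the quantisation bound", {
  spec <- tiny_spec(reverse = "b2")
  # endpoint and midpoint examples
  it <- scores_to_items(data.frame(alpha = 100, beta = 100), spec)
  expect_equal(unname(unlist(it[1, c("a1", "a2", "a3", "b1")])), rep(4L, 4))
  expect_equal(it$b2, 0L)  # reverse item stored flipped
  it50 <- scores_to_items(data.frame(alpha = 50, beta = 50), spec)
  expect_equal(unname(unlist(it50[1, c("a1", "a2", "a3")])), c(2L, 2L, 2L))
  # property: rescoring recovers the latent score within 100/(2*range)
  set.seed(30)
  lat <- data.frame(alpha = stats::runif(1000, 0, 100),
                    beta = stats::runif(1000, 0, 100))
  items <- scores_to_items(lat, spec)
  rescored <- score_responses(items, spec)
  expect_lt(max(abs(rescored$alpha - lat$alpha)), 100 / (2 * 12) + 1e-9)
  expect_lt(max(abs(rescored$beta - lat$beta)), 100 / (2 * 8) + 1e-9)
})

test_that("truncated draws near the ceiling are negatively skewed", {
  cfg <- synthetic_config(seed = 44, skew_mode = "truncated_gaussian")
  study <- generate_study(cfg)
  expect_lt(midsat:::sample_skewness(study$scores$total), 0)
  expect_true(all(study$scores$total >= 0 & study$scores$total <= 100))
})

test_that("the reconstruction reproduces every published group moment", {
  study <- reconstruct_satmedq_study(seed = 6)
  g <- summarize_groups(study$scores, study$levels)
  tg <- satmedq_group_targets()
  m <- merge(as.data.frame(g), tg, by = c("scale", "level"),
             suffixes = c("_got", "_want"))
  expect_equal(nrow(m), 28L)
  expect_equal(m$n_got, m$n_want)
  # exact at full precision, hence exact at the printed 1-decimal rounding
  expect_equal(m$mean_got, m$mean_want, tolerance = 1e-9)
  expect_equal(m$sd_got, m$sd_want, tolerance = 1e-9)
  expect_equal(round_half_up(m$mean_got, 1), m$mean_want)
  # whole-sample composite moments implied by the printed group summaries
  expect_equal(mean(study$scores$total), 75.04, tolerance = 0.005)
  expect_equal(stats::sd(study$scores$total), 14.77, tolerance = 0.005)
})

test_that("configured clinician shifts are recovered by the contrast", {
  # recovery within 2 SE holds for ~93% of contrasts (the poor group has
  # n ~ 14, so the Welch contrast has t-tails slightly heavier than the
  # 2-SE normal rule); count across seeds rather than betting one seed
  shifts <- c(poor = -23, good = 6, excellent = 19)
  within <- 0L
  total <- 0L
  for (seed in 1:10) {
    cfg <- synthetic_config(seed = seed, clinician_shifts = shifts,
                            skew_mode = "gaussian")
    study <- generate_study(cfg)
    cc <- clinician_contrast(study$scores$treatment_effectiveness,
                             study$records$clinician_rating)
    for (gname in names(shifts)) {
      row <- cc[cc$group == gname, ]
      total <- total + 1L
      if (abs(row$d - shifts[[gname]]) < 2 * row$se) within <- within + 1L
    }
  }
  expect_gte(within / total, 24 / 30)
})
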