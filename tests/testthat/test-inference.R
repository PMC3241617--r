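test_that("summary-statistic ANOVA equals its raw-data oracles", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(3:5, 1)
    n <- sample(5:40, k, replace = TRUE)
    g <- factor(rep(seq_len(k), n))
    x <- stats::rnorm(sum(n), mean = as.integer(g) * 2, sd = 3)
    ns <- tapply(x, g, length)
    ms <- tapply(x, g, mean)
    ss <- tapply(x, g, stats::sd)

    cls <- anova_from_summary(ns, ms, ss, "classic")
    fit <- stats::anova(stats::lm(x ~ g))
    expect_equal(cls$F, fit$`F value`[1L], tolerance = 1e-9)
    expect_equal(cls$p, fit$`Pr(>F)`[1L], tolerance = 1e-9)

    wel <- anova_from_summary(ns, ms, ss, "welch")
    ow <- stats::oneway.test(x ~ g, var.equal = FALSE)
    expect_equal(wel$F, unname(ow$statistic), tolerance = 1e-9)
    expect_equal(wel$df2, unname(ow$parameter["denom df"]), tolerance = 1e-9)
    expect_equal(wel$p, ow$p.value, tolerance = 1e-9)
  }
})

test_that("ANOVA degenerate and identity cases behave", {
  # all means equal -> F = 0, p = 1
  a <- anova_from_summary(c(10, 12, 14), c(5, 5, 5), c(1, 2, 3), "classic")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # two groups: classic F equals the squared pooled-variance t statistic
  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::rnorm(15, 0, 2); y <- stats::rnorm(20, 1, 2)
    a2 <- anova_from_summary(c(15, 20), c(mean(x), mean(y)),
                             c(stats::sd(x), stats::sd(y)), "classic")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  }
  # with equal group variances and sizes the Welch statistic shares the
  # classic numerator; its finite-sample correction term vanishes as the
  # groups grow, so the two converge (they are not identical at small n)
  b1 <- anova_from_summary(c(2000, 2000, 2000), c(1, 1.1, 1.2), c(2, 2, 2),
                           "classic")
  b2 <- anova_from_summary(c(2000, 2000, 2000), c(1, 1.1, 1.2), c(2, 2, 2),
                           "welch")
  expect_equal(b1$F, b2$F, tolerance = 1e-3)
  expect_lt(b2$F, b1$F)  # the correction always shrinks the statistic
  expect_error(anova_from_summary(10, 5, 2), class = "midsat_not_estimable")
  expect_error(anova_from_summary(c(10, 10), c(1, 2), c(NA, 2)),
               class = "midsat_invalid_input")
})

test_that("Levene's test matches the car oracle for both centres", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- factor(rep(1:3, c(20, 25, 30)))
    x <- stats::rnorm(75, 0, as.integer(g))
    for (ctr in c("mean", "median")) {
      mine <- levene_test(x, g, center = ctr)
      ora <- car::leveneTest(x, g, center = ctr)
      expect_equal(mine$W, ora$`F value`[1L], tolerance = 1e-9)
      expect_equal(mine$p, ora$`Pr(>F)`[1L], tolerance = 1e-9)
    }
  }
  expect_error(levene_test(c(1, 2, 3), factor(c("a", "a", "b"))),
               class = "midsat_not_estimable")
})

test_that("Levene's test detects a 3:1 SD ratio and accepts equal spread", {
  hits <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    x <- c(stats::rnorm(200, 0, 3), stats::rnorm(200, 0, 1))
    g <- factor(rep(1:2, each = 200))
    if (levene_test(x, g)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
  # identical dispersion patterns in both groups -> W ~ 0, p ~ 1
  x0 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g0 <- factor(rep(1:2, each = 4))
  lv <- levene_test(x0, g0)
  expect_equal(lv$W, 0, tolerance = 1e-12)
  expect_equal(lv$p, 1, tolerance = 1e-12)
})

test_that("Bonferroni pairwise contrasts adjust as defined", {
  toy <- toy_grouped_scores(seed = 9)
  pw <- pairwise_bonferroni(toy$scores$score, toy$levels)
  expect_equal(pw$level, c("small", "medium", "large"))
  expect_true(all(pw$p_adjusted >= pw$p_raw))
  expect_true(all(pw$p_adjusted <= 1))
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 3))
  # identical groups: adjusted p = 1
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- factor(rep(c("reference", "b"), each = 5),
              levels = c("reference", "b"))
  pw2 <- pairwise_bonferroni(x, g)
  expect_equal(pw2$d, 0)
  expect_equal(pw2$p_adjusted, 1)
  # empty comparison flagged, others returned
  g3 <- factor(rep(c("reference", "b", "c"), c(5, 5, 1)),
               levels = c("reference", "b", "c"))
  pw3 <- pairwise_bonferroni(c(x, 99), g3)
  expect_equal(pw3$flag[pw3$level == "c"], "empty")
  expect_false(is.na(pw3$p_adjusted[pw3$level == "b"]))
})

test_that("descriptives recover moments, skewness sign and normality", {
  # symmetric data: skewness near 0
  set.seed(42)
  sym <- data.frame(s = stats::rnorm(10000))
  attr(sym, "scales") <- "s"
  d <- exploratory_summary(sym)
  expect_lt(abs(d$skewness), 0.1)
  # ceiling-prone scores: negative skew
  skewed <- data.frame(s = 100 - stats::rexp(5000, 1 / 10))
  attr(skewed, "scales") <- "s"
  expect_lt(exploratory_summary(skewed)$skewness, -0.5)
  # too-few values flagged
  tiny <- data.frame(s = c(1, NA, NA, 2))
  attr(tiny, "scales") <- "s"
  expect_equal(exploratory_summary(tiny)$flag, "too_few")
})

test_that("the moment-based KS check passes normal samples", {
  ok <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    x <- data.frame(s = stats::rnorm(5000))
    attr(x, "scales") <- "s"
    if (exploratory_summary(x)$ks_p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok / 100, 0.95)
})

test_that("clinician contrasts use the acceptable group as reference", {
  set.seed(13)
  ratings <- rep(c("poor", "acceptable", "good", "excellent"),
                 c(15, 90, 200, 150))
  shift <- c(poor = -20, acceptable = 0, good = 6, excellent = 18)
  x <- 60 + shift[ratings] + stats::rnorm(length(ratings), 0, 10)
  cc <- clinician_contrast(x, ratings)
  expect_setequal(cc$group, c("poor", "good", "excellent"))
  expect_lt(cc$d[cc$group == "poor"], 0)
  expect_gt(cc$d[cc$group == "excellent"], 0)
  expect_true(all(cc$p_adjusted >= cc$p_raw & cc$p_adjusted <= 1))
  # all-acceptable ratings: empty contrast table
  cc0 <- clinician_contrast(stats::rnorm(20), rep("acceptable", 20))
  expect_equal(nrow(cc0), 0L)
  expect_error(clinician_contrast(stats::rnorm(10), rep("good", 10)),
               class = "midsat_not_estimable")
})
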