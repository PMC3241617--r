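make_summary <- function(means, ns = c(10, 10, 10, 10), sds = rep(5, 4)) {
  data.frame(scale = "s", level = factor(c("reference", "small", "medium",
                                           "large"),
                                         levels = c("reference", "small",
                                                    "medium", "large"),
                                         ordered = TRUE),
             n = ns, mean = means, sd = sds, flag = "",
             stringsAsFactors = FALSE)
}

test_that("anchor MID is the absolute small-vs-reference mean gap", {
  expect_equal(anchor_mid(make_summary(c(59.3, 72.7, 82.5, 89.3))),
               13.4, tolerance = 1e-12)
  expect_equal(anchor_mid(make_summary(c(70, 60, 50, 40))), 10)  # absolute
  expect_equal(anchor_mid(make_summary(rep(50, 4))), 0)
  g <- make_summary(c(59.3, 72.7, 82.5, 89.3), ns = c(0, 10, 10, 10))
  expect_error(anchor_mid(g), class = "midsat_not_estimable")
})

test_that("step differences preserve non-monotone patterns", {
  # side-effects pattern: the large step dips below the medium step
  g <- make_summary(c(76.5, 88.0, 94.4, 92.9))
  steps <- step_differences(g)
  expect_equal(unname(steps), c(11.5, 17.9, 16.4), tolerance = 1e-12)
  expect_lt(steps[["large"]], steps[["medium"]])
  # composite pattern from printed means
  g2 <- make_summary(c(59.3, 72.7, 82.5, 89.3))
  expect_equal(unname(step_differences(g2)), c(13.4, 23.2, 30.0),
               tolerance = 1e-12)
  expect_equal(unname(step_differences(make_summary(rep(1, 4)))), c(0, 0, 0))
  # empty non-reference level flagged, others returned
  g3 <- make_summary(c(50, 60, 70, 80), ns = c(10, 10, 0, 10))
  s3 <- step_differences(g3)
  expect_true(is.na(s3[["medium"]]))
  expect_equal(s3[["large"]], 30)
})

test_that("effect sizes carry the conventional magnitude labels", {
  expect_equal(effect_size(0, 10),
               list(effect_size = 0, es_label = "negligible"))
  expect_equal(effect_size(3, 10)$es_label, "small")
  expect_equal(effect_size(5, 10)$es_label, "moderate")
  expect_equal(effect_size(8, 10)$es_label, "large")
  expect_error(effect_size(5, 0), class = "midsat_not_estimable")
})

test_that("effect size is invariant to rescaling all scores", {
  for (c_mult in c(0.1, 3, 40)) {
    a <- effect_size(13.4, 14.77)
    b <- effect_size(13.4 * c_mult, 14.77 * c_mult)
    expect_equal(a$effect_size, b$effect_size, tolerance = 1e-12)
  }
})

test_that("SEM follows sd * sqrt(1 - reliability)", {
  expect_equal(sem(12, 1), 0)
  expect_equal(sem(12, 0), 12)
  expect_equal(sem(14.76, 0.840), 14.76 * sqrt(0.16))  # 5.904 -> 5.9
  expect_equal(round_half_up(sem(14.76, 0.840), 1), 5.9)
  expect_error(sem(12, 1.2), class = "midsat_invalid_reliability")
  # bounded by the SD and monotone decreasing in reliability
  rels <- seq(-0.5, 1, by = 0.25)
  vals <- vapply(rels, function(r) sem(10, r), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals[rels >= 0] <= 10))
})

test_that("half-SD halves the whole-sample SD", {
  expect_equal(half_sd(14.76), 7.38)
  expect_equal(round_half_up(half_sd(14.76), 1), 7.4)
  expect_equal(half_sd(24.4), 12.2)
  expect_equal(half_sd(0), 0)
  expect_error(half_sd(-1), class = "midsat_invalid_input")
})

test_that("Cronbach's alpha matches hand-evaluated and degenerate cases", {
  # perfectly parallel items
  set.seed(2)
  x <- stats::rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  # two items with exact variances 1, 1 and covariance 0.5 -> 2/3
  xy <- MASS::mvrnorm(40, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2),
                      empirical = TRUE)
  expect_equal(cronbach_alpha(xy), 2 / 3, tolerance = 1e-9)
  # perfectly anti-correlated items
  expect_lt(cronbach_alpha(cbind(x, -x + 0.3)), 0)
  expect_error(cronbach_alpha(cbind(x)), class = "midsat_invalid_input")
  expect_error(cronbach_alpha(cbind(rep(1, 10), rep(2, 10))),
               class = "midsat_undefined_alpha")
})

test_that("alpha agrees with the covariance-matrix oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:6, 1)
    n <- sample(20:60, 1)
    x <- matrix(stats::rnorm(n * k), n, k) +
      stats::rnorm(n)  # shared factor induces positive covariance
    # general identity: alpha from the covariance matrix
    C <- stats::cov(x)
    oracle <- (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
    expect_equal(cronbach_alpha(x), oracle, tolerance = 1e-9)
    # equal-variance form on variance-standardised items
    xs <- scale(x)
    Cs <- stats::cov(xs)
    cbar <- mean(Cs[upper.tri(Cs)])
    expect_equal(cronbach_alpha(xs),
                 k * cbar / (1 + (k - 1) * cbar), tolerance = 1e-9)
  }
})

test_that("listwise deletion governs alpha with missing rows", {
  set.seed(5)
  x <- matrix(stats::rnorm(60), 20, 3) + stats::rnorm(20)
  xm <- x
  xm[1:3, 1] <- NA
  expect_equal(cronbach_alpha(xm), cronbach_alpha(x[-(1:3), ]),
               tolerance = 1e-12)
})
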