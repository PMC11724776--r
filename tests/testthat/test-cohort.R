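test_that("HOMA-IR follows the fasting closed form", {
  expect_equal(homa_ir(90, 4.5), 1)
  expect_equal(homa_ir(405, 1), 1)
  expect_equal(homa_ir(90, 0), 0)
  expect_equal(homa_ir(c(90, 405), c(4.5, 1)), c(1, 1))
  expect_error(homa_ir(0, 4), "positive")
  expect_error(homa_ir(90, -1), "non-negative")
})

test_that("quartile ANOVA matches textbook sums of squares", {
  d <- tibble::tibble(
    quartile = factor(rep(c("Q1", "Q2", "Q3"), each = 3),
                      levels = paste0("Q", 1:4)),
    y = c(1, 2, 3, 2, 3, 4, 4, 5, 6)
  )
  # by hand: SSB = 14, SSW = 6, F = (14/2)/(6/6) = 7 on (2, 6) df
  res <- quartile_summary(d, "y")
  expect_equal(unique(res$p_anova), stats::pf(7, 2, 6, lower.tail = FALSE))
  expect_equal(res$mean, c(2, 3, 5))
  expect_equal(res$n, rep(3L, 3))
})

test_that("a clean gradient across quartiles yields a tiny p-for-trend", {
  set.seed(51)
  d <- tibble::tibble(
    quartile = factor(rep(paste0("Q", 1:4), each = 40),
                      levels = paste0("Q", 1:4)),
    y = rep(c(10, 20, 30, 40), each = 40) + rnorm(160, 0, 0.1)
  )
  res <- quartile_summary(d, "y")
  expect_lt(unique(res$p_trend), 1e-10)
  expect_gt(unique(res$trend_slope), 9)
  # a null variable shows no gradient
  d$z <- rnorm(160)
  res_null <- quartile_summary(d, "z")
  expect_lt(abs(unique(res_null$trend_slope)), 0.5)
})

test_that("zero-variance variables are flagged with undefined p-values", {
  d <- tibble::tibble(
    quartile = factor(rep(c("Q1", "Q2"), each = 5), levels = paste0("Q", 1:4)),
    y = rep(1, 10)
  )
  res <- quartile_summary(d, "y")
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$p_anova)))
})

test_that("p-for-trend is uniform under the null", {
  set.seed(52)
  pvals <- replicate(1000, {
    d <- tibble::tibble(
      quartile = factor(sample(paste0("Q", 1:4), 80, replace = TRUE),
                        levels = paste0("Q", 1:4)),
      y = rnorm(80)
    )
    unique(quartile_summary(d, "y")$p_trend)
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("adjusted association recovers an exact linear outcome", {
  set.seed(53)
  d <- tibble::tibble(
    total = sample(0:18, 60, replace = TRUE),
    age = runif(60, 3, 6),
    sex = factor(sample(c("boy", "girl"), 60, replace = TRUE)),
    y = 2 * total + 0.5 * age
  )
  # a noise-free outcome is the point here; lm warns about the perfect fit
  res <- suppressWarnings(adjusted_association(d, "y"))
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$ci_high - res$ci_low, 1e-8)
  expect_equal(res$n, 60L)
})

test_that("a score-independent outcome gives a null coefficient", {
  set.seed(54)
  d <- tibble::tibble(
    total = sample(0:18, 500, replace = TRUE),
    age = runif(500, 3, 6),
    sex = factor(sample(c("boy", "girl"), 500, replace = TRUE)),
    y = rnorm(500)
  )
  res <- adjusted_association(d, "y")
  expect_lt(abs(res$beta), 3 * res$se)
  expect_true(res$ci_low < 0 && res$ci_high > 0)
})

test_that("without covariates the slope is cov/var on centred data", {
  set.seed(55)
  d <- tibble::tibble(total = sample(0:18, 80, replace = TRUE))
  d$y <- 0.7 * d$total + rnorm(80)
  d$total_c <- d$total - mean(d$total)
  d2 <- tibble::tibble(total = d$total_c, y = d$y - mean(d$y))
  res <- adjusted_association(d2, "y", covariates = character())
  expect_equal(res$beta, stats::cov(d2$total, d2$y) / stats::var(d2$total),
               tolerance = 1e-12)
})

test_that("degenerate designs and short inputs raise errors", {
  d <- tibble::tibble(
    total = sample(0:18, 30, replace = TRUE),
    age = runif(30, 3, 6),
    sex = factor(sample(c("boy", "girl"), 30, replace = TRUE)),
    y = rnorm(30)
  )
  d$age2 <- d$age  # exact copy -> collinear
  expect_error(adjusted_association(d, "y", covariates = c("age", "age2")),
               "rank-deficient")
  expect_error(adjusted_association(d[1:5, ], "y"), "too few")
  expect_error(adjusted_association(d, "nope"), "lacks")
})

test_that("outcome effects are recovered from a synthetic cohort", {
  co <- generate_cohort(cohort_preset("calibrated", n = 2000, seed = 56))
  d <- dplyr::inner_join(score_cohort(co$questionnaire)[c("child_id", "total")],
                         co$outcomes, by = "child_id")
  res <- adjusted_association(d, "wc")
  truth <- default_outcome_effects()$wc$beta
  expect_lt(abs(res$beta - truth), 3 * res$se)
})

test_that("sensitivity analysis is the identity when nothing is dropped", {
  co <- generate_cohort(cohort_preset("calibrated", n = 300, seed = 57))
  full <- sensitivity_exclude(integer(0), co$questionnaire, co$outcomes,
                              outcomes = c("wc", "hdl"))
  split <- split(full, full$analysis)
  expect_equal(split$full$beta, split$reduced$beta, tolerance = 1e-12)
  expect_error(sensitivity_exclude(1:18, co$questionnaire, co$outcomes,
                                   outcomes = "wc"), "every item")
  expect_error(sensitivity_exclude(99, co$questionnaire, co$outcomes,
                                   outcomes = "wc"), "registry")
})

test_that("dropping items no child satisfies changes nothing", {
  co <- generate_cohort(cohort_preset("calibrated", n = 300, seed = 58))
  q <- co$questionnaire
  q$q09 <- 0  # nobody reaches the nuts criterion any more
  res <- sensitivity_exclude(9, q, co$outcomes, outcomes = c("wc", "hdl"))
  split <- split(res, res$analysis)
  expect_equal(split$full$beta, split$reduced$beta, tolerance = 1e-12)
})

test_that("descriptives route normal and skewed variables differently", {
  d <- tibble::tibble(
    g = rep(c("boy", "girl"), each = 3),
    x = c(1, 2, 3, 3, 4, 5),
    s = c(1, 2, 3, 3, 4, 5)
  )
  res <- describe_cohort(d, c("x", "s"), by = "g", skewed = "s")
  # pooled-variance t by hand: means 2 vs 4, s2p = 1, t = -2/sqrt(2/3)
  t_hand <- -2 / sqrt(1 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(t_hand, df = 4)
  expect_equal(unique(res$p_value[res$variable == "x"]), p_hand)
  expect_equal(unique(res$summary[res$variable == "x"]), "mean_sd")
  expect_equal(unique(res$summary[res$variable == "s"]), "median_iqr")
  # identical groups: no evidence of a difference
  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 4), x = rep(1:4, 2))
  res2 <- describe_cohort(d2, "x", by = "g")
  expect_equal(unique(res2$p_value), 1)
  # groups 10 SDs apart: overwhelming evidence
  d3 <- tibble::tibble(g = rep(c("a", "b"), each = 20),
                       x = c(rnorm(20), rnorm(20, 10)))
  expect_lt(unique(describe_cohort(d3, "x", by = "g")$p_value), 1e-10)
})
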