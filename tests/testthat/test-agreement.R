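test_that("2x2 cross-classification counts the four concordance cells", {
  t1 <- build_2x2(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(t1[c("a", "b", "c", "d")], list(a = 1L, b = 1L, c = 1L, d = 1L))
  t2 <- build_2x2(c(1, 0, 1), c(1, 0, 1))
  expect_equal(t2$b + t2$c, 0L)
  t3 <- build_2x2(c(1, 0), c(0, 1))
  expect_equal(t3$a + t3$d, 0L)
  expect_error(build_2x2(c(1, 0), c(1)), "length")
  expect_error(build_2x2(c(1, NA), c(1, 0)), "NA")
  expect_error(build_2x2(c(1, 2), c(1, 0)), "binary")
})

test_that("kappa matches hand-computed marginal products", {
  expect_equal(cohen_kappa(list(a = 50, b = 0, c = 0, d = 50))$kappa, 1)
  k <- cohen_kappa(list(a = 40, b = 10, c = 5, d = 45))
  expect_equal(k$po, 0.85)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.70)
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
})

test_that("kappa equals the generic cell-probability oracle on random tables", {
  set.seed(31)
  for (i in 1:200) {
    cells <- as.list(stats::setNames(rmultinom(1, 200, runif(4, .05, 1)),
                                     c("a", "b", "c", "d")))
    k <- cohen_kappa(cells)
    if (k$undefined) next
    expect_equal(k$kappa, oracle_kappa(cells$a, cells$b, cells$c, cells$d),
                 tolerance = 1e-12)
    # Po reconstruction identity holds to machine precision
    expect_equal(k$kappa * (1 - k$pe) + k$pe, k$po, tolerance = 1e-12)
  }
})

test_that("kappa is invariant to method swap and label swap", {
  set.seed(32)
  for (i in 1:50) {
    cl <- as.list(stats::setNames(rmultinom(1, 150, runif(4, .05, 1)),
                                  c("a", "b", "c", "d")))
    k <- cohen_kappa(cl)$kappa
    swap_methods <- cohen_kappa(list(a = cl$a, b = cl$c, c = cl$b, d = cl$d))
    swap_labels <- cohen_kappa(list(a = cl$d, b = cl$c, c = cl$b, d = cl$a))
    expect_equal(swap_methods$kappa, k, tolerance = 1e-12)
    expect_equal(swap_labels$kappa, k, tolerance = 1e-12)
  }
})

test_that("kappa is 1 exactly when both off-diagonal cells are empty", {
  expect_equal(cohen_kappa(list(a = 10, b = 0, c = 0, d = 3))$kappa, 1)
  expect_lt(cohen_kappa(list(a = 10, b = 1, c = 0, d = 3))$kappa, 1)
  expect_lt(cohen_kappa(list(a = 10, b = 0, c = 2, d = 3))$kappa, 1)
})

test_that("degenerate tables flag kappa as undefined, not zero", {
  k <- cohen_kappa(list(a = 100, b = 0, c = 0, d = 0))
  expect_true(k$undefined)
  expect_true(is.na(k$kappa))
  expect_error(cohen_kappa(list(a = 0, b = 0, c = 0, d = 0)), "empty")
})

test_that("interpretation bands follow the stated kappa scale", {
  expect_equal(as.character(kappa_band(c(0.665, 0.416, 0.058))),
               c("substantial", "moderate", "weak"))
  expect_equal(as.character(kappa_band(c(-1, 0.20, 0.21, 0.40, 0.41,
                                         0.60, 0.61, 0.80, 0.81, 1))),
               c("weak", "weak", "fair", "fair", "moderate", "moderate",
                 "substantial", "substantial", "almost_perfect",
                 "almost_perfect"))
  expect_error(kappa_band(1.2), "outside")
})

test_that("Bland-Altman closed forms hold", {
  ident <- bland_altman(c(3, 7, 11), c(3, 7, 11))
  expect_equal(ident$mean_difference, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
  offset <- bland_altman(c(8, 9, 15) + 5, c(8, 9, 15))
  expect_equal(offset$mean_difference, 5)
  expect_equal(c(offset$loa_low, offset$loa_high), c(5, 5))
  ba <- bland_altman(c(4, 5, 6), c(0, 0, 0))
  expect_equal(ba$mean_difference, 5)
  expect_equal(ba$sd_difference, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(3.04, 6.96))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("LoA width and mean difference satisfy their identities", {
  set.seed(33)
  x <- rnorm(200, 10, 2); y <- rnorm(200, 8, 2)
  ba <- bland_altman(x, y)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_difference)
  expect_equal(ba$mean_difference, mean(x) - mean(y))
})

test_that("independent raters with matched marginals give chance-level kappa", {
  set.seed(34)
  n <- 5000
  x <- rbinom(n, 1, 0.6); y <- rbinom(n, 1, 0.6)
  k <- cohen_kappa(build_2x2(x, y))
  expect_lt(abs(k$kappa), 3 * k$se)
})

test_that("per-item misreporting lowers kappa, and more of it lowers it more", {
  kappas <- vapply(c(0, 0.1, 0.25), function(p) {
    cfg <- cohort_config(n = 2000, seed = 35,
                         misreport = misreport_spec(p_flip_q = p,
                                                    direction = "symmetric"))
    co <- generate_cohort(cfg)
    v <- validate_items(score_cohort(co$questionnaire),
                        derive_ffq_scores(co$ffq))
    mean(v$kappa[v$item != "total"], na.rm = TRUE)
  }, numeric(1))
  expect_equal(kappas[1], 1)
  expect_true(all(diff(kappas) < 0))
})

test_that("validation report keeps zero-variance items, flagged undefined", {
  # four children all fully adherent on both instruments: every item is
  # constant on both methods, so every kappa is undefined but rows remain
  q4 <- dplyr::bind_rows(replicate(4, adherent_response(), simplify = FALSE))
  q4$child_id <- paste0("c", 1:4)
  f4 <- tibble::tibble(
    child_id = q4$child_id, olive_oil_main_fat = 1, olive_oil = 40,
    vegetables = 300, fruits = 400, freq_whole_grains = 7,
    fermented_dairy = 300, legumes = 40, fish_seafood = 60, nuts = 15,
    freq_white_meat = 5, freq_red_processed_meat = 0, butter_cream = 0,
    sugared_beverages = 0, freq_sweets_snacks = 0, freq_dairy_desserts = 0,
    freq_pastries = 0, freq_precooked = 0
  )
  v <- validate_items(score_cohort(q4), derive_ffq_scores(f4))
  expect_equal(nrow(v), 18L)  # 17 items + total row
  expect_true(all(v$undefined))
  expect_true(all(is.na(v$kappa)))
  expect_true(all(v$pct_agreement == 1))
})
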