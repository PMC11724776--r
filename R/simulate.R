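#' Default item prevalences for the calibrated cohort
#'
#' Fractions of children expected to score 1 on each item under the
#' administered questionnaire, used as calibration targets for the latent
#' trait model. Values for the 17 validated items are the prevalences
#' observed in the instrument's validation cohort; the sofrito item (11),
#' for which no prevalence was published, defaults to 0.60.
#'
#' @return Named numeric vector of length 18 (names `"1"`–`"18"`).
#' @export
default_item_marginals <- function() {
  c(`1` = .963, `2` = .677, `3` = .449, `4` = .399, `5` = .400, `6` = .599,
    `7` = .795, `8` = .600, `9` = .261, `10` = .826, `11` = .600, `12` = .572,
    `13` = .857, `14` = .721, `15` = .448, `16` = .418, `17` = .458,
    `18` = .717)
}

#' Calibrate item base rates to target marginal prevalences
#'
#' Items are Bernoulli with probability `plogis(base + loading * trait)`,
#' trait ~ Normal(0, trait_sd). For each item this solves for the base logit
#' whose implied marginal prevalence (integrating over the trait) equals the
#' target, by quadrature + root finding. With zero loading the solution is
#' simply `qlogis(target)`.
#'
#' @param target_marginals Named vector of target prevalences in (0, 1).
#' @param loadings Trait loadings, recycled to the targets' length.
#' @param trait_sd Latent trait standard deviation.
#' @return Named vector of base logits.
#' @examples
#' calibrate_to_marginals(c(`1` = 0.5), loadings = 0)  # 0
#' @export
calibrate_to_marginals <- function(target_marginals, loadings = 1,
                                   trait_sd = 1) {
  if (any(target_marginals <= 0 | target_marginals >= 1)) {
    stop("target marginals must lie strictly inside (0, 1)")
  }
  loadings <- rep_len(loadings, length(target_marginals))
  marginal_p <- function(b, lam) {
    if (lam == 0 || trait_sd == 0) return(stats::plogis(b))
    stats::integrate(function(z) {
      stats::plogis(b + lam * trait_sd * z) * stats::dnorm(z)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  out <- vapply(seq_along(target_marginals), function(i) {
    stats::uniroot(function(b) marginal_p(b, loadings[i]) - target_marginals[i],
                   lower = -30, upper = 30, tol = 1e-10)$root
  }, numeric(1))
  names(out) <- names(target_marginals)
  out
}

#' Misreporting specification
#'
#' Per-item probabilities of reporting an item state different from the true
#' one, separately for the administered questionnaire and the FFQ, with a
#' desirability direction: `"toward_point"` flips only non-compliant states
#' to compliant (social desirability — over-reporting healthy consumption or
#' under-reporting unhealthy consumption both move the indicator toward 1),
#' `"away_from_point"` the reverse, `"symmetric"` flips either way.
#'
#' @param p_flip_q,p_flip_ffq Flip probabilities in \[0, 1\], recycled over
#'   the 18 items.
#' @param direction One of `"toward_point"`, `"away_from_point"`,
#'   `"symmetric"`, recycled.
#' @return A tibble with columns `item_id`, `p_flip_q`, `p_flip_ffq`,
#'   `direction`.
#' @export
misreport_spec <- function(p_flip_q = 0, p_flip_ffq = 0,
                           direction = "toward_point") {
  tibble::tibble(
    item_id = 1:18,
    p_flip_q = rep_len(p_flip_q, 18L),
    p_flip_ffq = rep_len(p_flip_ffq, 18L),
    direction = rep_len(direction, 18L)
  )
}

#' Default outcome-effect parameters
#'
#' Linear effects of the true adherence score on each cardiometabolic
#' outcome: intercept, per-point slope, residual SD, and age/sex effects.
#' Signs follow the pattern reported for the instrument (negative for waist
#' circumference, triglycerides, HOMA-IR and BMI; positive for HDL and LDL
#' cholesterol); magnitudes are this package's own defaults, not published
#' values.
#'
#' @return Named list of per-outcome parameter lists
#'   `(intercept, beta, sd, age_coef, sex_coef)`.
#' @export
default_outcome_effects <- function() {
  eff <- function(intercept, beta, sd, age_coef = 0, sex_coef = 0) {
    list(intercept = intercept, beta = beta, sd = sd,
         age_coef = age_coef, sex_coef = sex_coef)
  }
  list(
    bmi = eff(16.4, -0.05, 1.9, age_coef = 0.3, sex_coef = 0.2),
    bmi_z = eff(0.4, -0.02, 1.3, sex_coef = 0.2),
    wc = eff(51.7, -0.15, 6.0, age_coef = 2.0, sex_coef = 0.3),
    sbp = eff(103.9, 0, 12.5, age_coef = 1.0),
    dbp = eff(64.0, 0, 11.5, age_coef = 0.5),
    total_chol = eff(164, 1.0, 22),
    hdl = eff(56, 0.3, 11),
    ldl = eff(95, 1.0, 20, sex_coef = 1),
    tg = eff(53, -0.5, 17, sex_coef = 3),
    glucose = eff(76, 0, 8, age_coef = 0.5, sex_coef = -1),
    homa = eff(0.85, -0.02, 0.35, sex_coef = 0.15)
  )
}

#' Configuration for a synthetic cohort
#'
#' A one-dimensional latent adherence trait drives all 18 item states;
#' observed questionnaire answers and FFQ intakes are drawn consistently
#' with (possibly misreported) item states; outcomes are linear in the true
#' score with Gaussian noise. Defaults emulate the instrument's validation
#' setting: children aged 3–6 years, 50.3% girls, item prevalences from
#' [default_item_marginals()].
#'
#' @param n Cohort size.
#' @param seed Integer seed; regeneration with the same config is
#'   bit-identical.
#' @param trait_sd Latent trait SD.
#' @param item_loadings Slopes of item logits on the trait (length 18 or
#'   recycled).
#' @param item_marginals Target marginal prevalences (length 18, in (0,1)).
#' @param misreport Misreporting table from [misreport_spec()].
#' @param outcome_effects See [default_outcome_effects()].
#' @param age_range Two ages in years, uniform sampling range.
#' @param girl_frac Fraction of girls.
#' @return A validated config list of class `med4child_config`.
#' @export
cohort_config <- function(n = 858L, seed = 1L, trait_sd = 1,
                          item_loadings = rep(1, 18L),
                          item_marginals = default_item_marginals(),
                          misreport = misreport_spec(),
                          outcome_effects = default_outcome_effects(),
                          age_range = c(3, 6),
                          girl_frac = 0.503) {
  item_loadings <- rep_len(item_loadings, 18L)
  stopifnot(
    n >= 1, trait_sd > 0,
    length(item_marginals) == 18L,
    all(item_marginals > 0 & item_marginals < 1),
    nrow(misreport) == 18L,
    all(misreport$p_flip_q >= 0 & misreport$p_flip_q <= 1),
    all(misreport$p_flip_ffq >= 0 & misreport$p_flip_ffq <= 1),
    all(misreport$direction %in%
          c("toward_point", "away_from_point", "symmetric")),
    length(age_range) == 2L, age_range[1] <= age_range[2],
    girl_frac >= 0, girl_frac <= 1,
    all(vapply(outcome_effects, function(e) e$sd > 0, logical(1)))
  )
  structure(list(
    n = as.integer(n), seed = as.integer(seed), trait_sd = trait_sd,
    item_loadings = item_loadings, item_marginals = item_marginals,
    misreport = misreport, outcome_effects = outcome_effects,
    age_range = age_range, girl_frac = girl_frac
  ), class = "med4child_config")
}

#' Preset cohort configurations
#'
#' * `"null"` — items independent of the trait (zero loadings, 50%
#'   marginals), no misreporting, zero outcome effects.
#' * `"calibrated"` — item prevalences calibrated to
#'   [default_item_marginals()], no misreporting, default outcome effects.
#' * `"biased"` — as calibrated, plus social-desirability misreporting on
#'   the administered questionnaire: strong toward-point flips (p = 0.30)
#'   on the unhealthy restraint items (12–18) and mild symmetric noise
#'   (p = 0.05) elsewhere.
#'
#' @param preset Preset name.
#' @param n,seed Passed to [cohort_config()].
#' @return A `med4child_config`.
#' @export
cohort_preset <- function(preset = c("null", "calibrated", "biased"),
                          n = 858L, seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    null = cohort_config(
      n = n, seed = seed, item_loadings = rep(0, 18L),
      item_marginals = stats::setNames(rep(0.5, 18L), 1:18),
      outcome_effects = lapply(default_outcome_effects(), function(e) {
        e$beta <- 0; e
      })
    ),
    calibrated = cohort_config(n = n, seed = seed),
    biased = {
      mis <- misreport_spec(
        p_flip_q = ifelse(1:18 %in% 12:18, 0.30, 0.05),
        p_flip_ffq = 0,
        direction = ifelse(1:18 %in% 12:18, "toward_point", "symmetric")
      )
      cohort_config(n = n, seed = seed, misreport = mis)
    }
  )
}

# flip true 0/1 states according to a misreporting row
apply_flips <- function(state, p, direction) {
  if (p == 0) return(state)
  u <- stats::runif(length(state))
  switch(direction,
    toward_point = ifelse(state == 0L & u < p, 1L, state),
    away_from_point = ifelse(state == 1L & u < p, 0L, state),
    symmetric = ifelse(u < p, 1L - state, state)
  )
}

# plausible upper bounds for questionnaire quantity draws, by item
questionnaire_bounds <- function() {
  c(`2` = 8, `3` = 6, `4` = 8, `5` = 14, `6` = 4, `7` = 10, `8` = 10,
    `9` = 10, `11` = 10, `12` = 10, `13` = 4, `14` = 14, `15` = 10,
    `16` = 10, `17` = 10, `18` = 7)
}

# plausible gram/day upper bounds for FFQ food-group draws
ffq_bounds <- function() {
  c(vegetables = 400, fruits = 600, olive_oil = 60, butter_cream = 40,
    fermented_dairy = 500, legumes = 80, fish_seafood = 120, nuts = 30,
    sugared_beverages = 500)
}

# quantity consistent with a 0/1 state: uniform on the satisfying
# (or violating) side of the threshold, inside [0, upper]
draw_quantity <- function(state, threshold, upper, direction) {
  stopifnot(upper > threshold)
  n <- length(state)
  satisfies <- state == 1L
  lo_sat <- if (direction == "less_than") 0 else threshold
  hi_sat <- if (direction == "less_than") threshold else upper
  lo_vio <- if (direction == "less_than") threshold else 0
  hi_vio <- if (direction == "less_than") upper else threshold
  u <- stats::runif(n)
  ifelse(satisfies, lo_sat + u * (hi_sat - lo_sat),
         lo_vio + u * (hi_vio - lo_vio))
}

#' Generate a synthetic validation cohort
#'
#' Draws a latent adherence trait per child, Bernoulli item states with
#' trait-dependent probabilities calibrated to the configured marginals,
#' then observed questionnaire quantities and FFQ gram/frequency intakes
#' consistent with the (possibly misreported) states, and cardiometabolic
#' outcomes linear in the true score. With zero misreporting the
#' questionnaire-scored and FFQ-derived item vectors both reproduce the
#' truth exactly, so every validation kappa is 1.
#'
#' @param config A [cohort_config()].
#' @return A list of class `med4child_cohort`: tibbles `truth`,
#'   `questionnaire`, `ffq`, `outcomes`, plus `config` and `hash` (a digest
#'   of the four tables for reproducibility checks).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "med4child_config"))
  set.seed(config$seed)
  n <- config$n
  reg <- med4child_registry()
  map <- ffq_mapping()
  child_id <- sprintf("child_%05d", seq_len(n))

  trait <- stats::rnorm(n, 0, config$trait_sd)
  base <- calibrate_to_marginals(config$item_marginals,
                                 config$item_loadings, config$trait_sd)
  truth <- matrix(NA_integer_, n, 18L,
                  dimnames = list(NULL, sprintf("item_%02d", 1:18)))
  for (i in 1:18) {
    p <- stats::plogis(base[i] + config$item_loadings[i] * trait)
    truth[, i] <- stats::rbinom(n, 1L, p)
  }

  q_state <- truth
  f_state <- truth
  for (i in 1:18) {
    mis <- config$misreport[config$misreport$item_id == i, ]
    q_state[, i] <- apply_flips(truth[, i], mis$p_flip_q, mis$direction)
    f_state[, i] <- apply_flips(truth[, i], mis$p_flip_ffq, mis$direction)
  }

  ## --- questionnaire answers -------------------------------------------
  qb <- questionnaire_bounds()
  questionnaire <- tibble::tibble(child_id = child_id)
  for (i in 1:18) {
    crit <- reg[reg$item_id == i, ]
    col <- sprintf("q%02d", i)
    if (crit$unit == "binary_preference") {
      questionnaire[[col]] <- as.numeric(q_state[, i])
    } else {
      questionnaire[[col]] <- draw_quantity(
        q_state[, i], crit$threshold, qb[[as.character(i)]], crit$direction)
    }
  }
  # raw/salad sub-answer: >= 1 serving/week whenever item 3 is compliant
  questionnaire$q03_raw <- ifelse(q_state[, 3] == 1L,
                                  1 + stats::runif(n) * 6, 0)

  ## --- FFQ intakes ------------------------------------------------------
  fb <- ffq_bounds()
  gram_thresh <- function(id) {
    m <- map[map$item_id == id, ]
    crit <- reg[reg$item_id == id, ]
    thr <- crit$threshold * m$grams_per_serving
    if (item_period(crit$unit) == "week") thr / 7 else thr
  }
  ffq <- tibble::tibble(child_id = child_id)
  # gram-mode items: draw the food-group intake on the correct side
  for (id in c(3, 4, 6, 7, 8, 9)) {
    m <- map[map$item_id == id, ]
    ffq[[m$food_group]] <- draw_quantity(f_state[, id], gram_thresh(id),
                                         fb[[m$food_group]], "at_least")
  }
  ffq$olive_oil <- draw_quantity(f_state[, 2], gram_thresh(2),
                                 fb[["olive_oil"]], "at_least")
  ffq$butter_cream <- draw_quantity(f_state[, 13], gram_thresh(13),
                                    fb[["butter_cream"]], "less_than")
  ffq$sugared_beverages <- draw_quantity(f_state[, 14], gram_thresh(14),
                                         fb[["sugared_beverages"]],
                                         "less_than")
  ffq$olive_oil_main_fat <- as.numeric(f_state[, 1])
  # frequency-mode items: occasions/week on the correct side, grams scaled
  for (id in c(5, 15, 16, 17, 18)) {
    m <- map[map$item_id == id, ]
    crit <- reg[reg$item_id == id, ]
    freq <- draw_quantity(f_state[, id], crit$threshold, 14, crit$direction)
    ffq[[paste0("freq_", m$food_group)]] <- freq
    ffq[[m$food_group]] <- freq * m$grams_per_serving / 7
  }
  # red meat (item 12) then white-meat preference (item 10) relative to it
  crit12 <- reg[reg$item_id == 12, ]
  red <- draw_quantity(f_state[, 12], crit12$threshold, 10, "less_than")
  white <- ifelse(f_state[, 10] == 1L,
                  red + 0.25 + stats::runif(n) * 7,
                  stats::runif(n) * pmax(red, 1e-6) * 0.99)
  ffq$freq_red_processed_meat <- red
  ffq$red_processed_meat <- red * 50 / 7
  ffq$freq_white_meat <- white
  ffq$white_meat <- white * 60 / 7
  # groups not scored by any item, for quartile summaries
  ffq$refined_cereals <- pmax(70 - 6 * trait + stats::rnorm(n, 0, 15), 0)
  ffq$energy_kcal_day <- pmax(stats::rnorm(n, 1819, 567), 500)

  ## --- outcomes ---------------------------------------------------------
  total_true <- as.integer(rowSums(truth))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  girl <- stats::rbinom(n, 1L, config$girl_frac)
  outcomes <- tibble::tibble(
    child_id = child_id, age = age,
    sex = factor(ifelse(girl == 1L, "girl", "boy"),
                 levels = c("boy", "girl"))
  )
  for (nm in names(config$outcome_effects)) {
    if (nm %in% c("homa", "insulin")) next
    e <- config$outcome_effects[[nm]]
    outcomes[[nm]] <- e$intercept + e$beta * total_true +
      e$age_coef * (age - mean(config$age_range)) + e$sex_coef * girl +
      stats::rnorm(n, 0, e$sd)
  }
  outcomes$glucose <- pmax(outcomes$glucose, 50)
  eh <- config$outcome_effects$homa
  outcomes$homa <- pmax(
    eh$intercept + eh$beta * total_true + eh$age_coef * (age - mean(config$age_range)) +
      eh$sex_coef * girl + stats::rnorm(n, 0, eh$sd),
    0.02
  )
  # insulin back-derived so that homa = insulin * glucose / 405 holds exactly
  outcomes$insulin <- outcomes$homa * 405 / outcomes$glucose

  truth_tbl <- tibble::tibble(child_id = child_id, trait = trait) |>
    dplyr::bind_cols(tibble::as_tibble(truth)) |>
    dplyr::mutate(total_true = total_true)

  out <- list(truth = truth_tbl, questionnaire = questionnaire,
              ffq = ffq, outcomes = outcomes, config = config)
  out$hash <- rlang::hash(list(out$truth, out$questionnaire,
                               out$ffq, out$outcomes))
  class(out) <- "med4child_cohort"
  out
}

#' @export
print.med4child_cohort <- function(x, ...) {
  cat("<med4child synthetic cohort>\n")
  cat("  n =", x$config$n, " seed =", x$config$seed, "\n")
  cat("  mean true score:", round(mean(x$truth$total_true), 2), "\n")
  cat("  hash:", x$hash, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the truth, questionnaire, FFQ and outcome tables as CSV plus a
#' YAML snapshot of the scalar configuration (n, seed, trait SD, marginals,
#' misreporting, age range, sex ratio).
#'
#' @param cohort A `med4child_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "med4child_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    truth = file.path(dir, "truth.csv"),
    questionnaire = file.path(dir, "questionnaire.csv"),
    ffq = file.path(dir, "ffq.csv"),
    outcomes = file.path(dir, "outcomes.csv")
  )
  readr::write_csv(cohort$truth, paths["truth"])
  readr::write_csv(cohort$questionnaire, paths["questionnaire"])
  readr::write_csv(cohort$ffq, paths["ffq"])
  readr::write_csv(cohort$outcomes, paths["outcomes"])
  cfg <- cohort$config
  snapshot <- list(
    n = cfg$n, seed = cfg$seed, trait_sd = cfg$trait_sd,
    item_loadings = as.numeric(cfg$item_loadings),
    item_marginals = as.numeric(cfg$item_marginals),
    misreport = lapply(seq_len(nrow(cfg$misreport)), function(i) {
      as.list(cfg$misreport[i, ])
    }),
    age_range = cfg$age_range, girl_frac = cfg$girl_frac,
    hash = cohort$hash
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(snapshot, cfg_path)
  invisible(c(paths, config = cfg_path))
}
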