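#' HOMA-IR insulin-resistance index
#'
#' Homeostatic model assessment of insulin resistance from fasting values:
#' insulin (microU/mL) x glucose (mg/dL) / 405.
#'
#' @param glucose_mg_dl Fasting glucose, mg/dL (> 0).
#' @param insulin_microU_ml Fasting insulin, microU/mL (>= 0).
#' @return HOMA-IR (dimensionless), vectorised.
#' @examples
#' homa_ir(90, 4.5)  # 1
#' @export
homa_ir <- function(glucose_mg_dl, insulin_microU_ml) {
  if (any(glucose_mg_dl <= 0, na.rm = TRUE)) {
    stop("glucose must be positive")
  }
  if (any(insulin_microU_ml < 0, na.rm = TRUE)) {
    stop("insulin must be non-negative")
  }
  insulin_microU_ml * glucose_mg_dl / 405
}

#' Food and nutrient intakes by score quartile
#'
#' Per-quartile means with 95% confidence intervals, one-way ANOVA p-value,
#' and a p-for-trend from ordinary least squares of the variable on the
#' integer quartile rank (1-4).
#'
#' @param data Data frame containing a `quartile` factor (see
#'   [assign_quartile()]) and the variables to summarise, e.g. the FFQ table
#'   joined to [score_cohort()] output.
#' @param variables Character vector of column names to summarise.
#' @return A tibble, one row per variable x quartile, with `mean`, `ci_low`,
#'   `ci_high`, `n`, plus variable-level `p_anova`, `p_trend` and
#'   `trend_slope` repeated across the rows; zero-variance variables are
#'   flagged via `degenerate` with NA p-values.
#' @export
quartile_summary <- function(data, variables) {
  stopifnot("quartile" %in% names(data))
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    stop("variables not in data: ", paste(missing_vars, collapse = ", "))
  }
  d <- data[!is.na(data$quartile), ]
  if (length(unique(d$quartile)) < 2) stop("need >= 2 non-empty quartile groups")

  purrr::map_dfr(variables, function(v) {
    x <- d[[v]]
    keep <- !is.na(x)
    x <- x[keep]; q <- droplevels(d$quartile[keep])
    degenerate <- stats::var(x) == 0
    if (degenerate) {
      p_anova <- NA_real_; p_trend <- NA_real_; slope <- NA_real_
    } else {
      p_anova <- stats::anova(stats::aov(x ~ q))[["Pr(>F)"]][1]
      fit <- stats::lm(x ~ as.integer(q))
      ct <- summary(fit)$coefficients
      slope <- ct[2, 1]; p_trend <- ct[2, 4]
    }
    by_q <- tibble::tibble(x = x, quartile = q) |>
      dplyr::group_by(quartile) |>
      dplyr::summarise(
        mean = mean(x), n = dplyr::n(),
        se = stats::sd(x) / sqrt(dplyr::n()), .groups = "drop"
      ) |>
      dplyr::mutate(
        ci_low = mean - stats::qt(0.975, pmax(n - 1, 1)) * se,
        ci_high = mean + stats::qt(0.975, pmax(n - 1, 1)) * se
      )
    by_q$variable <- v
    by_q$p_anova <- p_anova
    by_q$p_trend <- p_trend
    by_q$trend_slope <- slope
    by_q$degenerate <- degenerate
    dplyr::select(by_q, "variable", "quartile", "n", "mean",
                  "ci_low", "ci_high", "p_anova", "p_trend",
                  "trend_slope", "degenerate")
  })
}

#' Covariate-adjusted association between score and an outcome
#'
#' Ordinary least squares of the outcome on the total score plus covariates
#' (default age and sex, the study's adjustment set). Reports the
#' unstandardized per-point coefficient with its 95% CI and p-value, and a
#' separately labelled standardized coefficient (beta x SD(score)/SD(outcome));
#' the two are never mixed in one column pair.
#'
#' @param data Data frame with `total`, the outcome, and the covariates; sex
#'   may be a factor/character (encoded as a single indicator) or numeric.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate columns (default
#'   `c("age", "sex")`; may be empty).
#' @param min_n Minimum complete cases required (default 10).
#' @return One-row tibble: `outcome`, `n`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `beta_std`, `covariates`.
#' @export
adjusted_association <- function(data, outcome,
                                 covariates = c("age", "sex"),
                                 min_n = 10L) {
  needed <- c("total", outcome, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[needed]), needed, drop = FALSE]
  if (nrow(d) < max(min_n, length(covariates) + 3L)) {
    stop("too few complete cases for ", outcome, " (n = ", nrow(d), ")")
  }
  fit <- stats::lm(stats::reformulate(c("total", covariates),
                                      response = outcome), data = d)
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design for ", outcome, " (collinear covariates)")
  }
  ct <- summary(fit)$coefficients
  ci <- stats::confint(fit)["total", ]
  beta <- ct["total", 1]
  tibble::tibble(
    outcome = outcome,
    n = nrow(d),
    beta = beta,
    se = ct["total", 2],
    ci_low = ci[[1]],
    ci_high = ci[[2]],
    p_value = ct["total", 4],
    beta_std = beta * stats::sd(d$total) / stats::sd(d[[outcome]]),
    covariates = paste(covariates, collapse = "+")
  )
}

#' Sensitivity analysis excluding selected items
#'
#' Recomputes the total score without the given items (typically the
#' unhealthy, restraint-direction items flagged by the Bland-Altman
#' comparison) and refits the adjusted association for every outcome, side
#' by side with the full-score fits.
#'
#' @param items_to_drop Item ids removed from the score.
#' @param questionnaire Questionnaire answers (see [score_cohort()]).
#' @param outcomes_data Outcome table with `child_id`, covariates, outcomes.
#' @param outcomes Character vector of outcome columns to model.
#' @param registry Item registry.
#' @inheritParams adjusted_association
#' @return A tibble of [adjusted_association()] rows with an `analysis`
#'   column, `"full"` vs `"reduced"`.
#' @export
sensitivity_exclude <- function(items_to_drop, questionnaire, outcomes_data,
                                outcomes, registry = med4child_registry(),
                                covariates = c("age", "sex")) {
  items_to_drop <- as.integer(items_to_drop)
  if (!all(items_to_drop %in% registry$item_id)) {
    stop("items_to_drop outside the registry")
  }
  kept <- setdiff(registry$item_id, items_to_drop)
  if (!length(kept)) stop("cannot drop every item from the score")

  assoc_for <- function(items_used, label) {
    sc <- score_cohort(questionnaire, registry, items_used = items_used)
    d <- dplyr::inner_join(sc[c("child_id", "total")], outcomes_data,
                           by = "child_id")
    purrr::map_dfr(outcomes, function(o) {
      adjusted_association(d, o, covariates = covariates)
    }) |>
      dplyr::mutate(analysis = label, items = length(items_used))
  }
  dplyr::bind_rows(
    assoc_for(registry$item_id, "full"),
    assoc_for(kept, "reduced")
  )
}

#' Descriptive characteristics, optionally by group
#'
#' Mean +/- SD with a two-sample t-test for approximately normal variables;
#' variables flagged as skewed are reported as median (P25-P75) with a
#' Wilcoxon rank-sum test. Skewness routing is declared by the caller (not
#' auto-detected) so output is deterministic.
#'
#' @param data Data frame of measurements.
#' @param variables Character vector of columns to describe.
#' @param by Optional name of a two-level grouping column (e.g. `sex`).
#' @param skewed Variables (subset of `variables`) to summarise as
#'   median/IQR with a rank-based test.
#' @return A tibble with one row per variable (x group when `by` is given):
#'   `summary` ("mean_sd" or "median_iqr"), location/spread columns and, for
#'   grouped calls, the two-group `p_value`.
#' @export
describe_cohort <- function(data, variables, by = NULL, skewed = character()) {
  stopifnot(all(variables %in% names(data)),
            all(skewed %in% variables))
  summarise_one <- function(x, v) {
    x <- x[!is.na(x)]
    if (v %in% skewed) {
      tibble::tibble(variable = v, summary = "median_iqr", n = length(x),
                     location = stats::median(x),
                     spread_low = stats::quantile(x, .25, names = FALSE),
                     spread_high = stats::quantile(x, .75, names = FALSE))
    } else {
      tibble::tibble(variable = v, summary = "mean_sd", n = length(x),
                     location = mean(x), spread_low = mean(x) - stats::sd(x),
                     spread_high = mean(x) + stats::sd(x))
    }
  }
  if (is.null(by)) {
    return(purrr::map_dfr(variables, function(v) summarise_one(data[[v]], v)))
  }
  stopifnot(by %in% names(data))
  g <- factor(data[[by]])
  if (nlevels(g) != 2) stop("grouped description needs exactly 2 levels")
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    x1 <- x[keep & g == levels(g)[1]]
    x2 <- x[keep & g == levels(g)[2]]
    if (length(x1) < 2 || length(x2) < 2) stop("need n >= 2 per group for ", v)
    p <- if (v %in% skewed) {
      stats::wilcox.test(x1, x2, exact = FALSE)$p.value
    } else {
      stats::t.test(x1, x2, var.equal = TRUE)$p.value
    }
    dplyr::bind_rows(
      summarise_one(x1, v) |> dplyr::mutate(group = levels(g)[1]),
      summarise_one(x2, v) |> dplyr::mutate(group = levels(g)[2])
    ) |>
      dplyr::mutate(p_value = p)
  })
}
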