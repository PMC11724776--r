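#' Read and validate a delimited input table
#'
#' Reads a CSV with a header, renames columns to canonical names through an
#' optional dictionary, checks that mandatory columns are present, and
#' quarantines malformed rows (negative values in columns that must be
#' non-negative) instead of silently keeping them.
#'
#' @param path CSV file path.
#' @param dictionary Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(vegetables = "veg_g_day")`.
#' @param required Canonical column names that must be present; a schema
#'   error naming the missing ones is raised otherwise.
#' @param nonneg Canonical columns whose values must be non-negative; rows
#'   violating this are removed and attached as the `"quarantined"`
#'   attribute together with a reason.
#' @return A tibble; quarantined rows (possibly empty) in
#'   `attr(, "quarantined")`.
#' @export
read_table <- function(path, dictionary = NULL, required = NULL,
                       nonneg = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dictionary)) {
    present <- dictionary[dictionary %in% names(tbl)]
    if (length(present)) tbl <- dplyr::rename(tbl, !!!present)
  }
  if (!is.null(required)) {
    missing_cols <- setdiff(required, names(tbl))
    if (length(missing_cols)) {
      stop("schema error in ", path, ": missing mandatory column(s) ",
           paste(missing_cols, collapse = ", "))
    }
  }
  quarantined <- tbl[0, ]
  reason <- character()
  for (col in intersect(nonneg, names(tbl))) {
    bad <- !is.na(tbl[[col]]) & tbl[[col]] < 0
    if (any(bad)) {
      quarantined <- dplyr::bind_rows(quarantined, tbl[bad, ])
      reason <- c(reason, rep(paste0("negative ", col), sum(bad)))
      tbl <- tbl[!bad, ]
    }
  }
  quarantined$reason <- reason
  attr(tbl, "quarantined") <- quarantined
  tbl
}

#' Complete-case exclusion accounting
#'
#' Applies the analysis set's complete-case policy step by step and logs the
#' count excluded at each step, in the order: incomplete administered
#' questionnaire, incomplete FFQ, missing BMI, missing biochemical
#' parameters. The log mirrors the enrolled - excluded = analysed style of
#' participant-flow reporting.
#'
#' @param questionnaire,ffq,outcomes Input tables sharing `child_id`; the
#'   questionnaire table defines the enrolled set.
#' @param registry,mapping Item registry and FFQ mapping.
#' @param bmi_col Outcome column holding BMI.
#' @param biochem_cols Outcome columns all required for the biochemical
#'   panel.
#' @return A list: `log` (tibble with `step`, `n_excluded`, `n_remaining`),
#'   `analysed_ids`, `n_enrolled`, `n_excluded`, `n_analysed`, and
#'   `pct_girls` among the analysed (NA when `sex` is absent).
#' @export
exclusion_flow <- function(questionnaire, ffq, outcomes,
                           registry = med4child_registry(),
                           mapping = ffq_mapping(),
                           bmi_col = "bmi",
                           biochem_cols = c("total_chol", "hdl", "ldl",
                                            "tg", "glucose", "insulin")) {
  ids <- questionnaire$child_id
  n0 <- length(ids)
  log <- tibble::tibble(step = "enrolled", n_excluded = 0L, n_remaining = n0)
  drop_step <- function(ids, lost, step) {
    log <<- dplyr::bind_rows(log, tibble::tibble(
      step = step, n_excluded = length(lost),
      n_remaining = length(ids) - length(lost)))
    setdiff(ids, lost)
  }

  sq <- score_cohort(questionnaire, registry, policy = "complete_case")
  ids <- drop_step(ids, sq$child_id[sq$excluded], "missing_questionnaire")

  sf <- derive_ffq_scores(ffq, registry, mapping, policy = "complete_case")
  ffq_ok <- sf$child_id[!sf$excluded]
  ids <- drop_step(ids, setdiff(ids, ffq_ok), "missing_ffq")

  bmi_ok <- outcomes$child_id[!is.na(outcomes[[bmi_col]])]
  ids <- drop_step(ids, setdiff(ids, bmi_ok), "missing_bmi")

  bio_ok <- outcomes$child_id[
    stats::complete.cases(outcomes[, biochem_cols, drop = FALSE])]
  ids <- drop_step(ids, setdiff(ids, bio_ok), "missing_biochemical")

  pct_girls <- if ("sex" %in% names(outcomes)) {
    sx <- outcomes$sex[match(ids, outcomes$child_id)]
    100 * mean(sx == "girl")
  } else {
    NA_real_
  }
  list(log = log, analysed_ids = ids, n_enrolled = n0,
       n_excluded = n0 - length(ids), n_analysed = length(ids),
       pct_girls = pct_girls)
}

#' Pipeline run configuration
#'
#' Bundles the inputs and options of a full relative-validity run. Tables
#' may be given as in-memory data frames or CSV paths (read through
#' [read_table()] with the corresponding dictionary).
#'
#' @param questionnaire,ffq,outcomes Data frames or CSV paths.
#' @param dictionaries Optional named list of column dictionaries
#'   (`questionnaire`, `ffq`, `outcomes`), see [read_table()].
#' @param registry_path,mapping_path Optional YAML overrides for the item
#'   registry and FFQ mapping.
#' @param cutpoints Quartile cut points (see [assign_quartile()]).
#' @param cutoff Dichotomy cutoff.
#' @param policy Missing-data policy.
#' @param validation_items Item ids validated against the FFQ.
#' @param total_mode Total-score comparison mode, see [validate_items()].
#' @param sensitivity_items Items dropped in the sensitivity analysis
#'   (default the unhealthy restraint items 12-18).
#' @param outcome_vars Outcome columns modelled by [adjusted_association()].
#' @param quartile_vars FFQ columns summarised by quartile.
#' @param covariates Adjustment covariates.
#' @param seed Seed stamped into the outputs.
#' @param out_dir Optional output directory for the report files.
#' @return A list of class `med4child_run_config`.
#' @export
pipeline_config <- function(questionnaire, ffq, outcomes,
                            dictionaries = list(),
                            registry_path = NULL, mapping_path = NULL,
                            cutpoints = c(9L, 12L, 14L), cutoff = 10L,
                            policy = "complete_case",
                            validation_items = derivable_items(),
                            total_mode = "matched_items",
                            sensitivity_items = 12:18,
                            outcome_vars = c("bmi", "wc", "hdl", "ldl",
                                             "tg", "total_chol", "homa"),
                            quartile_vars = c("vegetables", "fruits",
                                              "olive_oil", "fish_seafood",
                                              "nuts", "refined_cereals"),
                            covariates = c("age", "sex"),
                            seed = 1L, out_dir = NULL) {
  stopifnot(!is.unsorted(cutpoints))
  structure(
    list(questionnaire = questionnaire, ffq = ffq, outcomes = outcomes,
         dictionaries = dictionaries, registry_path = registry_path,
         mapping_path = mapping_path, cutpoints = cutpoints, cutoff = cutoff,
         policy = policy, validation_items = validation_items,
         total_mode = total_mode, sensitivity_items = sensitivity_items,
         outcome_vars = outcome_vars, quartile_vars = quartile_vars,
         covariates = covariates, seed = as.integer(seed), out_dir = out_dir),
    class = "med4child_run_config"
  )
}

resolve_table <- function(x, dictionary = NULL, required = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file does not exist: ", x)
    read_table(x, dictionary = dictionary, required = required)
  } else {
    tibble::as_tibble(x)
  }
}

#' Run the full relative-validity pipeline
#'
#' Stages, in order: input reading and schema checks, complete-case
#' exclusion accounting, questionnaire scoring, FFQ score derivation,
#' per-item and total agreement, Bland-Altman comparison of the totals
#' (administered minus FFQ-derived, on the matched item set), food-group
#' summaries by score quartile, age/sex-adjusted outcome associations, and
#' the sensitivity analysis excluding the configured items. Deterministic
#' given inputs and seed; every written output is stamped with the package
#' version and a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list: `flow`, `scores_q`, `scores_ffq`, `validation`,
#'   `bland_altman`, `quartiles`, `associations`, `sensitivity`,
#'   `config_hash`, `version`. Written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "med4child_run_config"))
  registry <- med4child_registry(config$registry_path)
  mapping <- ffq_mapping(config$mapping_path)
  dicts <- config$dictionaries

  q <- resolve_table(config$questionnaire, dicts$questionnaire,
                     required = c("child_id", sprintf("q%02d", 1:18)))
  f <- resolve_table(config$ffq, dicts$ffq, required = "child_id")
  o <- resolve_table(config$outcomes, dicts$outcomes, required = "child_id")
  if (!"homa" %in% names(o) && all(c("glucose", "insulin") %in% names(o))) {
    o$homa <- homa_ir(o$glucose, o$insulin)
  }

  flow <- exclusion_flow(q, f, o, registry, mapping)
  keep <- flow$analysed_ids
  q <- q[q$child_id %in% keep, ]
  f <- f[f$child_id %in% keep, ]
  o <- o[o$child_id %in% keep, ]

  scores_q <- score_cohort(q, registry, policy = config$policy,
                           cutoff = config$cutoff,
                           cutpoints = config$cutpoints)
  scores_ffq <- derive_ffq_scores(f, registry, mapping,
                                  items_used = config$validation_items,
                                  policy = config$policy,
                                  cutoff = config$cutoff,
                                  cutpoints = config$cutpoints)
  validation <- validate_items(scores_q, scores_ffq,
                               items = config$validation_items,
                               registry = registry, cutoff = config$cutoff,
                               total_mode = config$total_mode)

  merged <- dplyr::inner_join(scores_q, scores_ffq, by = "child_id",
                              suffix = c("_q", "_f"))
  cols <- sprintf("item_%02d", sort(as.integer(config$validation_items)))
  ba <- bland_altman(rowSums(merged[paste0(cols, "_q")]),
                     rowSums(merged[paste0(cols, "_f")]))

  qdata <- dplyr::inner_join(f, scores_q[c("child_id", "quartile")],
                             by = "child_id")
  quartiles <- quartile_summary(qdata,
                                intersect(config$quartile_vars, names(f)))

  adata <- dplyr::inner_join(scores_q[c("child_id", "total")], o,
                             by = "child_id")
  outcome_vars <- intersect(config$outcome_vars, names(o))
  associations <- purrr::map_dfr(outcome_vars, function(v) {
    adjusted_association(adata, v, covariates = config$covariates)
  })
  sensitivity <- sensitivity_exclude(config$sensitivity_items, q, o,
                                     outcomes = outcome_vars,
                                     registry = registry,
                                     covariates = config$covariates)

  result <- list(
    flow = flow, scores_q = scores_q, scores_ffq = scores_ffq,
    validation = validation,
    bland_altman = ba[c("mean_difference", "sd_difference",
                        "loa_low", "loa_high", "n")],
    bland_altman_pairs = ba$pairs,
    quartiles = quartiles, associations = associations,
    sensitivity = sensitivity,
    # hash the analytic configuration only; where outputs land is not
    # part of what was computed
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    version = as.character(utils::packageVersion("med4child"))
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  stamp <- tibble::tibble(
    package_version = result$version,
    config_hash = result$config_hash,
    seed = config$seed
  )
  readr::write_csv(result$flow$log, out("flow_log.csv"))
  readr::write_csv(result$validation, out("validation_report.csv"))
  readr::write_csv(tibble::as_tibble(result$bland_altman),
                   out("bland_altman.csv"))
  readr::write_csv(result$quartiles, out("quartile_summary.csv"))
  readr::write_csv(result$associations, out("associations.csv"))
  readr::write_csv(result$sensitivity, out("sensitivity.csv"))
  readr::write_csv(stamp, out("run_stamp.csv"))
  writeLines(c(
    paste0("med4child ", result$version),
    paste0("config hash: ", result$config_hash),
    paste0("enrolled: ", result$flow$n_enrolled),
    paste0("excluded: ", result$flow$n_excluded),
    paste0("analysed: ", result$flow$n_analysed),
    paste0("girls (%): ", format(result$flow$pct_girls))
  ), out("log.txt"))
  invisible(NULL)
}
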