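#' Load the FFQ-to-item mapping
#'
#' The mapping translates food-group intakes from a semi-quantitative FFQ
#' (grams/day per group, optionally eating occasions/week in `freq_<group>`
#' columns) into the MED4CHILD item indicators, so the same serving-size
#' criteria can be applied to both instruments. Serving-size ranges are
#' collapsed to their midpoints by default (65 g vegetables, 55 g fish,
#' 17.5 g nuts); a tablespoon of olive oil is 10 mL at 0.92 g/mL = 9.2 g;
#' a beverage glass is 200 g. All of these are editable in the YAML.
#'
#' @param path Path to a mapping YAML file; defaults to the one shipped with
#'   the package.
#' @return A tibble with columns `item_id`, `mode`, `food_group`,
#'   `versus_group`, `binary_column`, `grams_per_serving`.
#' @export
ffq_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ffq_mapping.yaml",
                        package = "med4child", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw$items, function(it) {
    tibble::tibble(
      item_id = as.integer(it$item_id),
      mode = it$mode,
      food_group = it$food_group %||% NA_character_,
      versus_group = it$versus_group %||% NA_character_,
      binary_column = it$binary_column %||% NA_character_,
      grams_per_serving = as.numeric(it$grams_per_serving %||% NA_real_)
    )
  })
}

#' Convert a gram intake to servings
#'
#' @param grams_per_day Non-negative intake in grams/day.
#' @param grams_per_serving Grams in one serving (> 0).
#' @param period `"day"` or `"week"`; weekly servings are daily servings
#'   times 7.
#' @return Servings per the requested period.
#' @examples
#' intake_to_servings(130, 65)          # 2 servings/day
#' intake_to_servings(20, 40, "week")   # 3.5 servings/week
#' @export
intake_to_servings <- function(grams_per_day, grams_per_serving,
                               period = c("day", "week")) {
  period <- match.arg(period)
  if (any(grams_per_serving <= 0, na.rm = TRUE)) {
    stop("grams_per_serving must be positive")
  }
  if (any(grams_per_day < 0, na.rm = TRUE)) {
    stop("grams_per_day must be non-negative")
  }
  s <- grams_per_day / grams_per_serving
  if (period == "week") s * 7 else s
}

# period implied by the item's answer unit
item_period <- function(unit) {
  if (unit %in% c("servings_per_day", "tablespoons_per_day")) "day" else "week"
}

# vectorised indicator for one item over an FFQ table; NA = missing input
ffq_item_points <- function(ffq, item_id, registry, mapping) {
  map <- mapping[mapping$item_id == item_id, ]
  crit <- registry[registry$item_id == item_id, ]
  stopifnot(nrow(map) == 1L, nrow(crit) == 1L)
  n <- nrow(ffq)
  if (map$mode == "none") {
    return(structure(rep(NA_integer_, n), reason = "not_derivable"))
  }

  col_or_na <- function(col) {
    if (!is.na(col) && col %in% names(ffq)) ffq[[col]] else rep(NA_real_, n)
  }

  value <- switch(map$mode,
    grams = {
      g <- col_or_na(map$food_group)
      intake_to_servings(g, map$grams_per_serving, item_period(crit$unit))
    },
    freq_grams = {
      freq <- col_or_na(paste0("freq_", map$food_group))
      g <- col_or_na(map$food_group)
      fallback <- intake_to_servings(g, map$grams_per_serving, "week")
      ifelse(is.na(freq), fallback, freq)
    },
    preference = {
      wf <- col_or_na(paste0("freq_", map$food_group))
      rf <- col_or_na(paste0("freq_", map$versus_group))
      wg <- intake_to_servings(col_or_na(map$food_group),
                               map$grams_per_serving, "week")
      rg <- intake_to_servings(col_or_na(map$versus_group),
                               map$grams_per_serving, "week")
      w <- ifelse(is.na(wf), wg, wf)
      r <- ifelse(is.na(rf), rg, rf)
      return(as.integer(w > r))
    },
    binary_grams = {
      b <- col_or_na(map$binary_column)
      og <- col_or_na(map$food_group)
      bg <- col_or_na(map$versus_group)
      return(as.integer(ifelse(is.na(b), og > bg, b == 1)))
    },
    stop("unknown mapping mode: ", map$mode)
  )

  # item 3's raw/salad sub-condition is not separable in group-level FFQ
  # data; the main threshold alone decides (documented mapping limitation)
  point <- switch(crit$direction,
    at_least  = value >= crit$threshold,
    less_than = value < crit$threshold,
    yes       = value >= 1
  )
  as.integer(point)
}

#' Derive one item indicator from an FFQ record
#'
#' Applies the item's scoring criterion to FFQ-derived servings. The sofrito
#' item (11) has no FFQ counterpart and returns `NA` carrying a
#' `"not_derivable"` reason attribute; missing food groups yield plain `NA`
#' (a missing-value signal, never silently 0).
#'
#' @param item_id Item id, 1–18.
#' @param record One-row data frame (or named list) of FFQ intakes.
#' @param registry Item registry, see [med4child_registry()].
#' @param mapping FFQ mapping, see [ffq_mapping()].
#' @return `1L`, `0L` or `NA_integer_`.
#' @examples
#' rec <- tibble::tibble(nuts = 7.5)
#' derive_item_from_ffq(9, rec)  # 7.5/17.5*7 = 3 servings/week -> 1
#' @export
derive_item_from_ffq <- function(item_id, record,
                                 registry = med4child_registry(),
                                 mapping = ffq_mapping()) {
  if (!is.data.frame(record)) record <- tibble::as_tibble(as.list(record))
  stopifnot(nrow(record) == 1L)
  ffq_item_points(record, as.integer(item_id), registry, mapping)
}

#' Derive reference scores from an FFQ table
#'
#' Computes the 17 derivable item indicators from FFQ intakes and totals
#' them into the reference score used for validation. Output has the same
#' shape as [score_cohort()]; the sofrito column `item_11` is all-`NA`.
#'
#' @param ffq Data frame with `child_id` plus food-group gram columns and
#'   optional `freq_<group>` / `olive_oil_main_fat` columns.
#' @inheritParams score_cohort
#' @param mapping FFQ mapping, see [ffq_mapping()].
#' @param items_used Item ids entering the reference total (default the 17
#'   derivable items).
#' @return A tibble with `child_id`, `item_01`...`item_18`, `total`,
#'   `quartile`, `adherence`, `excluded`.
#' @export
derive_ffq_scores <- function(ffq,
                              registry = med4child_registry(),
                              mapping = ffq_mapping(),
                              items_used = derivable_items(),
                              policy = c("complete_case", "score_zero"),
                              cutoff = 10L,
                              cutpoints = c(9L, 12L, 14L)) {
  policy <- match.arg(policy)
  stopifnot("child_id" %in% names(ffq))
  items_used <- sort(as.integer(items_used))
  not_derivable <- mapping$item_id[mapping$mode == "none"]
  if (any(items_used %in% not_derivable)) {
    stop("items_used includes non-derivable items: ",
         paste(intersect(items_used, not_derivable), collapse = ", "))
  }
  n <- nrow(ffq)
  pts <- matrix(NA_integer_, n, 18L,
                dimnames = list(NULL, sprintf("item_%02d", 1:18)))
  for (id in items_used) pts[, id] <- ffq_item_points(ffq, id, registry, mapping)

  used <- pts[, items_used, drop = FALSE]
  if (policy == "score_zero") used[is.na(used)] <- 0L
  total <- as.integer(rowSums(used))
  excluded <- apply(used, 1L, anyNA)
  total[excluded] <- NA_integer_

  tibble::tibble(child_id = ffq$child_id) |>
    dplyr::bind_cols(tibble::as_tibble(pts)) |>
    dplyr::mutate(
      total = total,
      quartile = assign_quartile(total, cutpoints = cutpoints),
      adherence = dichotomize(total, cutoff = cutoff),
      excluded = excluded
    )
}
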