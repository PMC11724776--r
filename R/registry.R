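#' Load the MED4CHILD item registry
#'
#' The registry encodes, for each of the 18 items of the MED4CHILD screener,
#' the machine-readable criterion that earns 1 point: the answer unit, the
#' comparison direction (`at_least`, `less_than` or `yes` for binary
#' preference items), the threshold, and — where the instrument defines one —
#' the serving size in grams (as a `[low, high]` interval, e.g. 40–70 g for
#' fish). Item 3 additionally carries an extra sub-condition (at least one
#' raw/salad vegetable serving per week).
#'
#' @param path Path to a registry YAML file. Defaults to the versioned
#'   registry shipped with the package.
#' @param item7_threshold Lower bound used for the legumes item, whose
#'   criterion is printed as a "2–3 or more servings a week" range. Defaults
#'   to 2 (the lower bound); set to 3 for the stricter reading.
#' @param item11_threshold Servings-per-week threshold for the sofrito item,
#'   whose criterion is not fixed by the instrument's published table;
#'   defaults to 2 (the analogue in the adult 14-item screener).
#'
#' @return A tibble with one row per item and columns `item_id`, `label`,
#'   `unit`, `direction`, `threshold`, `serving_g_low`, `serving_g_high`,
#'   `extra_condition`, and `healthy` (`TRUE` for items rewarding consumption,
#'   `FALSE` for items rewarding restraint).
#' @examples
#' reg <- med4child_registry()
#' reg[reg$item_id == 9, c("label", "threshold", "serving_g_low")]
#' @export
med4child_registry <- function(path = NULL,
                               item7_threshold = 2,
                               item11_threshold = 2) {
  if (is.null(path)) {
    path <- system.file("extdata", "med4child_items.yaml",
                        package = "med4child", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  reg <- purrr::map_dfr(raw$items, function(it) {
    sg <- it$serving_g
    tibble::tibble(
      item_id = as.integer(it$item_id),
      label = it$label,
      unit = it$unit,
      direction = as.character(it$direction),
      threshold = as.numeric(it$threshold),
      serving_g_low = if (is.null(sg)) NA_real_ else as.numeric(sg[[1]]),
      serving_g_high = if (is.null(sg)) NA_real_ else as.numeric(sg[[2]]),
      extra_condition = it$extra_condition %||% NA_character_
    )
  })
  reg$threshold[reg$item_id == 7L] <- as.numeric(item7_threshold)
  reg$threshold[reg$item_id == 11L] <- as.numeric(item11_threshold)
  reg$healthy <- reg$direction != "less_than"
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  stopifnot(
    nrow(reg) == 18L,
    !anyDuplicated(reg$item_id),
    all(reg$item_id %in% 1:18),
    all(reg$threshold >= 0),
    all(reg$direction %in% c("at_least", "less_than", "yes")),
    all(reg$unit %in% c("servings_per_day", "servings_per_week",
                        "times_per_week", "tablespoons_per_day",
                        "binary_preference"))
  )
  sg <- !is.na(reg$serving_g_low)
  stopifnot(all(reg$serving_g_low[sg] <= reg$serving_g_high[sg]))
  invisible(reg)
}

#' Item ids derivable from the reference FFQ
#'
#' All items except the sofrito item (11), which has no counterpart in the
#' reference food-frequency questionnaire and is excluded from validation.
#'
#' @return Integer vector of 17 item ids.
#' @export
derivable_items <- function() setdiff(1:18, 11L)

# midpoint of the serving-size interval, used for gram conversions
serving_midpoint <- function(reg_row) {
  (reg_row$serving_g_low + reg_row$serving_g_high) / 2
}

`%||%` <- function(x, y) if (is.null(x)) y else x
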