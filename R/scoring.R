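#' Score a single MED4CHILD item
#'
#' Applies one item criterion to a reported quantity. `at_least` items earn
#' the point when the answer reaches the threshold, `less_than` items when it
#' stays strictly below it, and binary (`yes`) items when the answer is 1.
#' Item 3 carries a sub-condition (at least one raw/salad serving per week)
#' which is ANDed with the main threshold whenever a sub-answer is supplied.
#'
#' @param criterion One row of [med4child_registry()].
#' @param answer Reported quantity in the item's unit (0/1 for binary items),
#'   or `NA` if unanswered.
#' @param extra Optional sub-answer for the item's extra condition (for item
#'   3, raw/salad servings per week). When `NULL` the main threshold alone
#'   decides.
#' @return `1L`, `0L`, or `NA_integer_` for a missing answer (missingness is
#'   preserved so the completeness policy can act, it is never scored as 0).
#' @examples
#' reg <- med4child_registry()
#' score_item(reg[reg$item_id == 2, ], 3)   # >= 3 tbsp olive oil/day -> 1
#' score_item(reg[reg$item_id == 12, ], 2)  # "less than 2" at exactly 2 -> 0
#' @export
score_item <- function(criterion, answer, extra = NULL) {
  stopifnot(nrow(criterion) == 1L)
  if (is.na(answer)) return(NA_integer_)
  if (answer < 0) stop("answer for item ", criterion$item_id, " is negative")
  point <- switch(criterion$direction,
    at_least  = answer >= criterion$threshold,
    less_than = answer < criterion$threshold,
    yes = {
      if (!answer %in% c(0, 1)) {
        stop("binary item ", criterion$item_id, " expects 0/1, got ", answer)
      }
      answer == 1
    },
    stop("unknown direction: ", criterion$direction)
  )
  if (!is.na(criterion$extra_condition) && !is.null(extra)) {
    if (is.na(extra)) return(NA_integer_)
    point <- point && extra >= 1
  }
  as.integer(point)
}

#' Score a cohort of questionnaire responses
#'
#' Computes per-item points, the total score, its quartile and the
#' dichotomous adherence class for every child. Input answers are stored as
#' quantities (tablespoons/day, servings/day or /week, times/week) so the
#' thresholds are applied by the engine; binary items (1 and 10) take 0/1.
#'
#' @param questionnaire Data frame with `child_id` and answer columns
#'   `q01`...`q18`; an optional `q03_raw` column carries raw/salad vegetable
#'   servings per week for item 3's sub-condition.
#' @param registry Item registry, see [med4child_registry()].
#' @param items_used Item ids entering the total (default all 18; use
#'   [derivable_items()] for the 17-item validation set).
#' @param policy Missing-data policy: `"complete_case"` (default) marks any
#'   record missing an item in `items_used` as excluded (`NA` total);
#'   `"score_zero"` scores missing items as 0.
#' @param cutoff Dichotomy cutoff, see [dichotomize()].
#' @param cutpoints Quartile cut points, see [assign_quartile()].
#' @param input `"quantities"` (default) applies the thresholds to reported
#'   quantities; `"binary"` accepts field-collected forms where every answer
#'   is already the judged yes/no indicator (0/1), taken as the item point.
#' @return A tibble with `child_id`, per-item point columns `item_01` ...
#'   `item_18` (`NA` outside `items_used`), `total`, `quartile`,
#'   `adherence`, and a logical `excluded` flag.
#' @examples
#' q <- tibble::tibble(child_id = "c1", q01 = 1, q02 = 4, q03 = 2, q04 = 3,
#'   q05 = 4, q06 = 1, q07 = 3, q08 = 3, q09 = 3, q10 = 1, q11 = 2, q12 = 1,
#'   q13 = 0, q14 = 0, q15 = 0, q16 = 0, q17 = 1, q18 = 0)
#' score_cohort(q)$total  # every criterion satisfied -> 18
#' @export
score_cohort <- function(questionnaire,
                         registry = med4child_registry(),
                         items_used = registry$item_id,
                         policy = c("complete_case", "score_zero"),
                         cutoff = 10L,
                         cutpoints = c(9L, 12L, 14L),
                         input = c("quantities", "binary")) {
  policy <- match.arg(policy)
  input <- match.arg(input)
  validate_registry(registry)
  stopifnot("child_id" %in% names(questionnaire))
  items_used <- sort(as.integer(items_used))
  if (!all(items_used %in% registry$item_id)) {
    stop("items_used contains ids absent from the registry")
  }
  cols <- sprintf("q%02d", registry$item_id)
  missing_cols <- setdiff(cols[registry$item_id %in% items_used],
                          names(questionnaire))
  if (length(missing_cols)) {
    stop("questionnaire is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }

  n <- nrow(questionnaire)
  pts <- matrix(NA_integer_, n, 18L,
                dimnames = list(NULL, sprintf("item_%02d", 1:18)))
  for (id in registry$item_id) {
    col <- sprintf("q%02d", id)
    if (!col %in% names(questionnaire)) next
    crit <- registry[registry$item_id == id, ]
    extra <- if (!is.na(crit$extra_condition) &&
                 "q03_raw" %in% names(questionnaire) && id == 3L) {
      questionnaire$q03_raw
    } else {
      NULL
    }
    ans <- questionnaire[[col]]
    if (input == "binary") {
      if (!all(ans %in% c(0, 1, NA))) {
        stop("binary input mode expects 0/1 answers; column ", col,
             " has other values")
      }
      pts[, id] <- as.integer(ans)
    } else {
      pts[, id] <- vapply(seq_len(n), function(i) {
        score_item(crit, ans[i], extra = if (is.null(extra)) NULL else extra[i])
      }, integer(1))
    }
  }

  used <- pts[, items_used, drop = FALSE]
  if (policy == "score_zero") used[is.na(used)] <- 0L
  total <- as.integer(rowSums(used))
  excluded <- apply(used, 1L, anyNA)
  total[excluded] <- NA_integer_

  out <- tibble::as_tibble(pts)
  out[, setdiff(1:18, items_used)] <- NA_integer_
  tibble::tibble(child_id = questionnaire$child_id) |>
    dplyr::bind_cols(out) |>
    dplyr::mutate(
      total = total,
      quartile = assign_quartile(total, cutpoints = cutpoints),
      adherence = dichotomize(total, cutoff = cutoff),
      excluded = excluded
    )
}

#' Score one questionnaire response
#'
#' Convenience wrapper around [score_cohort()] for a single child.
#'
#' @param answers Named numeric vector (`q01`...`q18`, optionally `q03_raw`)
#'   or a one-row data frame.
#' @inheritParams score_cohort
#' @param child_id Identifier used when `answers` has none.
#' @return One-row tibble as returned by [score_cohort()].
#' @export
score_total <- function(answers, registry = med4child_registry(),
                        items_used = registry$item_id,
                        policy = c("complete_case", "score_zero"),
                        child_id = "child") {
  if (!is.data.frame(answers)) {
    answers <- tibble::as_tibble(as.list(answers))
  }
  if (!"child_id" %in% names(answers)) answers$child_id <- child_id
  unknown <- setdiff(grep("^q\\d{2}$", names(answers), value = TRUE),
                     sprintf("q%02d", registry$item_id))
  if (length(unknown)) {
    stop("answers contain unknown item columns: ",
         paste(unknown, collapse = ", "))
  }
  score_cohort(answers, registry, items_used, policy)
}

#' Assign score quartiles
#'
#' Maps total scores to adherence quartiles. The default fixed cut points
#' reproduce the study bands Q1 0–8, Q2 9–11, Q3 12–13, Q4 14–18; pass
#' `cutpoints = "empirical"` (with `cohort_totals`) to use sample quartiles
#' instead.
#'
#' @param total Integer total score(s), 0–18.
#' @param cutpoints Three ascending lower bounds of Q2–Q4, or `"empirical"`.
#' @param cohort_totals Totals used to derive empirical cut points.
#' @return Factor with levels `Q1`–`Q4` (`NA` preserved).
#' @export
assign_quartile <- function(total, cutpoints = c(9L, 12L, 14L),
                            cohort_totals = NULL) {
  if (identical(cutpoints, "empirical")) {
    if (is.null(cohort_totals)) {
      stop("empirical cut points require cohort_totals")
    }
    cutpoints <- stats::quantile(cohort_totals, c(.25, .5, .75),
                                 na.rm = TRUE, names = FALSE)
  }
  stopifnot(length(cutpoints) == 3L, !is.unsorted(cutpoints))
  ok <- is.na(total) | (total >= 0 & total <= 18)
  if (!all(ok)) stop("total score outside 0-18")
  idx <- findInterval(total, cutpoints) + 1L
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}

#' Dichotomise the total score
#'
#' Low adherence below the cutoff, high at or above it (default 10).
#'
#' @param total Integer total score(s).
#' @param cutoff Cutoff defining high adherence (default 10).
#' @return Factor with levels `low`, `high` (`NA` preserved).
#' @export
dichotomize <- function(total, cutoff = 10L) {
  factor(ifelse(total >= cutoff, "high", "low"), levels = c("low", "high"))
}
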