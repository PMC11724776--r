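#' Cross-classify two binary indicator vectors
#'
#' @param points1,points2 Equal-length binary (0/1) vectors without missing
#'   values; by convention method 1 is the administered questionnaire and
#'   method 2 the FFQ-derived reference.
#' @return Named list `a` (both 1), `b` (only method 1), `c` (only method
#'   2), `d` (both 0), `n`.
#' @export
build_2x2 <- function(points1, points2) {
  if (length(points1) != length(points2)) {
    stop("points1 and points2 differ in length")
  }
  if (anyNA(points1) || anyNA(points2)) stop("binary vectors contain NA")
  if (!all(points1 %in% c(0, 1)) || !all(points2 %in% c(0, 1))) {
    stop("inputs must be binary 0/1")
  }
  list(
    a = sum(points1 == 1 & points2 == 1),
    b = sum(points1 == 1 & points2 == 0),
    c = sum(points1 == 0 & points2 == 1),
    d = sum(points1 == 0 & points2 == 0),
    n = length(points1)
  )
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement kappa = (Po - Pe) / (1 - Pe), with Po the
#' observed agreement (a + d)/n and Pe the chance agreement from the
#' marginal products. The 95% CI is kappa +/- 1.96 SE with the large-sample
#' (Fleiss-type) standard error for two raters and two categories. A
#' degenerate table with Pe = 1 (both raters constant) has undefined kappa
#' and is flagged, not reported as a number.
#'
#' @param table 2x2 counts as produced by [build_2x2()] (a named list or
#'   vector with `a`, `b`, `c`, `d`).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list with `kappa`, `se`, `ci_low`, `ci_high`, `po`, `pe`,
#'   `undefined` (TRUE when Pe = 1).
#' @examples
#' cohen_kappa(list(a = 40, b = 10, c = 5, d = 45))$kappa  # 0.70
#' @export
cohen_kappa <- function(table, conf_level = 0.95) {
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  po <- (a + d) / n
  p1 <- (a + b) / n   # marginal of method 1
  p2 <- (a + c) / n   # marginal of method 2
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (abs(1 - pe) < .Machine$double.eps^0.75) {
    return(list(kappa = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, po = po, pe = pe, undefined = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)

  # large-sample variance (Fleiss, Cohen & Everitt), cell proportions p_ij
  p11 <- a / n; p10 <- b / n; p01 <- c / n; p00 <- d / n
  r1 <- c(p1, 1 - p1)        # method-1 marginals over categories (1, 0)
  r2 <- c(p2, 1 - p2)
  om <- 1 - kappa
  termA <- p11 * (1 - (r1[1] + r2[1]) * om)^2 +
           p00 * (1 - (r1[2] + r2[2]) * om)^2
  termB <- om^2 * (p10 * (r2[1] + r1[2])^2 + p01 * (r2[2] + r1[1])^2)
  termC <- (kappa - pe * om)^2
  var_k <- (termA + termB - termC) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se,
       ci_low = kappa - z * se, ci_high = kappa + z * se,
       po = po, pe = pe, undefined = FALSE)
}

#' Interpretation band for a kappa value
#'
#' Bands: kappa <= 0.20 weak; 0.21–0.40 fair; 0.41–0.60 moderate;
#' 0.61–0.80 substantial; > 0.80 almost perfect.
#'
#' @param kappa Kappa value(s) in \[-1, 1\] (NA allowed).
#' @return Factor with the five band levels.
#' @examples
#' kappa_band(c(0.665, 0.416, 0.058))
#' @export
kappa_band <- function(kappa) {
  if (any(kappa < -1 | kappa > 1, na.rm = TRUE)) {
    stop("kappa outside [-1, 1]")
  }
  cut(kappa, breaks = c(-1, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c("weak", "fair", "moderate", "substantial", "almost_perfect"),
      include.lowest = TRUE)
}

#' Bland-Altman agreement analysis for paired scores
#'
#' Differences are taken as `scores1 - scores2` (administered minus
#' FFQ-derived). Limits of agreement are mean difference +/- 1.96 SD of the
#' differences.
#'
#' @param scores1,scores2 Paired numeric vectors (n >= 2, no missing).
#' @return A list with `mean_difference`, `sd_difference`, `loa_low`,
#'   `loa_high`, `n`, and a tibble `pairs` of per-child (mean, difference).
#' @examples
#' ba <- bland_altman(c(10, 11, 12), c(6, 6, 6))
#' ba$mean_difference  # 5
#' @export
bland_altman <- function(scores1, scores2) {
  if (length(scores1) != length(scores2)) stop("paired vectors differ in length")
  if (anyNA(scores1) || anyNA(scores2)) stop("scores contain NA")
  n <- length(scores1)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs")
  diffs <- scores1 - scores2
  m <- mean(diffs)
  s <- stats::sd(diffs)
  list(
    mean_difference = m,
    sd_difference = s,
    loa_low = m - 1.96 * s,
    loa_high = m + 1.96 * s,
    n = n,
    pairs = tibble::tibble(mean = (scores1 + scores2) / 2, difference = diffs)
  )
}

#' Bland-Altman plot
#'
#' @param ba Result of [bland_altman()].
#' @return A ggplot object: per-child mean vs difference with the mean
#'   difference and limits of agreement as horizontal lines.
#' @export
plot_bland_altman <- function(ba) {
  ggplot2::ggplot(ba$pairs, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = ba$mean_difference, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two scores (points)",
                  y = "Administered - FFQ-derived (points)") +
    ggplot2::theme_minimal()
}

#' Per-item and total-score relative validity
#'
#' For each derivable item, cross-classifies the administered indicator with
#' the FFQ-derived one and reports both marginal prevalences, percent
#' agreement (a + d)/n, Cohen's kappa with its 95% CI and interpretation
#' band. A final `total` row reports the same statistics for the dichotomised
#' (>= cutoff) total scores. Items with undefined kappa (a method with zero
#' variance) are retained and flagged.
#'
#' @param scores_q Administered scores from [score_cohort()].
#' @param scores_ffq Reference scores from [derive_ffq_scores()].
#' @param items Item ids to validate (default the 17 derivable items).
#' @param registry Item registry (for labels).
#' @param cutoff Dichotomy cutoff for the total row.
#' @param total_mode `"matched_items"` (default) compares totals computed on
#'   the same item set on both instruments; `"all_items"` uses each score
#'   table's own total (18 items administered vs 17 FFQ-derived).
#' @return A tibble with columns `item`, `label`, `a`, `b`, `c`, `d`, `n`,
#'   `pct_method1`, `pct_method2`, `pct_agreement`, `kappa`, `ci_low`,
#'   `ci_high`, `band`, `undefined`.
#' @export
validate_items <- function(scores_q, scores_ffq,
                           items = derivable_items(),
                           registry = med4child_registry(),
                           cutoff = 10L,
                           total_mode = c("matched_items", "all_items")) {
  total_mode <- match.arg(total_mode)
  merged <- dplyr::inner_join(scores_q, scores_ffq, by = "child_id",
                              suffix = c("_q", "_f"))
  if (nrow(merged) == 0L) stop("no children shared between the two tables")

  row_for <- function(x, y, item, label) {
    keep <- !is.na(x) & !is.na(y)
    t22 <- build_2x2(x[keep], y[keep])
    k <- cohen_kappa(t22)
    tibble::tibble(
      item = item, label = label,
      a = t22$a, b = t22$b, c = t22$c, d = t22$d, n = t22$n,
      pct_method1 = (t22$a + t22$b) / t22$n,
      pct_method2 = (t22$a + t22$c) / t22$n,
      pct_agreement = (t22$a + t22$d) / t22$n,
      kappa = k$kappa, ci_low = k$ci_low, ci_high = k$ci_high,
      band = as.character(kappa_band(k$kappa)),
      undefined = k$undefined
    )
  }

  out <- purrr::map_dfr(sort(as.integer(items)), function(id) {
    col <- sprintf("item_%02d", id)
    row_for(merged[[paste0(col, "_q")]], merged[[paste0(col, "_f")]],
            as.character(id), registry$label[registry$item_id == id])
  })

  if (total_mode == "matched_items") {
    cols <- sprintf("item_%02d", sort(as.integer(items)))
    tq <- rowSums(merged[paste0(cols, "_q")])
    tf <- rowSums(merged[paste0(cols, "_f")])
  } else {
    tq <- merged$total_q
    tf <- merged$total_f
  }
  keep <- !is.na(tq) & !is.na(tf)
  out <- dplyr::bind_rows(out, row_for(
    as.integer(tq[keep] >= cutoff), as.integer(tf[keep] >= cutoff),
    "total", sprintf("Total score >= %d points", cutoff)
  ))
  out
}
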