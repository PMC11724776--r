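# shared fixtures and independent oracles, built in code

# questionnaire response satisfying every criterion (18/18 points)
adherent_response <- function(child_id = "c_adherent") {
  tibble::tibble(
    child_id = child_id,
    q01 = 1, q02 = 4, q03 = 3, q03_raw = 2, q04 = 4, q05 = 5, q06 = 2,
    q07 = 3, q08 = 4, q09 = 3, q10 = 1, q11 = 3,
    q12 = 0, q13 = 0, q14 = 0, q15 = 0, q16 = 0, q17 = 0, q18 = 0
  )
}

# response violating every criterion (0/18 points)
nonadherent_response <- function(child_id = "c_nonadherent") {
  tibble::tibble(
    child_id = child_id,
    q01 = 0, q02 = 1, q03 = 0.5, q03_raw = 0, q04 = 1, q05 = 1, q06 = 0,
    q07 = 1, q08 = 1, q09 = 0, q10 = 0, q11 = 0,
    q12 = 7, q13 = 2, q14 = 7, q15 = 3, q16 = 3, q17 = 4, q18 = 3
  )
}

# independent kappa oracle: generic k-category formula on the cell
# probability matrix (not the 2x2 shortcut used by the implementation)
oracle_kappa <- function(a, b, c, d) {
  p <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE) / (a + b + c + d)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  (po - pe) / (1 - pe)
}

# questionnaire + FFQ pair expressing identical underlying servings, so the
# two instruments must agree item by item on the 17 derivable items
mirrored_records <- function(n = 50, seed = 42) {
  set.seed(seed)
  q <- tibble::tibble(child_id = sprintf("c%03d", seq_len(n)))
  ffq <- tibble::tibble(child_id = q$child_id)
  q$q01 <- stats::rbinom(n, 1, 0.7); ffq$olive_oil_main_fat <- q$q01
  q$q02 <- stats::runif(n, 0, 8);  ffq$olive_oil <- q$q02 * 9.2
  q$q03 <- stats::runif(n, 0, 6);  ffq$vegetables <- q$q03 * 65
  q$q04 <- stats::runif(n, 0, 8);  ffq$fruits <- q$q04 * 100
  q$q05 <- stats::runif(n, 0, 14); ffq$freq_whole_grains <- q$q05
  q$q06 <- stats::runif(n, 0, 4);  ffq$fermented_dairy <- q$q06 * 125
  q$q07 <- stats::runif(n, 0, 10); ffq$legumes <- q$q07 * 40 / 7
  q$q08 <- stats::runif(n, 0, 10); ffq$fish_seafood <- q$q08 * 55 / 7
  q$q09 <- stats::runif(n, 0, 10); ffq$nuts <- q$q09 * 17.5 / 7
  white <- stats::runif(n, 0, 10); red <- stats::runif(n, 0, 10)
  q$q10 <- as.numeric(white > red)
  ffq$freq_white_meat <- white
  ffq$freq_red_processed_meat <- red
  q$q11 <- stats::runif(n, 0, 10)
  q$q12 <- red
  q$q13 <- stats::runif(n, 0, 4);  ffq$butter_cream <- q$q13 * 12
  q$q14 <- stats::runif(n, 0, 14); ffq$sugared_beverages <- q$q14 * 200 / 7
  q$q15 <- stats::runif(n, 0, 10); ffq$freq_sweets_snacks <- q$q15
  q$q16 <- stats::runif(n, 0, 10); ffq$freq_dairy_desserts <- q$q16
  q$q17 <- stats::runif(n, 0, 10); ffq$freq_pastries <- q$q17
  q$q18 <- stats::runif(n, 0, 7);  ffq$freq_precooked <- q$q18
  list(questionnaire = q, ffq = ffq)
}

# participant-flow fixture: 1509 enrolled; disjoint blocks missing the
# questionnaire (36), the FFQ (32), BMI (24) and biochemistry (559); the
# remaining 858 complete, 432 of them girls
flow_fixture <- function(seed = 11) {
  co <- generate_cohort(cohort_preset("calibrated", n = 1509, seed = seed))
  q <- co$questionnaire; f <- co$ffq; o <- co$outcomes
  q$q05[1:36] <- NA
  f$vegetables[37:68] <- NA
  o$bmi[69:92] <- NA
  o$insulin[93:651] <- NA
  analysed <- 652:1509
  o$sex[analysed] <- factor(
    rep(c("girl", "boy"), c(432, 426)), levels = c("boy", "girl"))
  list(questionnaire = q, ffq = f, outcomes = o)
}
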