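#' Candidate diagnosis universe observed in a cohort
#'
#' All distinct 3-character diagnosis codes present in the cohort's events
#' that fall into the configured ICD-10 chapters. The default keeps
#' chapters A through N (infectious diseases up to diseases of the
#' genitourinary system), excluding symptoms, injuries, pregnancy-related
#' codes and external causes (chapters O-Z), and always excludes the index
#' codes E10 and E11 themselves.
#'
#' @param cohort a `claims_cohort`.
#' @param chapters initial letters of the ICD-10 chapters to keep.
#' @return character vector of candidate codes, sorted.
#' @export
candidate_codes <- function(cohort, chapters = LETTERS[1:14]) {
  ev <- cohort$events
  codes <- unique(ev$code[ev$kind %chin% c("diag_main", "diag_side")])
  codes <- codes[substr(codes, 1, 1) %in% chapters]
  sort(setdiff(codes, c("E10", "E11")))
}

#' Enumerate the scheduled co-occurrence tests
#'
#' The screening grid: one test per candidate diagnosis, age group and
#' diabetes type. With 1051 candidate codes, 19 age groups and both
#' types this yields 39 938 scheduled tests.
#'
#' @param codes candidate diagnosis codes.
#' @param n_age_groups number of age strata.
#' @param types diabetes types screened.
#' @return `data.table` with one row per scheduled test (`code`,
#'   `age_group`, `diabetes_type`).
#' @export
comorbidity_test_grid <- function(codes, n_age_groups = 19,
                                  types = c("DM1", "DM2")) {
  CJ(code = codes, age_group = seq_len(n_age_groups) - 1L,
     diabetes_type = types)
}

# counts for all (code, age_group) cells of one diabetes type;
# a = diabetic & x, b = diabetic & not x, c = comparator & x,
# d = comparator & not x; comparator = same-age patients without the type
cooccur_counts <- function(cohort, codes, type) {
  pat <- cohort$patients
  is_dm <- if (type == "DM1") pat$dm1 else pat$dm2
  all_groups <- age_groups(cohort$age_group_width, cohort$max_age)$index
  margins <- pat[, .(n_dm = sum(if (type == "DM1") dm1 else dm2), n_group = .N),
                 by = age_group]
  margins <- margins[data.table(age_group = all_groups), on = "age_group"]
  for (col in c("n_dm", "n_group")) {
    set(margins, which(is.na(margins[[col]])), col, 0L)
  }
  ev <- cohort$events
  ux <- unique(ev[kind %chin% c("diag_main", "diag_side") & code %chin% codes,
                  .(patient_id, code)])
  ux <- pat[, .(patient_id, age_group, dm = is_dm)][ux, on = "patient_id"]
  cnt <- ux[, .(n_x_dm = sum(dm), n_x_nd = sum(!dm)), by = .(code, age_group)]
  grid <- CJ(code = codes, age_group = all_groups)
  cnt <- cnt[grid, on = c("code", "age_group")]
  for (col in c("n_x_dm", "n_x_nd")) {
    set(cnt, which(is.na(cnt[[col]])), col, 0L)
  }
  cnt <- margins[cnt, on = "age_group"]
  cnt[, `:=`(a = n_x_dm,
             b = n_dm - n_x_dm,
             c = n_x_nd,
             d = (n_group - n_dm) - n_x_nd)]
  cnt[, diabetes_type := type]
  cnt[, .(diabetes_type, code, age_group, a, b, c, d)][order(code, age_group)]
}

#' Build one 2x2 diabetes-by-diagnosis contingency table
#'
#' A patient "has x" if any main or side diagnosis of `code` occurs in
#' either study year. The comparator group consists of all cohort
#' patients of the age group who do not carry the diabetes type under
#' test (patients with the other type remain in the comparator).
#'
#' @param cohort a `claims_cohort`.
#' @param code candidate ICD-10 code.
#' @param age_group 0-based age group index.
#' @param type `"DM1"` or `"DM2"`.
#' @return one-row `data.table` with cells `a` (diabetes & x), `b`
#'   (diabetes & not x), `c` (no diabetes & x), `d` (no diabetes & not x).
#' @export
build_table <- function(cohort, code, age_group, type = c("DM2", "DM1")) {
  type <- match.arg(type)
  stopifnot(length(code) == 1L, length(age_group) == 1L)
  ag <- as.integer(age_group)
  tab <- cooccur_counts(cohort, code, type)
  sel <- tab[tab[["age_group"]] == ag]
  if (nrow(sel) == 0L) {
    sel <- data.table(diabetes_type = type, code = code,
                      age_group = as.integer(age_group),
                      a = 0L, b = 0L, c = 0L, d = 0L)
  }
  sel
}

#' Relative risk with Katz log-normal confidence interval
#'
#' For a 2x2 table, `rr = [a/(a+b)] / [c/(c+d)]` with the classical Katz
#' interval `exp(log(rr) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' Vectorised over cells; returns `NA` where a required margin or cell is
#' zero.
#'
#' @param a,b,c,d table cells (see [build_table()]).
#' @param conf_level confidence level.
#' @return `data.table` with columns `rr`, `ci_low`, `ci_high`.
#' @export
relative_risk_ci <- function(a, b, c, d, conf_level = 0.95) {
  n1 <- a + b
  n0 <- c + d
  rr <- (a / n1) / (c / n0)
  rr[n1 == 0 | n0 == 0 | c == 0] <- NA_real_
  se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.table(rr = rr,
             ci_low = exp(log(rr) - z * se),
             ci_high = exp(log(rr) + z * se))
}

#' Pearson chi-squared p-value for a 2x2 table
#'
#' One degree of freedom, upper-tail probability, no continuity
#' correction by default (large-sample claims setting); set
#' `correct = TRUE` for the Yates correction. Vectorised; `NA` where a
#' margin is zero (the test is undefined).
#'
#' @param a,b,c,d table cells.
#' @param correct apply the Yates continuity correction.
#' @return numeric vector of p-values.
#' @export
chi_squared_p <- function(a, b, c, d, correct = FALSE) {
  pearson_chisq_p(a, b, c, d, correct = correct)
}

#' Benjamini-Hochberg rejection flags
#'
#' Standard step-up rule at level `alpha` within one family of p-values:
#' reject the hypotheses with the k* smallest p-values where
#' k* = max\{k : p(k) <= (k/m) alpha\}, m = family size. The boundary is
#' inclusive. `NA` p-values (tests never run) are not part of the family
#' and are returned as `FALSE`.
#'
#' @param p p-values of one testing family.
#' @param alpha false-discovery-rate level.
#' @return logical rejection flags, same length and order as `p`.
#' @export
bh_adjust <- function(p, alpha) {
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (!any(ok)) return(out)
  out[ok] <- stats::p.adjust(p[ok], method = "BH") <= alpha
  out
}

#' Expected number of false positives among discoveries
#'
#' Under false-discovery-rate control at level `alpha`, a list of
#' `n_discoveries` discoveries is expected to contain
#' `alpha * n_discoveries` false positives.
#'
#' @param n_discoveries number of discoveries.
#' @param alpha FDR level.
#' @return expected count of false positives.
#' @export
expected_false_positives <- function(n_discoveries, alpha) {
  stopifnot(n_discoveries >= 0, alpha >= 0)
  alpha * n_discoveries
}

#' Run the age-stratified co-occurrence screen
#'
#' For every candidate diagnosis, age group and diabetes type, builds the
#' 2x2 contingency table of diabetes by diagnosis. Where every observed
#' cell is at least `min_cell` (default 10) *and* every expected cell
#' under independence is at least `min_expected` (default 10, the
#' classical validity condition for the chi-squared approximation; set to
#' 0 to apply the observed-cell rule alone), the relative risk with its
#' Katz 95% confidence interval and a chi-squared p-value are computed;
#' otherwise the cell is marked not computed. Without the expected-count
#' condition, tables whose expected co-occurrence count is far below the
#' observed threshold can pass the rule only by fluctuating upward, which
#' inflates the far tail of the chi-squared statistic and breaks
#' false-discovery-rate calibration. Benjamini-Hochberg control at level
#' `alpha` is applied separately within each (age group x diabetes type)
#' family of computed tests. A diagnosis significant in at least one age
#' group for a given type enters that type's comorbidity list. Following
#' the reporting convention of the method, the reported relative risk
#' `rr` is set to 1 wherever the cell was not computed or not
#' significant; the unmodified estimate is kept in `rr_raw`.
#'
#' @param cohort a `claims_cohort`.
#' @param codes candidate universe; defaults to [candidate_codes()] of the
#'   cohort.
#' @param alpha false-discovery-rate level.
#' @param min_cell minimum observed count required in every cell of a
#'   table for the test to be performed.
#' @param min_expected minimum expected count under independence required
#'   in every cell (chi-squared validity condition).
#' @param correct Yates continuity correction for the chi-squared test.
#' @param types diabetes types to screen.
#' @return A `cooccur_result`: list with `results` (one row per scheduled
#'   test), `comorbidities` (per-type character vectors and their
#'   `union`), `n_scheduled`, `alpha`, `min_cell` and `min_expected`.
#' @export
run_cooccurrence <- function(cohort, codes = NULL, alpha = 0.01,
                             min_cell = 10, min_expected = 10,
                             correct = FALSE, types = c("DM1", "DM2")) {
  codes <- codes %||% candidate_codes(cohort)
  res <- rbindlist(lapply(types, function(ty) cooccur_counts(cohort, codes, ty)))
  res[, computed := a >= min_cell & b >= min_cell & c >= min_cell & d >= min_cell]
  if (min_expected > 0) {
    n <- as.numeric(res$a) + res$b + res$c + res$d
    r1 <- as.numeric(res$a) + res$b; c1 <- as.numeric(res$a) + res$c
    e_min <- pmin(r1 * c1, r1 * (n - c1), (n - r1) * c1,
                  (n - r1) * (n - c1)) / n
    res[, computed := computed & !is.na(e_min) & e_min >= min_expected]
  }
  est <- relative_risk_ci(res$a, res$b, res$c, res$d)
  res[, `:=`(rr_raw = est$rr, ci_low = est$ci_low, ci_high = est$ci_high)]
  res[, p_value := chi_squared_p(a, b, c, d, correct = correct)]
  res[computed == FALSE, `:=`(rr_raw = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p_value = NA_real_)]
  res[, significant := bh_adjust(p_value, alpha),
      by = .(diabetes_type, age_group)]
  res[, rr := fifelse(computed & significant, rr_raw, 1.0)]
  comorb <- lapply(types, function(ty) {
    sort(unique(res[diabetes_type == ty & significant == TRUE, code]))
  })
  names(comorb) <- types
  comorb$union <- sort(unique(unlist(comorb)))
  structure(list(results = res[order(diabetes_type, code, age_group)],
                 comorbidities = comorb,
                 n_scheduled = nrow(comorbidity_test_grid(
                   codes, cohort$max_age %/% cohort$age_group_width, types)),
                 alpha = alpha, min_cell = min_cell,
                 min_expected = min_expected),
            class = "cooccur_result")
}

#' @export
print.cooccur_result <- function(x, ...) {
  cat(sprintf(
    "<cooccur_result> %d scheduled tests, alpha = %g: %s comorbidities (union %d)\n",
    x$n_scheduled, x$alpha,
    paste(sprintf("%s %d", names(x$comorbidities)[1:2],
                  lengths(x$comorbidities)[1:2]), collapse = ", "),
    length(x$comorbidities$union)))
  invisible(x)
}
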