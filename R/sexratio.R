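#' Smoothed log sex ratio of a binary attribute among diabetic patients
#'
#' For an age group with `d_f` female and `d_m` male diabetic patients of
#' whom `d_fx` and `d_mx` carry attribute x, the statistic is
#' `SR = log[(1 + d_m/d_mx) / (1 + d_f/d_fx)]` under the default
#' orientation: positive values indicate the attribute is more likely for
#' females, negative for males, zero at equal proportions. The "1 +"
#' smoothing inside each per-sex term is part of the statistic.
#' `orientation = "inverse_printed"` flips the quotient (female term in
#' the numerator), which negates the statistic.
#'
#' @param d_f,d_m female/male diabetic patients in the age group.
#' @param d_fx,d_mx females/males among them carrying the attribute.
#' @param orientation `"female_positive"` (default sign convention) or
#'   `"inverse_printed"`.
#' @return numeric SR values; `NA` where `d_fx` or `d_mx` is zero (the
#'   quotient is undefined; such cells are reported as zeroed).
#' @export
sex_ratio <- function(d_f, d_m, d_fx, d_mx,
                      orientation = c("female_positive", "inverse_printed")) {
  orientation <- match.arg(orientation)
  sr <- log((1 + d_m / d_mx) / (1 + d_f / d_fx))
  sr[d_fx == 0 | d_mx == 0] <- NA_real_
  if (orientation == "inverse_printed") sr <- -sr
  sr
}

#' Chi-squared significance of a sex ratio
#'
#' Pearson chi-squared p-value (1 df, no continuity correction) for the
#' 2x2 table of sex by attribute among the diabetic patients of one age
#' group: `[[d_fx, d_f - d_fx], [d_mx, d_m - d_mx]]`. Degenerate margins
#' give p = 1 (no evidence against independence).
#'
#' @inheritParams sex_ratio
#' @return numeric p-values.
#' @export
sr_significance <- function(d_f, d_m, d_fx, d_mx) {
  p <- pearson_chisq_p(d_fx, d_f - d_fx, d_mx, d_m - d_mx)
  p[is.na(p)] <- 1
  p
}

#' Attribute constructors for the sex-ratio analysis
#'
#' An attribute is a binary predicate over a patient's two-year record:
#' carrying a diagnosis code (main or side, either year), having any
#' prescription in an ATC group (by code prefix), or falling into a bin
#' of the per-patient count of diagnoses or prescriptions.
#'
#' @param code 3-character ICD-10 code.
#' @param prefix ATC code prefix (e.g. `"N05"` for psycholeptics at the
#'   3-digit level, `"A10"` for drugs used in diabetes).
#' @param kind count diagnoses (`"diag"`) or prescriptions (`"rx"`).
#' @param lower,upper half-open bin `[lower, upper)` for the event count.
#' @return an `sr_attribute` object.
#' @name sr_attributes
NULL

#' @rdname sr_attributes
#' @export
attr_diag <- function(code) {
  stopifnot(is_icd3(code))
  structure(list(type = "diag", code = code, name = paste0("diag:", code)),
            class = "sr_attribute")
}

#' @rdname sr_attributes
#' @export
attr_atc <- function(prefix) {
  structure(list(type = "atc", prefix = prefix, name = paste0("atc:", prefix)),
            class = "sr_attribute")
}

#' @rdname sr_attributes
#' @export
attr_count_bin <- function(kind = c("diag", "rx"), lower, upper = Inf) {
  kind <- match.arg(kind)
  stopifnot(lower >= 0, upper > lower)
  structure(list(type = "count_bin", kind = kind, lower = lower, upper = upper,
                 name = sprintf("n_%s:[%g,%g)", kind, lower, upper)),
            class = "sr_attribute")
}

# ids of cohort patients carrying the attribute
attribute_carriers <- function(cohort, attribute) {
  ev <- cohort$events
  switch(attribute$type,
    diag = unique(ev[kind %chin% c("diag_main", "diag_side") &
                       code == attribute$code, patient_id]),
    atc = unique(ev[kind == "rx" & startsWith(code, attribute$prefix),
                    patient_id]),
    count_bin = {
      kinds <- if (attribute$kind == "diag") c("diag_main", "diag_side") else "rx"
      cnt <- ev[kind %chin% kinds, .N, by = patient_id]
      ids <- cohort$patients$patient_id
      n <- cnt[data.table(patient_id = ids), on = "patient_id"]$N
      n[is.na(n)] <- 0L
      ids[n >= attribute$lower & n < attribute$upper]
    },
    stopf("unknown attribute type '%s'", attribute$type)
  )
}

#' Sex ratios per age group for a set of attributes
#'
#' Computes the smoothed log sex ratio [sex_ratio()] of each attribute in
#' each age group among diabetic patients, together with the chi-squared
#' significance [sr_significance()]. Non-significant values (p above
#' `p_zero`) and cells with zero co-occurrence in either sex are zeroed.
#' The diabetic denominator pools type 1 and type 2 patients by default;
#' `denominator = "DM1"` or `"DM2"` restricts to one type.
#'
#' @param cohort a `claims_cohort`.
#' @param attributes a list of [sr_attributes] objects (a single attribute
#'   is accepted); diagnosis codes given as plain strings are promoted via
#'   [attr_diag()].
#' @param p_zero significance threshold for the zeroing rule.
#' @param orientation see [sex_ratio()].
#' @param denominator `"pooled"` (all diabetic patients), `"DM1"` or
#'   `"DM2"`.
#' @return `data.table` with one row per (attribute, age group):
#'   the four counts, `sr` (zeroed where applicable), `sr_raw`,
#'   `p_value` and `zeroed` with its `zero_reason`.
#' @export
run_sex_ratio <- function(cohort, attributes, p_zero = 0.05,
                          orientation = c("female_positive", "inverse_printed"),
                          denominator = c("pooled", "DM1", "DM2")) {
  orientation <- match.arg(orientation)
  denominator <- match.arg(denominator)
  if (inherits(attributes, "sr_attribute")) attributes <- list(attributes)
  attributes <- lapply(attributes, function(a) {
    if (is.character(a)) attr_diag(a) else a
  })
  pat <- cohort$patients
  dm <- switch(denominator, pooled = pat$dm1 | pat$dm2,
               DM1 = pat$dm1, DM2 = pat$dm2)
  dmpat <- pat[dm]
  denom <- dmpat[, .N, by = .(age_group, sex)]
  groups <- age_groups(cohort$age_group_width, cohort$max_age)$index

  out <- rbindlist(lapply(attributes, function(attr) {
    carriers <- attribute_carriers(cohort, attr)
    num <- dmpat[patient_id %chin% carriers, .N, by = .(age_group, sex)]
    grid <- CJ(age_group = groups, sex = .sexes)
    tab <- denom[grid, on = c("age_group", "sex")]
    setnames(tab, "N", "n_dm")
    tab <- num[tab, on = c("age_group", "sex")]
    setnames(tab, "N", "n_x")
    for (col in c("n_dm", "n_x")) set(tab, which(is.na(tab[[col]])), col, 0L)
    wide <- dcast(tab, age_group ~ sex, value.var = c("n_dm", "n_x"))
    data.table(attribute = attr$name, age_group = wide$age_group,
               d_f = wide$n_dm_F, d_m = wide$n_dm_M,
               d_fx = wide$n_x_F, d_mx = wide$n_x_M)
  }))
  out[, sr_raw := sex_ratio(d_f, d_m, d_fx, d_mx, orientation = orientation)]
  out[, p_value := sr_significance(d_f, d_m, d_fx, d_mx)]
  out[, zero_reason := fifelse(
    d_fx == 0 | d_mx == 0, "zero co-occurrence",
    fifelse(p_value > p_zero, "not significant", ""))]
  out[, zeroed := zero_reason != ""]
  out[, sr := fifelse(zeroed, 0, sr_raw)]
  out[order(attribute, age_group)]
}
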