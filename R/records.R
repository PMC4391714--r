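#' Five-year age groups tiling the study age range
#'
#' The cohort is stratified into half-open five-year age intervals
#' \[0,5), \[5,10), ..., \[90,95): nineteen groups for the default maximum
#' age of 95. Ages at or above `max_age` are excluded at cohort
#' construction, so the groups partition the cohort exactly.
#'
#' @param width interval width in years.
#' @param max_age exclusive upper age bound in years.
#' @return A `data.table` with columns `index` (0-based), `lower`
#'   (inclusive), `upper` (exclusive) and `label`.
#' @export
#' @examples
#' age_groups()
age_groups <- function(width = 5, max_age = 95) {
  lower <- seq(0L, max_age - width, by = width)
  data.table(
    index = seq_along(lower) - 1L,
    lower = lower,
    upper = lower + as.integer(width),
    label = sprintf("%02d-%02d", lower, lower + as.integer(width) - 1L)
  )
}

# age -> group index; NA outside [0, max_age)
assign_age_group <- function(age, width = 5, max_age = 95) {
  idx <- age %/% width
  idx[age < 0 | age >= max_age] <- NA_integer_
  as.integer(idx)
}

.sexes <- c("M", "F")
.kinds <- c("diag_main", "diag_side", "rx")

validate_demographics <- function(demo, years) {
  req <- c("patient_id", "sex", "birth_year", "deceased")
  miss <- setdiff(req, names(demo))
  if (length(miss)) stopf("demographics table lacks column(s): %s", toString(miss))
  if (anyDuplicated(demo$patient_id)) {
    i <- which(duplicated(demo$patient_id))[1]
    stopf("duplicated patient_id '%s' (demographics row %d)", demo$patient_id[i], i)
  }
  bad <- which(!demo$sex %in% .sexes)
  if (length(bad)) stopf("unknown sex token '%s' (demographics row %d)", demo$sex[bad[1]], bad[1])
  bad <- which(!demo$deceased %in% c(0L, 1L))
  if (length(bad)) stopf("deceased must be 0 or 1 (demographics row %d)", bad[1])
  bad <- which(is.na(demo$birth_year) | demo$birth_year > max(years))
  if (length(bad)) stopf("invalid birth_year (demographics row %d)", bad[1])
  invisible(demo)
}

validate_events <- function(events, patient_ids, years) {
  req <- c("patient_id", "year", "kind", "code")
  miss <- setdiff(req, names(events))
  if (length(miss)) stopf("events table lacks column(s): %s", toString(miss))
  if (nrow(events) == 0L) return(invisible(events))
  bad <- which(!events$year %in% years)
  if (length(bad)) {
    stopf("event year %s outside study years {%s} (events row %d)",
          events$year[bad[1]], toString(years), bad[1])
  }
  bad <- which(!events$kind %in% .kinds)
  if (length(bad)) stopf("unknown event kind '%s' (events row %d)", events$kind[bad[1]], bad[1])
  is_diag <- events$kind %in% c("diag_main", "diag_side")
  bad <- which(is_diag & !is_icd3(events$code))
  if (length(bad)) {
    stopf("malformed ICD-10 code '%s', expected letter + two digits (events row %d)",
          events$code[bad[1]], bad[1])
  }
  bad <- which(!is_diag & !is_atc(events$code))
  if (length(bad)) stopf("malformed ATC code '%s' (events row %d)", events$code[bad[1]], bad[1])
  bad <- which(!events$patient_id %in% patient_ids)
  if (length(bad)) {
    stopf("event references unknown patient '%s' (events row %d)",
          events$patient_id[bad[1]], bad[1])
  }
  invisible(events)
}

#' Load a two-year claims dataset from delimited text files
#'
#' Reads the long/tidy interchange format: a demographics file with header
#' `patient_id,sex,birth_year,deceased` (sex `M`/`F`, deceased `0`/`1`) and
#' an events file with header `patient_id,year,kind,code` where `kind` is
#' one of `diag_main`, `diag_side`, `rx`. Diagnosis codes must be
#' 3-character ICD-10 (letter plus two digits); prescription codes must be
#' valid ATC codes. Every event row must reference a demographics row and
#' carry one of the two study years; violations raise an error naming the
#' offending row.
#'
#' @param demographics_path,events_path paths to the two delimited files.
#' @param years the two study calendar years.
#' @param sep field separator.
#' @return A `claims_data` object: a list with `data.table`s `demographics`
#'   and `events` plus the study `years`.
#' @seealso [write_claims()], [build_cohort()]
#' @export
read_claims <- function(demographics_path, events_path, years = c(2006L, 2007L),
                        sep = ",") {
  if (!file.exists(demographics_path)) stopf("no such file: %s", demographics_path)
  if (!file.exists(events_path)) stopf("no such file: %s", events_path)
  demo <- fread(demographics_path, sep = sep, colClasses = list(
    character = "patient_id", character = "sex"))
  events <- fread(events_path, sep = sep, colClasses = list(
    character = c("patient_id", "kind", "code")))
  if (nrow(events) == 0L) {
    events <- data.table(patient_id = character(), year = integer(),
                         kind = character(), code = character())
  }
  claims_data(demo, events, years = years)
}

#' Assemble a claims dataset from in-memory tables
#'
#' @param demographics data.frame with columns `patient_id`, `sex`,
#'   `birth_year`, `deceased`.
#' @param events data.frame with columns `patient_id`, `year`, `kind`,
#'   `code` (may have zero rows).
#' @param years the two study calendar years.
#' @return A validated `claims_data` object.
#' @export
claims_data <- function(demographics, events, years = c(2006L, 2007L)) {
  stopifnot(length(years) == 2L, years[1] != years[2])
  demo <- as.data.table(demographics)
  events <- as.data.table(events)
  demo[, `:=`(patient_id = as.character(patient_id),
              birth_year = as.integer(birth_year),
              deceased = as.integer(deceased))]
  if (nrow(events)) {
    events[, `:=`(patient_id = as.character(patient_id), year = as.integer(year))]
  }
  validate_demographics(demo, years)
  validate_events(events, demo$patient_id, years)
  structure(list(demographics = demo[], events = events[],
                 years = sort(as.integer(years))),
            class = "claims_data")
}

#' Write a claims dataset to the delimited interchange format
#'
#' @param data a `claims_data` object (or a list with `demographics` and
#'   `events` tables).
#' @param demographics_path,events_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_claims <- function(data, demographics_path, events_path) {
  fwrite(data$demographics[, .(patient_id, sex, birth_year, deceased)],
         demographics_path)
  ev <- data$events
  if (nrow(ev) == 0L) {
    writeLines("patient_id,year,kind,code", events_path)
  } else {
    fwrite(ev[, .(patient_id, year, kind, code)], events_path)
  }
  invisible(c(demographics_path, events_path))
}

#' @export
print.claims_data <- function(x, ...) {
  cat(sprintf("<claims_data> %d patients, %d events, years %s\n",
              nrow(x$demographics), nrow(x$events), paste(x$years, collapse = "-")))
  invisible(x)
}

#' Build the analysis cohort
#'
#' Applies the inclusion and exclusion rules: patients deceased during the
#' study window are removed, as are patients whose age (reference year
#' minus birth year) falls at or above `max_age`, so that the five-year
#' age groups tile the cohort exactly. Diabetes membership is assigned
#' from any E10 (type 1) or E11 (type 2) diagnosis event, main or side, in
#' either year; a patient carrying both codes belongs to both groups.
#' Under `definition = "prescription_a10"` (a robustness-check cohort
#' definition) diabetes membership is instead assigned from any
#' prescription event whose ATC code starts with `A10` (drugs used in
#' diabetes), without distinguishing the two types.
#'
#' @param data a `claims_data` object.
#' @param definition `"inpatient"` (diagnosis-based membership, the primary
#'   definition) or `"prescription_a10"`.
#' @param reference_year year used to compute age; defaults to the later
#'   study year.
#' @param max_age exclusive upper age bound (years).
#' @param age_group_width age stratum width (years).
#' @return A `claims_cohort`: list with `patients` (one row per retained
#'   patient: `patient_id`, `sex`, `age`, `age_group`, `dm1`, `dm2`),
#'   `events` (restricted to retained patients), the id sets `dm1_ids` and
#'   `dm2_ids`, and the configuration used.
#' @export
build_cohort <- function(data, definition = c("inpatient", "prescription_a10"),
                         reference_year = NULL, max_age = 95,
                         age_group_width = 5) {
  definition <- match.arg(definition)
  reference_year <- as.integer(reference_year %||% max(data$years))
  demo <- data$demographics
  events <- data$events

  pat <- demo[deceased == 0L]
  pat[, age := reference_year - birth_year]
  pat <- pat[age >= 0L & age < max_age]
  pat[, age_group := assign_age_group(age, age_group_width, max_age)]

  ev <- events[patient_id %chin% pat$patient_id]
  if (definition == "inpatient") {
    is_diag <- ev$kind %chin% c("diag_main", "diag_side")
    dm1_ids <- unique(ev$patient_id[is_diag & ev$code == "E10"])
    dm2_ids <- unique(ev$patient_id[is_diag & ev$code == "E11"])
  } else {
    a10 <- unique(ev$patient_id[ev$kind == "rx" & startsWith(ev$code, "A10")])
    dm1_ids <- dm2_ids <- a10
  }
  pat[, dm1 := patient_id %chin% dm1_ids]
  pat[, dm2 := patient_id %chin% dm2_ids]

  structure(list(
    patients = pat[, .(patient_id, sex, birth_year, age, age_group, dm1, dm2)],
    events = ev,
    dm1_ids = dm1_ids,
    dm2_ids = dm2_ids,
    years = data$years,
    definition = definition,
    reference_year = reference_year,
    max_age = as.integer(max_age),
    age_group_width = as.integer(age_group_width)
  ), class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat(sprintf(
    "<claims_cohort> %d patients (definition: %s), %d DM1, %d DM2, ref. year %d\n",
    nrow(x$patients), x$definition, length(x$dm1_ids), length(x$dm2_ids),
    x$reference_year))
  invisible(x)
}

#' Cohort summary counts
#'
#' Tabulates the cohort by sex overall and within the type 1 and type 2
#' diabetes groups, and gives the per-age-group composition (patient
#' counts by sex and the fraction of each age group carrying each
#' diabetes type -- the age/sex prevalence profile of the cohort).
#'
#' @param cohort a `claims_cohort`.
#' @return A list with `counts` (rows `DM1`, `DM2`, `cohort`; columns
#'   `male`, `female`, `total`) and `by_age` (per age group and sex:
#'   `n`, `n_dm1`, `n_dm2`, `frac_dm1`, `frac_dm2`).
#' @export
cohort_summary <- function(cohort) {
  pat <- cohort$patients
  count_row <- function(sub, label) {
    data.table(group = label,
               male = sum(sub$sex == "M"),
               female = sum(sub$sex == "F"))
  }
  counts <- rbind(count_row(pat[dm1 == TRUE], "DM1"),
                  count_row(pat[dm2 == TRUE], "DM2"),
                  count_row(pat, "cohort"))
  counts[, total := male + female]

  groups <- age_groups(cohort$age_group_width, cohort$max_age)
  if (nrow(pat)) {
    by_age <- pat[, .(n = .N, n_dm1 = sum(dm1), n_dm2 = sum(dm2)),
                  by = .(age_group, sex)]
  } else {
    by_age <- data.table(age_group = integer(), sex = character(),
                         n = integer(), n_dm1 = integer(), n_dm2 = integer())
  }
  grid <- CJ(age_group = groups$index, sex = .sexes)
  by_age <- by_age[grid, on = c("age_group", "sex")]
  for (col in c("n", "n_dm1", "n_dm2")) {
    set(by_age, which(is.na(by_age[[col]])), col, 0L)
  }
  by_age[, `:=`(frac_dm1 = ifelse(n > 0, n_dm1 / n, NA_real_),
                frac_dm2 = ifelse(n > 0, n_dm2 / n, NA_real_))]
  by_age <- groups[by_age, on = c(index = "age_group")]
  setnames(by_age, "index", "age_group")
  list(counts = counts[], by_age = by_age[order(age_group, sex)])
}
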