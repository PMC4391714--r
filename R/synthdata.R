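#' Default candidate diagnosis universe for the synthetic generator
#'
#' Forty-two 3-character ICD-10 codes from chapters A-N: the 22 codes of
#' the packaged reference list of well-established diabetic complications
#' (see [reference_comorbidities()]) plus twenty further codes spread over
#' the chapters, so that planted and null codes coexist.
#'
#' @return character vector of ICD-10 codes.
#' @export
default_code_universe <- function() {
  sort(unique(c(
    reference_comorbidities(),
    c("A09", "A41", "B18", "C25", "C34", "D50", "E03", "E66", "F03", "F32",
      "G20", "G40", "H25", "J18", "J44", "K80", "K81", "L89", "M48", "N39")
  )))
}

#' Default parameter pieces of the synthetic generator
#'
#' Building blocks of the default [sim_config()]: the hospitalised-
#' population age weights, the age/sex diabetes prevalence bands, the
#' per-code baseline prevalences, the planted relative-risk, sex and
#' temporal effects, and the prescription (ATC) universe. Exported so
#' that calibration and recovery experiments can start from the defaults
#' and override single pieces.
#'
#' @param codes diagnosis code universe (where applicable).
#' @return A numeric vector or `data.table`, matching the corresponding
#'   `sim_config()` argument.
#' @name sim_defaults
NULL

#' @rdname sim_defaults
#' @export
default_age_weights <- function() {
  age <- 0:94
  # hospitalised-population shape: early-childhood bump, dip around age ten,
  # then monotone rise into old age
  w <- 0.35 + 1.6 * (age / 94)^1.4 + 0.55 * exp(-((age - 2) / 3.5)^2) -
    0.12 * exp(-((age - 10) / 5)^2)
  w / sum(w)
}

#' @rdname sim_defaults
#' @export
default_dm_prevalence <- function() {
  rbind(
    data.table(type = "DM1", sex = "*", age_lo = c(0, 20, 60),
               age_hi = c(20, 60, 95), prob = c(0.006, 0.008, 0.012)),
    data.table(type = "DM2", sex = "M", age_lo = c(0, 30, 50, 70),
               age_hi = c(30, 50, 70, 95), prob = c(0.002, 0.02, 0.10, 0.16)),
    data.table(type = "DM2", sex = "F", age_lo = c(0, 30, 50, 70),
               age_hi = c(30, 50, 70, 95), prob = c(0.002, 0.018, 0.09, 0.18))
  )
}

#' @rdname sim_defaults
#' @export
default_baseline_prevalence <- function(codes) {
  base <- rep_len(c(0.010, 0.025, 0.045, 0.015, 0.060, 0.020, 0.035, 0.008),
                  length(codes))
  names(base) <- codes
  if ("I10" %in% codes) base["I10"] <- 0.15  # hypertension is common
  base
}

#' @rdname sim_defaults
#' @export
default_rr_effects <- function(codes) {
  ref <- intersect(reference_comorbidities(), codes)
  rr <- rep_len(c(4, 2, 6, 3), length(ref))
  rbind(
    data.table(code = ref, type = "DM1", age_lo = 0, age_hi = 95, rr = rr),
    data.table(code = ref, type = "DM2", age_lo = 0, age_hi = 95, rr = rr)
  )
}

#' @rdname sim_defaults
#' @export
default_sex_effects <- function() c(E66 = 2.0, N39 = 2.0, I10 = 1.5, C34 = 0.5)

#' @rdname sim_defaults
#' @export
default_temporal_effects <- function() {
  data.table(code = c("F32", "I50", "J18"),
             type = c("DM1", "DM2", "DM2"),
             sex = c("M", "F", "M"),
             lambda = c(3, 3, 3))
}

#' @rdname sim_defaults
#' @export
default_atc_universe <- function() {
  c(A10 = 0.010, N02 = 0.060, N05 = 0.040, N06 = 0.030, C03 = 0.050,
    C07 = 0.060, C09 = 0.070, C10 = 0.050, L01 = 0.010)
}

#' Configuration of the synthetic claims generator
#'
#' Defines a two-year synthetic claims population with planted,
#' recoverable structure: an age pyramid and sex balance emulating a
#' hospitalised population, age- and sex-dependent diabetes prevalence,
#' per-diagnosis baseline prevalence modulated by an age profile,
#' multiplicative relative-risk effects for diabetic patients, sex
#' effects, and temporal lead effects (extra fresh second-year main
#' diagnoses in patients with first-year diabetes). Passing `NULL` for
#' `rr_effects`, `sex_effects` or `temporal_effects` removes the
#' corresponding planted structure; an all-`NULL` configuration is a
#' global null in which diagnosis occurrence is independent of diabetes,
#' sex-balanced, and exchangeable between the two years.
#'
#' @param n_patients number of simulated persons.
#' @param seed integer seed; the generator is fully reproducible given the
#'   seed and the configuration.
#' @param p_female probability a patient is female.
#' @param p_deceased probability the deceased-in-window flag is set (such
#'   patients are generated, then removed at cohort construction).
#' @param age_weights sampling weights over ages 0..94.
#' @param dm_prevalence `data.frame(type, sex, age_lo, age_hi, prob)` of
#'   diabetes prevalence; `sex = "*"` applies to both sexes. Bands are
#'   half-open `[age_lo, age_hi)`.
#' @param codes candidate ICD-10 diagnosis universe.
#' @param baseline_prevalence named per-code per-window occurrence
#'   probability at the reference age profile (before effects).
#' @param age_profile multiplier applied to baselines as a function of
#'   age: numeric vector of length 95 (ages 0..94).
#' @param rr_effects `data.frame(code, type, age_lo, age_hi, rr)`: planted
#'   multiplicative relative risks for diabetic patients, or `NULL`.
#' @param sex_effects named per-code female/male rate ratio, or `NULL`.
#' @param temporal_effects `data.frame(code, type, sex, lambda)`: planted
#'   lead effects, or `NULL`. Among patients of the given sex with a
#'   first-year diagnosis of the given diabetes type and no occurrence of
#'   `code` in year one, an extra fresh year-two main diagnosis of `code`
#'   is added with probability `(lambda - 1)` times the patient's baseline
#'   occurrence probability (capped at 1); `lambda = 1` plants nothing.
#' @param persistence probability an occurring condition is coded in both
#'   years; the remainder is split evenly between year-one-only and
#'   year-two-only, so the null generator is exchangeable in the year
#'   labels.
#' @param main_diag_prob probability a diagnosis event is coded as a main
#'   (rather than side) diagnosis.
#' @param atc_prevalence named per-ATC-code baseline prescription
#'   probability.
#' @param atc_dm_mult named per-ATC-code multiplier applied to diabetic
#'   patients (default: antidiabetic drugs `A10` are 60 times more likely,
#'   supporting the prescription-based cohort definition).
#' @param atc_sex_effects named per-ATC-code female/male rate ratio.
#' @param t1,t2 the two study calendar years.
#' @return A validated `sim_config` object (a list).
#' @seealso [simulate_population()], [planted_truth()]
#' @export
sim_config <- function(n_patients = 10000,
                       seed = 1L,
                       p_female = 0.57,
                       p_deceased = 0.02,
                       age_weights = default_age_weights(),
                       dm_prevalence = default_dm_prevalence(),
                       codes = default_code_universe(),
                       baseline_prevalence = default_baseline_prevalence(codes),
                       age_profile = 0.35 + 1.3 * ((0:94) / 94)^1.2,
                       rr_effects = default_rr_effects(codes),
                       sex_effects = default_sex_effects(),
                       temporal_effects = default_temporal_effects(),
                       persistence = 0.5,
                       main_diag_prob = 0.35,
                       atc_prevalence = default_atc_universe(),
                       atc_dm_mult = c(A10 = 60),
                       atc_sex_effects = c(N05 = 2.0, C10 = 0.6),
                       t1 = 2006L, t2 = 2007L) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    p_female = p_female, p_deceased = p_deceased,
    age_weights = age_weights,
    dm_prevalence = as.data.table(dm_prevalence),
    codes = codes,
    baseline_prevalence = baseline_prevalence,
    age_profile = age_profile,
    rr_effects = if (!is.null(rr_effects)) as.data.table(rr_effects),
    sex_effects = sex_effects,
    temporal_effects = if (!is.null(temporal_effects)) as.data.table(temporal_effects),
    persistence = persistence, main_diag_prob = main_diag_prob,
    atc_prevalence = atc_prevalence,
    atc_dm_mult = atc_dm_mult,
    atc_sex_effects = atc_sex_effects,
    t1 = as.integer(t1), t2 = as.integer(t2)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, what) {
    bad <- which(is.na(x) | x < 0 | x > 1)
    if (length(bad)) {
      nm <- if (!is.null(names(x))) names(x)[bad[1]] else as.character(bad[1])
      stopf("invalid %s entry '%s': probability must be in [0, 1]", what, nm)
    }
  }
  if (cfg$n_patients < 1L) stopf("invalid n_patients: must be >= 1")
  if (cfg$t1 == cfg$t2) stopf("invalid study years: t1 must differ from t2")
  chk_prob(cfg$p_female, "p_female"); chk_prob(cfg$p_deceased, "p_deceased")
  chk_prob(cfg$persistence, "persistence")
  chk_prob(cfg$main_diag_prob, "main_diag_prob")
  if (length(cfg$age_weights) != 95 || any(cfg$age_weights < 0)) {
    stopf("invalid age_weights: need 95 non-negative weights (ages 0..94)")
  }
  if (length(cfg$age_profile) != 95 || any(cfg$age_profile < 0)) {
    stopf("invalid age_profile: need 95 non-negative multipliers (ages 0..94)")
  }
  bad <- which(!is_icd3(cfg$codes))
  if (length(bad)) stopf("invalid code universe entry '%s'", cfg$codes[bad[1]])
  if (!setequal(names(cfg$baseline_prevalence), cfg$codes)) {
    stopf("baseline_prevalence must name exactly the code universe")
  }
  chk_prob(cfg$baseline_prevalence, "baseline_prevalence")
  chk_prob(cfg$dm_prevalence$prob, "dm_prevalence")
  if (!all(cfg$dm_prevalence$type %in% c("DM1", "DM2"))) {
    stopf("invalid dm_prevalence entry: type must be DM1 or DM2")
  }
  if (!is.null(cfg$rr_effects)) {
    if (!all(c("code", "type", "age_lo", "age_hi", "rr") %in% names(cfg$rr_effects))) {
      stopf("rr_effects needs columns code, type, age_lo, age_hi, rr")
    }
    bad <- which(!(cfg$rr_effects$rr > 0))
    if (length(bad)) stopf("invalid rr_effects entry '%s': rr must be > 0",
                           cfg$rr_effects$code[bad[1]])
    bad <- which(!cfg$rr_effects$code %in% cfg$codes)
    if (length(bad)) stopf("rr_effects entry '%s' not in code universe",
                           cfg$rr_effects$code[bad[1]])
  }
  if (!is.null(cfg$sex_effects)) {
    bad <- which(!(cfg$sex_effects > 0))
    if (length(bad)) stopf("invalid sex_effects entry '%s': ratio must be > 0",
                           names(cfg$sex_effects)[bad[1]])
  }
  if (!is.null(cfg$temporal_effects)) {
    if (!all(c("code", "type", "sex", "lambda") %in% names(cfg$temporal_effects))) {
      stopf("temporal_effects needs columns code, type, sex, lambda")
    }
    bad <- which(!(cfg$temporal_effects$lambda > 0))
    if (length(bad)) stopf("invalid temporal_effects entry '%s': lambda must be > 0",
                           cfg$temporal_effects$code[bad[1]])
  }
  chk_prob(cfg$atc_prevalence, "atc_prevalence")
  invisible(cfg)
}

# prevalence lookup vectorised over patients
dm_prev_lookup <- function(dm_prevalence, type_, age, sex) {
  p <- numeric(length(age))
  rows <- dm_prevalence[type == type_]
  for (i in seq_len(nrow(rows))) {
    sel <- age >= rows$age_lo[i] & age < rows$age_hi[i] &
      (rows$sex[i] == "*" | sex == rows$sex[i])
    p[sel] <- rows$prob[i]
  }
  p
}

# draw year pattern for occurring conditions: 1 = year-1 only, 2 = year-2
# only, 3 = both; symmetric in the year labels
draw_year_pattern <- function(n, persistence) {
  u <- runif(n)
  pattern <- integer(n)
  pattern[u < persistence] <- 3L
  lone <- u >= persistence
  pattern[lone] <- 1L + (u[lone] >= persistence + (1 - persistence) / 2)
  pattern
}

# expand (patient index, pattern) into event rows for one code
pattern_events <- function(idx, pattern, code, t1, t2, main_diag_prob,
                           kind_rx = FALSE) {
  idx1 <- idx[pattern != 2L]
  idx2 <- idx[pattern != 1L]
  pid <- c(idx1, idx2)
  yr <- c(rep(t1, length(idx1)), rep(t2, length(idx2)))
  if (kind_rx) {
    kind <- rep("rx", length(pid))
  } else {
    kind <- ifelse(runif(length(pid)) < main_diag_prob, "diag_main", "diag_side")
  }
  list(idx = pid, year = yr, kind = kind, code = rep(code, length(pid)))
}

#' Simulate a two-year synthetic claims population
#'
#' Draws patients (age, sex, deceased flag), diabetes status, diagnosis
#' occurrences with planted relative-risk, sex and temporal effects, and
#' prescription events, and assembles them into the long/tidy claims
#' interchange format. The generator is deterministic given
#' `config$seed`: two calls with the same configuration produce identical
#' datasets.
#'
#' @param config a [sim_config()].
#' @return A list with `data` (a `claims_data` object) and `truth` (the
#'   [planted_truth()] of the configuration).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    n <- config$n_patients
    t1 <- config$t1; t2 <- config$t2
    age <- sample(0:94, n, replace = TRUE, prob = config$age_weights)
    sex <- ifelse(runif(n) < config$p_female, "F", "M")
    deceased <- as.integer(runif(n) < config$p_deceased)

    dm1 <- runif(n) < dm_prev_lookup(config$dm_prevalence, "DM1", age, sex)
    dm2 <- runif(n) < dm_prev_lookup(config$dm_prevalence, "DM2", age, sex)

    ev <- list()
    # diabetes diagnosis events; remember who carries a year-1 diagnosis,
    # the anchor for the planted temporal effects
    dm_t1 <- list(DM1 = logical(n), DM2 = logical(n))
    for (ty in c("DM1", "DM2")) {
      has <- if (ty == "DM1") dm1 else dm2
      idx <- which(has)
      pattern <- draw_year_pattern(length(idx), config$persistence)
      dm_t1[[ty]][idx[pattern != 2L]] <- TRUE
      ev[[length(ev) + 1L]] <- pattern_events(
        idx, pattern, if (ty == "DM1") "E10" else "E11",
        t1, t2, config$main_diag_prob)
    }

    amult <- config$age_profile[age + 1L]
    fem <- sex == "F"
    te <- config$temporal_effects
    for (x in config$codes) {
      p_base <- config$baseline_prevalence[[x]] * amult
      if (!is.null(config$sex_effects) && x %in% names(config$sex_effects)) {
        p_base[fem] <- p_base[fem] * config$sex_effects[[x]]
      }
      mult <- rep(1, n)
      if (!is.null(config$rr_effects)) {
        eff <- config$rr_effects[code == x]
        for (i in seq_len(nrow(eff))) {
          has <- if (eff$type[i] == "DM1") dm1 else dm2
          sel <- has & age >= eff$age_lo[i] & age < eff$age_hi[i]
          mult[sel] <- pmax(mult[sel], eff$rr[i])
        }
      }
      p <- pmin(1, p_base * mult)
      occ <- runif(n) < p
      idx <- which(occ)
      pattern <- draw_year_pattern(length(idx), config$persistence)
      ev[[length(ev) + 1L]] <- pattern_events(idx, pattern, x, t1, t2,
                                              config$main_diag_prob)
      if (!is.null(te) && x %in% te$code) {
        # planted lead effect: fresh year-2 main diagnoses among patients
        # with year-1 diabetes and no year-1 occurrence of x
        has_x_t1 <- logical(n)
        has_x_t1[idx[pattern != 2L]] <- TRUE
        rows <- te[code == x]
        for (i in seq_len(nrow(rows))) {
          qual <- dm_t1[[rows$type[i]]] & sex == rows$sex[i] & !has_x_t1
          # boost acts on the patient's baseline risk, independent of any
          # planted relative-risk effect
          p_extra <- pmin(1, pmax(0, rows$lambda[i] - 1) * p_base)
          extra <- which(qual & runif(n) < p_extra)
          if (length(extra)) {
            ev[[length(ev) + 1L]] <- list(
              idx = extra, year = rep(t2, length(extra)),
              kind = rep("diag_main", length(extra)),
              code = rep(x, length(extra)))
          }
        }
      }
    }

    # prescriptions
    for (x in names(config$atc_prevalence)) {
      p <- rep(config$atc_prevalence[[x]], n)
      if (x %in% names(config$atc_sex_effects)) {
        p[fem] <- p[fem] * config$atc_sex_effects[[x]]
      }
      if (x %in% names(config$atc_dm_mult)) {
        p[dm1 | dm2] <- p[dm1 | dm2] * config$atc_dm_mult[[x]]
      }
      occ <- which(runif(n) < pmin(1, p))
      pattern <- draw_year_pattern(length(occ), config$persistence)
      ev[[length(ev) + 1L]] <- pattern_events(occ, pattern, x, t1, t2,
                                              config$main_diag_prob,
                                              kind_rx = TRUE)
    }

    pid <- sprintf("P%07d", seq_len(n))
    events <- rbindlist(lapply(ev, as.data.table))
    events <- unique(data.table(
      patient_id = pid[events$idx], year = as.integer(events$year),
      kind = events$kind, code = events$code))
    setkey(events, patient_id, year, kind, code)
    demo <- data.table(patient_id = pid, sex = sex,
                       birth_year = as.integer(t2 - age), deceased = deceased)
    list(data = claims_data(demo, events, years = c(t1, t2)),
         truth = planted_truth(config))
  })
}

#' Planted truth of a simulation configuration
#'
#' Pure function of the configuration (no randomness): the effects a
#' correct analysis should recover.
#'
#' @param config a [sim_config()].
#' @return A list with `rr` (planted relative risks per code, diabetes
#'   type and age band; codes without an effect have true RR 1),
#'   `sex_sign` (per code: `"F"` female excess, `"M"` male excess,
#'   `"none"`), and `lead_pairs` (planted temporal lead effects,
#'   `lambda > 1`).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base <- CJ(code = config$codes, type = c("DM1", "DM2"))
  base[, `:=`(age_lo = 0, age_hi = 95, rr = 1)]
  if (!is.null(config$rr_effects) && nrow(config$rr_effects)) {
    eff <- config$rr_effects[, .(code, type, age_lo, age_hi, rr)]
    base <- rbind(base[!eff, on = c("code", "type")], eff)
  }
  setkey(base, code, type)
  sgn <- rep("none", length(config$codes))
  names(sgn) <- config$codes
  if (!is.null(config$sex_effects)) {
    se <- config$sex_effects[names(config$sex_effects) %in% config$codes]
    sgn[names(se)[se > 1]] <- "F"
    sgn[names(se)[se < 1]] <- "M"
  }
  leads <- if (!is.null(config$temporal_effects)) {
    config$temporal_effects[lambda > 1,
                            .(code, type, sex, lambda)]
  } else {
    data.table(code = character(), type = character(), sex = character(),
               lambda = numeric())
  }
  list(
    rr = base[],
    sex_sign = data.table(code = config$codes, sign = unname(sgn[config$codes])),
    lead_pairs = leads
  )
}
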