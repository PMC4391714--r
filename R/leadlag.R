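# --- internal engine -------------------------------------------------------
#
# The lead/lag statistics and the surrogate test depend only on, per
# patient: which years hold an event of the index diagnosis d_i (main or
# side), of the candidate x (main or side), and of a MAIN diagnosis of
# d_i / x -- plus, for the permutation null, the patient's total number of
# diagnosis events in each year (codes other than d_i and x matter only
# through these counts, because a surrogate permutes the patient's whole
# multiset of diagnosis years). build_pair_env() extracts that reduced
# representation once per (d_i, x, sex); surrogates then resample the year
# labels of the d_i/x event slots by sequential sampling without
# replacement from the patient's year multiset, which is equivalent to a
# uniformly random permutation of all the patient's diagnosis years.

build_pair_env <- function(cohort, d_i, x, sex_, max_age = NULL) {
  t1 <- cohort$years[1]; t2 <- cohort$years[2]
  pat <- cohort$patients[sex == sex_]
  ev <- cohort$events[patient_id %chin% pat$patient_id &
                        kind %chin% c("diag_main", "diag_side")]
  tot <- ev[, .(n_tot = .N, n_t1 = sum(year == t1)), by = patient_id]
  special <- ev[code %chin% c(d_i, x)]
  ids <- sort(unique(special$patient_id))
  P <- length(ids)
  special[, pid := match(patient_id, ids)]
  setorder(special, pid)
  special[, pos := seq_len(.N), by = pid]
  tot <- tot[data.table(patient_id = ids), on = "patient_id"]
  lag_ok <- rep(TRUE, P)
  if (!is.null(max_age)) {
    age_of <- pat$age[match(ids, pat$patient_id)]
    lag_ok <- age_of <= max_age
  }
  list(
    P = P, t1 = t1, t2 = t2,
    slot_pid = special$pid,
    slot_pos = special$pos,
    slot_is_di = special$code == d_i,
    slot_is_x = special$code == x,
    slot_is_main = special$kind == "diag_main",
    slot_year = special$year,
    pat_n_tot = tot$n_tot,
    pat_n_t1 = tot$n_t1,
    lag_ok = lag_ok
  )
}

# per-patient flags from slot year labels
pair_flags <- function(env, slot_year) {
  P <- env$P
  f <- function(sel) {
    v <- logical(P); v[env$slot_pid[sel]] <- TRUE; v
  }
  y1 <- slot_year == env$t1
  list(
    di_t1 = f(env$slot_is_di & y1),
    di_t2 = f(env$slot_is_di & !y1),
    x_t1 = f(env$slot_is_x & y1),
    x_t2 = f(env$slot_is_x & !y1),
    xm_t1 = f(env$slot_is_x & env$slot_is_main & y1),
    xm_t2 = f(env$slot_is_x & env$slot_is_main & !y1),
    dim_t1 = f(env$slot_is_di & env$slot_is_main & y1),
    dim_t2 = f(env$slot_is_di & env$slot_is_main & !y1)
  )
}

# conditional probabilities and indicators from flags; zero_undefined
# controls the 0-denominator convention (NA for observed data, 0 inside
# the surrogate loop where an indicator value is always needed)
pair_stats <- function(fl, lag_ok, zero_undefined = FALSE) {
  prop <- function(num, den) {
    d <- sum(den)
    if (d == 0L) {
      if (zero_undefined) 0 else NA_real_
    } else sum(num & den) / d
  }
  lead_fwd_den <- fl$di_t1 & !fl$x_t1
  lead_rev_den <- fl$di_t2 & !fl$x_t2
  lag_fwd_den <- fl$x_t1 & !fl$di_t1 & lag_ok
  lag_rev_den <- fl$x_t2 & !fl$di_t2 & lag_ok
  p_lead_fwd <- prop(fl$xm_t2, lead_fwd_den)
  p_lead_rev <- prop(fl$xm_t1, lead_rev_den)
  p_lag_fwd <- prop(fl$dim_t2, lag_fwd_den)
  p_lag_rev <- prop(fl$dim_t1, lag_rev_den)
  list(p_lead_fwd = p_lead_fwd, p_lead_rev = p_lead_rev,
       p_lag_fwd = p_lag_fwd, p_lag_rev = p_lag_rev,
       i_lead = p_lead_fwd - p_lead_rev,
       i_lag = p_lag_fwd - p_lag_rev)
}

# resample slot years: a uniformly random permutation of each patient's
# diagnosis-year multiset, restricted to the d_i/x slots
permute_slot_years <- function(env) {
  k_rem <- env$pat_n_t1
  n_rem <- env$pat_n_tot
  yr <- integer(length(env$slot_pid))
  max_pos <- if (length(env$slot_pos)) max(env$slot_pos) else 0L
  for (j in seq_len(max_pos)) {
    sel <- which(env$slot_pos == j)
    pid <- env$slot_pid[sel]
    take_t1 <- runif(length(sel)) < k_rem[pid] / n_rem[pid]
    yr[sel] <- ifelse(take_t1, env$t1, env$t2)
    k_rem[pid] <- k_rem[pid] - take_t1
    n_rem[pid] <- n_rem[pid] - 1L
  }
  yr
}

# --- exported operations ---------------------------------------------------

#' Conditional two-year incidence probability for a diagnosis pair
#'
#' The building block of the lead indicator: the forward direction is
#' `p(x, t2 | d_i, not x, t1)` -- among patients of the given sex with a
#' diagnosis of `d_i` (main or side) in year 1 and no diagnosis of `x`
#' (main or side) in year 1, the fraction acquiring a *main* diagnosis of
#' `x` in year 2. The reverse direction exchanges the two years.
#'
#' @param cohort a `claims_cohort`.
#' @param d_i index diagnosis code (`"E10"` or `"E11"`).
#' @param x candidate diagnosis code.
#' @param sex `"M"` or `"F"`.
#' @param direction `"forward"` or `"reverse"`.
#' @param max_age optional inclusive age cap restricting the analysis
#'   population.
#' @return the probability, or `NA` if the denominator is empty.
#' @export
pair_probability <- function(cohort, d_i, x, sex,
                             direction = c("forward", "reverse"),
                             max_age = NULL) {
  direction <- match.arg(direction)
  env <- build_pair_env(cohort, d_i, x, sex, max_age = max_age)
  if (!is.null(max_age)) {
    # cap applies to the whole analysis population here
    keep <- env$lag_ok
  } else keep <- rep(TRUE, env$P)
  fl <- pair_flags(env, env$slot_year)
  if (direction == "forward") {
    den <- fl$di_t1 & !fl$x_t1 & keep
    num <- fl$xm_t2
  } else {
    den <- fl$di_t2 & !fl$x_t2 & keep
    num <- fl$xm_t1
  }
  if (sum(den) == 0L) return(NA_real_)
  sum(num & den) / sum(den)
}

#' Lead and lag indicators for one (index, candidate, sex) triple
#'
#' The lead indicator is the difference of the forward and reverse
#' conditional probabilities of [pair_probability()]; positive values
#' indicate the candidate diagnosis tends to be newly coded *after* the
#' index diagnosis. The lag indicator exchanges the roles of `d_i` and
#' `x` (is the index diagnosis newly coded after the candidate?). For the
#' type 1 index diagnosis (`d_i = "E10"`) the lag analysis is restricted
#' to patients aged `max_age_lag_dm1` or younger. The pair is excluded
#' when fewer than `z` patients of the given sex have a main diagnosis of
#' `x` in year 2 together with `d_i` in either year; an indicator whose
#' conditional probabilities have an empty denominator is reported as `NA`
#' without excluding the other indicator.
#'
#' @inheritParams pair_probability
#' @param z minimum qualifying-patient threshold.
#' @param max_age_lag_dm1 inclusive age cap for the DM1 lag analysis.
#' @return one-row `data.table`: `d_i`, `x`, `sex`, `n_qualifying`,
#'   `excluded`, `excluded_reason`, `i_lead`, `i_lag` and the four
#'   conditional probabilities (`NA` when excluded).
#' @export
lead_lag_indicators <- function(cohort, d_i, x, sex, z = 50,
                                max_age_lag_dm1 = 30) {
  env <- build_pair_env(cohort, d_i, x, sex,
                        max_age = if (d_i == "E10") max_age_lag_dm1)
  fl <- pair_flags(env, env$slot_year)
  n_qual <- sum(fl$xm_t2 & (fl$di_t1 | fl$di_t2))
  st <- pair_stats(fl, env$lag_ok, zero_undefined = FALSE)
  excluded <- n_qual < z
  reason <- if (excluded) {
    sprintf("below threshold z (%d < %d)", n_qual, as.integer(z))
  } else ""
  # an empty denominator leaves that indicator (only) undefined
  if (excluded) st <- lapply(st, function(.) NA_real_)
  data.table(
    d_i = d_i, x = x, sex = sex, n_qualifying = n_qual,
    excluded = excluded, excluded_reason = reason,
    i_lead = st$i_lead, i_lag = st$i_lag,
    p_lead_fwd = st$p_lead_fwd, p_lead_rev = st$p_lead_rev,
    p_lag_fwd = st$p_lag_fwd, p_lag_rev = st$p_lag_rev
  )
}

#' Surrogate-data permutation test for the lead/lag indicators
#'
#' Surrogate datasets keep every patient's multiset of diagnosis events
#' (codes and main/side flags) fixed and replace the year labels by a
#' uniformly random permutation of that patient's own years; prescriptions
#' are untouched. The indicators are recomputed on each surrogate and the
#' p-value is the fraction of surrogates whose indicator reaches the
#' observed value (`ties = "ge"`, the conservative convention;
#' `ties = "gt"` counts strictly larger values only). Surrogate `r` uses a
#' sub-seed derived from `seed`, so individual surrogates are reproducible
#' in isolation.
#'
#' @inheritParams lead_lag_indicators
#' @param n_surrogates number of surrogate datasets.
#' @param seed integer seed for the permutation stream.
#' @param ties `"ge"` or `"gt"`.
#' @return a list with `p_lead`, `p_lag`, the observed indicators and the
#'   surrogate exceedance counts.
#' @export
surrogate_test <- function(cohort, d_i, x, sex, n_surrogates = 1000,
                           seed = 1L, z = 50, max_age_lag_dm1 = 30,
                           ties = c("ge", "gt")) {
  ties <- match.arg(ties)
  obs <- lead_lag_indicators(cohort, d_i, x, sex, z = z,
                             max_age_lag_dm1 = max_age_lag_dm1)
  if (obs$excluded) {
    stopf("pair (%s, %s, %s) is excluded: %s", d_i, x, sex, obs$excluded_reason)
  }
  env <- build_pair_env(cohort, d_i, x, sex,
                        max_age = if (d_i == "E10") max_age_lag_dm1)
  sub_seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                           n_surrogates))
  surr_lead <- numeric(n_surrogates)
  surr_lag <- numeric(n_surrogates)
  for (r in seq_len(n_surrogates)) {
    yr <- local_seed(sub_seeds[r], permute_slot_years(env))
    st <- pair_stats(pair_flags(env, yr), env$lag_ok, zero_undefined = TRUE)
    surr_lead[r] <- st$i_lead
    surr_lag[r] <- st$i_lag
  }
  cmp <- if (ties == "ge") `>=` else `>`
  n_ge_lead <- if (is.na(obs$i_lead)) NA_integer_ else
    sum(cmp(surr_lead, obs$i_lead))
  n_ge_lag <- if (is.na(obs$i_lag)) NA_integer_ else
    sum(cmp(surr_lag, obs$i_lag))
  list(p_lead = n_ge_lead / n_surrogates,
       p_lag = n_ge_lag / n_surrogates,
       i_lead = obs$i_lead, i_lag = obs$i_lag,
       n_ge_lead = n_ge_lead, n_ge_lag = n_ge_lag,
       n_surrogates = n_surrogates)
}

#' Run the lead/lag analysis over a set of candidate diagnoses
#'
#' Computes [lead_lag_indicators()] for every combination of index
#' diagnosis (E10 for DM1, E11 for DM2), candidate code and sex, and runs
#' the [surrogate_test()] for pairs passing the frequency threshold.
#'
#' @param cohort a `claims_cohort`.
#' @param codes candidate codes; defaults to [candidate_codes()].
#' @param types diabetes types (`"DM1"` maps to index code E10, `"DM2"`
#'   to E11).
#' @param sexes sexes to analyse.
#' @param z minimum qualifying-patient threshold.
#' @param n_surrogates surrogates per pair.
#' @param seed master seed; each pair derives its own sub-seed.
#' @param p_threshold significance threshold for the permutation test.
#' @param max_age_lag_dm1 inclusive age cap for the DM1 lag analysis.
#' @return `data.table` with one row per (index, candidate, sex):
#'   indicators, permutation p-values and significance flags (`NA` for
#'   excluded pairs).
#' @export
run_leadlag <- function(cohort, codes = NULL, types = c("DM1", "DM2"),
                        sexes = c("M", "F"), z = 50, n_surrogates = 1000,
                        seed = 1L, p_threshold = 0.01, max_age_lag_dm1 = 30) {
  codes <- codes %||% candidate_codes(cohort)
  index_codes <- c(DM1 = "E10", DM2 = "E11")[types]
  empty <- data.table(
    d_i = character(), x = character(), sex = character(),
    n_qualifying = integer(), excluded = logical(),
    excluded_reason = character(), i_lead = numeric(), i_lag = numeric(),
    p_lead_fwd = numeric(), p_lead_rev = numeric(), p_lag_fwd = numeric(),
    p_lag_rev = numeric(), p_lead = numeric(), p_lag = numeric(),
    sig_lead = logical(), sig_lag = logical())
  if (length(codes) == 0L) return(empty)
  grid <- CJ(d_i = unname(index_codes), x = codes, sex = sexes)
  pair_seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            nrow(grid)))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- lead_lag_indicators(cohort, grid$d_i[i], grid$x[i], grid$sex[i],
                               z = z, max_age_lag_dm1 = max_age_lag_dm1)
    if (!res$excluded) {
      st <- surrogate_test(cohort, grid$d_i[i], grid$x[i], grid$sex[i],
                           n_surrogates = n_surrogates, seed = pair_seeds[i],
                           z = z, max_age_lag_dm1 = max_age_lag_dm1)
      res[, `:=`(p_lead = st$p_lead, p_lag = st$p_lag,
                 sig_lead = st$p_lead < p_threshold,
                 sig_lag = st$p_lag < p_threshold)]
    } else {
      res[, `:=`(p_lead = NA_real_, p_lag = NA_real_,
                 sig_lead = NA, sig_lag = NA)]
    }
    rows[[i]] <- res
  }
  rbindlist(rows)
}
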