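# Brute-force reference implementations used as independent oracles.
# They are deliberately naive (loops, definitions transcribed literally)
# and share no code with the package internals.

# Benjamini-Hochberg step-up by definition
bf_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0L
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k / m * alpha) k_star <- k
  }
  rej <- rep(FALSE, m)
  if (k_star > 0L) rej[ord[seq_len(k_star)]] <- TRUE
  rej
}

# Pearson chi-squared via expected counts
bf_chisq_stat <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  e <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - e)^2 / e)
}

bf_chisq_p <- function(a, b, c, d) {
  pchisq(bf_chisq_stat(a, b, c, d), df = 1, lower.tail = FALSE)
}

# Katz log-normal CI, transcribed from the definition
bf_rr_ci <- function(a, b, c, d, conf = 0.95) {
  p1 <- a / (a + b)
  p0 <- c / (c + d)
  rr <- p1 / p0
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- qnorm(1 - (1 - conf) / 2)
  c(rr = rr, lo = exp(log(rr) - z * se), hi = exp(log(rr) + z * se))
}

# smoothed log sex ratio, female-positive orientation
bf_sr <- function(d_f, d_m, d_fx, d_mx) {
  log((1 + d_m / d_mx) / (1 + d_f / d_fx))
}

# naive per-patient lead/lag indicators. events: data.frame with
# patient_id, year, kind, code; patients: patient_id, sex, age.
bf_leadlag <- function(patients, events, d_i, x, sex, t1, t2,
                       max_age_lag_dm1 = 30) {
  has <- function(pid, code_, yr, main_only = FALSE) {
    e <- events[events$patient_id == pid & events$code == code_ &
                  events$year == yr &
                  events$kind %in% c("diag_main", "diag_side"), , drop = FALSE]
    if (main_only) e <- e[e$kind == "diag_main", , drop = FALSE]
    nrow(e) > 0
  }
  ids <- patients$patient_id[patients$sex == sex]
  prob <- function(ids, cond_code, cond_yr, out_code, out_yr) {
    den <- 0; num <- 0
    for (pid in ids) {
      if (has(pid, cond_code, cond_yr) && !has(pid, out_code, cond_yr)) {
        den <- den + 1
        if (has(pid, out_code, out_yr, main_only = TRUE)) num <- num + 1
      }
    }
    if (den == 0) return(NA_real_)
    num / den
  }
  i_lead <- prob(ids, d_i, t1, x, t2) - prob(ids, d_i, t2, x, t1)
  lag_ids <- ids
  if (d_i == "E10") {
    lag_ids <- ids[patients$age[match(ids, patients$patient_id)] <=
                     max_age_lag_dm1]
  }
  i_lag <- prob(lag_ids, x, t1, d_i, t2) - prob(lag_ids, x, t2, d_i, t1)
  list(i_lead = i_lead, i_lag = i_lag)
}

# --- fixture builders -------------------------------------------------------

# demographics table with n patients, all alive, born so age = `age`
make_demo <- function(n, sex = rep(c("M", "F"), length.out = n), age = 50,
                      deceased = 0L, ref_year = 2007) {
  data.frame(patient_id = sprintf("p%04d", seq_len(n)),
             sex = sex, birth_year = ref_year - age,
             deceased = rep(deceased, length.out = n),
             stringsAsFactors = FALSE)
}

make_events <- function(patient_id, year, kind, code) {
  data.frame(patient_id = patient_id, year = year, kind = kind, code = code,
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(patient_id = character(), year = integer(),
             kind = character(), code = character(), stringsAsFactors = FALSE)
}

# cohort in which `n_dm` patients carry a diabetes diagnosis of `type_code`
# and, among them / among the comparator, given numbers carry code x
make_2x2_cohort <- function(a, b, c, d, x = "I10", type_code = "E11",
                            age = 52, sex_alt = TRUE) {
  n <- a + b + c + d
  demo <- make_demo(n, sex = if (sex_alt) rep(c("M", "F"), length.out = n)
                    else rep("M", n), age = age)
  ids <- demo$patient_id
  dm_ids <- ids[seq_len(a + b)]
  x_ids <- c(ids[seq_len(a)], ids[a + b + seq_len(c)])
  ev <- rbind(
    make_events(dm_ids, 2006, "diag_side", type_code),
    if (length(x_ids)) make_events(x_ids, 2007, "diag_main", x)
  )
  build_cohort(claims_data(demo, ev))
}

# random small 2x2 tables passing the cell rule
random_tables <- function(n, seed, min_cell = 1, max_cell = 400) {
  set.seed(seed)
  data.frame(a = sample(min_cell:max_cell, n, TRUE),
             b = sample(min_cell:max_cell, n, TRUE),
             c = sample(min_cell:max_cell, n, TRUE),
             d = sample(min_cell:max_cell, n, TRUE))
}
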