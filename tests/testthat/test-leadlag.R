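# fixture: 100 males with the index diagnosis in both years and no
# candidate diagnosis in year 1; `gain` of them acquire a main diagnosis
# of x in year 2
lead_fixture <- function(n = 100, gain = 30, d_i = "E11", x = "I50") {
  demo <- make_demo(n, sex = rep("M", n), age = 60)
  ids <- demo$patient_id
  ev <- rbind(
    make_events(ids, 2006, "diag_main", d_i),
    make_events(ids, 2007, "diag_side", d_i),
    if (gain > 0) make_events(ids[seq_len(gain)], 2007, "diag_main", x)
  )
  build_cohort(claims_data(demo, ev))
}

test_that("pair probabilities are hand-countable proportions", {
  co <- lead_fixture(n = 100, gain = 30)
  expect_equal(pair_probability(co, "E11", "I50", "M", "forward"), 0.30)
  expect_equal(pair_probability(co, "E11", "I50", "M", "reverse"), 0)
  # nobody has x at all -> both probabilities zero
  co0 <- lead_fixture(gain = 0)
  expect_equal(pair_probability(co0, "E11", "I50", "M", "forward"), 0)
  expect_equal(pair_probability(co0, "E11", "I50", "M", "reverse"), 0)
  # no patient of the requested sex with the index code -> undefined
  expect_true(is.na(pair_probability(co, "E11", "I50", "F", "forward")))
})

test_that("duplicating every patient leaves the probabilities unchanged", {
  co <- lead_fixture(n = 50, gain = 10)
  demo2 <- rbind(make_demo(50, sex = "M", age = 60),
                 within(make_demo(50, sex = "M", age = 60),
                        patient_id <- sub("^p", "q", patient_id)))
  ev <- as.data.frame(co$events)
  ev2 <- rbind(ev, within(ev, patient_id <- sub("^p", "q", patient_id)))
  co2 <- build_cohort(claims_data(demo2, ev2))
  expect_equal(pair_probability(co2, "E11", "I50", "M", "forward"),
               pair_probability(co, "E11", "I50", "M", "forward"))
})

test_that("lead indicator equals the difference of the hand-counted probabilities", {
  co <- lead_fixture(n = 100, gain = 30)
  res <- lead_lag_indicators(co, "E11", "I50", "M", z = 10)
  expect_false(res$excluded)
  expect_equal(res$i_lead, 0.30)
  # 30 qualifying patients sit below the default threshold of 50
  res50 <- lead_lag_indicators(co, "E11", "I50", "M", z = 50)
  expect_true(res50$excluded)
  expect_match(res50$excluded_reason, "below threshold")
  # threshold boundary: 49 qualifying patients with z = 50 are excluded
  co49 <- lead_fixture(n = 100, gain = 49)
  expect_true(lead_lag_indicators(co49, "E11", "I50", "M", z = 50)$excluded)
  expect_false(lead_lag_indicators(co49, "E11", "I50", "M", z = 49)$excluded)
})

test_that("a year-symmetric dataset has zero indicators", {
  n <- 40
  demo <- make_demo(n, sex = "F", age = 55)
  ids <- demo$patient_id
  # identical diagnosis sets in both years for every patient
  ev <- rbind(
    make_events(ids[1:25], 2006, "diag_main", "E11"),
    make_events(ids[1:25], 2007, "diag_main", "E11"),
    make_events(ids[16:40], 2006, "diag_main", "J18"),
    make_events(ids[16:40], 2007, "diag_main", "J18")
  )
  co <- build_cohort(claims_data(demo, ev))
  res <- lead_lag_indicators(co, "E11", "J18", "F", z = 5)
  expect_equal(res$i_lead, 0)
  expect_equal(res$i_lag, 0)
})

test_that("globally swapping the year labels negates the indicators", {
  set.seed(77)
  n <- 80
  demo <- make_demo(n, age = 50)
  ids <- demo$patient_id
  rand_ev <- function(code) {
    pick <- sample(ids, 45)
    make_events(pick, sample(c(2006, 2007), 45, TRUE),
                sample(c("diag_main", "diag_side"), 45, TRUE), code)
  }
  ev <- rbind(rand_ev("E11"), rand_ev("I50"), rand_ev("J18"))
  co <- build_cohort(claims_data(demo, ev))
  ev_sw <- within(ev, year <- ifelse(year == 2006, 2007, 2006))
  co_sw <- build_cohort(claims_data(demo, ev_sw))
  a <- lead_lag_indicators(co, "E11", "I50", "M", z = 1)
  b <- lead_lag_indicators(co_sw, "E11", "I50", "M", z = 1)
  if (!a$excluded && !b$excluded) {
    expect_equal(a$i_lead, -b$i_lead)
    expect_equal(a$i_lag, -b$i_lag)
  } else {
    expect_equal(a$excluded, b$excluded)
  }
})

test_that("indicators match a naive per-patient implementation", {
  set.seed(31)
  codes <- c("E10", "E11", "I10", "J18")
  for (rep in 1:15) {
    n <- 60
    demo <- make_demo(n, age = sample(10:80, n, TRUE))
    ids <- demo$patient_id
    ev <- do.call(rbind, lapply(codes, function(cd) {
      pick <- sample(ids, sample(20:40, 1))
      make_events(pick, sample(c(2006, 2007), length(pick), TRUE),
                  sample(c("diag_main", "diag_side"), length(pick), TRUE), cd)
    }))
    co <- build_cohort(claims_data(demo, ev))
    d_i <- sample(c("E10", "E11"), 1)
    x <- sample(c("I10", "J18"), 1)
    sx <- sample(c("M", "F"), 1)
    got <- lead_lag_indicators(co, d_i, x, sx, z = 1)
    ref <- bf_leadlag(as.data.frame(co$patients), as.data.frame(co$events),
                      d_i, x, sx, 2006, 2007)
    if (!got$excluded) {
      expect_equal(got$i_lead, ref$i_lead, tolerance = 1e-12)
      expect_equal(got$i_lag, ref$i_lag, tolerance = 1e-12)
    } else {
      expect_true(anyNA(c(ref$i_lead, ref$i_lag)) ||
                    got$n_qualifying < 1)
    }
  }
})

test_that("DM1 lag analysis is restricted to patients aged 30 or younger", {
  n <- 70
  demo <- make_demo(n, sex = "M", age = c(rep(c(20, 70), each = 30), rep(70, 10)))
  ids <- demo$patient_id
  young <- ids[1:30]; old <- ids[31:60]; extra <- ids[61:70]
  # young: x in both years, half acquire a main E10 in year 2
  # old: same pattern -- but must not influence the DM1 lag indicator
  # extras keep the lead denominators populated so the pair is not excluded
  ev <- rbind(
    make_events(c(young, old), 2006, "diag_main", "G40"),
    make_events(c(young, old), 2007, "diag_main", "G40"),
    make_events(c(young[1:15], old[1:5]), 2007, "diag_main", "E10"),
    make_events(extra[1:5], 2006, "diag_main", "E10"),
    make_events(extra[6:10], 2007, "diag_main", "E10")
  )
  co <- build_cohort(claims_data(demo, ev))
  res <- lead_lag_indicators(co, "E10", "G40", "M", z = 1)
  expect_false(res$excluded)
  # lag forward: among the 30 young with G40 in t1 and no E10 in t1,
  # 15 gain a main E10 in t2; the 30 old with the same pattern are capped out
  expect_equal(res$p_lag_fwd, 0.5)
})

test_that("a permutation-invariant dataset gives surrogate p-values of 1", {
  demo <- make_demo(25, sex = "M", age = 60)
  ids <- demo$patient_id
  ev <- rbind(
    make_events(ids[1:5], 2007, "diag_main", "E11"),   # qualify: x & d_i in t2
    make_events(ids[1:5], 2007, "diag_main", "I50"),
    make_events(ids[6:10], 2006, "diag_main", "E11"),
    make_events(ids[11:15], 2007, "diag_main", "E11"),
    make_events(ids[16:20], 2006, "diag_main", "I50"),
    make_events(ids[21:25], 2007, "diag_main", "I50")
  )
  co <- build_cohort(claims_data(demo, ev))
  st <- surrogate_test(co, "E11", "I50", "M", n_surrogates = 50, seed = 1,
                       z = 5)
  expect_equal(st$p_lead, 1)
  expect_equal(st$p_lag, 1)
})

test_that("the surrogate test is reproducible and detects a planted lead", {
  cfg <- sim_config(
    n_patients = 50000, seed = 41,
    rr_effects = NULL, sex_effects = NULL,
    temporal_effects = data.frame(code = "I50", type = "DM2", sex = "F",
                                  lambda = 3))
  co <- build_cohort(simulate_population(cfg)$data)
  st1 <- surrogate_test(co, "E11", "I50", "F", n_surrogates = 200, seed = 6)
  st2 <- surrogate_test(co, "E11", "I50", "F", n_surrogates = 200, seed = 6)
  expect_identical(st1, st2)
  expect_lt(st1$p_lead, 0.01)
  expect_gt(st1$i_lead, 0)
})

test_that("raising the exclusion threshold never adds pairs", {
  co <- lead_fixture(n = 100, gain = 30)
  kept <- function(z) !lead_lag_indicators(co, "E11", "I50", "M", z = z)$excluded
  flags <- vapply(c(1, 10, 30, 31, 100), kept, logical(1))
  expect_equal(flags, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})
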