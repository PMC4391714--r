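test_that("age groups tile [0, 95) in five-year intervals", {
  g <- age_groups()
  expect_equal(nrow(g), 19L)
  expect_equal(g$lower, seq(0, 90, by = 5))
  expect_equal(g$upper, g$lower + 5L)
  # every age 0..94 maps to exactly one group; 95 and above to none
  idx <- assign_age_group(0:94)
  expect_false(anyNA(idx))
  expect_equal(as.vector(table(idx)), rep(5L, 19))
  expect_true(is.na(assign_age_group(95)))
  expect_true(is.na(assign_age_group(-1)))
})

test_that("loading validates schema and rejects malformed rows by position", {
  demo <- make_demo(3)
  d1 <- withr::local_tempfile(fileext = ".csv")
  e1 <- withr::local_tempfile(fileext = ".csv")

  # empty events file, 3-row demographics -> 3 patients, no events
  write_claims(claims_data(demo, empty_events()), d1, e1)
  loaded <- read_claims(d1, e1)
  expect_equal(nrow(loaded$demographics), 3L)
  expect_equal(nrow(loaded$events), 0L)

  # 2-character diagnosis code is rejected with the row number
  bad <- make_events("p0001", 2006, "diag_main", "E1")
  expect_error(claims_data(demo, bad), "E1.*row 1")
  # unknown sex token
  demo_bad <- make_demo(2); demo_bad$sex[2] <- "X"
  expect_error(claims_data(demo_bad, empty_events()), "sex token 'X'.*row 2")
  # year outside the study window
  bad <- make_events("p0001", 2009, "diag_main", "E11")
  expect_error(claims_data(demo, bad), "2009.*row 1")
  # event referencing an unknown patient
  bad <- make_events("ghost", 2006, "diag_main", "E11")
  expect_error(claims_data(demo, bad), "unknown patient 'ghost'")
  # duplicate patient id
  demo_dup <- rbind(make_demo(2), make_demo(1))
  expect_error(claims_data(demo_dup, empty_events()), "duplicated patient_id")
})

test_that("a generated dataset round-trips through the interchange format", {
  sim <- simulate_population(sim_config(n_patients = 300, seed = 11))
  d1 <- withr::local_tempfile(fileext = ".csv")
  e1 <- withr::local_tempfile(fileext = ".csv")
  write_claims(sim$data, d1, e1)
  back <- read_claims(d1, e1)
  expect_equal(as.data.frame(back$demographics),
               as.data.frame(sim$data$demographics))
  expect_equal(as.data.frame(back$events), as.data.frame(sim$data$events))
})

test_that("cohort construction applies the exclusion and membership rules", {
  demo <- make_demo(6, age = c(50, 50, 96, 95, 94, 20))
  demo$deceased[2] <- 1L
  ev <- rbind(
    make_events("p0001", 2006, "diag_side", "E10"),  # side diagnosis counts
    make_events("p0006", 2007, "diag_main", "E11"),
    make_events("p0006", 2007, "diag_main", "E10")   # mixed coding: both
  )
  co <- build_cohort(claims_data(demo, ev))
  ids <- co$patients$patient_id
  expect_false("p0002" %in% ids)         # deceased removed
  expect_false("p0003" %in% ids)         # age 96 removed
  expect_false("p0004" %in% ids)         # age 95 outside [90,95)
  expect_true("p0005" %in% ids)          # age 94 retained
  expect_true("p0001" %in% co$dm1_ids)   # E10 side diagnosis -> DM1
  expect_true(all(c("p0006") %in% co$dm1_ids))
  expect_true("p0006" %in% co$dm2_ids)   # patient with both codes in both sets
  # exclusions only ever shrink the cohort
  co_loose <- build_cohort(claims_data(demo, ev), max_age = 200)
  expect_gte(nrow(co_loose$patients), nrow(co$patients))
})

test_that("prescription-based cohort definition uses ATC A10", {
  demo <- make_demo(4)
  ev <- rbind(make_events("p0001", 2006, "rx", "A10BA02"),
              make_events("p0002", 2006, "rx", "N05"),
              make_events("p0003", 2006, "diag_main", "E11"))
  co <- build_cohort(claims_data(demo, ev), definition = "prescription_a10")
  expect_equal(co$dm1_ids, "p0001")
  expect_equal(co$dm2_ids, "p0001")
})

test_that("age-group partition covers the cohort exactly", {
  sim <- simulate_population(sim_config(n_patients = 2000, seed = 5))
  co <- build_cohort(sim$data)
  expect_false(anyNA(co$patients$age_group))
  expect_true(all(co$patients$age_group %in% 0:18))
  s <- cohort_summary(co)
  expect_equal(sum(s$by_age$n), nrow(co$patients))
})

test_that("cohort summary totals are male + female, empty cohort is all zero", {
  sim <- simulate_population(sim_config(n_patients = 500, seed = 2))
  co <- build_cohort(sim$data)
  s <- cohort_summary(co)
  expect_equal(s$counts$total, s$counts$male + s$counts$female)
  expect_equal(s$counts[s$counts$group == "cohort", ]$total, nrow(co$patients))

  demo <- make_demo(2, deceased = 1L)  # everyone excluded
  co0 <- build_cohort(claims_data(demo, empty_events()))
  s0 <- cohort_summary(co0)
  expect_equal(s0$counts$total, c(0L, 0L, 0L))
  expect_equal(sum(s0$by_age$n), 0L)
})
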