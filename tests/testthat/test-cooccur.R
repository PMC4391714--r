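test_that("contingency tables count carriers by hand", {
  # 10 patients: 4 DM2 of whom 3 have x; 6 non-DM2 of whom 1 has x
  co <- make_2x2_cohort(a = 3, b = 1, c = 1, d = 5)
  tab <- build_table(co, "I10", age_group = 10L, type = "DM2")
  expect_equal(unlist(tab[, c("a", "b", "c", "d")]),
               c(a = 3L, b = 1L, c = 1L, d = 5L))
  # a group with no diabetics has empty diabetic margins
  tab0 <- build_table(co, "I10", age_group = 0L, type = "DM2")
  expect_equal(tab0$a + tab0$b, 0L)
})

test_that("side diagnoses count as carrying the code", {
  demo <- make_demo(2, age = 52)
  ev <- rbind(make_events("p0001", 2006, "diag_side", "E11"),
              make_events("p0001", 2007, "diag_side", "I10"))
  co <- build_cohort(claims_data(demo, ev))
  tab <- build_table(co, "I10", age_group = 10L, type = "DM2")
  expect_equal(tab$a, 1L)
})

test_that("relative risk and Katz interval match the hand-computed example", {
  est <- relative_risk_ci(20, 180, 50, 1750)
  expect_equal(est$rr, 3.6)
  expect_equal(est$ci_low, 2.1888, tolerance = 1e-4)
  expect_equal(est$ci_high, 5.9210, tolerance = 1e-4)
  # identical proportions give RR exactly 1
  expect_equal(relative_risk_ci(20, 180, 200, 1800)$rr, 1)
})

test_that("relative risk / CI / chi-squared match brute force on random tables", {
  tabs <- random_tables(1000, seed = 8)
  est <- relative_risk_ci(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- chi_squared_p(tabs$a, tabs$b, tabs$c, tabs$d)
  for (i in seq_len(nrow(tabs))) {
    ref <- bf_rr_ci(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(est$rr[i], unname(ref["rr"]), tolerance = 1e-12)
    expect_equal(est$ci_low[i], unname(ref["lo"]), tolerance = 1e-12)
    expect_equal(est$ci_high[i], unname(ref["hi"]), tolerance = 1e-12)
    expect_equal(p[i], bf_chisq_p(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]),
                 tolerance = 1e-10)
  }
  # spot-check against the standard library implementation too
  i <- 17
  ct <- chisq.test(matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]),
                          2, byrow = TRUE), correct = FALSE)
  expect_equal(p[i], unname(ct$p.value), tolerance = 1e-12)
})

test_that("chi-squared has the expected closed-form properties", {
  expect_equal(chi_squared_p(20, 180, 50, 1750), 1.3464e-7, tolerance = 1e-4)
  # perfectly proportional table: statistic 0, p = 1
  expect_equal(chi_squared_p(10, 90, 30, 270), 1)
  # scaling all cells by 10 scales the statistic by 10
  stat <- function(a, b, c, d) qchisq(chi_squared_p(a, b, c, d), 1,
                                      lower.tail = FALSE)
  expect_equal(stat(120, 340, 560, 780), 10 * stat(12, 34, 56, 78),
               tolerance = 1e-9)
  # zero margin is undefined
  expect_true(is.na(chi_squared_p(0, 0, 5, 5)))
})

test_that("Benjamini-Hochberg step-up matches its definition", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_adjust(rep(1, 5), 0.05), rep(FALSE, 5))
  # boundary is inclusive: a single p exactly at alpha is rejected
  expect_true(bh_adjust(0.05, 0.05))
  expect_equal(bh_adjust(numeric(0), 0.05), logical(0))
  # brute-force equivalence on random families
  set.seed(123)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    alpha <- sample(c(0.001, 0.01, 0.05, 0.1), 1)
    expect_identical(bh_adjust(p, alpha), bf_bh(p, alpha))
  }
})

test_that("cell rule marks small tables as not computed, RR reported as 1", {
  co <- make_2x2_cohort(a = 5, b = 100, c = 50, d = 1000)
  res <- run_cooccurrence(co, codes = "I10", alpha = 0.01)$results
  row <- res[res$diabetes_type == "DM2" & res$age_group == 10L, ]
  expect_false(row$computed)
  expect_equal(row$rr, 1)
  expect_true(is.na(row$p_value))
})

test_that("the screening grid enumerates codes x age groups x types", {
  codes <- sprintf("Q%02d", 1:7)
  expect_equal(nrow(comorbidity_test_grid(codes)), 7 * 19 * 2)
  co <- make_2x2_cohort(20, 20, 20, 20)
  expect_equal(run_cooccurrence(co, codes = codes)$n_scheduled, 7 * 19 * 2)
})

test_that("expected false positives is alpha times the discovery count", {
  expect_equal(expected_false_positives(123, 0.01), 1.23)
  expect_equal(expected_false_positives(100, 0.01), 1.0)
  expect_equal(expected_false_positives(0, 0.05), 0)
})

test_that("table margins add up to the age-group cohort size", {
  sim <- simulate_population(sim_config(n_patients = 3000, seed = 14))
  co <- build_cohort(sim$data)
  res <- run_cooccurrence(co, alpha = 0.01)$results
  sizes <- table(factor(co$patients$age_group, levels = 0:18))
  bysize <- res$a + res$b + res$c + res$d
  expect_equal(bysize, as.integer(sizes[as.character(res$age_group)]),
               ignore_attr = TRUE)
})

test_that("discovery lists are nested across increasing FDR levels", {
  sim <- simulate_population(sim_config(n_patients = 20000, seed = 9))
  co <- build_cohort(sim$data)
  lists <- lapply(c(0.001, 0.01, 0.1), function(al)
    run_cooccurrence(co, alpha = al)$comorbidities$union)
  expect_true(all(lists[[1]] %in% lists[[2]]))
  expect_true(all(lists[[2]] %in% lists[[3]]))
})

test_that("planted comorbidities are recovered in the comorbidity list", {
  cfg <- sim_config(
    n_patients = 50000, seed = 17,
    rr_effects = data.frame(code = c("I50", "N18"), type = "DM2",
                            age_lo = 0, age_hi = 95, rr = 4),
    sex_effects = NULL, temporal_effects = NULL)
  co <- build_cohort(simulate_population(cfg)$data)
  found <- run_cooccurrence(co, alpha = 0.01)$comorbidities$DM2
  expect_true(all(c("I50", "N18") %in% found))
})
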