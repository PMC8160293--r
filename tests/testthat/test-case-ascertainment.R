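index_date <- as.Date("2005-06-01")

test_that("claims before day 7 are attributed to the index event", {
  cl <- make_claims("P1", days = 5, sources = "emergency", codes = "850",
                    systems = "ICD9")
  idx <- data.frame(patient_id = "P1", index_date = index_date)
  h <- apply_case_definitions(cl, idx)
  expect_false(h$hit_er)
  expect_true(is.na(h$first_hit_day))
  # same claim at day 7 counts
  cl$service_date <- index_date + 7
  h7 <- apply_case_definitions(cl, idx)
  expect_true(h7$hit_er)
  expect_identical(h7$first_hit_day, 7L)
})

test_that("radiology billing pairs with a trauma claim within one day", {
  idx <- data.frame(patient_id = "P1", index_date = index_date)
  cl <- make_claims(c("P1", "P1"), days = c(100, 101),
                    sources = c("radiology_billing", "outpatient"),
                    codes = c("08258", "920"), systems = c("billing", "ICD9"))
  h <- apply_case_definitions(cl, idx)
  expect_true(h$hit_radiology_trauma)
  expect_false(h$hit_outpatient)  # trauma code 920 is not a TBI code
  expect_identical(h$first_hit_day, 100L)
  # two days apart: no pair
  cl2 <- cl; cl2$service_date[2] <- index_date + 102
  expect_false(apply_case_definitions(cl2, idx)$hit_radiology_trauma)
  # unpaired radiology claim alone never qualifies
  expect_false(apply_case_definitions(cl[1, ], idx)$hit_radiology_trauma)
})

test_that("empty claim streams and unknown sources are handled", {
  idx <- data.frame(patient_id = "P1", index_date = index_date)
  h <- apply_case_definitions(make_claims(character(), integer(), character(),
                                          character(), character()), idx)
  expect_false(any(h$hit_outpatient, h$hit_er, h$hit_dad,
                   h$hit_radiology_trauma))
  expect_true(is.na(h$first_hit_day))
  bad <- make_claims("P1", 100, "clinic", "850", "ICD9")
  expect_error(apply_case_definitions(bad, idx), "invalid claim records")
})

test_that("ICD-10 DAD codes and dotted codes are recognised", {
  idx <- data.frame(patient_id = "P1", index_date = index_date)
  cl <- make_claims(c("P1", "P1"), days = c(50, 60),
                    sources = c("dad", "outpatient"),
                    codes = c("S06.0", "850.1"), systems = c("ICD10", "ICD9"))
  h <- apply_case_definitions(cl, idx)
  expect_true(h$hit_dad)
  expect_true(h$hit_outpatient)
  expect_identical(h$first_hit_day, 50L)
})

test_that("pattern index encoding round-trips and counts conserve", {
  expect_identical(pattern_index(c(1, 0, 0, 1)), 9L)
  for (i in 0:15) expect_identical(pattern_index(pattern_flags(i)), i)
  h0 <- make_hits(matrix(0, 3, 4))
  expect_identical(as.integer(build_response_patterns(h0)[1]), 3L)
  h1 <- build_response_patterns(make_hits(c(1, 0, 0, 1), days = 10))
  expect_identical(as.integer(h1["1001"]), 1L)
  set.seed(4)
  flags <- matrix(rbinom(4 * 10000, 1, 0.3), ncol = 4)
  expect_identical(sum(build_response_patterns(make_hits(flags, 10))), 10000L)
})

test_that("model dimension counting matches the published scheme", {
  d2 <- model_dimensions(4, 2)
  expect_identical(d2$n_patterns, 16L)
  expect_identical(d2$degrees_of_freedom, 15L)
  expect_identical(d2$n_parameters, 9L)
  expect_identical(model_dimensions(4, 3)$n_parameters, 13L)
  d1 <- model_dimensions(1, 2)
  expect_identical(c(d1$n_patterns, d1$degrees_of_freedom, d1$n_parameters),
                   c(2L, 1L, 3L))
  expect_error(model_dimensions(0, 2))
})

test_that("person-time truncates at first hit, exit and one year", {
  idx <- data.frame(patient_id = c("A", "B", "C"),
                    index_date = rep(index_date, 3))
  exits <- data.frame(patient_id = c("A", "B", "C"),
                      exit_date = index_date + c(500, 500, 200))
  hits <- data.frame(patient_id = c("A", "B", "C"),
                     first_hit_day = c(NA, 100L, NA))
  pt <- compute_person_time(idx, hits, exits)
  expect_equal(pt$per_patient$person_years, c(1, 100 / 365, 200 / 365))
  expect_equal(pt$total, 1 + 300 / 365)
  bad <- exits; bad$exit_date[1] <- index_date - 1
  expect_error(compute_person_time(idx, hits, bad), "exit precedes")
})

test_that("crude incidence is cases per 100 person-years", {
  expect_equal(crude_incidence(10, 250), 4)
  expect_equal(crude_incidence(0, 100), 0)
  expect_error(crude_incidence(5, 0), "positive")
})

test_that("crude median time uses the lower-median convention", {
  expect_identical(crude_median_time(make_hits(c(1, 0, 0, 0), days = 98)), 98L)
  h3 <- make_hits(matrix(1, 3, 4), days = c(10, 20, 30))
  expect_identical(crude_median_time(h3), 20L)
  h4 <- make_hits(matrix(1, 4, 4), days = c(10, 20, 30, 40))
  expect_identical(crude_median_time(h4), 20L)
  expect_error(crude_median_time(make_hits(c(0, 0, 0, 0))), "no patient")
})

test_that("widening the window never loses hits; narrowing never adds cases", {
  cfg <- sim_config(n_patients = 4000, incident_prob_by_age = c(1, 1, 1),
                    followup_noise_rate = 0.01, censor_prob = 0.2, seed = 31)
  sim <- simulate_population(cfg)
  cl <- emit_claims(sim$patients, sim$truth, cfg)
  idx <- sim$truth[, c("patient_id", "index_date")]
  h_narrow <- apply_case_definitions(cl, idx,
                                     window = ascertainment_window(7, 180))
  h_wide <- apply_case_definitions(cl, idx,
                                   window = ascertainment_window(7, 365))
  for (j in paste0("hit_", def_names))
    expect_true(all(h_wide[[j]] >= h_narrow[[j]]))
  h30 <- apply_case_definitions(cl, idx, window = ascertainment_window(30, 365))
  expect_lte(sum(!is.na(h30$first_hit_day)), sum(!is.na(h_wide$first_hit_day)))
})
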