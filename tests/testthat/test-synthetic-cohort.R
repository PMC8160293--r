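test_that("config validation names the offending field", {
  expect_error(sim_config(censor_prob = 1.5), "censor_prob")
  expect_error(sim_config(age_group_probs = c(0.5, 0.4, 0.2)),
               "age_group_probs")
  expect_error(sim_config(se_by_definition = c(0.1, 0.1, 0.1, 0.1),
                          sp_by_definition = c(0.5, 0.5, 0.5, 0.5)),
               "Se \\+ Sp")
})

test_that("zero and saturated recurrence rates give degenerate truth", {
  cfg0 <- sim_config(n_patients = 500, incident_prob_by_age = c(0, 0, 0),
                     seed = 3)
  sim0 <- simulate_population(cfg0)
  expect_false(any(sim0$truth$is_incident_tbi))
  expect_false(any(sim0$truth$has_recurrence))

  cfg1 <- sim_config(n_patients = 500, incident_prob_by_age = c(1, 1, 1),
                     recurrence_rate_by_age_severity = matrix(1, 3, 2),
                     sex_log_odds_ratio = 0, censor_prob = 0, seed = 3)
  sim1 <- simulate_population(cfg1)
  expect_true(all(sim1$truth$is_incident_tbi))
  expect_true(all(sim1$truth$has_recurrence))
  expect_true(all(!is.na(sim1$truth$recurrence_day)))
})

test_that("latent truth respects its structural invariants", {
  cfg <- sim_config(n_patients = 5000, seed = 17)
  sim <- simulate_population(cfg)
  tr <- sim$truth
  expect_true(all(tr$is_incident_tbi[tr$has_recurrence]))
  expect_identical(is.na(tr$recurrence_day), !tr$has_recurrence)
  expect_true(all(tr$recurrence_day >= 7 & tr$recurrence_day <= 365,
                  na.rm = TRUE))
  expect_true(all(sim$patients$entry_date <= sim$patients$exit_date))
  expect_true(all(tr$incident_membership_prob >= 0 &
                    tr$incident_membership_prob <= 1))
})

test_that("empirical recurrence fraction matches the configured rate", {
  cfg <- sim_config(n_patients = 100000, incident_prob_by_age = c(1, 1, 1),
                    recurrence_rate_by_age_severity = matrix(0.05, 3, 2),
                    sex_log_odds_ratio = 0, seed = 29)
  sim <- simulate_population(cfg)
  frac <- mean(sim$truth$has_recurrence[sim$truth$is_incident_tbi])
  se3 <- 3 * sqrt(0.05 * 0.95 / sum(sim$truth$is_incident_tbi))
  expect_lt(abs(frac - 0.05), se3)
})

test_that("simulation and claim emission are seed-deterministic", {
  cfg <- sim_config(n_patients = 2000, seed = 7)
  a <- simulate_population(cfg); b <- simulate_population(cfg)
  expect_identical(a, b)
  expect_identical(emit_claims(a$patients, a$truth, cfg),
                   emit_claims(b$patients, b$truth, cfg))
  cfg2 <- sim_config(n_patients = 2000, seed = 8)
  expect_false(identical(simulate_population(cfg2), a))
})

test_that("claims stay inside each patient's observation interval", {
  cfg <- sim_config(n_patients = 5000, censor_prob = 0.4, seed = 13)
  sim <- simulate_population(cfg)
  cl <- emit_claims(sim$patients, sim$truth, cfg)
  m <- match(cl$patient_id, sim$patients$patient_id)
  expect_true(all(cl$service_date >= sim$patients$entry_date[m]))
  expect_true(all(cl$service_date <= sim$patients$exit_date[m]))
  expect_true(all(cl$source %in% c("outpatient", "emergency",
                                   "hospital_physician", "dad",
                                   "radiology_billing")))
})

test_that("perfect tests yield pattern 1111 for cases and 0000 otherwise", {
  cfg <- sim_config(n_patients = 3000, incident_prob_by_age = c(1, 1, 1),
                    se_by_definition = rep(1 - 1e-12, 4),
                    sp_by_definition = rep(1 - 1e-12, 4),
                    followup_noise_rate = 0, censor_prob = 0, seed = 19)
  sim <- simulate_population(cfg)
  cl <- emit_claims(sim$patients, sim$truth, cfg)
  hits <- apply_case_definitions(cl, sim$truth[, c("patient_id", "index_date")])
  h <- hits[match(sim$truth$patient_id, hits$patient_id), ]
  flags <- as.matrix(h[, paste0("hit_", def_names)])
  expect_true(all(rowSums(flags[sim$truth$has_recurrence, ]) == 4))
  expect_true(all(rowSums(flags[!sim$truth$has_recurrence, ]) == 0))
})

test_that("generated signals calibrate to the configured Se and Sp", {
  cfg <- sim_config(n_patients = 50000, incident_prob_by_age = c(1, 1, 1),
                    followup_noise_rate = 0, censor_prob = 0, seed = 11)
  sim <- simulate_population(cfg)
  cl <- emit_claims(sim$patients, sim$truth, cfg)
  hits <- apply_case_definitions(cl, sim$truth[, c("patient_id", "index_date")])
  h <- hits[match(sim$truth$patient_id, hits$patient_id), ]
  rec <- sim$truth$has_recurrence
  for (j in 1:4) {
    hj <- h[[paste0("hit_", def_names[j])]]
    se_hat <- mean(hj[rec]); sp_hat <- mean(!hj[!rec])
    se_true <- cfg$se_by_definition[j]; sp_true <- cfg$sp_by_definition[j]
    expect_lt(abs(se_hat - se_true),
              3 * sqrt(se_true * (1 - se_true) / sum(rec)))
    expect_lt(abs(sp_hat - sp_true),
              3 * sqrt(sp_true * (1 - sp_true) / sum(!rec)))
  }
})

test_that("early follow-up noise concentrates in days 7-30", {
  cfg <- sim_config(n_patients = 30000, incident_prob_by_age = c(1, 1, 1),
                    recurrence_rate_by_age_severity = matrix(0, 3, 2),
                    followup_noise_rate = 0.01, censor_prob = 0, seed = 5)
  sim <- simulate_population(cfg)
  cl <- emit_claims(sim$patients, sim$truth, cfg)
  rel <- as.integer(cl$service_date -
                      sim$truth$index_date[match(cl$patient_id,
                                                 sim$truth$patient_id)])
  early <- sum(rel >= 7 & rel <= 30, na.rm = TRUE)
  later <- sum(rel >= 31 & rel <= 54, na.rm = TRUE)
  expect_gt(early, later)
})

test_that("predicted cohorts follow the membership probabilities", {
  truth <- data.frame(patient_id = sprintf("P%03d", 1:200),
                      incident_membership_prob = rep(c(1, 0, 0.5),
                                                     c(50, 50, 100)))
  m <- draw_incident_cohorts(truth, n_cohorts = 1000, seed = 2)
  expect_identical(dim(m), c(200L, 1000L))
  expect_true(all(m[1:50, ]))
  expect_false(any(m[51:100, ]))
  freq <- rowMeans(m[101:200, ])
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 1000)))
  expect_error(draw_incident_cohorts(truth, n_cohorts = 0), "n_cohorts")
})

test_that("written simulation files round-trip through CSV", {
  cfg <- sim_config(n_patients = 300, seed = 23)
  sim <- simulate_population(cfg)
  cl <- emit_claims(sim$patients, sim$truth, cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, cl, cfg, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "claims.csv"), stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(cl))
  meta <- jsonlite::read_json(file.path(dir, "sim_metadata.json"))
  expect_equal(as.numeric(meta$seed), 23)
})
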