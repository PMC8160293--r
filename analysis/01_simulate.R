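#!/usr/bin/env Rscript
# Stage 1: generate the synthetic surveillance cohort.
#
# Builds a dynamic claims cohort whose structure mirrors the rTBI
# surveillance setting: true index TBI episodes in two severity groupings,
# latent 1-year recurrence, four imperfect case-definition signals, excess
# false follow-up claims in days 7-30, and censoring. Writes patients/truth/
# claims CSVs under results/analysis/sim/.

suppressPackageStartupMessages(library(rtbisurv))

out <- "results/analysis/sim"
cfg <- sim_config(n_patients = 20000, seed = 20260926)
sim <- simulate_population(cfg)
claims <- emit_claims(sim$patients, sim$truth, cfg)
write_simulation(sim, claims, cfg, out)

n_idx <- sum(sim$truth$is_incident_tbi)
message(sprintf("cohort: %d patients, %d true index TBI (%.1f%%), %d with recurrence",
                cfg$n_patients, n_idx, 100 * n_idx / cfg$n_patients,
                sum(sim$truth$has_recurrence)))
message(sprintf("claims emitted: %d rows -> %s", nrow(claims), out))
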