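#!/usr/bin/env Rscript
# Stage 3: fit the two-class Bayesian latent class model across predicted
# index cohorts and pool.
#
# For each age group, draws predicted index-TBI cohorts from the upstream
# membership probabilities, refits the model on each cohort's 16
# response-pattern counts, pools equal per-cohort draw budgets, then pools
# across age groups weighted by mean predicted cohort size. Desk scale:
# 50 predicted cohorts, 2 chains x 1,500 iterations each (the published
# analysis used 1,000 cohorts and 3 x 20,000; see the methods vignette).

suppressPackageStartupMessages(library(rtbisurv))

sim_dir <- "results/analysis/sim"
out <- "results/analysis"
truth <- read.csv(file.path(sim_dir, "truth.csv"), stringsAsFactors = FALSE)
truth$index_date <- as.Date(truth$index_date)
patients <- read.csv(file.path(sim_dir, "patients.csv"), stringsAsFactors = FALSE)
hits <- read.csv(file.path(out, "definition_hits.csv"), stringsAsFactors = FALSE)

members <- draw_incident_cohorts(truth, n_cohorts = 50, seed = 20260926)
settings <- mcmc_settings(n_chains = 2, n_iterations = 1500, burn_in = 500,
                          seed = 20260926)
age_of <- patients$age_group[match(truth$patient_id, patients$patient_id)]

pooled_by_stratum <- list(); sizes <- numeric()
for (ag in c("children", "adults", "elderly")) {
  rows <- which(age_of == ag)
  counts_list <- lapply(seq_len(ncol(members)), function(m) {
    ids <- truth$patient_id[rows][members[rows, m] &
                                    !is.na(truth$index_date[rows])]
    build_response_patterns(hits[hits$patient_id %in% ids, ])
  })
  multi <- run_multi_cohort(counts_list, settings = settings)
  message(sprintf("%s: %d/%d cohort fits converged", ag,
                  sum(vapply(multi$fits[multi$status$ok], `[[`, logical(1),
                             "converged")), length(counts_list)))
  pooled_by_stratum[[ag]] <- pool_draws(multi$fits, per_cohort_draw_budget = 100)
  sizes[ag] <- mean(vapply(counts_list, sum, numeric(1)))
}
w <- stratum_weights(sizes)
message("stratum weights: ",
        paste(sprintf("%s %.3f", names(w), w), collapse = ", "))
pooled_by_stratum$overall <-
  pool_across_strata(pooled_by_stratum, w, seed = 20260926)

summaries <- do.call(rbind, lapply(names(pooled_by_stratum), function(ag) {
  sm <- summarize_draws(pooled_by_stratum[[ag]])
  cbind(age_group = ag, sm)
}))
write.csv(summaries, file.path(out, "pooled_parameters.csv"), row.names = FALSE)
print(subset(summaries, parameter == "pi"), row.names = FALSE)

dir.create(file.path(out, "draws"), showWarnings = FALSE)
for (ag in names(pooled_by_stratum))
  write.csv(pooled_by_stratum[[ag]],
            file.path(out, "draws", paste0("pooled_", ag, ".csv")),
            row.names = FALSE)
message("pooled draws and parameter summaries written")
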