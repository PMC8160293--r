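# Shared fixture builders: everything is generated in code at test time.

def_names <- c("outpatient", "er", "dad", "radiology_trauma")

# Multinomial response-pattern counts drawn from the two-class model itself.
make_lcm_counts <- function(n, pi, se, sp, seed = 1) {
  set.seed(seed)
  patterns <- rtbisurv:::pattern_matrix(length(se))
  probs <- pattern_likelihood(lcm_params(pi, se, sp), patterns)
  as.numeric(rmultinom(1, n, probs))
}

# A hits data.frame from explicit flags and first-hit days.
make_hits <- function(flags, days = NA_integer_) {
  flags <- matrix(flags, ncol = 4, byrow = is.null(dim(flags)))
  data.frame(patient_id = sprintf("P%03d", seq_len(nrow(flags))),
             hit_outpatient = flags[, 1] == 1, hit_er = flags[, 2] == 1,
             hit_dad = flags[, 3] == 1, hit_radiology_trauma = flags[, 4] == 1,
             first_hit_day = as.integer(rep_len(days, nrow(flags))),
             stringsAsFactors = FALSE)
}

# One-patient claim stream.
make_claims <- function(patient_id, days, sources, codes, systems,
                        index_date = as.Date("2005-06-01")) {
  data.frame(patient_id = patient_id, service_date = index_date + days,
             source = sources, code = codes, code_system = systems,
             stringsAsFactors = FALSE)
}

fast_settings <- function(seed = 1, chains = 2, iters = 1500, burn = 500) {
  mcmc_settings(n_chains = chains, n_iterations = iters, burn_in = burn,
                seed = seed)
}

generating_params <- list(pi = 0.05, se = c(0.3, 0.45, 0.12, 0.8),
                          sp = c(0.98, 0.99, 0.995, 0.99))
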