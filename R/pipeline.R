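#' Validate a claims CSV file
#'
#' Checks the schema the ascertainment stage expects: columns patient_id,
#' service_date (ISO 8601), source, code, code_system; known source and code
#' system values; parseable dates. Reports offending line numbers (1-based,
#' counting the header as line 1).
#'
#' @param path CSV path.
#' @return list: n_rows, errors (data.frame line/problem), date_range.
#' @export
validate_claims_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  if (!nrow(df)) stop("no records in claims file", call. = FALSE)
  errs <- list()
  need <- c("patient_id", "service_date", "source", "code", "code_system")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L
  bad <- !(df$source %in% CLAIM_SOURCES)
  if (any(bad)) errs <- c(errs, list(data.frame(
    line = line[bad], problem = paste0("unknown source '", df$source[bad], "'"))))
  bad <- !(df$code_system %in% CODE_SYSTEMS)
  if (any(bad)) errs <- c(errs, list(data.frame(
    line = line[bad], problem = paste0("unknown code_system '",
                                       df$code_system[bad], "'"))))
  dates <- suppressWarnings(as.Date(df$service_date))
  bad <- is.na(dates)
  if (any(bad)) errs <- c(errs, list(data.frame(
    line = line[bad], problem = "unparseable service_date")))
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), problem = character())
  list(n_rows = nrow(df), errors = errors,
       date_range = if (all(is.na(dates))) NULL else range(dates, na.rm = TRUE))
}

# Ascertain one age stratum and build per-cohort pattern counts.
stratum_patterns <- function(truth, patients, claims, members, specs, window) {
  hits <- apply_case_definitions(
    claims, truth[, c("patient_id", "index_date")], specs, window)
  lapply(seq_len(ncol(members)), function(m) {
    ids <- truth$patient_id[members[, m] & !is.na(truth$index_date)]
    build_response_patterns(hits[hits$patient_id %in% ids, , drop = FALSE])
  })
}

#' Run the full surveillance analysis pipeline on synthetic data
#'
#' Simulate -> ascertain -> fit across predicted cohorts -> pool -> check ->
#' derive, per age stratum, then pool across strata weighted by mean
#' predicted cohort size. Writes the report files (crude estimates, pooled
#' parameter summaries, predictive-value table, posterior predictive checks)
#' and a manifest recording the seed and per-stage status.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory; created if needed.
#' @param n_cohorts predicted index cohorts per stratum (desk-scale default
#'   20; the published analysis used 1,000).
#' @param settings an [mcmc_settings()]; desk-scale default 2 chains x 1,500
#'   iterations, burn-in 500.
#' @param priors an [lcm_priors()].
#' @param window an [ascertainment_window()]; pass `min_day = 30` for the
#'   30-day exclusion sensitivity analysis.
#' @param per_cohort_draw_budget pooled draws retained per cohort.
#' @param seed master seed for cohort prediction and pooling.
#' @return the run manifest (invisibly), a list.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, n_cohorts = 20,
                         settings = mcmc_settings(n_chains = 2,
                                                  n_iterations = 1500,
                                                  burn_in = 500),
                         priors = lcm_priors(),
                         window = ascertainment_window(),
                         per_cohort_draw_budget = 100, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- list()

  sim <- simulate_population(config)
  claims <- emit_claims(sim$patients, sim$truth, config)
  write_simulation(sim, claims, config, out_dir)
  stage$simulate <- "ok"

  members <- draw_incident_cohorts(sim$truth, n_cohorts, seed = seed)
  specs <- case_definition_specs()
  crude_rows <- list(); pooled_by_stratum <- list(); sizes <- numeric()
  ppc_rows <- list()

  for (ag in AGE_GROUPS) {
    in_ag <- sim$patients$age_group == ag
    truth_ag <- sim$truth[in_ag, , drop = FALSE]
    pats_ag <- sim$patients[in_ag, , drop = FALSE]
    idx <- truth_ag[!is.na(truth_ag$index_date), , drop = FALSE]
    if (!nrow(idx)) next
    hits <- apply_case_definitions(
      claims, idx[, c("patient_id", "index_date")], specs, window)
    pt <- compute_person_time(idx[, c("patient_id", "index_date")], hits,
                              pats_ag[, c("patient_id", "exit_date")], window)
    n_cases <- sum(!is.na(hits$first_hit_day))
    crude_rows[[ag]] <- data.frame(
      age_group = ag, n_suspected_index = nrow(idx), n_suspected_rtbi = n_cases,
      crude_incidence_per100py = crude_incidence(n_cases, pt$total),
      crude_median_days = if (n_cases) crude_median_time(hits) else NA_integer_,
      stringsAsFactors = FALSE)

    pats_list <- stratum_patterns(truth_ag, pats_ag, claims,
                                  members[in_ag, , drop = FALSE], specs, window)
    multi <- run_multi_cohort(pats_list, priors = priors, settings = settings)
    pooled <- pool_draws(multi$fits, per_cohort_draw_budget)
    pooled_by_stratum[[ag]] <- pooled
    sizes[ag] <- mean(vapply(pats_list, sum, numeric(1)))

    ppc <- posterior_predictive_check(pooled, pats_list[[1]],
                                      n_reps = 200, seed = seed)
    ppc$age_group <- ag
    ppc_rows[[ag]] <- ppc
  }
  stage$fit <- "ok"

  overall <- pool_across_strata(pooled_by_stratum, stratum_weights(sizes),
                                seed = seed)
  pooled_by_stratum$overall <- overall
  summaries <- do.call(rbind, lapply(names(pooled_by_stratum), function(ag) {
    sm <- summarize_draws(pooled_by_stratum[[ag]])
    sm$age_group <- ag
    sm
  }))

  # predictive-value table computed draw-wise, mirrored per stratum
  pv <- do.call(rbind, lapply(names(pooled_by_stratum), function(ag) {
    d <- pooled_by_stratum[[ag]]
    do.call(rbind, lapply(DEFINITION_NAMES, function(def) {
      pd <- ppv(d[, "pi"], d[, paste0("se_", def)], d[, paste0("sp_", def)])
      nd <- npv(d[, "pi"], d[, paste0("se_", def)], d[, paste0("sp_", def)])
      data.frame(age_group = ag, definition = def,
                 ppv_median = median(pd), ppv_low = hdi(pd)[["lower"]],
                 ppv_high = hdi(pd)[["upper"]],
                 npv_median = median(nd), npv_low = hdi(nd)[["lower"]],
                 npv_high = hdi(nd)[["upper"]], stringsAsFactors = FALSE)
    }))
  }))
  stage$pool <- "ok"

  crude <- do.call(rbind, crude_rows)
  write.csv(crude, file.path(out_dir, "crude_estimates.csv"), row.names = FALSE)
  write.csv(summaries, file.path(out_dir, "pooled_parameters.csv"),
            row.names = FALSE)
  write.csv(pv, file.path(out_dir, "predictive_values.csv"), row.names = FALSE)
  write.csv(do.call(rbind, ppc_rows), file.path(out_dir, "ppc_results.csv"),
            row.names = FALSE)

  manifest <- list(
    seed = seed, n_cohorts = n_cohorts,
    window = unclass(window),
    settings = unclass(settings),
    config_seed = config$seed, n_patients = config$n_patients,
    stages = stage,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = c("patients.csv", "truth.csv", "claims.csv", "sim_metadata.json",
                "crude_estimates.csv", "pooled_parameters.csv",
                "predictive_values.csv", "ppc_results.csv", "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
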