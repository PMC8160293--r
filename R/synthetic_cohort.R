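AGE_GROUPS <- c("children", "adults", "elderly")
SEVERITIES <- c("mildest_more_severe", "most_severe")
CLAIM_SOURCES <- c("outpatient", "emergency", "hospital_physician", "dad",
                   "radiology_billing")
CODE_SYSTEMS <- c("ICD9", "ICD10", "billing")

#' Configuration for the synthetic claims cohort generator
#'
#' Bundles every data-generating assumption of the simulated surveillance
#' population: a dynamic cohort with staggered entry, true index TBI episodes
#' in two severity groupings, latent recurrence within 365 days of the index
#' event, four imperfect binary case-definition signals, an excess of false
#' post-index follow-up claims concentrated in days 7-30, and censoring.
#'
#' Defaults echo the published Montreal claims cohort where a value is
#' printed there (age-specific recurrence risks, sensitivities and
#' specificities of the four definitions, median times to recurrence,
#' male fraction of the index cohorts) and are otherwise documented choices
#' (see the methods vignette).
#'
#' @param n_patients number of patients in the dynamic cohort.
#' @param study_window two `Date`s, cohort start and end.
#' @param age_group_probs length-3 probabilities (children/adults/elderly)
#'   summing to 1.
#' @param sex_prob_by_age per-age-group probability of male sex.
#' @param incident_prob_by_age per-age-group probability of a true index TBI.
#' @param severity_prob probability an index TBI is "most severe".
#' @param recurrence_rate_by_age_severity 3 x 2 matrix (rows children/adults/
#'   elderly, columns mildest_more_severe / most_severe) of true 1-year
#'   recurrence probabilities for female patients; male recurrence odds are
#'   shifted by `sex_log_odds_ratio`.
#' @param sex_log_odds_ratio male-vs-female log odds ratio on recurrence.
#' @param recurrence_median_days per-age-group median of the recurrence-time
#'   distribution (discretised exponential on days 7-365).
#' @param se_by_definition true sensitivities of the four definitions
#'   (outpatient, er, dad, radiology_trauma).
#' @param sp_by_definition true specificities, same order. Each definition
#'   must satisfy Se + Sp > 1 (latent-class identifiability).
#' @param followup_noise_rate per-definition daily probability of a false
#'   qualifying claim-set at day 7, decaying geometrically (factor 0.85/day)
#'   to ~day 30; emulates follow-up care for the index injury that is
#'   falsely suggestive of recurrence.
#' @param censor_prob probability a patient leaves the cohort before
#'   day 365 of follow-up.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 20000,
                       study_window = as.Date(c("2000-01-01", "2014-12-31")),
                       age_group_probs = c(children = 0.19, adults = 0.64,
                                           elderly = 0.17),
                       sex_prob_by_age = c(children = 0.603, adults = 0.567,
                                           elderly = 0.379),
                       incident_prob_by_age = c(children = 0.12, adults = 0.04,
                                                elderly = 0.09),
                       severity_prob = 0.10,
                       recurrence_rate_by_age_severity =
                         matrix(c(0.0169, 0.0285,
                                  0.0357, 0.1149,
                                  0.0903, 0.0949),
                                nrow = 3, byrow = TRUE,
                                dimnames = list(AGE_GROUPS, SEVERITIES)),
                       sex_log_odds_ratio = log(1.4),
                       recurrence_median_days = c(children = 120, adults = 75,
                                                  elderly = 109),
                       se_by_definition = c(outpatient = 0.19, er = 0.42,
                                            dad = 0.14, radiology_trauma = 0.79),
                       sp_by_definition = c(outpatient = 0.9516, er = 0.9898,
                                            dad = 0.9876,
                                            radiology_trauma = 0.9874),
                       followup_noise_rate = 0.002,
                       censor_prob = 0.15,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop_config("n_patients", "must be a positive count")
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || study_window[1] >= study_window[2])
    stop_config("study_window", "must be two ordered dates")
  check_prob(age_group_probs, "age_group_probs")
  if (length(age_group_probs) != 3 || abs(sum(age_group_probs) - 1) > 1e-12)
    stop_config("age_group_probs", "must be a 3-vector summing to 1")
  check_prob(sex_prob_by_age, "sex_prob_by_age")
  check_prob(incident_prob_by_age, "incident_prob_by_age")
  check_prob(severity_prob, "severity_prob")
  check_prob(recurrence_rate_by_age_severity, "recurrence_rate_by_age_severity")
  if (!all(dim(as.matrix(recurrence_rate_by_age_severity)) == c(3, 2)))
    stop_config("recurrence_rate_by_age_severity", "must be a 3 x 2 matrix")
  check_prob(se_by_definition, "se_by_definition")
  check_prob(sp_by_definition, "sp_by_definition")
  if (length(se_by_definition) != 4 || length(sp_by_definition) != 4)
    stop_config("se_by_definition", "se/sp must each have 4 entries")
  if (any(se_by_definition + sp_by_definition <= 1))
    stop_config("sp_by_definition",
                "each definition needs Se + Sp > 1 for identifiability")
  if (!is.numeric(followup_noise_rate) || any(followup_noise_rate < 0))
    stop_config("followup_noise_rate", "must be non-negative")
  check_prob(censor_prob, "censor_prob")
  if (any(recurrence_median_days <= 7))
    stop_config("recurrence_median_days", "medians must exceed 7 days")
  cfg <- list(
    n_patients = as.integer(n_patients), study_window = study_window,
    age_group_probs = age_group_probs, sex_prob_by_age = sex_prob_by_age,
    incident_prob_by_age = incident_prob_by_age, severity_prob = severity_prob,
    recurrence_rate_by_age_severity = as.matrix(recurrence_rate_by_age_severity),
    sex_log_odds_ratio = sex_log_odds_ratio,
    recurrence_median_days = recurrence_median_days,
    se_by_definition = se_by_definition, sp_by_definition = sp_by_definition,
    followup_noise_rate = followup_noise_rate, censor_prob = censor_prob,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Recurrence day: exponential waiting time after day 7 with the configured
# median, inverse-CDF truncated at day 365 so every recurrent case has
# exactly one day in [7, 365].
draw_recurrence_day <- function(n, median_days) {
  rate <- log(2) / (median_days - 7)
  fmax <- 1 - exp(-rate * 358)
  u <- runif(n, 0, fmax)
  day <- 7 + floor(-log(1 - u) / rate)
  pmin(pmax(day, 7L), 365L)
}

#' Simulate the dynamic cohort and its latent TBI truth
#'
#' Generates `n_patients` patients with staggered cohort entry, assigns true
#' index TBI episodes by age-specific probabilities, a severity grouping, a
#' latent 1-year recurrence (with a male/female odds shift), a recurrence day
#' on \[7, 365\], censoring, and a posterior membership probability emulating
#' the upstream incident-TBI latent class model: true index cases receive a
#' high Beta-distributed membership probability, a small fraction of
#' non-cases receive a low one, and everyone else 0.
#'
#' @param config a [sim_config()].
#' @return list with `patients` (patient_id, sex, age_group, entry_date,
#'   exit_date) and `truth` (patient_id, is_incident_tbi,
#'   incident_membership_prob, index_date, severity, has_recurrence,
#'   recurrence_day).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_patients
  win <- config$study_window
  span <- as.integer(win[2] - win[1])

  age <- sample(AGE_GROUPS, n, replace = TRUE, prob = config$age_group_probs)
  ai <- match(age, AGE_GROUPS)
  male <- runif(n) < config$sex_prob_by_age[ai]
  # entry capped so that a full 365-day post-index follow-up always fits
  # inside the study window (index offset <= 90, administrative tail 430)
  entry <- win[1] + floor(runif(n) * max(1, span - 520))
  incident <- runif(n) < config$incident_prob_by_age[ai]
  index_off <- ifelse(incident, floor(runif(n) * 90), NA_integer_)
  index_date <- entry + index_off

  severity <- rep(NA_character_, n)
  severity[incident] <- ifelse(runif(sum(incident)) < config$severity_prob,
                               "most_severe", "mildest_more_severe")
  si <- match(severity, SEVERITIES)

  # female recurrence risk from the age x severity table; male odds shifted
  p_rec <- rep(0, n)
  idx <- which(incident)
  base <- config$recurrence_rate_by_age_severity[cbind(ai[idx], si[idx])]
  logit <- qlogis(pmin(pmax(base, 1e-9), 1 - 1e-9)) +
    config$sex_log_odds_ratio * male[idx]
  p_rec[idx] <- ifelse(base %in% c(0, 1), base, plogis(logit))
  has_rec <- runif(n) < p_rec

  rec_day <- rep(NA_integer_, n)
  ridx <- which(has_rec)
  if (length(ridx))
    rec_day[ridx] <- draw_recurrence_day(length(ridx),
                                         config$recurrence_median_days[ai[ridx]])

  # censoring: leave before completing 365 days of post-index follow-up
  censored <- runif(n) < config$censor_prob
  fu_anchor <- ifelse(incident, as.numeric(index_date - win[1]),
                      as.numeric(entry - win[1]))
  exit_off <- ifelse(censored, floor(runif(n, 1, 365)), 430)
  exit_date <- pmin(win[1] + fu_anchor + exit_off, win[2])

  # upstream incident-model membership probability
  memb <- numeric(n)
  memb[incident] <- rbeta(sum(incident), 18, 2)
  spurious <- !incident & runif(n) < 0.03
  memb[spurious] <- rbeta(sum(spurious), 2, 18)

  pid <- sprintf("P%06d", seq_len(n))
  list(
    patients = data.frame(
      patient_id = pid, sex = ifelse(male, "M", "F"), age_group = age,
      entry_date = entry, exit_date = exit_date, stringsAsFactors = FALSE),
    truth = data.frame(
      patient_id = pid, is_incident_tbi = incident,
      incident_membership_prob = memb, index_date = index_date,
      severity = severity, has_recurrence = has_rec,
      recurrence_day = rec_day, stringsAsFactors = FALSE))
}

TBI_ICD9_CODES <- c("800", "801", "802", "803", "804", "850", "851", "852",
                    "853", "854", "9501", "9502", "9503", "95901")
TBI_ICD10_CODES <- c("S02", "S06", "S07", "S097", "S098", "S099",
                     "T902", "T905")
RADIOLOGY_BILLING_CODES <- c("08258", "08259", "08570", "08010", "08013")
TRAUMA_PREFIXES <- c("8", "91", "92", "93")

# One qualifying claim-set for definition j at follow-up day `day`.
# Definitions 1-3 are a single TBI-coded claim in their source; definition 4
# is a radiology billing claim plus a trauma-coded physician claim within
# 1 day. DAD coding switches from ICD-9 to ICD-10 in 2007.
definition_claims <- function(pid, index_date, day, j) {
  date <- index_date + day
  if (j == 1L) {
    data.frame(patient_id = pid, service_date = date, source = "outpatient",
               code = "850", code_system = "ICD9", stringsAsFactors = FALSE)
  } else if (j == 2L) {
    data.frame(patient_id = pid, service_date = date, source = "emergency",
               code = "8540", code_system = "ICD9", stringsAsFactors = FALSE)
  } else if (j == 3L) {
    icd10 <- as.integer(format(date, "%Y")) >= 2007
    data.frame(patient_id = pid, service_date = date, source = "dad",
               code = ifelse(icd10, "S060", "850"),
               code_system = ifelse(icd10, "ICD10", "ICD9"),
               stringsAsFactors = FALSE)
  } else {
    n <- length(pid)
    rad_code <- sample(RADIOLOGY_BILLING_CODES, n, replace = TRUE)
    off <- sample(0:1, n, replace = TRUE)
    rbind(
      data.frame(patient_id = pid, service_date = date,
                 source = "radiology_billing", code = rad_code,
                 code_system = "billing", stringsAsFactors = FALSE),
      data.frame(patient_id = pid, service_date = date + off,
                 source = "outpatient", code = "920", code_system = "ICD9",
                 stringsAsFactors = FALSE))
  }
}

#' Emit the administrative claim stream implied by the latent truth
#'
#' For each true recurrence at day d, definition j produces a qualifying
#' claim-set at d with probability `se_by_definition[j]`. For every index
#' patient, definition j additionally produces a false qualifying claim-set
#' at a uniform day of the follow-up window with probability
#' `1 - sp_by_definition[j]`, plus excess early false claim-sets in days 7-30
#' at `followup_noise_rate` per day with geometric decay (the follow-up-care
#' artefact the 30-day sensitivity analysis probes). Claims outside a
#' patient's observation interval are never emitted.
#'
#' @param patients,truth as returned by [simulate_population()].
#' @param config the same [sim_config()].
#' @return data.frame of claims: patient_id, service_date, source, code,
#'   code_system.
#' @export
emit_claims <- function(patients, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  out <- list(); k <- 0L
  add <- function(df) { k <<- k + 1L; out[[k]] <<- df }

  inc <- truth$is_incident_tbi
  exit_day <- as.numeric(patients$exit_date - truth$index_date)  # NA if no index

  # true-recurrence signals
  for (j in 1:4) {
    det <- inc & truth$has_recurrence &
      !is.na(truth$recurrence_day) & truth$recurrence_day <= exit_day &
      runif(nrow(truth)) < config$se_by_definition[j]
    det[is.na(det)] <- FALSE
    if (any(det))
      add(definition_claims(truth$patient_id[det], truth$index_date[det],
                            truth$recurrence_day[det], j))
  }

  # background false positives for non-recurrent follow-up: total
  # per-definition probability 1 - Sp over the window, uniform over days
  # 7..min(365, exit); recurrent cases signal only through the Se channel,
  # keeping the configured Se/Sp exactly the marginal signal probabilities
  iidx <- which(inc)
  fidx <- which(inc & !truth$has_recurrence)
  for (j in 1:4) {
    fp <- fidx[runif(length(fidx)) < 1 - config$sp_by_definition[j]]
    if (length(fp)) {
      hi <- pmin(365, floor(exit_day[fp]))
      ok <- fp[hi >= 7]
      hi <- hi[hi >= 7]
      if (length(ok)) {
        day <- 7 + floor(runif(length(ok)) * (hi - 6))
        add(definition_claims(truth$patient_id[ok], truth$index_date[ok],
                              pmin(day, hi), j))
      }
    }
  }

  # excess early noise, days 7-30, geometric decay
  if (config$followup_noise_rate > 0 && length(iidx)) {
    decay <- 0.85 ^ (0:23)
    for (j in 1:4) {
      p_day <- pmin(config$followup_noise_rate * decay, 1)
      for (d in seq_along(p_day)) {
        day <- 6 + d
        hit <- iidx[runif(length(iidx)) < p_day[d] & exit_day[iidx] >= day]
        hit <- hit[!is.na(hit)]
        if (length(hit))
          add(definition_claims(truth$patient_id[hit], truth$index_date[hit],
                                day, j))
      }
    }
  }

  # sparse background claims for non-index patients (parsed, never counted:
  # hospital physician claims are not an rTBI definition)
  non <- which(!inc)
  bg <- non[runif(length(non)) < 0.02]
  if (length(bg)) {
    off <- floor(runif(length(bg)) *
                   pmax(1, as.numeric(patients$exit_date[bg] -
                                        patients$entry_date[bg])))
    add(data.frame(patient_id = patients$patient_id[bg],
                   service_date = patients$entry_date[bg] + off,
                   source = "hospital_physician", code = "850",
                   code_system = "ICD9", stringsAsFactors = FALSE))
  }

  if (k == 0L)
    return(data.frame(patient_id = character(), service_date = as.Date(character()),
                      source = character(), code = character(),
                      code_system = character(), stringsAsFactors = FALSE))
  claims <- do.call(rbind, out)
  # enforce the observation interval
  m <- match(claims$patient_id, patients$patient_id)
  keep <- claims$service_date >= patients$entry_date[m] &
    claims$service_date <= patients$exit_date[m]
  claims <- claims[keep, , drop = FALSE]
  claims <- claims[order(claims$patient_id, claims$service_date), , drop = FALSE]
  rownames(claims) <- NULL
  claims
}

#' Draw predicted index-TBI cohorts from membership probabilities
#'
#' Emulates carrying uncertainty over from the upstream incident-TBI model:
#' each predicted cohort includes patient i independently with probability
#' `incident_membership_prob[i]`. The published analysis predicted 1,000
#' cohorts, the default here.
#'
#' @param truth truth data.frame from [simulate_population()].
#' @param n_cohorts number of predicted cohorts (default 1000).
#' @param seed integer seed.
#' @return logical matrix, patients x cohorts.
#' @export
draw_incident_cohorts <- function(truth, n_cohorts = 1000, seed = 1L) {
  if (!is.numeric(n_cohorts) || n_cohorts < 1)
    stop("n_cohorts must be at least 1", call. = FALSE)
  n_cohorts <- as.integer(n_cohorts)
  set.seed(derive_seed(seed, 3L))
  p <- truth$incident_membership_prob
  m <- matrix(runif(length(p) * n_cohorts) < p, nrow = length(p))
  rownames(m) <- truth$patient_id
  m
}

#' Write a simulated dataset as plain-text files
#'
#' Writes patients, truth and claims CSVs plus a JSON metadata file recording
#' the full configuration and seed.
#'
#' @param sim list with `patients` and `truth` from [simulate_population()].
#' @param claims claims data.frame from [emit_claims()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, claims, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.csv", "truth.csv", "claims.csv",
                            "sim_metadata.json"))
  write.csv(sim$patients, paths[1], row.names = FALSE)
  write.csv(sim$truth, paths[2], row.names = FALSE)
  write.csv(claims, paths[3], row.names = FALSE)
  meta <- unclass(config)
  meta$study_window <- format(meta$study_window)
  jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
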