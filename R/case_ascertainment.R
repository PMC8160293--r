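DEFINITION_NAMES <- c("outpatient", "er", "dad", "radiology_trauma")

#' Surveillance case-definition specification
#'
#' The four claims-based rTBI case definitions: (1) outpatient physician
#' claim with a TBI diagnostic code, (2) emergency-department physician claim
#' with a TBI code, (3) any TBI code in the hospital discharge abstract
#' database (DAD), and (4) a head-radiology billing claim (CT/MRI/skull
#' x-ray) paired with a physician claim carrying any trauma diagnosis within
#' `pairing_window_days`. Hospital (inpatient) physician claims are parsed
#' but never used as a definition. Code lists are overridable; the defaults
#' are common TBI surveillance code families with dots stripped.
#'
#' @param tbi_icd9,tbi_icd10 character vectors of ICD code prefixes counted
#'   as TBI (dots removed).
#' @param trauma_code_prefixes prefixes of any-trauma diagnostic codes
#'   (default the 8XX, 91X, 92X, 93X families).
#' @param radiology_billing_codes head-imaging billing codes.
#' @param pairing_window_days maximum day gap between the radiology claim and
#'   the trauma-coded physician claim.
#' @return object of class `case_definition_specs`.
#' @export
case_definition_specs <- function(tbi_icd9 = TBI_ICD9_CODES,
                                  tbi_icd10 = TBI_ICD10_CODES,
                                  trauma_code_prefixes = TRAUMA_PREFIXES,
                                  radiology_billing_codes = RADIOLOGY_BILLING_CODES,
                                  pairing_window_days = 1L) {
  stopifnot(length(tbi_icd9) > 0, length(tbi_icd10) > 0,
            length(trauma_code_prefixes) > 0,
            length(radiology_billing_codes) > 0, pairing_window_days >= 0)
  structure(list(tbi_icd9 = toupper(gsub("\\.", "", tbi_icd9)),
                 tbi_icd10 = toupper(gsub("\\.", "", tbi_icd10)),
                 trauma_code_prefixes = toupper(gsub("\\.", "", trauma_code_prefixes)),
                 radiology_billing_codes = radiology_billing_codes,
                 pairing_window_days = as.integer(pairing_window_days)),
            class = "case_definition_specs")
}

#' Post-index ascertainment window
#'
#' Claims in the first `min_day - 1` days after the index TBI are attributed
#' to the index event; the recurrence window runs from `min_day` (default 7)
#' to `max_day` (default 365) days post-index. Setting `min_day = 30`
#' reproduces the 30-day exclusion sensitivity analysis.
#'
#' @param min_day,max_day integers, 0 < min_day < max_day.
#' @return object of class `ascertainment_window`.
#' @export
ascertainment_window <- function(min_day = 7L, max_day = 365L) {
  if (!(min_day > 0 && min_day < max_day))
    stop("ascertainment window requires 0 < min_day < max_day", call. = FALSE)
  structure(list(min_day = as.integer(min_day), max_day = as.integer(max_day)),
            class = "ascertainment_window")
}

matches_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' Apply the four case definitions to a claim stream
#'
#' A definition is met iff a qualifying claim (or, for the radiology
#' definition, a radiology + trauma pair with dates at most
#' `pairing_window_days` apart and the radiology claim inside the window)
#' falls in `[index + min_day, index + max_day]`. The hit day of the
#' radiology definition is the radiology claim's day.
#'
#' @param claims claims data.frame (patient_id, service_date, source, code,
#'   code_system).
#' @param index_episodes data.frame with patient_id and index_date; one row
#'   per index patient to ascertain.
#' @param specs a [case_definition_specs()].
#' @param window an [ascertainment_window()].
#' @return data.frame with patient_id, hit_outpatient, hit_er, hit_dad,
#'   hit_radiology_trauma (logical) and first_hit_day (integer, NA when no
#'   definition is met).
#' @export
apply_case_definitions <- function(claims, index_episodes,
                                   specs = case_definition_specs(),
                                   window = ascertainment_window()) {
  stopifnot(inherits(specs, "case_definition_specs"),
            inherits(window, "ascertainment_window"))
  bad_source <- !(claims$source %in% CLAIM_SOURCES)
  bad_system <- !(claims$code_system %in% CODE_SYSTEMS)
  if (any(bad_source | bad_system))
    stop(sprintf("invalid claim records at rows: %s",
                 paste(utils::head(which(bad_source | bad_system), 20),
                       collapse = ", ")), call. = FALSE)

  idx <- index_episodes[!is.na(index_episodes$index_date), , drop = FALSE]
  n <- nrow(idx)
  hits <- matrix(FALSE, n, 4, dimnames = list(NULL, DEFINITION_NAMES))
  day_mat <- matrix(NA_integer_, n, 4)
  if (nrow(claims)) {
    m <- match(claims$patient_id, idx$patient_id)
    rel <- as.integer(claims$service_date - idx$index_date[m])
    code <- toupper(gsub("\\.", "", claims$code))
    is_tbi <- (claims$code_system == "ICD9" &
                 matches_prefix(code, specs$tbi_icd9)) |
      (claims$code_system == "ICD10" & matches_prefix(code, specs$tbi_icd10))
    in_win <- !is.na(rel) & rel >= window$min_day & rel <= window$max_day

    take_first <- function(sel) {
      first <- tapply(rel[sel], m[sel], min)
      list(rows = as.integer(names(first)), day = as.integer(first))
    }
    src <- claims$source
    for (j in 1:3) {
      want <- c("outpatient", "emergency", "dad")[j]
      sel <- in_win & src == want & is_tbi
      if (any(sel)) {
        f <- take_first(sel)
        hits[f$rows, j] <- TRUE
        day_mat[f$rows, j] <- f$day
      }
    }
    # radiology + trauma pairing, per patient
    rad_sel <- in_win & src == "radiology_billing" &
      claims$code %in% specs$radiology_billing_codes
    trauma_sel <- !is.na(m) & src %in% c("outpatient", "emergency",
                                         "hospital_physician") &
      claims$code_system %in% c("ICD9", "ICD10") &
      matches_prefix(code, specs$trauma_code_prefixes)
    if (any(rad_sel) && any(trauma_sel)) {
      rad_by <- split(rel[rad_sel], m[rad_sel])
      tr_by <- split(rel[trauma_sel], m[trauma_sel])
      common <- intersect(names(rad_by), names(tr_by))
      for (p in common) {
        rd <- rad_by[[p]]; td <- tr_by[[p]]
        ok <- rd[vapply(rd, function(d) any(abs(td - d) <= specs$pairing_window_days),
                        logical(1))]
        if (length(ok)) {
          i <- as.integer(p)
          hits[i, 4] <- TRUE
          day_mat[i, 4] <- min(ok)
        }
      }
    }
  }
  first_hit <- suppressWarnings(apply(day_mat, 1, min, na.rm = TRUE))
  first_hit[!is.finite(first_hit)] <- NA_integer_
  data.frame(patient_id = idx$patient_id,
             hit_outpatient = hits[, 1], hit_er = hits[, 2],
             hit_dad = hits[, 3], hit_radiology_trauma = hits[, 4],
             first_hit_day = as.integer(first_hit),
             stringsAsFactors = FALSE)
}

#' Encode/decode the 16 case-definition response patterns
#'
#' The pattern index encodes the four flags in the fixed bit order
#' (outpatient, er, dad, radiology_trauma) with outpatient as the most
#' significant bit: index = 8 y1 + 4 y2 + 2 y3 + y4, in 0..15.
#'
#' @param flags logical/0-1 vector of length 4, or a matrix with 4 columns.
#' @return integer index (vector).
#' @export
pattern_index <- function(flags) {
  if (is.null(dim(flags))) flags <- matrix(flags, ncol = 4, byrow = TRUE)
  as.integer(flags %*% c(8, 4, 2, 1))
}

#' @rdname pattern_index
#' @param index integer in 0..15.
#' @return `pattern_flags`: 0/1 matrix with one row per index.
#' @export
pattern_flags <- function(index) {
  stopifnot(all(index >= 0 & index <= 15))
  t(vapply(as.integer(index),
           function(i) as.integer(intToBits(i)[4:1] != 0), integer(4)))
}

#' Tabulate the 16 response patterns
#'
#' @param hits data.frame from [apply_case_definitions()] (or any data.frame
#'   with the four hit_* logical columns).
#' @return object of class `response_pattern_counts`: a named integer
#'   16-vector whose names are the binary patterns "0000".."1111".
#' @export
build_response_patterns <- function(hits) {
  flags <- as.matrix(hits[, paste0("hit_", DEFINITION_NAMES)]) * 1
  idx <- pattern_index(flags)
  counts <- tabulate(idx + 1L, nbins = 16L)
  names(counts) <- vapply(0:15, function(i)
    paste(pattern_flags(i), collapse = ""), character(1))
  structure(as.integer(counts), names = names(counts),
            class = "response_pattern_counts")
}

#' Pattern/parameter counting for latent class models
#'
#' With J case definitions there are 2^J response patterns and 2^J - 1
#' degrees of freedom. The parameter count follows the published counting:
#' one incidence parameter plus one response probability per definition per
#' class, i.e. 1 + K x J — nine parameters for the two-class four-definition
#' model and thirteen for the three-class one.
#'
#' @param n_definitions number of case definitions (>= 1).
#' @param n_classes number of latent classes (>= 2).
#' @return named list: n_patterns, degrees_of_freedom, n_parameters.
#' @export
model_dimensions <- function(n_definitions, n_classes) {
  if (!(n_definitions >= 1 && n_classes >= 2))
    stop("need n_definitions >= 1 and n_classes >= 2", call. = FALSE)
  list(n_patterns = as.integer(2^n_definitions),
       degrees_of_freedom = as.integer(2^n_definitions - 1),
       n_parameters = 1L + as.integer(n_classes) * as.integer(n_definitions))
}

#' Person-time at risk for the recurrence analysis
#'
#' Each patient contributes follow-up from the index event until the first
#' qualifying case-definition hit, cohort exit, or `max_day`, whichever comes
#' first, expressed in years of exactly 365 days.
#'
#' @param index_episodes data.frame with patient_id and index_date.
#' @param hits data.frame from [apply_case_definitions()].
#' @param exits data.frame with patient_id and exit_date.
#' @param window an [ascertainment_window()].
#' @return list with `per_patient` (patient_id, person_years) and `total`.
#' @export
compute_person_time <- function(index_episodes, hits, exits,
                                window = ascertainment_window()) {
  idx <- index_episodes[!is.na(index_episodes$index_date), , drop = FALSE]
  exit_day <- as.numeric(exits$exit_date[match(idx$patient_id, exits$patient_id)] -
                           idx$index_date)
  if (any(exit_day < 0, na.rm = TRUE))
    stop("cohort exit precedes the index date", call. = FALSE)
  exit_day[is.na(exit_day)] <- Inf
  hit_day <- hits$first_hit_day[match(idx$patient_id, hits$patient_id)]
  hit_day[is.na(hit_day)] <- Inf
  days <- pmin(hit_day, exit_day, window$max_day)
  py <- days / 365
  list(per_patient = data.frame(patient_id = idx$patient_id,
                                person_years = py, stringsAsFactors = FALSE),
       total = sum(py))
}

#' Crude incidence per 100 person-years
#'
#' @param n_cases number of suspected cases.
#' @param person_years total person-time at risk.
#' @return rate per 100 person-years.
#' @export
crude_incidence <- function(n_cases, person_years) {
  if (!(is.numeric(person_years) && person_years > 0))
    stop("person_years must be positive", call. = FALSE)
  100 * n_cases / person_years
}

#' Crude median time to recurrence
#'
#' Median of `first_hit_day` over patients meeting at least one definition,
#' using the lower-median convention for even counts.
#'
#' @param hits data.frame from [apply_case_definitions()].
#' @return days (integer).
#' @export
crude_median_time <- function(hits) {
  d <- hits$first_hit_day[!is.na(hits$first_hit_day)]
  if (!length(d)) stop("no patient met any case definition", call. = FALSE)
  lower_median(d)
}
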