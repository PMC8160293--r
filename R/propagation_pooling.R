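#' Refit the latent class model across predicted index cohorts
#'
#' Runs one [fit_two_class()] per predicted cohort with a cohort-specific
#' seed derived deterministically from the master seed. Individual cohort
#' failures are recorded, not fatal; the run only errors when every cohort
#' fails.
#'
#' @param cohort_counts list of pattern-count vectors (or matrices when the
#'   sex covariate is active), one per predicted cohort.
#' @param priors an [lcm_priors()].
#' @param settings an [mcmc_settings()]; its seed acts as the master seed.
#' @param covariates passed through to [fit_two_class()].
#' @return list with `fits` (NULL where a cohort failed) and `status`
#'   data.frame (cohort, ok, message).
#' @export
run_multi_cohort <- function(cohort_counts, priors = lcm_priors(),
                             settings = mcmc_settings(), covariates = NULL) {
  if (!length(cohort_counts)) stop("need at least one cohort", call. = FALSE)
  fits <- vector("list", length(cohort_counts))
  ok <- logical(length(cohort_counts))
  msg <- character(length(cohort_counts))
  for (i in seq_along(cohort_counts)) {
    s <- settings
    s$seed <- derive_seed(settings$seed, 1000L + i)
    res <- tryCatch(
      withCallingHandlers(
        fit_two_class(cohort_counts[[i]], covariates = covariates,
                      priors = priors, settings = s),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res; ok[i] <- TRUE
    }
  }
  if (!any(ok))
    stop(paste("all cohort fits failed;", msg[1]), call. = FALSE)
  list(fits = fits,
       status = data.frame(cohort = seq_along(cohort_counts), ok = ok,
                           message = msg, stringsAsFactors = FALSE))
}

#' Pool posterior draws across cohort fits
#'
#' Thins each cohort's post-burn-in draws (all chains concatenated) to an
#' equal per-cohort budget and stacks them — the multiple-imputation-style
#' mixture of posteriors. Pooled size is `M x budget`.
#'
#' @param fits list of `posterior_draws` objects (NULL entries skipped).
#' @param per_cohort_draw_budget draws retained per cohort.
#' @return numeric matrix of pooled draws (rows) by parameter (columns).
#' @export
pool_draws <- function(fits, per_cohort_draw_budget = 100) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no successful fits to pool", call. = FALSE)
  pars <- lapply(fits, `[[`, "parameters")
  if (length(unique(vapply(pars, paste, character(1), collapse = ","))) != 1)
    stop("parameter sets differ across cohorts", call. = FALSE)
  budget <- as.integer(per_cohort_draw_budget)
  pooled <- lapply(fits, function(f) {
    all <- do.call(rbind, f$chains)
    if (budget > nrow(all))
      stop(sprintf("draw budget %d exceeds available %d draws per cohort",
                   budget, nrow(all)), call. = FALSE)
    all[round(seq(1, nrow(all), length.out = budget)), , drop = FALSE]
  })
  do.call(rbind, pooled)
}

#' Cohort-size weights for pooling across age strata
#'
#' @param sizes named vector of index-cohort sizes per stratum.
#' @return object of class `stratum_weights`: weights normalised to sum 1.
#' @export
stratum_weights <- function(sizes) {
  if (any(sizes < 0) || sum(sizes) <= 0)
    stop("cohort sizes must be non-negative with a positive total", call. = FALSE)
  structure(sizes / sum(sizes), class = "stratum_weights")
}

#' Pool posterior draws across strata, weighted by cohort size
#'
#' Draws a mixture of the stratum posteriors: each pooled draw comes from
#' stratum s with probability `weights[s]`. The pooled sample is
#' size-matched to the largest stratum pool.
#'
#' @param stratum_draws list of draw matrices (same columns), one per stratum.
#' @param weights a [stratum_weights()] (or vector summing to 1).
#' @param seed integer seed for the mixture resampling.
#' @return pooled draw matrix.
#' @export
pool_across_strata <- function(stratum_draws, weights, seed = 1L) {
  w <- as.numeric(weights)
  if (length(w) != length(stratum_draws))
    stop("one weight per stratum required", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-6)
    stop("weights must sum to 1", call. = FALSE)
  set.seed(derive_seed(seed, 7L))
  size <- max(vapply(stratum_draws, nrow, integer(1)))
  pick <- sample.int(length(w), size, replace = TRUE, prob = w)
  rows <- lapply(seq_along(w), function(s) {
    n_s <- sum(pick == s)
    if (!n_s) return(NULL)
    stratum_draws[[s]][sample.int(nrow(stratum_draws[[s]]), n_s,
                                  replace = TRUE), , drop = FALSE]
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Summarise pooled draws as median and 95% HDI
#'
#' @param draws numeric vector, or matrix with one column per parameter.
#' @param prob interval mass (default 0.95).
#' @return data.frame: parameter, median, hdi_low, hdi_high, n_draws.
#' @export
summarize_draws <- function(draws, prob = 0.95) {
  if (is.null(dim(draws)))
    draws <- matrix(draws, ncol = 1, dimnames = list(NULL, "value"))
  if (!nrow(draws)) stop("no draws to summarise", call. = FALSE)
  if (nrow(draws) < 100)
    warning("fewer than 100 draws: interval estimates will be unstable",
            call. = FALSE)
  res <- lapply(colnames(draws), function(p) {
    x <- draws[, p]
    h <- hdi(x, prob)
    data.frame(parameter = p, median = median(x),
               hdi_low = h[["lower"]], hdi_high = h[["upper"]],
               n_draws = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
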