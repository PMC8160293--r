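DEFINITION_PAIRS <- t(combn(4, 2))

#' Observed pairwise agreement between case definitions
#'
#' For each of the 6 pairs (j, k), the proportion of subjects with identical
#' results on definitions j and k (raw concordance).
#'
#' @param patterns a `response_pattern_counts` vector (or any length-2^4
#'   count vector in the documented bit order).
#' @return named numeric vector of 6 agreement proportions.
#' @export
pairwise_agreement <- function(patterns) {
  counts <- as.numeric(patterns)
  n <- sum(counts)
  if (n == 0) stop("empty pattern counts", call. = FALSE)
  Y <- pattern_matrix(4)
  out <- apply(DEFINITION_PAIRS, 1, function(pr)
    sum(counts[Y[, pr[1]] == Y[, pr[2]]]) / n)
  names(out) <- apply(DEFINITION_PAIRS, 1, function(pr)
    paste(DEFINITION_NAMES[pr], collapse = ":"))
  out
}

#' Posterior predictive check of pairwise case-definition agreement
#'
#' For a subsample of retained posterior draws, simulates a replicate
#' pattern-count dataset of the observed size from the fitted two-class
#' model, computes the 6 pairwise agreements, and reports per pair the
#' Bayesian p-value: the probability that the observed agreement exceeds the
#' predicted one. Values outside (0.05, 0.95) flag a conditional-independence
#' violation.
#'
#' @param draws a `posterior_draws` object or a pooled draw matrix holding
#'   columns pi, se_*, sp_*.
#' @param observed a `response_pattern_counts` vector.
#' @param n_reps number of predictive replicates (>= 100).
#' @param seed integer seed.
#' @return data.frame: pair, observed, predicted_mean, bayesian_p, flagged.
#' @export
posterior_predictive_check <- function(draws, observed, n_reps = 500,
                                       seed = 1L) {
  if (n_reps < 100) stop("n_reps must be at least 100", call. = FALSE)
  mat <- if (inherits(draws, "posterior_draws")) do.call(rbind, draws$chains)
         else as.matrix(draws)
  need <- c("pi", paste0("se_", DEFINITION_NAMES), paste0("sp_", DEFINITION_NAMES))
  if (!all(need %in% colnames(mat)))
    stop("draws do not carry the 9 two-class model parameters", call. = FALSE)
  counts <- as.numeric(observed)
  if (length(counts) != 16)
    stop("observed counts must cover the 16 response patterns", call. = FALSE)
  n <- sum(counts)
  obs <- pairwise_agreement(counts)

  set.seed(derive_seed(seed, 11L))
  take <- round(seq(1, nrow(mat), length.out = min(n_reps, nrow(mat))))
  rep_ag <- matrix(NA_real_, length(take), 6)
  for (r in seq_along(take)) {
    th <- mat[take[r], ]
    pp <- all_pattern_probs(th["pi"], th[paste0("se_", DEFINITION_NAMES)],
                            th[paste0("sp_", DEFINITION_NAMES)])
    rep_counts <- as.numeric(rmultinom(1, n, pp))
    rep_ag[r, ] <- pairwise_agreement(rep_counts)
  }
  bayes_p <- colMeans(outer(rep(1, length(take)), obs) > rep_ag)
  data.frame(pair = names(obs), observed = as.numeric(obs),
             predicted_mean = colMeans(rep_ag), bayesian_p = bayes_p,
             flagged = bayes_p < 0.05 | bayes_p > 0.95,
             stringsAsFactors = FALSE)
}

#' Prior-sensitivity analysis
#'
#' Refits the model under each prior configuration of a grid and flags a
#' parameter as prior-sensitive when its 95% credible interval under an
#' alternative prior fails to overlap the primary-analysis interval.
#'
#' @param data pattern counts passed to [fit_two_class()].
#' @param prior_grid named list of [lcm_priors()] objects; the first entry is
#'   the primary analysis.
#' @param settings an [mcmc_settings()].
#' @return list with `table` (prior_setting, parameter, median, hdi_low,
#'   hdi_high, overlaps_primary) and `sensitive_parameters`.
#' @export
prior_sensitivity <- function(data, prior_grid, settings = mcmc_settings()) {
  if (!length(prior_grid)) stop("empty prior grid", call. = FALSE)
  if (is.null(names(prior_grid)))
    names(prior_grid) <- paste0("prior", seq_along(prior_grid))
  summaries <- lapply(seq_along(prior_grid), function(i) {
    s <- settings
    s$seed <- derive_seed(settings$seed, 2000L + i)
    fit <- suppressWarnings(fit_two_class(data, priors = prior_grid[[i]],
                                          settings = s))
    sm <- summarize_draws(do.call(rbind, fit$chains))
    sm$prior_setting <- names(prior_grid)[i]
    sm
  })
  primary <- summaries[[1]]
  tab <- do.call(rbind, summaries)
  m <- match(tab$parameter, primary$parameter)
  tab$overlaps_primary <- tab$hdi_low <= primary$hdi_high[m] &
    tab$hdi_high >= primary$hdi_low[m]
  sensitive <- unique(tab$parameter[!tab$overlaps_primary])
  list(table = tab[, c("prior_setting", "parameter", "median", "hdi_low",
                       "hdi_high", "overlaps_primary")],
       sensitive_parameters = sensitive)
}
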