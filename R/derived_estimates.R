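#' Positive and negative predictive values
#'
#' Standard Bayes identities given prevalence, sensitivity, specificity:
#' `ppv = pi Se / (pi Se + (1 - pi)(1 - Sp))` and
#' `npv = (1 - pi) Sp / ((1 - pi) Sp + pi (1 - Se))`. All three arguments
#' may be vectors (e.g. posterior draws), in which case the value is
#' computed draw-wise.
#'
#' @param pi prevalence in (0, 1).
#' @param se,sp sensitivity and specificity in (0, 1).
#' @return probability (vector).
#' @export
ppv <- function(pi, se, sp) {
  check_pred_args(pi, se, sp)
  den <- pi * se + (1 - pi) * (1 - sp)
  if (any(den == 0)) stop("ppv undefined: zero flagged probability", call. = FALSE)
  pi * se / den
}

#' @rdname ppv
#' @export
npv <- function(pi, se, sp) {
  check_pred_args(pi, se, sp)
  den <- (1 - pi) * sp + pi * (1 - se)
  if (any(den == 0)) stop("npv undefined: zero unflagged probability", call. = FALSE)
  (1 - pi) * sp / den
}

check_pred_args <- function(pi, se, sp) {
  if (any(c(pi, se, sp) <= 0) || any(c(pi, se, sp) >= 1))
    stop("pi, se and sp must lie strictly in (0, 1)", call. = FALSE)
}

#' Probability a response pattern belongs to a true rTBI case
#'
#' Bayes posterior over the latent class given the observed pattern:
#' `pi * P(pattern | case) / P(pattern)`.
#'
#' @param pattern 0/1 vector of length J (or matrix of patterns by row).
#' @param params an [lcm_params()].
#' @return probability in \[0, 1\] (vector).
#' @export
classification_probability <- function(pattern, params) {
  stopifnot(inherits(params, "lcm_params"))
  if (is.null(dim(pattern)))
    pattern <- matrix(pattern, ncol = length(params$se), byrow = TRUE)
  a <- exp(pattern %*% log(params$se) +
             (1 - pattern) %*% log(1 - params$se))
  den <- pattern_likelihood(params, pattern)
  if (any(den == 0)) stop("pattern has zero likelihood", call. = FALSE)
  as.numeric(params$pi * a) / den
}

#' Measurement-error-adjusted incidence (Rogan-Gladen)
#'
#' Corrects an apparent (crude) 1-year risk for imperfect sensitivity and
#' specificity: `adjusted = (apparent + Sp - 1) / (Se + Sp - 1)`, clamped to
#' \[0, 1\] with a flag. Rates per 100 person-years can be adjusted by
#' dividing by 100 first (small-rate approximation) and rescaling.
#'
#' @param apparent apparent proportion in \[0, 1\].
#' @param se,sp sensitivity and specificity of the case definition;
#'   `se + sp` must exceed 1.
#' @return list of class `adjusted_incidence`: apparent, adjusted, se_used,
#'   sp_used, clamped.
#' @export
adjust_crude_incidence <- function(apparent, se, sp) {
  if (any(se + sp <= 1))
    stop("se + sp must exceed 1 for the adjustment to be identified",
         call. = FALSE)
  if (any(apparent < 0) || any(apparent > 1))
    stop("apparent must be a proportion in [0, 1]", call. = FALSE)
  raw <- (apparent + sp - 1) / (se + sp - 1)
  adj <- pmin(pmax(raw, 0), 1)
  structure(list(apparent = apparent, adjusted = adj, se_used = se,
                 sp_used = sp, clamped = any(raw != adj)),
            class = "adjusted_incidence")
}

#' Weighted (adjusted) median time to recurrence
#'
#' Each suspected event is weighted by the probability it is real — the
#' product of the upstream incident-membership probability and the
#' pattern-conditional classification probability. The weighted median is
#' the smallest event day whose cumulative weight reaches half the total
#' weight. With `weights = 1` this reduces to [crude_median_time()]'s
#' estimand (up to the even-count tie convention, which for unit weights
#' coincides with the lower median).
#'
#' When a pooled draw matrix is supplied together with per-event pattern
#' indices and membership probabilities, the weighted median is recomputed
#' per draw and summarised as median + 95% HDI.
#'
#' @param days event days since index.
#' @param weights per-event weights in \[0, 1\] (ignored when `draws` given).
#' @param draws optional pooled draw matrix with pi/se_*/sp_* columns.
#' @param pattern_idx integer 0..15 pattern index per event (with `draws`).
#' @param membership_prob upstream membership probability per event
#'   (default 1).
#' @return a single day, or with `draws` a list (median, hdi_low, hdi_high).
#' @export
adjusted_median_time <- function(days, weights = NULL, draws = NULL,
                                 pattern_idx = NULL, membership_prob = 1) {
  if (is.null(draws)) {
    stopifnot(!is.null(weights), length(weights) == length(days))
    return(weighted_median_day(days, weights))
  }
  stopifnot(!is.null(pattern_idx), length(pattern_idx) == length(days))
  mat <- if (inherits(draws, "posterior_draws")) do.call(rbind, draws$chains)
         else as.matrix(draws)
  flags <- pattern_flags(pattern_idx)
  memb <- rep_len(membership_prob, length(days))
  med <- apply(mat, 1, function(th) {
    p <- lcm_params(th[["pi"]], th[paste0("se_", DEFINITION_NAMES)],
                    th[paste0("sp_", DEFINITION_NAMES)])
    w <- memb * classification_probability(flags, p)
    weighted_median_day(days, w)
  })
  h <- hdi(med)
  list(median = median(med), hdi_low = h[["lower"]], hdi_high = h[["upper"]])
}

weighted_median_day <- function(days, weights) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive total", call. = FALSE)
  o <- order(days)
  d <- days[o]; w <- weights[o]
  d[which(cumsum(w) >= sum(w) / 2)[1]]
}
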