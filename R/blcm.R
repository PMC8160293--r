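#' Parameters of the two-class latent class model
#'
#' The nine parameters of the conditional-independence two-class model: the
#' latent rTBI prevalence `pi` and, for each case definition, a sensitivity
#' and a specificity. When the logistic sex covariate is active, `pi` is
#' replaced per subject by `plogis(beta0 + beta_sex * male)`.
#'
#' @param pi latent-class prevalence in (0, 1).
#' @param se,sp numeric vectors of sensitivities/specificities in (0, 1),
#'   one per definition.
#' @param beta0,beta_sex optional logistic coefficients on the latent
#'   prevalence.
#' @return object of class `lcm_params`.
#' @export
lcm_params <- function(pi, se, sp, beta0 = NULL, beta_sex = NULL) {
  stopifnot(length(se) == length(sp))
  if (any(c(pi, se, sp) <= 0) || any(c(pi, se, sp) >= 1))
    stop("pi, se and sp must all lie strictly in (0, 1)", call. = FALSE)
  structure(list(pi = pi, se = as.numeric(se), sp = as.numeric(sp),
                 beta0 = beta0, beta_sex = beta_sex), class = "lcm_params")
}

#' Prior constraints for the latent class model
#'
#' Truncated Beta priors used as parameter constraints. By default all shapes
#' are Beta(1, 1) and the constrained set comprises the prevalence
#' (truncated to (0, 0.25)), every specificity (truncated to (0.7, 1)) and
#' the ER and DAD sensitivities (truncated to (0.02, 0.9)); the remaining
#' sensitivities are unconstrained on (0, 1). These bounds reconstruct the
#' published "non-informative prior information used as constraints" and are
#' fully overridable. Constrained definitions additionally enforce
#' Se + Sp > 1 during sampling, which pins the labelling of the two classes.
#'
#' @param n_definitions number of case definitions.
#' @param pi_bounds,sp_bounds length-2 truncation ranges.
#' @param se_bounds 2-column matrix of per-definition sensitivity ranges
#'   (rows recycled from the default when omitted).
#' @param constrained indices of definitions whose updates must respect
#'   Se + Sp > 1 (default: er and dad, i.e. 2 and 3, when 4 definitions).
#' @param shapes Beta shape parameters `c(a, b)` shared by all priors.
#' @return object of class `lcm_priors`.
#' @export
lcm_priors <- function(n_definitions = 4,
                       pi_bounds = c(0, 0.25),
                       sp_bounds = c(0.7, 1),
                       se_bounds = NULL,
                       constrained = if (n_definitions == 4) c(2L, 3L) else integer(),
                       shapes = c(1, 1)) {
  J <- as.integer(n_definitions)
  if (is.null(se_bounds)) {
    se_bounds <- matrix(c(0, 1), J, 2, byrow = TRUE)
    se_bounds[constrained, 1] <- 0.02
    se_bounds[constrained, 2] <- 0.9
  }
  se_bounds <- matrix(as.numeric(se_bounds), J, 2)
  sp_bounds <- matrix(as.numeric(sp_bounds), J, 2, byrow = TRUE)
  rng <- rbind(pi_bounds, se_bounds, sp_bounds)
  if (any(rng[, 1] < 0) || any(rng[, 2] > 1) || any(rng[, 1] >= rng[, 2]))
    stop("truncation ranges must be sub-intervals of (0, 1)", call. = FALSE)
  structure(list(n_definitions = J, shapes = as.numeric(shapes),
                 pi_bounds = as.numeric(pi_bounds), se_bounds = se_bounds,
                 sp_bounds = sp_bounds, constrained = as.integer(constrained)),
            class = "lcm_priors")
}

#' MCMC settings
#'
#' Defaults mirror the published sampler configuration: three parallel
#' chains of 20,000 iterations with a burn-in of 5,000.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iterations iterations per chain.
#' @param burn_in discarded initial iterations (< n_iterations).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain c uses a seed derived from it.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iterations = 20000, burn_in = 5000,
                          thin = 1, seed = 1L) {
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations", call. = FALSE)
  if (n_chains < 1) stop("need at least one chain", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_settings")
}

# 2^J x J 0/1 matrix of response patterns in the documented bit order
# (definition 1 is the most significant bit).
pattern_matrix <- function(J) {
  idx <- 0:(2^J - 1)
  m <- vapply(idx, function(i)
    as.integer(rev(intToBits(i)[1:J]) != 0), integer(J))
  m <- if (J == 1) matrix(m, ncol = 1) else t(m)
  colnames(m) <- if (J == 4) DEFINITION_NAMES else paste0("def", seq_len(J))
  m
}

# P(pattern | class) for both classes, given se/sp vectors: returns list
# with a (class 1, length 2^J) and b (class 0).
class_pattern_probs <- function(se, sp) {
  Y <- pattern_matrix(length(se))
  a <- exp(Y %*% log(se) + (1 - Y) %*% log(1 - se))
  b <- exp(Y %*% log(1 - sp) + (1 - Y) %*% log(sp))
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Likelihood of a response pattern under the two-class model
#'
#' Returns `pi * prod_j Se_j^y (1-Se_j)^(1-y) + (1-pi) * prod_j
#' (1-Sp_j)^y Sp_j^(1-y)`; the sum over all 2^J patterns is 1.
#'
#' @param params an [lcm_params()].
#' @param pattern 0/1 vector of length J (or matrix of patterns by row).
#' @return probability (vector).
#' @export
pattern_likelihood <- function(params, pattern) {
  stopifnot(inherits(params, "lcm_params"))
  if (is.null(dim(pattern)))
    pattern <- matrix(pattern, ncol = length(params$se), byrow = TRUE)
  y <- pattern
  a <- exp(y %*% log(params$se) + (1 - y) %*% log(1 - params$se))
  b <- exp(y %*% log(1 - params$sp) + (1 - y) %*% log(params$sp))
  as.numeric(params$pi * a + (1 - params$pi) * b)
}

# All 2^J pattern probabilities at once.
all_pattern_probs <- function(pi, se, sp) {
  cp <- class_pattern_probs(se, sp)
  pi * cp$a + (1 - pi) * cp$b
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance comparison: with M chains of length
#' N, `R-hat = sqrt(((N-1)/N * W + B/N) / W)`. Values below 1.1 are the
#' conventional convergence criterion.
#'
#' @param chains list of numeric matrices (iterations x parameters), one per
#'   chain, with identical column names.
#' @return named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("gelman_rubin needs at least 2 chains", call. = FALSE)
  chains <- lapply(chains, as.matrix)
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1 || n < 10)
    stop("each chain needs at least 10 draws of equal length", call. = FALSE)
  p <- ncol(chains[[1]])
  rhat <- numeric(p)
  for (k in seq_len(p)) {
    x <- vapply(chains, function(ch) ch[, k], numeric(n))
    w <- mean(apply(x, 2, var))
    if (!is.finite(w) || w == 0)
      stop("zero within-chain variance: degenerate draws", call. = FALSE)
    b <- n * var(colMeans(x))
    rhat[k] <- sqrt(((n - 1) / n * w + b / n) / w)
  }
  names(rhat) <- colnames(chains[[1]])
  rhat
}

parameter_names <- function(J, covariates = FALSE) {
  defs <- if (J == 4) DEFINITION_NAMES else paste0("def", seq_len(J))
  c("pi", paste0("se_", defs), paste0("sp_", defs),
    if (covariates) c("beta0", "beta_sex"))
}

# One Gibbs chain on aggregated (pattern x sex-stratum) counts.
# counts: matrix 2^J x S (S = 1 without covariates, 2 with), male: length-S
# 0/1 covariate per stratum.
run_chain <- function(counts, male, priors, n_iter, burn_in, thin, seed,
                      covariates) {
  set.seed(seed)
  J <- priors$n_definitions
  Y <- pattern_matrix(J)
  S <- ncol(counts)
  N <- sum(counts)
  a0 <- priors$shapes[1]; b0 <- priors$shapes[2]

  # initial values drawn from the priors
  pi <- rbeta_trunc(1, a0, b0, priors$pi_bounds[1] + 1e-6,
                    priors$pi_bounds[2] - 1e-6)
  se <- vapply(seq_len(J), function(j)
    rbeta_trunc(1, a0, b0, priors$se_bounds[j, 1] + 1e-6,
                priors$se_bounds[j, 2] - 1e-6), numeric(1))
  sp <- vapply(seq_len(J), function(j)
    rbeta_trunc(1, a0, b0, max(priors$sp_bounds[j, 1],
                               if (j %in% priors$constrained) 1 - se[j] else 0) + 1e-6,
                priors$sp_bounds[j, 2] - 1e-6), numeric(1))
  beta <- c(qlogis(pi), 0)
  step <- c(0.1, 0.1)
  acc <- 0L; n_prop <- 0L

  keep <- seq(burn_in + 1L, n_iter, by = thin)
  pnames <- parameter_names(J, covariates)
  out <- matrix(NA_real_, length(keep), length(pnames),
                dimnames = list(NULL, pnames))
  row <- 0L

  for (it in seq_len(n_iter)) {
    cp <- class_pattern_probs(se, sp)
    # per-stratum prevalence
    pis <- if (covariates) plogis(beta[1] + beta[2] * male) else pi
    # data augmentation: latent class-1 count per (pattern, stratum) cell
    Z <- matrix(0, nrow(counts), S)
    for (s in seq_len(S)) {
      ps <- if (covariates) pis[s] else pi
      q <- ps * cp$a / (ps * cp$a + (1 - ps) * cp$b)
      Z[, s] <- rbinom(nrow(counts), counts[, s], q)
    }
    z_pat <- rowSums(Z)                       # class-1 counts by pattern
    n1 <- sum(z_pat); n0 <- N - n1
    y1 <- as.numeric(t(Y) %*% z_pat)          # positives among class 1
    y0 <- as.numeric(t(Y) %*% (rowSums(counts) - z_pat))

    # conjugate truncated-Beta updates; constrained definitions keep
    # Se_j + Sp_j > 1 (label-switching guard)
    for (j in seq_len(J)) {
      lo_se <- priors$se_bounds[j, 1]
      if (j %in% priors$constrained) lo_se <- max(lo_se, 1 - sp[j])
      se[j] <- rbeta_trunc(1, a0 + y1[j], b0 + n1 - y1[j],
                           lo_se, priors$se_bounds[j, 2])
      lo_sp <- priors$sp_bounds[j, 1]
      if (j %in% priors$constrained) lo_sp <- max(lo_sp, 1 - se[j])
      sp[j] <- rbeta_trunc(1, a0 + n0 - y0[j], b0 + y0[j],
                           lo_sp, priors$sp_bounds[j, 2])
    }

    if (!covariates) {
      pi <- rbeta_trunc(1, a0 + n1, b0 + n0,
                        priors$pi_bounds[1], priors$pi_bounds[2])
    } else {
      # random-walk Metropolis on (beta0, beta_sex) given the latent counts;
      # flat prior, with rejection when any stratum prevalence reaches 0.5
      # (label guard on the logistic layer)
      z_s <- colSums(Z); n_s <- colSums(counts)
      loglik <- function(bb) {
        p <- plogis(bb[1] + bb[2] * male)
        if (any(p >= 0.5)) return(-Inf)
        sum(z_s * log(p) + (n_s - z_s) * log1p(-p))
      }
      ll <- loglik(beta)
      for (comp in 1:2) {
        prop <- beta
        prop[comp] <- prop[comp] + rnorm(1, 0, step[comp])
        llp <- loglik(prop)
        n_prop <- n_prop + 1L
        if (is.finite(llp) && log(runif(1)) < llp - ll) {
          beta <- prop; ll <- llp; acc <- acc + 1L
        }
        # adapt during burn-in only
        if (it <= burn_in && it %% 50 == 0)
          step[comp] <- step[comp] * if (acc / max(1, n_prop) > 0.35) 1.1 else 0.9
      }
      pi <- sum(plogis(beta[1] + beta[2] * male) * n_s) / N
    }

    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(pi, se, sp, if (covariates) beta)
    }
  }
  list(draws = out[seq_len(row), , drop = FALSE],
       acceptance = if (covariates) acc / max(1L, n_prop) else NA_real_)
}

#' Fit the two-class Bayesian latent class model by Gibbs sampling
#'
#' Alternates (a) data augmentation of each subject's latent class from its
#' posterior probability given the response pattern and current parameters,
#' and (b) conjugate truncated-Beta updates of the prevalence and of each
#' definition's sensitivity and specificity. Aggregated pattern counts are
#' the sufficient statistic and the fitting unit; when the sex covariate is
#' active, counts are aggregated by pattern x sex and the logistic
#' coefficients (beta0, beta_sex) are updated by a random-walk Metropolis
#' step whose scale adapts during burn-in only.
#'
#' @param data a `response_pattern_counts` vector (from
#'   [build_response_patterns()]), a plain length-2^J count vector, or — when
#'   `covariates` is supplied — a 2^J x 2 matrix of counts with columns
#'   (female, male).
#' @param covariates NULL, or `list(male = c(0, 1))` marking the sex strata
#'   of the count columns.
#' @param priors an [lcm_priors()].
#' @param settings an [mcmc_settings()].
#' @return object of class `posterior_draws`: list with `parameters`,
#'   `chains` (list of post-burn-in draw matrices), `rhat`, `acceptance`,
#'   `settings`, and `converged` (all R-hat < 1.1). A warning is issued —
#'   never silence — when any R-hat is 1.1 or larger.
#' @export
fit_two_class <- function(data, covariates = NULL, priors = lcm_priors(),
                          settings = mcmc_settings()) {
  stopifnot(inherits(priors, "lcm_priors"), inherits(settings, "mcmc_settings"))
  counts <- if (is.matrix(data)) data else matrix(as.numeric(data), ncol = 1)
  if (sum(counts) == 0) stop("empty pattern counts", call. = FALSE)
  J <- priors$n_definitions
  if (nrow(counts) != 2^J)
    stop(sprintf("expected %d pattern counts for %d definitions", 2^J, J),
         call. = FALSE)
  use_cov <- !is.null(covariates)
  male <- if (use_cov) covariates$male else 0
  if (use_cov && length(male) != ncol(counts))
    stop("covariates$male must mark each count column", call. = FALSE)

  chains <- vector("list", settings$n_chains)
  accs <- numeric(settings$n_chains)
  for (c in seq_len(settings$n_chains)) {
    res <- run_chain(counts, male, priors, settings$n_iterations,
                     settings$burn_in, settings$thin,
                     derive_seed(settings$seed, 100L + c), use_cov)
    chains[[c]] <- res$draws
    accs[c] <- res$acceptance
  }
  rhat <- if (settings$n_chains >= 2) gelman_rubin(chains) else
    setNames(rep(NA_real_, ncol(chains[[1]])), colnames(chains[[1]]))
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning(sprintf("non-convergence: R-hat >= 1.1 for %s",
                    paste(names(rhat)[which(rhat >= 1.1)], collapse = ", ")),
            call. = FALSE)
  structure(list(parameters = colnames(chains[[1]]), chains = chains,
                 rhat = rhat, acceptance = accs, settings = settings,
                 priors = priors, converged = converged),
            class = "posterior_draws")
}

#' Brute-force grid posterior for small latent class models
#'
#' Evaluates the unnormalised posterior of the two-class model on a lattice
#' over (pi, Se, Sp) and normalises it — an exhaustive-integration oracle for
#' validating the Gibbs sampler. Only small instances are accepted: at most
#' 2 definitions and at most 2e7 lattice points.
#'
#' @param pattern_counts length-2^J counts (J <= 2).
#' @param grid_resolution lattice points per axis.
#' @param priors an [lcm_priors()] with matching `n_definitions`.
#' @return list with per-parameter marginal grids (`grid`, `prob`), and
#'   `mean` / `median` per parameter.
#' @export
brute_force_posterior <- function(pattern_counts, grid_resolution = 25,
                                  priors = lcm_priors(n_definitions = 2)) {
  counts <- as.numeric(pattern_counts)
  J <- priors$n_definitions
  if (J > 2) stop("brute-force grid supports at most 2 definitions", call. = FALSE)
  stopifnot(length(counts) == 2^J)
  g <- as.integer(grid_resolution)
  if (g^(2 * J + 1) > 2e7)
    stop(sprintf("grid too large: %d^%d points exceeds 2e7", g, 2 * J + 1),
         call. = FALSE)

  axis <- function(bounds) bounds[1] + (seq_len(g) - 0.5) / g * diff(bounds)
  a0 <- priors$shapes[1]; b0 <- priors$shapes[2]
  prior_w <- function(x) dbeta(x, a0, b0)

  pi_g <- axis(priors$pi_bounds)
  se_g <- lapply(seq_len(J), function(j) axis(priors$se_bounds[j, ]))
  sp_g <- lapply(seq_len(J), function(j) axis(priors$sp_bounds[j, ]))
  Y <- pattern_matrix(J)

  # class-conditional pattern probabilities on the (se) and (sp) sub-grids;
  # expand.grid varies the first axis fastest, which matches the column-major
  # reshape into the marginalisation array below
  se_grid <- if (J == 2) expand.grid(se1 = se_g[[1]], se2 = se_g[[2]]) else
    data.frame(se1 = se_g[[1]])
  sp_grid <- if (J == 2) expand.grid(sp1 = sp_g[[1]], sp2 = sp_g[[2]]) else
    data.frame(sp1 = sp_g[[1]])
  A <- sapply(seq_len(2^J), function(p) {
    y <- Y[p, ]
    apply(se_grid, 1, function(se) prod(se^y * (1 - se)^(1 - y)))
  })  # (g^J) x 2^J
  B <- sapply(seq_len(2^J), function(p) {
    y <- Y[p, ]
    apply(sp_grid, 1, function(sp) prod((1 - sp)^y * sp^(1 - y)))
  })
  lw <- log(apply(se_grid, 1, function(se) prod(prior_w(se)))) %o% rep(1, nrow(sp_grid)) +
    rep(1, nrow(se_grid)) %o% log(apply(sp_grid, 1, function(sp) prod(prior_w(sp))))

  npi <- length(pi_g)
  logpost <- matrix(NA_real_, npi, nrow(se_grid) * nrow(sp_grid))
  for (i in seq_len(npi)) {
    pi <- pi_g[i]
    ll <- lw
    for (p in seq_len(2^J)) {
      if (counts[p] == 0) next
      pp <- pi * A[, p] %o% rep(1, nrow(B)) + (1 - pi) * rep(1, nrow(A)) %o% B[, p]
      ll <- ll + counts[p] * log(pp)
    }
    logpost[i, ] <- as.numeric(ll) + log(prior_w(pi))
  }
  post <- exp(logpost - max(logpost))     # one global shift keeps slices comparable
  post <- post / sum(post)

  dims <- c(npi, rep(g, 2 * J))
  full <- array(as.numeric(post), dim = dims)  # column-major: pi axis fastest
  grids <- c(list(pi = pi_g), setNames(se_g, paste0("se", seq_len(J))),
             setNames(sp_g, paste0("sp", seq_len(J))))
  marg <- lapply(seq_along(dims), function(d) apply(full, d, sum))
  names(marg) <- names(grids)
  summ <- lapply(names(grids), function(nm) {
    gr <- grids[[nm]]; pr <- marg[[nm]]
    cum <- cumsum(pr)
    list(grid = gr, prob = pr, mean = sum(gr * pr),
         median = gr[which(cum >= 0.5)[1]])
  })
  names(summ) <- names(grids)
  c(summ, list(mean = vapply(summ, `[[`, numeric(1), "mean"),
               median = vapply(summ, `[[`, numeric(1), "median")))
}

#' Export posterior draws as a long-format data.frame
#'
#' @param fit a `posterior_draws` object.
#' @return data.frame with chain, iteration, parameter, value.
#' @export
draws_long <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  do.call(rbind, lapply(seq_along(fit$chains), function(c) {
    m <- fit$chains[[c]]
    data.frame(chain = c, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.numeric(m), stringsAsFactors = FALSE)
  }))
}
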