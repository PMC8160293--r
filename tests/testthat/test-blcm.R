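test_that("pattern likelihood matches hand-computed values and normalises", {
  p <- lcm_params(0.3, rep(1 - 1e-15, 4), rep(1 - 1e-15, 4))
  expect_equal(pattern_likelihood(p, c(1, 1, 1, 1)), 0.3, tolerance = 1e-9)
  expect_equal(pattern_likelihood(p, c(0, 0, 0, 0)), 0.7, tolerance = 1e-9)
  expect_lt(pattern_likelihood(p, c(1, 0, 0, 0)), 1e-9)

  p2 <- lcm_params(0.1, rep(0.5, 4), rep(0.9, 4))
  expect_equal(pattern_likelihood(p2, c(0, 0, 0, 0)),
               0.1 * 0.5^4 + 0.9 * 0.9^4)
  expect_equal(pattern_likelihood(p2, c(0, 0, 0, 0)), 0.59674,
               tolerance = 1e-5)

  set.seed(8)
  for (i in 1:1000) {
    pr <- lcm_params(runif(1, 0.01, 0.99), runif(4, 0.01, 0.99),
                     runif(4, 0.01, 0.99))
    expect_equal(sum(pattern_likelihood(pr, pattern_flags(0:15))), 1,
                 tolerance = 1e-12)
  }
  expect_error(lcm_params(0, rep(0.5, 4), rep(0.9, 4)), "strictly")
})

test_that("degenerate data with perfect tests are recovered", {
  counts <- rep(0, 16)
  counts[pattern_index(c(1, 1, 1, 1)) + 1] <- 2000   # all-positive cases
  counts[1] <- 8000                                  # all-negative non-cases
  pr <- lcm_priors(sp_bounds = c(0.7, 1), se_bounds = matrix(c(0, 1), 4, 2,
                                                             byrow = TRUE),
                   constrained = integer())
  fit <- fit_two_class(counts, priors = pr, settings = fast_settings(seed = 2))
  d <- do.call(rbind, fit$chains)
  expect_lt(abs(median(d[, "pi"]) - 0.2), 0.02)
  expect_true(all(apply(d[, paste0("se_", def_names)], 2, median) > 0.99))
  expect_true(all(apply(d[, paste0("sp_", def_names)], 2, median) > 0.99))
})

test_that("draws honour truncation ranges and the label constraint", {
  counts <- make_lcm_counts(5000, generating_params$pi, generating_params$se,
                            generating_params$sp, seed = 12)
  pr <- lcm_priors()
  fit <- fit_two_class(counts, priors = pr, settings = fast_settings(seed = 3))
  d <- do.call(rbind, fit$chains)
  expect_true(all(d[, "pi"] > 0 & d[, "pi"] < 0.25))
  for (j in 1:4)
    expect_true(all(d[, paste0("sp_", def_names[j])] >= pr$sp_bounds[j, 1]))
  for (j in pr$constrained)
    expect_true(all(d[, paste0("se_", def_names[j])] +
                      d[, paste0("sp_", def_names[j])] > 1))
  expect_true(all(d[, "se_er"] >= 0.02 & d[, "se_er"] <= 0.9))
})

test_that("identical settings and seed reproduce identical draws", {
  counts <- make_lcm_counts(3000, 0.08, generating_params$se,
                            generating_params$sp, seed = 4)
  f1 <- fit_two_class(counts, settings = fast_settings(seed = 5, iters = 600,
                                                       burn = 200))
  f2 <- fit_two_class(counts, settings = fast_settings(seed = 5, iters = 600,
                                                       burn = 200))
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_two_class(counts, settings = fast_settings(seed = 6, iters = 600,
                                                       burn = 200))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("empty pattern counts are rejected", {
  expect_error(fit_two_class(rep(0, 16)), "empty")
  expect_error(fit_two_class(rep(1, 8)), "expected 16")
})

test_that("gelman_rubin separates mixed from unmixed chains", {
  set.seed(10)
  same <- list(matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x")),
               matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(gelman_rubin(same)[["x"]], 1.05)
  shifted <- list(matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x")),
                  matrix(rnorm(1000, mean = 5), ncol = 1,
                         dimnames = list(NULL, "x")))
  expect_gt(gelman_rubin(shifted)[["x"]], 1.1)
  expect_error(gelman_rubin(same[1]), "at least 2 chains")
  expect_error(gelman_rubin(list(matrix(rep(1, 50), ncol = 1),
                                 matrix(rep(1, 50), ncol = 1))),
               "zero within-chain variance")
})

test_that("gelman_rubin agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(11)
  chains <- lapply(1:3, function(i)
    matrix(rnorm(2000, mean = 0.1 * i), ncol = 2,
           dimnames = list(NULL, c("a", "b"))))
  ours <- gelman_rubin(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[, 1]
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("non-convergence raises a warning, never silence", {
  # two chains locked into disjoint prevalence ranges cannot mix
  counts <- make_lcm_counts(200, 0.1, generating_params$se,
                            generating_params$sp, seed = 14)
  expect_warning(
    {
      fit <- fit_two_class(counts,
                           priors = lcm_priors(pi_bounds = c(0.001, 0.999),
                                               sp_bounds = c(0.01, 1),
                                               se_bounds = matrix(c(0.01, 0.99),
                                                                  4, 2,
                                                                  byrow = TRUE),
                                               constrained = integer()),
                           settings = fast_settings(seed = 15, iters = 120,
                                                    burn = 20))
      expect_false(fit$converged)
    },
    "R-hat")
})

test_that("the sex covariate on latent prevalence is recovered", {
  set.seed(9)
  n <- 50000
  male <- rbinom(n, 1, 0.5)
  pi_i <- plogis(qlogis(0.04) + log(1.4) * male)
  cls <- rbinom(n, 1, pi_i)
  se <- generating_params$se; sp <- generating_params$sp
  Y <- sapply(1:4, function(j)
    rbinom(n, 1, ifelse(cls == 1, se[j], 1 - sp[j])))
  idx <- pattern_index(Y)
  counts <- cbind(tabulate(idx[male == 0] + 1, 16),
                  tabulate(idx[male == 1] + 1, 16))
  fit <- fit_two_class(counts, covariates = list(male = c(0, 1)),
                       settings = fast_settings(seed = 2, iters = 4000,
                                                burn = 1000))
  d <- do.call(rbind, fit$chains)
  or_sex <- median(exp(d[, "beta_sex"]))
  expect_gt(or_sex, 1.2)
  expect_lt(or_sex, 1.65)
  expect_true(all(fit$rhat < 1.1))
})

test_that("the brute-force grid refuses oversized instances", {
  expect_error(brute_force_posterior(rep(1, 16), 10,
                                     priors = lcm_priors(n_definitions = 4)),
               "at most 2 definitions")
  expect_error(brute_force_posterior(rep(1, 4), 200,
                                     priors = lcm_priors(n_definitions = 2)),
               "grid too large")
})

test_that("with no observations the grid posterior equals the prior", {
  pr <- lcm_priors(n_definitions = 1, pi_bounds = c(0, 1),
                   sp_bounds = c(0, 1),
                   se_bounds = matrix(c(0, 1), 1, 2), constrained = integer())
  bf <- brute_force_posterior(c(0, 0), grid_resolution = 21, priors = pr)
  # flat Beta(1,1) prior on a flat grid: uniform marginals, mean 0.5
  expect_equal(bf$pi$mean, 0.5, tolerance = 1e-9)
  expect_true(all(abs(bf$pi$prob - 1 / 21) < 1e-12))
})

test_that("all-positive two-test data push prevalence towards one", {
  pr <- lcm_priors(n_definitions = 2, pi_bounds = c(0, 1),
                   sp_bounds = c(0.5, 1),
                   se_bounds = matrix(c(0.9, 1, 0.9, 1), 2, 2, byrow = TRUE),
                   constrained = integer())
  bf <- brute_force_posterior(c(0, 0, 0, 200), grid_resolution = 15,
                              priors = pr)
  expect_gt(bf$pi$mean, 0.9)
})
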