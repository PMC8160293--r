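#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rbeta qbeta pbeta dbeta runif rexp rmultinom
#'   plogis qlogis median quantile rnorm var setNames
#' @importFrom utils read.csv write.csv combn head
NULL

# Draw from Beta(shape1, shape2) truncated to (lower, upper) by inverse CDF.
# Falls back to the nearest bound when the truncation mass underflows.
rbeta_trunc <- function(n, shape1, shape2, lower = 0, upper = 1) {
  plo <- pbeta(lower, shape1, shape2)
  phi <- pbeta(upper, shape1, shape2)
  if (phi - plo < .Machine$double.xmin) {
    # all posterior mass numerically outside (lower, upper): pin to the
    # nearer bound so the chain cannot escape its constraint
    return(rep(if (plo >= 1) upper else lower, n))
  }
  u <- runif(n, plo, phi)
  x <- qbeta(u, shape1, shape2)
  pmin(pmax(x, lower + 1e-12), upper - 1e-12)
}

# Lower-median convention: for an even count the lower of the two central
# order statistics is returned.
lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Shortest 95% highest-density interval from posterior draws
#'
#' Computes the shortest contiguous interval containing a given mass of the
#' empirical distribution, the usual sample-based HDI estimator.
#'
#' @param x numeric vector of draws.
#' @param prob interval mass, default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) > 0, prob > 0, prob <= 1)
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Deterministic per-task seed fan-out from a master seed, kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1103L + as.numeric(index) * 12289) %% 2147483587)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config(field, "all values must be probabilities in [0, 1]")
  invisible(x)
}
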