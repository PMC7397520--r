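# Truncated-normal machinery for the cohort generator.
#
# Draws use the inverse-CDF method (exact, vectorized, no rejection).  The
# generator parameterizes each group by the *mean of the truncated
# distribution* — the quantity a clinical table reports — so the parent
# location is solved for numerically; the sd is on the parent (pre-truncation)
# scale.

# Mean of N(mu, sigma^2) truncated to [lower, upper].
tnorm_mean <- function(mu, sigma, lower, upper) {
  if (sigma == 0) return(mu)
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Parent location mu0 such that the [lower, upper]-truncated N(mu0, sigma^2)
# has mean `target_mean`.  tnorm_mean is strictly increasing in mu, with
# limits (lower, upper), so a root exists for any target inside the bounds.
tnorm_calibrate_location <- function(target_mean, sigma, lower, upper) {
  if (target_mean <= lower || target_mean >= upper)
    stop("target mean must lie strictly inside the truncation bounds",
         call. = FALSE)
  if (sigma == 0) return(target_mean)
  stats::uniroot(
    function(mu) tnorm_mean(mu, sigma, lower, upper) - target_mean,
    interval = c(lower - 5 * sigma, upper + 5 * sigma),
    tol = 1e-12
  )$root
}

# n draws from N(mu, sigma^2) truncated to [lower, upper] (closed interval),
# by inverse CDF; uses the current RNG stream.
rtnorm <- function(n, mu, sigma, lower, upper) {
  if (sigma == 0) return(rep(mu, n))
  pa <- stats::pnorm(lower, mu, sigma)
  pb <- stats::pnorm(upper, mu, sigma)
  x <- stats::qnorm(stats::runif(n, pa, pb), mu, sigma)
  pmin(pmax(x, lower), upper)  # guard floating-point spill at the bounds
}
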