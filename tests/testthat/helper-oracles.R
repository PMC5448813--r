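# Numeric-integration oracle for the posterior weight: product of the
# joint-prior Gaussian with a narrow two-Gaussian mixture likelihood at
# modes {0, 1}, normalised on a fine grid; returns the mass above 0.5.
posterior_ccw_numeric <- function(mu_m, pi_m, mode_sd = 1e-3) {
  th <- seq(-0.25, 1.25, length.out = 60001)
  prior <- if (pi_m == 0) rep(1, length(th))
           else dnorm(th, mu_m, 1 / sqrt(pi_m))
  lik <- 0.5 * dnorm(th, 0, mode_sd) + 0.5 * dnorm(th, 1, mode_sd)
  post <- prior * lik
  sum(post[th > 0.5]) / sum(post)
}

# Gaussian-product oracle for combine_prior: moments of the normalised
# product of the two component densities on a fine grid.
gaussian_product_numeric <- function(mu1, pi1, mu2, pi2) {
  th <- seq(-4, 5, length.out = 200001)
  d <- dnorm(th, mu1, 1 / sqrt(pi1)) * dnorm(th, mu2, 1 / sqrt(pi2))
  d <- d / sum(d)
  m <- sum(th * d)
  v <- sum((th - m)^2 * d)
  list(mu = m, pi = 1 / v)
}

# a small session/subject pair reused across tests
small_subject <- function(seed = 7, freq = 0.30, runs = 1, pairs = 4,
                          pi_init = 3.5, pi_stereo = 5) {
  synth_subject(model_params(pi_init, pi_stereo, 1),
                build_session(freq, runs = runs, pairs_per_run = pairs),
                seed = seed)
}
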