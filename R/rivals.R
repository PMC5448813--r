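#' Rival model parameter constructors
#'
#' Canonical parameterisations of the three established model classes of
#' bistable perception used for comparison with the predictive-coding
#' model:
#'
#' * **oscillator** — two firing-rate populations with mutual inhibition
#'   and slow self-adaptation; alternations arise deterministically when
#'   adaptation is supra-threshold.
#' * **attractor** — an overdamped particle in a symmetric double well;
#'   transitions are driven purely by noise (Kramers escape).
#' * **intermediate** — the oscillator with additive noise on the drives,
#'   combining adaptation and noise.
#'
#' @param inhibition Cross-inhibition strength (>= 0).
#' @param adapt_strength Self-adaptation strength (>= 0).
#' @param adapt_tau Adaptation time constant in seconds (> 0).
#' @param drive Constant input drive to both populations.
#' @param gain Slope of the sigmoidal population gain function.
#' @param rate_tau Firing-rate time constant in seconds (> 0).
#' @param noise Additive noise amplitude (0 for the pure oscillator).
#' @return A parameter list of class `pc_oscillator` / `pc_attractor`.
#' @name rival_params
NULL

#' @rdname rival_params
#' @export
oscillator_params <- function(inhibition = 2, adapt_strength = 1.2,
                              adapt_tau = 4, drive = 0.8, gain = 8,
                              rate_tau = 0.4, noise = 0, noise_tau = 0.5) {
  stopifnot(adapt_tau > 0, rate_tau > 0, inhibition >= 0,
            adapt_strength >= 0, noise >= 0, noise_tau > 0)
  structure(list(inhibition = inhibition, adapt_strength = adapt_strength,
                 adapt_tau = adapt_tau, drive = drive, gain = gain,
                 rate_tau = rate_tau, noise = noise, noise_tau = noise_tau),
            class = "pc_oscillator")
}

#' @rdname rival_params
#' @param barrier Height of the double-well barrier (> 0).
#' @param relax_tau Relaxation time constant in seconds (> 0).
#' @export
attractor_params <- function(barrier = 1, noise = 0.75, relax_tau = 1) {
  stopifnot(barrier > 0, noise >= 0, relax_tau > 0)
  structure(list(barrier = barrier, noise = noise, relax_tau = relax_tau),
            class = "pc_attractor")
}

# Euler(-Maruyama) loop shared by oscillator/intermediate.
# States: r1, r2 (rates), a1, a2 (adaptation), n1, n2 (OU drive noise,
# time constant p$noise_tau, stationary sd `noise`).
.osc_integrate <- function(p, n_steps, dt, noise) {
  r1 <- 0.6; r2 <- 0.4; a1 <- a2 <- 0   # slight asymmetry breaks the tie
  n1 <- n2 <- 0
  R1 <- numeric(n_steps); R2 <- numeric(n_steps)
  tau_n <- p$noise_tau
  sq <- noise * sqrt(2 * dt / tau_n)
  e1 <- if (noise > 0) stats::rnorm(n_steps) else numeric(n_steps)
  e2 <- if (noise > 0) stats::rnorm(n_steps) else numeric(n_steps)
  for (t in seq_len(n_steps)) {
    if (noise > 0) {
      n1 <- n1 - dt * n1 / tau_n + sq * e1[t]
      n2 <- n2 - dt * n2 / tau_n + sq * e2[t]
    }
    s1 <- 1 / (1 + exp(-p$gain *
      (p$drive + n1 - p$inhibition * r2 - p$adapt_strength * a1)))
    s2 <- 1 / (1 + exp(-p$gain *
      (p$drive + n2 - p$inhibition * r1 - p$adapt_strength * a2)))
    r1 <- r1 + dt * (s1 - r1) / p$rate_tau
    r2 <- r2 + dt * (s2 - r2) / p$rate_tau
    a1 <- a1 + dt * (r1 - a1) / p$adapt_tau
    a2 <- a2 + dt * (r2 - a2) / p$adapt_tau
    if (r1 > 10 || r2 > 10 || !is.finite(r1) || !is.finite(r2))
      stop("oscillator integration diverged; reduce dt", call. = FALSE)
    R1[t] <- r1; R2[t] <- r2
  }
  list(r1 = R1, r2 = R2)
}

#' Simulate the mutual-inhibition oscillator
#'
#' Euler integration of two firing-rate populations with sigmoidal gain,
#' cross-inhibition and slow self-adaptation. With zero noise and
#' supra-threshold adaptation the system is a deterministic relaxation
#' oscillator; the percept at any time is the currently dominant
#' population.
#'
#' @param params An [oscillator_params()].
#' @param total_s Simulated time in seconds.
#' @param dt Integration step in seconds (must be well below
#'   `adapt_tau`).
#' @param seed Seed (only relevant when `noise > 0`).
#' @return An object of class `pc_rival_traj`: `time`, `state` (here the
#'   rate difference `r1 - r2`), `dt`, `kind`.
#' @export
simulate_oscillator <- function(params, total_s, dt = 0.05, seed = NULL) {
  if (dt >= params$adapt_tau / 10)
    stop("'dt' must be small relative to the adaptation time constant",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(total_s / dt)
  tr <- .osc_integrate(params, n, dt, params$noise)
  structure(list(time = seq_len(n) * dt, state = tr$r1 - tr$r2,
                 dt = dt, kind = if (params$noise > 0) "intermediate"
                 else "oscillator"),
            class = "pc_rival_traj")
}

#' Simulate the noise-driven attractor
#'
#' Overdamped Langevin dynamics in the symmetric double-well potential
#' \eqn{V(x) = h (x^2 - 1)^2} with barrier height `h` between the wells at
#' \eqn{x = \pm 1}. The percept is the sign of the state; without noise
#' the particle never leaves its well, and at low noise escape times are
#' approximately exponential (Kramers regime).
#'
#' @param params An [attractor_params()].
#' @inheritParams simulate_oscillator
#' @return A `pc_rival_traj` with `state` = particle position.
#' @export
simulate_attractor <- function(params, total_s, dt = 0.05, seed = NULL) {
  h <- params$barrier
  tau <- params$relax_tau
  # Euler stability near the wells: curvature 8h/tau must satisfy
  # dt * 8h/tau < 2
  if (dt * 8 * h / tau >= 2)
    stop("integration step too large for this barrier; reduce dt",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(total_s / dt)
  x <- 1
  out <- numeric(n)
  sq <- params$noise * sqrt(dt)
  eps <- stats::rnorm(n)
  for (t in seq_len(n)) {
    x <- x - dt * 4 * h * x * (x^2 - 1) / tau + sq * eps[t]
    # reflect rare noise excursions outside the physically relevant range
    if (x > 5) x <- 5 else if (x < -5) x <- -5
    out[t] <- x
  }
  structure(list(time = seq_len(n) * dt, state = out, dt = dt,
                 kind = "attractor"),
            class = "pc_rival_traj")
}

#' Simulate the intermediate (adaptation + noise) model
#'
#' The oscillator dynamics with additive noise on the input drives; in the
#' zero-noise limit this reproduces [simulate_oscillator()] exactly, and
#' with weak adaptation its duration statistics approach the noise-driven
#' regime.
#'
#' @param params An [oscillator_params()] with `noise > 0`.
#' @inheritParams simulate_oscillator
#' @export
simulate_intermediate <- function(params, total_s, dt = 0.05, seed = NULL) {
  simulate_oscillator(params, total_s, dt = dt, seed = seed)
}

#' Percept sequence of a rival trajectory at given times
#'
#' @param traj A `pc_rival_traj`.
#' @param times Times (seconds) at which to read out the percept.
#' @return 0/1 vector (1 where the state difference is positive).
#' @export
rival_percepts <- function(traj, times) {
  idx <- pmin(pmax(round(times / traj$dt), 1), length(traj$state))
  as.numeric(traj$state[idx] > 0)
}

# state difference of a rival model at overlap times, for fitting
.rival_state_at <- function(kind, theta, session_times, total_s, dt, seed) {
  if (kind %in% c("oscillator", "intermediate")) {
    p <- oscillator_params(
      adapt_strength = exp(theta[["log_adapt_strength"]]),
      adapt_tau = exp(theta[["log_adapt_tau"]]),
      noise = if (kind == "intermediate") exp(theta[["log_noise"]]) else 0)
    burn <- 30
    tr <- simulate_oscillator(p, total_s + 2 * burn, dt = dt, seed = seed)
    rival_state <- tr$state
    times <- session_times + burn + theta[["offset"]]
  } else if (kind == "attractor") {
    p <- attractor_params(barrier = exp(theta[["log_barrier"]]),
                          noise = exp(theta[["log_noise"]]))
    tr <- simulate_attractor(p, total_s + 10, dt = dt, seed = seed)
    rival_state <- tr$state
    times <- session_times
  } else stop("unknown rival kind: ", kind, call. = FALSE)
  idx <- pmin(pmax(round(times / dt), 1), length(rival_state))
  rival_state[idx]
}

#' Default priors on rival model parameters
#'
#' Weakly informative Gaussian priors in log space, analogous to the
#' behavioural-model priors: adaptation strength and time constant around
#' their canonical values, noise around 1, and (for the deterministic
#' oscillator) a phase-offset nuisance with a wide Gaussian prior, without
#' which a deterministic oscillation could not be aligned to stochastic
#' data.
#'
#' @param kind `"oscillator"`, `"attractor"` or `"intermediate"`.
#' @return Named list of `list(mean, var)` priors per log-parameter.
#' @export
rival_priors <- function(kind) {
  switch(kind,
    oscillator = list(log_adapt_strength = list(mean = log(1.2), var = 0.5),
                      log_adapt_tau = list(mean = log(4), var = 0.5),
                      offset = list(mean = 0, var = 100)),
    intermediate = list(log_adapt_strength = list(mean = log(1.2), var = 0.5),
                        log_adapt_tau = list(mean = log(4), var = 0.5),
                        log_noise = list(mean = log(0.3), var = 1),
                        offset = list(mean = 0, var = 100)),
    attractor = list(log_barrier = list(mean = log(1), var = 0.5),
                     log_noise = list(mean = log(0.75), var = 0.5)),
    stop("unknown rival kind: ", kind, call. = FALSE))
}

#' Fit a rival model to a response series
#'
#' Maps the rival model's state difference at the scored overlap times
#' through a logistic response function to a Bernoulli choice
#' probability, and performs the same MAP + Laplace-evidence procedure as
#' the behavioural variants, so that rival and predictive-coding log
#' evidences are directly comparable in [rfx_bms()]. The likelihood uses
#' the identical scored-overlap convention (first overlap of each block
#' and missing reports excluded). Stochastic rivals (attractor,
#' intermediate) are evaluated with frozen noise: the same seeded noise
#' path is reused across parameter evaluations.
#'
#' @param kind `"oscillator"`, `"attractor"` or `"intermediate"`.
#' @param responses,session Aligned response series and session.
#' @param priors Priors from [rival_priors()].
#' @param response_gain Fixed slope of the logistic choice mapping
#'   (default 5).
#' @param dt Integration step for the rival dynamics (default 0.1 s).
#' @param n_starts,seed Multi-start controls.
#' @return A list with `map_log_params`, `neg_log_joint`, `log_evidence`,
#'   `hessian`, `kind`.
#' @export
fit_rival <- function(kind, responses, session, priors = rival_priors(kind),
                      response_gain = 5, dt = 0.1, n_starts = 3,
                      seed = NULL) {
  aligned <- .align_data(responses, session)
  # scored-overlap mask: same convention as the behavioural likelihood
  first_of_block <- c(TRUE, diff(aligned$block_id) != 0)
  scored <- !first_of_block & !is.na(aligned$y)
  if (!any(scored)) stop("no scored overlaps in the data", call. = FALSE)
  y <- aligned$y[scored]
  times <- session$overlaps$time_s[scored]
  total_s <- max(session$overlaps$time_s) + 1
  nm <- names(priors)
  noise_seed <- if (is.null(seed)) 1L else seed
  nlj <- function(x) {
    theta <- stats::setNames(as.list(x), nm)
    s <- .rival_state_at(kind, theta, times, total_s, dt, noise_seed)
    p <- pmin(pmax(1 / (1 + exp(-response_gain * s)), 1e-12), 1 - 1e-12)
    ll <- sum(log(ifelse(y == 1, p, 1 - p)))
    lp <- sum(vapply(nm, function(k)
      stats::dnorm(x[[match(k, nm)]], priors[[k]]$mean,
                   sqrt(priors[[k]]$var), log = TRUE), 1))
    -(ll + lp)
  }
  pm <- vapply(nm, function(k) priors[[k]]$mean, 1)
  ps <- vapply(nm, function(k) sqrt(priors[[k]]$var), 1)
  starts <- .draw_starts(n_starts, pm, ps, seed)
  # coarser optimiser settings: the simulated likelihood surface is only
  # piecewise smooth, so high-precision line searches buy nothing
  res <- .map_laplace(nlj, starts, pm, ps, hess_step = 1e-3,
                      reltol = 1e-8, maxit = 60)
  list(map_log_params = stats::setNames(res$map, nm),
       neg_log_joint = res$value,
       log_evidence = res$log_evidence,
       hessian = res$hessian, pd_adjusted = res$pd_adjusted,
       kind = kind)
}
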