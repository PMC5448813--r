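#' Simulate a perceptual time-course from the model
#'
#' Iterates the per-overlap belief-update cycle with decisions sampled from
#' the predicted response probability, producing a stochastic perceptual
#' time-course. By default every overlap is ambiguous (`mu_stereo = 0.5`),
#' which together with `pi_stereo = 0` reproduces the pure bistable
#' regime: spontaneous alternations whose dominance-phase durations follow
#' a gamma-like distribution.
#'
#' @param params A [model_params()] object. For the canonical ambiguous
#'   simulation use `model_params(pi_init = 3.5, pi_stereo = 0, zeta = 1)`.
#' @param total_seconds Total simulated time in seconds.
#' @param sampling_rate_hz Overlap frequency in Hz (one belief update per
#'   overlap); the canonical value is 0.33.
#' @param inputs Optional data frame with columns `mu_stereo` and
#'   `condition` giving per-overlap input; recycled/truncated to the
#'   simulation length. `NULL` (default) means purely ambiguous input.
#' @param seed Integer seed for the decision sampler; `NULL` uses the
#'   current RNG state.
#' @return An object of class `pc_simulation`: list with `decisions`
#'   (0/1 vector), `records` (per-overlap data frame with `p_ccw`,
#'   `y_predicted`, `pe`, `pi_stability`), `dt` (seconds per overlap),
#'   `params` and `seed`.
#' @examples
#' sim <- simulate_timecourse(model_params(3.5, 0, 1), 3000, 0.33, seed = 1)
#' mean(phase_durations(sim$decisions, sim$dt))
#' @export
simulate_timecourse <- function(params, total_seconds, sampling_rate_hz,
                                inputs = NULL, seed = NULL) {
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be positive", call. = FALSE)
  n <- floor(total_seconds * sampling_rate_hz)
  if (n < 2)
    stop("simulation horizon must cover at least 2 overlaps", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu_stereo <- rep(0.5, n)
  if (!is.null(inputs)) {
    mu_stereo <- rep(inputs$mu_stereo, length.out = n)
    amb <- rep(inputs$condition == "ambiguous", length.out = n)
    mu_stereo[amb] <- 0.5
  }
  pi_init <- params$pi_init
  pi_stereo <- params$pi_stereo
  zeta <- params$zeta
  # start from a fresh phase: random initial percept, full stability
  mu <- as.numeric(stats::runif(1) < 0.5)
  u <- stats::runif(n)
  y <- numeric(n)
  p_ccw <- y_pred <- pe <- pi_stab <- numeric(n)
  pi <- pi_init
  for (t in seq_len(n)) {
    pm <- pi + pi_stereo
    mm <- if (pm == 0) 0.5 else (pi * mu + pi_stereo * mu_stereo[t]) / pm
    p <- 1 / (1 + exp(-pm * (mm - 0.5)))
    yp <- if (zeta == 1) p else 1 / (1 + exp(-zeta * log(p / (1 - p))))
    yt <- as.numeric(u[t] < yp)
    e <- abs(yt - p)
    if (yt != mu) {
      mu <- yt
      pi <- pi_init
    } else {
      pi <- 1 / (1 / pi + e)
    }
    y[t] <- yt; p_ccw[t] <- p; y_pred[t] <- yp; pe[t] <- e; pi_stab[t] <- pi
  }
  structure(list(decisions = y,
                 records = data.frame(p_ccw = p_ccw, y_predicted = y_pred,
                                      pe = pe, pi_stability = pi_stab),
                 dt = 1 / sampling_rate_hz,
                 params = params,
                 seed = seed),
            class = "pc_simulation")
}

#' Dominance-phase durations from a decision sequence
#'
#' Converts runs of constant perceptual decision into phase durations in
#' seconds. The first and last runs are truncated by the observation window
#' and are excluded.
#'
#' @param decisions 0/1 decision vector.
#' @param dt Seconds per overlap.
#' @return Numeric vector of complete phase durations in seconds (possibly
#'   empty, e.g. for a constant sequence).
#' @export
phase_durations <- function(decisions, dt) {
  if (length(decisions) < 2)
    stop("need at least 2 decisions", call. = FALSE)
  runs <- rle(as.vector(decisions))$lengths
  if (length(runs) <= 2) return(numeric(0))
  runs[-c(1L, length(runs))] * dt
}

#' Summary statistics of dominance-phase durations
#'
#' Arithmetic mean, median, coefficient of variation, and a
#' maximum-likelihood gamma fit (shape/scale). The classical signature of
#' bistable perception is a gamma-like duration distribution with shape
#' greater than 1 (sharp rise, slow fall).
#'
#' @param durations Phase durations in seconds; the gamma fit requires at
#'   least 30 values (otherwise `NA` with a warning).
#' @return A list with `n`, `mean`, `median`, `cv`, `gamma_shape`,
#'   `gamma_scale`.
#' @export
duration_stats <- function(durations) {
  if (length(durations) < 2)
    stop("need at least 2 complete phase durations", call. = FALSE)
  shape <- scale <- NA_real_
  if (length(durations) >= 30 && stats::sd(durations) > 0) {
    fit <- tryCatch(
      fitdistrplus::fitdist(as.numeric(durations), "gamma",
                            method = "mle", keepdata = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) {
      shape <- unname(fit$estimate["shape"])
      scale <- 1 / unname(fit$estimate["rate"])
    }
  } else if (length(durations) < 30) {
    warning("fewer than 30 durations: gamma fit skipped", call. = FALSE)
  }
  list(n = length(durations),
       mean = mean(durations),
       median = stats::median(durations),
       cv = stats::sd(durations) / mean(durations),
       gamma_shape = shape,
       gamma_scale = scale)
}

#' Semi-analytic expected dominance duration (stay-path oracle)
#'
#' Under purely ambiguous input the belief state within a dominance phase
#' evolves deterministically as long as the percept is maintained: after
#' each stay the prediction error `1 - p_stay` accumulates on the variance
#' of the stability prior. The phase length in overlaps is therefore
#' geometric-like with hazard sequence `1 - p_stay(j)`, and its expectation
#' has the closed survival-product form
#' \deqn{E[L] = 1 + \sum_k \prod_{j \le k} p_{stay}(j).}
#' This is an independent route to the mean dominance duration against
#' which stochastic simulations can be checked.
#'
#' @param params A [model_params()] object (ambiguous regime:
#'   `pi_stereo = 0`).
#' @param sampling_rate_hz Overlap frequency in Hz.
#' @param kmax Truncation order for the survival product (the tail decays
#'   geometrically with ratio < 0.54).
#' @return Expected dominance-phase duration in seconds.
#' @export
expected_phase_duration <- function(params, sampling_rate_hz, kmax = 2000) {
  pi <- params$pi_init
  zeta <- params$zeta
  cum <- 1
  e_len <- 1
  for (k in seq_len(kmax)) {
    p <- 1 / (1 + exp(-pi * 0.5))          # posterior weight for staying
    p_stay <- if (zeta == 1) p else 1 / (1 + exp(-zeta * log(p / (1 - p))))
    cum <- cum * p_stay
    e_len <- e_len + cum
    pi <- 1 / (1 / pi + (1 - p))           # deterministic all-stay update
    if (cum < 1e-12) break
  }
  e_len / sampling_rate_hz
}
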