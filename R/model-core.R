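#' Model parameters for the predictive-coding model
#'
#' The model has three free quantities: the initial precision of the
#' stability prior (`pi_init`), the precision of the stereodisparity weight
#' (`pi_stereo`), and the inverse decision temperature of the response model
#' (`zeta`). Setting a precision to zero disables the corresponding
#' component exactly (a flat distribution contributes nothing to the joint
#' prior).
#'
#' @param pi_init Initial precision of the stability prior (dimensionless,
#'   \eqn{\ge 0}; 0 disables perceptual stability). Default 3.5, the value
#'   used for time-course simulation.
#' @param pi_stereo Precision of the stereodisparity weight
#'   (dimensionless, \eqn{\ge 0}; 0 disables disambiguation).
#' @param zeta Inverse decision temperature of the response model
#'   (\eqn{> 0}). Default 1, in which case the predicted response equals
#'   the posterior weight.
#' @return An object of class `pc_params`.
#' @examples
#' model_params(pi_init = 3.5, pi_stereo = 0)
#' @export
model_params <- function(pi_init = 3.5, pi_stereo = 0, zeta = 1) {
  for (nm in c("pi_init", "pi_stereo", "zeta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (pi_init < 0 || pi_stereo < 0)
    stop("precisions must be non-negative (0 disables the component)",
         call. = FALSE)
  if (zeta <= 0)
    stop("'zeta' must be strictly positive", call. = FALSE)
  structure(list(pi_init = pi_init, pi_stereo = pi_stereo, zeta = zeta),
            class = "pc_params")
}

#' @export
print.pc_params <- function(x, ...) {
  cat("Predictive-coding model parameters\n")
  cat(sprintf("  pi_init   = %g%s\n", x$pi_init,
              if (x$pi_init == 0) "  (stability prior disabled)" else ""))
  cat(sprintf("  pi_stereo = %g%s\n", x$pi_stereo,
              if (x$pi_stereo == 0) "  (stereodisparity disabled)" else ""))
  cat(sprintf("  zeta      = %g\n", x$zeta))
  invisible(x)
}

#' Perceptual state
#'
#' The evolving stability prior: a Gaussian belief centred on the percept
#' adopted at the previous overlap. `mu_stability` is coded 0 = clockwise,
#' 1 = counter-clockwise; `pi_stability` is its precision, reset to
#' `pi_init` immediately after a perceptual transition and eroded by
#' prediction errors while a percept is maintained.
#'
#' @param mu_stability Previous perceptual decision, 0 or 1.
#' @param pi_stability Precision of the stability prior (\eqn{\ge 0}).
#' @return An object of class `pc_state`.
#' @export
perceptual_state <- function(mu_stability, pi_stability) {
  if (!mu_stability %in% c(0, 1))
    stop("'mu_stability' must be 0 (clockwise) or 1 (counter-clockwise)",
         call. = FALSE)
  if (!is.finite(pi_stability) || pi_stability < 0)
    stop("'pi_stability' must be finite and non-negative", call. = FALSE)
  structure(list(mu_stability = mu_stability, pi_stability = pi_stability),
            class = "pc_state")
}

#' Combine the stability prior with the stereodisparity weight
#'
#' Gaussian precision-weighted fusion of the stability prior
#' (`mu_stability`, `pi_stability`) with the stereodisparity weight
#' (`mu_stereo`, `pi_stereo`) into the joint prior placed on the bimodal
#' likelihood:
#' \deqn{\pi_m = \pi_{stability} + \pi_{stereo}, \quad
#'   \mu_m = (\pi_{stability}\mu_{stability} +
#'            \pi_{stereo}\mu_{stereo}) / \pi_m.}
#' When both precisions are zero the joint prior is flat and `mu_m = 0.5`
#' by convention. On ambiguous overlaps `mu_stereo = 0.5`, which cancels
#' exactly from the posterior weight, so the stereodisparity term only
#' biases replay overlaps.
#'
#' @param state A [perceptual_state()].
#' @param mu_stereo Mean of the stereodisparity weight: 0.5 on ambiguous
#'   overlaps, 0 or 1 on replay overlaps.
#' @param params A [model_params()] object.
#' @return A list with elements `mu_m` and `pi_m`.
#' @export
combine_prior <- function(state, mu_stereo, params) {
  if (!is.finite(mu_stereo)) stop("'mu_stereo' must be finite", call. = FALSE)
  pi_m <- state$pi_stability + params$pi_stereo
  mu_m <- if (pi_m == 0) 0.5 else
    (state$pi_stability * state$mu_stability +
       params$pi_stereo * mu_stereo) / pi_m
  list(mu_m = mu_m, pi_m = pi_m)
}

#' Posterior weight for counter-clockwise rotation
#'
#' The sensory input at an overlap is a bimodal likelihood with equal modes
#' at 0 (clockwise) and 1 (counter-clockwise). In the narrow-mode limit the
#' posterior mass above 0.5 depends only on the joint-prior density ratio
#' at the two modes, which gives the closed form
#' \deqn{P(\theta > 0.5) = \mathrm{logistic}(\pi_m (\mu_m - 0.5)).}
#' The weight is 0.5 whenever the joint prior is flat (`pi_m = 0`) or
#' centred (`mu_m = 0.5`), and strictly inside (0, 1) for finite inputs.
#'
#' @param mu_m,pi_m Mean and precision of the joint prior.
#' @return `P(theta > 0.5)`, the probability of perceiving
#'   counter-clockwise rotation.
#' @export
posterior_ccw <- function(mu_m, pi_m) {
  if (!is.finite(mu_m) || !is.finite(pi_m))
    stop("'mu_m' and 'pi_m' must be finite", call. = FALSE)
  if (pi_m < 0) stop("'pi_m' must be non-negative", call. = FALSE)
  # keep strictly inside (0,1) where the logistic saturates in floating point
  min(max(stats::plogis(pi_m * (mu_m - 0.5)), 1e-12), 1 - 1e-12)
}

#' Response model: unit-square sigmoid
#'
#' Maps the posterior weight onto a predicted response probability with a
#' unit-square sigmoid controlled by the inverse decision temperature
#' \eqn{\zeta}:
#' \deqn{y_{predicted} = \frac{p^{\zeta}}{p^{\zeta} + (1-p)^{\zeta}}.}
#' The identity for \eqn{\zeta = 1}; 0.5 is a fixed point for all
#' \eqn{\zeta}.
#'
#' @param p_ccw Posterior weight in (0, 1).
#' @param zeta Inverse decision temperature (\eqn{> 0}).
#' @return Predicted response probability in (0, 1).
#' @export
response_probability <- function(p_ccw, zeta) {
  if (zeta <= 0) stop("'zeta' must be strictly positive", call. = FALSE)
  if (any(!is.finite(p_ccw)) || any(p_ccw <= 0) || any(p_ccw >= 1))
    stop("'p_ccw' must lie strictly inside (0, 1)", call. = FALSE)
  # p^z / (p^z + (1-p)^z) computed on the logit scale for stability
  pmin(pmax(stats::plogis(zeta * stats::qlogis(p_ccw)), 1e-12), 1 - 1e-12)
}

#' Prediction error at an overlap
#'
#' The residual posterior evidence for the suppressed percept: the absolute
#' difference between the perceptual decision and the posterior weight,
#' `|y - P(theta > 0.5)|`, bounded by \[0, 1\] and approaching 0.5 as the
#' posterior relaxes to equivocality.
#'
#' @param y Perceptual decision, 0 or 1.
#' @param p_ccw Posterior weight for counter-clockwise rotation.
#' @return Prediction error in \[0, 1\].
#' @export
prediction_error <- function(y, p_ccw) {
  if (!all(y %in% c(0, 1)))
    stop("'y' must be 0 or 1", call. = FALSE)
  abs(y - p_ccw)
}

#' Update the stability prior after a decision
#'
#' If the decision differs from the current percept (a transition), the
#' stability prior is re-centred on the new percept and its precision reset
#' to `pi_init`. Otherwise the prediction error accumulates on the variance
#' of the prior,
#' \deqn{1/\pi' = 1/\pi + PE,}
#' so that sustained residual evidence for the suppressed percept gradually
#' erodes perceptual stability.
#'
#' @param state A [perceptual_state()].
#' @param y Decision at the current overlap, 0 or 1.
#' @param pe Prediction error at the current overlap, in \[0, 1\].
#' @param params A [model_params()] object.
#' @return The updated [perceptual_state()].
#' @export
update_state <- function(state, y, pe, params) {
  if (!y %in% c(0, 1)) stop("'y' must be 0 or 1", call. = FALSE)
  if (!is.finite(pe) || pe < 0 || pe > 1)
    stop("'pe' must lie in [0, 1]", call. = FALSE)
  if (y != state$mu_stability)
    perceptual_state(y, params$pi_init)
  else
    perceptual_state(state$mu_stability, 1 / (1 / state$pi_stability + pe))
}

#' One belief-update step at an overlap
#'
#' Executes the full per-overlap cycle: combine the stability prior with
#' the stereodisparity weight, evaluate the posterior weight for
#' counter-clockwise rotation, map it through the response model, take a
#' decision (observed, or sampled from the predicted response
#' probability), compute the prediction error, and update the stability
#' prior.
#'
#' @param state A [perceptual_state()].
#' @param mu_stereo Stereodisparity mean at this overlap (0.5 ambiguous;
#'   0/1 replay).
#' @param params A [model_params()] object.
#' @param decision Observed decision (0/1), or `NULL` to sample from
#'   `Bernoulli(y_predicted)` using the session RNG.
#' @return A list with the updated `state` and a `record` list holding
#'   `mu_m`, `pi_m`, `p_ccw`, `y_predicted`, `y` and `pe`.
#' @export
step_overlap <- function(state, mu_stereo, params, decision = NULL) {
  jp <- combine_prior(state, mu_stereo, params)
  p_ccw <- posterior_ccw(jp$mu_m, jp$pi_m)
  y_pred <- response_probability(p_ccw, params$zeta)
  y <- if (is.null(decision)) {
    as.numeric(stats::runif(1) < y_pred)
  } else {
    if (!decision %in% c(0, 1))
      stop("observed decision must be 0 or 1", call. = FALSE)
    decision
  }
  pe <- prediction_error(y, p_ccw)
  list(state = update_state(state, y, pe, params),
       record = list(mu_m = jp$mu_m, pi_m = jp$pi_m, p_ccw = p_ccw,
                     y_predicted = y_pred, y = y, pe = pe))
}

# Tight inner filter over aligned overlap vectors. Sequential by necessity:
# the stability prior at overlap t depends on the decision at t-1.
# block_id marks block membership (state resets at every change);
# y may contain NA (carried forward, unscored). Returns per-overlap vectors.
.filter_core <- function(block_id, condition_ambiguous, mu_stereo, y,
                         pi_init, pi_stereo, zeta) {
  n <- length(y)
  mu_m <- pi_m <- p_ccw <- y_pred <- y_out <- pe <-
    pi_stab <- numeric(n)
  scored <- logical(n)
  mu <- 0
  pi <- 0
  prev_block <- NA_integer_
  last_y <- 0
  for (t in seq_len(n)) {
    new_block <- !identical(block_id[t], prev_block)
    if (new_block) pi <- 0  # no stability prior at a block start
    ms <- if (condition_ambiguous[t]) 0.5 else mu_stereo[t]
    pm <- pi + pi_stereo
    mm <- if (pm == 0) 0.5 else (pi * mu + pi_stereo * ms) / pm
    p <- 1 / (1 + exp(-pm * (mm - 0.5)))
    yp <- if (zeta == 1) p else
      1 / (1 + exp(-zeta * log(p / (1 - p))))
    obs <- y[t]
    missing_y <- is.na(obs)
    yt <- if (missing_y) last_y else obs
    e <- abs(yt - p)
    mu_m[t] <- mm; pi_m[t] <- pm; p_ccw[t] <- p; y_pred[t] <- yp
    y_out[t] <- yt; pe[t] <- e; pi_stab[t] <- pi
    scored[t] <- !new_block && !missing_y
    if (new_block || yt != mu) {
      mu <- yt
      pi <- pi_init
    } else {
      pi <- 1 / (1 / pi + e)
    }
    last_y <- yt
    prev_block <- block_id[t]
  }
  list(mu_m = mu_m, pi_m = pi_m, p_ccw = p_ccw, y_predicted = y_pred,
       y = y_out, pe = pe, pi_stability = pi_stab, scored = scored)
}

#' Deterministic belief trajectory from observed responses
#'
#' Replays the belief-update cycle through a session using the observed
#' perceptual reports as decisions, producing the per-overlap trajectory
#' (joint prior, posterior weight, predicted response, prediction error)
#' used both for model inversion and as the prediction-error time-course
#' for model-based fMRI.
#'
#' The state is re-initialised at every block start: the first overlap of a
#' block carries no stability prior, is excluded from the fitting
#' likelihood (`scored = FALSE`), and the prior is then centred on the
#' first reported percept with precision `pi_init`. Missing reports (`NA`)
#' carry the previous decision forward for state propagation but are also
#' unscored.
#'
#' @param responses A response series data frame with columns `run`,
#'   `block`, `overlap_index`, `time_s`, `condition`, `response`
#'   (0/1/`NA`), one row per session overlap, in session order (see
#'   [read_responses()]).
#' @param session A [build_session()] object whose `overlaps` table aligns
#'   row-for-row with `responses`.
#' @param params A [model_params()] object.
#' @return A data frame with one row per overlap: the session columns plus
#'   `mu_m`, `pi_m`, `p_ccw`, `y_predicted`, `y`, `pe`, `pi_stability` and
#'   `scored`.
#' @export
filter_responses <- function(responses, session, params) {
  ov <- session$overlaps
  if (nrow(ov) != nrow(responses))
    stop("responses (", nrow(responses), " rows) do not match session overlaps (",
         nrow(ov), " rows)", call. = FALSE)
  if (!all(responses$run == ov$run) || !all(responses$block == ov$block))
    stop("responses are not aligned with the session overlap timeline",
         call. = FALSE)
  amb <- ov$condition == "ambiguous"
  if (any(!amb & is.na(ov$mu_stereo)))
    stop("replay overlaps carry no mu_stereo; generate or load the replay ",
         "disparity sequence first", call. = FALSE)
  res <- .filter_core(block_id = as.integer(interaction(ov$run, ov$block, drop = TRUE)),
                      condition_ambiguous = amb,
                      mu_stereo = ov$mu_stereo,
                      y = responses$response,
                      pi_init = params$pi_init,
                      pi_stereo = params$pi_stereo,
                      zeta = params$zeta)
  cbind(ov[c("run", "block", "overlap_index", "time_s", "condition")],
        as.data.frame(res))
}
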