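#' Behavioural model variants
#'
#' The four behavioural models are all combinations of the two conceptual
#' components: the stereodisparity likelihood weight and the perceptual
#' stability prior. Disabling a component fixes its precision to zero,
#' which removes the distribution from the model exactly.
#'
#' * variant 1: no stereodisparity, no stability (chance model)
#' * variant 2: stability only
#' * variant 3: stereodisparity only
#' * variant 4: both (the full predictive-coding model)
#'
#' @param id Integer 1-4.
#' @return A list with `id`, `use_stereo`, `use_stability`.
#' @export
variant_spec <- function(id) {
  if (!id %in% 1:4) stop("variant id must be 1, 2, 3 or 4", call. = FALSE)
  list(id = id,
       use_stereo = id %in% c(3, 4),
       use_stability = id %in% c(2, 4))
}

#' Log-normal parameter priors for model inversion
#'
#' Precisions are modelled as log-normal: the inversion operates on
#' log-parameters with Gaussian priors. Defaults: `pi_init` prior mean
#' log(3), variance 5; `pi_stereo` prior mean log(5), variance 5; `zeta`
#' fixed at 1 (set `zeta_fixed = FALSE` for a free `zeta` with prior mean
#' log(1), variance 1).
#'
#' @param pi_init_mean,pi_init_var Prior mean/variance of `log(pi_init)`.
#' @param pi_stereo_mean,pi_stereo_var Prior mean/variance of
#'   `log(pi_stereo)`.
#' @param zeta_fixed Keep `zeta = 1` fixed (default `TRUE`).
#' @param zeta_mean,zeta_var Prior for `log(zeta)` when free.
#' @return An object of class `pc_priors`.
#' @export
prior_spec <- function(pi_init_mean = log(3), pi_init_var = 5,
                       pi_stereo_mean = log(5), pi_stereo_var = 5,
                       zeta_fixed = TRUE, zeta_mean = log(1), zeta_var = 1) {
  structure(list(
    pi_init = list(mean = pi_init_mean, var = pi_init_var),
    pi_stereo = list(mean = pi_stereo_mean, var = pi_stereo_var),
    zeta = list(fixed = zeta_fixed, mean = zeta_mean, var = zeta_var)),
    class = "pc_priors")
}

# names of the free (log-)parameters of a variant
.free_names <- function(variant, priors) {
  nm <- character(0)
  if (variant$use_stability) nm <- c(nm, "pi_init")
  if (variant$use_stereo) nm <- c(nm, "pi_stereo")
  if (!priors$zeta$fixed) nm <- c(nm, "zeta")
  nm
}

# assemble full model_params from named log-parameters of a variant
.variant_params <- function(log_params, variant, priors) {
  g <- function(nm) if (nm %in% names(log_params)) exp(log_params[[nm]]) else NULL
  model_params(
    pi_init = if (variant$use_stability) g("pi_init") else 0,
    pi_stereo = if (variant$use_stereo) g("pi_stereo") else 0,
    zeta = if (priors$zeta$fixed) 1 else g("zeta"))
}

# precompute the aligned arrays used by the likelihood, once per data set
.align_data <- function(responses, session) {
  ov <- session$overlaps
  if (nrow(ov) != nrow(responses))
    stop("responses do not match session overlaps", call. = FALSE)
  list(block_id = as.integer(interaction(ov$run, ov$block, drop = TRUE)),
       ambiguous = ov$condition == "ambiguous",
       mu_stereo = ov$mu_stereo,
       y = responses$response)
}

.nlj_from_aligned <- function(log_params, aligned, variant, priors) {
  if (any(!is.finite(unlist(log_params))))
    stop("non-finite parameters", call. = FALSE)
  par <- .variant_params(log_params, variant, priors)
  tr <- .filter_core(aligned$block_id, aligned$ambiguous, aligned$mu_stereo,
                     aligned$y, par$pi_init, par$pi_stereo, par$zeta)
  sc <- tr$scored
  if (!any(sc)) stop("no scored overlaps in the data", call. = FALSE)
  yp <- pmin(pmax(tr$y_predicted[sc], 1e-12), 1 - 1e-12)
  ll <- sum(log(ifelse(tr$y[sc] == 1, yp, 1 - yp)))
  lp <- 0
  for (nm in names(log_params)) {
    pr <- priors[[nm]]
    lp <- lp + stats::dnorm(log_params[[nm]], pr$mean, sqrt(pr$var),
                            log = TRUE)
  }
  -(ll + lp)
}

#' Negative log-joint of a behavioural model variant
#'
#' The objective minimised during inversion: minus the sum of the Bernoulli
#' log-likelihood of the observed decisions under the predicted response
#' probabilities (from the deterministic belief trajectory,
#' [filter_responses()]) over all scored overlaps, and the Gaussian
#' log-priors of the enabled log-parameters.
#'
#' @param log_params Named vector/list of log-parameters (subset of
#'   `pi_init`, `pi_stereo`, `zeta` enabled by the variant).
#' @param responses,session Aligned response series and session.
#' @param variant A [variant_spec()].
#' @param priors A [prior_spec()].
#' @return Scalar negative log-joint (nats).
#' @export
neg_log_joint <- function(log_params, responses, session, variant, priors) {
  .nlj_from_aligned(as.list(log_params), .align_data(responses, session),
                    variant, priors)
}

# Generic multi-start BFGS MAP + finite-difference Hessian + Laplace
# evidence over a negative log-joint in R^d. Used by both the behavioural
# variants and the rival models so evidences are directly comparable.
.map_laplace <- function(nlj, starts, prior_means, prior_sds,
                         hess_step = 1e-4, reltol = 1e-10, maxit = 500) {
  d <- length(prior_means)
  if (d == 0) {
    v <- nlj(numeric(0))
    return(list(map = numeric(0), value = v, log_evidence = -v,
                hessian = matrix(0, 0, 0), pd_adjusted = FALSE,
                convergence = 0L))
  }
  f_safe <- function(x) {
    v <- tryCatch(nlj(x), error = function(e) Inf)
    if (!is.finite(v)) .Machine$double.xmax / 2 else v
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[s, ], f_safe, method = "BFGS",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  x <- best$par
  # central finite-difference Hessian
  h <- hess_step
  H <- matrix(NA_real_, d, d)
  f0 <- best$value
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (f_safe(x + ei) - 2 * f0 + f_safe(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (f_safe(x + ei + ej) - f_safe(x + ei - ej) -
             f_safe(x - ei + ej) + f_safe(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  pd_adjusted <- FALSE
  if (any(ev <= 0)) {
    # nearest positive-definite correction: floor the eigenvalues
    e <- eigen(H, symmetric = TRUE)
    lam <- pmax(e$values, 1e-6)
    H <- e$vectors %*% diag(lam, d) %*% t(e$vectors)
    ev <- lam
    pd_adjusted <- TRUE
  }
  log_evidence <- -f0 + d / 2 * log(2 * pi) - 0.5 * sum(log(ev))
  list(map = x, value = f0, log_evidence = log_evidence, hessian = H,
       pd_adjusted = pd_adjusted, convergence = best$convergence)
}

# draw multi-start matrix: first row at the prior means, the rest sampled
# from the priors
.draw_starts <- function(n_starts, prior_means, prior_sds, seed = NULL) {
  d <- length(prior_means)
  if (d == 0) return(matrix(0, 1, 0))
  if (!is.null(seed)) set.seed(seed)
  n_starts <- max(1L, n_starts)
  st <- matrix(0, n_starts, d)
  st[1, ] <- prior_means
  if (n_starts > 1)
    for (s in 2:n_starts)
      st[s, ] <- stats::rnorm(d, prior_means, prior_sds)
  st
}

#' MAP inversion of a behavioural model variant
#'
#' Multi-start quasi-Newton (BFGS) minimisation of [neg_log_joint()] in
#' log-parameter space; the first start sits at the prior means, the
#' remaining starts are drawn from the priors. Deterministic given `seed`.
#'
#' @param responses,session Aligned response series and session (one run
#'   or several; runs are typically fitted separately, see
#'   [fit_subject()]).
#' @param variant A [variant_spec()] (or id 1-4).
#' @param priors A [prior_spec()].
#' @param n_starts Number of optimisation starts (default 8).
#' @param seed Seed for the start sampler.
#' @return An object of class `pc_fit`: `map_log_params` (named),
#'   `params` (a [model_params()] at the MAP), `neg_log_joint`,
#'   `log_evidence` (Laplace, nats), `hessian`
#'   (log-space, finite-difference), `pd_adjusted` flag, `convergence`,
#'   `variant` and the MAP `trajectory`.
#' @export
fit_map <- function(responses, session, variant, priors = prior_spec(),
                    n_starts = 8, seed = NULL) {
  if (is.numeric(variant)) variant <- variant_spec(variant)
  nm <- .free_names(variant, priors)
  aligned <- .align_data(responses, session)
  nlj <- function(x) {
    .nlj_from_aligned(stats::setNames(as.list(x), nm), aligned, variant,
                      priors)
  }
  pm <- vapply(nm, function(p) priors[[p]]$mean, 1)
  ps <- vapply(nm, function(p) sqrt(priors[[p]]$var), 1)
  starts <- .draw_starts(n_starts, pm, ps, seed)
  res <- .map_laplace(nlj, starts, pm, ps)
  map <- stats::setNames(res$map, nm)
  par <- .variant_params(as.list(map), variant, priors)
  traj <- filter_responses(responses, session, par)
  structure(list(map_log_params = map, params = par,
                 neg_log_joint = res$value,
                 log_evidence = res$log_evidence,
                 hessian = res$hessian, pd_adjusted = res$pd_adjusted,
                 convergence = res$convergence,
                 variant = variant, trajectory = traj),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("Variant %d fit: log-evidence %.2f nats\n",
              x$variant$id, x$log_evidence))
  if (length(x$map_log_params))
    print(round(exp(x$map_log_params), 3))
  invisible(x)
}

#' Laplace approximation to the log model evidence
#'
#' Approximates the log marginal likelihood around the MAP estimate:
#' \deqn{\log Z \approx -E(\hat\theta) + \frac{d}{2}\log 2\pi
#'   - \frac{1}{2}\log \det H,}
#' where `E` is the negative log-joint, `d` the number of free parameters
#' and `H` the Hessian of `E` at the MAP (finite differences in log
#' space). For `d = 0` the evidence equals minus the negative log-joint
#' exactly. A non-positive-definite Hessian is floored to the nearest
#' positive-definite matrix and flagged.
#'
#' @param fit A `pc_fit` from [fit_map()] (the evidence is computed during
#'   fitting; this accessor re-derives it from the stored Hessian).
#' @return Log evidence in nats.
#' @export
laplace_evidence <- function(fit) {
  d <- length(fit$map_log_params)
  if (d == 0) return(-fit$neg_log_joint)
  -fit$neg_log_joint + d / 2 * log(2 * pi) -
    0.5 * determinant(fit$hessian, logarithm = TRUE)$modulus[1]
}

#' Fit all model variants to one subject
#'
#' Runs are fitted independently and their log evidences summed per
#' variant; parameter point estimates are summarised as geometric means
#' across runs (arithmetic means in log space).
#'
#' @param subject A `pc_subject` (or list with `responses` and `session`).
#' @param variants Variant ids to fit (default 1:4).
#' @param priors A [prior_spec()].
#' @param n_starts,seed Passed to [fit_map()].
#' @return List with `log_evidence` (named vector per variant), `fits`
#'   (variant x run list), and `params` (geometric-mean parameter summary
#'   per variant).
#' @export
fit_subject <- function(subject, variants = 1:4, priors = prior_spec(),
                        n_starts = 8, seed = NULL) {
  responses <- subject$responses
  session <- subject$session
  runs <- sort(unique(responses$run))
  le <- stats::setNames(numeric(length(variants)),
                        paste0("variant", variants))
  fits <- list()
  params <- list()
  for (vi in seq_along(variants)) {
    v <- variant_spec(variants[vi])
    run_fits <- lapply(runs, function(r) {
      idx <- responses$run == r
      ses_r <- session
      ses_r$overlaps <- session$overlaps[session$overlaps$run == r, ]
      fit_map(responses[idx, ], ses_r, v, priors, n_starts = n_starts,
              seed = seed)
    })
    le[vi] <- sum(vapply(run_fits, `[[`, 1, "log_evidence"))
    nm <- .free_names(v, priors)
    params[[paste0("variant", variants[vi])]] <- if (length(nm)) {
      lp <- rowMeans(matrix(vapply(run_fits, function(f) f$map_log_params[nm],
                                   numeric(length(nm))),
                            nrow = length(nm)))
      stats::setNames(exp(lp), nm)
    } else numeric(0)
    fits[[paste0("variant", variants[vi])]] <- run_fits
  }
  list(log_evidence = le, fits = fits, params = params)
}

#' Fit a cohort: subjects x variants log-evidence matrix
#'
#' Applies [fit_subject()] to every subject, assembling the
#' subjects-by-models log-evidence matrix consumed by random-effects model
#' selection, plus per-subject geometric-mean parameter estimates. A
#' failing fit is flagged (`NA` row entries) and the cohort continues.
#'
#' @param cohort A `pc_cohort` (or plain list of `pc_subject`s).
#' @param variants Variant ids (default 1:4).
#' @param priors,n_starts,seed Passed down to [fit_map()].
#' @param progress Print a line per subject.
#' @return List with `evidence` (matrix), `params` (list per subject) and
#'   `errors` (character, one per failed fit).
#' @export
fit_cohort <- function(cohort, variants = 1:4, priors = prior_spec(),
                       n_starts = 8, seed = NULL, progress = FALSE) {
  subjects <- if (inherits(cohort, "pc_cohort")) cohort$subjects else cohort
  n <- length(subjects)
  if (n < 1) stop("need at least one subject", call. = FALSE)
  L <- matrix(NA_real_, n, length(variants),
              dimnames = list(paste0("subject", seq_len(n)),
                              paste0("variant", variants)))
  params <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(fit_subject(subjects[[i]], variants, priors,
                                n_starts = n_starts, seed = seed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("subject %d: %s", i, conditionMessage(res)))
    } else {
      L[i, ] <- res$log_evidence
      params[[i]] <- res$params
    }
    if (progress)
      message(sprintf("fitted subject %d/%d", i, n))
  }
  list(evidence = L, params = params, errors = errors)
}

#' Read/write a subjects-by-models log-evidence matrix as TSV
#'
#' @param evidence Numeric matrix (subjects x models).
#' @param path File path.
#' @name evidence_io
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(as.data.frame(evidence), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname evidence_io
#' @export
read_evidence <- function(path) {
  as.matrix(utils::read.delim(path))
}
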