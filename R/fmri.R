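#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: difference of two gamma densities with response
#' delay 6 s, undershoot delay 16 s, unit dispersions, response/undershoot
#' ratio 6, and 32 s support. The kernel is normalised to unit peak, so a
#' unit-amplitude stick event produces a regressor peaking at 1.
#'
#' @param dt Sampling interval of the kernel in seconds.
#' @param length_s Kernel support in seconds (default 32).
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...`.
#' @examples
#' k <- hrf_kernel(0.1)
#' (which.max(k) - 1) * 0.1   # peak close to 5 s
#' @export
hrf_kernel <- function(dt, length_s = 32) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build event lists for the three fMRI design variants
#'
#' Extracts, from a session and its belief trajectory, the stick events
#' and parametric modulators of one of the three design-matrix variants:
#'
#' * `"PE"` — sticks for all overlaps and all transitions, plus the
#'   absolute prediction error as a parametric modulator on the overlap
#'   sticks;
#' * `"Conventional"` — overlap sticks plus transition sticks split into
#'   ambiguous and replay transitions (no modulator);
#' * `"Block"` — overlap and transition sticks plus an ambiguity
#'   indicator (1 ambiguous, 0 replay) as the overlap modulator.
#'
#' Transitions are overlaps at which the reported percept differs from the
#' previous report within the same block.
#'
#' @param session A [build_session()] object (one run: subset the overlap
#'   table first, or use [subject_designs()]).
#' @param trajectory Trajectory from [filter_responses()], aligned to the
#'   session overlaps (supplies decisions and prediction errors).
#' @param model_kind `"PE"`, `"Conventional"` or `"Block"`.
#' @return An object of class `pc_events`: list of regressors, each with
#'   `onsets` (s) and `weights` (modulator values; all 1 for plain
#'   sticks), plus `model_kind`.
#' @export
build_events <- function(session, trajectory, model_kind) {
  model_kind <- match.arg(model_kind, c("PE", "Conventional", "Block"))
  ov <- session$overlaps
  if (nrow(ov) != nrow(trajectory) ||
      !all(abs(ov$time_s - trajectory$time_s) < 1e-9))
    stop("trajectory is not aligned to the session overlaps", call. = FALSE)
  block <- interaction(ov$run, ov$block, drop = TRUE)
  y <- trajectory$y
  prev_y <- c(NA, y[-length(y)])
  same_block <- c(FALSE, block[-1] == block[-length(block)])
  is_trans <- same_block & !is.na(prev_y) & y != prev_y
  t_ov <- ov$time_s
  regs <- list(overlaps = list(onsets = t_ov,
                               weights = rep(1, length(t_ov))))
  if (model_kind == "Conventional") {
    regs$transitions_ambiguous <- list(
      onsets = t_ov[is_trans & ov$condition == "ambiguous"], weights = NULL)
    regs$transitions_replay <- list(
      onsets = t_ov[is_trans & ov$condition == "replay"], weights = NULL)
  } else {
    regs$transitions <- list(onsets = t_ov[is_trans], weights = NULL)
  }
  for (nm in names(regs))
    if (is.null(regs[[nm]]$weights))
      regs[[nm]]$weights <- rep(1, length(regs[[nm]]$onsets))
  if (model_kind == "PE")
    regs$overlaps_x_pe <- list(onsets = t_ov, weights = abs(trajectory$pe))
  if (model_kind == "Block")
    regs$overlaps_x_ambiguity <- list(
      onsets = t_ov, weights = as.numeric(ov$condition == "ambiguous"))
  structure(list(regressors = regs, model_kind = model_kind),
            class = "pc_events")
}

#' Discrete-cosine high-pass basis
#'
#' The drift basis used for high-pass filtering: cosine regressors up to
#' the cutoff period (default 128 s, i.e. a 1/128 Hz high-pass).
#'
#' @param n_scans Number of scans.
#' @param TR Repetition time in seconds.
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return Matrix `n_scans x K` (K may be 0 for short runs).
#' @export
dct_basis <- function(n_scans, TR, cutoff_s = 128) {
  K <- floor(2 * n_scans * TR / cutoff_s)
  i <- 0:(n_scans - 1)
  X <- vapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * i + 1) * k / (2 * n_scans)),
    numeric(n_scans))
  matrix(X, nrow = n_scans)
}

# residual-forming projection of the DCT drift space
.hp_project <- function(M, dct) {
  if (is.null(dct) || ncol(dct) == 0) return(M)
  M - dct %*% crossprod(dct, M)
}

#' Build a design matrix from an event list
#'
#' Events are placed as weighted sticks on a fine time grid (16 bins per
#' TR), convolved with the canonical HRF, and sampled at scan acquisition
#' times. Parametric modulators are mean-centred before convolution (so
#' the modulated regressor is orthogonal to the stick in expectation, but
#' no further serial orthogonalisation is applied: each model is compared
#' with its stated regressors). A constant column is appended, and the
#' discrete-cosine high-pass basis (1/128 Hz) is attached for projection
#' at fit time.
#'
#' @param events A [build_events()] object.
#' @param TR Repetition time in seconds (default 2).
#' @param n_scans Number of scans.
#' @param highpass_s High-pass cutoff period (default 128 s; `NULL`
#'   disables).
#' @param nuisance Optional matrix of nuisance covariates
#'   (`n_scans` rows), e.g. synthetic realignment parameters.
#' @param center_modulators Mean-centre modulator weights (default TRUE).
#' @param fine_per_TR Fine-grid bins per TR for convolution (default 16).
#' @return An object of class `pc_design`: `X` (scans x regressors, named
#'   columns), `TR`, `dct` (high-pass basis), `model_kind`.
#' @export
build_design <- function(events, TR = 2, n_scans, highpass_s = 128,
                         nuisance = NULL, center_modulators = TRUE,
                         fine_per_TR = 16) {
  res <- TR / fine_per_TR
  horizon <- n_scans * TR
  n_fine <- ceiling(horizon / res) + 1
  h <- hrf_kernel(res)
  scan_idx <- round((0:(n_scans - 1)) * TR / res) + 1
  cols <- list()
  for (nm in names(events$regressors)) {
    reg <- events$regressors[[nm]]
    w <- reg$weights
    modulator <- startsWith(nm, "overlaps_x_")
    if (modulator && center_modulators && length(w) > 0)
      w <- w - mean(w)
    keep <- reg$onsets < horizon
    if (any(!keep))
      warning("events beyond the scan horizon truncated for '", nm, "'",
              call. = FALSE)
    fine <- numeric(n_fine)
    idx <- round(reg$onsets[keep] / res) + 1
    for (j in seq_along(idx))
      fine[idx[j]] <- fine[idx[j]] + w[keep][j]
    conv <- stats::convolve(fine, rev(h), type = "open")[seq_len(n_fine)]
    cols[[nm]] <- conv[scan_idx]
  }
  X <- do.call(cbind, cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans)
      stop("'nuisance' must have n_scans rows", call. = FALSE)
    colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, constant = 1)
  dct <- if (is.null(highpass_s)) NULL else dct_basis(n_scans, TR, highpass_s)
  structure(list(X = X, TR = TR, n_scans = n_scans, dct = dct,
                 model_kind = events$model_kind),
            class = "pc_design")
}

#' The three design matrices for one subject run
#'
#' Convenience wrapper: filters the subject's responses at given
#' parameters, builds the PE, Conventional and Block event lists for one
#' run, and returns the three design matrices.
#'
#' @param subject A `pc_subject`.
#' @param params Parameters for the belief trajectory (default: the
#'   subject's ground truth).
#' @param run Which run (default 1).
#' @param TR,n_scans,highpass_s Passed to [build_design()]. Defaults:
#'   TR 2 s; `n_scans` 415 for the 0.24 Hz design, else 402.
#' @return Named list of three `pc_design` objects.
#' @export
subject_designs <- function(subject, params = subject$true_params, run = 1,
                            TR = 2, n_scans = NULL, highpass_s = 128) {
  if (is.null(n_scans))
    n_scans <- if (subject$session$overlap_frequency_hz == 0.24) 415L
               else 402L
  ses <- subject$session
  keep <- ses$overlaps$run == run
  ses$overlaps <- ses$overlaps[keep, ]
  traj <- filter_responses(subject$responses[keep, ], ses, params)
  out <- lapply(c(PE = "PE", Conventional = "Conventional", Block = "Block"),
                function(kind)
                  build_design(build_events(ses, traj, kind), TR = TR,
                               n_scans = n_scans, highpass_s = highpass_s))
  out
}

#' Simulate voxel time-series from a design
#'
#' Linear mixture of the design's task regressors (all columns except the
#' constant) with white Gaussian noise:
#' `Y = betas X' + noise`. Used to create synthetic voxel populations
#' whose generating model is known.
#'
#' @param design A `pc_design`.
#' @param betas Vector of regression weights (length = number of task
#'   regressors), or a `n_voxels x p` matrix for voxel-specific weights.
#' @param noise_sd White-noise standard deviation.
#' @param n_voxels Number of voxels.
#' @param seed Integer seed.
#' @return Matrix `n_voxels x n_scans`.
#' @export
simulate_bold <- function(design, betas, noise_sd, n_voxels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- design$X[, colnames(design$X) != "constant", drop = FALSE]
  B <- if (is.matrix(betas)) betas
       else matrix(betas, n_voxels, ncol(X), byrow = TRUE)
  if (ncol(B) != ncol(X))
    stop("betas must match the ", ncol(X), " task regressors", call. = FALSE)
  B %*% t(X) + noise_sd * matrix(stats::rnorm(n_voxels * design$n_scans),
                                 n_voxels, design$n_scans)
}

#' Voxel-wise GLM with a t-contrast
#'
#' Ordinary least squares per voxel after projecting the high-pass drift
#' basis out of both the data and the design, with
#' `t = c' beta_hat / se(c' beta_hat)`.
#'
#' @param Y Data matrix, voxels x scans.
#' @param design A `pc_design`.
#' @param contrast Numeric contrast vector over design columns (recycled
#'   names checked against `colnames(X)` when named).
#' @return List with `betas` (voxels x p), `t` (vector), `df`.
#' @export
glm_contrast <- function(Y, design, contrast) {
  X <- .hp_project(design$X, design$dct)
  Yt <- t(.hp_project(t(Y), design$dct))
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design is rank deficient after filtering; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qx))
  B <- Yt %*% X %*% XtXinv                       # voxels x p
  fitted <- B %*% t(X)
  res <- Yt - fitted
  df <- nrow(X) - p - if (is.null(design$dct)) 0 else ncol(design$dct)
  sigma2 <- rowSums(res^2) / df
  cvec <- rep_len(contrast, p)
  se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
  list(betas = B, t = drop(B %*% cvec) / se, df = df)
}

#' Voxel-wise log model evidence (Bayesian linear model)
#'
#' Closed-form marginal likelihood of a conjugate Bayesian linear model:
#' after high-pass projection, each voxel's time-series is standardised
#' and the task regressors are standardised; the regression weights carry
#' a zero-mean unit-variance Gaussian prior (identical scale across
#' compared models, so evidences are comparable) and the noise is unit
#' Gaussian, giving
#' \deqn{y \sim N(0, I_n + X X').}
#' The log density is evaluated via the Woodbury identity. Larger models
#' pay the usual Occam penalty through the determinant term.
#'
#' @param Y Data matrix, voxels x scans.
#' @param design A `pc_design`.
#' @return Vector of log evidences (nats), one per voxel.
#' @export
voxel_evidence <- function(Y, design) {
  X <- .hp_project(design$X, design$dct)
  X <- X[, colnames(design$X) != "constant", drop = FALSE]
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0))
    stop("constant task regressor after filtering", call. = FALSE)
  Xs <- scale(X)
  n <- nrow(Xs); p <- ncol(Xs)
  Yt <- .hp_project(t(Y), design$dct)           # scans x voxels
  Ys <- scale(Yt)                               # standardise each voxel
  Ys[, attr(Ys, "scaled:scale") == 0] <- 0      # flat voxels carry no signal
  M <- diag(p) + crossprod(Xs)
  cM <- chol(M)
  logdet <- 2 * sum(log(diag(cM)))
  XtY <- crossprod(Xs, Ys)                      # p x voxels
  w <- backsolve(cM, forwardsolve(t(cM), XtY))  # M^{-1} X' y
  quad <- colSums(Ys^2) - colSums(XtY * w)
  -n / 2 * log(2 * pi) - 0.5 * logdet - 0.5 * quad
}

#' Group-level voxel-wise exceedance maps
#'
#' Stacks per-subject voxel evidence maps (voxels x models), runs
#' random-effects model selection per voxel, and returns the per-model
#' exceedance probabilities together with the winning model per voxel.
#'
#' @param evidence_maps List over subjects of voxels-x-models matrices
#'   (identical dimensions and model order).
#' @param n_samples Dirichlet samples per voxel for the exceedance
#'   estimate (default 2e4).
#' @param seed Integer seed.
#' @return List with `xp` (voxels x models matrix), `winner` (index of
#'   the max-exceedance model per voxel), `expected_freq`.
#' @export
group_epm <- function(evidence_maps, n_samples = 2e4, seed = NULL) {
  dims <- unique(lapply(evidence_maps, dim))
  if (length(dims) != 1)
    stop("all subjects must share the same voxel grid and model set",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nv <- dims[[1]][1]; K <- dims[[1]][2]
  xp <- ef <- matrix(NA_real_, nv, K)
  for (v in seq_len(nv)) {
    L <- t(vapply(evidence_maps, function(m) m[v, ], numeric(K)))
    b <- rfx_bms(L)
    xp[v, ] <- exceedance_prob(b$alpha, n_samples = n_samples)
    ef[v, ] <- b$expected_freq
  }
  colnames(xp) <- colnames(ef) <- colnames(evidence_maps[[1]])
  list(xp = xp, winner = max.col(xp, ties.method = "first"),
       expected_freq = ef)
}

#' Threshold an exceedance map
#'
#' Display-convention utility: marks voxels whose exceedance probability
#' passes a threshold (default 0.99) and, when a grid dimension is given,
#' removes connected clusters of fewer than `cluster_min` voxels
#' (6-connectivity on a 3-D grid, 2-connectivity in 1-D).
#'
#' @param xp Vector of exceedance probabilities (one model).
#' @param gamma Threshold (default 0.99).
#' @param dim Optional integer vector giving the voxel grid dimensions
#'   (`prod(dim) == length(xp)`).
#' @param cluster_min Minimum cluster size kept (default 10; only applied
#'   when `dim` is given).
#' @return Logical vector of surviving voxels.
#' @export
epm_threshold <- function(xp, gamma = 0.99, dim = NULL, cluster_min = 10) {
  pass <- xp > gamma
  if (is.null(dim)) return(pass)
  if (prod(dim) != length(xp))
    stop("'dim' does not match the number of voxels", call. = FALSE)
  arr <- array(pass, dim = dim)
  lab <- array(0L, dim = dim)
  nd <- length(dim)
  cur <- 0L
  coords <- which(arr, arr.ind = TRUE)
  coords <- matrix(coords, ncol = nd)
  # flood fill over the face-neighbour graph
  for (s in seq_len(nrow(coords))) {
    start <- coords[s, ]
    if (lab[matrix(start, 1)] != 0L) next
    cur <- cur + 1L
    queue <- list(start)
    lab[matrix(start, 1)] <- cur
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nd)) for (step in c(-1L, 1L)) {
        c1 <- c0; c1[d] <- c1[d] + step
        if (c1[d] < 1 || c1[d] > dim[d]) next
        i1 <- matrix(c1, 1)
        if (arr[i1] && lab[i1] == 0L) {
          lab[i1] <- cur
          queue[[length(queue) + 1L]] <- c1
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  keep_lab <- which(sizes >= cluster_min)
  as.vector(arr & array(lab %in% keep_lab, dim = dim))
}

#' Epoch-average a signal around events
#'
#' Averages a regularly sampled signal across epochs aligned to event
#' times, linearly interpolating at the requested lags. Used to
#' visualise the pre-transition build-up of prediction-error-related
#' signal.
#'
#' @param signal Numeric vector sampled every `TR` seconds (first sample
#'   at t = 0).
#' @param event_times Event times in seconds (e.g. perceptual
#'   transitions).
#' @param TR Sampling interval of `signal`.
#' @param lags_s Lags (seconds, relative to each event) at which to read
#'   the signal; negative = before the event.
#' @return Named vector: mean signal at each lag across events.
#' @export
epoch_average <- function(signal, event_times, TR, lags_s) {
  t_grid <- (seq_along(signal) - 1) * TR
  out <- vapply(lags_s, function(l) {
    at <- event_times + l
    at <- at[at >= 0 & at <= max(t_grid)]
    if (!length(at)) return(NA_real_)
    mean(stats::approx(t_grid, signal, xout = at)$y)
  }, numeric(1))
  stats::setNames(out, paste0("lag", lags_s))
}
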