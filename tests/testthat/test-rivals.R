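test_that("the oscillator needs inhibition and adaptation to alternate", {
  # zero inhibition: populations decouple and settle; no alternations
  tr0 <- simulate_oscillator(oscillator_params(inhibition = 0), 300,
                             dt = 0.05)
  expect_lte(length(phase_durations(as.numeric(tr0$state > 0), 0.05)), 2)
  late <- tr0$state[5000:6000]
  expect_lt(diff(range(late)), 1e-6)
  # canonical regime: deterministic relaxation oscillation, CV about 0
  tr <- simulate_oscillator(oscillator_params(), 400, dt = 0.05)
  d <- phase_durations(as.numeric(tr$state > 0), 0.05)
  expect_gt(length(d), 10)
  expect_lt(stats::sd(d) / mean(d), 0.05)
  expect_error(simulate_oscillator(oscillator_params(), 100, dt = 3),
               "small")
})

test_that("stronger adaptation shortens oscillator dominance phases", {
  means <- vapply(c(1.2, 1.6, 2.0), function(phi) {
    tr <- simulate_oscillator(oscillator_params(adapt_strength = phi),
                              400, dt = 0.05)
    mean(phase_durations(as.numeric(tr$state > 0), 0.05))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the attractor needs noise to escape and feels the barrier", {
  tr0 <- simulate_attractor(attractor_params(noise = 0), 200, dt = 0.05,
                            seed = 1)
  expect_true(all(tr0$state > 0))            # stays in its well
  means <- vapply(c(0.7, 1.3), function(h) {
    tr <- simulate_attractor(attractor_params(barrier = h), 3000,
                             dt = 0.05, seed = 2)
    # read percepts on a coarse grid to suppress crossing chatter
    y <- rival_percepts(tr, seq(1, 3000, by = 1))
    mean(phase_durations(y, 1))
  }, numeric(1))
  expect_gt(means[2], means[1])              # higher barrier, longer phases
})

test_that("attractor escape times are approximately exponential", {
  tr <- simulate_attractor(attractor_params(), 6000, dt = 0.05, seed = 3)
  y <- rival_percepts(tr, seq(1, 6000, by = 1))
  d <- phase_durations(y, 1)
  expect_gt(length(d), 100)
  # exponential signature: CV near 1 (grid-censored, so allow slack)
  expect_gt(stats::sd(d) / mean(d), 0.7)
  expect_lt(stats::sd(d) / mean(d), 1.4)
})

test_that("the intermediate model nests the oscillator and adds noise", {
  p0 <- oscillator_params(noise = 0)
  a <- simulate_oscillator(p0, 100, dt = 0.05, seed = 4)
  b <- simulate_intermediate(p0, 100, dt = 0.05, seed = 4)
  expect_identical(a$state, b$state)         # zero-noise limit is exact
  ti <- simulate_intermediate(oscillator_params(noise = 0.3), 2000,
                              dt = 0.05, seed = 5)
  d <- phase_durations(as.numeric(ti$state > 0), 0.05)
  cv <- stats::sd(d) / mean(d)
  expect_gt(cv, 0.1)                         # noisier than the pure oscillator
  expect_lt(cv, 1.0)                         # more regular than pure noise
})

test_that("rival duration distributions are right-skewed and gamma-like", {
  ti <- simulate_intermediate(oscillator_params(noise = 0.3), 3000,
                              dt = 0.05, seed = 6)
  st <- duration_stats(phase_durations(as.numeric(ti$state > 0), 0.05))
  expect_gt(st$gamma_shape, 1)
})

test_that("rival fitting scores data with the shared likelihood machinery", {
  # subjects whose reports follow an oscillator read out at overlap times
  ses <- build_session(0.30, runs = 1, pairs_per_run = 4)
  make_osc_subject <- function(seed) {
    tr <- simulate_oscillator(oscillator_params(noise = 0.15), 500,
                              dt = 0.05, seed = seed)
    resp <- ses$overlaps[c("run", "block", "overlap_index", "time_s",
                           "condition")]
    resp$response <- rival_percepts(tr, ses$overlaps$time_s + 30)
    resp
  }
  ses$overlaps$mu_stereo[ses$overlaps$condition == "replay"] <- 0.5
  le <- vapply(1:3, function(i) {
    resp <- make_osc_subject(i)
    f_osc <- fit_rival("oscillator", resp, ses, n_starts = 2, seed = i)
    f_att <- fit_rival("attractor", resp, ses, n_starts = 2, seed = i)
    expect_true(is.finite(f_osc$log_evidence))
    expect_true(is.finite(f_att$log_evidence))
    c(osc = f_osc$log_evidence, att = f_att$log_evidence)
  }, numeric(2))
  # summed over subjects, the generating class wins
  expect_gt(sum(le["osc", ]), sum(le["att", ]))
})

test_that("constant responses are best served by a frozen rival", {
  ses <- build_session(0.30, runs = 1, pairs_per_run = 2)
  ses$overlaps$mu_stereo[ses$overlaps$condition == "replay"] <- 1
  resp <- ses$overlaps[c("run", "block", "overlap_index", "time_s",
                         "condition")]
  resp$response <- 1
  f <- fit_rival("attractor", resp, ses, n_starts = 2, seed = 1)
  # MAP noise shrinks: the model freezes into one well
  expect_lt(exp(f$map_log_params["log_noise"]), 0.75)
  expect_true(is.finite(f$log_evidence))
})
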