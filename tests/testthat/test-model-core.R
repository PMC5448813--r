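test_that("parameter and state validation rejects invalid values", {
  expect_error(model_params(pi_init = -1), "non-negative")
  expect_error(model_params(zeta = 0), "zeta")
  expect_error(model_params(pi_init = NA), "finite")
  expect_error(perceptual_state(2, 1), "0 .*or 1")
  expect_error(perceptual_state(1, -0.5), "non-negative")
})

test_that("combine_prior is precision-weighted Gaussian fusion", {
  # stability only: single-component product
  jp <- combine_prior(perceptual_state(1, 3.5), 0.5,
                      model_params(3.5, 0, 1))
  expect_equal(jp$mu_m, 1.0)
  expect_equal(jp$pi_m, 3.5)
  # symmetric precisions pull the mean to the midpoint
  jp <- combine_prior(perceptual_state(1, 2), 0, model_params(3.5, 2, 1))
  expect_equal(jp$mu_m, 0.5)
  expect_equal(jp$pi_m, 4.0)
  # general case against the numeric Gaussian-product oracle
  jp <- combine_prior(perceptual_state(0, 3), 1, model_params(3.5, 1, 1))
  ora <- gaussian_product_numeric(0, 3, 1, 1)
  expect_equal(jp$mu_m, ora$mu, tolerance = 1e-6)
  expect_equal(jp$pi_m, ora$pi, tolerance = 1e-4)
  expect_equal(jp$mu_m, 0.25)
  expect_equal(jp$pi_m, 4.0)
  # flat joint prior falls back to the midpoint
  jp <- combine_prior(perceptual_state(0, 0), 1, model_params(0, 0, 1))
  expect_equal(jp$mu_m, 0.5)
  expect_equal(jp$pi_m, 0)
})

test_that("posterior weight matches the numeric mixture-posterior oracle", {
  for (mu_m in c(0.1, 0.25, 0.5, 0.8, 1.0)) {
    for (pi_m in c(0, 0.5, 2, 3.5, 8)) {
      expect_equal(posterior_ccw(mu_m, pi_m),
                   posterior_ccw_numeric(mu_m, pi_m),
                   tolerance = 1e-4,
                   label = sprintf("p_ccw(mu=%g, pi=%g)", mu_m, pi_m))
    }
  }
  expect_equal(posterior_ccw(0.5, 7), 0.5)
  expect_equal(posterior_ccw(0.9, 0), 0.5)
  expect_error(posterior_ccw(Inf, 1), "finite")
})

test_that("response model is a unit-square sigmoid with fixed point 0.5", {
  expect_equal(response_probability(0.73, 1), 0.73)
  expect_equal(response_probability(0.5, 7.3), 0.5)
  expect_equal(response_probability(0.8, 2), 0.64 / (0.64 + 0.04))
  expect_error(response_probability(0.8, 0), "positive")
  expect_error(response_probability(1.2, 1), "inside")
  # stays inside (0,1) even for extreme zeta
  expect_true(response_probability(0.99, 20) < 1)
  expect_true(response_probability(0.01, 20) > 0)
})

test_that("prediction error is the residual posterior mass", {
  expect_equal(prediction_error(1, 0.8), 0.2)
  expect_equal(prediction_error(0, 0.8), 0.8)
  eps <- 1e-6
  expect_equal(prediction_error(1, 1 - eps), eps)
  expect_error(prediction_error(2, 0.5), "0 or 1")
})

test_that("state update resets on transition, accumulates PE otherwise", {
  p <- model_params(3.5, 0, 1)
  st <- update_state(perceptual_state(0, 1.2), 1, 0.3, p)
  expect_equal(st$mu_stability, 1)
  expect_equal(st$pi_stability, 3.5)   # reset to pi_init on a transition
  st <- update_state(perceptual_state(1, 3.5), 1, 0, p)
  expect_equal(st$pi_stability, 3.5)   # zero error is a no-op
  st <- update_state(perceptual_state(1, 3.5), 1, 0.148, p)
  expect_equal(st$pi_stability, 1 / (1 / 3.5 + 0.148), tolerance = 1e-12)
})

test_that("step_overlap composes the closed forms and enforces contracts", {
  p <- model_params(3.5, 0, 1)
  # fresh state after a transition, ambiguous input
  out <- step_overlap(perceptual_state(1, 3.5), 0.5, p, decision = 1)
  expect_equal(out$record$p_ccw, plogis(3.5 / 2))
  expect_equal(out$record$y_predicted, out$record$p_ccw)  # zeta = 1
  expect_equal(out$record$pe, 1 - plogis(3.5 / 2))
  # observed stay: variance grows
  expect_lt(out$state$pi_stability, 3.5)
  # overwhelming opposing disparity forces a transition
  p2 <- model_params(3.5, 1e6, 1)
  out2 <- step_overlap(perceptual_state(1, 3.5), 0, p2)
  expect_equal(out2$record$y, 0)
  expect_error(step_overlap(perceptual_state(1, 3.5), 0.5, p, decision = 2),
               "0 or 1")
})

test_that("label symmetry: relabelling percepts mirrors the trajectory", {
  s <- small_subject(seed = 11)
  par <- model_params(3, 4, 1)
  tr1 <- filter_responses(s$responses, s$session, par)
  # flip responses and replay disparities
  s2 <- s
  s2$responses$response <- 1 - s2$responses$response
  repl <- s2$session$overlaps$condition == "replay"
  s2$session$overlaps$mu_stereo[repl] <- 1 - s2$session$overlaps$mu_stereo[repl]
  tr2 <- filter_responses(s2$responses, s2$session, par)
  expect_equal(tr2$p_ccw, 1 - tr1$p_ccw, tolerance = 1e-12)
  expect_equal(tr2$pe, tr1$pe, tolerance = 1e-12)
  expect_equal(tr2$pi_stability, tr1$pi_stability, tolerance = 1e-12)
})

test_that("within an ambiguous dominance phase pe rises and precision falls", {
  ses <- build_session(0.30, runs = 1, pairs_per_run = 1)
  n <- nrow(ses$overlaps)
  resp <- ses$overlaps[c("run", "block", "overlap_index", "time_s",
                         "condition")]
  resp$response <- rep(1, n)                      # constant percept
  amb <- ses$overlaps$condition == "ambiguous"
  ses$overlaps$mu_stereo[!amb] <- 1
  tr <- filter_responses(resp, ses, model_params(3.5, 0, 1))
  pe_amb <- tr$pe[amb][-1]              # first overlap has no stability prior
  expect_true(all(diff(pe_amb) > 0))              # strictly increasing
  expect_true(all(pe_amb < 0.5))
  pi_amb <- tr$pi_stability[amb]
  expect_true(all(diff(pi_amb[-1]) < 0))          # strictly decreasing
  expect_true(all(tr$p_ccw > 0 & tr$p_ccw < 1))
  expect_true(all(tr$pe >= 0 & tr$pe <= 1))
})

test_that("alternating reports give a constant transition-sized error", {
  ses <- build_session(0.30, runs = 1, pairs_per_run = 1)
  amb_rows <- ses$overlaps$condition == "ambiguous"
  ses$overlaps <- ses$overlaps[amb_rows, ]
  n <- nrow(ses$overlaps)
  resp <- ses$overlaps[c("run", "block", "overlap_index", "time_s",
                         "condition")]
  resp$response <- rep_len(c(1, 0), n)
  tr <- filter_responses(resp, ses, model_params(3.5, 0, 1))
  # every scored decision opposes the freshly reset prior, so the error is
  # the full posterior weight of the abandoned percept
  expect_equal(tr$pe[tr$scored], rep(plogis(3.5 / 2), sum(tr$scored)),
               tolerance = 1e-12)
  expect_equal(tr$pi_stability[tr$scored],
               rep(3.5, sum(tr$scored)), tolerance = 1e-12)
})

test_that("misaligned or incomplete inputs raise data errors", {
  s <- small_subject(seed = 3)
  expect_error(filter_responses(s$responses[-1, ], s$session,
                                s$true_params), "match")
  ses <- build_session(0.30, runs = 1, pairs_per_run = 1)
  resp <- ses$overlaps[c("run", "block", "overlap_index", "time_s",
                         "condition")]
  resp$response <- 1
  expect_error(filter_responses(resp, ses, model_params(3.5, 5, 1)),
               "replay")
})

test_that("missing reports propagate state but are unscored", {
  s <- small_subject(seed = 5)
  r <- s$responses
  r$response[c(5, 9)] <- NA
  tr <- filter_responses(r, s$session, s$true_params)
  expect_false(any(tr$scored[c(5, 9)]))
  expect_equal(tr$y[5], tr$y[4])     # carried forward
})
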