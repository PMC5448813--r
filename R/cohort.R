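#' Generate a synthetic subject
#'
#' Simulates one subject through a session: ambiguous blocks are generated
#' by the stochastic belief-update cycle; each replay block then presents
#' the disparity sequence that mimics the decisions of the preceding
#' ambiguous block (as in the experimental design), and the subject's
#' responses to it are again simulated from the model with the subject's
#' own `pi_stereo`.
#'
#' At each block start the subject holds no stability prior: the first
#' decision is driven by the stereodisparity weight alone (a fair coin on
#' ambiguous blocks), after which the stability prior is centred on it
#' with precision `pi_init`.
#'
#' @param params A [model_params()] object (the subject's ground truth).
#' @param session A [build_session()] object.
#' @param seed Integer seed.
#' @return An object of class `pc_subject`: list with `true_params`,
#'   `session` (replay `mu_stereo` filled in), `responses` (one row per
#'   overlap) and `seed`.
#' @export
synth_subject <- function(params, session = build_session(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ov <- session$overlaps
  resp <- rep(NA_real_, nrow(ov))
  key <- interaction(ov$run, ov$block, drop = TRUE)
  block_rows <- split(seq_len(nrow(ov)), key)
  # preserve session order of blocks
  block_rows <- block_rows[order(vapply(block_rows, min, 1L))]
  prev_amb_decisions <- NULL
  for (rows in block_rows) {
    cond <- ov$condition[rows[1]]
    if (cond == "replay") {
      if (is.null(prev_amb_decisions))
        stop("replay block without preceding ambiguous block", call. = FALSE)
      ov$mu_stereo[rows] <- replay_from_decisions(prev_amb_decisions,
                                                  length(rows))
    }
    y <- numeric(length(rows))
    state <- NULL
    for (k in seq_along(rows)) {
      i <- rows[k]
      if (k == 1) {
        # block start: stereodisparity only
        st0 <- perceptual_state(0, 0)
        out <- step_overlap(st0, ov$mu_stereo[i], params)
      } else {
        out <- step_overlap(state, ov$mu_stereo[i], params)
      }
      state <- if (k == 1)
        perceptual_state(out$record$y, params$pi_init) else out$state
      y[k] <- out$record$y
    }
    resp[rows] <- y
    if (cond == "ambiguous") prev_amb_decisions <- y
  }
  session$overlaps <- ov
  responses <- cbind(ov[c("run", "block", "overlap_index", "time_s",
                          "condition")],
                     data.frame(response = resp))
  structure(list(true_params = params, session = session,
                 responses = responses, seed = seed),
            class = "pc_subject")
}

#' Default cohort parameter sampler
#'
#' Draws subject-level ground-truth parameters from log-normal population
#' distributions centred on the canonical values: `pi_init` around 3.5 and
#' `pi_stereo` around 5, both with a log-scale standard deviation of 0.3
#' (moderate inter-individual variability); `zeta` fixed at 1.
#'
#' @param n Number of subjects.
#' @return A list of [model_params()] objects.
#' @export
default_param_sampler <- function(n) {
  lapply(seq_len(n), function(i)
    model_params(pi_init = stats::rlnorm(1, log(3.5), 0.3),
                 pi_stereo = stats::rlnorm(1, log(5), 0.3),
                 zeta = 1))
}

#' Generate a synthetic cohort
#'
#' Emulates the study scale: `n_subjects` subjects balanced over the three
#' overlap-frequency levels, each with ground-truth parameters drawn by
#' `param_sampler` and responses generated by [synth_subject()]. All
#' randomness derives from `master_seed`, and the ground truth is retained
#' for recovery studies.
#'
#' @param n_subjects Number of subjects (default 20, the study scale).
#' @param param_sampler Function `n -> list of model_params`.
#' @param frequencies Overlap-frequency levels cycled over subjects.
#' @param master_seed Integer master seed.
#' @param runs,pairs_per_run Session dimensions (defaults 3 and 8).
#' @return An object of class `pc_cohort`: list of `pc_subject`s plus a
#'   `manifest` data frame (subject, frequency, seed, true parameters).
#' @export
synth_cohort <- function(n_subjects = 20,
                         param_sampler = default_param_sampler,
                         frequencies = c(0.24, 0.30, 0.40),
                         master_seed = 1, runs = 3, pairs_per_run = 8) {
  if (n_subjects < 1) stop("'n_subjects' must be at least 1", call. = FALSE)
  set.seed(master_seed)
  params <- param_sampler(n_subjects)
  freq <- rep(frequencies, length.out = n_subjects)
  seeds <- (master_seed * 1000L + seq_len(n_subjects)) %% .Machine$integer.max
  subjects <- lapply(seq_len(n_subjects), function(i) {
    synth_subject(params[[i]],
                  build_session(freq[i], runs = runs,
                                pairs_per_run = pairs_per_run),
                  seed = seeds[i])
  })
  manifest <- data.frame(
    subject = seq_len(n_subjects),
    overlap_frequency_hz = freq,
    seed = seeds,
    pi_init = vapply(params, `[[`, 1, "pi_init"),
    pi_stereo = vapply(params, `[[`, 1, "pi_stereo"),
    zeta = vapply(params, `[[`, 1, "zeta"))
  structure(list(subjects = subjects, manifest = manifest,
                 master_seed = master_seed),
            class = "pc_cohort")
}

#' Empirical transition probability
#'
#' Fraction of within-block overlap-to-overlap steps at which the reported
#' percept changed, the behavioural measure that anchors the stability
#' parameter: subjects with a stronger initial stabilisation (`pi_init`)
#' switch less often.
#'
#' @param responses Response series data frame (or a `pc_subject`).
#' @param condition Which blocks to score (default `"ambiguous"`).
#' @return Transition probability per overlap step.
#' @export
transition_frequency <- function(responses, condition = "ambiguous") {
  if (inherits(responses, "pc_subject")) responses <- responses$responses
  r <- responses[responses$condition %in% condition, ]
  key <- interaction(r$run, r$block, drop = TRUE)
  ch <- unlist(lapply(split(r$response, key), function(y) {
    y <- y[!is.na(y)]
    if (length(y) < 2) return(numeric(0))
    diff(y) != 0
  }), use.names = FALSE)
  if (length(ch) == 0) return(NA_real_)
  mean(ch)
}
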