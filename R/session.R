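#' Build a session timeline (ambiguous/replay block design)
#'
#' Constructs the deterministic overlap timeline of the fMRI study design:
#' each run contains pairs of an ambiguous block followed by its replay
#' block, with 10 s fixation after every block. The rotational speed of the
#' stimulus sets the overlap frequency, and the block duration is matched
#' to the speed level (0.24 Hz -> 42.8 s, 0.30 Hz -> 40.90 s,
#' 0.40 Hz -> 41 s). Overlaps within a block are spaced at one overlap
#' period, the first one period after block onset.
#'
#' @param overlap_frequency_hz One of 0.24, 0.30, 0.40.
#' @param runs Number of runs (default 3).
#' @param pairs_per_run Ambiguous/replay block pairs per run (default 8).
#' @param fixation_s Fixation gap after each block in seconds (default 10).
#' @return An object of class `pc_session`: a list with the design
#'   constants plus a `blocks` table (`run`, `block`, `pair`, `condition`,
#'   `onset_s`, `duration_s`) and an `overlaps` table (`run`, `block`,
#'   `pair`, `condition`, `overlap_index`, `time_s`, `mu_stereo`). Replay
#'   overlaps carry `mu_stereo = NA` until a replay disparity sequence is
#'   attached (see [replay_from_decisions()] and [synth_subject()]).
#' @examples
#' s <- build_session(0.30, runs = 1, pairs_per_run = 2)
#' table(s$overlaps$condition)
#' @export
build_session <- function(overlap_frequency_hz = 0.30, runs = 3,
                          pairs_per_run = 8, fixation_s = 10) {
  freqs <- c(0.24, 0.30, 0.40)
  durs <- c(42.8, 40.90, 41)
  i <- match(overlap_frequency_hz, freqs)
  if (is.na(i))
    stop("'overlap_frequency_hz' must be one of 0.24, 0.30, 0.40",
         call. = FALSE)
  if (runs < 1 || pairs_per_run < 1)
    stop("'runs' and 'pairs_per_run' must be at least 1", call. = FALSE)
  dur <- durs[i]
  n_ov <- floor(dur * overlap_frequency_hz)
  period <- 1 / overlap_frequency_hz

  blocks <- do.call(rbind, lapply(seq_len(runs), function(r) {
    onset <- 0
    rows <- vector("list", 2 * pairs_per_run)
    b <- 0
    for (p in seq_len(pairs_per_run)) {
      for (cond in c("ambiguous", "replay")) {
        b <- b + 1
        rows[[b]] <- data.frame(run = r, block = b, pair = p,
                                condition = cond, onset_s = onset,
                                duration_s = dur)
        onset <- onset + dur + fixation_s
      }
    }
    do.call(rbind, rows)
  }))
  overlaps <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(j) {
    bl <- blocks[j, ]
    data.frame(run = bl$run, block = bl$block, pair = bl$pair,
               condition = bl$condition,
               overlap_index = seq_len(n_ov),
               time_s = bl$onset_s + seq_len(n_ov) * period,
               mu_stereo = if (bl$condition == "ambiguous") 0.5 else NA_real_)
  }))
  rownames(blocks) <- rownames(overlaps) <- NULL
  structure(list(overlap_frequency_hz = overlap_frequency_hz,
                 runs = runs, pairs_per_run = pairs_per_run,
                 fixation_s = fixation_s, block_duration_s = dur,
                 overlaps_per_block = n_ov,
                 run_duration_s = 2 * pairs_per_run * (dur + fixation_s),
                 blocks = blocks, overlaps = overlaps),
            class = "pc_session")
}

#' @export
print.pc_session <- function(x, ...) {
  cat(sprintf("Session: %d run(s), %d ambiguous/replay pairs per run\n",
              x$runs, x$pairs_per_run))
  cat(sprintf("  overlap frequency %.2f Hz, block %.4g s, fixation %g s\n",
              x$overlap_frequency_hz, x$block_duration_s, x$fixation_s))
  cat(sprintf("  %d overlaps per block, %d overlaps total\n",
              x$overlaps_per_block, nrow(x$overlaps)))
  invisible(x)
}

#' Replay disparity sequence mimicking an ambiguous block
#'
#' In the replay condition the disambiguated stimulus reproduces the
#' perceptual time-course of the preceding ambiguous block: the
#' stereodisparity mean at replay overlap k equals the decision reported
#' at overlap k of that block. The sequence is truncated or padded (with
#' its last value) to the requested replay length.
#'
#' @param ambiguous_decisions 0/1 decisions of the preceding ambiguous
#'   block.
#' @param n_out Number of replay overlaps (default: same length).
#' @return Numeric vector of `mu_stereo` values in \{0, 1\}.
#' @export
replay_from_decisions <- function(ambiguous_decisions,
                                  n_out = length(ambiguous_decisions)) {
  y <- as.numeric(ambiguous_decisions)
  if (length(y) == 0) stop("empty decision sequence", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("decisions must be 0 or 1", call. = FALSE)
  if (n_out <= length(y)) y[seq_len(n_out)]
  else c(y, rep(y[length(y)], n_out - length(y)))
}

#' Read/write session timelines and response series
#'
#' Sessions serialise to JSON (design constants plus the block and overlap
#' tables); response series to tab-separated text with columns `run`,
#' `block`, `overlap_index`, `time_s`, `condition`, `response` (0/1 or NA).
#' Round-trips are exact.
#'
#' @param session A [build_session()] object.
#' @param path File path.
#' @return `read_session()` returns a `pc_session`; `read_responses()` a
#'   data frame; the writers return `path` invisibly.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_session <- function(session, path) {
  x <- unclass(session)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname session_io
#' @export
read_session <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$blocks <- as.data.frame(x$blocks)
  x$overlaps <- as.data.frame(x$overlaps)
  if (is.null(x$overlaps$mu_stereo)) x$overlaps$mu_stereo <- NA_real_
  x$overlaps$mu_stereo <- as.numeric(x$overlaps$mu_stereo)
  structure(x, class = "pc_session")
}

#' @rdname session_io
#' @param responses Response series data frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.table(responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_responses <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a belief trajectory as tab-separated text
#'
#' Writes the per-overlap trajectory returned by [filter_responses()]
#' (joint prior, posterior weight, predicted response, decision,
#' prediction error) for downstream use, e.g. as the prediction-error
#' modulator of an fMRI design.
#'
#' @param trajectory Data frame from [filter_responses()].
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
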