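#' Generate a pseudo-random cue sequence
#'
#' Builds the cue track used for decoder calibration: a pseudo-random order
#' of active-state blocks, each active state appearing exactly `n_reps`
#' times, with a rest block interleaved before every active block. Block
#' durations are drawn from the programmable set `{2, 4}` seconds.
#'
#' @param states State labels; the first entry is the rest state.
#' @param n_reps Repetitions per active state (>= 1). The walking models in
#'   the clinical protocol were trained on 30 repetitions per active state.
#' @param durations Allowed block durations in seconds, a subset of
#'   `c(2, 4)`. A single value fixes all blocks; both values are sampled
#'   uniformly per block.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#'
#' @return Tibble with one row per cue block: `state`, `duration_s`,
#'   `onset_s` (block start), `offset_s`.
#' @examples
#' cues <- make_cue_sequence(c("rest", "hipL", "hipR"), n_reps = 2, seed = 1)
#' table(cues$state)
#' @export
make_cue_sequence <- function(states, n_reps, durations = 2, seed = 1L) {
  if (length(states) < 1L) {
    abort("Empty state list.", class = "bsitools_config_error")
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) {
    abort("`n_reps` must be >= 1.", class = "bsitools_config_error")
  }
  if (length(durations) < 1L || !all(durations %in% c(2, 4))) {
    abort("`durations` must be drawn from {2, 4} seconds.",
          class = "bsitools_config_error")
  }
  rest <- states[1L]
  active <- if (length(states) > 1L) states[-1L] else states[1L]
  with_seed(seed, {
    order <- rep(active, each = n_reps)
    order <- order[sample.int(length(order))]
    if (length(states) > 1L) {
      blocks <- as.vector(rbind(rest, order))
    } else {
      blocks <- order # single-state track: no interleave possible
    }
    dur <- if (length(durations) == 1L) {
      rep(durations, length(blocks))
    } else {
      sample(durations, length(blocks), replace = TRUE)
    }
    tibble(state = blocks, duration_s = dur,
           onset_s = cumsum(c(0, dur[-length(dur)])),
           offset_s = cumsum(dur))
  })
}

#' Expand a block cue track to per-sample labels
#'
#' @param cues Block tibble from [make_cue_sequence()].
#' @param fs Sampling rate in Hz.
#' @param n Optional total sample count (defaults to the track length).
#' @return Character vector of state labels, one per sample.
#' @export
expand_cues <- function(cues, fs, n = NULL) {
  total <- sum(cues$duration_s)
  n <- n %||% round(total * fs)
  t <- (seq_len(n) - 1) / fs
  idx <- findInterval(t, cues$onset_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(cues)] <- nrow(cues)
  cues$state[idx]
}

#' State label at given time points
#'
#' @param cues Block cue tibble.
#' @param t Numeric vector of times in seconds.
#' @return Character labels; times beyond the track get the last block's label.
#' @export
cue_state_at <- function(cues, t) {
  idx <- findInterval(t - 1e-9, cues$onset_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(cues)] <- nrow(cues)
  cues$state[idx]
}
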