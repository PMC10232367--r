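# Shared fixtures, generated in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- make()
  fixture_env[[name]]
}

# Small two-state simulator config with one strongly informative channel.
tiny_config <- function(seed = 7, gain = 3) {
  sim_config(
    seed = seed, n_channels = 4L, states = c("rest", "hipL"),
    informative_map = data.frame(state = "hipL", channel = 2L,
                                 band = "40-100", gain = gain),
    n_reps = 4L, cue_duration_s = 2
  )
}

# Welch band-power ratio between active and rest epochs (oracle for the
# simulator's band-power contrast).
welch_band_ratio <- function(x, labels, active, fs, lo, hi, seg_s = 1) {
  bp <- function(seg) {
    pt <- welch_psd(seg, fs, seg_s = seg_s)
    sum(pt$psd[pt$freq >= lo & pt$freq < hi])
  }
  bp(x[labels == active]) / bp(x[labels == "rest"])
}

# Random simplex vector.
rsimplex <- function(K) {
  e <- stats::rexp(K)
  e / sum(e)
}

# Brute-force one-step forward recursion (independent of hmm_filter).
forward_step_oracle <- function(alpha_em, Tm, alpha_prev) {
  un <- numeric(length(alpha_em))
  for (j in seq_along(un)) {
    acc <- 0
    for (i in seq_along(un)) acc <- acc + alpha_prev[i] * Tm[i, j]
    un[j] <- alpha_em[j] * acc
  }
  un / sum(un)
}

# A tiny program library for controller tests.
tiny_programs <- function() {
  dplyr::bind_rows(
    stim_program("p_hipL", cathodes = 0, anodes = 1,
                 amplitude_range = c(14, 16), target = "hipL"),
    stim_program("p_hipR", cathodes = 2, anodes = 3,
                 amplitude_range = c(14, 16), target = "hipR")
  )
}
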