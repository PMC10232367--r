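#' Synthetic-session configuration
#'
#' Defines the generative conditions for a simulated recording session:
#' channel count, sampling rate, decoder states, which channels carry
#' state-dependent band-power modulation (and how strongly), the background
#' spectrum and optional mains contamination.
#'
#' Band-power gains are *power* ratios (active state vs rest), not amplitude
#' ratios. The background is coloured Gaussian noise with power spectral
#' density proportional to `1/f^background_exponent`.
#'
#' @param seed Integer master seed; every random draw in the session is
#'   derived deterministically from it.
#' @param n_channels Number of ECoG channels (default 64: two 32-channel
#'   epidural grids).
#' @param fs Sampling rate in Hz (default 586).
#' @param states Character vector of state labels; the first entry is the
#'   rest state. Default: rest plus hip/knee/ankle bilaterally (7 states).
#' @param informative_map Tibble with columns `state`, `channel`, `band`
#'   (one of `"0.5-10"`, `"10-40"`, `"40-100"`, `"100-200"`) and `gain`
#'   (power ratio > 0). `NULL` uses [default_informative_map()].
#' @param background_exponent Spectral slope of the 1/f background
#'   (default 1).
#' @param line_noise_hz Optional mains frequency to superimpose (e.g. 50);
#'   `NULL` for none.
#' @param effect_size Dimensionless contrast scale; configured gains `g` are
#'   rescaled to `1 + effect_size * (g - 1)`.
#' @param n_reps Cue repetitions per active state used when a session
#'   generates its own cue sequence (default 30).
#' @param cue_duration_s Cue block duration(s) in seconds, drawn from
#'   `{2, 4}` (default 2).
#'
#' @return An object of class `bsi_sim_config`.
#' @seealso [simulate_session()], [simulate_ecog()], [make_cue_sequence()]
#' @export
sim_config <- function(seed = 1L,
                       n_channels = 64L,
                       fs = 586,
                       states = c("rest", "hipL", "kneeL", "ankleL",
                                  "hipR", "kneeR", "ankleR"),
                       informative_map = NULL,
                       background_exponent = 1,
                       line_noise_hz = NULL,
                       effect_size = 1,
                       n_reps = 30L,
                       cue_duration_s = 2) {
  stopifnot_scalar_number(fs, "fs")
  stopifnot_scalar_number(effect_size, "effect_size")
  if (length(states) < 1L || anyDuplicated(states)) {
    abort("`states` must be a non-empty set of unique labels.",
          class = "bsitools_config_error")
  }
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) {
    abort("`n_channels` must be positive.", class = "bsitools_config_error")
  }
  # All four synthesized bands must live strictly below Nyquist.
  if (fs <= 2 * 200) {
    abort("`fs` must exceed twice the highest synthesized band edge (200 Hz).",
          class = "bsitools_config_error")
  }
  if (!all(cue_duration_s %in% c(2, 4))) {
    abort("`cue_duration_s` values must be 2 or 4 seconds.",
          class = "bsitools_config_error")
  }
  if (is.null(informative_map)) {
    informative_map <- default_informative_map(n_channels, states)
  }
  informative_map <- as_tibble(informative_map)
  required <- c("state", "channel", "band", "gain")
  if (!all(required %in% names(informative_map))) {
    abort("`informative_map` needs columns state, channel, band, gain.",
          class = "bsitools_config_error")
  }
  if (any(!informative_map$state %in% states)) {
    abort("`informative_map` refers to unknown states.",
          class = "bsitools_config_error")
  }
  if (any(!informative_map$band %in% names(ecog_bands()))) {
    abort("`informative_map` bands must be one of 0.5-10, 10-40, 40-100, 100-200.",
          class = "bsitools_config_error")
  }
  if (any(informative_map$gain <= 0)) {
    abort("`informative_map` gains must be positive power ratios.",
          class = "bsitools_config_error")
  }
  if (any(informative_map$channel < 1 | informative_map$channel > n_channels)) {
    abort("`informative_map` channel indices out of range.",
          class = "bsitools_config_error")
  }
  for (st in unique(informative_map$state)) {
    ch <- unique(informative_map$channel[informative_map$state == st])
    if (length(ch) >= n_channels) {
      abort("Informative channel set must not cover all channels.",
            class = "bsitools_config_error")
    }
  }
  informative_map$gain <- 1 + effect_size * (informative_map$gain - 1)
  if (any(informative_map$gain <= 0)) {
    abort("`effect_size` drives a gain non-positive.",
          class = "bsitools_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_channels = n_channels, fs = fs,
         states = states, informative_map = informative_map,
         background_exponent = background_exponent,
         line_noise_hz = line_noise_hz, effect_size = effect_size,
         n_reps = as.integer(n_reps), cue_duration_s = cue_duration_s),
    class = "bsi_sim_config"
  )
}

#' Frequency bands used for synthesis and mapping
#'
#' The four canonical ECoG bands (Hz) used for informative-channel synthesis,
#' weight projections and signal-stability reporting.
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
ecog_bands <- function() {
  list("0.5-10" = c(0.5, 10), "10-40" = c(10, 40),
       "40-100" = c(40, 100), "100-200" = c(100, 200))
}

#' Default informative-channel map
#'
#' Assigns each active state a dedicated block of three channels carrying
#' beta-band (10-40 Hz, power ratio 2) and gamma-band (40-100 Hz, power
#' ratio 3) modulation, emulating somatotopically segregated
#' movement-related information spread over beta and gamma bands.
#'
#' @param n_channels Total channel count.
#' @param states State labels (first = rest, which gets no modulation).
#' @return Tibble with columns `state`, `channel`, `band`, `gain`.
#' @export
default_informative_map <- function(n_channels, states) {
  active <- states[-1L]
  per_state <- 3L
  need <- length(active) * per_state
  if (need >= n_channels) {
    per_state <- max(1L, (n_channels - 1L) %/% max(1L, length(active)))
    need <- length(active) * per_state
  }
  if (need >= n_channels) {
    abort("Too few channels to reserve informative sets below all-channels.",
          class = "bsitools_config_error")
  }
  purrr::map_dfr(seq_along(active), function(i) {
    ch <- (i - 1L) * per_state + seq_len(per_state)
    tidyr::expand_grid(state = active[i], channel = ch,
                       tibble(band = c("10-40", "40-100"), gain = c(2, 3)))
  })
}

#' @export
print.bsi_sim_config <- function(x, ...) {
  cat("<bsi_sim_config> ", x$n_channels, " channels @ ", x$fs, " Hz, ",
      length(x$states), " states, seed ", x$seed, "\n", sep = "")
  cat("  informative entries: ", nrow(x$informative_map),
      "; background 1/f^", x$background_exponent, "\n", sep = "")
  invisible(x)
}
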