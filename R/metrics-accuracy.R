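#' Delay-compensated decoding accuracy
#'
#' Normalized cross-correlation between the cued state indicator `Z` and
#' the decoded state indicator after delay compensation:
#' `accuracy = sum_t Z(t - tau) Zhat(t) / sum_t Z(t)`, where `tau`
#' maximizes the cross-correlation over a configurable lag window. Ties in
#' the lag search resolve to the smallest |tau|.
#'
#' @param cued Indicator vector (0/1) of the cued state per sample.
#' @param decoded Decoded indicator (or probability) track, same length
#'   and sampling as `cued`.
#' @param dt Sampling interval of both tracks in seconds (e.g. 0.1 at the
#'   decoder cadence).
#' @param max_lag_s Lag search half-window in seconds (default 5).
#' @return Tibble: `accuracy`, `tau_s` (compensated delay), `method`.
#' @export
decoding_accuracy <- function(cued, decoded, dt, max_lag_s = 5) {
  if (length(cued) != length(decoded)) {
    abort("`cued` and `decoded` must have equal length.",
          class = "bsitools_input_error")
  }
  total <- sum(cued)
  if (total == 0) {
    abort("`cued` is identically zero; accuracy undefined.",
          class = "bsitools_input_error")
  }
  n <- length(cued)
  L <- min(n - 1L, round(max_lag_s / dt))
  lags <- -L:L
  cc <- vapply(lags, function(tau) {
    # sum_t Z(t - tau) * Zhat(t), zero outside the support
    if (tau >= 0) {
      t_idx <- (1L + tau):n
      sum(cued[t_idx - tau] * decoded[t_idx])
    } else {
      t_idx <- 1L:(n + tau)
      sum(cued[t_idx - tau] * decoded[t_idx])
    }
  }, numeric(1))
  best <- which(cc == max(cc))
  tau <- lags[best[which.min(abs(lags[best]))]]
  tibble(accuracy = max(cc) / total, tau_s = tau * dt,
         method = "xcorr_delay_compensated")
}

#' Chance level of a K-state decoder
#'
#' Accuracy of a uniform random classifier, `100 / K` percent, rounded to
#' the nearest integer percent (14% for the seven-state decoder).
#'
#' @param K Number of states (>= 2).
#' @return Integer percentage.
#' @export
chance_level <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 2) {
    abort("`K` must be a single integer >= 2.",
          class = "bsitools_config_error")
  }
  as.integer(round(100 / K))
}

#' Muscle-response (EMG) accuracy
#'
#' Builds the binary EMG envelope — the mean absolute z-score over a
#' sliding `window_s` window exceeding 1 — and reports the fraction of
#' envelope-active time during which the decoded state was active:
#' `accuracy = sum_t EMG(t) Zhat(t) / sum_t EMG(t)`.
#'
#' @param decoded Decoded state indicator, one value per EMG sample.
#' @param emg Raw EMG trace (same length).
#' @param fs Sampling rate of both in Hz.
#' @param window_s Envelope window `T` in seconds (default 0.2).
#' @return Tibble: `accuracy`, `active_fraction` (envelope duty cycle),
#'   `method`.
#' @export
emg_accuracy <- function(decoded, emg, fs, window_s = 0.2) {
  if (length(decoded) != length(emg)) {
    abort("`decoded` and `emg` must have equal length.",
          class = "bsitools_input_error")
  }
  s <- sd(emg)
  if (!is.finite(s) || s == 0) {
    abort("EMG has zero variance; envelope undefined.",
          class = "bsitools_input_error")
  }
  z <- (emg - mean(emg)) / s
  env <- roll_mean_forward(abs(z), round(window_s * fs)) > 1
  if (!any(env)) {
    abort("EMG envelope never active; accuracy undefined.",
          class = "bsitools_input_error")
  }
  tibble(accuracy = sum(env * decoded) / sum(env),
         active_fraction = mean(env), method = "emg_envelope")
}

#' Stepping accuracy from decoded probability profiles
#'
#' During free walking there is no cue; the decoded probability curve of
#' each hip-flexion state is profiled around every step: the peak
#' probability within the step window and the width of the curve above
#' half of that peak (full width at half maximum).
#'
#' @param prob Decoded probability track for one state (per window).
#' @param t Window timestamps in seconds.
#' @param step_onsets Step onset times (s); each step's window runs to the
#'   next onset (the last to the end of the track).
#' @return List of class `bsi_stepping`: `steps` (per step: `onset_s`,
#'   `peak`, `width_s`) and `summary` (`peak_mean`, `peak_sd`,
#'   `width_mean`, `width_sd`). Empty tibbles when no steps are given.
#' @export
stepping_accuracy <- function(prob, t, step_onsets) {
  dt <- if (length(t) > 1L) median(diff(t)) else NA_real_
  if (length(step_onsets) == 0L) {
    return(structure(list(steps = tibble(onset_s = numeric(),
                                         peak = numeric(),
                                         width_s = numeric()),
                          summary = tibble(peak_mean = NA_real_,
                                           peak_sd = NA_real_,
                                           width_mean = NA_real_,
                                           width_sd = NA_real_)),
                     class = "bsi_stepping"))
  }
  bounds <- c(step_onsets, max(t) + dt)
  steps <- purrr::map_dfr(seq_along(step_onsets), function(i) {
    inw <- t >= bounds[i] & t < bounds[i + 1L]
    if (!any(inw)) {
      return(tibble(onset_s = step_onsets[i], peak = NA_real_,
                    width_s = NA_real_))
    }
    p <- prob[inw]
    peak <- max(p)
    tibble(onset_s = step_onsets[i], peak = peak,
           width_s = sum(p > peak / 2) * dt)
  })
  structure(
    list(steps = steps,
         summary = tibble(peak_mean = mean(steps$peak, na.rm = TRUE),
                          peak_sd = sd(steps$peak),
                          width_mean = mean(steps$width_s, na.rm = TRUE),
                          width_sd = sd(steps$width_s))),
    class = "bsi_stepping"
  )
}

#' @export
print.bsi_stepping <- function(x, ...) {
  s <- x$summary
  cat("<bsi_stepping> ", nrow(x$steps), " steps; peak ",
      round(s$peak_mean, 3), " +/- ", round(s$peak_sd, 3), ", width ",
      round(s$width_mean, 2), " +/- ", round(s$width_sd, 2), " s\n",
      sep = "")
  invisible(x)
}

#' @param x A `bsi_stepping`.
#' @param ... Unused.
#' @rdname stepping_accuracy
#' @export
tidy.bsi_stepping <- function(x, ...) x$steps

#' @rdname stepping_accuracy
#' @export
glance.bsi_stepping <- function(x, ...) x$summary
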