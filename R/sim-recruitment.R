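#' Ground-truth recruitment parameters
#'
#' One row per (electrode configuration, muscle) pair: motor threshold and
#' saturation amplitude (mA), maximal response (z-units) and the standard
#' deviation of additive measurement noise. The noiseless mean response is
#' a saturating raised-cosine sigmoid that is exactly 0 at threshold, half
#' of the maximum at the midpoint and exactly maximal at saturation.
#'
#' @param config_ids Character vector of electrode-configuration ids.
#' @param muscles Character vector of muscle labels.
#' @param threshold,saturation Matrices (config x muscle) or scalars, mA.
#' @param max_resp Matrix or scalar: maximal response per pair (z-units).
#' @param noise_sd Scalar measurement noise sd.
#' @return Tibble of class `bsi_recruitment_truth`.
#' @export
recruitment_truth <- function(config_ids, muscles, threshold, saturation,
                              max_resp, noise_sd = 0.05) {
  grid <- tidyr::expand_grid(config = config_ids, muscle = muscles)
  expand_par <- function(p) {
    if (length(p) == 1L) return(rep(p, nrow(grid)))
    as.vector(t(matrix(p, nrow = length(config_ids))))
  }
  out <- dplyr::mutate(grid,
                       threshold = expand_par(threshold),
                       saturation = expand_par(saturation),
                       max_resp = expand_par(max_resp),
                       noise_sd = noise_sd)
  if (any(out$threshold >= out$saturation)) {
    abort("Recruitment threshold must be below saturation.",
          class = "bsitools_config_error")
  }
  class(out) <- c("bsi_recruitment_truth", class(out))
  out
}

#' Raised-cosine recruitment sigmoid
#'
#' Mean muscle response to a stimulation amplitude: 0 below threshold,
#' `max_resp` above saturation, and a smooth monotone raised-cosine ramp in
#' between (exactly `max_resp / 2` at the midpoint).
#'
#' @param amplitude Amplitude(s) in mA.
#' @param threshold,saturation Curve parameters in mA.
#' @param max_resp Maximal response.
#' @return Mean responses, same length as `amplitude`.
#' @export
recruitment_sigmoid <- function(amplitude, threshold, saturation, max_resp) {
  x <- pmin(pmax((amplitude - threshold) / (saturation - threshold), 0), 1)
  max_resp * (1 - cos(pi * x)) / 2
}

#' Simulate recruitment-curve responses
#'
#' Emulates recruitment-curve acquisition: single pulses of increasing
#' amplitude (one per second in the clinical protocol), with the mean
#' response given by [recruitment_sigmoid()] plus Gaussian noise.
#'
#' @param truth A [recruitment_truth()] table.
#' @param amplitudes Strictly increasing amplitude grid (mA).
#' @param seed Integer seed for the measurement noise.
#' @return Tibble: `config`, `muscle`, `amplitude`, `response`.
#' @export
simulate_recruitment_responses <- function(truth, amplitudes, seed = 1L) {
  if (length(amplitudes) < 1L || is.unsorted(amplitudes, strictly = TRUE)) {
    abort("`amplitudes` must be a strictly increasing grid.",
          class = "bsitools_config_error")
  }
  with_seed(derive_seed(seed, "recruitment"), {
    out <- tidyr::expand_grid(dplyr::as_tibble(truth), amplitude = amplitudes)
    out$response <- recruitment_sigmoid(out$amplitude, out$threshold,
                                        out$saturation, out$max_resp) +
      rnorm(nrow(out), sd = out$noise_sd)
    dplyr::select(out, "config", "muscle", "amplitude", "response")
  })
}
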