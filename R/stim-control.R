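#' Proportional control: mixture output to stimulation amplitudes
#'
#' Control model for six-joint proportional control in static conditions:
#' each active state's mixture output `u_k` is linearly rescaled into the
#' amplitude range of that state's stimulation program. Outputs below the
#' activation threshold `theta_u` produce no command; `u_k` is clamped to
#' `[0, 1]` before rescaling, so amplitudes never leave the program range.
#'
#' @param u Named mixture-output vector (names = states; rest included).
#' @param programs Program tibble with a `target` column covering every
#'   active state that exceeds `theta_u`.
#' @param theta_u Activation threshold on `u` (default 0.1).
#' @param t Timestamp attached to the emitted commands (default 0).
#' @return Tibble of commands: `t`, `program`, `state`, `amplitude_mA`.
#' @export
proportional_controller <- function(u, programs, theta_u = 0.1, t = 0) {
  states <- names(u)
  if (is.null(states)) {
    abort("`u` must be named by state.", class = "bsitools_input_error")
  }
  active <- states[-1L]
  out <- list()
  for (k in active) {
    uk <- u[[k]]
    if (!is.finite(uk) || uk <= theta_u) next
    pr <- programs[!is.na(programs$target) & programs$target == k, ]
    if (nrow(pr) == 0L) {
      abort(sprintf("No stimulation program for active state '%s'.", k),
            class = "bsitools_config_error")
    }
    pr <- pr[1L, ]
    amp <- pr$a_min + min(max(uk, 0), 1) * (pr$a_max - pr$a_min)
    out[[k]] <- tibble(t = t, program = pr$id, state = k,
                       amplitude_mA = amp)
  }
  if (length(out) == 0L) {
    return(tibble(t = numeric(), program = character(), state = character(),
                  amplitude_mA = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Walking control: one joint at a time from gate probabilities
#'
#' Control model for standing and walking: the mixture-of-experts layer is
#' removed and the stimulation amplitude is driven by the maximum filtered
#' state probability, for the argmax state's program only — left and right
#' steps must never be commanded simultaneously. The probability is
#' rescaled from `[p0, 1]` onto the program's amplitude range. An argmax at
#' rest (ties resolve toward rest) emits nothing.
#'
#' @param alpha_hat Named filtered posterior (simplex; first name = rest).
#' @param programs Program tibble (`target` column keyed by state).
#' @param p0 Probability mapped to `A_min` (default 0.5).
#' @param t Timestamp for the command (default 0).
#' @return Tibble with zero rows (rest) or one command row.
#' @export
walking_controller <- function(alpha_hat, programs, p0 = 0.5, t = 0) {
  states <- names(alpha_hat)
  if (is.null(states)) {
    abort("`alpha_hat` must be named by state.",
          class = "bsitools_input_error")
  }
  k <- which.max(alpha_hat) # ties resolve to the first (rest-first order)
  if (k == 1L) {
    return(tibble(t = numeric(), program = character(), state = character(),
                  amplitude_mA = numeric()))
  }
  pr <- programs[!is.na(programs$target) & programs$target == states[k], ]
  if (nrow(pr) == 0L) {
    return(tibble(t = numeric(), program = character(), state = character(),
                  amplitude_mA = numeric()))
  }
  pr <- pr[1L, ]
  scale <- min(max((alpha_hat[[k]] - p0) / (1 - p0), 0), 1)
  tibble(t = t, program = pr$id, state = states[k],
         amplitude_mA = pr$a_min + scale * (pr$a_max - pr$a_min))
}

#' Dispatch decoder-cadence commands to the 300 ms stimulation cadence
#'
#' The decoder emits commands every 100 ms but updated commands reach the
#' implanted pulse generator every 300 ms: within each 300 ms tick the
#' latest command per program wins, and emitted timestamps are tick-aligned.
#'
#' @param commands Command tibble (`t`, `program`, `amplitude_mA`, ...)
#'   with non-decreasing timestamps.
#' @param tick_s Dispatch cadence in seconds (default 0.3).
#' @return Tibble with at most one row per (tick, program): `t` (tick
#'   start), `program`, `amplitude_mA`.
#' @export
dispatch <- function(commands, tick_s = 0.3) {
  if (nrow(commands) == 0L) {
    return(tibble(t = numeric(), program = character(),
                  amplitude_mA = numeric()))
  }
  if (is.unsorted(commands$t)) {
    abort("Command timestamps must be non-decreasing.",
          class = "bsitools_input_error")
  }
  cmd <- dplyr::mutate(commands, .tick = floor(.data$t / tick_s + 1e-9))
  out <- dplyr::slice_tail(
    dplyr::group_by(cmd, .data$.tick, .data$program), n = 1L)
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, .data$.tick, .data$program)
  dplyr::select(dplyr::mutate(out, t = .data$.tick * tick_s),
                "t", "program", "amplitude_mA")
}
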