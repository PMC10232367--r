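#' Simulate a complete co-registered session
#'
#' Generates the full synthetic session the decoder and evaluators operate
#' on: ECoG with state-locked band-power modulation, the cue track, EMG
#' driven through the recruitment ground truth by (optional) stimulation
#' commands, and knee-angle kinematics with one raised-cosine dip per
#' programmed step. All streams share one time base and every draw derives
#' from the configuration seed.
#'
#' @param config A [sim_config()].
#' @param cues Optional block cue tibble; defaults to a pseudo-random
#'   sequence generated from `config` (`n_reps`, `cue_duration_s`).
#' @param commands Optional scripted stimulation commands (tibble with
#'   `t`, `program`, `amplitude_mA`, optional `duration_s`, default 0.3 s)
#'   driving EMG through `recruitment`; `NULL` leaves EMG as pure noise.
#' @param recruitment Optional [recruitment_truth()]; required when
#'   `commands` reference programs. Program ids must match its `config`
#'   column.
#' @param steps Optional tibble of programmed steps: `onset_s`,
#'   `step_length_cm`, optional `side` (`"left"`/`"right"`, alternating by
#'   default).
#' @param emg_noise_sd Baseline EMG noise sd (mV scale), default 0.05.
#' @return Object of class `bsi_session`: list with `ecog`, `fs`, `cues`,
#'   `emg` (muscles x samples), `muscles`, `knee_angle` (2 x samples, rows
#'   left/right), `steps` (ground truth with `failed` flags), and `truth`.
#' @export
simulate_session <- function(config, cues = NULL, commands = NULL,
                             recruitment = NULL, steps = NULL,
                             emg_noise_sd = 0.05) {
  stopifnot(inherits(config, "bsi_sim_config"))
  fs <- config$fs
  if (is.null(cues)) {
    cues <- make_cue_sequence(config$states, config$n_reps,
                              config$cue_duration_s,
                              seed = derive_seed(config$seed, "cues"))
  }
  ecog <- simulate_ecog(config, cues)
  n <- ncol(ecog)

  muscles <- if (!is.null(recruitment)) unique(recruitment$muscle) else
    c("iliopsoas_l", "iliopsoas_r")
  emg <- with_seed(derive_seed(config$seed, "emg"), {
    m <- matrix(rnorm(length(muscles) * n, sd = emg_noise_sd),
                nrow = length(muscles), dimnames = list(muscles, NULL))
    if (!is.null(commands) && nrow(commands) > 0L) {
      if (is.null(recruitment)) {
        abort("`commands` require a `recruitment` truth table.",
              class = "bsitools_config_error")
      }
      dur <- commands[["duration_s"]] %||% rep(0.3, nrow(commands))
      if (length(dur) == 1L) dur <- rep(dur, nrow(commands))
      for (i in seq_len(nrow(commands))) {
        rows <- recruitment[recruitment$config == commands$program[i], ]
        if (nrow(rows) == 0L) {
          abort(sprintf("No recruitment truth for program '%s'.",
                        commands$program[i]),
                class = "bsitools_config_error")
        }
        i0 <- max(1L, floor(commands$t[i] * fs) + 1L)
        i1 <- min(n, ceiling((commands$t[i] + dur[i]) * fs))
        if (i1 < i0) next
        for (j in seq_len(nrow(rows))) {
          gain <- recruitment_sigmoid(commands$amplitude_mA[i],
                                      rows$threshold[j], rows$saturation[j],
                                      rows$max_resp[j])
          if (gain <= 0) next
          mi <- match(rows$muscle[j], muscles)
          m[mi, i0:i1] <- m[mi, i0:i1] + gain * abs(rnorm(i1 - i0 + 1L))
        }
      }
    }
    m
  })

  knee <- matrix(170, nrow = 2L, ncol = n,
                 dimnames = list(c("left", "right"), NULL))
  step_truth <- tibble(onset_s = numeric(), step_length_cm = numeric(),
                       side = character(), failed = logical())
  if (!is.null(steps) && nrow(steps) > 0L) {
    side <- steps[["side"]] %||%
      rep(c("left", "right"), length.out = nrow(steps))
    dip_dur <- 1                            # s, raised-cosine knee dip
    dip_depth <- 60                         # deg: 170 -> 110, crosses 135
    for (i in seq_len(nrow(steps))) {
      i0 <- max(1L, round(steps$onset_s[i] * fs) + 1L)
      i1 <- min(n, i0 + round(dip_dur * fs) - 1L)
      if (i1 <= i0) next
      u <- seq(0, 1, length.out = i1 - i0 + 1L)
      r <- match(side[i], c("left", "right"))
      knee[r, i0:i1] <- knee[r, i0:i1] - dip_depth * (1 - cos(2 * pi * u)) / 2
    }
    step_truth <- tibble(onset_s = steps$onset_s,
                         step_length_cm = steps$step_length_cm,
                         side = side,
                         failed = steps$step_length_cm < 10)
  }

  structure(
    list(ecog = ecog, fs = fs, cues = cues, emg = emg, muscles = muscles,
         knee_angle = knee, steps = step_truth,
         truth = list(config = config, recruitment = recruitment)),
    class = "bsi_session"
  )
}

#' @export
print.bsi_session <- function(x, ...) {
  cat("<bsi_session> ", nrow(x$ecog), " channels x ", ncol(x$ecog),
      " samples @ ", x$fs, " Hz (", round(ncol(x$ecog) / x$fs, 1), " s)\n",
      sep = "")
  cat("  cue blocks: ", nrow(x$cues), "; muscles: ",
      paste(x$muscles, collapse = ", "), "; steps: ", nrow(x$steps),
      "\n", sep = "")
  invisible(x)
}
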