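#' Z-scored selectivity of muscle responses across configurations
#'
#' Muscle response amplitudes are normalized by z-scoring across all
#' electrode configurations (per muscle, and per period when a `period`
#' column is present). For each stimulation period the average absolute
#' z-score is reported, and a polar summary (per-muscle mean |z|) is
#' returned for a chosen configuration. Muscles with zero variance across
#' configurations get z = 0.
#'
#' @param responses Tibble with columns `config`, `muscle`, `response` and
#'   optionally `period` (and `amplitude`, treated as a period when
#'   `period` is absent).
#' @param polar_config Configuration id for the polar summary (default:
#'   the first).
#' @return List of class `bsi_selectivity`: `zscores` (input + `z`),
#'   `period_summary` (`config`, `period`, `mean_abs_z`), `polar`
#'   (`muscle`, `mean_abs_z` for `polar_config`).
#' @export
zscore_selectivity <- function(responses, polar_config = NULL) {
  if (length(unique(responses$config)) < 2L) {
    abort("Need at least two configurations to z-score across.",
          class = "bsitools_input_error")
  }
  if (!"period" %in% names(responses)) {
    responses$period <- if ("amplitude" %in% names(responses)) {
      responses$amplitude
    } else {
      1
    }
  }
  z <- dplyr::mutate(
    dplyr::group_by(responses, .data$muscle, .data$period),
    z = {
      s <- sd(.data$response)
      if (!is.finite(s) || s == 0) {
        rep(0, dplyr::n())
      } else {
        (.data$response - mean(.data$response)) / s
      }
    })
  z <- dplyr::ungroup(z)
  period_summary <- dplyr::summarise(
    dplyr::group_by(z, .data$config, .data$period),
    mean_abs_z = mean(abs(.data$z)), .groups = "drop")
  polar_config <- polar_config %||% z$config[1L]
  polar <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(z, .data$config == polar_config),
                    .data$muscle),
    mean_abs_z = mean(abs(.data$z)), .groups = "drop")
  structure(list(zscores = z, period_summary = period_summary,
                 polar = polar, polar_config = polar_config),
            class = "bsi_selectivity")
}

#' @export
print.bsi_selectivity <- function(x, ...) {
  cat("<bsi_selectivity> ", length(unique(x$zscores$config)),
      " configurations x ", length(unique(x$zscores$muscle)),
      " muscles\n", sep = "")
  invisible(x)
}

#' @param object A `bsi_selectivity`.
#' @param ... Unused.
#' @rdname zscore_selectivity
#' @export
autoplot.bsi_selectivity <- function(object, ...) {
  ggplot2::ggplot(object$polar,
                  ggplot2::aes(.data$muscle, .data$mean_abs_z)) +
    ggplot2::geom_col(width = 1, fill = "steelblue", alpha = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::labs(title = paste("Configuration", object$polar_config),
                  x = NULL, y = "mean |z|") +
    ggplot2::theme_minimal()
}

#' Estimate motor threshold and saturation from a recruitment curve
#'
#' Enforces monotonicity with an isotonic fit, then reads the amplitudes at
#' which the response first reaches 10% (motor threshold) and 90%
#' (saturation) of the maximum, by linear interpolation.
#'
#' @param amplitude Increasing amplitude grid (mA).
#' @param response Measured responses.
#' @return List: `threshold`, `saturation`, `max_resp` (isotonic maximum).
#' @export
fit_recruitment_curve <- function(amplitude, response) {
  iso <- isoreg(amplitude, response)$yf
  mx <- max(iso)
  if (mx <= 0) {
    return(list(threshold = NA_real_, saturation = NA_real_, max_resp = mx))
  }
  cross <- function(level) {
    i <- which(iso >= level)[1L]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(amplitude[1L])
    a0 <- amplitude[i - 1L]; a1 <- amplitude[i]
    y0 <- iso[i - 1L]; y1 <- iso[i]
    if (y1 == y0) return(a1)
    a0 + (level - y0) / (y1 - y0) * (a1 - a0)
  }
  list(threshold = cross(0.1 * mx), saturation = cross(0.9 * mx),
       max_resp = mx)
}

#' Grid search for the most selective stimulation configuration
#'
#' Explores the electrode configurations (and frequencies, when present)
#' of a recruitment data set and selects the one that maximizes the
#' selectivity of the target muscle group: the z-scored target response
#' minus the largest z-scored non-target response, at the best amplitude.
#' The amplitude range of the returned program is the `[motor threshold,
#' saturation]` interval estimated from the target's recruitment curve.
#' Equal scores break deterministically toward the lower threshold.
#'
#' @param responses Tibble: `config`, `muscle`, `amplitude`, `response`,
#'   optional `frequency_hz`.
#' @param target Target muscle label.
#' @param noise_level Responses are considered above noise when the
#'   target's isotonic maximum exceeds this (default 3 x the median
#'   absolute response at the lowest amplitude).
#' @param programs Optional tibble mapping `config` to electrode sets; when
#'   absent, placeholder electrodes are attached.
#' @return List of class `bsi_program_selection`: `viable`, `config`,
#'   `score`, `threshold`, `saturation`, `program` (a [stim_program()] row
#'   or `NULL`), and the per-configuration `scores` table.
#' @export
recruitment_grid_search <- function(responses, target, noise_level = NULL,
                                    programs = NULL) {
  if (!target %in% responses$muscle) {
    abort(sprintf("Target muscle '%s' absent from responses.", target),
          class = "bsitools_input_error")
  }
  sel <- zscore_selectivity(responses)
  z <- sel$zscores
  per_cfg_amp <- dplyr::summarise(
    dplyr::group_by(z, .data$config, .data$period),
    score = {
      zt <- .data$z[.data$muscle == target]
      zn <- .data$z[.data$muscle != target]
      if (length(zt) == 0L) -Inf else
        mean(zt) - if (length(zn)) max(zn) else 0
    },
    .groups = "drop")
  scores <- dplyr::summarise(dplyr::group_by(per_cfg_amp, .data$config),
                             score = max(.data$score), .groups = "drop")

  if (is.null(noise_level)) {
    a0 <- min(responses$amplitude)
    noise_level <- 3 * median(abs(responses$response[
      responses$amplitude == a0]))
  }
  curves <- dplyr::group_by(
    dplyr::filter(responses, .data$muscle == target), .data$config)
  curves <- dplyr::summarise(
    curves,
    fit = list(fit_recruitment_curve(.data$amplitude, .data$response)),
    .groups = "drop")
  curves$max_resp <- purrr::map_dbl(curves$fit, "max_resp")
  curves$threshold <- purrr::map_dbl(curves$fit, "threshold")
  curves$saturation <- purrr::map_dbl(curves$fit, "saturation")
  tab <- dplyr::left_join(scores, dplyr::select(curves, -"fit"),
                          by = "config")
  viable_tab <- dplyr::filter(tab, .data$max_resp > noise_level,
                              is.finite(.data$score),
                              is.finite(.data$threshold),
                              is.finite(.data$saturation),
                              .data$threshold < .data$saturation)
  if (nrow(viable_tab) == 0L) {
    return(structure(list(viable = FALSE, config = NA_character_,
                          score = NA_real_, threshold = NA_real_,
                          saturation = NA_real_, program = NULL,
                          scores = tab),
                     class = "bsi_program_selection"))
  }
  best <- dplyr::arrange(viable_tab, dplyr::desc(.data$score),
                         .data$threshold, .data$config)[1L, ]
  prog <- NULL
  if (!is.null(programs) && best$config %in% programs$config) {
    pr <- programs[programs$config == best$config, ][1L, ]
    prog <- stim_program(best$config, pr$cathodes[[1L]], pr$anodes[[1L]],
                         pr[["frequency_hz"]] %||% 40,
                         pr[["pulse_width_us"]] %||% 300,
                         c(best$threshold, best$saturation), target)
  } else {
    prog <- stim_program(best$config, cathodes = 0L, anodes = 1L,
                         amplitude_range = c(best$threshold,
                                             best$saturation),
                         target = target)
  }
  structure(list(viable = TRUE, config = best$config, score = best$score,
                 threshold = best$threshold, saturation = best$saturation,
                 program = prog, scores = tab),
            class = "bsi_program_selection")
}

#' @export
print.bsi_program_selection <- function(x, ...) {
  if (!x$viable) {
    cat("<bsi_program_selection> no viable program\n")
  } else {
    cat("<bsi_program_selection> config ", x$config, " (score ",
        round(x$score, 3), "), amplitude range [",
        round(x$threshold, 2), ", ", round(x$saturation, 2), "] mA\n",
        sep = "")
  }
  invisible(x)
}
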