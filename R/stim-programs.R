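#' Define an epidural stimulation program
#'
#' A program fixes the electrode configuration (cathodes/anodes on the
#' 16-contact paddle), pulse frequency, pulse width and the amplitude range
#' the controllers may command, for one target joint or muscle group.
#'
#' @param id Program identifier.
#' @param cathodes,anodes Disjoint, non-empty subsets of electrode indices
#'   0-15.
#' @param frequency_hz Pulse frequency (e.g. 40).
#' @param pulse_width_us Pulse width in microseconds (e.g. 300).
#' @param amplitude_range `c(A_min, A_max)` in mA with `0 <= A_min < A_max`
#'   (e.g. `c(14, 16)`).
#' @param target Target joint/muscle label (decoder state it serves).
#' @return One-row tibble of class `bsi_stim_program` with list-columns for
#'   the electrode sets.
#' @export
stim_program <- function(id, cathodes, anodes, frequency_hz = 40,
                         pulse_width_us = 300, amplitude_range = c(14, 16),
                         target = NA_character_) {
  cathodes <- as.integer(cathodes)
  anodes <- as.integer(anodes)
  if (length(cathodes) == 0L || length(anodes) == 0L ||
      length(intersect(cathodes, anodes)) > 0L) {
    abort("Cathode and anode sets must be non-empty and disjoint.",
          class = "bsitools_config_error")
  }
  if (any(c(cathodes, anodes) < 0L) || any(c(cathodes, anodes) > 15L)) {
    abort("Electrode indices must lie in 0-15.",
          class = "bsitools_config_error")
  }
  if (length(amplitude_range) != 2L || amplitude_range[1] < 0 ||
      amplitude_range[1] >= amplitude_range[2]) {
    abort("`amplitude_range` must satisfy 0 <= A_min < A_max.",
          class = "bsitools_config_error")
  }
  out <- tibble(id = id, cathodes = list(cathodes), anodes = list(anodes),
                frequency_hz = frequency_hz, pulse_width_us = pulse_width_us,
                a_min = amplitude_range[1], a_max = amplitude_range[2],
                target = target)
  class(out) <- c("bsi_stim_program", class(out))
  out
}

#' Save / load a stimulation-program library as JSON
#'
#' @param programs Tibble of programs (rows from [stim_program()]).
#' @param path JSON file path.
#' @return `read_program_library()` returns the program tibble.
#' @export
write_program_library <- function(programs, path) {
  recs <- purrr::map(seq_len(nrow(programs)), function(i) {
    list(id = programs$id[i],
         cathodes = programs$cathodes[[i]], anodes = programs$anodes[[i]],
         frequency_hz = programs$frequency_hz[i],
         pulse_width_us = programs$pulse_width_us[i],
         amplitude_range = c(programs$a_min[i], programs$a_max[i]),
         target = programs$target[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_program_library
#' @param path JSON file path.
#' @export
read_program_library <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(recs, function(r) {
    stim_program(r$id, unlist(r$cathodes), unlist(r$anodes),
                 r$frequency_hz, r$pulse_width_us,
                 unlist(r$amplitude_range), r$target %||% NA_character_)
  })
}
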