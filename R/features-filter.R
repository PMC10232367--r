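#' Zero-phase band-pass preprocessing of raw ECoG
#'
#' Applies a 4th-order Butterworth band-pass (1-300 Hz nominal) forward and
#' backward per channel, removing DC/drift and out-of-band energy without
#' phase distortion. The upper edge is capped at `0.99 * fs / 2` so the
#' nominal 300 Hz passband remains realizable at 586 Hz sampling.
#'
#' @param ecog Numeric matrix, channels x samples (a vector is treated as
#'   one channel).
#' @param fs Sampling rate in Hz.
#' @param low,high Passband edges in Hz (defaults 1 and 300).
#' @param order Butterworth order per edge (default 4).
#' @return Filtered matrix of the same shape, with `fs` attribute.
#' @export
preprocess_ecog <- function(ecog, fs = attr(ecog, "fs"), low = 1, high = 300,
                            order = 4L) {
  if (is.vector(ecog)) ecog <- matrix(ecog, nrow = 1L)
  stopifnot_scalar_number(fs, "fs")
  high <- min(high, 0.99 * fs / 2)
  if (low <= 0 || low >= high) {
    abort("Invalid passband.", class = "bsitools_config_error")
  }
  # filtfilt needs comfortably more samples than the filter warm-up.
  if (ncol(ecog) < 6L * (2L * order + 1L)) {
    abort("Signal shorter than the filter warm-up.",
          class = "bsitools_input_error")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(ecog, 1L, function(ch) signal::filtfilt(bf, ch)))
  dimnames(out) <- dimnames(ecog)
  attr(out, "fs") <- fs
  out
}
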