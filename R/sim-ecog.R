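#' Simulate multichannel ECoG with state-locked band-power modulation
#'
#' Generates coloured Gaussian background noise (power spectral density
#' proportional to `1/f^background_exponent`) on every channel and, during
#' active cue blocks, adds independent band-limited noise on the configured
#' informative channels so that the *power* in the configured band is
#' multiplied by the configured gain relative to rest.
#'
#' Because the added component is independent of the background, band powers
#' add: a gain `g` is realized by injecting band-limited noise with variance
#' `(g - 1)` times the background's variance in that band.
#'
#' @param config A [sim_config()].
#' @param cues Block cue tibble from [make_cue_sequence()].
#' @return Numeric matrix, channels x samples (arbitrary microvolt scale),
#'   with attributes `fs` and `t`.
#' @export
simulate_ecog <- function(config, cues) {
  stopifnot(inherits(config, "bsi_sim_config"))
  fs <- config$fs
  n <- round(sum(cues$duration_s) * fs)
  if (n < 2L) abort("Cue track too short.", class = "bsitools_config_error")
  nch <- config$n_channels

  # Symmetric spectral amplitude shaping for the 1/f background, unit
  # overall variance. DC removed; amplitudes floored below 0.5 Hz.
  freqs <- fft_bin_freqs(n, fs)
  a <- pmax(abs(freqs), 0.5)^(-config$background_exponent / 2)
  a[1L] <- 0
  a <- a / sqrt(mean(a^2))

  labels <- expand_cues(cues, fs, n)
  bands <- ecog_bands()

  with_seed(derive_seed(config$seed, "ecog"), {
    ecog <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      ecog[ch, ] <- Re(fft(fft(rnorm(n)) * a, inverse = TRUE)) / n
    }
    imap <- config$informative_map
    if (nrow(imap) > 0L) {
      for (i in seq_len(nrow(imap))) {
        gain <- imap$gain[i]
        if (abs(gain - 1) < .Machine$double.eps) next
        band <- bands[[imap$band[i]]]
        mask <- as.numeric(abs(freqs) >= band[1] & abs(freqs) < band[2])
        gate <- as.numeric(labels == imap$state[i])
        ch <- imap$channel[i]
        if (gain >= 1) {
          # Independent band-limited noise with variance (gain-1) x the
          # background's band power.
          bg_band_var <- mean((a * mask)^2)
          y <- Re(fft(fft(rnorm(n)) * mask, inverse = TRUE)) / n
          y <- y / sqrt(mean(mask)) * sqrt((gain - 1) * bg_band_var)
        } else {
          # Power suppression: attenuate the background's own band
          # component so its power scales by `gain` during active blocks.
          b <- Re(fft(fft(ecog[ch, ]) * mask, inverse = TRUE)) / n
          y <- (sqrt(gain) - 1) * b
        }
        ecog[ch, ] <- ecog[ch, ] + y * gate
      }
    }
    if (!is.null(config$line_noise_hz)) {
      tvec <- (seq_len(n) - 1) / fs
      line <- 0.2 * sin(2 * pi * config$line_noise_hz * tvec)
      ecog <- sweep(ecog, 2L, line, `+`)
    }
    attr(ecog, "fs") <- fs
    attr(ecog, "t") <- (seq_len(n) - 1) / fs
    ecog
  })
}

# Signed FFT bin frequencies for an n-point transform at rate fs.
fft_bin_freqs <- function(n, fs) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}
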