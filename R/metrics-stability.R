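#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed segments (default 2 s,
#' 50% overlap), one-sided density scaling so that the integral of the PSD
#' over frequency equals the signal variance.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Tibble: `freq` (Hz), `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) {
    abort("Signal shorter than one Welch segment.",
          class = "bsitools_input_error")
  }
  stepn <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = stepn)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)) # Hann
  U <- sum(w^2)
  half <- nseg %/% 2 + 1L
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)] * w
    P <- Mod(fft(seg))^2
    acc <- acc + P[seq_len(half)]
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when nseg even)
  dbl <- rep(2, half)
  dbl[1L] <- 1
  if (nseg %% 2 == 0) dbl[half] <- 1
  tibble(freq = (seq_len(half) - 1L) * fs / nseg, psd = psd * dbl)
}

band_power_from_psd <- function(psd_tab, lo, hi) {
  df <- psd_tab$freq[2L] - psd_tab$freq[1L]
  sum(psd_tab$psd[psd_tab$freq >= lo & psd_tab$freq < hi]) * df
}

#' Resting-state ECoG signal stability
#'
#' Quantifies signal power of a resting recording over a 90 s analysis
#' window starting 20 s after onset: Welch PSD per channel, root mean
#' square over 0.5-292 Hz, band powers for the four canonical bands
#' (normalized by bandwidth before conversion to dB) and per-band SNR
#' against the 250-260 Hz noise band — all averaged across electrodes.
#'
#' @param ecog Channels x samples matrix (vector = one channel).
#' @param fs Sampling rate (Hz).
#' @param start_s Analysis window start (default 20 s).
#' @param dur_s Analysis window length (default 90 s).
#' @param seg_s,overlap Welch settings (2 s Hann, 50%).
#' @return List of class `bsi_stability`: `rms` (electrode-averaged),
#'   `bands` tibble (`band`, `power` linear, `power_db` bandwidth
#'   normalized, `snr_db`), and `noise_power` (250-260 Hz density).
#' @export
signal_stability <- function(ecog, fs, start_s = 20, dur_s = 90,
                             seg_s = 2, overlap = 0.5) {
  if (is.vector(ecog)) ecog <- matrix(ecog, nrow = 1L)
  if (ncol(ecog) / fs < start_s + dur_s) {
    abort(sprintf("Recording must be at least %g s.", start_s + dur_s),
          class = "bsitools_input_error")
  }
  idx <- (round(start_s * fs) + 1L):round((start_s + dur_s) * fs)
  bands <- ecog_bands()
  per_ch <- purrr::map_dfr(seq_len(nrow(ecog)), function(ch) {
    pt <- welch_psd(ecog[ch, idx], fs, seg_s, overlap)
    bp <- purrr::map_dbl(bands, ~band_power_from_psd(pt, .x[1], .x[2]))
    tibble(channel = ch,
           rms = sqrt(band_power_from_psd(pt, 0.5, 292)),
           band = names(bands), power = unname(bp),
           noise = band_power_from_psd(pt, 250, 260) / 10) # per-Hz density
  })
  bandwidth <- purrr::map_dbl(bands, ~diff(.x))
  avg <- dplyr::summarise(dplyr::group_by(per_ch, .data$band),
                          power = mean(.data$power),
                          noise = mean(.data$noise), .groups = "drop")
  avg <- avg[match(names(bands), avg$band), ]
  avg$power_norm <- avg$power / bandwidth
  avg$power_db <- 10 * log10(avg$power_norm)
  avg$snr_db <- ifelse(avg$noise > 0,
                       10 * log10(avg$power_norm / avg$noise), NA_real_)
  structure(
    list(rms = mean(per_ch$rms[!duplicated(per_ch$channel)]),
         bands = dplyr::select(avg, "band", "power", "power_db", "snr_db"),
         noise_power = mean(avg$noise)),
    class = "bsi_stability"
  )
}

#' @export
print.bsi_stability <- function(x, ...) {
  cat("<bsi_stability> rms ", signif(x$rms, 4), "\n", sep = "")
  print(x$bands)
  invisible(x)
}

#' @param x A `bsi_stability`.
#' @param ... Unused.
#' @rdname signal_stability
#' @export
tidy.bsi_stability <- function(x, ...) x$bands

#' @rdname signal_stability
#' @export
glance.bsi_stability <- function(x, ...) {
  tibble(rms = x$rms, noise_power = x$noise_power)
}

# Full-signal |CWT| at the canonical frequencies via FFT convolution with
# zero padding (offline spectrograms; the causal decoder path uses the
# epoch-based operators instead).
cwt_mag_full <- function(x, fs, freqs = ccwt_freqs(), omega0 = 6) {
  n <- length(x)
  hw <- min(n, max(3L, ceiling(4 * omega0 / (2 * pi * min(freqs)) * fs)))
  m <- stats::nextn(n + 2L * hw, 2L)
  X <- fft(c(x, numeric(m - n)))
  out <- matrix(0, nrow = length(freqs), ncol = n)
  for (f in seq_along(freqs)) {
    sigma <- omega0 / (2 * pi * freqs[f])
    offs <- seq(-hw, hw)
    kern <- exp(-(offs / fs)^2 / (2 * sigma^2)) *
      exp(complex(imaginary = -2 * pi * freqs[f] * offs / fs))
    kern <- kern / sqrt(sum(Mod(kern)^2))
    kv <- complex(real = numeric(m))
    kv[((offs) %% m) + 1L] <- kern
    conv <- fft(X * fft(kv), inverse = TRUE) / m
    out[f, ] <- Mod(conv[seq_len(n)])
  }
  rownames(out) <- paste0("f", freqs)
  out
}

#' Z-scored wavelet spectrogram
#'
#' Continuous wavelet magnitudes at the 24 canonical frequencies, averaged
#' over 500 ms windows advanced every 100 ms, then z-scored over time
#' within each frequency band. Constant bands are set to zero.
#'
#' @param x Signal vector (or channels x samples matrix, averaged).
#' @param fs Sampling rate (Hz).
#' @param window_s Averaging window (default 0.5 s).
#' @param step_s Frame step (default 0.1 s).
#' @return List of class `bsi_spectrogram`: `z` (freq x frames), `raw`,
#'   `t` (frame right edges), `freqs`.
#' @export
zscored_spectrogram <- function(x, fs, window_s = 0.5, step_s = 0.1) {
  if (is.matrix(x)) x <- colMeans(x)
  if (length(x) < round(window_s * fs)) {
    abort("Signal shorter than one spectrogram window.",
          class = "bsitools_input_error")
  }
  mag <- cwt_mag_full(x, fs)
  fr <- frame_average(mag, fs, window_s, step_s)
  z <- t(apply(fr$S, 1L, function(row) {
    s <- sd(row)
    if (!is.finite(s) || s == 0) rep(0, length(row)) else
      (row - mean(row)) / s
  }))
  structure(list(z = z, raw = fr$S, t = fr$t, freqs = ccwt_freqs()),
            class = "bsi_spectrogram")
}

# Average columns of a (freq x samples) magnitude matrix over sliding
# windows: frame j covers (t_j - window, t_j].
frame_average <- function(mag, fs, window_s, step_s) {
  n <- ncol(mag)
  nw <- round(window_s * fs)
  ends_t <- seq(window_s, n / fs + 1e-9, by = step_s)
  ends_i <- round(ends_t * fs)
  ends_t <- ends_t[ends_i <= n]
  ends_i <- ends_i[ends_i <= n]
  S <- vapply(ends_i, function(e) {
    rowMeans(mag[, (e - nw + 1L):e, drop = FALSE])
  }, numeric(nrow(mag)))
  list(S = matrix(S, nrow = nrow(mag)), t = ends_t)
}

#' @param object A `bsi_spectrogram`.
#' @param ... Unused.
#' @rdname zscored_spectrogram
#' @export
autoplot.bsi_spectrogram <- function(object, ...) {
  df <- tibble(t = rep(object$t, each = length(object$freqs)),
               freq = rep(object$freqs, times = length(object$t)),
               z = as.vector(object$z))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, factor(.data$freq),
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-0.5, 0.5),
                                  oob = scales_squish) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "z") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid a scales dependency in Imports
scales_squish <- function(x, range = c(-0.5, 0.5)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Reinforcement of movement-related cortical features over time
#'
#' For each electrode and each of several time periods, computes the
#' median event-locked spectrogram (default -2 s to +2 s around each
#' event), takes its standard deviation over all time-frequency entries as
#' the modulation depth, and fits a single linear trend of modulation
#' versus period index pooled over electrodes. A positive slope indicates
#' reinforcement of the cortical features with practice.
#'
#' @param ecog Channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param events List of event-time vectors (seconds), one per period
#'   (clinically 4 periods of 100 events; configurable).
#' @param half_window_s Half window around each event (default 2 s).
#' @param window_s,step_s Spectrogram frame settings (0.5 s / 0.1 s).
#' @return List of class `bsi_reinforcement`: `modulation` tibble
#'   (`electrode`, `period`, `sd`), `slope`, `fit` (the pooled `lm`).
#' @export
feature_reinforcement <- function(ecog, fs, events, half_window_s = 2,
                                  window_s = 0.5, step_s = 0.1) {
  if (is.vector(ecog)) ecog <- matrix(ecog, nrow = 1L)
  if (length(events) < 1L || all(lengths(events) == 0L)) {
    abort("No events supplied.", class = "bsitools_input_error")
  }
  n_periods <- length(events)
  rows <- list()
  for (ch in seq_len(nrow(ecog))) {
    mag <- cwt_mag_full(ecog[ch, ], fs)
    fr <- frame_average(mag, fs, window_s, step_s)
    for (p in seq_len(n_periods)) {
      evs <- events[[p]]
      mats <- purrr::map(evs, function(e) {
        inw <- fr$t >= e - half_window_s & fr$t <= e + half_window_s
        if (!any(inw)) return(NULL)
        fr$S[, inw, drop = FALSE]
      })
      mats <- purrr::compact(mats)
      if (length(mats) == 0L) next
      nc <- min(purrr::map_int(mats, ncol))
      arr <- simplify2array(purrr::map(mats, ~.x[, seq_len(nc),
                                                 drop = FALSE]))
      med <- apply(arr, c(1L, 2L), median)
      rows[[length(rows) + 1L]] <-
        tibble(electrode = ch, period = p, sd = sd(as.vector(med)))
    }
  }
  modulation <- dplyr::bind_rows(rows)
  fit <- lm(sd ~ period, data = modulation)
  structure(list(modulation = modulation,
                 slope = unname(coef(fit)[["period"]]), fit = fit),
            class = "bsi_reinforcement")
}

#' @export
print.bsi_reinforcement <- function(x, ...) {
  cat("<bsi_reinforcement> slope ", signif(x$slope, 4), " per period (",
      length(unique(x$modulation$electrode)), " electrodes, ",
      length(unique(x$modulation$period)), " periods)\n", sep = "")
  invisible(x)
}

#' @param x A `bsi_reinforcement`.
#' @param ... Unused.
#' @rdname feature_reinforcement
#' @export
tidy.bsi_reinforcement <- function(x, ...) x$modulation

#' @rdname feature_reinforcement
#' @export
glance.bsi_reinforcement <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(slope = x$slope,
         slope_se = sm$coefficients["period", "Std. Error"],
         p_value = sm$coefficients["period", "Pr(>|t|)"])
}
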