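#' Wavelet centre frequencies of the decoder front end
#'
#' The fixed 24-bin frequency axis of the feature tensor:
#' 2, 5, 10, ..., 100, 125, 150, 200 Hz. Any other axis is a hard error
#' throughout the package.
#'
#' @return Numeric vector of length 24 (Hz).
#' @export
ccwt_freqs <- function() c(2, seq(5, 100, by = 5), 125, 150, 200)

assert_ccwt_freqs <- function(freqs) {
  if (length(freqs) != 24L || !isTRUE(all.equal(freqs, ccwt_freqs()))) {
    abort("The frequency axis must be exactly the 24 canonical bins.",
          class = "bsitools_config_error")
  }
}

# Operator cache: complex Morlet transforms of a reflect-padded epoch are
# linear maps of the epoch, so for a fixed (epoch length, fs) we prebuild
# the n x (24 n) real/imaginary matrices once and reuse them for every
# epoch and every channel.
.ccwt_cache <- new.env(parent = emptyenv())

ccwt_operator <- function(n, fs, omega0 = 6, freqs = ccwt_freqs()) {
  assert_ccwt_freqs(freqs)
  key <- paste(n, fs, omega0, sep = "_")
  hit <- .ccwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n / fs < 1 / min(freqs) - 1e-9) {
    warn(sprintf(
      "Epoch (%.0f ms) is shorter than one cycle of the lowest frequency (%g Hz); low-frequency coefficients rely on reflection padding.",
      1000 * n / fs, min(freqs)))
  }
  nf <- length(freqs)
  Mre <- matrix(0, nrow = n, ncol = nf * n)
  Mim <- matrix(0, nrow = n, ncol = nf * n)
  jj <- seq_len(n)
  # Offset matrices for the three terms of the reflect-padding operator:
  # CWT_i = sum_j e_j [k(j - i) + k(1 - j - i) + k(2n + 1 - j - i)].
  D1 <- outer(jj, jj, `-`)            # middle copy
  D2 <- outer(1 - jj, jj, `-`)        # left reflection
  D3 <- outer(2 * n + 1 - jj, jj, `-`)  # right reflection
  offs <- seq(-(3 * n), 3 * n)        # covers all three offset ranges
  for (f in seq_len(nf)) {
    sigma <- omega0 / (2 * pi * freqs[f])
    tau <- offs / fs
    kern <- exp(-tau^2 / (2 * sigma^2)) *
      exp(complex(imaginary = -2 * pi * freqs[f] * tau))
    kern <- kern / sqrt(sum(Mod(kern)^2))
    lut <- function(D) matrix(kern[D + 3 * n + 1L], nrow = n)
    Kf <- lut(D1) + lut(D2) + lut(D3)
    cols <- (f - 1L) * n + jj
    Mre[, cols] <- Re(Kf)
    Mim[, cols] <- Im(Kf)
  }
  op <- list(Mre = Mre, Mim = Mim, n = n, fs = fs, freqs = freqs,
             omega0 = omega0)
  .ccwt_cache[[key]] <- op
  op
}

# Averaging decimation matrix: n positions -> n_taps contiguous block
# means (anti-aliasing by averaging rather than naive subsampling).
tap_matrix <- function(n, n_taps) {
  brk <- floor(seq(0, n, length.out = n_taps + 1L))
  Tm <- matrix(0, nrow = n, ncol = n_taps)
  for (k in seq_len(n_taps)) {
    idx <- (brk[k] + 1L):brk[k + 1L]
    Tm[idx, k] <- 1 / length(idx)
  }
  Tm
}

# |CWT| of a stack of epochs (rows) for every centre frequency, decimated
# to n_taps block means. Returns n_epochs x (nf * n_taps), frequency-major.
ccwt_magnitudes <- function(E, fs, n_taps, omega0 = 6) {
  n <- ncol(E)
  op <- ccwt_operator(n, fs, omega0)
  Cre <- E %*% op$Mre
  Cim <- E %*% op$Mim
  mag <- sqrt(Cre * Cre + Cim * Cim)
  Tm <- tap_matrix(n, n_taps)
  nf <- length(op$freqs)
  out <- matrix(0, nrow = nrow(E), ncol = nf * n_taps)
  for (f in seq_len(nf)) {
    out[, (f - 1L) * n_taps + seq_len(n_taps)] <-
      mag[, (f - 1L) * n + seq_len(n), drop = FALSE] %*% Tm
  }
  out
}

#' Complex Morlet wavelet features of one epoch
#'
#' Maps a single multichannel epoch to the decoder's feature tensor: the
#' magnitude of the complex continuous wavelet transform (Morlet,
#' `omega0 = 6`) at the 24 canonical centre frequencies, decimated along
#' time to `n_taps` contiguous block means. The epoch is reflect-padded at
#' both edges, so the transform uses no samples outside the epoch.
#'
#' @param epoch Numeric matrix, channels x samples (vector = one channel).
#' @param fs Sampling rate in Hz.
#' @param n_taps Temporal taps to retain, 2-5 (default 5).
#' @param omega0 Morlet centre parameter (default 6).
#' @return Array channels x 24 x n_taps of non-negative magnitudes.
#' @export
ccwt_epoch_features <- function(epoch, fs, n_taps = 5L, omega0 = 6) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1L)
  n_taps <- as.integer(n_taps)
  if (n_taps < 2L || n_taps > 5L) {
    abort("`n_taps` must be between 2 and 5.", class = "bsitools_config_error")
  }
  len_ms <- 1000 * ncol(epoch) / fs
  if (len_ms < 200 - 1e-6 || len_ms > 500 + 1e-6) {
    abort("Epoch length must lie in [200, 500] ms.",
          class = "bsitools_config_error")
  }
  mags <- ccwt_magnitudes(epoch, fs, n_taps, omega0)
  nf <- length(ccwt_freqs())
  out <- array(0, dim = c(nrow(epoch), nf, n_taps))
  for (f in seq_len(nf)) {
    out[, f, ] <- mags[, (f - 1L) * n_taps + seq_len(n_taps), drop = FALSE]
  }
  dimnames(out) <- list(NULL, paste0("f", ccwt_freqs()), NULL)
  out
}

#' Sliding-window feature stream at the decoder cadence
#'
#' Computes one feature tensor per 100 ms step. The tensor timestamped `t`
#' is computed from the epoch `(t - epoch_s, t]` only (reflect-padded
#' within the epoch), so features are causal: appending future samples
#' never changes them.
#'
#' @param ecog Channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch length in seconds, 0.2-0.5 (default 0.5).
#' @param step_s Window step in seconds (default 0.1).
#' @param n_taps Temporal taps (default 5).
#' @param omega0 Morlet centre parameter (default 6).
#' @param chunk Windows processed per block matrix product (memory knob).
#' @return Object of class `bsi_features`: list with `x` (windows x F
#'   matrix; F = channels * 24 * n_taps, channel-major then frequency then
#'   tap), `t` (right-edge timestamps), `n_channels`, `freqs`, `n_taps`,
#'   `epoch_s`, `fs` and `config_hash`.
#' @export
feature_stream <- function(ecog, fs = attr(ecog, "fs"), epoch_s = 0.5,
                           step_s = 0.1, n_taps = 5L, omega0 = 6,
                           chunk = 2048L) {
  if (is.vector(ecog)) ecog <- matrix(ecog, nrow = 1L)
  stopifnot_scalar_number(fs, "fs")
  if (epoch_s < 0.2 - 1e-9 || epoch_s > 0.5 + 1e-9) {
    abort("`epoch_s` must lie in [0.2, 0.5] s.",
          class = "bsitools_config_error")
  }
  n_taps <- as.integer(n_taps)
  if (n_taps < 2L || n_taps > 5L) {
    abort("`n_taps` must be between 2 and 5.", class = "bsitools_config_error")
  }
  n <- ncol(ecog)
  n_ep <- round(epoch_s * fs)
  total_s <- n / fs
  ends_t <- if (total_s + 1e-9 >= epoch_s) {
    seq(epoch_s, total_s + 1e-9, by = step_s)
  } else {
    numeric(0)
  }
  ends_t <- ends_t[round(ends_t * fs) <= n + 1e-9]
  n_win <- length(ends_t)
  nf <- length(ccwt_freqs())
  Fdim <- nrow(ecog) * nf * n_taps
  feats <- matrix(0, nrow = n_win, ncol = Fdim)
  if (n_win > 0L) {
    ends_i <- round(ends_t * fs)
    per_ch <- nf * n_taps
    for (ch in seq_len(nrow(ecog))) {
      cols <- (ch - 1L) * per_ch + seq_len(per_ch)
      for (c0 in seq(1L, n_win, by = chunk)) {
        c1 <- min(n_win, c0 + chunk - 1L)
        idx <- outer(ends_i[c0:c1] - n_ep, seq_len(n_ep), `+`)
        E <- matrix(ecog[ch, idx], nrow = c1 - c0 + 1L)
        feats[c0:c1, cols] <- ccwt_magnitudes(E, fs, n_taps, omega0)
      }
    }
  }
  structure(
    list(x = feats, t = ends_t, n_channels = nrow(ecog),
         freqs = ccwt_freqs(), n_taps = n_taps, epoch_s = epoch_s,
         step_s = step_s, fs = fs,
         config_hash = feature_config_hash(nrow(ecog), fs, epoch_s, n_taps,
                                           omega0)),
    class = "bsi_features"
  )
}

feature_config_hash <- function(n_channels, fs, epoch_s, n_taps, omega0) {
  fnv1a32_hex(c(n_channels, fs, epoch_s, n_taps, omega0, ccwt_freqs()))
}

#' @export
print.bsi_features <- function(x, ...) {
  cat("<bsi_features> ", nrow(x$x), " windows x ", ncol(x$x),
      " features (", x$n_channels, " ch x 24 freq x ", x$n_taps,
      " taps), epoch ", 1000 * x$epoch_s, " ms @ ", 1000 * x$step_s,
      " ms cadence\n", sep = "")
  invisible(x)
}

# Map flat feature indices back to (channel, frequency, tap); used for
# weight projections and the informative-channel concentration checks.
feature_index_table <- function(n_channels, n_taps) {
  nf <- length(ccwt_freqs())
  tidyr::expand_grid(channel = seq_len(n_channels),
                     freq = ccwt_freqs(),
                     tap = seq_len(n_taps))
}
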