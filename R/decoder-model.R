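#' Create an (uninitialized) Markov-switching multilinear decoder
#'
#' The decoder couples a *gate* — a linear discriminative classifier whose
#' scores pass through a softmax and are then filtered by a hidden-Markov
#' transition model — with per-state linear *experts* that regress the
#' continuous movement command. Coefficients start at zero (uniform state
#' probabilities, zero commands) and are learned online by
#' [calibrate_online()] / [rew_update()].
#'
#' @param states State labels; the first entry is the rest state, whose
#'   expert is fixed at zero output.
#' @param features A `bsi_features` object, or a list with fields
#'   `n_channels`, `fs`, `epoch_s`, `n_taps` describing the front end the
#'   model is bound to. Models refuse to decode feature streams whose
#'   configuration fingerprint differs.
#' @param lambda Forgetting factor per 15 s batch, in (0, 1] (default 0.99).
#' @param method Coefficient fit from the decayed cross-moment
#'   accumulators: `"pls"` (default) extracts `n_comp` latent partial
#'   least squares components (SIMPLS on the moments — the estimator
#'   family designed for this decoder, robust to the strong collinearity
#'   of wavelet features); `"ls"` solves the normal equations directly
#'   with a ridge fallback on rank deficiency (equals the pooled
#'   least-squares fit at `lambda = 1`).
#' @param n_comp Latent components for `method = "pls"` (default 30; with
#'   `n_comp >= rank(X)` the PLS fit reproduces least squares).
#' @param ridge_rel Relative ridge used by `method = "ls"` when the
#'   accumulated cross-moments are rank deficient (default 1e-4 of the
#'   mean diagonal).
#' @param trans_eps Transition smoothing pseudo-count added to every cell
#'   before row normalization (default 1).
#' @param batch_s Update batch length in seconds (default 15).
#' @param Fdim Explicit feature dimension; an alternative to `features`
#'   for models operating on generic flattened regressors (used by the
#'   recursive-fit oracles and unit problems).
#' @return Object of class `bsi_mslm`.
#' @export
mslm_model <- function(states = c("rest", "hipL", "kneeL", "ankleL",
                                  "hipR", "kneeR", "ankleR"),
                       features = NULL, lambda = 0.99,
                       method = c("pls", "ls"), n_comp = 30L,
                       ridge_rel = 1e-4, trans_eps = 1, batch_s = 15,
                       Fdim = NULL) {
  method <- match.arg(method)
  if (lambda <= 0 || lambda > 1) {
    abort("`lambda` must lie in (0, 1].", class = "bsitools_config_error")
  }
  K <- length(states)
  if (K < 2L) abort("Need at least two states.",
                    class = "bsitools_config_error")
  if (is.null(features) && is.null(Fdim)) {
    abort("Provide `features` or `Fdim`.", class = "bsitools_config_error")
  }
  if (!is.null(features)) {
    feat <- list(n_channels = features$n_channels, fs = features$fs,
                 epoch_s = features$epoch_s, n_taps = features$n_taps,
                 omega0 = features$omega0 %||% 6,
                 step_s = features$step_s %||% 0.1)
    feat$config_hash <- features$config_hash %||%
      feature_config_hash(feat$n_channels, feat$fs, feat$epoch_s,
                          feat$n_taps, feat$omega0)
    Fdim <- feat$n_channels * length(ccwt_freqs()) * feat$n_taps
  } else {
    feat <- list(n_channels = NA_integer_, fs = NA_real_, epoch_s = NA_real_,
                 n_taps = NA_integer_, omega0 = 6, step_s = 0.1,
                 config_hash = fnv1a32_hex(c("generic", Fdim)))
  }
  structure(
    list(states = states, K = K, Fdim = Fdim, feat = feat,
         beta_gate = matrix(0, K, Fdim), b_gate = numeric(K),
         trans_counts = matrix(0, K, K, dimnames = list(states, states)),
         trans_eps = trans_eps,
         beta_exp = matrix(0, K, Fdim), b_exp = numeric(K),
         calib = list(lambda = lambda, method = method,
                      n_comp = as.integer(n_comp), ridge_rel = ridge_rel,
                      batch_s = batch_s,
                      Sxx = matrix(0, Fdim, Fdim),
                      Sxy_gate = matrix(0, Fdim, K),
                      Sxy_exp = matrix(0, Fdim, K),
                      sx = numeric(Fdim), sy_gate = numeric(K),
                      sy_exp = numeric(K), sw = 0,
                      n_updates = 0L, ridge_events = 0L)),
    class = "bsi_mslm"
  )
}

#' @export
print.bsi_mslm <- function(x, ...) {
  cat("<bsi_mslm> ", x$K, " states (", paste(x$states, collapse = ", "),
      "), ", x$Fdim, " features\n", sep = "")
  cat("  updates: ", x$calib$n_updates, "; lambda ", x$calib$lambda,
      "; transition mass ", sum(x$trans_counts), "\n", sep = "")
  invisible(x)
}

#' Row-stochastic transition matrix from cumulative counts
#'
#' Adds `eps` pseudo-counts to every cell (preventing absorbing zeros)
#' before row-normalizing; rows of the result sum to one.
#'
#' @param counts K x K cumulative transition counts.
#' @param eps Smoothing pseudo-count per cell (default 1).
#' @return Row-stochastic K x K matrix (`T[i, j]` = P(j at t+1 | i at t)).
#' @export
normalize_transitions <- function(counts, eps = 1) {
  if (eps <= 0) abort("`eps` must be positive.",
                      class = "bsitools_config_error")
  sm <- counts + eps
  sm / rowSums(sm)
}

#' Accumulate cued state transitions
#'
#' Increments `counts[i, j]` by the number of observed transitions from
#' state `i` to state `j` in a cue stream sampled at the decoder cadence.
#'
#' @param counts K x K count matrix with state dimnames.
#' @param cue_stream Character vector of cued states, one per window.
#' @return Updated count matrix.
#' @export
update_transitions <- function(counts, cue_stream) {
  states <- rownames(counts)
  idx <- match(cue_stream, states)
  if (anyNA(idx)) {
    abort(sprintf("Unknown cue label(s): %s",
                  paste(unique(cue_stream[is.na(idx)]), collapse = ", ")),
          class = "bsitools_input_error")
  }
  if (length(idx) >= 2L) {
    from <- idx[-length(idx)]
    to <- idx[-1L]
    for (k in seq_along(from)) {
      counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    }
  }
  counts
}

# Fingerprint guard: a model only decodes features produced with the same
# front-end configuration.
assert_feature_compat <- function(model, features) {
  h <- features$config_hash %||% ""
  if (!identical(h, model$feat$config_hash)) {
    abort("Feature configuration fingerprint does not match the model.",
          class = "bsitools_input_error")
  }
}

#' @rdname mslm_model
#' @param x A `bsi_mslm` model.
#' @param ... Unused.
#' @export
glance.bsi_mslm <- function(x, ...) {
  tibble(states = x$K, features = x$Fdim,
         n_updates = x$calib$n_updates, lambda = x$calib$lambda,
         transition_mass = sum(x$trans_counts),
         ridge_events = x$calib$ridge_events)
}

#' Tidy decoder coefficients
#'
#' Returns one row per (head, state, channel, frequency, tap) coefficient,
#' suitable for weight projections onto the spatial or spectral dimension.
#'
#' @param x A `bsi_mslm` model.
#' @param head `"gate"` or `"expert"`.
#' @param ... Unused.
#' @return Tibble: `head`, `state`, `channel`, `freq`, `tap`, `estimate`.
#' @export
tidy.bsi_mslm <- function(x, head = c("gate", "expert"), ...) {
  head <- match.arg(head)
  beta <- if (head == "gate") x$beta_gate else x$beta_exp
  idx <- feature_index_table(x$feat$n_channels, x$feat$n_taps)
  purrr::map_dfr(seq_len(x$K), function(k) {
    dplyr::mutate(idx, head = head, state = x$states[k],
                  estimate = beta[k, ], .before = 1L)
  })
}

#' Project gate weights onto channels per frequency band
#'
#' Sums absolute gate coefficients within the four canonical bands for each
#' channel, emulating spatial weight maps per band.
#'
#' @param model A `bsi_mslm`.
#' @param state State label to project (default: all active states pooled).
#' @return Tibble: `channel`, `band`, `weight`.
#' @export
gate_weight_projection <- function(model, state = NULL) {
  tw <- tidy.bsi_mslm(model, "gate")
  if (!is.null(state)) tw <- dplyr::filter(tw, .data$state %in% !!state)
  bands <- ecog_bands()
  tw$band <- NA_character_
  for (b in names(bands)) {
    inb <- tw$freq >= bands[[b]][1] & tw$freq < bands[[b]][2]
    tw$band[inb] <- b
  }
  tw$band[tw$freq >= 200] <- "100-200" # top edge inclusive
  dplyr::summarise(dplyr::group_by(tw, .data$channel, .data$band),
                   weight = sum(abs(.data$estimate)), .groups = "drop")
}
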