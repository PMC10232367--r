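#' Recursive exponentially weighted update of gate and experts
#'
#' Maintains cross-moment accumulators (`sum w x x'`, `sum w x y'` and the
#' weighted means needed for centring), decays them by the forgetting
#' factor `lambda`, augments them with the new batch and refits both
#' heads from the accumulators — by default via partial least squares on
#' the moments (SIMPLS, `n_comp` latent components per head), or by
#' direct least squares (`method = "ls"`, ridge fallback on rank
#' deficiency, recorded in `calib$ridge_events`). Because the fit is a
#' pure function of the accumulators, with `lambda = 1` the refit equals
#' the same estimator's pooled fit of all data seen so far (exactly the
#' least-squares solution when the components span the feature space);
#' with `lambda < 1` earlier batches are geometrically down-weighted.
#'
#' @param model A [mslm_model()].
#' @param X Feature batch, windows x F.
#' @param Y_gate One-hot cued-state matrix, windows x K.
#' @param Y_exp Desired continuous movement per state, windows x K
#'   (`NULL` = zeros; the rest column is ignored).
#' @param lambda Forgetting factor for this update (default: the model's).
#' @return The updated model.
#' @export
rew_update <- function(model, X, Y_gate, Y_exp = NULL,
                       lambda = model$calib$lambda) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  if (n < 1L) abort("Empty batch.", class = "bsitools_input_error")
  if (lambda <= 0 || lambda > 1) {
    abort("`lambda` must lie in (0, 1].", class = "bsitools_config_error")
  }
  if (ncol(X) != model$Fdim || ncol(Y_gate) != model$K) {
    abort("Batch dimensions do not match the model.",
          class = "bsitools_input_error")
  }
  Y_exp <- Y_exp %||% matrix(0, n, model$K)
  cal <- model$calib
  cal$Sxx <- lambda * cal$Sxx + crossprod(X)
  cal$Sxy_gate <- lambda * cal$Sxy_gate + crossprod(X, Y_gate)
  cal$Sxy_exp <- lambda * cal$Sxy_exp + crossprod(X, Y_exp)
  cal$sx <- lambda * cal$sx + colSums(X)
  cal$sy_gate <- lambda * cal$sy_gate + colSums(Y_gate)
  cal$sy_exp <- lambda * cal$sy_exp + colSums(Y_exp)
  cal$sw <- lambda * cal$sw + n
  cal$n_updates <- cal$n_updates + 1L

  xb <- cal$sx / cal$sw
  Sxx_c <- cal$Sxx - tcrossprod(cal$sx) / cal$sw
  Sxy_g <- cal$Sxy_gate - tcrossprod(cal$sx, cal$sy_gate) / cal$sw
  Sxy_e <- cal$Sxy_exp - tcrossprod(cal$sx, cal$sy_exp) / cal$sw

  K <- model$K
  if (identical(cal$method, "ls")) {
    sol <- solve_moments(Sxx_c, cbind(Sxy_g, Sxy_e), cal$ridge_rel)
    if (sol$ridged) cal$ridge_events <- cal$ridge_events + 1L
    B <- sol$B
  } else {
    # the gate and the experts regress different responses, so each head
    # gets its own latent PLS subspace
    B <- cbind(pls_moments(Sxx_c, Sxy_g, cal$n_comp)$B,
               pls_moments(Sxx_c, Sxy_e, cal$n_comp)$B)
  }
  model$beta_gate <- t(B[, seq_len(K), drop = FALSE])
  model$beta_exp <- t(B[, K + seq_len(K), drop = FALSE])
  model$beta_exp[1L, ] <- 0 # rest expert outputs zero by construction
  model$b_gate <- drop(cal$sy_gate / cal$sw - model$beta_gate %*% xb)
  model$b_exp <- drop(cal$sy_exp / cal$sw - model$beta_exp %*% xb)
  model$b_exp[1L] <- 0
  model$calib <- cal
  model
}

# SIMPLS from centred cross-product moments: extracts up to `ncomp`
# latent components from (X'X, X'Y) without touching the raw data, so it
# plugs directly into the exponentially decayed accumulators. With
# ncomp >= rank(X) it reproduces the least-squares solution.
pls_moments <- function(Sxx_c, Sxy, ncomp) {
  Fd <- nrow(Sxx_c)
  ny <- ncol(Sxy)
  ncomp <- min(ncomp, Fd)
  S <- Sxy
  R <- matrix(0, Fd, ncomp)
  Q <- matrix(0, ny, ncomp)
  V <- matrix(0, Fd, ncomp)
  used <- 0L
  s_tol <- max(abs(Sxy)) * 1e-10
  t_tol <- max(diag(Sxx_c)) * 1e-12
  if (!is.finite(s_tol) || s_tol == 0 || !is.finite(t_tol) || t_tol <= 0) {
    return(list(B = matrix(0, Fd, ny), ncomp = 0L))
  }
  for (a in seq_len(ncomp)) {
    if (max(abs(S)) <= s_tol) break
    # dominant right singular vector of the deflated covariance
    q <- eigen(crossprod(S), symmetric = TRUE)$vectors[, 1L]
    r <- drop(S %*% q)
    tt <- drop(crossprod(r, Sxx_c %*% r))
    if (!is.finite(tt) || tt <= t_tol * sum(r^2)) break
    r <- r / sqrt(tt)                 # score t = Xc r has unit norm
    p <- drop(Sxx_c %*% r)            # x-loading
    v <- p
    if (used > 0L) {
      Vu <- V[, seq_len(used), drop = FALSE]
      v <- v - Vu %*% crossprod(Vu, v)
      v <- v - Vu %*% crossprod(Vu, v) # re-orthogonalize for stability
    }
    nv <- sqrt(drop(crossprod(v)))
    if (!is.finite(nv) || nv <= sqrt(t_tol)) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)    # deflate the covariance
    used <- used + 1L
    R[, used] <- r
    Q[, used] <- drop(crossprod(Sxy, r)) # y-loading against original Y
    V[, used] <- v
  }
  if (used == 0L) return(list(B = matrix(0, Fd, ny), ncomp = 0L))
  idx <- seq_len(used)
  list(B = R[, idx, drop = FALSE] %*% t(Q[, idx, drop = FALSE]),
       ncomp = used)
}

# Solve Sxx_c B = Sxy for possibly rank-deficient centred moments.
# Plain Cholesky when the factorization is comfortably positive definite;
# otherwise a fixed small relative ridge.
solve_moments <- function(Sxx_c, Sxy, ridge_rel) {
  if (all(abs(Sxx_c) < .Machine$double.eps)) {
    return(list(B = matrix(0, nrow(Sxx_c), ncol(Sxy)), ridged = FALSE))
  }
  R <- tryCatch(chol(Sxx_c), error = function(e) NULL)
  if (!is.null(R)) {
    dr <- diag(R)
    if (min(dr) <= 0 || min(dr) / max(dr) < 1e-6) R <- NULL
  }
  ridged <- FALSE
  if (is.null(R)) {
    ridged <- TRUE
    ridge <- ridge_rel * mean(diag(Sxx_c))
    R <- chol(Sxx_c + diag(ridge, nrow(Sxx_c)))
    if (getOption("bsitools.verbose", FALSE)) {
      inform("Rank-deficient accumulators: ridge fallback applied.")
    }
  }
  list(B = backsolve(R, backsolve(R, Sxy, transpose = TRUE)), ridged = ridged)
}

#' Desired-movement targets for expert training
#'
#' During cued calibration the desired continuous movement for the cued
#' state is a 0 to 1 ramp over each cue block (configurable shape); all
#' other states, and rest, get zero.
#'
#' @param cues Block cue tibble.
#' @param t Window timestamps (s).
#' @param states State labels.
#' @param shape `"ramp"` (default) or `"step"`.
#' @return Matrix windows x K.
#' @export
expert_targets <- function(cues, t, states, shape = c("ramp", "step")) {
  shape <- match.arg(shape)
  idx <- findInterval(t - 1e-9, cues$onset_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(cues)] <- nrow(cues)
  lab <- cues$state[idx]
  frac <- (t - cues$onset_s[idx]) / cues$duration_s[idx]
  frac <- pmin(pmax(frac, 0), 1)
  if (shape == "step") frac <- as.numeric(frac > 0)
  Y <- matrix(0, length(t), length(states))
  ki <- match(lab, states)
  ok <- !is.na(ki) & ki > 1L
  Y[cbind(which(ok), ki[ok])] <- frac[ok]
  Y
}

#' Iterative online decoder calibration
#'
#' Streams a calibration session through the decoder: every 15 s batch is
#' first decoded with the current model (prequential, i.e. held-out,
#' accuracy), the decoder output is blended with the cue according to the
#' current assistance level (`output = (1 - a) * decoded + a * cue`), and
#' the gate/expert coefficients and the transition counts are then updated
#' from that batch. Assistance decreases progressively (linearly to zero
#' over `assist_batches` updates) as the model is calibrated.
#'
#' @param model A [mslm_model()].
#' @param features `bsi_features` stream of the calibration session.
#' @param cues Block cue tibble aligned with the stream.
#' @param assist_init Initial assistance level in `[0, 1]` (default 1).
#' @param assist_batches Batches over which assistance decays to zero
#'   (default 10).
#' @param target_shape Desired-movement shape for experts (`"ramp"`).
#' @return List of class `bsi_calibration`: `model` (updated) and
#'   `history`, a tibble with one row per batch: `batch`, `t_start`,
#'   `assistance`, `acc_raw` (prequential decoder accuracy vs cue),
#'   `acc_output` (after assistance blending) and `ridge_used`.
#' @export
calibrate_online <- function(model, features, cues, assist_init = 1,
                             assist_batches = 10L,
                             target_shape = "ramp") {
  assert_feature_compat(model, features)
  step_s <- model$feat$step_s
  per_batch <- max(1L, round(model$calib$batch_s / step_s))
  n <- nrow(features$x)
  if (n < per_batch) {
    abort("Stream shorter than one 15 s calibration batch.",
          class = "bsitools_input_error")
  }
  cue_lab <- cue_state_at(cues, features$t)
  Y_gate_all <- matrix(0, n, model$K)
  ki <- match(cue_lab, model$states)
  if (anyNA(ki)) {
    abort("Cue labels outside the model's state set.",
          class = "bsitools_input_error")
  }
  Y_gate_all[cbind(seq_len(n), ki)] <- 1
  Y_exp_all <- expert_targets(cues, features$t, model$states, target_shape)

  n_batch <- n %/% per_batch
  history <- vector("list", n_batch)
  alpha <- rep(1 / model$K, model$K)
  for (b in seq_len(n_batch)) {
    rows <- ((b - 1L) * per_batch + 1L):(b * per_batch)
    a <- max(0, assist_init * (1 - (b - 1L) / assist_batches))
    Xb <- features$x[rows, , drop = FALSE]
    # Prequential decode with the pre-update model.
    ridge_before <- model$calib$ridge_events
    D <- Xb %*% t(model$beta_gate) +
      matrix(model$b_gate, length(rows), model$K, byrow = TRUE)
    Tn <- normalize_transitions(model$trans_counts, model$trans_eps)
    pred <- character(length(rows))
    pred_out <- character(length(rows))
    for (i in seq_along(rows)) {
      alpha <- hmm_filter(softmax(D[i, ]), Tn, alpha)
      pred[i] <- model$states[which.max(alpha)]
      blended <- (1 - a) * alpha + a * Y_gate_all[rows[i], ]
      pred_out[i] <- model$states[which.max(blended)]
    }
    model <- rew_update(model, Xb, Y_gate_all[rows, , drop = FALSE],
                        Y_exp_all[rows, , drop = FALSE])
    model$trans_counts <- update_transitions(model$trans_counts,
                                             cue_lab[rows])
    history[[b]] <- tibble(
      batch = b, t_start = features$t[rows[1L]], assistance = a,
      acc_raw = mean(pred == cue_lab[rows]),
      acc_output = mean(pred_out == cue_lab[rows]),
      ridge_used = model$calib$ridge_events > ridge_before)
  }
  structure(list(model = model, history = dplyr::bind_rows(history)),
            class = "bsi_calibration")
}

#' @export
print.bsi_calibration <- function(x, ...) {
  cat("<bsi_calibration> ", nrow(x$history), " batches; final prequential accuracy ",
      round(100 * dplyr::last(x$history$acc_raw), 1), "%\n", sep = "")
  invisible(x)
}

#' @param x A `bsi_calibration`.
#' @param ... Unused.
#' @rdname calibrate_online
#' @export
tidy.bsi_calibration <- function(x, ...) x$history

#' @rdname calibrate_online
#' @export
glance.bsi_calibration <- function(x, ...) {
  tibble(n_batches = nrow(x$history),
         final_acc_raw = dplyr::last(x$history$acc_raw),
         final_assistance = dplyr::last(x$history$assistance),
         ridge_batches = sum(x$history$ridge_used))
}

#' @rdname calibrate_online
#' @param object A `bsi_calibration`.
#' @export
autoplot.bsi_calibration <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("acc_raw", "acc_output", "assistance"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_start, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
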