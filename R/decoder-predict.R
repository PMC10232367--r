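#' Gate emission probabilities for one feature window
#'
#' Computes the linear discriminant scores `d = beta_gate . vec(x) + b_gate`
#' and their softmax, the emission probability vector of the hidden-Markov
#' gate. Numerically stable for arbitrarily large scores.
#'
#' @param model A [mslm_model()].
#' @param x Feature tensor (channels x 24 x taps) or flattened numeric
#'   vector of length `model$Fdim`.
#' @return List with `d_gate` (length K) and `alpha_emission` (simplex).
#' @export
emission_probabilities <- function(model, x) {
  x <- flatten_features(model, x)
  d <- drop(model$beta_gate %*% x) + model$b_gate
  list(d_gate = d, alpha_emission = softmax(d))
}

softmax <- function(d) {
  e <- exp(d - max(d))
  e / sum(e)
}

flatten_features <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != model$Fdim) {
    abort(sprintf("Feature dimension %d does not match model (%d).",
                  length(x), model$Fdim),
          class = "bsitools_input_error")
  }
  x
}

#' One step of HMM filtering of emission probabilities
#'
#' Weights the emission probabilities by the transition prior from the
#' previous filtered posterior and renormalizes onto the simplex:
#' `alpha_hat ~ alpha_emission * (alpha_prev %*% T)` with a row-stochastic
#' transition matrix `T`.
#'
#' @param alpha_emission Simplex vector (length K).
#' @param transition Row-stochastic K x K matrix.
#' @param alpha_prev Previous filtered posterior (simplex, length K).
#' @return Filtered posterior `alpha_hat` (simplex).
#' @export
hmm_filter <- function(alpha_emission, transition, alpha_prev) {
  prior <- drop(alpha_prev %*% transition)
  un <- unname(alpha_emission * prior)
  s <- sum(un)
  if (s <= 0 || !is.finite(s)) {
    # Degenerate prior support: fall back to the emission alone.
    return(unname(alpha_emission / sum(alpha_emission)))
  }
  un / s
}

#' Per-state expert predictions
#'
#' Linear regression output of every expert for one feature window; the
#' rest-state expert is fixed at zero by construction.
#'
#' @inheritParams emission_probabilities
#' @return Numeric vector `phi` of length K.
#' @export
expert_predict <- function(model, x) {
  x <- flatten_features(model, x)
  phi <- drop(model$beta_exp %*% x) + model$b_exp
  phi[1L] <- 0
  phi
}

#' Mixture-of-experts output
#'
#' Soft-mixes expert predictions with the filtered state probabilities:
#' `U_k = phi_k * alpha_k * prod_{i != k} (1 - alpha_i)`.
#'
#' @param phi Expert predictions (length K).
#' @param alpha_hat Filtered state probabilities (simplex, length K).
#' @return Numeric vector `u` of length K.
#' @export
mixture <- function(phi, alpha_hat) {
  K <- length(phi)
  vapply(seq_len(K), function(k) {
    phi[k] * alpha_hat[k] * prod(1 - alpha_hat[-k])
  }, numeric(1))
}

#' Single decoding step (100 ms window)
#'
#' Composition of the three decoder stages: linear gate scores with softmax
#' normalization, HMM transition filtering against the previous posterior,
#' and soft mixing of the expert predictions.
#'
#' @param model A [mslm_model()].
#' @param x Feature tensor or flattened vector for one window.
#' @param alpha_prev Previous filtered posterior; `NULL` starts uniform.
#' @return List with `d_gate`, `alpha_emission`, `alpha_hat`, `u` and
#'   `state` (argmax of `alpha_hat`; ties resolve toward the rest state by
#'   state order).
#' @export
decode_step <- function(model, x, alpha_prev = NULL) {
  alpha_prev <- alpha_prev %||% rep(1 / model$K, model$K)
  em <- emission_probabilities(model, x)
  Tn <- normalize_transitions(model$trans_counts, model$trans_eps)
  alpha_hat <- hmm_filter(em$alpha_emission, Tn, alpha_prev)
  phi <- expert_predict(model, x)
  u <- mixture(phi, alpha_hat)
  list(d_gate = em$d_gate, alpha_emission = em$alpha_emission,
       alpha_hat = alpha_hat, u = u,
       state = model$states[which.max(alpha_hat)])
}

#' Decode a whole feature stream
#'
#' Sequentially applies [decode_step()] across all windows (the filtered
#' posterior chains through `alpha_prev`), with the linear algebra batched
#' for speed. Identical to calling [decode_step()] window by window.
#'
#' @param model A [mslm_model()].
#' @param features A `bsi_features` stream (fingerprint-checked).
#' @param alpha0 Initial posterior (default uniform).
#' @return Object of class `bsi_decoding`: list with `t`, matrices
#'   `alpha_emission`, `alpha_hat`, `u` (windows x K) and `state` labels.
#' @export
decode_stream <- function(model, features, alpha0 = NULL) {
  assert_feature_compat(model, features)
  X <- features$x
  n <- nrow(X)
  K <- model$K
  D <- X %*% t(model$beta_gate) +
    matrix(model$b_gate, n, K, byrow = TRUE)
  Phi <- X %*% t(model$beta_exp) + matrix(model$b_exp, n, K, byrow = TRUE)
  Phi[, 1L] <- 0
  Em <- t(apply(D, 1L, softmax))
  Tn <- normalize_transitions(model$trans_counts, model$trans_eps)
  Ah <- matrix(0, n, K)
  U <- matrix(0, n, K)
  alpha <- alpha0 %||% rep(1 / K, K)
  for (i in seq_len(n)) {
    alpha <- hmm_filter(Em[i, ], Tn, alpha)
    Ah[i, ] <- alpha
    U[i, ] <- mixture(Phi[i, ], alpha)
  }
  colnames(Em) <- colnames(Ah) <- colnames(U) <- model$states
  structure(
    list(t = features$t, alpha_emission = Em, alpha_hat = Ah, u = U,
         state = model$states[max.col(Ah, ties.method = "first")],
         states = model$states),
    class = "bsi_decoding"
  )
}

#' @export
print.bsi_decoding <- function(x, ...) {
  cat("<bsi_decoding> ", length(x$t), " windows, states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a decoded stream into long format
#'
#' @param x A `bsi_decoding`.
#' @param ... Unused.
#' @return Tibble: `t`, `state`, `alpha_hat`, `u`, `decoded` (argmax label).
#' @export
tidy.bsi_decoding <- function(x, ...) {
  K <- length(x$states)
  tibble(t = rep(x$t, each = K),
         state = rep(x$states, times = length(x$t)),
         alpha_hat = as.vector(t(x$alpha_hat)),
         u = as.vector(t(x$u)),
         decoded = rep(x$state, each = K))
}

#' Plot decoded state probabilities
#'
#' @param object A `bsi_decoding`.
#' @param ... Unused.
#' @return A ggplot of the filtered probabilities over time.
#' @export
autoplot.bsi_decoding <- function(object, ...) {
  df <- tidy.bsi_decoding(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$alpha_hat,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(hat(alpha)),
                  colour = "state") +
    ggplot2::theme_minimal()
}
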