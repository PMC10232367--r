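#' Gate coefficient vectors for model-stability analysis
#'
#' Averages the gate coefficients of selected states over the temporal
#' taps, yielding one (channels x 24 frequencies) vector per state per
#' model.
#'
#' @param model A `bsi_mslm`.
#' @param states States to extract (default: all).
#' @return Matrix (length(states) x channels*24) with state rownames.
#' @export
gate_state_vectors <- function(model, states = model$states) {
  nf <- length(ccwt_freqs())
  nt <- model$feat$n_taps
  nc <- model$feat$n_channels
  out <- matrix(0, length(states), nc * nf,
                dimnames = list(states, NULL))
  for (s in seq_along(states)) {
    k <- match(states[s], model$states)
    if (is.na(k)) abort("Unknown state.", class = "bsitools_input_error")
    arr <- array(model$beta_gate[k, ], dim = c(nt, nf, nc)) # tap fastest
    out[s, ] <- as.vector(apply(arr, c(2L, 3L), mean))      # avg over taps
  }
  out
}

#' PCA stability of walking-model gate coefficients
#'
#' Principal component analysis over the per-state gate coefficient
#' vectors of a set of models (e.g. idle, left hip, right hip across
#' months of use). Scores are reported in the first three components; for
#' each state, a Gaussian ellipsoid mesh of exactly `mesh_points` points
#' is built at the `contour_sd` standard-deviation contour of the state's
#' score distribution.
#'
#' @param coefs Matrix, one row per (model, state) coefficient vector.
#' @param states Character vector labelling each row's state.
#' @param models Identifier per row (same length).
#' @param n_components Components retained (default 3).
#' @param mesh_points Ellipsoid mesh size (default 1600).
#' @param contour_sd Contour radius in standard deviations (default 1.4).
#' @return List of class `bsi_model_pca`: `scores` tibble (`model`,
#'   `state`, `PC1..PCn`), `ellipsoids` tibble (`state`, `x`, `y`, `z`),
#'   `var_explained` (per component, fraction).
#' @export
model_stability_pca <- function(coefs, states, models,
                                n_components = 3L, mesh_points = 1600L,
                                contour_sd = 1.4) {
  coefs <- as.matrix(coefs)
  if (nrow(coefs) < n_components) {
    abort("Fewer coefficient vectors than requested components.",
          class = "bsitools_input_error")
  }
  pca <- prcomp(coefs, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pca$x))
  sc <- pca$x[, seq_len(ncomp), drop = FALSE]
  scores <- dplyr::bind_cols(tibble(model = models, state = states),
                             as_tibble(sc))
  ve <- pca$sdev^2 / sum(pca$sdev^2)

  mesh <- unit_sphere_mesh(mesh_points)
  ellipsoids <- purrr::map_dfr(unique(states), function(st) {
    pts <- sc[states == st, , drop = FALSE]
    mu <- colMeans(pts)
    cv <- if (nrow(pts) > 1L) stats::cov(pts) else
      diag(0, ncol(pts))
    ee <- eigen(cv, symmetric = TRUE)
    A <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), ncol(pts))
    m3 <- mesh[, seq_len(min(3L, ncol(pts))), drop = FALSE]
    xyz <- sweep(contour_sd * m3 %*% t(A[, seq_len(ncol(m3)),
                                         drop = FALSE]),
                 2L, mu, `+`)
    tibble(state = st, x = xyz[, 1L],
           y = if (ncol(xyz) > 1L) xyz[, 2L] else 0,
           z = if (ncol(xyz) > 2L) xyz[, 3L] else 0)
  })
  structure(list(scores = scores, ellipsoids = ellipsoids,
                 var_explained = ve),
            class = "bsi_model_pca")
}

# Deterministic mesh of exactly n points on the unit sphere
# (latitude-longitude grid, n = nu * nv).
unit_sphere_mesh <- function(n) {
  nu <- floor(sqrt(n))
  while (n %% nu != 0L) nu <- nu - 1L
  nv <- n %/% nu
  u <- seq(0, pi, length.out = nu)
  v <- seq(0, 2 * pi, length.out = nv + 1L)[seq_len(nv)]
  g <- tidyr::expand_grid(u = u, v = v)
  cbind(sin(g$u) * cos(g$v), sin(g$u) * sin(g$v), cos(g$u))
}

#' @export
print.bsi_model_pca <- function(x, ...) {
  cat("<bsi_model_pca> ", nrow(x$scores), " coefficient vectors, PC1-3 explain ",
      round(100 * sum(x$var_explained[seq_len(min(3, length(x$var_explained)))]), 1),
      "% variance\n", sep = "")
  invisible(x)
}

#' @param x A `bsi_model_pca`.
#' @param ... Unused.
#' @rdname model_stability_pca
#' @export
tidy.bsi_model_pca <- function(x, ...) x$scores

#' @rdname model_stability_pca
#' @export
glance.bsi_model_pca <- function(x, ...) {
  tibble(n_vectors = nrow(x$scores),
         pc1_var = x$var_explained[1L],
         pc123_var = sum(x$var_explained[seq_len(min(3,
                                                     length(x$var_explained)))]))
}
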