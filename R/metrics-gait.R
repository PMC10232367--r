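#' Detect stepping attempts from the knee-angle trace
#'
#' A stepping attempt is detected when the knee angle drops below 135
#' degrees, with a 2 s refractory period between steps. A step is flagged
#' as failed when its step length is below 10 cm.
#'
#' @param knee_angle Knee angle trace in degrees.
#' @param fs Sampling rate (Hz).
#' @param step_lengths Optional step lengths (cm) matched to detected
#'   steps in order (recycled NA when shorter).
#' @param threshold_deg Detection threshold (default 135).
#' @param refractory_s Minimum separation between steps (default 2).
#' @param fail_below_cm Failure rule on step length (default 10).
#' @return Tibble of class `bsi_step_events`: `onset_s`, `step_length_cm`,
#'   `failed` (onsets strictly increasing, spacing >= refractory).
#' @export
detect_steps <- function(knee_angle, fs, step_lengths = NULL,
                         threshold_deg = 135, refractory_s = 2,
                         fail_below_cm = 10) {
  below <- knee_angle < threshold_deg
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  onsets <- numeric(0)
  last <- -Inf
  for (i in crossings) {
    t_i <- (i - 1) / fs
    if (t_i - last >= refractory_s) {
      onsets <- c(onsets, t_i)
      last <- t_i
    }
  }
  lens <- rep(NA_real_, length(onsets))
  if (!is.null(step_lengths) && length(onsets) > 0L) {
    m <- min(length(onsets), length(step_lengths))
    lens[seq_len(m)] <- step_lengths[seq_len(m)]
  }
  out <- tibble(onset_s = onsets, step_length_cm = lens,
                failed = !is.na(lens) & lens < fail_below_cm)
  class(out) <- c("bsi_step_events", class(out))
  out
}

#' Muscles and parameter names of the gait analysis
#'
#' The six muscles recorded bilaterally during gait and the 26 kinematic
#' and EMG parameters quantified per gait cycle.
#'
#' @return Character vectors.
#' @export
gait_muscles <- function() {
  c("vastus_lateralis", "tibialis_anterior", "rectus_femoris",
    "iliopsoas", "semitendinosus", "medial_gastrocnemius")
}

#' @rdname gait_muscles
#' @export
gait_param_names <- function() {
  c("step_length", "step_height", "knee_height", "knee_angle",
    "knee_max_angle", "hip_angle", "hip_max_angle", "limb_angle",
    as.vector(t(outer(gait_muscles(),
                      c("activation", "stance_activation",
                        "swing_activation"), paste, sep = "_"))))
}

#' Per-cycle gait parameters
#'
#' Computes the 26 kinematic and EMG parameters per gait cycle: step
#' length and height, knee height, mean and maximum knee/hip angles, mean
#' limb angle, and total/stance/swing activation (mean rectified envelope)
#' for six muscles. The swing phase is the portion of the cycle with knee
#' flexion (knee angle below `swing_knee_deg`); the remainder is stance.
#'
#' @param kin Per-sample kinematics: data frame with columns `knee_angle`,
#'   `hip_angle`, `limb_angle`, `foot_x` (m, direction of progression),
#'   `foot_y` (m, vertical), `knee_y` (m).
#' @param emg Muscles x samples matrix with rownames covering
#'   `gait_muscles()`.
#' @param fs Sampling rate of both (Hz).
#' @param cycles Tibble with `start_s`, `end_s` per cycle; `NULL` derives
#'   cycles from successive knee-dip onsets ([detect_steps()]).
#' @param swing_knee_deg Knee-angle threshold separating swing from stance
#'   (default 160).
#' @return Tibble: `cycle`, then the 26 parameters of
#'   `gait_param_names()`.
#' @export
gait_cycle_params <- function(kin, emg, fs, cycles = NULL,
                              swing_knee_deg = 160) {
  needed <- c("knee_angle", "hip_angle", "limb_angle", "foot_x", "foot_y",
              "knee_y")
  missing_k <- setdiff(needed, names(kin))
  if (length(missing_k) > 0L) {
    abort(paste0("Missing kinematic channel(s): ",
                 paste(missing_k, collapse = ", ")),
          class = "bsitools_input_error")
  }
  missing_m <- setdiff(gait_muscles(), rownames(emg))
  if (length(missing_m) > 0L) {
    abort(paste0("Missing muscle channel(s): ",
                 paste(missing_m, collapse = ", ")),
          class = "bsitools_input_error")
  }
  if (is.null(cycles)) {
    on <- detect_steps(kin$knee_angle, fs)$onset_s
    if (length(on) < 2L) {
      abort("Need at least two knee-dip onsets to segment cycles.",
            class = "bsitools_input_error")
    }
    cycles <- tibble(start_s = on[-length(on)], end_s = on[-1L])
  }
  if (nrow(cycles) < 1L) {
    abort("Need at least one gait cycle.", class = "bsitools_input_error")
  }
  purrr::map_dfr(seq_len(nrow(cycles)), function(ci) {
    i0 <- max(1L, round(cycles$start_s[ci] * fs) + 1L)
    i1 <- min(nrow(kin), round(cycles$end_s[ci] * fs))
    sl <- i0:i1
    swing <- kin$knee_angle[sl] < swing_knee_deg
    row <- list(cycle = ci,
                step_length = abs(kin$foot_x[i1] - kin$foot_x[i0]),
                step_height = max(kin$foot_y[sl]) - min(kin$foot_y[sl]),
                knee_height = max(kin$knee_y[sl]),
                knee_angle = mean(kin$knee_angle[sl]),
                knee_max_angle = max(kin$knee_angle[sl]),
                hip_angle = mean(kin$hip_angle[sl]),
                hip_max_angle = max(kin$hip_angle[sl]),
                limb_angle = mean(kin$limb_angle[sl]))
    for (m in gait_muscles()) {
      env <- abs(emg[m, sl])
      row[[paste0(m, "_activation")]] <- mean(env)
      row[[paste0(m, "_stance_activation")]] <-
        if (any(!swing)) mean(env[!swing]) else 0
      row[[paste0(m, "_swing_activation")]] <-
        if (any(swing)) mean(env[swing]) else 0
    }
    as_tibble(row)
  })
}

#' PCA of gait parameters and distances to a reference cohort
#'
#' Fits a PCA over pooled, standardized gait-cycle parameters and reports
#' per-condition centroids and their distances to a reference condition
#' (e.g. healthy individuals) in the first `n_components` components.
#'
#' @param params Gait-parameter tibble ([gait_cycle_params()] output) plus
#'   a `condition` column; the `cycle` column is ignored if present.
#' @param reference Condition label serving as reference centroid.
#' @param n_components Components used for distances (default 3).
#' @return List of class `bsi_gait_pca`: `scores` (condition + PCs per
#'   cycle), `centroids`, `distances` (`condition`,
#'   `distance_to_reference`), `var_explained`, `loadings`.
#' @export
gait_pca <- function(params, reference, n_components = 3L) {
  if (!"condition" %in% names(params)) {
    abort("`params` must carry a `condition` column.",
          class = "bsitools_input_error")
  }
  if (!reference %in% params$condition) {
    abort("Reference condition absent from `params`.",
          class = "bsitools_input_error")
  }
  vars <- intersect(gait_param_names(), names(params))
  X <- as.matrix(params[, vars])
  sds <- apply(X, 2L, sd)
  keep <- is.finite(sds) & sds > 0
  pca <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ncomp <- min(n_components, ncol(pca$x))
  sc <- as_tibble(pca$x[, seq_len(ncomp), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(condition = params$condition), sc)
  centroids <- dplyr::summarise(dplyr::group_by(scores, .data$condition),
                                dplyr::across(dplyr::starts_with("PC"),
                                              mean),
                                .groups = "drop")
  ref <- as.numeric(centroids[centroids$condition == reference,
                              -1L, drop = FALSE])
  centm <- as.matrix(centroids[, -1L, drop = FALSE])
  distances <- tibble(
    condition = centroids$condition,
    distance_to_reference =
      sqrt(rowSums(sweep(centm, 2L, ref, `-`)^2)))
  structure(list(scores = scores, centroids = centroids,
                 distances = distances,
                 var_explained = pca$sdev^2 / sum(pca$sdev^2),
                 loadings = pca$rotation[, seq_len(ncomp), drop = FALSE]),
            class = "bsi_gait_pca")
}

#' @export
print.bsi_gait_pca <- function(x, ...) {
  cat("<bsi_gait_pca> ", nrow(x$scores), " cycles, ",
      length(unique(x$scores$condition)), " conditions\n", sep = "")
  print(x$distances)
  invisible(x)
}

#' @param x A `bsi_gait_pca`.
#' @param ... Unused.
#' @rdname gait_pca
#' @export
tidy.bsi_gait_pca <- function(x, ...) x$scores

#' @rdname gait_pca
#' @export
glance.bsi_gait_pca <- function(x, ...) {
  tibble(n_cycles = nrow(x$scores),
         pc123_var = sum(x$var_explained[seq_len(min(3,
                                                     length(x$var_explained)))]))
}
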