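#' Run one pipeline stage
#'
#' Thin orchestration over the package's modules, mirroring the clinical
#' workflow: `simulate` a session, `calibrate` the decoder online,
#' `decode` a session with a calibrated model, run the `closedloop`
#' walking controller at the 300 ms command cadence, and `eval`uate
#' decoding accuracy against the cues. Every stage is deterministic given
#' the config seed and writes its artefacts under `out_dir`.
#'
#' @param command One of `"simulate"`, `"calibrate"`, `"decode"`,
#'   `"closedloop"`, `"eval"`.
#' @param config Config list (see [default_run_config()]); partial configs
#'   are validated and merged.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress lines.
#' @return Invisibly, a named list of artefact paths (plus stage results).
#' @export
run_pipeline <- function(command = c("simulate", "calibrate", "decode",
                                     "closedloop", "eval"),
                         config = list(), out_dir = ".", quiet = FALSE) {
  command <- match.arg(command)
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- lapply(cfg$paths, function(f) file.path(out_dir, f))
  say <- function(...) if (!quiet) inform(sprintf(...))
  cfg_hash <- fnv1a32_hex(jsonlite::toJSON(cfg, auto_unbox = TRUE))

  switch(command,
    simulate = {
      sc <- sim_config(seed = cfg$seed,
                       n_channels = cfg$simulate$n_channels,
                       fs = cfg$simulate$fs, states = cfg$simulate$states,
                       background_exponent =
                         cfg$simulate$background_exponent,
                       effect_size = cfg$simulate$effect_size,
                       n_reps = cfg$simulate$n_reps,
                       cue_duration_s = cfg$simulate$cue_duration_s)
      session <- simulate_session(sc)
      save_session(session, p$session)
      write_table_csv(session$cues, p$cues)
      say("simulate: %d channels, %.0f s, config %s",
          nrow(session$ecog), ncol(session$ecog) / session$fs, cfg_hash)
      invisible(list(session = p$session, cues = p$cues))
    },
    calibrate = {
      session <- load_session(p$session)
      feats <- session_features(session, cfg)
      model <- mslm_model(states = session$truth$config$states,
                         features = feats, lambda = cfg$decoder$lambda,
                         ridge_rel = cfg$decoder$ridge_rel,
                         trans_eps = cfg$decoder$trans_eps,
                         batch_s = cfg$decoder$batch_s)
      cal <- calibrate_online(model, feats, session$cues,
                              assist_init = cfg$decoder$assist_init,
                              assist_batches = cfg$decoder$assist_batches)
      if (!quiet) {
        for (b in seq_len(nrow(cal$history))) {
          h <- cal$history[b, ]
          say("calibrate: batch %d assistance %.2f heldout_acc %.3f",
              h$batch, h$assistance, h$acc_raw)
        }
      }
      save_model(cal$model, p$model)
      write_table_csv(cal$history, p$history)
      invisible(list(model = p$model, history = p$history,
                     calibration = cal))
    },
    decode = {
      session <- load_session(p$session)
      model <- load_model(p$model)
      feats <- session_features(session, cfg)
      dec <- decode_stream(model, feats)
      save_decoding(dec, p$decoding)
      say("decode: %d windows, config %s", length(dec$t), cfg_hash)
      invisible(list(decoding = p$decoding, result = dec))
    },
    closedloop = {
      session <- load_session(p$session)
      model <- load_model(p$model)
      feats <- session_features(session, cfg)
      dec <- decode_stream(model, feats)
      programs <- if (file.exists(p$programs)) {
        read_program_library(p$programs)
      } else {
        default_program_library(model$states,
                                cfg$controller$amplitude_range)
      }
      cmds <- purrr::map_dfr(seq_along(dec$t), function(i) {
        walking_controller(setNames(dec$alpha_hat[i, ], model$states),
                           programs, p0 = cfg$controller$p0,
                           t = dec$t[i])
      })
      ticked <- dispatch(cmds, tick_s = cfg$controller$tick_ms / 1000)
      write_table_csv(ticked, p$commands)
      say("closedloop: %d commands at %d ms cadence", nrow(ticked),
          cfg$controller$tick_ms)
      invisible(list(commands = p$commands, result = ticked))
    },
    eval = {
      session <- load_session(p$session)
      dec <- load_decoding(p$decoding)
      states <- dec$states
      cue_lab <- cue_state_at(session$cues, dec$t)
      dt <- if (length(dec$t) > 1L) median(diff(dec$t)) else 0.1
      per_state <- purrr::map_dfr(states[-1L], function(st) {
        Z <- as.numeric(cue_lab == st)
        Zhat <- as.numeric(dec$state == st)
        if (sum(Z) == 0) {
          return(tibble(state = st, accuracy = NA_real_, tau_s = NA_real_))
        }
        acc <- decoding_accuracy(Z, Zhat, dt)
        tibble(state = st, accuracy = acc$accuracy, tau_s = acc$tau_s)
      })
      report <- list(
        config_hash = cfg_hash,
        package_version = as.character(utils::packageVersion("bsitools")),
        n_windows = length(dec$t),
        window_accuracy = mean(dec$state == cue_lab),
        per_state = per_state,
        mean_state_accuracy = mean(per_state$accuracy, na.rm = TRUE),
        chance_level_pct = chance_level(length(states)))
      jsonlite::write_json(report, p$report, auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
      say("eval: mean state accuracy %.3f; chance level %d%%",
          report$mean_state_accuracy, report$chance_level_pct)
      invisible(list(report = p$report, result = report))
    }
  )
}

# Band-pass preprocess + wavelet features with the config's settings.
session_features <- function(session, cfg) {
  filt <- preprocess_ecog(session$ecog, session$fs)
  feature_stream(filt, session$fs,
                 epoch_s = cfg$features$epoch_ms / 1000,
                 step_s = cfg$features$step_ms / 1000,
                 n_taps = cfg$features$n_taps)
}

# One placeholder program per active state when no library file exists.
default_program_library <- function(states, amplitude_range = c(14, 16)) {
  purrr::map_dfr(seq_along(states[-1L]), function(i) {
    stim_program(paste0("cfg_", states[-1L][i]),
                 cathodes = (2L * (i - 1L)) %% 16L,
                 anodes = (2L * (i - 1L) + 1L) %% 16L,
                 amplitude_range = amplitude_range,
                 target = states[-1L][i])
  })
}

#' Parameter-recovery experiment on a synthetic calibration session
#'
#' End-to-end check of the decoding chain under known ground truth:
#' simulates a seeded seven-state calibration session with strong
#' band-power effects (30 repetitions per active state by default),
#' band-passes it, extracts wavelet features, calibrates the decoder
#' online on the first part of the stream and evaluates window-level state
#' accuracy on the held-out tail. Also reports how strongly the top-decile
#' gate-weight mass concentrates on the simulator's informative channels.
#'
#' @param seed Master seed.
#' @param n_channels Channels (default 64).
#' @param n_reps Cue repetitions per active state (default 30).
#' @param effect_size Contrast scale of the simulator (default 1 = the
#'   configured strong gains).
#' @param epoch_s,n_taps Feature settings for this experiment (defaults
#'   0.3 s and 2 taps; see the methods vignette for the rationale).
#' @param holdout_frac Fraction of trailing batches held out (default 0.2).
#' @return List: `heldout_accuracy` (window-level, on the held-out tail),
#'   `chance` (fraction), `history` (calibration tibble),
#'   `weight_enrichment` (share of top-decile gate-weight mass on
#'   informative channels divided by their base rate), `informative_share`,
#'   `model`, `n_heldout`.
#' @export
recovery_experiment <- function(seed = 1L, n_channels = 64L, n_reps = 30L,
                                effect_size = 1, epoch_s = 0.3,
                                n_taps = 2L, holdout_frac = 0.2) {
  sc <- sim_config(seed = seed, n_channels = n_channels,
                   effect_size = effect_size, n_reps = n_reps,
                   cue_duration_s = 2)
  session <- simulate_session(sc)
  filt <- preprocess_ecog(session$ecog, session$fs)
  feats <- feature_stream(filt, session$fs, epoch_s = epoch_s,
                          n_taps = n_taps)
  per_batch <- round(15 / feats$step_s)
  n_batches <- nrow(feats$x) %/% per_batch
  n_train_batches <- max(1L, floor((1 - holdout_frac) * n_batches))
  n_train <- n_train_batches * per_batch
  train <- subset_features(feats, seq_len(n_train))
  test <- subset_features(feats, (n_train + 1L):nrow(feats$x))

  model <- mslm_model(states = sc$states, features = feats)
  cal <- calibrate_online(model, train, session$cues)
  dec <- decode_stream(cal$model, test)
  cue_test <- cue_state_at(session$cues, test$t)
  heldout_accuracy <- mean(dec$state == cue_test)

  # Weight concentration: which channels carry the top decile of |beta|?
  idx <- feature_index_table(n_channels, n_taps)
  w <- colSums(abs(cal$model$beta_gate))
  informative <- unique(sc$informative_map$channel)
  top <- w >= quantile(w, 0.9)
  top_share <- mean(idx$channel[top] %in% informative)
  base_rate <- length(informative) / n_channels
  list(heldout_accuracy = heldout_accuracy,
       chance = 1 / length(sc$states),
       history = cal$history,
       weight_enrichment = top_share / base_rate,
       informative_share = top_share,
       model = cal$model,
       n_heldout = length(cue_test))
}

# Restrict a feature stream to a window subset (keeps metadata/fingerprint).
subset_features <- function(features, rows) {
  features$x <- features$x[rows, , drop = FALSE]
  features$t <- features$t[rows]
  features
}
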