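test_that("decoding accuracy compensates injected delays exactly", {
  dt <- 0.1
  Z <- rep(0, 300)
  Z[c(51:70, 121:140, 201:220)] <- 1
  # perfect decoding: accuracy 1 at zero lag
  perfect <- decoding_accuracy(Z, Z, dt)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$tau_s, 0)
  # all-zero decoding: accuracy 0
  expect_equal(decoding_accuracy(Z, rep(0, 300), dt)$accuracy, 0)
  # 0.5 s delayed copy: lag recovered, accuracy restored to 1
  lagged <- c(rep(0, 5), Z[1:295])
  acc <- decoding_accuracy(Z, lagged, dt)
  expect_equal(acc$tau_s, 0.5)
  expect_equal(acc$accuracy, 1)
  # shift invariance within the search window (property)
  for (shift in c(2, 17, 43)) {
    sh <- c(rep(0, shift), Z[1:(300 - shift)])
    expect_equal(decoding_accuracy(Z, sh, dt)$accuracy, 1)
  }
  expect_error(decoding_accuracy(rep(0, 10), rep(1, 10), dt),
               class = "bsitools_input_error")
})

test_that("chance level is 100/K rounded to integer percent", {
  expect_identical(chance_level(7), 14L)
  expect_identical(chance_level(2), 50L)
  expect_identical(chance_level(100), 1L)
  expect_error(chance_level(1), class = "bsitools_config_error")
})

test_that("EMG accuracy thresholds the envelope per the formula", {
  fs <- 500
  n <- 10 * fs
  set.seed(33)
  decoded <- rep(0, n)
  decoded[(2 * fs):(4 * fs)] <- 1
  decoded[(6 * fs):(8 * fs)] <- 1
  # bursts inside decoded-active epochs (interior by more than the 200 ms
  # forward envelope window, which otherwise leads the burst onset)
  emg <- rnorm(n, sd = 0.01)
  burst <- which(decoded == 1)
  burst <- burst[burst > 2.3 * fs & burst < 3.7 * fs |
                   burst > 6.3 * fs & burst < 7.7 * fs]
  emg[burst] <- rnorm(length(burst), sd = 1)
  acc <- emg_accuracy(decoded, emg, fs)
  expect_equal(acc$accuracy, 1)
  # bursts covering half the active time and nothing else: still 1.0
  # (the metric reads the fraction of envelope-active time inside Zhat)
  emg2 <- rnorm(n, sd = 0.01)
  emg2[(2.3 * fs):(3.3 * fs)] <- rnorm(fs + 1, sd = 1)
  emg2[(6.3 * fs):(7.3 * fs)] <- rnorm(fs + 1, sd = 1)
  acc2 <- emg_accuracy(decoded, emg2, fs)
  expect_equal(acc2$accuracy, 1)
  # direct-formula oracle on a random instance
  emg3 <- rnorm(n)
  z <- (emg3 - mean(emg3)) / sd(emg3)
  env <- bsitools:::roll_mean_forward(abs(z), round(0.2 * fs)) > 1
  expect_equal(emg_accuracy(decoded, emg3, fs)$accuracy,
               sum(env * decoded) / sum(env), tolerance = 1e-12)
  # degenerate inputs
  expect_error(emg_accuracy(decoded, rep(1, n), fs),
               class = "bsitools_input_error")
  # sub-threshold oscillation: envelope never active
  expect_error(emg_accuracy(decoded, sin(2 * pi * 50 * seq_len(n) / fs),
                            fs),
               class = "bsitools_input_error")
})

test_that("stepping accuracy profiles peaks and half-widths", {
  dt <- 0.1
  t <- seq(0, 30, by = dt)
  prob <- rep(0, length(t))
  # two identical rectangular pulses of height 1, width 2 s
  prob[t >= 3 & t < 5] <- 1
  prob[t >= 13 & t < 15] <- 1
  sa <- stepping_accuracy(prob, t, c(2, 12))
  expect_equal(sa$summary$peak_mean, 1)
  expect_equal(sa$summary$peak_sd, 0)
  expect_equal(sa$summary$width_mean, 2, tolerance = 0.11)
  expect_equal(sa$summary$width_sd, 0)
  # triangular pulse of height h: FWHM = half of the base (geometry)
  tri <- rep(0, length(t))
  up <- seq(0, 0.8, length.out = 21)
  tri[101:121] <- up
  tri[122:141] <- rev(up)[2:21]
  st <- stepping_accuracy(tri, t, 9.5)
  expect_equal(st$steps$peak, 0.8, tolerance = 1e-9)
  expect_equal(st$steps$width_s, 2, tolerance = 0.15)
  # no steps -> empty report, not an error
  none <- stepping_accuracy(prob, t, numeric(0))
  expect_equal(nrow(none$steps), 0)
})

test_that("signal stability: flat spectrum, tone concentration, dB scaling", {
  fs <- 586
  set.seed(44)
  n <- 115 * fs
  white <- rnorm(n)
  stab <- signal_stability(white, fs)
  # Parseval oracle: unit-variance white noise has RMS ~ 1
  expect_equal(stab$rms, 1, tolerance = 0.02)
  # flat spectrum: normalized band powers agree across bands
  expect_lt(max(stab$bands$power_db) - min(stab$bands$power_db), 0.5)
  # band powers sum to at most the total power
  expect_lt(sum(stab$bands$power), 1.05)
  # 30 Hz tone + tiny noise: the 10-40 Hz band captures ~ A^2/2
  amp <- 2
  tone <- amp * sin(2 * pi * 30 * seq(0, (n - 1)) / fs) + rnorm(n, sd = 0.01)
  ts <- signal_stability(tone, fs)
  p1040 <- ts$bands$power[ts$bands$band == "10-40"]
  expect_gt(p1040, 0.95 * amp^2 / 2)
  expect_lt(p1040, 1.05 * amp^2 / 2)
  # doubling the amplitude adds ~ 6.02 dB to every band power
  ts2 <- signal_stability(2 * tone, fs)
  expect_equal(ts2$bands$power_db - ts$bands$power_db,
               rep(20 * log10(2), 4), tolerance = 0.1,
               ignore_attr = TRUE)
  # SNR defined against the 250-260 Hz noise band
  expect_true(all(is.finite(stab$bands$snr_db)))
  expect_error(signal_stability(white[1:(100 * fs)], fs),
               class = "bsitools_input_error")
})

test_that("z-scored spectrograms normalize per band and localize bursts", {
  fs <- 586
  set.seed(55)
  n <- 20 * fs
  x <- rnorm(n, sd = 0.1)
  burst <- (8 * fs):(12 * fs)
  x[burst] <- x[burst] + sin(2 * pi * 40 * burst / fs)
  sp <- zscored_spectrogram(x, fs)
  # per-band mean ~ 0 and sd ~ 1 after normalization
  expect_lt(max(abs(rowMeans(sp$z))), 1e-9)
  expect_equal(apply(sp$z, 1, sd), rep(1, 24), tolerance = 1e-9)
  # ridge location: strongest positive z at the 40 Hz bin inside the burst
  f40 <- which(ccwt_freqs() == 40)
  inside <- sp$t >= 8.5 & sp$t <= 11.5
  expect_gt(mean(sp$z[f40, inside]), 1)
  expect_lt(mean(sp$z[f40, !inside]), 0)
  # white noise shows no sustained half-vs-half structure
  spn <- zscored_spectrogram(rnorm(n), fs)
  halves <- abs(rowMeans(spn$z[, seq_len(ncol(spn$z) / 2)]) -
                  rowMeans(spn$z[, -seq_len(ncol(spn$z) / 2)]))
  expect_lt(max(halves), 1)
})

test_that("feature reinforcement: null slope without modulation, positive with", {
  fs <- 586
  set.seed(66)
  n <- 60 * fs
  events <- split(seq(3, 57, length.out = 16), rep(1:4, each = 4))
  # stationary signal: no event-locked change -> slope ~ 0
  ec <- matrix(rnorm(3 * n, sd = 1), nrow = 3)
  null_fit <- feature_reinforcement(ec, fs, events)
  expect_lt(abs(null_fit$slope), 2 * glance(null_fit)$slope_se + 0.02)
  # modulation amplitude grows across periods -> positive slope
  ec2 <- matrix(rnorm(3 * n, sd = 0.3), nrow = 3)
  for (p in 1:4) {
    for (e in events[[p]]) {
      w <- round((e - 0.5) * fs):round((e + 0.5) * fs)
      ec2[, w] <- ec2[, w] + (p / 2) * sin(2 * pi * 30 * w / fs)
    }
  }
  pos_fit <- feature_reinforcement(ec2, fs, events)
  expect_gt(pos_fit$slope, 0)
  expect_error(feature_reinforcement(ec, fs, list(numeric(0))),
               class = "bsitools_input_error")
})

test_that("model-stability PCA: variance structure and 1,600-point ellipsoids", {
  set.seed(77)
  # vectors on a line: PC1 explains ~ all variance
  base <- rnorm(50)
  line <- outer(seq(1, 3, length.out = 9), base) +
    matrix(rnorm(9 * 50, sd = 1e-6), 9)
  pca_line <- model_stability_pca(line, states = rep(c("a", "b", "c"), 3),
                                  models = rep(1:3, each = 3))
  expect_gt(pca_line$var_explained[1], 0.999)
  # ellipsoid mesh has exactly 1,600 points per state
  clusters <- rbind(matrix(rnorm(60, mean = 0), 6),
                    matrix(rnorm(60, mean = 30), 6))
  pca_cl <- model_stability_pca(clusters,
                                states = rep(c("idle", "hipL"), each = 6),
                                models = rep(1:6, 2))
  per_state <- table(pca_cl$ellipsoids$state)
  expect_true(all(per_state == 1600))
  # widely separated clusters yield non-overlapping ellipsoids
  a <- pca_cl$ellipsoids[pca_cl$ellipsoids$state == "idle", c("x", "y", "z")]
  b <- pca_cl$ellipsoids[pca_cl$ellipsoids$state == "hipL", c("x", "y", "z")]
  ca <- colMeans(a); cb <- colMeans(b)
  ra <- max(sqrt(rowSums(sweep(as.matrix(a), 2, ca)^2)))
  rb <- max(sqrt(rowSums(sweep(as.matrix(b), 2, cb)^2)))
  expect_gt(sqrt(sum((ca - cb)^2)), ra + rb)
  expect_error(model_stability_pca(line[1:2, ], states = c("a", "b"),
                                   models = 1:2),
               class = "bsitools_input_error")
})

test_that("step detection applies the 135-degree, 2 s and 10 cm rules", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  knee <- rep(170, length(t))
  dip <- function(at) {
    w <- which(t >= at & t < at + 1)
    knee[w] <<- 170 - 60 * (1 - cos(2 * pi * seq(0, 1,
                                                 length.out = length(w)))) / 2
  }
  dip(2); dip(7); dip(12)
  st <- detect_steps(knee, fs, step_lengths = c(30, 30, 5))
  expect_equal(nrow(st), 3)
  expect_equal(sum(st$failed), 1)
  expect_true(all(diff(st$onset_s) >= 2))
  # dips 1 s apart merge under the refractory rule
  knee2 <- rep(170, length(t))
  w1 <- which(t >= 2 & t < 2.4)
  w2 <- which(t >= 3 & t < 3.4)
  knee2[c(w1, w2)] <- 120
  expect_equal(nrow(detect_steps(knee2, fs)), 1)
  # no dip below threshold -> no steps
  expect_equal(nrow(detect_steps(rep(150, 500) * 0 + 150, fs)), 0)
  # idempotence and 2x resampling invariance
  st_up <- detect_steps(knee[seq(1, length(knee), by = 2)], fs / 2,
                        step_lengths = c(30, 30, 5))
  expect_equal(nrow(st_up), 3)
  expect_equal(st_up$onset_s, st$onset_s, tolerance = 0.05)
})

test_that("gait parameters read constructed cycles exactly; PCA separates cohorts", {
  fs <- 100
  n <- 12 * fs
  t <- seq_len(n) / fs
  knee <- rep(170, n)
  for (at in c(2, 5, 8)) {
    w <- which(t >= at & t < at + 1)
    knee[w] <- 170 - 60 * (1 - cos(2 * pi * seq(0, 1,
                                                length.out = length(w)))) / 2
  }
  kin <- data.frame(knee_angle = knee, hip_angle = 160,
                    limb_angle = 10, foot_x = 0, foot_y = 0, knee_y = 0.5)
  # 0.40 m of forward foot progression within each cycle
  kin$foot_x <- approx(c(0, 2, 5, 8, 12), c(0, 0, 0.4, 0.8, 0.8),
                       xout = t)$y
  kin$foot_y <- 0.05 * (knee < 160)
  emg <- matrix(abs(rnorm(6 * n, sd = 0.1)), 6,
                dimnames = list(gait_muscles(), NULL))
  gp <- gait_cycle_params(kin, emg, fs)
  expect_equal(nrow(gp), 2)
  expect_equal(names(gp), c("cycle", gait_param_names()))
  expect_equal(gp$step_length[1], 0.4, tolerance = 0.02)
  expect_equal(gp$knee_max_angle[1], 170)
  expect_equal(gp$hip_angle[1], 160)
  # missing channels produce a named error
  expect_error(gait_cycle_params(kin[, -2], emg, fs), "hip_angle",
               class = "bsitools_input_error")
  expect_error(gait_cycle_params(kin, emg[-1, ], fs), "vastus",
               class = "bsitools_input_error")
  # identical cycles -> zero distance in PC space; a shifted cohort loads
  # on the shifted parameter's direction
  set.seed(88)
  base <- gp[rep(1, 20), ]
  jitter <- function(df) {
    df$knee_angle <- df$knee_angle + rnorm(nrow(df), sd = 0.5)
    df$step_length <- df$step_length + rnorm(nrow(df), sd = 0.01)
    df
  }
  cohort_a <- jitter(base); cohort_a$condition <- "A"
  cohort_b <- jitter(base); cohort_b$condition <- "B"
  cohort_c <- jitter(base); cohort_c$step_length <-
    cohort_c$step_length + 0.3; cohort_c$condition <- "C"
  pooled <- rbind(cohort_a, cohort_b, cohort_c)
  gpca <- gait_pca(pooled, reference = "A")
  d <- gpca$distances
  expect_lt(d$distance_to_reference[d$condition == "B"],
            0.3 * d$distance_to_reference[d$condition == "C"])
  # the C centroid shift loads on step_length's PC direction
  shift_dir <- abs(gpca$loadings["step_length", ])
  expect_equal(unname(which.max(shift_dir)), which.max(abs(
    as.numeric(gpca$centroids[gpca$centroids$condition == "C", -1]) -
      as.numeric(gpca$centroids[gpca$centroids$condition == "A", -1]))))
})
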