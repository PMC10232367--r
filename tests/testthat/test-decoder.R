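make_tiny_model <- function(K = 3, Fdim = 6, lambda = 1, ...) {
  mslm_model(states = c("rest", letters[seq_len(K - 1)]), Fdim = Fdim,
             lambda = lambda, ...)
}

test_that("softmax emissions: uniform at zero scores, shift invariant, closed form", {
  m <- make_tiny_model()
  em <- emission_probabilities(m, rep(0.5, 6))
  expect_equal(em$alpha_emission, rep(1 / 3, 3))
  # shift invariance
  m$beta_gate <- matrix(rnorm(18), 3)
  m$b_gate <- c(0.3, -1, 2)
  x <- rnorm(6)
  a1 <- emission_probabilities(m, x)$alpha_emission
  m$b_gate <- m$b_gate + 7.5
  a2 <- emission_probabilities(m, x)$alpha_emission
  expect_equal(a1, a2, tolerance = 1e-12)
  # K = 2 closed form: d = (ln 2, 0) -> (2/3, 1/3)
  m2 <- mslm_model(states = c("rest", "a"), Fdim = 2)
  m2$b_gate <- c(log(2), 0)
  expect_equal(emission_probabilities(m2, c(0, 0))$alpha_emission,
               c(2 / 3, 1 / 3), tolerance = 1e-12)
  # numerically stable under huge scores
  m2$b_gate <- c(1e4, 0)
  expect_equal(emission_probabilities(m2, c(0, 0))$alpha_emission,
               c(1, 0), tolerance = 1e-12)
  expect_error(emission_probabilities(m, rnorm(5)),
               class = "bsitools_input_error")
})

test_that("HMM filtering matches the brute-force forward recursion", {
  # printed closed-form instance
  ah <- hmm_filter(c(0.8, 0.2),
                   matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE),
                   c(0.6, 0.4))
  expect_equal(ah, c(0.528, 0.068) / 0.596, tolerance = 1e-12)
  # uniform transition rows leave the emission untouched
  Tm <- matrix(1 / 3, 3, 3)
  em <- c(0.5, 0.3, 0.2)
  expect_equal(hmm_filter(em, Tm, c(0.9, 0.05, 0.05)), em)
  # identity transition with one-hot prior is absorbing
  expect_equal(hmm_filter(rep(1 / 3, 3), diag(3), c(0, 1, 0)), c(0, 1, 0))
  # random instances vs the independent forward-step oracle
  set.seed(404)
  for (rep in 1:200) {
    K <- sample(2:5, 1)
    Tm <- matrix(stats::rexp(K * K), K)
    Tm <- Tm / rowSums(Tm)
    em <- rsimplex(K)
    ap <- rsimplex(K)
    expect_equal(hmm_filter(em, Tm, ap), forward_step_oracle(em, Tm, ap),
                 tolerance = 1e-12)
  }
})

test_that("alpha-hat stays on the simplex over long streams", {
  set.seed(5)
  K <- 4
  Tm <- matrix(stats::rexp(K * K), K)
  Tm <- Tm / rowSums(Tm)
  alpha <- rep(1 / K, K)
  for (i in 1:5000) {
    alpha <- hmm_filter(rsimplex(K), Tm, alpha)
    stopifnot(abs(sum(alpha) - 1) < 1e-9, all(alpha >= 0))
  }
  expect_lt(abs(sum(alpha) - 1), 1e-9)
})

test_that("experts are linear with a zero rest output; mixture follows the product formula", {
  m <- make_tiny_model()
  expect_equal(expert_predict(m, rnorm(6)), rep(0, 3))
  m$beta_exp <- matrix(rnorm(18), 3)
  m$b_exp <- rep(0, 3)
  x <- rnorm(6)
  expect_equal(expert_predict(m, 2 * x)[-1], 2 * expert_predict(m, x)[-1],
               tolerance = 1e-12)
  # dense-algebra oracle
  phi <- expert_predict(m, x)
  expect_equal(phi[-1], drop(m$beta_exp %*% x)[-1], tolerance = 1e-12)
  expect_equal(phi[1], 0)
  # mixture closed forms
  expect_equal(mixture(c(1, 1, 1), c(0.5, 0.5, 0)), c(0.25, 0.25, 0))
  expect_equal(mixture(c(2, -1, 3), c(0, 1, 0)), c(0, -1, 0))
  # direct-formula oracle on random instances
  set.seed(8)
  for (rep in 1:50) {
    K <- sample(2:6, 1)
    phi <- rnorm(K)
    a <- rsimplex(K)
    direct <- vapply(seq_len(K), function(k) {
      phi[k] * a[k] * prod(1 - a[setdiff(seq_len(K), k)])
    }, numeric(1))
    expect_equal(mixture(phi, a), direct, tolerance = 1e-12)
    expect_true(all(mixture(phi, a)[a == 0] == 0))
  }
})

test_that("decode_step composes the stages and is pure in alpha_prev", {
  m <- make_tiny_model()
  # uninitialized model: uniform posterior, zero commands
  st <- decode_step(m, rnorm(6))
  expect_equal(st$alpha_hat, rep(1 / 3, 3))
  expect_equal(st$u, rep(0, 3))
  # streaming equals repeated decode_step with chained alpha_prev
  set.seed(12)
  m$beta_gate <- matrix(rnorm(18), 3)
  m$trans_counts[] <- matrix(c(5, 1, 1, 1, 5, 1, 1, 1, 5), 3)
  X <- matrix(rnorm(10 * 6), 10)
  feats <- list(x = X, t = seq(0.5, length.out = 10, by = 0.1),
                config_hash = m$feat$config_hash)
  dec <- decode_stream(m, feats)
  alpha <- NULL
  for (i in 1:10) {
    s <- decode_step(m, X[i, ], alpha)
    alpha <- s$alpha_hat
    expect_equal(dec$alpha_hat[i, ], alpha, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(dec$u[i, ], s$u, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("transition counting and smoothing behave exactly", {
  states <- c("rest", "A", "B")
  cnt <- matrix(0, 3, 3, dimnames = list(states, states))
  # constant stream of length n -> diagonal count n - 1
  cnt1 <- update_transitions(cnt, rep("A", 7))
  expect_equal(cnt1["A", "A"], 6)
  expect_equal(sum(cnt1), 6)
  # alternating stream counts directed transitions
  cnt2 <- update_transitions(cnt, c("A", "B", "A", "B"))
  expect_equal(cnt2["A", "B"], 2)
  expect_equal(cnt2["B", "A"], 1)
  expect_error(update_transitions(cnt, c("A", "Z")),
               class = "bsitools_input_error")
  # smoothing: rows sum to one for any counts when eps > 0
  Tn <- normalize_transitions(cnt2, eps = 1)
  expect_equal(rowSums(Tn), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(Tn > 0))
})

test_that("recursive updates reproduce pooled and geometrically weighted fits", {
  set.seed(31)
  for (method in c("ls", "pls")) {
    for (rep in 1:5) {
      Fd <- sample(5:40, 1)
      K <- 3
      n1 <- sample(50:200, 1)
      n2 <- sample(50:200, 1)
      X1 <- matrix(rnorm(n1 * Fd), n1)
      X2 <- matrix(rnorm(n2 * Fd), n2)
      B <- matrix(rnorm(Fd * K), Fd)
      mk_y <- function(X) X %*% B + 0.1 * rnorm(nrow(X) * K) + 1.5
      Y1 <- mk_y(X1); Y2 <- mk_y(X2)
      # with components spanning the feature space, PLS equals least
      # squares, so both methods must match the pooled lm oracle
      m <- make_tiny_model(K = K, Fdim = Fd, method = method, n_comp = Fd)
      m <- rew_update(m, X1, Y1, lambda = 1)
      m <- rew_update(m, X2, Y2, lambda = 1)
      # direct moment solves agree to 1e-8; the PLS route reaches the
      # same solution through F deflation steps, so allow round-off
      tol <- if (method == "ls") 1e-8 else 1e-6
      fit <- lm(rbind(Y1, Y2) ~ rbind(X1, X2))
      expect_equal(max(abs(m$beta_gate - t(coef(fit)[-1, ]))), 0,
                   tolerance = tol)
      expect_equal(max(abs(m$b_gate - coef(fit)[1, ])), 0,
                   tolerance = tol)
      # lambda = 0.5 halves the first batch's influence per update
      m5 <- make_tiny_model(K = K, Fdim = Fd, method = method, n_comp = Fd)
      m5 <- rew_update(m5, X1, Y1, lambda = 1)
      m5 <- rew_update(m5, X2, Y2, lambda = 0.5)
      wfit <- lm(rbind(Y1, Y2) ~ rbind(X1, X2),
                 weights = c(rep(0.5, n1), rep(1, n2)))
      expect_equal(max(abs(m5$beta_gate - t(coef(wfit)[-1, ]))), 0,
                   tolerance = tol)
    }
  }
  # all-zero targets give zero coefficients under centring
  for (method in c("ls", "pls")) {
    m0 <- make_tiny_model(Fdim = 8, method = method)
    m0 <- rew_update(m0, matrix(rnorm(80), 10), matrix(0, 10, 3))
    expect_equal(max(abs(m0$beta_gate)), 0, tolerance = 1e-10)
    expect_equal(max(abs(m0$b_gate)), 0, tolerance = 1e-10)
  }
})

test_that("truncated-component recursive PLS is order-consistent at lambda = 1", {
  # the recursive fit is a pure function of the pooled moments, so any
  # batch split must give the same truncated-PLS coefficients
  set.seed(101)
  Fd <- 30; K <- 3
  X <- matrix(rnorm(300 * Fd), 300)
  Y <- X[, 1:3] %*% diag(c(2, -1, 0.5)) + 0.2 * matrix(rnorm(900), 300)
  one <- rew_update(make_tiny_model(K, Fd, n_comp = 5), X, Y, lambda = 1)
  two <- make_tiny_model(K, Fd, n_comp = 5)
  two <- rew_update(two, X[1:120, ], Y[1:120, ], lambda = 1)
  two <- rew_update(two, X[121:300, ], Y[121:300, ], lambda = 1)
  expect_equal(two$beta_gate, one$beta_gate, tolerance = 1e-8)
  expect_equal(two$b_gate, one$b_gate, tolerance = 1e-8)
})

test_that("rank-deficient batches fall back to a logged ridge (ls method)", {
  m <- make_tiny_model(Fdim = 10, lambda = 1, method = "ls")
  X <- matrix(rnorm(40), 4) # n << F: singular moments
  Y <- matrix(rnorm(12), 4)
  m <- rew_update(m, X, Y)
  expect_equal(m$calib$ridge_events, 1L)
  expect_true(all(is.finite(m$beta_gate)))
})

test_that("online calibration: assistance schedule, determinism, guards", {
  cfg <- sim_config(seed = 77, n_channels = 4L, states = c("rest", "hipL"),
                    informative_map = data.frame(state = "hipL",
                                                 channel = 2L,
                                                 band = "40-100", gain = 4),
                    n_reps = 8L, cue_duration_s = 2)
  sess <- simulate_session(cfg)
  feats <- suppressWarnings(
    feature_stream(preprocess_ecog(sess$ecog, sess$fs), sess$fs,
                   epoch_s = 0.3, n_taps = 2))
  model <- mslm_model(states = cfg$states, features = feats)
  cal <- calibrate_online(model, feats, sess$cues, assist_batches = 2)
  # a 32 s stream yields two full 15 s batches
  expect_equal(nrow(cal$history), 2)
  # assistance starts at 1 and is monotone non-increasing
  expect_equal(cal$history$assistance[1], 1)
  expect_true(all(diff(cal$history$assistance) <= 0))
  # while assistance is 1 the blended output follows the cue exactly
  expect_equal(cal$history$acc_output[1], 1)
  # rerun with the same inputs is identical
  cal2 <- calibrate_online(mslm_model(states = cfg$states,
                                      features = feats),
                           feats, sess$cues, assist_batches = 2)
  expect_identical(cal$history, cal2$history)
  expect_equal(cal$model$beta_gate, cal2$model$beta_gate)
  # too-short stream errors
  short <- bsitools:::subset_features(feats, 1:10)
  expect_error(calibrate_online(model, short, sess$cues),
               class = "bsitools_input_error")
  # mismatched fingerprint refused
  other <- feats
  other$config_hash <- "deadbeef"
  expect_error(decode_stream(cal$model, other),
               class = "bsitools_input_error")
})

test_that("gate weights concentrate on the simulator's informative channel", {
  cfg <- sim_config(seed = 19, n_channels = 6L, states = c("rest", "hipL"),
                    informative_map = data.frame(state = "hipL",
                                                 channel = c(2L, 2L),
                                                 band = c("10-40", "40-100"),
                                                 gain = c(2, 4)),
                    n_reps = 10L, cue_duration_s = 2)
  sess <- simulate_session(cfg)
  feats <- suppressWarnings(
    feature_stream(preprocess_ecog(sess$ecog, sess$fs), sess$fs,
                   epoch_s = 0.3, n_taps = 2))
  # latent capacity matched to this small problem (see methods vignette)
  cal <- calibrate_online(mslm_model(states = cfg$states, features = feats,
                                     n_comp = 5L),
                          feats, sess$cues)
  idx <- bsitools:::feature_index_table(6L, 2L)
  w <- colSums(abs(cal$model$beta_gate))
  top <- w >= quantile(w, 0.9)
  # top-decile weight mass sits mostly on the informative channel
  expect_gt(mean(idx$channel[top] == 2L), 3 * 1 / 6)
  # decoding the calibration stream recovers the cues well above chance
  dec <- decode_stream(cal$model, feats)
  acc <- mean(dec$state == cue_state_at(sess$cues, feats$t))
  expect_gt(acc, 0.75)
})
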