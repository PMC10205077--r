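# generator: MVAR realizations, behavioural sampling, session simulation

test_that("mvar_generate with zero coefficients returns the noise draws exactly", {
  K <- 3; n <- 200; burn <- 50
  m <- mvar_model(list(matrix(0, K, K)), diag(K), 1250)
  X <- mvar_generate(m, n, seed = 42, burn_in = burn)
  set.seed(42)
  E <- matrix(rnorm(K * (n + burn)), K, n + burn)
  expect_identical(X, E[, (burn + 1):(burn + n)])
})

test_that("AR(1) realization reproduces the closed-form stationary variance", {
  m <- mvar_model(list(matrix(0.9, 1, 1)), matrix(1, 1, 1), 1250)
  x <- mvar_generate(m, 1e5, seed = 7)
  expect_equal(var(as.vector(x)), 1 / (1 - 0.81), tolerance = 0.1)
})

test_that("directed lag-1 coupling shows up as asymmetric lagged cross-correlation", {
  B1 <- matrix(c(0.3, 0.5, 0, 0.3), 2, 2)  # 1 -> 2 at lag 1
  m <- mvar_model(list(B1), diag(2), 1250)
  X <- mvar_generate(m, 2e4, seed = 11)
  n <- ncol(X)
  c12 <- cor(X[1, -n], X[2, -1])  # x1(t-1) vs x2(t)
  c21 <- cor(X[2, -n], X[1, -1])
  expect_gt(c12, c21)
  expect_gt(c12, 0.2)
})

test_that("unstable models are rejected with the spectral radius in the message", {
  m <- mvar_model(list(matrix(1.05, 1, 1)), matrix(1, 1, 1), 1250)
  expect_error(mvar_generate(m, 100, seed = 1), "radius.*1\\.05")
})

test_that("generation is bit-reproducible for a fixed seed", {
  m <- ar2_base(2)
  expect_identical(mvar_generate(m, 500, seed = 3), mvar_generate(m, 500, seed = 3))
  expect_false(identical(mvar_generate(m, 500, seed = 3), mvar_generate(m, 500, seed = 4)))
})

test_that("sample_behavior alternates conditions and uses the stated latency means", {
  p <- behavior_params()
  expect_equal(unname(p$latency_mean), c(0.736, 0.818))
  tr <- sample_behavior(p, 60, seed = 1)
  expect_equal(nrow(tr), 60)
  expect_equal(sum(tr$condition == "word"), 30)
  expect_equal(sum(tr$condition == "pseudoword"), 30)
  expect_equal(tr$condition, rep(c("word", "pseudoword"), 30))
  # ordering invariants
  expect_true(all(tr$cue_onset_s < tr$stimulus_onset_s))
  expect_true(all(tr$stimulus_onset_s < tr$speech_onset_s))
  expect_true(all(tr[, c("c1_dur_s", "v_dur_s", "c2_dur_s")] > 0))
  # ISI bounds: stimulus = cue + 250 ms + U(500, 1000) ms
  isi <- tr$stimulus_onset_s - tr$cue_onset_s - 0.25
  expect_true(all(isi >= 0.5 & isi <= 1.0))
})

test_that("zero-variance behaviour parameters give identical trials at the means", {
  p <- behavior_params(latency_sd = c(word = 0, pseudoword = 0),
                       c1_sd = c(0, 0), v_sd = c(0, 0), c2_sd = c(0, 0),
                       isi_range = c(0.75, 0.75))
  tr <- sample_behavior(p, 10, seed = 5)
  lat <- tr$speech_onset_s - tr$stimulus_onset_s
  expect_equal(lat[tr$condition == "word"], rep(0.736, 5))
  expect_equal(lat[tr$condition == "pseudoword"], rep(0.818, 5))
  expect_equal(unique(tr$c1_dur_s[tr$condition == "word"]), 0.093)
})

test_that("behaviour sampling validates its inputs", {
  expect_error(behavior_params(latency_mean = c(word = -0.1, pseudoword = 0.8)),
               "positive")
  expect_error(sample_behavior(behavior_params(), 7, seed = 1), "even")
})

test_that("coupling and network constructors enforce their invariants", {
  expect_error(coupling_event("a", "a", 0.5), "differ")
  expect_error(coupling_event("a", "b", 0.5, window = c(0.2, 0.1)), "precede")
  ch <- data.frame(id = c("STG1", "STN1"), region = c("STG", "STN"),
                   stringsAsFactors = FALSE)
  # reciprocal lag-2 pair beyond the 1 - r^2 stability bound must be rejected
  expect_error(network_spec(ch, ar2_base(2), list(
    coupling_event("STG1", "STN1", 0.5, lag = 2, window = c(-0.3, 0.3)),
    coupling_event("STN1", "STG1", 0.5, lag = 2, window = c(-0.3, 0.3)))),
    "unstable")
})

test_that("simulate_session records ground-truth coupling intervals per trial", {
  ses <- simulate_session(tiny_network(), n_trials = 4, seed = 9)
  tt <- ses$truth_table
  expect_equal(nrow(tt), 4)
  expect_equal(tt$start_s - ses$trials$speech_onset_s, rep(-0.45, 4))
  expect_equal(tt$end_s - ses$trials$speech_onset_s, rep(-0.40, 4))
  # condition-specific couplings are only active on matching trials
  net <- network_spec(tiny_network()$channels, ar2_base(2),
                      list(coupling_event("STG1", "STN1", 0.25, lag = 2,
                                          window = c(-0.45, -0.40),
                                          condition = "word")))
  ses2 <- simulate_session(net, n_trials = 4, seed = 9)
  expect_equal(sort(unique(ses2$truth_table$trial_id)),
               which(ses2$trials$condition == "word"))
})

test_that("null network gives near-zero lagged cross-correlations", {
  ses <- simulate_session(tiny_network(couple = FALSE), n_trials = 4, seed = 2)
  X <- ses$recording$signals
  n <- ncol(X)
  for (lag in 0:3) {
    cc <- cor(X[1, 1:(n - lag)], X[2, (1 + lag):n])
    expect_lt(abs(cc), 0.05)  # Monte-Carlo envelope at n ~ 5e4
  }
})

test_that("two seeds differ in signals but share schema and trial counts", {
  s1 <- simulate_session(tiny_network(), n_trials = 4, seed = 1)
  s2 <- simulate_session(tiny_network(), n_trials = 4, seed = 2)
  expect_false(identical(s1$recording$signals[, 1:1000], s2$recording$signals[, 1:1000]))
  expect_identical(dim(s1$recording$signals)[1], dim(s2$recording$signals)[1])
  expect_identical(nrow(s1$trials), nrow(s2$trials))
  expect_identical(s1$trials$condition, s2$trials$condition)
  # determinism: same seed, same everything
  expect_identical(s1$recording$signals,
                   simulate_session(tiny_network(), n_trials = 4, seed = 1)$recording$signals)
})

test_that("overlapping trial epochs abort with the trial indices named", {
  expect_error(
    simulate_session(tiny_network(), n_trials = 4, seed = 1,
                     lead_s = 0.05, gap_s = 0.01),
    "overlapping.*1")
})

test_that("the default cohort matches the paradigm design", {
  cohort <- build_default_cohort(seed = 1, n_trials = 4)
  expect_length(cohort, 10)
  expect_length(unique(attr(cohort, "subjects")), 4)
  for (ses in cohort) {
    expect_equal(sum(ses$truth$channels$region == "STN"), 3)
    cps <- ses$truth$couplings
    gw <- vapply(cps, function(cp)
      if (cp$source == "STG1" && cp$condition == "word") cp$gain else NA_real_, 1)
    gp <- vapply(cps, function(cp)
      if (cp$source == "STG1" && cp$condition == "pseudoword") cp$gain else NA_real_, 1)
    expect_gt(min(gw, na.rm = TRUE), max(gp, na.rm = TRUE))
  }
  # default design: 10 sessions x 60 trials = 600 recorded trials
  expect_equal(eval(formals(build_default_cohort)$n_trials) *
                 eval(formals(build_default_cohort)$n_sessions), 600)
})

test_that("every emitted base model passes the stability guard", {
  for (seed in 1:3) {
    net <- default_network(gain_jitter = 1.1)
    expect_true(mvar_is_stable(net$base_model))
    all_on <- ercflow:::apply_couplings(net$base_model, net$couplings, net$channels$id)
    expect_true(mvar_is_stable(all_on))
  }
})
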