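# smoothing, session/group significance, contrasts, flow integration

test_that("2D moving average preserves constants and locates steps", {
  const <- matrix(3.7, 31, 100)
  expect_equal(smooth_tf(const, c(9, 5)), const)

  # unit step along time: the smoothed curve crosses 0.5 at the true edge
  step <- matrix(rep(c(rep(0, 50), rep(1, 50)), each = 11), nrow = 11)
  sm <- smooth_tf(step, c(9, 5))
  cross <- which(sm[6, ] >= 0.5)[1]
  expect_lte(abs(cross - 51), 1)

  expect_error(smooth_tf(matrix(0, 3, 3), c(9, 5)), "larger")
  expect_error(smooth_tf(const, c(8, 5)), "odd")
})

test_that("interior variance shrinks by the kernel area under i.i.d. noise", {
  set.seed(99)
  ratios <- replicate(100, {
    f <- matrix(rnorm(31 * 80), 31, 80)
    sm <- smooth_tf(f, c(9, 5))
    var(as.vector(sm[11:21, 21:60]))
  })
  expect_equal(mean(ratios), 1 / 45, tolerance = 0.2)
})

test_that("session ERC is calibrated under the null and reports increases only", {
  # statistically identical task and baseline (100+ directed pairs)
  set.seed(1234)
  K <- 11; nf <- 13; nw_t <- 60; nw_b <- 40
  mk <- function(nw) fake_flow_tensor(
    array(abs(rnorm(K * K * nf * nw, 0.1, 0.02)), c(K, K, nf, nw)),
    channels = paste0("ch", 1:K), freqs = seq(60, 180, 10),
    times = seq(-0.4, length.out = nw, by = 0.0056))
  erc <- erc_session(mk(nw_t), mk(nw_b), stats_config())
  expect_lte(mean(erc$mask, na.rm = TRUE), 0.05)
  expect_true(all(erc$delta[erc$mask] > 0))

  # a pair uniformly below baseline is never reported
  task <- mk(nw_t); base <- mk(nw_b)
  task[2, 1, , ] <- 0.01
  base[2, 1, , ] <- base[2, 1, , ] + 0.2
  erc2 <- erc_session(task, base, stats_config())
  expect_false(any(erc2$mask[2, 1, , ]))

  # baseline shorter than the smoothing kernel is rejected
  expect_error(erc_session(mk(nw_t), mk(5), stats_config()), "kernel")
})

test_that("an injected directed burst is detected at the right time, in the right direction", {
  # ground-truth STG -> STN coupling confined to (-0.45, -0.40) s
  detect <- function(seed) {
    ses <- simulate_session(tiny_network(gain = 0.4), n_trials = 60, seed = seed)
    base <- epoch(ses$recording, "cue", c(-0.52, 0))
    resp <- epoch(ses$recording, "speech_onset", c(-0.5, 0.5))
    ft <- sliding_sddtf(resp, p = 4, groups = 5)
    fb <- sliding_sddtf(base, p = 4, groups = 5)
    erc <- erc_session(ft, fb)
    fwd <- apply(erc$mask[2, 1, , ], 2, any)   # STG1 -> STN1
    rev <- mean(erc$mask[1, 2, , ])
    t_sig <- erc$times[fwd]
    hit <- any(t_sig >= -0.45 - 0.14 & t_sig <= -0.40 + 0.14)
    c(hit = hit, rev = rev)
  }
  res <- vapply(1:3, detect, c(hit = 0, rev = 0))
  expect_equal(unname(res["hit", ]), c(1, 1, 1))
  expect_lte(max(res["rev", ]), 0.05)
})

test_that("group pooling masks shared effects and stays calibrated under the null", {
  # synthetic session-level results built directly on the statistics layer
  mk_erc <- function(seed, effect = 0) {
    set.seed(seed)
    K <- 2; nf <- 13; nw <- 50
    times <- seq(-0.45, length.out = nw, by = 0.0056)
    delta <- array(rnorm(K * K * nf * nw, 0, 0.01), c(K, K, nf, nw))
    on <- times >= -0.40 & times <= -0.30
    delta[2, 1, , on] <- delta[2, 1, , on] + effect
    mask <- array(FALSE, dim(delta))
    # only session-significant pairs enter a class course
    if (effect > 0) mask[2, 1, , on] <- TRUE
    structure(list(delta = delta, q = array(0.5, dim(delta)), mask = mask,
                   baseline_mean = array(0.1, c(K, K, nf)),
                   channels = c("STG1", "STN1"), regions = c("STG", "STN"),
                   freqs = seq(60, 180, 10), times = times,
                   cfg = stats_config()),
              class = "erc_result")
  }
  grp <- erc_group(lapply(1:10, mk_erc, effect = 0.05))
  cls <- grp$classes[["STG->STN"]]
  on <- grp$times >= -0.40 & grp$times <= -0.30
  expect_true(all(cls$mask[on]))
  expect_equal(cls$n_sessions, 10)

  # null sessions carry no significant pairs: the group result is empty
  expect_warning(null_grp <- erc_group(lapply(11:20, mk_erc, effect = 0)),
                 "no region-pair class")
  expect_length(null_grp$classes, 0)

  expect_error(erc_group(list(mk_erc(1))), ">= 2")
})

test_that("condition contrasts are signed, paired and calibrated", {
  mk_erc <- function(seed, effect) {
    set.seed(seed)
    K <- 2; nf <- 5; nw <- 60
    times <- seq(-0.35, length.out = nw, by = 0.0056)
    delta <- array(rnorm(K * K * nf * nw, 0, 0.01), c(K, K, nf, nw))
    on <- times >= -0.208 & times <= -0.117
    delta[2, 1, , on] <- delta[2, 1, , on] + effect
    mask <- array(FALSE, dim(delta))
    mask[2, 1, , on] <- TRUE  # condition-neutral pair selection
    structure(list(delta = delta, mask = mask,
                   channels = c("STG1", "STN1"),
                   regions = c("STG", "STN"), freqs = seq(60, 180, 30),
                   times = times, cfg = stats_config()),
              class = "erc_result")
  }
  words <- erc_group(lapply(1:10, function(s) mk_erc(s, 0.06)))
  pseudo <- erc_group(lapply(1:10, function(s) mk_erc(100 + s, 0.03)))
  ctr <- condition_contrast(words, pseudo)
  cc <- ctr[["STG->STN"]]
  on <- attr(ctr, "times") >= -0.208 & attr(ctr, "times") <= -0.117
  expect_true(any(cc$mask[on] == 1))
  expect_false(any(cc$mask[on] == -1))
  wt <- attr(ctr, "window_tests")
  lex <- wt[wt$window == "lexical_contrast", ]
  expect_gt(lex$diff, 0)
  expect_lte(lex$q, 0.05)

  # identical conditions: masked fraction within the FDR level
  same <- erc_group(lapply(21:30, function(s) mk_erc(s, 0.05)))
  same2 <- erc_group(lapply(21:30, function(s) mk_erc(s, 0.05)))
  ctr0 <- condition_contrast(same, same2)
  expect_lte(mean(ctr0[["STG->STN"]]$mask != 0), 0.05)
  wt0 <- attr(ctr0, "window_tests")
  expect_true(all(wt0$q > 0.05))

  # named preset intervals are exposed
  pr <- erc_presets()
  expect_equal(pr$lexical_contrast, c(-0.208, -0.117))
  expect_equal(pr$pre_speech_burst, c(-0.45, -0.40))
})

test_that("flow integration averages significant increases and zeroes the rest", {
  K <- 2; nf <- 3; nw <- 40
  times <- seq(-0.5, length.out = nw, by = 0.0056)
  delta <- array(0, c(K, K, nf, nw))
  mask <- array(FALSE, dim(delta))
  iv <- times >= -0.45 & times < -0.40
  delta[2, 1, , iv] <- 0.07
  mask[2, 1, , iv] <- TRUE
  erc <- structure(list(delta = delta, mask = mask,
                        channels = c("STG1", "STN1"), regions = c("STG", "STN"),
                        freqs = c(60, 120, 180), times = times,
                        cfg = stats_config()),
                   class = "erc_result")
  g <- integrate_flows(erc, c(-0.45, -0.40))
  expect_equal(g$weight[g$source == "STG1" & g$target == "STN1"], 0.07)
  expect_equal(g$weight[g$source == "STN1" & g$target == "STG1"], 0)

  empty <- erc
  empty$mask[] <- FALSE
  g0 <- integrate_flows(empty, c(-0.45, -0.40))
  expect_true(all(g0$weight == 0))

  expect_error(integrate_flows(erc, c(-0.4, -0.45)), "interval")
  expect_error(integrate_flows(erc, c(5, 6)), "time grid")
})
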