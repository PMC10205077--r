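#' Time-localized, condition-dependent directed coupling
#'
#' A coupling event adds a cross-channel lag coefficient `gain` from `source`
#' to `target`, switched on inside a time `window` (seconds, half-open,
#' relative to each trial's alignment event — speech onset) with a short
#' raised-cosine taper at the edges. `condition` restricts the coupling to
#' word trials, pseudoword trials, or both.
#'
#' @param source,target channel ids (must differ)
#' @param gain dimensionless coefficient magnitude added at lag `lag`
#' @param lag lag in samples (>= 1)
#' @param window numeric length-2, `(start_s, end_s)` half-open, relative to
#'   the alignment event
#' @param condition one of `"word"`, `"pseudoword"`, `"both"`
#' @return a `coupling_event` list
#' @export
coupling_event <- function(source, target, gain, lag = 2L,
                           window = c(-0.45, -0.40), condition = "both") {
  assert_that(!identical(source, target), "coupling source must differ from target")
  assert_that(is.finite(gain), "gain must be finite")
  assert_that(length(window) == 2 && window[1] < window[2],
              "window start must precede end")
  assert_that(lag >= 1, "lag must be >= 1 sample")
  condition <- match.arg(condition, c("word", "pseudoword", "both"))
  structure(list(source = source, target = target, gain = gain,
                 lag = as.integer(lag), window = as.numeric(window),
                 condition = condition),
            class = "coupling_event")
}

#' Ground-truth network specification for session simulation
#'
#' Couples a stable base MVAR model (the background dynamics of every channel)
#' with a set of [coupling_event()]s that are switched on in trial-locked
#' windows. Stability is verified for the base model alone, with each coupling
#' active individually, and with all couplings active simultaneously.
#'
#' @param channels data.frame with columns `id`, `region`
#'   (STN/PreCG/PoCG/STG), and optionally `activated` (logical; whether the
#'   channel receives the task-evoked high-gamma amplitude envelope)
#' @param base_model an [mvar_model()] describing background dynamics
#' @param couplings list of [coupling_event()]
#' @param noise_sd per-channel innovation SD multipliers (recycled)
#' @return a `network_spec` object
#' @export
network_spec <- function(channels, base_model, couplings = list(),
                         noise_sd = 1) {
  assert_that(is.data.frame(channels) && all(c("id", "region") %in% names(channels)),
              "channels must be a data.frame with id and region")
  K <- nrow(channels)
  assert_that(nrow(base_model$noise_cov) == K,
              "base_model dimension must match channel count")
  if (is.null(channels$activated)) channels$activated <- TRUE
  assert_that(!anyDuplicated(channels$id), "channel ids must be unique")
  for (cp in couplings) {
    assert_that(all(c(cp$source, cp$target) %in% channels$id),
                "coupling references unknown channel id")
  }
  check_sets <- c(list(list()), lapply(couplings, list), list(couplings))
  for (set in check_sets) {
    m <- apply_couplings(base_model, set, channels$id)
    if (!mvar_is_stable(m)) {
      stop_ercflow("network unstable (companion spectral radius %.4f) with coupling set of size %d",
                   mvar_spectral_radius(m), length(set))
    }
  }
  structure(list(channels = channels, base_model = base_model,
                 couplings = couplings,
                 noise_sd = rep_len(noise_sd, K)),
            class = "network_spec")
}

# base model with a subset of couplings switched fully on (used for stability
# checks and for oracle computations of the true spectral quantities)
apply_couplings <- function(base_model, couplings, ids) {
  p_need <- max(c(base_model$order, vapply(couplings, `[[`, 1L, "lag")))
  coefs <- vector("list", p_need)
  K <- nrow(base_model$noise_cov)
  for (j in seq_len(p_need)) {
    coefs[[j]] <- if (j <= base_model$order) base_model$coefs[[j]] else matrix(0, K, K)
  }
  for (cp in couplings) {
    si <- match(cp$source, ids); ti <- match(cp$target, ids)
    coefs[[cp$lag]][ti, si] <- coefs[[cp$lag]][ti, si] + cp$gain
  }
  mvar_model(coefs, base_model$noise_cov, base_model$sampling_rate)
}

#' Behavioural paradigm parameters
#'
#' Defaults encode the cued overt-reading paradigm: a 250 ms preparatory cue,
#' a uniform 500-1000 ms interstimulus interval, and per-condition reading
#' latencies and consonant-vowel-consonant (C1/V/C2) articulation durations.
#' Latency/duration distributions are truncated normal (at zero). Default
#' means are 736 ms (word) / 818 ms (pseudoword) latency, with C1/V/C2 means
#' of 93/217/170 ms (word) and 105/203/187 ms (pseudoword); trial-level SDs
#' are back-computed from the published standard errors as SEM * sqrt(30),
#' 30 being the per-condition trial count of one session.
#'
#' @param latency_mean,latency_sd named numeric `(word, pseudoword)`, seconds
#' @param c1_mean,c1_sd,v_mean,v_sd,c2_mean,c2_sd phoneme duration
#'   distributions, seconds
#' @param isi_range uniform interstimulus-interval range, seconds
#' @param cue_duration preparatory cue duration, seconds
#' @return a `behavior_params` object
#' @export
behavior_params <- function(latency_mean = c(word = 0.736, pseudoword = 0.818),
                            latency_sd = c(word = 0.034, pseudoword = 0.050) * sqrt(30),
                            c1_mean = c(word = 0.093, pseudoword = 0.105),
                            c1_sd = c(word = 0.003, pseudoword = 0.004) * sqrt(30),
                            v_mean = c(word = 0.217, pseudoword = 0.203),
                            v_sd = c(word = 0.005, pseudoword = 0.004) * sqrt(30),
                            c2_mean = c(word = 0.170, pseudoword = 0.187),
                            c2_sd = c(word = 0.005, pseudoword = 0.005) * sqrt(30),
                            isi_range = c(0.5, 1.0),
                            cue_duration = 0.25) {
  nm2 <- function(x) {  # accept unnamed (word, pseudoword) pairs
    assert_that(length(x) == 2, "per-condition parameters need two values")
    if (is.null(names(x))) names(x) <- c("word", "pseudoword")
    x
  }
  latency_mean <- nm2(latency_mean); latency_sd <- nm2(latency_sd)
  c1_mean <- nm2(c1_mean); c1_sd <- nm2(c1_sd)
  v_mean <- nm2(v_mean); v_sd <- nm2(v_sd)
  c2_mean <- nm2(c2_mean); c2_sd <- nm2(c2_sd)
  means <- c(latency_mean, c1_mean, v_mean, c2_mean)
  sds <- c(latency_sd, c1_sd, v_sd, c2_sd)
  assert_that(all(means > 0), "all means must be positive")
  assert_that(all(sds >= 0), "SDs must be >= 0")
  assert_that(isi_range[1] <= isi_range[2], "isi range low must be <= high")
  structure(list(latency_mean = latency_mean, latency_sd = latency_sd,
                 c1_mean = c1_mean, c1_sd = c1_sd,
                 v_mean = v_mean, v_sd = v_sd,
                 c2_mean = c2_mean, c2_sd = c2_sd,
                 isi_range = as.numeric(isi_range),
                 cue_duration = cue_duration),
            class = "behavior_params")
}

#' Generate a stationary MVAR realization
#'
#' Runs the recursion \eqn{x(t) = \sum_j B_j x(t-j) + e(t)} with Gaussian
#' innovations \eqn{e(t) \sim N(0, \Sigma_e)}, discarding `burn_in` samples so
#' the returned segment is (approximately) a draw from the stationary
#' distribution. Innovations are drawn column-wise: with all coefficients
#' zero the output equals the innovation draws exactly.
#'
#' @param model a stable [mvar_model()]
#' @param n_samples number of samples to return
#' @param seed integer seed (reproducible output for a fixed seed)
#' @param burn_in samples discarded at the start
#' @return K x n_samples signal matrix
#' @export
mvar_generate <- function(model, n_samples, seed, burn_in = 1000L) {
  if (!mvar_is_stable(model)) {
    stop_ercflow("unstable MVAR model: companion spectral radius = %.4f (must be < 1)",
                 mvar_spectral_radius(model))
  }
  assert_that(n_samples > 0, "n_samples must be positive")
  K <- nrow(model$noise_cov)
  set.seed(as.integer(seed))
  ntot <- n_samples + burn_in
  L <- chol_psd(model$noise_cov)
  E <- t(L) %*% matrix(rnorm(K * ntot), K, ntot)
  X <- mvar_recurse(model$coefs, E)
  X[, (burn_in + 1):ntot, drop = FALSE]
}

# Cholesky tolerant of semi-definite matrices (eigendecomposition fallback)
chol_psd <- function(S) {
  r <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(r)) return(r)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

# plain recursion engine: X[, t] = sum_j B_j X[, t-j] + E[, t]
mvar_recurse <- function(coefs, E) {
  p <- length(coefs)
  if (p == 0) return(E)
  K <- nrow(E); ntot <- ncol(E)
  X <- E
  for (t in seq_len(ntot)) {
    xt <- E[, t]
    for (j in seq_len(min(p, t - 1))) xt <- xt + coefs[[j]] %*% X[, t - j]
    X[, t] <- xt
  }
  X
}

#' Sample trial timings for one session
#'
#' Conditions strictly alternate (word, pseudoword, ...). Each trial consists
#' of a preparatory cue, a uniform ISI, stimulus presentation, a reading
#' latency drawn from the condition's truncated-normal distribution, and
#' C1/V/C2 articulation. Absolute onset times are laid out sequentially with
#' enough inter-trial margin for baseline epoching.
#'
#' @param params a [behavior_params()]
#' @param n_trials even trial count (strict alternation)
#' @param seed integer seed
#' @param first condition of the first trial
#' @param lead_s quiet time before each cue (inter-trial interval), seconds
#' @param gap_s quiet time appended after articulation, seconds
#' @return data.frame of trial timings (one row per trial): `trial_id`,
#'   `condition`, `cue_onset_s`, `stimulus_onset_s`, `speech_onset_s`,
#'   `c1_dur_s`, `v_dur_s`, `c2_dur_s`
#' @export
sample_behavior <- function(params, n_trials, seed, first = "word",
                            lead_s = 1.6, gap_s = 1.0) {
  assert_that(inherits(params, "behavior_params"), "params must be behavior_params")
  assert_that(n_trials %% 2 == 0 && n_trials > 0,
              "n_trials must be even for strict condition alternation")
  first <- match.arg(first, c("word", "pseudoword"))
  set.seed(as.integer(seed))
  conds <- rep(c(first, setdiff(c("word", "pseudoword"), first)),
               length.out = n_trials)
  isi <- runif(n_trials, params$isi_range[1], params$isi_range[2])
  lat <- rtruncnorm0(n_trials, params$latency_mean[conds], params$latency_sd[conds])
  c1 <- rtruncnorm0(n_trials, params$c1_mean[conds], params$c1_sd[conds])
  v  <- rtruncnorm0(n_trials, params$v_mean[conds], params$v_sd[conds])
  c2 <- rtruncnorm0(n_trials, params$c2_mean[conds], params$c2_sd[conds])
  cue <- numeric(n_trials)
  t_end <- 0.5
  for (i in seq_len(n_trials)) {
    cue[i] <- t_end + lead_s
    t_end <- cue[i] + params$cue_duration + isi[i] + lat[i] + c1[i] + v[i] + c2[i] + gap_s
  }
  stim <- cue + params$cue_duration + isi
  data.frame(trial_id = seq_len(n_trials), condition = conds,
             cue_onset_s = cue, stimulus_onset_s = stim,
             speech_onset_s = stim + lat,
             c1_dur_s = c1, v_dur_s = v, c2_dur_s = c2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate one recording session from a ground-truth network
#'
#' Generates a continuous multichannel recording by running the base MVAR
#' recursion with (a) coupling coefficients switched on inside each trial's
#' coupling windows (10 ms raised-cosine taper) and (b) a task-evoked
#' amplitude envelope that scales the innovation SD of activated channels by
#' `activation_gain` between stimulus onset and 500 ms after speech onset
#' (50 ms cosine ramps), producing the event-related high-gamma power
#' augmentation that the channel screen looks for. Scaling the innovations
#' leaves the transfer function and coherence structure unchanged, so the
#' envelope itself induces no spurious flow changes.
#'
#' @param net a [network_spec()]
#' @param params a [behavior_params()]
#' @param n_trials trials per session (even)
#' @param seed integer seed
#' @param fs sampling rate in Hz (the base model's rate by default)
#' @param activation_gain innovation-SD multiplier during the task interval
#'   (2 = +6 dB power)
#' @param coupling_ramp_s raised-cosine taper length for coupling windows
#' @param lead_s,gap_s inter-trial quiet time before the cue and after
#'   articulation, seconds (must leave room for epoching)
#' @return a `simulated_session`: list with `recording`
#'   ([session_recording()]), `truth` (the network spec), `truth_table`
#'   (per-trial absolute activation intervals of each coupling), `trials`,
#'   and `seed`
#' @export
simulate_session <- function(net, params = behavior_params(), n_trials = 60L,
                             seed = 1L, fs = NULL, activation_gain = 2,
                             coupling_ramp_s = 0.010, lead_s = 1.6, gap_s = 1.0) {
  assert_that(inherits(net, "network_spec"), "net must be a network_spec")
  fs <- fs %||% net$base_model$sampling_rate
  seeds <- derive_seeds(seed, 2)
  trials <- sample_behavior(params, n_trials, seeds[1], lead_s = lead_s, gap_s = gap_s)

  # epochable span per trial; collisions would corrupt epoch alignment
  span_lo <- trials$cue_onset_s - 1.0
  span_hi <- trials$speech_onset_s + 1.1
  if (n_trials > 1) {
    bad <- which(span_lo[-1] < span_hi[-n_trials])
    if (length(bad)) {
      stop_ercflow("overlapping trial epochs at trial indices: %s",
                   paste(bad, bad + 1L, sep = "-", collapse = ", "))
    }
  }

  dur <- max(span_hi) + 1.0
  n <- ceiling(dur * fs)
  tgrid <- (seq_len(n) - 1) / fs
  K <- nrow(net$channels)

  # task-evoked amplitude envelope (activated channels only)
  env <- rep(1, n)
  for (i in seq_len(n_trials)) {
    w <- taper_weight(tgrid, trials$stimulus_onset_s[i],
                      trials$speech_onset_s[i] + 0.5, 0.05)
    env <- pmax(env, 1 + (activation_gain - 1) * w)
  }

  # per-coupling taper weight vectors over the whole recording, plus the
  # per-trial truth table of active intervals
  ids <- net$channels$id
  cw <- list(); tt <- list()
  for (ci in seq_along(net$couplings)) {
    cp <- net$couplings[[ci]]
    w <- numeric(n)
    sel <- if (cp$condition == "both") seq_len(n_trials) else which(trials$condition == cp$condition)
    for (i in sel) {
      s0 <- trials$speech_onset_s[i] + cp$window[1]
      s1 <- trials$speech_onset_s[i] + cp$window[2]
      w <- pmax(w, taper_weight(tgrid, s0, s1, coupling_ramp_s))
      tt[[length(tt) + 1L]] <- data.frame(
        trial_id = i, source = cp$source, target = cp$target,
        gain = cp$gain, condition = cp$condition,
        start_s = s0, end_s = s1, stringsAsFactors = FALSE)
    }
    cw[[ci]] <- list(si = match(cp$source, ids), ti = match(cp$target, ids),
                     gain = cp$gain, lag = cp$lag, w = w)
  }
  truth_table <- if (length(tt)) do.call(rbind, tt) else
    data.frame(trial_id = integer(), source = character(), target = character(),
               gain = numeric(), condition = character(),
               start_s = numeric(), end_s = numeric())

  X <- generate_session_signals(net, n, seeds[2], env, cw)
  rownames(X) <- ids

  rec <- session_recording(X, fs, net$channels, trials)
  structure(list(recording = rec, truth = net, truth_table = truth_table,
                 trials = trials, seed = as.integer(seed)),
            class = "simulated_session")
}

# time-varying MVAR engine: base coefficients plus tapered coupling terms and
# an innovation-SD envelope for activated channels
generate_session_signals <- function(net, n, seed, env, cw) {
  model <- net$base_model
  K <- nrow(net$channels)
  p <- max(c(model$order, vapply(cw, function(z) z$lag, 1L), 1L))
  set.seed(as.integer(seed))
  E <- matrix(rnorm(K * n), K, n) * net$noise_sd
  act <- net$channels$activated
  E[act, ] <- E[act, , drop = FALSE] * rep(env, each = sum(act))
  coefs <- model$coefs
  nb <- length(coefs)
  X <- E
  for (t in seq_len(n)) {
    xt <- E[, t]
    for (j in seq_len(min(nb, t - 1))) xt <- xt + coefs[[j]] %*% X[, t - j]
    for (cpl in cw) {
      if (t > cpl$lag && cpl$w[t] != 0) {
        xt[cpl$ti] <- xt[cpl$ti] + cpl$w[t] * cpl$gain * X[cpl$si, t - cpl$lag]
      }
    }
    X[, t] <- xt
  }
  X
}

#' Default ground-truth network motif
#'
#' Eight channels: three STN sites, one precentral (PreCG), one postcentral
#' (PoCG), one superior temporal (STG) site, and two non-activated cortical
#' contacts (screened out downstream, and keeping the common-average
#' reference from making the modelled subset rank deficient). Background
#' dynamics are an AR(2) resonance near 120 Hz (pole radius 0.85), a
#' band-limited high-gamma carrier. Ground-truth couplings target distinct
#' STN sites (no single channel accumulates variance) with gains bounded so
#' that a driven channel's amplitude stays well under the 8-robust-SD
#' artifact threshold (a gain g inflates the target SD by roughly
#' sqrt(1 + (g/(1-r))^2) through the resonance):
#' \itemize{
#'   \item STG -> STN1 burst in (-450, -400) ms before speech onset, both
#'     conditions (gain 0.25);
#'   \item STG -> STN1 lexicality-modulated flow in (-208, -117) ms, word
#'     gain 0.35 > pseudoword gain 0.10 (the separation realizes the
#'     paradigm's lexicality effect at cohort sample sizes; the pooled
#'     effective gain stays 0.225);
#'   \item reciprocal STN2 <-> PoCG in (-300, +400) ms (gain 0.15 each way;
#'     a reciprocal lag-2 pair is stable only for gain < 1 - r^2 = 0.2775);
#'   \item PreCG -> STN3 in (-350, -150) ms (gain 0.20).
#' }
#'
#' @param fs sampling rate, Hz
#' @param gain_jitter multiplicative jitter applied to all coupling gains
#'   (per-session variability; 1 = none)
#' @return a [network_spec()]
#' @export
default_network <- function(fs = 1250, gain_jitter = 1) {
  channels <- data.frame(
    id = c("STN1", "STN2", "STN3", "PreCG1", "PoCG1", "STG1", "PoCG2", "STG2"),
    region = c("STN", "STN", "STN", "PreCG", "PoCG", "STG", "PoCG", "STG"),
    activated = c(rep(TRUE, 6), FALSE, FALSE),
    stringsAsFactors = FALSE)
  K <- nrow(channels)
  r <- 0.85; th <- 2 * pi * 120 / fs
  B1 <- diag(rep(2 * r * cos(th), K))
  B2 <- diag(rep(-r^2, K))
  base <- mvar_model(list(B1, B2), diag(K), fs)
  g <- gain_jitter
  couplings <- list(
    coupling_event("STG1", "STN1", 0.25 * g, lag = 2, window = c(-0.45, -0.40),
                   condition = "both"),
    coupling_event("STG1", "STN1", 0.35 * g, lag = 2, window = c(-0.208, -0.117),
                   condition = "word"),
    coupling_event("STG1", "STN1", 0.10 * g, lag = 2, window = c(-0.208, -0.117),
                   condition = "pseudoword"),
    coupling_event("STN2", "PoCG1", 0.15 * g, lag = 2, window = c(-0.30, 0.40),
                   condition = "both"),
    coupling_event("PoCG1", "STN2", 0.15 * g, lag = 2, window = c(-0.30, 0.40),
                   condition = "both"),
    coupling_event("PreCG1", "STN3", 0.20 * g, lag = 2, window = c(-0.35, -0.15),
                   condition = "both"))
  network_spec(channels, base, couplings)
}

#' Build the default synthetic cohort
#'
#' Ten sessions across four subjects (4/3/2/1 sessions each), 60 trials per
#' session with alternating word/pseudoword conditions (600 trials in total).
#' Every session shares the [default_network()] motif with per-session
#' multiplicative gain jitter (uniform within 10%) and its own RNG stream;
#' each session records three STN sites plus the cortical contacts.
#'
#' @param seed master integer seed
#' @param n_sessions number of sessions
#' @param n_trials trials per session
#' @return list of `simulated_session` objects (class `erc_cohort`), with
#'   subject assignments in `attr(, "subjects")`
#' @export
build_default_cohort <- function(seed = 1L, n_sessions = 10L, n_trials = 60L) {
  subjects <- rep(1:4, c(4, 3, 2, 1))[seq_len(n_sessions)]
  seeds <- derive_seeds(seed, 2 * n_sessions)
  sessions <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    set.seed(seeds[i])
    jit <- runif(1, 0.9, 1.1)
    net <- default_network(gain_jitter = jit)
    sessions[[i]] <- simulate_session(net, behavior_params(), n_trials,
                                      seed = seeds[n_sessions + i])
    sessions[[i]]$subject <- subjects[i]
    sessions[[i]]$session <- i
  }
  structure(sessions, class = "erc_cohort", subjects = subjects)
}
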