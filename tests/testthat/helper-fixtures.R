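# shared fixtures: tiny networks, tone recordings, epoch builders, and the
# independent SdDTF oracle used by the dual-route checks

# diagonal AR(2) resonance base model (the synthetic carrier)
ar2_base <- function(K, fs = 1250, r = 0.85, f0 = 120) {
  th <- 2 * pi * f0 / fs
  mvar_model(list(diag(K) * (2 * r * cos(th)), diag(K) * (-r^2)),
             diag(K), fs)
}

# minimal two/three channel network with one condition-independent coupling
tiny_network <- function(K = 2, gain = 0.25, window = c(-0.45, -0.40),
                         couple = TRUE) {
  ids <- c("STG1", "STN1", "PoCG1")[seq_len(K)]
  regions <- c("STG", "STN", "PoCG")[seq_len(K)]
  channels <- data.frame(id = ids, region = regions, activated = TRUE,
                         stringsAsFactors = FALSE)
  cps <- if (couple && K >= 2) {
    list(coupling_event("STG1", "STN1", gain, lag = 2, window = window))
  } else list()
  network_spec(channels, ar2_base(K), cps)
}

# epochs of stationary MVAR data cut from one long realization (cheap multi-
# trial fixture; segments are far enough apart to be effectively independent)
stationary_epochs <- function(model, n_trials, n_samples, seed,
                              window = c(0, n_samples / model$sampling_rate),
                              alignment = "cue") {
  K <- nrow(model$noise_cov)
  gapped <- n_samples + 50
  X <- mvar_generate(model, n_trials * gapped, seed)
  data <- array(NA_real_, c(n_trials, K, n_samples))
  for (i in seq_len(n_trials)) {
    data[i, , ] <- X[, ((i - 1) * gapped + 1):((i - 1) * gapped + n_samples), drop = FALSE]
  }
  channels <- data.frame(id = paste0("ch", seq_len(K)),
                         region = rep("STN", K), stringsAsFactors = FALSE)
  trials <- data.frame(trial_id = seq_len(n_trials),
                       condition = rep(c("word", "pseudoword"), length.out = n_trials),
                       kept = TRUE, reject_reason = NA_character_,
                       stringsAsFactors = FALSE)
  epoch_set(data, alignment, window, model$sampling_rate, channels, trials)
}

# single-channel recording holding a pure tone (for filter/resampler checks)
tone_recording <- function(freq, fs, dur = 2, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- matrix(amp * sin(2 * pi * freq * t), nrow = 1)
  rownames(x) <- "ch1"
  session_recording(x, fs,
                    data.frame(id = "ch1", region = "STG", stringsAsFactors = FALSE),
                    data.frame(trial_id = 1L, condition = "word",
                               cue_onset_s = 0.6, stimulus_onset_s = 0.9,
                               speech_onset_s = 1.2, stringsAsFactors = FALSE))
}

fft_amplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(fft(x)) / n * 2
  f <- (0:(n - 1)) * fs / n
  sp[which.min(abs(f[1:(n %/% 2)] - freq))]
}

# independent SdDTF oracle: recomputes transfer matrix, spectral matrix,
# partial coherence and the normalized flow directly from the model's true
# coefficients, sharing no code with the package path
oracle_sddtf <- function(coefs, sigma, fs, freqs) {
  K <- nrow(sigma)
  g <- array(NA_real_, c(K, K, length(freqs)))
  for (fi in seq_along(freqs)) {
    A <- diag(K) + 0i
    for (j in seq_along(coefs)) {
      A <- A - coefs[[j]] * exp(-2i * pi * freqs[fi] * j / fs)
    }
    H <- solve(A)
    S <- H %*% sigma %*% Conj(t(H))
    M <- solve(S)
    cmat <- matrix(0, K, K)
    for (k in 1:K) for (l in 1:K) {
      cmat[k, l] <- Mod(M[k, l]) / sqrt(Re(M[k, k]) * Re(M[l, l]))
    }
    g[, , fi] <- Mod(H) * cmat
    diag(g[, , fi]) <- 0
  }
  g / sqrt(sum(g^2))
}

# synthetic flow tensor with given values (for statistics-layer tests)
fake_flow_tensor <- function(values, channels, freqs, times,
                             regions = rep("STN", length(channels))) {
  structure(values, class = "flow_tensor", freqs = freqs, times = times,
            channels = channels, regions = regions, p = 2)
}

# synthetic power tensor (for screen calibration tests)
fake_power_tensor <- function(values, freqs, times, conditions,
                              channels = paste0("ch", seq_len(dim(values)[2]))) {
  structure(values, class = "power_tensor", freqs = freqs, times = times,
            channels = channels, regions = rep("STN", length(channels)),
            conditions = conditions)
}
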