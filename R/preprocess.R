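#' Continuous session recording
#'
#' @param signals K x n numeric matrix (channels x samples); row names are
#'   channel ids
#' @param sampling_rate Hz
#' @param channels data.frame with `id`, `region` (and optional extra columns)
#' @param events trial event table (one row per trial) with at least
#'   `trial_id`, `condition`, `cue_onset_s`, `stimulus_onset_s`,
#'   `speech_onset_s`
#' @return a `session_recording`
#' @export
session_recording <- function(signals, sampling_rate, channels, events) {
  assert_that(is.matrix(signals) && is.numeric(signals), "signals must be a numeric matrix")
  assert_that(!anyNA(signals), "signals must not contain NA")
  assert_that(nrow(signals) == nrow(channels),
              "signals rows must match channel table")
  need <- c("trial_id", "condition", "cue_onset_s", "stimulus_onset_s", "speech_onset_s")
  assert_that(all(need %in% names(events)),
              "events must contain %s", paste(need, collapse = ", "))
  if (is.null(rownames(signals))) rownames(signals) <- channels$id
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 channels = channels, events = events),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("session_recording: %d channels x %d samples @ %g Hz, %d trials\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Trial-aligned epoch set
#'
#' @param data trials x channels x samples array
#' @param alignment name of the alignment event (`"cue"`, `"stimulus"`,
#'   `"speech_onset"`)
#' @param window `(start_s, end_s)` half-open, relative to the alignment event
#' @param sampling_rate Hz
#' @param channels channel table
#' @param trials per-trial metadata (`trial_id`, `condition`, `kept`,
#'   `reject_reason`); rejected trials are excluded from `data`
#' @return an `epoch_set`
#' @export
epoch_set <- function(data, alignment, window, sampling_rate, channels, trials) {
  assert_that(length(dim(data)) == 3, "data must be trials x channels x samples")
  ns <- round((window[2] - window[1]) * sampling_rate)
  assert_that(abs(ns - (window[2] - window[1]) * sampling_rate) < 1e-6,
              "window length x sampling rate must be an integer sample count")
  assert_that(dim(data)[3] == ns, "data sample count inconsistent with window")
  assert_that(dim(data)[1] == sum(trials$kept), "data must hold kept trials only")
  structure(list(data = data, alignment = alignment, window = as.numeric(window),
                 sampling_rate = sampling_rate, channels = channels,
                 trials = trials),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples, aligned to %s, window [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$alignment, x$window[1], x$window[2]))
  invisible(x)
}

# time axis of epoch samples (seconds relative to the alignment event)
epoch_times <- function(ep) {
  ep$window[1] + (seq_len(dim(ep$data)[3]) - 1) / ep$sampling_rate
}

## ---- FIR design and zero-phase filtering -----------------------------------

# Hamming-windowed sinc low-pass; Hamming gives ~53 dB stopband, comfortably
# past the 40 dB design target. Transition width sets the order (~3.3/df).
fir_lowpass <- function(fs, cutoff, transition) {
  N <- ceiling(3.3 * fs / transition)
  if (N %% 2 == 0) N <- N + 1
  m <- seq_len(N) - (N + 1) / 2
  h <- 2 * cutoff / fs * sinc(2 * cutoff / fs * m)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(N) - 1) / (N - 1))
  h <- h * w
  h / sum(h)  # unit DC gain
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# band-pass as difference of two low-passes; cutoffs at band edge -/+ half a
# transition so the stopband (>= 40 dB) is reached one transition width out
fir_bandpass <- function(fs, low, high, transition = 10) {
  hl <- fir_lowpass(fs, high + transition / 2, transition)
  hh <- fir_lowpass(fs, low - transition / 2, transition)
  n <- max(length(hl), length(hh))
  pad <- function(h) {  # center both kernels at the same midpoint
    k <- (n - length(h)) / 2
    c(rep(0, floor(k)), h, rep(0, ceiling(k)))
  }
  pad(hl) - pad(hh)
}

# single-pass FIR with zero padding, delay-compensated (symmetric kernels)
fir_apply <- function(x, h) {
  n <- length(x); N <- length(h)
  y <- convolve(x, rev(h), type = "open")
  d <- (N - 1) / 2
  y[(d + 1):(d + n)]
}

# forward-backward application: zero net phase, squared magnitude response
fir_filtfilt <- function(x, h) {
  rev(fir_apply(rev(fir_apply(x, h)), h))
}

## ---- operations ------------------------------------------------------------

#' Resample a session recording
#'
#' Anti-alias filters (zero-phase FIR low-pass with cutoff at 0.45 of the
#' target rate) and resamples onto the target grid; when the rate ratio is an
#' integer the signal is decimated, otherwise linearly interpolated. Event
#' times are in seconds and are untouched.
#'
#' @param rec a [session_recording()]
#' @param target_rate Hz; must exceed twice the 180 Hz analysis band edge
#' @return resampled `session_recording`
#' @export
resample_recording <- function(rec, target_rate) {
  assert_that(target_rate > 2 * 180,
              "target rate %g Hz violates Nyquist for the 60-180 Hz band", target_rate)
  fs <- rec$sampling_rate
  if (isTRUE(all.equal(fs, target_rate))) return(rec)
  X <- rec$signals
  if (target_rate < fs) {
    h <- fir_lowpass(fs, 0.45 * target_rate, 0.1 * target_rate)
    X <- t(apply(X, 1, fir_filtfilt, h = h))
  }
  t_old <- (seq_len(ncol(X)) - 1) / fs
  n_new <- floor(t_old[length(t_old)] * target_rate) + 1
  t_new <- (seq_len(n_new) - 1) / target_rate
  ratio <- fs / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- round(t_new * fs) + 1
    Y <- X[, idx, drop = FALSE]
  } else {
    Y <- t(apply(X, 1, function(x) approx(t_old, x, xout = t_new)$y))
  }
  rownames(Y) <- rownames(rec$signals)
  session_recording(Y, target_rate, rec$channels, rec$events)
}

#' Cut trial-aligned epochs from a continuous recording
#'
#' Epoch time zero sits at the alignment event; the sample interval is
#' half-open `[start, end)`. Trials whose window falls outside the recording
#' are flagged as rejected (with a reason) rather than silently dropped.
#'
#' @param rec a [session_recording()]
#' @param alignment `"cue"`, `"stimulus"` or `"speech_onset"`
#' @param window `(start_s, end_s)` relative to the alignment event
#' @return an [epoch_set()]
#' @export
epoch <- function(rec, alignment = c("cue", "stimulus", "speech_onset"),
                  window) {
  alignment <- match.arg(alignment)
  col <- switch(alignment, cue = "cue_onset_s", stimulus = "stimulus_onset_s",
                speech_onset = "speech_onset_s")
  fs <- rec$sampling_rate
  ns <- round((window[2] - window[1]) * fs)
  assert_that(ns >= 1, "window must span at least one sample")
  off <- round(window[1] * fs)
  ev <- rec$events[[col]]
  ntr <- nrow(rec$events); K <- nrow(rec$signals)
  kept <- rep(TRUE, ntr); reason <- rep(NA_character_, ntr)
  starts <- round(ev * fs) + off  # 0-based index of first sample
  oob <- is.na(ev) | starts < 0 | (starts + ns) > ncol(rec$signals)
  kept[oob] <- FALSE
  reason[oob] <- ifelse(is.na(ev[oob]), "missing event", "window out of bounds")
  data <- array(NA_real_, c(sum(kept), K, ns))
  ki <- 0L
  for (i in which(kept)) {
    ki <- ki + 1L
    data[ki, , ] <- rec$signals[, (starts[i] + 1):(starts[i] + ns)]
  }
  trials <- rec$events
  trials$kept <- kept
  trials$reject_reason <- reason
  epoch_set(data, alignment, window, fs, rec$channels, trials)
}

#' Automated amplitude-based artifact rejection
#'
#' Algorithmic surrogate for visual inspection: a trial is flagged when its
#' peak absolute deviation on any channel exceeds `threshold` times that
#' channel's robust SD (median absolute deviation across all kept epochs).
#' The attached report gives counts and the rejection percentage.
#'
#' @param ep an [epoch_set()]
#' @param threshold robust-SD multiplier (default 8)
#' @return the epoch set with flagged trials removed; the rejection report is
#'   in `attr(, "rejection_report")`
#' @export
reject_artifacts <- function(ep, threshold = 8) {
  nt <- dim(ep$data)[1]
  assert_that(nt >= 1, "need at least one trial")
  K <- dim(ep$data)[2]
  bad <- rep(FALSE, nt)
  details <- list()
  for (k in seq_len(K)) {
    xk <- ep$data[, k, , drop = TRUE]
    if (nt == 1) xk <- matrix(xk, nrow = 1)
    med <- median(xk)
    rsd <- mad(xk)
    if (rsd == 0) next
    peak <- apply(abs(xk - med), 1, max)
    hit <- peak > threshold * rsd
    if (any(hit)) {
      details[[length(details) + 1L]] <- data.frame(
        trial_id = ep$trials$trial_id[ep$trials$kept][hit],
        channel = ep$channels$id[k],
        reason = sprintf("peak %.1f robust SDs", peak[hit] / rsd),
        stringsAsFactors = FALSE)
      bad <- bad | hit
    }
  }
  if (all(bad)) stop_ercflow("artifact rejection removed all %d trials", nt)
  report <- list(
    n_total = nt, n_rejected = sum(bad),
    pct_rejected = rejection_pct(sum(bad), nt),
    details = if (length(details)) do.call(rbind, details) else
      data.frame(trial_id = integer(), channel = character(), reason = character()))
  out <- ep
  out$data <- ep$data[!bad, , , drop = FALSE]
  kept_idx <- which(ep$trials$kept)
  out$trials$kept[kept_idx[bad]] <- FALSE
  out$trials$reject_reason[kept_idx[bad]] <- "amplitude artifact"
  attr(out, "rejection_report") <- report
  out
}

#' Trial rejection percentage
#'
#' @param n_rejected,n_total counts
#' @return percentage rounded to two decimals (e.g. 7 of 600 -> 1.17)
#' @export
rejection_pct <- function(n_rejected, n_total) {
  round(100 * n_rejected / n_total, 2)
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across the reference
#' group from each group channel. Channels outside the group are untouched.
#'
#' @param ep an [epoch_set()]
#' @param group channel ids forming the reference group (default: all)
#' @return re-referenced epoch set
#' @export
common_average_reference <- function(ep, group = NULL) {
  ids <- ep$channels$id
  group <- group %||% ids
  gi <- match(group, ids)
  assert_that(!anyNA(gi), "unknown channel id in CAR group")
  assert_that(length(gi) >= 2, "CAR group must contain at least 2 channels")
  out <- ep
  g <- ep$data[, gi, , drop = FALSE]
  ref <- apply(g, c(1, 3), mean)  # trials x samples
  for (k in gi) out$data[, k, ] <- out$data[, k, ] - ref
  out
}

#' Zero-phase FIR band-pass filtering of epochs
#'
#' Forward-backward application of a Hamming-windowed sinc band-pass
#' (stopband at least 40 dB one transition width outside the band), giving
#' zero net phase. Edge effects are confined to one filter length at each
#' epoch end; that length is recorded in `attr(, "filter_edge_s")`.
#'
#' @param ep an [epoch_set()]
#' @param band `(low_Hz, high_Hz)`, default the 60-180 Hz high-gamma band
#' @param transition transition width in Hz
#' @param notch optional vector of line frequencies to notch out with narrow
#'   (2 Hz) zero-phase band-stops (off by default for synthetic data)
#' @return filtered epoch set
#' @export
bandpass_zero_phase <- function(ep, band = c(60, 180), transition = 10,
                                notch = NULL) {
  fs <- ep$sampling_rate
  assert_that(band[1] > 0 && band[2] < fs / 2 && band[1] < band[2],
              "band (%g, %g) Hz must lie inside (0, %g) Hz", band[1], band[2], fs / 2)
  h <- fir_bandpass(fs, band[1], band[2], transition)
  out <- ep
  nt <- dim(ep$data)[1]; K <- dim(ep$data)[2]
  for (i in seq_len(nt)) for (k in seq_len(K)) {
    x <- ep$data[i, k, ]
    x <- fir_filtfilt(x, h)
    if (!is.null(notch)) {
      for (f0 in notch) {
        hn <- fir_bandpass(fs, f0 - 1, f0 + 1, transition = 2)
        x <- x - fir_filtfilt(x, hn)
      }
    }
    out$data[i, k, ] <- x
  }
  attr(out, "filter_edge_s") <- (length(h) - 1) / fs
  out
}
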