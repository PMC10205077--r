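#' Pipeline configuration
#'
#' Aggregates every analysis parameter; validated for internal consistency
#' (the window and step must be integer sample counts at the analysis rate,
#' the frequency grid must sit inside the band, the band inside Nyquist).
#'
#' @param analysis_rate analysis sampling rate, Hz (1250 makes the 140 ms
#'   window exactly 175 samples and the 5.6 ms step exactly 7)
#' @param band high-gamma band, Hz
#' @param baseline_window cue-aligned baseline epoch, seconds
#' @param response_window speech-onset-aligned response epoch, seconds
#' @param window_len_s,step_s sliding MVAR window geometry
#' @param p_range candidate AIC model orders
#' @param freqs SdDTF frequency grid, Hz
#' @param alpha FDR level
#' @param kernel smoothing kernel `c(n_time, n_freq)`
#' @param n_groups trial-group replicate count for ERC inference (see
#'   [sliding_sddtf()]); df of the session-level test is `n_groups - 1`
#' @param artifact_sd robust-SD multiplier for artifact rejection
#' @param trim_fraction fraction of smallest edges hidden in flow diagrams
#' @param notch optional line-noise notch frequencies (NULL = off)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(analysis_rate = 1250, band = c(60, 180),
                            baseline_window = c(-0.52, 0),
                            response_window = c(-0.5, 0.5),
                            window_len_s = 0.140, step_s = 0.0056,
                            p_range = 2:8, freqs = seq(60, 180, by = 4),
                            alpha = 0.05, kernel = c(9, 5), n_groups = 5,
                            artifact_sd = 8, trim_fraction = 0.15,
                            notch = NULL) {
  assert_that(n_groups >= 2, "need at least 2 trial groups for inference")
  assert_that(band[2] < analysis_rate / 2, "band must lie below Nyquist")
  assert_that(all(freqs >= band[1] & freqs <= band[2]),
              "frequency grid must lie inside the band")
  for (w in list(baseline_window, response_window, c(0, window_len_s), c(0, step_s))) {
    n <- (w[2] - w[1]) * analysis_rate
    assert_that(abs(n - round(n)) < 1e-6,
                "interval (%g, %g) s is not an integer sample count at %g Hz",
                w[1], w[2], analysis_rate)
  }
  cfg <- structure(list(analysis_rate = analysis_rate, band = band,
                        baseline_window = baseline_window,
                        response_window = response_window,
                        window_len_s = window_len_s, step_s = step_s,
                        p_range = p_range, freqs = freqs,
                        n_groups = n_groups,
                        stats = stats_config(alpha, kernel),
                        artifact_sd = artifact_sd,
                        trim_fraction = trim_fraction, notch = notch),
                   class = "pipeline_config")
  cfg$hash <- fnv1a_hash(unclass(cfg))
  cfg
}

# epoch with one filter length of padding and reject artifacts; reference and
# filtering are applied later (car_bandpass) so the activation screen can run
# on unreferenced epochs -- the common average would leak task power into
# quiet channels and bias the screen
padded_epochs <- function(rec, alignment, window, cfg, pad_s = 0.36) {
  fs <- rec$sampling_rate
  pad <- round(pad_s * fs) / fs
  ep <- epoch(rec, alignment, c(window[1] - pad, window[2] + pad))
  reject_artifacts(ep, cfg$artifact_sd)
}

# common average reference then zero-phase band-pass on padded epochs, and
# trim back to the target window: the band-pass contract stays epoch-level
# while its edge effects stay out of the analysis span
car_bandpass <- function(ep, window, cfg, pad_s = 0.36) {
  fs <- ep$sampling_rate
  pad <- round(pad_s * fs) / fs
  report <- attr(ep, "rejection_report")
  ep <- common_average_reference(ep)
  ep <- bandpass_zero_phase(ep, cfg$band, notch = cfg$notch)
  npad <- round(pad * fs)
  ns <- dim(ep$data)[3]
  ep2 <- epoch_set(ep$data[, , (npad + 1):(ns - npad), drop = FALSE],
                   ep$alignment, window, fs, ep$channels, ep$trials)
  attr(ep2, "rejection_report") <- report
  ep2
}

# trim padded epochs without referencing/filtering (for the power screen)
trim_epochs <- function(ep, window, pad_s = 0.36) {
  fs <- ep$sampling_rate
  npad <- round(pad_s * fs)
  ns <- dim(ep$data)[3]
  epoch_set(ep$data[, , (npad + 1):(ns - npad), drop = FALSE],
            ep$alignment, window, fs, ep$channels, ep$trials)
}

subset_channels <- function(ep, ids) {
  ki <- match(ids, ep$channels$id)
  epoch_set(ep$data[, ki, , drop = FALSE], ep$alignment, ep$window,
            ep$sampling_rate, ep$channels[ki, , drop = FALSE], ep$trials)
}

subset_trials <- function(ep, keep) {
  trials <- ep$trials
  kept_idx <- which(trials$kept)
  drop_idx <- kept_idx[!keep]
  trials$kept[drop_idx] <- FALSE
  trials$reject_reason[drop_idx] <- "condition subset"
  epoch_set(ep$data[keep, , , drop = FALSE], ep$alignment, ep$window,
            ep$sampling_rate, ep$channels, trials)
}

#' Run the full analysis on one session
#'
#' Stages: (1) schema validation and resampling to the analysis rate;
#' (2) padded epoching of cue-aligned baseline and speech-onset-aligned
#' response epochs, amplitude artifact rejection, common average reference
#' over all retained channels, zero-phase 60-180 Hz FIR band-pass;
#' (3) high-gamma activation screen and channel selection; (4) AIC order
#' selection and sliding-window SdDTF on baseline and response epochs, for
#' pooled trials and per condition; (5) session-level ERC statistics;
#' (6) behavioural metrics. Deterministic given (data, config).
#'
#' @param session a `simulated_session`, [session_recording()], or path to a
#'   session directory (see [write_session()])
#' @param cfg a [pipeline_config()]
#' @param conditions condition sets to analyze
#' @return a `session_bundle`: selection table, flow tensors, `erc_result`s
#'   per condition set, behaviour table, rejection report, provenance
#' @export
run_session <- function(session, cfg = pipeline_config(),
                        conditions = c("pooled", "word", "pseudoword")) {
  if (is.character(session)) session <- read_session(session)
  rec <- if (inherits(session, "simulated_session")) session$recording else session
  assert_that(inherits(rec, "session_recording"),
              "session must be a recording, simulated session, or directory path")
  rec <- resample_recording(rec, cfg$analysis_rate)

  base_raw <- padded_epochs(rec, "cue", cfg$baseline_window, cfg)
  resp_raw <- padded_epochs(rec, "speech_onset", cfg$response_window, cfg)
  rejection <- attr(resp_raw, "rejection_report")

  # keep the trial intersection so task and baseline tensors pair up
  keep_ids <- intersect(base_raw$trials$trial_id[base_raw$trials$kept],
                        resp_raw$trials$trial_id[resp_raw$trials$kept])
  base_raw <- subset_trials(base_raw, base_raw$trials$trial_id[base_raw$trials$kept] %in% keep_ids)
  resp_raw <- subset_trials(resp_raw, resp_raw$trials$trial_id[resp_raw$trials$kept] %in% keep_ids)

  # screen on unreferenced epochs; CAR would leak task power across channels
  sel <- activation_screen(timefreq_power(trim_epochs(resp_raw, cfg$response_window)),
                           timefreq_power(trim_epochs(base_raw, cfg$baseline_window)),
                           alpha = cfg$stats$alpha, band = cfg$band)
  chosen <- sel$channel[sel$selected]
  if (length(chosen) < 2) {
    warning("fewer than 2 channels passed the activation screen; using all channels",
            call. = FALSE)
    chosen <- sel$channel
  }
  base_ep <- car_bandpass(base_raw, cfg$baseline_window, cfg)
  resp_ep <- car_bandpass(resp_raw, cfg$response_window, cfg)
  base_sel <- subset_channels(base_ep, chosen)
  resp_sel <- subset_channels(resp_ep, chosen)

  grid_task <- window_grid(resp_sel, cfg$window_len_s, cfg$step_s)
  grid_base <- window_grid(base_sel, cfg$window_len_s, cfg$step_s)
  p <- select_order_aic(resp_sel, cfg$p_range, grid = grid_task)

  suff <- check_sufficiency(length(chosen), p, grid_task$Ns, dim(resp_sel$data)[1])
  if (!suff$pass) {
    stop_ercflow("aborting: sample-sufficiency ratio K(p+1)/(Ns*nt) = %.3f >= 0.1", suff$ratio)
  }

  conds <- resp_sel$trials$condition[resp_sel$trials$kept]
  flows <- list(); ercs <- list()
  for (cs in conditions) {
    keep <- if (cs == "pooled") rep(TRUE, length(conds)) else conds == cs
    if (sum(keep) < 2) next
    # replicate fits need ~10 trials each to stay well conditioned on
    # band-pass-filtered data; cap the group count accordingly
    g_eff <- max(2L, min(cfg$n_groups, floor(sum(keep) / 10)))
    tb <- sliding_sddtf(subset_trials(base_sel, keep), p, freqs = cfg$freqs,
                        groups = g_eff)
    tt <- sliding_sddtf(subset_trials(resp_sel, keep), p, freqs = cfg$freqs,
                        groups = g_eff)
    flows[[cs]] <- list(task = tt, baseline = tb)
    ercs[[cs]] <- erc_session(tt, tb, cfg$stats)
  }

  behavior <- response_metrics(rec$events[rec$events$trial_id %in% keep_ids, ])
  structure(list(selection = sel, flows = flows, erc = ercs,
                 behavior = behavior, rejection = rejection, order = p,
                 sufficiency = suff, channels = chosen,
                 provenance = list(config_hash = cfg$hash,
                                   package = as.character(utils::packageVersion("ercflow")))),
            class = "session_bundle")
}

#' Group-level analysis across sessions
#'
#' Runs (or accepts) session bundles, pools session-level ERC into directed
#' region-pair classes, tests group significance per condition set, contrasts
#' word versus pseudoword, and integrates flows over the preset intervals.
#'
#' @param sessions list of sessions (inputs accepted by [run_session()]) or
#'   precomputed `session_bundle`s
#' @param cfg a [pipeline_config()]
#' @return an `erc_group_report`: `group` (per condition set), `contrast`,
#'   `graphs` (integrated flow graphs per preset), provenance
#' @export
run_group <- function(sessions, cfg = pipeline_config()) {
  assert_that(length(sessions) >= 2, "group analysis needs >= 2 sessions")
  in_rates <- vapply(sessions, function(s) {
    if (inherits(s, "simulated_session")) s$recording$sampling_rate
    else if (inherits(s, "session_recording")) s$sampling_rate
    else NA_real_
  }, 1)
  known <- which(!is.na(in_rates))
  if (length(unique(in_rates[known])) > 1) {
    odd <- known[in_rates[known] != in_rates[known][1]]
    stop_ercflow("mixed sampling rates across sessions: %s",
                 paste(odd, collapse = ", "))
  }
  bundles <- lapply(sessions, function(s) {
    if (inherits(s, "session_bundle")) s else run_session(s, cfg)
  })
  rates <- vapply(bundles, function(b) {
    length(b$erc[["pooled"]]$freqs)
  }, 1L)
  if (length(unique(rates)) > 1) {
    stop_ercflow("heterogeneous frequency grids across sessions: %s",
                 paste(which(rates != rates[1]), collapse = ", "))
  }
  group <- list()
  for (cs in c("pooled", "word", "pseudoword")) {
    ercs <- lapply(bundles, function(b) b$erc[[cs]])
    have <- !vapply(ercs, is.null, TRUE)
    pooled_sel <- lapply(bundles, function(b) b$erc[["pooled"]])[have]
    if (sum(have) >= 2) {
      group[[cs]] <- erc_group(ercs[have], cfg$stats, select_from = pooled_sel)
    }
  }
  contrast <- if (!is.null(group$word) && !is.null(group$pseudoword)) {
    condition_contrast(group$word, group$pseudoword, cfg$stats)
  }
  graphs <- lapply(erc_presets(), function(iv) {
    if (!is.null(group$pooled)) integrate_flows(group$pooled, iv)
  })
  structure(list(bundles = bundles, group = group, contrast = contrast,
                 graphs = graphs,
                 provenance = list(config_hash = cfg$hash, n_sessions = length(bundles))),
            class = "erc_group_report")
}

## ---- session directory I/O -------------------------------------------------

#' Write a session to a plain-text directory
#'
#' Layout: `signals.csv` (one column per channel, one row per sample),
#' `events.csv` (the trial table), `truth.json` (ground-truth network, for
#' simulated sessions), `meta.json` (sampling rate, channel table, subject/
#' session/seed).
#'
#' @param session a `simulated_session` or [session_recording()]
#' @param path directory to create
#' @return `path`, invisibly
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rec <- if (inherits(session, "simulated_session")) session$recording else session
  utils::write.csv(as.data.frame(t(rec$signals)),
                   file.path(path, "signals.csv"), row.names = FALSE)
  utils::write.csv(rec$events, file.path(path, "events.csv"), row.names = FALSE)
  meta <- list(sampling_rate_hz = rec$sampling_rate, channels = rec$channels,
               subject = session$subject %||% NA, session = session$session %||% NA,
               seed = session$seed %||% NA)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (inherits(session, "simulated_session")) {
    truth <- list(
      channels = session$truth$channels,
      noise_sd = session$truth$noise_sd,
      base_coefs = lapply(session$truth$base_model$coefs, identity),
      couplings = lapply(session$truth$couplings, unclass),
      truth_table = session$truth_table)
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session directory written by [write_session()]
#'
#' @param path session directory
#' @return a [session_recording()]
#' @export
read_session <- function(path) {
  for (f in c("signals.csv", "events.csv", "meta.json")) {
    assert_that(file.exists(file.path(path, f)),
                "invalid session directory: missing %s", f)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  sig <- as.matrix(utils::read.csv(file.path(path, "signals.csv"), check.names = FALSE))
  events <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  session_recording(t(sig), meta$sampling_rate_hz,
                    as.data.frame(meta$channels), events)
}
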