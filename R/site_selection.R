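#' Per-trial time-frequency power (short-time Fourier transform)
#'
#' Hann-tapered STFT per trial and channel; power at the requested
#' frequencies is taken from the nearest FFT bins. Defaults: 100 ms windows
#' stepped by 10 ms (rounded to integer samples).
#'
#' @param ep an [epoch_set()]
#' @param freqs frequency grid, Hz (default 60-180 in 10 Hz steps, the FFT
#'   bin spacing of a 100 ms window at 1250 Hz)
#' @param window_s,step_s STFT window length and step, seconds
#' @return a `power_tensor`: array trials x channels x freqs x times plus
#'   grid and condition metadata
#' @export
timefreq_power <- function(ep, freqs = seq(60, 180, by = 10),
                           window_s = 0.100, step_s = 0.010) {
  fs <- ep$sampling_rate
  assert_that(max(freqs) <= fs / 2, "frequency above Nyquist (%g Hz)", fs / 2)
  L <- round(window_s * fs)
  st <- max(1L, round(step_s * fs))
  n <- dim(ep$data)[3]
  assert_that(n >= L, "epoch too short for the %g s STFT window", window_s)
  starts <- seq(1L, n - L + 1L, by = st)
  centers <- ep$window[1] + (starts - 1 + L / 2) / fs
  fft_freqs <- (0:(L - 1)) * fs / L
  bins <- vapply(freqs, function(f) which.min(abs(fft_freqs[1:(L %/% 2 + 1)] - f)), 1L)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  nt <- dim(ep$data)[1]; K <- dim(ep$data)[2]
  P <- array(NA_real_, c(nt, K, length(freqs), length(starts)))
  seg_idx <- outer(seq_len(L), starts - 1L, `+`)  # L x n_windows
  for (i in seq_len(nt)) for (k in seq_len(K)) {
    segs <- matrix(ep$data[i, k, ][seg_idx], nrow = L) * hann
    spec <- mvfft(segs)
    P[i, k, , ] <- Mod(spec[bins, , drop = FALSE])^2
  }
  structure(P, class = "power_tensor", freqs = freqs, times = centers,
            channels = ep$channels$id, regions = ep$channels$region,
            conditions = ep$trials$condition[ep$trials$kept])
}

#' High-gamma activation screen
#'
#' Implements the channel-selection rule: per channel and frequency, each
#' post-stimulus time point's log power is compared to the same trial's mean
#' baseline log power with a paired two-sided t statistic across trials, and
#' a channel is selected iff any point in the screen band shows a
#' significant power increase. The statistic is two-sided but the selection
#' criterion is augmentation only.
#'
#' Family-level significance is calibrated by a bootstrap-t max-statistic
#' reference (resampling trials of the mean-centred differences): spectrogram
#' power is chi-square-like and skewed, which inflates the parametric t
#' distribution's far tail exactly where a many-point family is decided, so
#' tabulated t + FDR over the family selects far more than alpha under the
#' null. The bootstrap-t null of the family maximum is second-order accurate
#' and restores the advertised calibration. The reported `min_q` is the
#' channel-level bootstrap p-value of the largest increase.
#'
#' Selection is computed for pooled trials and per condition. The bootstrap
#' uses a private, fixed RNG stream: results are deterministic for fixed
#' inputs and the caller's RNG state is untouched.
#'
#' @param task,baseline `power_tensor`s with identical channels and
#'   frequency grids (same trials)
#' @param alpha selection level
#' @param band frequency screen band, Hz
#' @param n_boot bootstrap resamples for the max-t reference
#' @return a `channel_selection` data.frame: per channel, pooled and
#'   per-condition `selected` flags and smallest q-values
#' @export
activation_screen <- function(task, baseline, alpha = 0.05, band = c(60, 180),
                              n_boot = 500) {
  assert_that(identical(attr(task, "channels"), attr(baseline, "channels")),
              "task and baseline channels differ")
  assert_that(identical(attr(task, "freqs"), attr(baseline, "freqs")),
              "task and baseline frequency grids differ")
  assert_that(dim(task)[1] == dim(baseline)[1],
              "task and baseline must hold the same trials")
  nt <- dim(task)[1]
  assert_that(nt >= 2, "need at least 2 trials")
  fsel <- which(attr(task, "freqs") >= band[1] & attr(task, "freqs") <= band[2])
  conds <- attr(task, "conditions")
  sets <- list(pooled = seq_len(nt))
  for (cn in unique(conds)) sets[[cn]] <- which(conds == cn)
  K <- dim(task)[2]
  res <- data.frame(channel = attr(task, "channels"),
                    region = attr(task, "regions"),
                    stringsAsFactors = FALSE)
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_rng)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(1906L)
  for (sn in names(sets)) {
    idx <- sets[[sn]]
    sel <- logical(K); minq <- rep(NA_real_, K)
    n_i <- length(idx)
    # common bootstrap weights across channels (fixed private stream)
    W <- matrix(rmultinom(n_boot, n_i, rep(1, n_i)), n_i, n_boot) / n_i
    for (k in seq_len(K)) {
      n_f <- length(fsel)
      eps <- 1e-4 * mean(baseline[, k, fsel, ])  # relative noise floor
      lt <- log10(task[idx, k, fsel, , drop = FALSE] + eps)
      lb <- log10(baseline[idx, k, fsel, , drop = FALSE] + eps)
      nw <- dim(lt)[4]
      dim(lt) <- c(n_i, n_f, nw)
      dim(lb) <- c(n_i, n_f, dim(baseline)[4])
      bmean <- apply(lb, c(1, 2), mean)  # trials x freq: per-trial baseline mean
      d <- lt - array(bmean, c(n_i, n_f, nw))
      dim(d) <- c(n_i, n_f * nw)
      mu <- colMeans(d)
      se <- pmax(apply(d, 2, sd), .Machine$double.eps) / sqrt(n_i)
      t_obs <- max(mu / se)  # largest increase in the family
      # bootstrap-t null of the family maximum from centred differences
      dc <- sweep(d, 2, mu)
      m1 <- crossprod(dc, W)                     # point x boot means
      m2 <- crossprod(dc^2, W)
      vb <- pmax((m2 - m1^2) * n_i / (n_i - 1), .Machine$double.xmin)
      tb <- m1 / (sqrt(vb) / sqrt(n_i))
      max_tb <- apply(tb, 2, max)
      p_chan <- (1 + sum(max_tb >= t_obs)) / (1 + n_boot)
      sel[k] <- p_chan <= alpha && t_obs > 0
      minq[k] <- p_chan
    }
    res[[paste0("selected_", sn)]] <- sel
    res[[paste0("min_q_", sn)]] <- minq
  }
  res$selected <- res$selected_pooled
  class(res) <- c("channel_selection", "data.frame")
  res
}

#' Selection summary table
#'
#' Counts and percentages (one decimal) of selected channels per region,
#' given the number of implanted contacts per region.
#'
#' @param sel a `channel_selection` (or data.frame with `region` and
#'   `selected*` columns)
#' @param implanted named counts of implanted contacts per region; defaults
#'   to the observed channel counts
#' @param condition which selection flag to summarize (`"pooled"`, `"word"`,
#'   `"pseudoword"`)
#' @return data.frame: region, n_selected, n_implanted, pct
#' @examples
#' selection_pct(53, 124)  # 42.7
#' selection_pct(10, 30)   # 33.3
#' @export
selection_summary <- function(sel, implanted = NULL, condition = "pooled") {
  col <- paste0("selected_", condition)
  assert_that(col %in% names(sel), "no selection flags for condition %s", condition)
  regions <- sort(unique(sel$region))
  if (is.null(implanted)) implanted <- table(sel$region)
  out <- data.frame(region = regions,
                    n_selected = vapply(regions, function(r) sum(sel[[col]][sel$region == r]), 1L),
                    n_implanted = as.integer(implanted[regions]),
                    stringsAsFactors = FALSE, row.names = NULL)
  assert_that(all(out$n_implanted >= out$n_selected),
              "implanted counts must be >= selected counts")
  out$pct <- selection_pct(out$n_selected, out$n_implanted)
  out
}

#' Selection percentage at one-decimal reporting precision
#'
#' @param n_selected,n_implanted counts
#' @return `100 * n_selected / n_implanted` rounded to one decimal
#' @export
selection_pct <- function(n_selected, n_implanted) {
  round(100 * n_selected / n_implanted, 1)
}
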