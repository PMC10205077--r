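#' Statistical configuration for ERC testing
#'
#' @param alpha significance level after FDR correction
#' @param kernel smoothing kernel dimensions `c(n_time, n_freq)` in grid
#'   points (both odd); default 9 x 5 is about 50 ms x 20 Hz on the default
#'   grids
#' @return a `stats_config`
#' @export
stats_config <- function(alpha = 0.05, kernel = c(9, 5)) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(all(kernel %% 2 == 1), "kernel dims must be odd")
  structure(list(alpha = alpha, kernel = as.integer(kernel),
                 multiple_testing = "BH", report = "increases_only"),
            class = "stats_config")
}

# truncated 1D running mean (kernel shrinks at the edges; no padding values
# are invented), vectorized over the margin via cumulative sums
running_mean <- function(x, width) {
  n <- length(x); h <- (width - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Two-dimensional moving-average smoothing
#'
#' Centered 2D moving average of a frequency x time field. The uniform
#' rectangular kernel makes the 2D truncated mean exactly separable, so edges
#' are handled by shrinking the kernel to the available support rather than
#' inventing padding values. The moving average reduces random noise while
#' retaining a sharp step response, which keeps onset times of flow changes
#' localized.
#'
#' @param field matrix (rows = frequency, cols = time)
#' @param kernel `c(n_time, n_freq)` odd kernel dimensions
#' @return smoothed matrix of the same shape
#' @export
smooth_tf <- function(field, kernel = c(9, 5)) {
  assert_that(is.matrix(field), "field must be a matrix")
  assert_that(all(kernel %% 2 == 1), "kernel dims must be odd")
  assert_that(kernel[1] <= ncol(field) && kernel[2] <= nrow(field),
              "kernel (%d x %d) larger than field (%d x %d)",
              kernel[1], kernel[2], ncol(field), nrow(field))
  out <- t(apply(field, 1, running_mean, width = kernel[1]))   # over time
  if (nrow(field) == 1) out <- matrix(out, nrow = 1)
  out <- apply(out, 2, running_mean, width = kernel[2])        # over frequency
  if (nrow(field) == 1) out <- matrix(out, nrow = 1)
  out
}

# Benjamini-Hochberg adjusted q-values on an array, preserving shape
bh_adjust <- function(p) {
  q <- p.adjust(as.vector(p), method = "BH")
  array(q, dim(p))
}

#' Session-level event-related causality
#'
#' For every directed channel pair, the task and baseline SdDTF fields are
#' smoothed with the 2D moving average and task points are t-tested
#' (two-sided) against the pair's baseline flow at the same frequency; the
#' pair's (f, t) family is then FDR-corrected. Only task-related increases
#' are retained in the significance mask; decreases are never reported.
#'
#' Two inference routes, chosen by the tensors' shape:
#' \itemize{
#'   \item replicate route (5D tensors from `sliding_sddtf(..., groups = G)`,
#'     the pipeline default): per trial group, the task point minus that
#'     group's mean baseline gives one replicate difference; a one-sample t
#'     across the G groups (df = G - 1) tests it against zero. Replicates
#'     carry the full estimation noise -- including the per-epoch noise-floor
#'     level that heavily overlapping windows cannot reveal -- so the test is
#'     calibrated under the null.
#'   \item pooled route (4D tensors): task points are referenced to the
#'     pooled across-window baseline distribution per frequency. Only valid
#'     when windows are (nearly) independent draws; with the default 140 ms /
#'     5.6 ms sliding geometry it understates uncertainty.
#' }
#'
#' @param task,baseline `flow_tensor`s from [sliding_sddtf()] with matching
#'   channels, frequency grids and replicate structure
#' @param cfg a [stats_config()]
#' @return an `erc_result` with arrays `delta` (smoothed task - baseline
#'   mean), `q`, `mask` (all K x K x nf x nw), `baseline_mean`
#'   (K x K x nf), and grid metadata
#' @export
erc_session <- function(task, baseline, cfg = stats_config()) {
  assert_that(identical(attr(task, "channels"), attr(baseline, "channels")),
              "task and baseline channels differ")
  assert_that(identical(attr(task, "freqs"), attr(baseline, "freqs")),
              "task and baseline frequency grids differ")
  G <- attr(task, "groups") %||% 0L
  assert_that(identical(G, attr(baseline, "groups") %||% 0L),
              "task and baseline replicate structure differs")
  nb <- dim(baseline)[4]
  assert_that(nb >= cfg$kernel[1],
              "baseline (%d windows) shorter than smoothing kernel (%d)", nb, cfg$kernel[1])
  K <- dim(task)[1]; nf <- dim(task)[3]; nw <- dim(task)[4]
  delta <- array(NA_real_, c(K, K, nf, nw))
  qv <- array(NA_real_, c(K, K, nf, nw))
  bmean <- array(NA_real_, c(K, K, nf))
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (k == l) next
    if (G >= 2) {
      dg <- array(NA_real_, c(nf, nw, G))
      mb_g <- matrix(NA_real_, nf, G)
      for (g in seq_len(G)) {
        ftg <- smooth_tf(matrix(task[k, l, , , g], nf, nw), cfg$kernel)
        fbg <- smooth_tf(matrix(baseline[k, l, , , g], nf, nb), cfg$kernel)
        mb_g[, g] <- rowMeans(fbg)
        dg[, , g] <- ftg - mb_g[, g]
      }
      d <- apply(dg, c(1, 2), mean)
      v <- apply(dg, c(1, 2), var)
      # moderated variance: replicate variance pooled over time per
      # frequency (replicate noise is stationary across the epoch, true
      # effects are sparse in time), with df credited only for effectively
      # independent (non-overlapping) windows of the sliding grid
      overlap <- attr(task, "overlap") %||% 25
      v_pool <- rowMeans(v)
      df <- (G - 1) * min(nw, max(1, round(nw / overlap)))
      tstat <- d / sqrt(pmax(v_pool, .Machine$double.xmin) / G)
      p <- 2 * pt(-abs(tstat), df = df)
      bmean[k, l, ] <- rowMeans(mb_g)
    } else {
      ft <- smooth_tf(matrix(task[k, l, , ], nf, nw), cfg$kernel)
      fb <- smooth_tf(matrix(baseline[k, l, , ], nf, nb), cfg$kernel)
      mb <- rowMeans(fb)
      sb <- pmax(apply(fb, 1, sd), .Machine$double.eps)
      d <- ft - mb
      tstat <- d / (sb * sqrt(1 + 1 / nb))
      p <- 2 * pt(-abs(tstat), df = nb - 1)
      bmean[k, l, ] <- mb
    }
    delta[k, l, , ] <- d
    qv[k, l, , ] <- bh_adjust(p)
  }
  mask <- !is.na(qv) & qv <= cfg$alpha & delta > 0
  structure(list(delta = delta, q = qv, mask = mask, baseline_mean = bmean,
                 channels = attr(task, "channels"),
                 regions = attr(task, "regions"),
                 freqs = attr(task, "freqs"), times = attr(task, "times"),
                 cfg = cfg),
            class = "erc_result")
}

# per-session directed region-pair class time courses: mean of the smoothed
# task-baseline difference over the class's *session-significant* channel
# pairs (those with any point in the selector's mask) and the band. Only
# session-significant flows are carried to the group level; averaging over
# every pair of a class would dilute a single coupled site pair by the
# class's pair count. `select` supplies the mask used for pair inclusion
# (for per-condition courses it is the pooled-trials result, so that pair
# selection is condition-neutral and contrasts stay unbiased).
class_courses <- function(erc, select = erc) {
  reg <- erc$regions
  K <- length(erc$channels); nw <- length(erc$times)
  classes <- list()
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (k == l) next
    if (!any(select$mask[k, l, , ])) next
    cls <- paste0(reg[l], "->", reg[k])
    d <- colMeans(matrix(erc$delta[k, l, , ], ncol = nw))  # mean over freq
    classes[[cls]] <- rbind(classes[[cls]], d)
  }
  lapply(classes, colMeans)
}

#' Group-level event-related causality
#'
#' Pools session-level ERC into directed region-pair classes (e.g.
#' `STG->STN`). Each session contributes one class time course (its smoothed
#' task-baseline flow change averaged over the class's channel pairs and the
#' analysis band). Per class and time point, the null hypothesis of zero mean
#' difference is tested with a two-sided t test whose normalizing standard
#' error is the standard deviation of the estimated mean difference
#' (across-session SD / sqrt(n)), followed by BH-FDR across the class's time
#' points. Masks keep significant positive means only.
#'
#' @param sessions list of `erc_result`s sharing grids
#' @param cfg a [stats_config()]
#' @param select_from optional list of `erc_result`s (same sessions) whose
#'   masks determine which channel pairs enter each class; defaults to the
#'   sessions' own masks. Pass the pooled-trials results here when grouping
#'   per-condition results, so pair selection is condition-neutral.
#' @return an `erc_group` with, per class: session course matrix, mean,
#'   confidence band, q-values, mask, n_sessions; empty (with a warning) if
#'   no class reaches two sessions
#' @export
erc_group <- function(sessions, cfg = stats_config(), select_from = NULL) {
  assert_that(length(sessions) >= 2, "group analysis needs >= 2 sessions")
  select_from <- select_from %||% sessions
  assert_that(length(select_from) == length(sessions),
              "select_from must match sessions")
  t0 <- sessions[[1]]$times
  for (s in sessions) {
    assert_that(isTRUE(all.equal(s$times, t0)), "sessions have mismatched time grids")
  }
  courses <- Map(class_courses, sessions, select_from)
  all_classes <- unique(unlist(lapply(courses, names)))
  out <- list()
  for (cls in all_classes) {
    have <- which(vapply(courses, function(cc) cls %in% names(cc), TRUE))
    if (length(have) < 2) {
      warning(sprintf("class %s present in < 2 sessions; excluded", cls), call. = FALSE)
      next
    }
    M <- do.call(rbind, lapply(courses[have], `[[`, cls))  # sessions x time
    n <- nrow(M)
    mu <- colMeans(M)
    se <- apply(M, 2, sd) / sqrt(n)
    se <- pmax(se, .Machine$double.eps)
    tstat <- mu / se
    p <- 2 * pt(-abs(tstat), df = n - 1)
    q <- p.adjust(p, method = "BH")
    ci <- qt(0.975, df = n - 1) * se
    out[[cls]] <- list(courses = M, sessions = have, mean = mu, ci = ci,
                       q = q, mask = q <= cfg$alpha & mu > 0, n_sessions = n)
  }
  if (length(out) == 0) {
    warning("no region-pair class with significant flow in >= 2 sessions",
            call. = FALSE)
  }
  structure(list(classes = out, times = t0, cfg = cfg), class = "erc_group")
}

#' Word-versus-pseudoword condition contrast
#'
#' Pairs the two conditions' group results session by session and, per
#' directed region-pair class and time point, tests word minus pseudoword
#' class courses with a paired two-sided t test, BH-FDR corrected across the
#' class's time points. The mask is signed: +1 where word > pseudoword
#' significantly, -1 for the reverse.
#'
#' @param words,pseudo `erc_group` results for the two conditions, built from
#'   the same sessions
#' @param cfg a [stats_config()]
#' @param windows named list of `(start_s, end_s)` intervals additionally
#'   tested at the window level (class course differences averaged over the
#'   interval, one paired t per class and window, BH across classes); the
#'   [erc_presets()] intervals by default. This is how an effect confined to
#'   a known pre-speech window is reported when the per-time-point masks lack
#'   power.
#' @return list per class: `diff` (mean word - pseudoword course), `q`,
#'   signed `mask`; time grid in `attr(, "times")` and the window-level test
#'   table in `attr(, "window_tests")`
#' @export
condition_contrast <- function(words, pseudo, cfg = stats_config(),
                               windows = erc_presets()) {
  assert_that(isTRUE(all.equal(words$times, pseudo$times)),
              "condition results have mismatched time grids")
  out <- list()
  wrows <- list()
  for (cls in intersect(names(words$classes), names(pseudo$classes))) {
    cw <- words$classes[[cls]]; cp <- pseudo$classes[[cls]]
    if (!identical(cw$sessions, cp$sessions)) {
      stop_ercflow("class %s built from different session sets in the two conditions", cls)
    }
    D <- cw$courses - cp$courses
    n <- nrow(D)
    mu <- colMeans(D)
    se <- pmax(apply(D, 2, sd) / sqrt(n), .Machine$double.eps)
    p <- 2 * pt(-abs(mu / se), df = n - 1)
    q <- p.adjust(p, method = "BH")
    out[[cls]] <- list(diff = mu, q = q,
                       mask = ifelse(q <= cfg$alpha, sign(mu), 0),
                       n_sessions = n)
    for (wn in names(windows)) {
      on <- words$times >= windows[[wn]][1] & words$times < windows[[wn]][2]
      if (!any(on)) next
      wi <- rowMeans(D[, on, drop = FALSE])
      tw <- mean(wi) / max(sd(wi) / sqrt(n), .Machine$double.eps)
      wrows[[length(wrows) + 1L]] <- data.frame(
        class = cls, window = wn, diff = mean(wi), t = tw,
        p = 2 * pt(-abs(tw), df = n - 1), n_sessions = n,
        stringsAsFactors = FALSE)
    }
  }
  wt <- if (length(wrows)) do.call(rbind, wrows) else NULL
  if (!is.null(wt)) {
    wt$q <- ave(wt$p, wt$window, FUN = function(p) p.adjust(p, "BH"))
  }
  attr(out, "times") <- words$times
  attr(out, "window_tests") <- wt
  out
}

#' Named preset integration intervals
#'
#' `pre_speech_burst`: (-450, -400) ms before speech onset (the interval of
#' significantly stronger STG-to-STN propagation versus baseline);
#' `lexical_contrast`: (-208, -117) ms (the pre-speech window of significant
#' word/pseudoword differences); `flow_integration`: (-500, -300) ms (the
#' interval used for integrated single-session flow diagrams).
#'
#' @return named list of `(start_s, end_s)` intervals
#' @export
erc_presets <- function() {
  list(pre_speech_burst = c(-0.450, -0.400),
       lexical_contrast = c(-0.208, -0.117),
       flow_integration = c(-0.500, -0.300))
}

#' Integrate significant flows over a time interval
#'
#' For a session-level result, each directed channel pair's weight is the
#' mean of its significant (masked) smoothed flow increase over the interval
#' (and band); for a group result, each class's weight is the mean of the
#' significant group mean course. Pairs or classes with no significant points
#' in the interval get weight zero.
#'
#' @param erc an `erc_result` or `erc_group`
#' @param interval `(start_s, end_s)`, or the name of an [erc_presets()]
#'   entry
#' @param band frequency band to integrate over (session level; default all)
#' @return a `flow_graph` data.frame: `source`, `target`, `source_region`,
#'   `target_region`, `weight`
#' @export
integrate_flows <- function(erc, interval = "pre_speech_burst", band = NULL) {
  if (is.character(interval)) interval <- erc_presets()[[interval]]
  assert_that(!is.null(interval) && interval[1] < interval[2],
              "empty or invalid integration interval")
  ti <- which(erc$times >= interval[1] & erc$times < interval[2])
  assert_that(length(ti) > 0, "interval outside the result's time grid")
  if (inherits(erc, "erc_result")) {
    fi <- if (is.null(band)) seq_along(erc$freqs) else
      which(erc$freqs >= band[1] & erc$freqs <= band[2])
    K <- length(erc$channels)
    rows <- list()
    for (k in seq_len(K)) for (l in seq_len(K)) {
      if (k == l) next
      d <- erc$delta[k, l, fi, ti, drop = FALSE]
      m <- erc$mask[k, l, fi, ti, drop = FALSE]
      w <- if (any(m)) mean(d[m]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        source = erc$channels[l], target = erc$channels[k],
        source_region = erc$regions[l], target_region = erc$regions[k],
        weight = w, stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)
  } else if (inherits(erc, "erc_group")) {
    rows <- lapply(names(erc$classes), function(cls) {
      cc <- erc$classes[[cls]]
      m <- cc$mask[ti]
      w <- if (any(m)) mean(cc$mean[ti][m]) else 0
      parts <- strsplit(cls, "->", fixed = TRUE)[[1]]
      data.frame(source = parts[1], target = parts[2],
                 source_region = parts[1], target_region = parts[2],
                 weight = w, stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, rows)
  } else stop_ercflow("unsupported object for flow integration")
  class(g) <- c("flow_graph", "data.frame")
  attr(g, "interval") <- interval
  g
}
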