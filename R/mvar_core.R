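#' Sample-sufficiency check for short-window MVAR fitting
#'
#' Multi-trial short-window estimation is considered data-sufficient when
#' \deqn{\frac{K(p+1)}{N_s n_t} < 0.1}
#' where K is the channel count, p the model order, \eqn{N_s} the samples per
#' window and \eqn{n_t} the number of trials.
#'
#' @param K,p,Ns,nt channel count, model order, samples per window, trials
#' @return list with the `ratio` and a `pass` flag
#' @examples
#' check_sufficiency(K = 10, p = 12, Ns = 175, nt = 60)  # ratio ~0.0124, pass
#' @export
check_sufficiency <- function(K, p, Ns, nt) {
  assert_that(all(c(K, p, Ns, nt) >= 1), "all counts must be >= 1")
  assert_that(Ns * nt > 0, "zero denominator in sufficiency ratio")
  ratio <- K * (p + 1) / (Ns * nt)
  list(ratio = ratio, pass = ratio < 0.1)
}

#' Sliding-window grid
#'
#' Default geometry: 140 ms windows shifted by 5.6 ms, which at the 1250 Hz
#' analysis rate is exactly 175 samples stepped by 7.
#'
#' @param ep an [epoch_set()]
#' @param window_len_s window length in seconds
#' @param step_s window shift in seconds
#' @return a `window_grid`: 1-based window start indices, sample counts, and
#'   window-center times (seconds relative to the alignment event)
#' @export
window_grid <- function(ep, window_len_s = 0.140, step_s = 0.0056) {
  fs <- ep$sampling_rate
  Ns <- round(window_len_s * fs)
  st <- round(step_s * fs)
  assert_that(abs(Ns - window_len_s * fs) < 1e-6 && abs(st - step_s * fs) < 1e-6,
              "window length and step must be integer sample counts at %g Hz", fs)
  n_ep <- dim(ep$data)[3]
  assert_that(n_ep >= Ns, "epoch (%d samples) shorter than one window (%d samples)",
              n_ep, Ns)
  starts <- seq(1L, n_ep - Ns + 1L, by = st)
  centers <- ep$window[1] + (starts - 1 + Ns / 2) / fs
  structure(list(starts = starts, Ns = Ns, step = st,
                 window_len_s = window_len_s, step_s = step_s,
                 times = centers, K = dim(ep$data)[2], nt = dim(ep$data)[1]),
            class = "window_grid")
}

# multichannel Yule-Walker on a trials x channels x samples array.
# Lag covariances are averaged across trials (per-trial, per-window mean
# removed first); the biased (divide by Ns) estimator keeps the block-Toeplitz
# system well behaved. A tiny relative ridge on the Toeplitz diagonal guards
# against the extreme ill-conditioning of steeply band-pass-filtered signals
# (out-of-band covariance eigenvalues are ~1e-10 of in-band ones); at 1e-8 of
# the mean channel power it is far below estimation noise on any test case.
mvar_yule_walker <- function(X, p, fs, ridge = 1e-8) {
  nt <- dim(X)[1]; K <- dim(X)[2]; Ns <- dim(X)[3]
  assert_that(Ns > p, "window of %d samples too short for order %d", Ns, p)
  # K x (Ns * nt) layout, trial-blocked columns, centred per trial and channel
  M <- aperm(X, c(2, 3, 1))
  dim(M) <- c(K, Ns * nt)
  grp <- rep(seq_len(nt), each = Ns)
  mu <- t(rowsum(t(M), grp, reorder = FALSE)) / Ns       # K x nt
  M <- M - mu[, grp, drop = FALSE]
  tpos <- rep(seq_len(Ns), nt)
  R <- vector("list", p + 1)
  R[[1]] <- tcrossprod(M) / (nt * Ns)
  for (j in seq_len(p)) {
    # sum over trials and t of x(t) x(t-j)^T, lags never crossing trials;
    # unbiased normalization (Ns - j): at short windows the biased (/Ns)
    # variant tapers coefficients enough to distort order selection
    sel <- which(tpos > j)
    R[[j + 1]] <- tcrossprod(M[, sel, drop = FALSE], M[, sel - j, drop = FALSE]) / (nt * (Ns - j))
  }
  Rv <- function(j) if (j >= 0) R[[j + 1]] else t(R[[-j + 1]])
  # solve [R(1) ... R(p)] = [B_1 ... B_p] T,  T[(m),(s)] = R(s - m)
  Tm <- matrix(0, K * p, K * p)
  for (m in seq_len(p)) for (s in seq_len(p)) {
    Tm[((m - 1) * K + 1):(m * K), ((s - 1) * K + 1):(s * K)] <- Rv(s - m)
  }
  C <- do.call(cbind, lapply(seq_len(p), Rv))
  diag(Tm) <- diag(Tm) + ridge * mean(diag(R[[1]]))
  B <- tryCatch(C %*% solve(Tm),
                error = function(e) {
                  v <- diag(R[[1]])
                  flat <- paste(colnames(v) %||% which(v < 1e-12 * max(v)), collapse = ", ")
                  stop_ercflow("singular lag covariance in Yule-Walker solve (suspect channels: %s): %s",
                               flat, conditionMessage(e))
                })
  coefs <- lapply(seq_len(p), function(m) B[, ((m - 1) * K + 1):(m * K), drop = FALSE])
  Sigma <- R[[1]]
  for (m in seq_len(p)) Sigma <- Sigma - coefs[[m]] %*% t(R[[m + 1]])
  Sigma <- (Sigma + t(Sigma)) / 2
  # small-sample fits on steeply filtered data can return an indefinite
  # residual covariance; clamp its spectrum to a tiny positive floor so the
  # spectral matrix downstream stays PSD
  es <- eigen(Sigma, symmetric = TRUE)
  floor_ev <- 1e-10 * max(abs(es$values), .Machine$double.xmin)
  if (min(es$values) < floor_ev) {
    Sigma <- es$vectors %*% (pmax(es$values, floor_ev) * t(es$vectors))
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  # construct directly: the constructor's validation checks cost more than
  # the solve itself when called once per (window, trial group)
  structure(list(order = p, coefs = coefs, noise_cov = Sigma,
                 sampling_rate = fs),
            class = "mvar_model")
}

# enforce stationarity of an estimated model: poles at radius rho >= target
# are shrunk radially (B_j <- c^j B_j maps every pole lambda to c * lambda).
# Without this, a window fit with poles on the unit circle puts unbounded
# transfer-function mass at one frequency and hogs the SdDTF normalization.
stabilize_mvar <- function(model, target = 0.995) {
  rho <- mvar_spectral_radius(model)
  if (!is.finite(rho) || rho < target) return(model)
  cshrink <- target / rho
  model$coefs <- lapply(seq_along(model$coefs),
                        function(j) model$coefs[[j]] * cshrink^j)
  model
}

#' Fit an MVAR model in one sliding window (or on whole epochs)
#'
#' Lag covariances are computed per trial within the window (per-trial mean
#' removed), averaged across trials, and the Yule-Walker equations are solved
#' for the coefficient matrices and innovation covariance.
#'
#' @param ep an [epoch_set()]
#' @param p model order
#' @param window window index into `grid` (NULL fits the whole epoch)
#' @param grid a [window_grid()] (required when `window` is given)
#' @param on_insufficient what to do when the sample-sufficiency inequality
#'   fails: `"warn"` (default) or `"error"`
#' @return an [mvar_model()]
#' @export
fit_mvar_window <- function(ep, p, window = NULL, grid = NULL,
                            on_insufficient = c("warn", "error")) {
  on_insufficient <- match.arg(on_insufficient)
  if (is.null(window)) {
    X <- ep$data
  } else {
    assert_that(!is.null(grid), "grid required when window index is given")
    s <- grid$starts[window]
    X <- ep$data[, , s:(s + grid$Ns - 1), drop = FALSE]
  }
  suff <- check_sufficiency(dim(X)[2], p, dim(X)[3], dim(X)[1])
  if (!suff$pass) {
    msg <- sprintf("sample sufficiency violated: K(p+1)/(Ns*nt) = %.3f >= 0.1", suff$ratio)
    if (on_insufficient == "error") stop_ercflow(msg) else warning(msg, call. = FALSE)
  }
  mvar_yule_walker(X, p, ep$sampling_rate)
}

# innovation covariance from the fitted model's one-step-ahead residuals,
# evaluated on a common conditioning range t > t0 (per-trial demeaned). AIC
# compares candidate orders on this covariance: the Yule-Walker identity
# covariance is too optimistic about extra lags, and a shared sample range is
# essential -- otherwise each order is scored on a different sample set and
# the score differences are dominated by sampling noise, not fit quality.
mvar_residual_cov <- function(X, coefs, t0 = length(coefs)) {
  nt <- dim(X)[1]; K <- dim(X)[2]; Ns <- dim(X)[3]
  p <- length(coefs)
  assert_that(t0 >= p && t0 < Ns, "conditioning range must cover the order")
  mu <- apply(X, c(1, 2), mean)
  X <- X - array(rep(mu, Ns), dim(X))
  SS <- matrix(0, K, K)
  for (i in seq_len(nt)) {
    xi <- matrix(X[i, , ], K, Ns)
    pred <- matrix(0, K, Ns - t0)
    for (j in seq_len(p)) {
      pred <- pred + coefs[[j]] %*% xi[, (t0 + 1 - j):(Ns - j), drop = FALSE]
    }
    e <- xi[, (t0 + 1):Ns, drop = FALSE] - pred
    SS <- SS + tcrossprod(e)
  }
  SS / (nt * (Ns - t0))
}

#' AIC model-order selection
#'
#' Fits each candidate order on a stratified sample of sliding windows and
#' returns the single global order minimizing the median AIC, with
#' \deqn{AIC(p) = N \log\det\hat\Sigma_e(p) + 2 p K^2}
#' where \eqn{\hat\Sigma_e(p)} is the covariance of the fitted model's
#' one-step-ahead residuals evaluated on the common conditioning range
#' t > max(p_range), and \eqn{N = n_t (N_s - \max p)} the residual count
#' (shared across candidates so that AIC differences reflect fit quality).
#'
#' @param ep an [epoch_set()]
#' @param p_range candidate orders
#' @param grid a [window_grid()]; NULL treats the whole epoch as one window
#' @param n_windows number of evenly spaced windows sampled from the grid
#' @return selected order (integer); per-order median AICs in
#'   `attr(, "aic")`
#' @export
select_order_aic <- function(ep, p_range = 2:8, grid = NULL, n_windows = 9) {
  assert_that(length(p_range) >= 1, "empty candidate order range")
  widx <- if (is.null(grid)) NA_integer_ else
    unique(round(seq(1, length(grid$starts), length.out = min(n_windows, length(grid$starts)))))
  aic <- sapply(p_range, function(p) {
    vals <- sapply(widx, function(w) {
      m <- fit_mvar_window(ep, p, window = if (is.na(w)) NULL else w, grid = grid)
      X <- if (is.na(w)) ep$data else {
        s <- grid$starts[w]
        ep$data[, , s:(s + grid$Ns - 1), drop = FALSE]
      }
      K <- dim(X)[2]
      pmax <- max(p_range)
      N <- dim(X)[1] * (dim(X)[3] - pmax)
      ld <- determinant(mvar_residual_cov(X, m$coefs, t0 = pmax), logarithm = TRUE)
      N * as.numeric(ld$modulus) + 2 * p * K^2
    })
    median(vals)
  })
  p_sel <- p_range[which.min(aic)]
  attr(p_sel, "aic") <- setNames(aic, p_range)
  p_sel
}

#' Spectral decomposition of an MVAR model
#'
#' At each frequency f the coefficient polynomial
#' \eqn{A(f) = I - \sum_j B_j e^{-2\pi i f j / f_s}} is inverted to the
#' transfer matrix \eqn{H(f) = A(f)^{-1}} (directed relationships); the
#' spectral matrix is \eqn{S(f) = H \Sigma_e H^*}; partial coherence
#' (direct relationships, with all other channels' linear contributions
#' removed) comes from the normalized inverse spectral matrix,
#' \eqn{c_{kl} = M_{kl} / \sqrt{M_{kk} M_{ll}}}, \eqn{M = S^{-1}}.
#'
#' @param model a stable [mvar_model()]
#' @param freqs frequency grid in Hz
#' @param check verify model stability first (skipped inside tight loops over
#'   estimated window models, where occasional marginal instability of an
#'   estimate is harmless for the frequency-domain algebra)
#' @return `spectral_decomposition`: complex arrays `h`, `s`, `c`
#'   (K x K x nf) and the frequency grid
#' @export
spectral_decomposition <- function(model, freqs, check = TRUE) {
  if (check) assert_that(mvar_is_stable(model), "model must be stable")
  K <- nrow(model$noise_cov); nf <- length(freqs)
  fs <- model$sampling_rate
  H <- array(complex(real = 0), c(K, K, nf))
  S <- H; Cc <- H
  I <- diag(K)
  p <- model$order
  ridge <- diag(1e-10 + 0i, K)
  ex <- exp(outer(seq_len(p), freqs, function(j, f) -2i * pi * f * j / fs))
  fi <- 0L
  tryCatch(
    for (fi in seq_len(nf)) {
      A <- I + 0i
      for (j in seq_len(p)) A <- A - model$coefs[[j]] * ex[j, fi]
      Hf <- solve(A)
      Sf <- Hf %*% model$noise_cov %*% Conj(t(Hf))
      # tiny relative ridge: band-pass-filtered fits leave the spectral
      # matrix with near-null modes far below estimation noise
      M <- solve(Sf + ridge * mean(Re(diag(Sf))))
      # noisy small-sample fits can leave Sigma_e (hence M) marginally
      # indefinite; clamp the normalizing diagonal away from zero
      d <- sqrt(pmax(Re(diag(M)), 1e-12 * max(abs(M))))
      H[, , fi] <- Hf
      S[, , fi] <- Sf
      Cc[, , fi] <- M / (d %*% t(d))
    },
    error = function(e)
      stop_ercflow("spectral decomposition failed at f = %g Hz: %s",
                   freqs[max(fi, 1L)], conditionMessage(e)))
  structure(list(h = H, s = S, c = Cc, freqs = freqs, K = K),
            class = "spectral_decomposition")
}

#' Short-time direct directed transfer function (one window)
#'
#' \deqn{z_{kl}(f) = \frac{|h_{kl}(f)\, c_{kl}(f)|}
#'   {\sqrt{\sum_f \sum_{k \ne l} |h_{kl}(f) c_{kl}(f)|^2}}}
#' combining the transfer matrix (directed relationship) with partial
#' coherence (direct relationship). The normalization family runs over the
#' decomposition's frequency grid and all ordered off-diagonal pairs within
#' the window, so values lie in [0, 1] and the family's squares sum to one.
#'
#' @param dec a [spectral_decomposition()]
#' @return K x K x nf array of z values (target k, source l, frequency);
#'   diagonal entries are zero
#' @export
sddtf <- function(dec) {
  g <- Mod(dec$h) * Mod(dec$c)
  for (fi in seq_len(dim(g)[3])) diag(g[, , fi]) <- 0
  if (!all(is.finite(g))) stop_ercflow("degenerate input: non-finite h*c")
  den <- sqrt(sum(g^2))
  # fully independent channels: zero numerators AND zero denominator; the
  # meaningful value is zero flow everywhere, not an error
  z <- if (den == 0) g else g / den
  attr(z, "freqs") <- dec$freqs
  z
}

#' SdDTF over a sliding-window grid
#'
#' Fits an MVAR model in every window and evaluates the SdDTF, producing the
#' flow tensor z(target, source, frequency, window time). Window timestamps
#' are window centers.
#'
#' @param ep an [epoch_set()]
#' @param p model order
#' @param grid a [window_grid()] (default geometry if NULL)
#' @param freqs frequency grid in Hz (default 60-180 Hz in 4 Hz steps)
#' @param groups optional replicate count G: trials are split round-robin
#'   into G groups and the SdDTF estimated per group, yielding a 5D tensor
#'   (K x K x nf x n_windows x G) whose replicate spread carries honest
#'   uncertainty for the ERC statistics (sliding windows overlap heavily, so
#'   across-window spread alone understates estimation noise)
#' @param on_insufficient forwarded to [fit_mvar_window()]
#' @return a `flow_tensor`: array K x K x nf x n_windows (x G) with
#'   attributes `freqs`, `times`, `channels`, `regions`, `p`, `groups`
#' @export
sliding_sddtf <- function(ep, p, grid = NULL, freqs = seq(60, 180, by = 4),
                          groups = NULL, on_insufficient = c("warn", "error")) {
  on_insufficient <- match.arg(on_insufficient)
  grid <- grid %||% window_grid(ep)
  nt <- dim(ep$data)[1]
  gidx <- if (is.null(groups)) rep(1L, nt) else {
    assert_that(groups >= 2 && groups <= nt, "groups must be in [2, n_trials]")
    rep_len(seq_len(groups), nt)
  }
  G <- max(gidx)
  suff <- check_sufficiency(dim(ep$data)[2], p, grid$Ns, min(table(gidx)))
  if (!suff$pass && on_insufficient == "error") {
    stop_ercflow("sample sufficiency violated: ratio = %.3f >= 0.1", suff$ratio)
  }
  K <- dim(ep$data)[2]; nf <- length(freqs); nw <- length(grid$starts)
  Z <- array(NA_real_, c(K, K, nf, nw, G))
  for (g in seq_len(G)) {
    epg <- ep
    epg$data <- ep$data[gidx == g, , , drop = FALSE]
    epg$trials <- ep$trials   # metadata untouched; fits only use $data
    for (w in seq_len(nw)) {
      m <- fit_mvar_window(epg, p, window = w, grid = grid,
                           on_insufficient = on_insufficient)
      m <- stabilize_mvar(m)
      Z[, , , w, g] <- sddtf(spectral_decomposition(m, freqs, check = FALSE))
    }
  }
  if (is.null(groups)) Z <- array(Z, c(K, K, nf, nw))
  structure(Z, class = "flow_tensor", freqs = freqs, times = grid$times,
            channels = ep$channels$id, regions = ep$channels$region, p = p,
            groups = if (is.null(groups)) NULL else G,
            overlap = grid$Ns / grid$step, sufficiency = suff)
}
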