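#' @keywords internal
#' @importFrom stats rnorm runif qnorm pnorm pt qt sd mad median approx
#'   convolve mvfft p.adjust setNames
"_PACKAGE"

# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ercflow <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_ercflow(fmt, ...)
  invisible(TRUE)
}

#' Derive independent child seeds from a master seed
#'
#' Uses the master seed to draw `n` integer seeds below 2^31 so that nested
#' stages (behaviour sampling, signal generation, per-session simulation) get
#' reproducible, non-colliding RNG streams.
#'
#' @param seed master integer seed
#' @param n number of child seeds
#' @return integer vector of length `n`
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# truncated-normal sampler, truncation at zero; exact inverse-CDF so it is
# deterministic given the RNG state and degenerates cleanly at sd = 0
rtruncnorm0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- numeric(n)
  pos <- sd > 0
  out[!pos] <- mean[!pos]
  if (any(pos)) {
    lo <- pnorm(0, mean[pos], sd[pos])
    u <- runif(sum(pos), lo, 1)
    out[pos] <- qnorm(u, mean[pos], sd[pos])
  }
  out
}

# FNV-1a 32-bit hash over serialized R objects; used for provenance strings
# (no cryptographic intent, just a stable fingerprint without extra deps)
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# raised-cosine on/off taper weight for a half-open activation window
# [start, end); `ramp` seconds of cosine at each edge, evaluated at times `t`
taper_weight <- function(t, start, end, ramp) {
  w <- numeric(length(t))
  inside <- t >= start & t < end
  w[inside] <- 1
  if (ramp > 0) {
    up <- t >= start & t < start + ramp
    w[up] <- 0.5 * (1 - cos(pi * (t[up] - start) / ramp))
    dn <- t >= end - ramp & t < end
    w[dn] <- pmin(w[dn], 0.5 * (1 - cos(pi * (end - t[dn]) / ramp)))
  }
  w
}
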