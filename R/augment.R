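# ---------------------------------------------------------------------------
# Time-domain training-set augmentation: jittering (white Gaussian noise),
# time-warping (smooth random distortion of the time axis) and pooling
# (local averaging that lowers resolution without changing length).
# Each training cycle yields 4 cycles: 1 raw + 3 augmented.
# ---------------------------------------------------------------------------

#' Augmentation configuration
#'
#' @param jitter_mu,jitter_sigma Gaussian noise moments (defaults 0 / 0.03).
#' @param warp_knots number of random warp knots (default 4).
#' @param warp_mu,warp_sigma knot magnitude moments (defaults 1 / 0.2).
#' @param pool_window odd pooling window (default 3).
#' @return list of settings.
#' @export
augmentation_config <- function(jitter_mu = 0, jitter_sigma = 0.03,
                                warp_knots = 4, warp_mu = 1, warp_sigma = 0.2,
                                pool_window = 3) {
  if (jitter_sigma <= 0 || warp_sigma <= 0) stop("sigmas must be positive")
  if (warp_knots < 2) stop("at least 2 warp knots required")
  if (pool_window < 3 || pool_window %% 2 == 0)
    stop("pool window must be odd and >= 3")
  list(jitter_mu = jitter_mu, jitter_sigma = jitter_sigma,
       warp_knots = warp_knots, warp_mu = warp_mu, warp_sigma = warp_sigma,
       pool_window = pool_window)
}

#' Jittering: add white Gaussian noise
#'
#' @param x frames x channels matrix (or vector).
#' @param sigma noise standard deviation (default 0.03).
#' @param mu noise mean (default 0).
#' @param seed optional seed for reproducibility.
#' @return matrix of the same shape.
#' @export
jitter <- function(x, sigma = 0.03, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x + rnorm(length(x), mean = mu, sd = sigma)
}

# Monotone time map for warping: a cubic spline through `knots` random
# speed magnitudes ~ N(mu, sigma), clamped to >= 0.1 so the integrated map
# is strictly increasing, then rescaled to fix both endpoints.
warp_time_map <- function(n, knots = 4, mu = 1, sigma = 0.2, seed = NULL,
                          magnitudes = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(magnitudes)) magnitudes <- rnorm(knots, mu, sigma)
  pos <- seq(1, n, length.out = knots)
  speed <- spline(pos, magnitudes, xout = seq_len(n))$y
  speed <- pmax(speed, 0.1)
  cumulative <- cumsum(speed)
  1 + (cumulative - cumulative[1]) / (cumulative[n] - cumulative[1]) * (n - 1)
}

#' Time-warping: resample along a smooth random monotone time map
#'
#' A warping-speed curve is built from a cubic spline through `knots` random
#' magnitudes (mean `mu`, sd `sigma`, clamped positive) and integrated into a
#' strictly increasing time map fixing both endpoints; every channel is
#' linearly resampled along the map, preserving length.
#'
#' @inheritParams jitter
#' @param knots,mu,sigma warp parameters (defaults 4 knots, N(1, 0.2)).
#' @param time_map optionally, a precomputed map (to warp targets
#'   identically to inputs).
#' @return list with `x` (warped series) and `time_map`.
#' @export
time_warp <- function(x, knots = 4, mu = 1, sigma = 0.2, seed = NULL,
                      time_map = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 8) stop("at least 8 frames are required for warping")
  if (is.null(time_map))
    time_map <- warp_time_map(n, knots, mu, sigma, seed)
  out <- apply(x, 2, function(col) approx(seq_len(n), col, xout = time_map)$y)
  dimnames(out) <- dimnames(x)
  list(x = out, time_map = time_map)
}

#' Pooling: centred moving average with edge replication
#'
#' Reduces the resolution of the series without changing its length.
#'
#' @param x frames x channels matrix (or vector).
#' @param window odd window size (default 3).
#' @return matrix of the same shape.
#' @export
pool <- function(x, window = 3) {
  if (window %% 2 == 0) stop("pool window must be odd")
  vec <- !is.matrix(x)
  x <- as.matrix(x)
  n <- nrow(x)
  h <- (window - 1) / 2
  ext <- rbind(x[rep(1, h), , drop = FALSE], x, x[rep(n, h), , drop = FALSE])
  out <- apply(ext, 2, function(col)
    stats::filter(col, rep(1 / window, window), sides = 2))
  out <- out[(h + 1):(h + n), , drop = FALSE]
  dimnames(out) <- dimnames(x)
  if (vec) drop(out) else out
}

#' Build the 4-fold augmented training set
#'
#' For every training cycle, emits the raw cycle plus one jittered, one
#' time-warped and one pooled copy (4x the count). Jittering and pooling are
#' applied to the inputs only (targets copied unchanged); time-warping is
#' applied to inputs and targets with the same time map, and the phase
#' labels are resampled along that map so input-target-phase alignment is
#' preserved.
#'
#' @param cycles list of training cycles; each a list with `x` (frames x
#'   channels input matrix), `y` (frames x 3 CG target), `phases` (integer
#'   labels), plus any metadata carried through.
#' @param config an [augmentation_config()].
#' @param seed master seed; per-trial operator seeds derive from it.
#' @param enabled set `FALSE` to pass the input set through unchanged.
#' @return list of cycles, 4x the input length (raw cycles first for each
#'   trial, each tagged with an `augmentation` field).
#' @export
build_training_set <- function(cycles, config = augmentation_config(),
                               seed = 1L, enabled = TRUE) {
  if (!length(cycles)) stop("no training cycles supplied")
  if (!enabled) return(cycles)
  set.seed(as.integer(seed))
  op_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * length(cycles)),
                     ncol = 2)
  out <- vector("list", 4 * length(cycles))
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    raw <- cyc; raw$augmentation <- "raw"

    jit <- cyc
    jit$x <- jitter(cyc$x, sigma = config$jitter_sigma, mu = config$jitter_mu,
                    seed = op_seeds[i, 1])
    jit$augmentation <- "jitter"

    wr <- cyc
    w <- time_warp(cyc$x, knots = config$warp_knots, mu = config$warp_mu,
                   sigma = config$warp_sigma, seed = op_seeds[i, 2])
    wr$x <- w$x
    wr$y <- time_warp(cyc$y, time_map = w$time_map)$x
    if (!is.null(cyc$phases))
      wr$phases <- enforce_contiguous_phases(cyc$phases[round(w$time_map)])
    wr$augmentation <- "warp"

    pl <- cyc
    pl$x <- pool(cyc$x, window = config$pool_window)
    pl$augmentation <- "pool"

    out[[4 * i - 3]] <- raw
    out[[4 * i - 2]] <- jit
    out[[4 * i - 1]] <- wr
    out[[4 * i]] <- pl
  }
  out
}
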