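# ---------------------------------------------------------------------------
# Preprocessing: zero-phase Butterworth filtering, cycle extraction,
# 100-frame time normalization, weight / leg-length normalization, and the
# local gait-frame transform of the CG trajectory.
# ---------------------------------------------------------------------------

#' Zero-phase Butterworth lowpass filter
#'
#' 4th-order Butterworth lowpass applied forward and backward (zero phase
#' lag, so pressures stay synchronized with the CG targets). The series is
#' extended by odd reflection at both ends before filtering to suppress edge
#' transients, then cropped back to its original length.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param sample_rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist rate.
#' @param order filter order (default 4).
#' @return filtered series with the same shape as `x`.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff, order = 4) {
  if (cutoff >= sample_rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (is.matrix(x)) {
    out <- apply(x, 2, lowpass_filter, sample_rate = sample_rate,
                 cutoff = cutoff, order = order)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n <= 3 * order) stop("signal too short for the requested filter order")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  pad <- min(n - 1, max(30, round(3 * sample_rate / cutoff)))
  # odd (point-symmetric) reflection about each endpoint; the first sample is
  # subtracted before filtering (unit DC gain) so the zero-state transient
  # acts on a signal starting at zero
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  ext <- c(left, x, right)
  fwd <- as.numeric(signal::filter(bf, ext - ext[1])) + ext[1]
  r <- rev(fwd)
  bwd <- rev(as.numeric(signal::filter(bf, r - r[1])) + r[1])
  bwd[(pad + 1):(pad + n)]
}

#' Extract one gait cycle between two heel strikes
#'
#' Returns the half-open segment `[hs1, hs2)` (1-based frame indices), so
#' consecutive cycles tile the recording without duplicated frames.
#'
#' @param x vector or matrix time series (rows = frames).
#' @param heel_strikes integer vector `c(hs1, hs2)` with `hs1 < hs2`.
#' @return the extracted segment (same column structure as `x`).
#' @export
extract_cycle <- function(x, heel_strikes) {
  hs1 <- heel_strikes[1]; hs2 <- heel_strikes[2]
  nf <- if (is.matrix(x)) nrow(x) else length(x)
  if (hs2 <= hs1) stop("second heel strike must come after the first")
  if (hs1 < 1 || hs2 > nf + 1) stop("heel strikes outside the signal")
  idx <- hs1:(hs2 - 1)
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Time-normalize a cycle to a fixed number of frames
#'
#' Linear interpolation on a uniform grid that includes both endpoints, so
#' the first and last input samples are preserved exactly.
#'
#' @param x vector or matrix (rows = frames).
#' @param n_frames output length (default 100).
#' @return resampled series with exactly `n_frames` frames.
#' @export
time_normalize <- function(x, n_frames = 100) {
  nf <- if (is.matrix(x)) nrow(x) else length(x)
  if (nf < 2) stop("at least 2 frames are required")
  grid <- seq(1, nf, length.out = n_frames)
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) approx(seq_len(nf), col, xout = grid)$y)
    dimnames(out) <- list(NULL, colnames(x))
    out
  } else {
    approx(seq_len(nf), x, xout = grid)$y
  }
}

#' Normalize pressures by body weight
#'
#' Divides by the body-weight force `weight * g` (g = 9.81 m/s^2), yielding
#' dimensionless pressures in units of body weight.
#'
#' @param pressures matrix in N.
#' @param weight body mass in kg (> 0).
#' @return dimensionless matrix.
#' @export
normalize_pressure_by_weight <- function(pressures, weight) {
  if (weight <= 0) stop("weight must be positive")
  pressures / (weight * 9.81)
}

#' Transform a global CG trajectory into the local gait frame
#'
#' The origin is placed at the double-support midpoint; the x-axis is the
#' horizontal walking direction, the z-axis the vertical, and the y-axis
#' their cross product `z x x` (right-handed, pointing left), giving axes
#' ordered (anterior/posterior, medial/lateral, proximal/distal).
#'
#' @param cg_global frames x 3 matrix (mm).
#' @param origin 3-vector: midpoint of double support.
#' @param walking_direction 3-vector (need not be unit or horizontal).
#' @param vertical 3-vector, default `c(0, 0, 1)`.
#' @return frames x 3 matrix with columns `ap`, `ml`, `pd`.
#' @export
cg_to_local_frame <- function(cg_global, origin, walking_direction,
                              vertical = c(0, 0, 1)) {
  z <- vertical / sqrt(sum(vertical^2))
  wd <- walking_direction - sum(walking_direction * z) * z
  if (sqrt(sum(wd^2)) < 1e-9)
    stop("walking direction is parallel to the vertical")
  x <- wd / sqrt(sum(wd^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  out <- sweep(cg_global, 2, origin) %*% t(R)
  colnames(out) <- c("ap", "ml", "pd")
  out
}

#' Normalize a CG trajectory by leg length
#'
#' Elementwise division by the subject's leg length; the raw millimetre
#' trajectory is retained as the `"raw_mm"` attribute for metric reporting.
#'
#' @param cg frames x 3 matrix in mm.
#' @param leg_length leg length in mm (> 0).
#' @return dimensionless frames x 3 matrix with attribute `raw_mm`.
#' @export
normalize_cg_by_leg_length <- function(cg, leg_length) {
  if (leg_length <= 0) stop("leg length must be positive")
  out <- cg / leg_length
  attr(out, "raw_mm") <- cg
  out
}

#' Preprocessing configuration
#'
#' @param sample_rate_hz raw sampling rate.
#' @param pressure_cutoff_hz lowpass cutoff for pressure channels.
#' @param cg_cutoff_hz lowpass cutoff for CG/marker channels.
#' @param filter_order Butterworth order.
#' @param n_frames frames per normalized cycle.
#' @param weight_norm `"force"` divides by `kg x 9.81` N; `"kg"` divides by
#'   mass only.
#' @return list of settings.
#' @export
preprocess_config <- function(sample_rate_hz = 100, pressure_cutoff_hz = 7,
                              cg_cutoff_hz = 10, filter_order = 4,
                              n_frames = 100,
                              weight_norm = c("force", "kg")) {
  list(sample_rate_hz = sample_rate_hz, pressure_cutoff_hz = pressure_cutoff_hz,
       cg_cutoff_hz = cg_cutoff_hz, filter_order = filter_order,
       n_frames = n_frames, weight_norm = match.arg(weight_norm))
}

#' Detect mid-stance events from the vertical CG trajectory
#'
#' Mid-stance coincides with a local maximum of the vertical CG (the pole
#' where potential and kinetic energy interchange), so the right and left
#' mid-stance frames are re-derived from the resampled vertical trajectory:
#' the argmax within each single-support window. Heel-strike and toe-off
#' frames are kept from the supplied schedule.
#'
#' @param pd vertical CG series on the normalized cycle.
#' @param events a [gait_event_schedule()] providing LTO / LHS.
#' @return an updated `gait_events` schedule.
#' @export
detect_midstance_events <- function(pd, events) {
  n <- length(pd)
  r_win <- (events$lto_frame + 2):(events$lhs_frame - 2)
  l_lo <- min(events$lhs_frame + events$lto_frame, n - 4)
  l_win <- l_lo:(n - 2)
  gait_event_schedule(events$lto_frame,
                      r_win[which.max(pd[r_win])],
                      events$lhs_frame,
                      l_win[which.max(pd[l_win])])
}

#' Preprocess one synthetic (or recorded) trial into a normalized cycle
#'
#' Runs the full preprocessing path: lowpass filtering (7 Hz pressures,
#' 10 Hz CG by default), right-heel-strike to right-heel-strike cycle
#' extraction, 100-frame time normalization, body-weight normalization of
#' pressures, local gait-frame transform of the CG (origin at the first
#' double-support midpoint, x along the walking direction) and leg-length
#' normalization.
#'
#' @param trial an `insole_trial`.
#' @param config a [preprocess_config()].
#' @return a `pressure_cycle`: list with `pressures` (100 x 18,
#'   weight-normalized), `cg` (100 x 3, leg-length-normalized, attribute
#'   `raw_mm`), `events` (normalized schedule), `profile`, `subject`.
#' @export
preprocess_trial <- function(trial, config = preprocess_config()) {
  n <- nrow(trial$pressures)
  press <- lowpass_filter(trial$pressures, config$sample_rate_hz,
                          config$pressure_cutoff_hz, config$filter_order)
  press <- pmax(press, 0)
  cg <- lowpass_filter(trial$cg_global, config$sample_rate_hz,
                       config$cg_cutoff_hz, config$filter_order)

  press <- extract_cycle(press, c(1, n + 1))
  cg <- extract_cycle(cg, c(1, n + 1))
  press <- time_normalize(press, config$n_frames)
  cg <- time_normalize(cg, config$n_frames)

  denom <- if (config$weight_norm == "force") trial$profile$weight * 9.81 else
    trial$profile$weight
  press <- press / denom

  # double-support midpoint: horizontal CG averaged over the initial
  # double-support (RHS to LTO), projected to the ground plane
  ds <- 1:max(trial$events$lto_frame, 2)
  origin <- c(mean(cg[ds, 1]), mean(cg[ds, 2]), 0)
  wd <- cg[config$n_frames, ] - cg[1, ]
  cg_local <- cg_to_local_frame(cg, origin, c(wd[1], wd[2], 0))
  cg_norm <- normalize_cg_by_leg_length(cg_local, trial$profile$leg_length)
  events <- detect_midstance_events(cg_local[, "pd"], trial$events)

  structure(list(pressures = press, cg = cg_norm, events = events,
                 profile = trial$profile,
                 subject = if (is.null(trial$subject)) NA_integer_ else trial$subject),
            class = "pressure_cycle")
}

#' Preprocess every trial of a cohort
#'
#' @param cohort an `insole_cohort`.
#' @param config a [preprocess_config()].
#' @return list of `pressure_cycle` objects (one per trial, same order as
#'   the cohort manifest).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  lapply(cohort$trials, preprocess_trial, config = config)
}
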