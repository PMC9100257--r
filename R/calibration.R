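# ---------------------------------------------------------------------------
# Piezo-resistive sensor calibration: exponential voltage-to-force law
#   force = a * exp(b * voltage) + c
# ---------------------------------------------------------------------------

#' Fit an exponential voltage-to-force calibration curve
#'
#' Least-squares fit of `force = a * exp(b * voltage) + c`. The nonlinear fit
#' is initialized by log-linear regression on the positive forces; the offset
#' `c` defaults to 0 (absorbing the sensor baseline only when requested).
#'
#' @param voltage sensor output in V.
#' @param force reference force in N (nonnegative).
#' @param sensor_id identifier stored with the curve.
#' @param fit_offset if `TRUE`, fit the additive offset `c`; otherwise `c = 0`.
#' @return a `calibration_curve`: list with `sensor_id`, `params` (a, b, c),
#'   `r` (Pearson correlation predicted vs observed), `rmse_n` (RMSE in N),
#'   `voltage_range`.
#' @export
fit_calibration <- function(voltage, force, sensor_id = "sensor",
                            fit_offset = FALSE) {
  if (length(voltage) != length(force)) stop("voltage and force lengths differ")
  if (length(voltage) < 5) stop("at least 5 calibration points are required")
  if (any(force < 0)) stop("forces must be nonnegative")

  pos <- force > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(force[pos]) ~ voltage[pos])
    a0 <- exp(stats::coef(lf)[1]); b0 <- stats::coef(lf)[2]
  } else {
    a0 <- max(force, 1e-3); b0 <- 0.1
  }
  start <- list(a = unname(a0), b = unname(b0))
  if (fit_offset) start$c <- 0

  fml <- if (fit_offset) force ~ a * exp(b * voltage) + c else
    force ~ a * exp(b * voltage)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(voltage = voltage, force = force),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  params <- c(a = unname(cf["a"]), b = unname(cf["b"]),
              c = if (fit_offset) unname(cf["c"]) else 0)
  pred <- params["a"] * exp(params["b"] * voltage) + params["c"]
  structure(list(sensor_id = sensor_id, params = params,
                 r = stats::cor(pred, force),
                 rmse_n = sqrt(mean((pred - force)^2)),
                 voltage_range = range(voltage)),
            class = "calibration_curve")
}

#' Apply a calibration curve to a voltage series
#'
#' Elementwise application of the fitted exponential law; negative outputs
#' are clamped to 0. Voltages outside the calibrated range (plus the
#' extrapolation margin) trigger a warning but are still converted.
#'
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param voltage voltage series.
#' @param extrapolation_margin allowed excursion beyond the calibrated
#'   voltage range, as a fraction of that range.
#' @return force series in N, all values >= 0.
#' @export
apply_calibration <- function(curve, voltage, extrapolation_margin = 0.1) {
  if (!inherits(curve, "calibration_curve")) stop("curve must be a calibration_curve")
  rng <- curve$voltage_range
  margin <- extrapolation_margin * diff(rng)
  if (any(voltage < rng[1] - margin | voltage > rng[2] + margin))
    warning("voltages outside the calibrated range; extrapolating")
  p <- curve$params
  pmax(p["a"] * exp(p["b"] * voltage) + p["c"], 0)
}

#' Write calibration curves to CSV
#' @param curves list of `calibration_curve` objects.
#' @param path output CSV path.
#' @export
write_calibration <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(sensor_id = cv$sensor_id, a = cv$params["a"], b = cv$params["b"],
               c = cv$params["c"], r = cv$r, rmse_n = cv$rmse_n,
               v_min = cv$voltage_range[1], v_max = cv$voltage_range[2])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read calibration curves written by [write_calibration()]
#' @param path CSV path.
#' @return list of `calibration_curve` objects.
#' @export
read_calibration <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) structure(
    list(sensor_id = df$sensor_id[i],
         params = c(a = df$a[i], b = df$b[i], c = df$c[i]),
         r = df$r[i], rmse_n = df$rmse_n[i],
         voltage_range = c(df$v_min[i], df$v_max[i])),
    class = "calibration_curve"))
}
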