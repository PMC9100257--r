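# ---------------------------------------------------------------------------
# Per-frame insole parameters: 9 sensor pressures, three zone sums, total
# force and 2-D centre of pressure per foot -- 15 channels per foot, 30 in
# total (left foot first, then right).
# ---------------------------------------------------------------------------

#' Default insole sensor layout
#'
#' Nominal adult-foot coordinates (mm, x anterior from the heel, y medial)
#' for the 9 sensors of each insole: two heel sensors (rear zone), two
#' midfoot sensors (mid zone) and five forefoot/hallux sensors (front zone).
#' The left foot mirrors the right in y.
#'
#' @return data.frame with columns `foot` ("L"/"R"), `sensor_id` (1-9),
#'   `x_mm`, `y_mm`, `zone` ("rear"/"mid"/"front").
#' @export
default_sensor_layout <- function() {
  right <- data.frame(
    foot = "R", sensor_id = 1:9,
    x_mm = c(25, 35, 110, 120, 175, 180, 185, 190, 230),
    y_mm = c(-10, 12, -25, 20, -35, -15, 5, 25, 15),
    zone = c("rear", "rear", "mid", "mid",
             "front", "front", "front", "front", "front"))
  left <- right
  left$foot <- "L"
  left$y_mm <- -left$y_mm
  rbind(left, right)
}

#' Read / write a sensor layout CSV
#'
#' @param path CSV with columns foot, sensor_id, x_mm, y_mm, zone.
#' @return data.frame layout.
#' @export
read_sensor_layout <- function(path) {
  layout <- read.csv(path, stringsAsFactors = FALSE)
  validate_layout(layout)
  layout
}

#' @rdname read_sensor_layout
#' @param layout a layout data.frame.
#' @export
write_sensor_layout <- function(layout, path) {
  validate_layout(layout)
  write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

validate_layout <- function(layout) {
  need <- c("foot", "sensor_id", "x_mm", "y_mm", "zone")
  if (!all(need %in% names(layout))) stop("layout must have columns: ",
                                          paste(need, collapse = ", "))
  for (ft in c("L", "R")) {
    sub <- layout[layout$foot == ft, ]
    if (nrow(sub) != 9) stop("layout must have 9 sensors per foot")
    if (!setequal(sub$sensor_id, 1:9)) stop("sensor ids must be 1..9 per foot")
    if (!all(c("rear", "mid", "front") %in% sub$zone))
      stop("every zone must contain at least one sensor")
  }
  invisible(layout)
}

#' Centre of pressure of one foot
#'
#' Pressure-weighted mean of the sensor positions at each frame. Frames
#' whose total pressure falls below `eps` (swing) hold the last valid COP;
#' leading invalid frames are back-filled from the first valid one, so the
#' series has no load-dependent discontinuities.
#'
#' @param foot_pressures frames x 9 matrix (columns = sensors 1-9).
#' @param layout layout rows for this foot (or a full layout plus `foot`).
#' @param foot `"L"` or `"R"` when `layout` covers both feet.
#' @param eps total-pressure floor below which the COP is held. With
#'   weight-normalized pressures the default 1e-3 is 0.1% of body-weight
#'   force.
#' @return frames x 2 matrix, columns `cop_x`, `cop_y` (mm).
#' @export
compute_cop <- function(foot_pressures, layout = default_sensor_layout(),
                        foot = NULL, eps = 1e-3) {
  if (!is.null(foot)) layout <- layout[layout$foot == foot, ]
  layout <- layout[order(layout$sensor_id), ]
  if (nrow(layout) != 9 || ncol(foot_pressures) != 9)
    stop("layout must cover the 9 pressure channels")
  total <- rowSums(foot_pressures)
  if (all(total < eps)) stop("all frames unloaded: COP undefined for this cycle")
  cx <- as.vector(foot_pressures %*% layout$x_mm) / total
  cy <- as.vector(foot_pressures %*% layout$y_mm) / total
  valid <- total >= eps
  cx[!valid] <- NA; cy[!valid] <- NA
  first <- which(valid)[1]
  if (first > 1) { cx[1:(first - 1)] <- cx[first]; cy[1:(first - 1)] <- cy[first] }
  # hold last valid value through unloaded frames
  for (i in seq_along(cx)[-1]) {
    if (is.na(cx[i])) { cx[i] <- cx[i - 1]; cy[i] <- cy[i - 1] }
  }
  cbind(cop_x = cx, cop_y = cy)
}

#' Names of the 30 insole parameters
#'
#' Left-foot channels first (9 sensors, rear/mid/front zone sums, total,
#' COP x, COP y), then the same 15 for the right foot.
#' @return character vector of length 30.
#' @export
parameter_names <- function() {
  one <- function(ft) c(paste0(ft, "_s", 1:9), paste0(ft, "_rear"),
                        paste0(ft, "_mid"), paste0(ft, "_front"),
                        paste0(ft, "_total"), paste0(ft, "_copx"),
                        paste0(ft, "_copy"))
  c(one("L"), one("R"))
}

#' Compute the 30 per-frame insole parameters of a cycle
#'
#' For each foot: the 9 sensor pressures, the rear-, mid- and front-zone
#' sums, the total sum, and the COP x/y coordinates.
#'
#' @param cycle a `pressure_cycle` (or a frames x 18 matrix with columns
#'   L1..L9, R1..R9).
#' @param layout sensor layout (both feet).
#' @param cop_eps swing floor passed to [compute_cop()].
#' @return a `parameter_series`: frames x 30 matrix with the names of
#'   [parameter_names()].
#' @export
compute_parameters <- function(cycle, layout = default_sensor_layout(),
                               cop_eps = 1e-3) {
  press <- if (inherits(cycle, "pressure_cycle")) cycle$pressures else cycle
  if (ncol(press) != 18) stop("expected 18 pressure channels")
  validate_layout(layout)
  out <- NULL
  for (ft in c("L", "R")) {
    fp <- press[, paste0(ft, 1:9), drop = FALSE]
    lt <- layout[layout$foot == ft, ]
    lt <- lt[order(lt$sensor_id), ]
    zones <- sapply(c("rear", "mid", "front"), function(z) {
      idx <- lt$sensor_id[lt$zone == z]
      rowSums(fp[, idx, drop = FALSE])
    })
    cop <- compute_cop(fp, lt, eps = cop_eps)
    out <- cbind(out, fp, zones, rowSums(fp), cop)
  }
  colnames(out) <- parameter_names()
  class(out) <- c("parameter_series", class(out))
  out
}
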