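#' @useDynLib insoleCG, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cor predict quantile rnorm runif sd spline t.test var
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Synthetic gait generator
#
# Emulates the paired insole-pressure / center-of-gravity recordings the
# estimation protocol consumes: per-sensor stance activations timed by gait
# events, a 3-axis CG trajectory phase-locked to those events (double-bump
# vertical, single-oscillation medial/lateral, monotone anterior/posterior),
# weight-scaled pressures, and young-vs-old differences in CG sway amplitude.
# ---------------------------------------------------------------------------

#' Gait event schedule on the 100-frame normalized cycle
#'
#' Events are expressed as frame counts on the normalized cycle, with right
#' heel strike (RHS) fixed at 0 and the cycle end at 100. Frame f of the
#' 1-based 100-frame cycle covers normalized time `[f-1, f)`.
#'
#' @param lto_frame left toe-off.
#' @param r_midstance_frame right mid-stance (vertical-CG peak of the first
#'   stance).
#' @param lhs_frame left heel strike.
#' @param l_midstance_frame left mid-stance.
#' @return object of class `gait_events`.
#' @export
gait_event_schedule <- function(lto_frame = 12, r_midstance_frame = 30,
                                lhs_frame = 50, l_midstance_frame = 80) {
  ev <- list(rhs_frame = 0L, lto_frame = as.integer(lto_frame),
             r_midstance_frame = as.integer(r_midstance_frame),
             lhs_frame = as.integer(lhs_frame),
             l_midstance_frame = as.integer(l_midstance_frame),
             cycle_end = 100L)
  ord <- c(0L, ev$lto_frame, ev$r_midstance_frame, ev$lhs_frame,
           ev$l_midstance_frame, 100L)
  if (any(diff(ord) <= 0))
    stop("gait events must satisfy 0 < LTO < R mid-stance < LHS < L mid-stance < 100")
  structure(ev, class = "gait_events")
}

#' Subject profile for the synthetic generator
#'
#' Group defaults reproduce the study populations: young adults
#' (weight 69.59 kg, medial/lateral CG peak-to-valley 45.25 mm,
#' proximal/distal 41.36 mm) and elderly adults (65.76 kg, 64.32 mm,
#' 46.84 mm), walking at 1.41 m/s.
#'
#' @param group `"young"` or `"old"`.
#' @param weight body mass in kg.
#' @param leg_length leg length in mm.
#' @param ml_pv_amplitude medial/lateral CG peak-to-valley range in mm.
#' @param pd_pv_amplitude proximal/distal CG peak-to-valley range in mm.
#' @param walking_speed m/s.
#' @param seed integer identifier used to derive per-trial randomness.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(group = c("young", "old"),
                            weight = NULL, leg_length = NULL,
                            ml_pv_amplitude = NULL, pd_pv_amplitude = NULL,
                            walking_speed = NULL, seed = 1L) {
  group <- match.arg(group)
  d <- group_defaults()[[group]]
  p <- list(group = group,
            weight = if (is.null(weight)) d$weight else weight,
            leg_length = if (is.null(leg_length)) d$leg_length else leg_length,
            ml_pv_amplitude = if (is.null(ml_pv_amplitude)) d$ml else ml_pv_amplitude,
            pd_pv_amplitude = if (is.null(pd_pv_amplitude)) d$pd else pd_pv_amplitude,
            walking_speed = if (is.null(walking_speed)) d$speed else walking_speed,
            seed = as.integer(seed))
  with(p, {
    if (weight <= 0 || leg_length <= 0 || ml_pv_amplitude <= 0 ||
        pd_pv_amplitude <= 0 || walking_speed <= 0)
      stop("subject profile values must be positive")
  })
  structure(p, class = "subject_profile")
}

# Population means and standard deviations behind the group defaults.
group_defaults <- function() {
  list(
    young = list(weight = 69.59, weight_sd = 6.13,
                 leg_length = 913, leg_length_sd = 36,
                 ml = 45.25, ml_sd = 2.53, pd = 41.36, pd_sd = 2.11,
                 speed = 1.41, speed_sd = 0.05),
    old = list(weight = 65.76, weight_sd = 5.86,
               leg_length = 892, leg_length_sd = 30,
               ml = 64.32, ml_sd = 2.87, pd = 46.84, pd_sd = 2.72,
               speed = 1.41, speed_sd = 0.05)
  )
}

# Piecewise half-cosine interpolation through knots: smooth (zero slope at
# every knot) and strictly monotone within each segment, so local extrema
# occur exactly at the knots.
cosine_knot_curve <- function(t, knots_t, knots_v) {
  v <- numeric(length(t))
  for (i in seq_len(length(knots_t) - 1L)) {
    t1 <- knots_t[i]; t2 <- knots_t[i + 1L]
    idx <- which(t >= t1 & (t < t2 | (i == length(knots_t) - 1L & t <= t2)))
    if (!length(idx)) next
    u <- (t[idx] - t1) / (t2 - t1)
    v[idx] <- knots_v[i] + (knots_v[i + 1L] - knots_v[i]) * (1 - cos(pi * u)) / 2
  }
  v
}

# Nominal per-sensor activation timing within stance (fraction of stance
# duration) and relative amplitude. Sensors 1-2 heel, 3-4 midfoot, 5-8
# forefoot, 9 hallux: heel earliest, hallux latest.
sensor_activation_table <- function() {
  data.frame(
    sensor = 1:9,
    zone = c("rear", "rear", "mid", "mid", "front", "front", "front", "front", "front"),
    center = c(0.18, 0.22, 0.42, 0.48, 0.66, 0.70, 0.74, 0.78, 0.86),
    width = c(0.16, 0.16, 0.20, 0.20, 0.16, 0.16, 0.16, 0.16, 0.14),
    amp = c(1.00, 0.95, 0.50, 0.55, 0.80, 0.90, 0.90, 0.80, 0.70)
  )
}

# Smooth unimodal per-sensor envelopes over stance-relative time u in [0,1];
# tapered to zero at both stance edges so swing frames are exactly zero.
stance_envelopes <- function(u) {
  act <- sensor_activation_table()
  inside <- u >= 0 & u <= 1
  env <- matrix(0, nrow = length(u), ncol = 9)
  taper <- ifelse(inside, sqrt(pmax(4 * u * (1 - u), 0)), 0)
  for (s in 1:9) {
    g <- exp(-0.5 * ((u - act$center[s]) / act$width[s])^2)
    env[, s] <- act$amp[s] * g * taper
  }
  env
}

#' Generate one synthetic gait trial
#'
#' Produces one raw gait cycle (right heel strike to the next right heel
#' strike) of 18-channel plantar pressure at 100 samples/s together with the
#' global-frame CG trajectory. Pressures are smooth per-sensor stance
#' activations (heel sensors early stance, forefoot late stance) scaled so
#' the summed peak force is about 1.1 x body-weight force; the vertical CG
#' has exactly two local maxima per cycle at the two mid-stance events, the
#' medial/lateral CG is a single oscillation with the profile's peak-to-valley
#' range, and the anterior/posterior CG increases monotonically.
#'
#' @param profile a [subject_profile()].
#' @param trial_seed integer seed for this trial's randomness.
#' @param n_raw_frames number of raw samples in the cycle; default derived
#'   from a random cycle duration of 1.0-1.2 s at 100 samples/s.
#' @param noise_scale multiplier on all noise sources (0 = noise free).
#' @param pressure_noise_frac sd of the signal-proportional Gaussian pressure
#'   noise, as a fraction of the instantaneous pressure.
#' @param cg_noise_mm sd of white Gaussian marker noise on each CG axis (mm).
#' @param cg_drift_mm amplitude of a smooth low-frequency CG drift (mm).
#' @param event_jitter maximum absolute integer jitter applied to each
#'   interior gait event on the normalized cycle.
#' @return an `insole_trial`: list with `pressures` (frames x 18, N, columns
#'   L1..L9 then R1..R9), `cg_global` (frames x 3 mm, columns x = walking
#'   direction, y = left, z = up), `events`, `profile`, `sample_rate_hz`.
#' @export
generate_trial <- function(profile, trial_seed = 1L, n_raw_frames = NULL,
                           noise_scale = 1, pressure_noise_frac = 0.02,
                           cg_noise_mm = 0.3, cg_drift_mm = 0.5,
                           event_jitter = 3L) {
  if (!inherits(profile, "subject_profile")) stop("profile must be a subject_profile")
  set.seed(as.integer(trial_seed))

  jit <- function(x) x + sample(seq(-event_jitter, event_jitter), 1L)
  events <- gait_event_schedule(jit(12), jit(30), jit(50), jit(80))

  duration <- runif(1, 1.0, 1.2)
  if (is.null(n_raw_frames)) n_raw_frames <- as.integer(round(100 * duration))
  if (n_raw_frames < 50) stop("n_raw_frames must be at least 50")
  n <- n_raw_frames
  s <- (seq_len(n) - 1) / n * 100       # normalized cycle position, [0, 100)
  tsec <- (seq_len(n) - 1) / 100

  # --- CG trajectory (global frame, mm) -----------------------------------
  ap <- profile$walking_speed * 1000 * duration * (s / 100) +
    5 * sin(2 * pi * 2 * s / 100)
  ml <- cosine_knot_curve(s, c(0, events$r_midstance_frame,
                               events$l_midstance_frame, 100),
                          c(0, -profile$ml_pv_amplitude / 2,
                            profile$ml_pv_amplitude / 2, 0))
  z0 <- profile$leg_length
  pd <- cosine_knot_curve(s, c(0, events$r_midstance_frame, events$lhs_frame,
                               events$l_midstance_frame, 100),
                          c(z0, z0 + profile$pd_pv_amplitude, z0,
                            z0 + profile$pd_pv_amplitude, z0))
  cg <- cbind(x = ap, y = ml, z = pd)

  # --- plantar pressures ---------------------------------------------------
  # Stance-relative time is anchored to the trial's events (mid-stance at
  # canonical stance fraction 0.45), so midfoot loading peaks at the actual
  # mid-stance: the sequencing heel strike -> mid-stance -> push-off stays
  # identifiable from the pressures alone.
  rto <- min(events$lhs_frame + events$lto_frame, 96)
  u_right <- approx(c(0, events$r_midstance_frame, rto), c(0, 0.45, 1),
                    xout = s, rule = 2)$y               # right stance [0, rto]
  left_start <- events$lhs_frame
  left_end <- 100 + events$lto_frame                    # wraps past cycle end
  s_left <- ifelse(s < events$lhs_frame, s + 100, s)
  u_left <- approx(c(left_start, events$l_midstance_frame, left_end),
                   c(0, 0.45, 1), xout = s_left, rule = 2)$y

  right <- stance_envelopes(u_right)
  left <- stance_envelopes(u_left)
  press <- cbind(left, right)
  total <- rowSums(press)
  scale <- 1.1 * profile$weight * 9.81 / max(total)
  press <- press * scale

  if (noise_scale > 0) {
    noise <- matrix(rnorm(length(press)), nrow = n) *
      (noise_scale * pressure_noise_frac * press)
    press <- pmax(press + noise, 0)
    drift_f <- runif(3, 0.5, 1.5)
    drift_ph <- runif(3, 0, 2 * pi)
    drift <- sapply(1:3, function(a)
      noise_scale * cg_drift_mm * sin(2 * pi * drift_f[a] * tsec + drift_ph[a]))
    cg <- cg + drift + matrix(rnorm(length(cg), sd = noise_scale * cg_noise_mm),
                              nrow = n)
  }

  colnames(press) <- c(paste0("L", 1:9), paste0("R", 1:9))
  structure(list(pressures = press, cg_global = cg, events = events,
                 profile = profile, sample_rate_hz = 100,
                 duration_s = duration, trial_seed = as.integer(trial_seed)),
            class = "insole_trial")
}

#' Generate a synthetic cohort
#'
#' Draws subject profiles from the group default distributions (young and
#' elderly means and standard deviations) and generates `trials_per_subject`
#' gait trials per subject. Deterministic given `seed`.
#'
#' @param n_young,n_old subjects per group.
#' @param trials_per_subject trials per subject.
#' @param seed master seed; all subject and trial seeds derive from it.
#' @param ... further arguments passed to [generate_trial()] (e.g.
#'   `noise_scale`).
#' @return an `insole_cohort`: list with `trials` (list of `insole_trial`)
#'   and `manifest` (data.frame: trial_id, subject, group, trial, seed).
#' @export
generate_cohort <- function(n_young = 15, n_old = 15, trials_per_subject = 3,
                            seed = 1L, ...) {
  if (n_young < 1 || n_old < 1 || trials_per_subject < 1)
    stop("all counts must be >= 1")
  set.seed(as.integer(seed))
  n_sub <- n_young + n_old
  groups <- rep(c("young", "old"), c(n_young, n_old))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_sub * trials_per_subject),
                        nrow = n_sub)
  defs <- group_defaults()
  trials <- list()
  manifest <- NULL
  for (i in seq_len(n_sub)) {
    d <- defs[[groups[i]]]
    set.seed(sub_seeds[i])
    prof <- subject_profile(
      group = groups[i],
      weight = max(rnorm(1, d$weight, d$weight_sd), 40),
      leg_length = max(rnorm(1, d$leg_length, d$leg_length_sd), 700),
      ml_pv_amplitude = max(rnorm(1, d$ml, d$ml_sd), 5),
      pd_pv_amplitude = max(rnorm(1, d$pd, d$pd_sd), 5),
      walking_speed = max(rnorm(1, d$speed, d$speed_sd), 0.5),
      seed = sub_seeds[i])
    for (k in seq_len(trials_per_subject)) {
      tr <- generate_trial(prof, trial_seed = trial_seeds[i, k], ...)
      tr$subject <- i
      trials[[length(trials) + 1L]] <- tr
      manifest <- rbind(manifest, data.frame(
        trial_id = length(trials), subject = i, group = groups[i], trial = k,
        seed = trial_seeds[i, k]))
    }
  }
  structure(list(trials = trials, manifest = manifest,
                 seed = as.integer(seed)), class = "insole_cohort")
}

#' @export
print.insole_cohort <- function(x, ...) {
  cat(sprintf("insole_cohort: %d trials, %d subjects (%d young, %d old)\n",
              length(x$trials), length(unique(x$manifest$subject)),
              length(unique(x$manifest$subject[x$manifest$group == "young"])),
              length(unique(x$manifest$subject[x$manifest$group == "old"]))))
  invisible(x)
}

# --- disk round trip -------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort to a directory of per-trial CSV files plus a JSON manifest
#'
#' Numbers are written with 17 significant digits so that
#' [read_cohort()] round-trips bit-exactly.
#'
#' @param cohort an `insole_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = cohort$seed, manifest = cohort$manifest,
               subjects = lapply(split(cohort$manifest, cohort$manifest$subject),
                                 function(m) {
                                   tr <- cohort$trials[[m$trial_id[1]]]
                                   p <- tr$profile
                                   list(subject = m$subject[1], group = p$group,
                                        weight = fmt_num(p$weight),
                                        leg_length = fmt_num(p$leg_length),
                                        ml_pv_amplitude = fmt_num(p$ml_pv_amplitude),
                                        pd_pv_amplitude = fmt_num(p$pd_pv_amplitude),
                                        walking_speed = fmt_num(p$walking_speed),
                                        seed = p$seed)
                                 }),
               events = lapply(cohort$trials, function(tr) unclass(tr$events)),
               duration_s = fmt_num(vapply(cohort$trials, function(tr)
                 tr$duration_s, numeric(1))),
               trial_seed = vapply(cohort$trials, function(tr) tr$trial_seed,
                                   integer(1)))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    df <- data.frame(frame = seq_len(nrow(tr$pressures)))
    for (j in colnames(tr$pressures)) df[[j]] <- fmt_num(tr$pressures[, j])
    for (j in colnames(tr$cg_global)) df[[paste0("cg_", j)]] <-
        fmt_num(tr$cg_global[, j])
    write.csv(df, file.path(dir, sprintf("trial_%04d.csv", i)),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json` and `trial_*.csv`.
#' @return an `insole_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  manifest <- as.data.frame(meta$manifest)
  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    df <- read.csv(file.path(dir, sprintf("trial_%04d.csv", i)))
    press <- as.matrix(df[, c(paste0("L", 1:9), paste0("R", 1:9))])
    cg <- as.matrix(df[, c("cg_x", "cg_y", "cg_z")])
    colnames(cg) <- c("x", "y", "z")
    sub <- meta$subjects[[as.character(manifest$subject[i])]]
    prof <- subject_profile(group = sub$group,
                            weight = as.numeric(sub$weight),
                            leg_length = as.numeric(sub$leg_length),
                            ml_pv_amplitude = as.numeric(sub$ml_pv_amplitude),
                            pd_pv_amplitude = as.numeric(sub$pd_pv_amplitude),
                            walking_speed = as.numeric(sub$walking_speed),
                            seed = sub$seed)
    ev <- if (is.data.frame(meta$events)) as.list(meta$events[i, ]) else
      meta$events[[i]]
    trials[[i]] <- structure(
      list(pressures = press, cg_global = cg,
           events = gait_event_schedule(ev$lto_frame, ev$r_midstance_frame,
                                        ev$lhs_frame, ev$l_midstance_frame),
           profile = prof, sample_rate_hz = 100,
           duration_s = as.numeric(meta$duration_s)[i],
           trial_seed = meta$trial_seed[i], subject = manifest$subject[i]),
      class = "insole_trial")
  }
  structure(list(trials = trials, manifest = manifest, seed = meta$seed),
            class = "insole_cohort")
}
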