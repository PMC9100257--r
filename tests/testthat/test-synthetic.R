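test_that("event schedules validate their ordering", {
  ev <- gait_event_schedule()
  expect_s3_class(ev, "gait_events")
  expect_error(gait_event_schedule(lto_frame = 40, r_midstance_frame = 30),
               "gait events")
})

test_that("generated trials honour the configured CG geometry", {
  prof <- subject_profile("young", seed = 7)
  tr <- generate_trial(prof, trial_seed = 3, noise_scale = 0)

  # ML peak-to-valley matches the configured amplitude before noise
  ml_pv <- diff(range(tr$cg_global[, "y"]))
  expect_lt(abs(ml_pv - 45.25) / 45.25, 0.10)

  # anterior trajectory is monotone increasing
  expect_true(all(diff(tr$cg_global[, "x"]) > 0))

  # pressures nonnegative, summed peak force about 1.1 x body weight
  expect_true(all(tr$pressures >= 0))
  expect_equal(max(rowSums(tr$pressures)), 1.1 * prof$weight * 9.81,
               tolerance = 1e-10)
})

test_that("noise-free vertical CG has exactly two maxima at the mid-stances", {
  prof <- subject_profile("old", seed = 21)
  tr <- generate_trial(prof, trial_seed = 9, noise_scale = 0)
  cy <- preprocess_trial(tr)
  z <- attr(cy$cg, "raw_mm")[, "pd"]
  # brute-force scan for interior local maxima
  locmax <- which(diff(sign(diff(z))) == -2) + 1
  expect_length(locmax, 2)
  expect_equal(locmax, c(cy$events$r_midstance_frame, cy$events$l_midstance_frame))
  # detected mid-stances stay close to the scheduled events
  expect_lte(abs(cy$events$r_midstance_frame - tr$events$r_midstance_frame), 2)
  expect_lte(abs(cy$events$l_midstance_frame - tr$events$l_midstance_frame), 2)
})

test_that("trials are deterministic given the seed", {
  prof <- subject_profile("young", seed = 1)
  a <- generate_trial(prof, trial_seed = 5, noise_scale = 0)
  b <- generate_trial(prof, trial_seed = 5, noise_scale = 0)
  expect_identical(a, b)
  a2 <- generate_trial(prof, trial_seed = 5)
  b2 <- generate_trial(prof, trial_seed = 5)
  expect_identical(a2, b2)
})

test_that("swing-phase channels stay below 1% of the peak pressure", {
  for (seed in 1:5) {
    tr <- generate_trial(subject_profile("young", seed = seed),
                         trial_seed = seed)
    n <- nrow(tr$pressures)
    s <- (seq_len(n) - 1) / n * 100
    rto <- min(tr$events$lhs_frame + tr$events$lto_frame, 96)
    peak <- max(tr$pressures)
    right_swing <- s > rto + 1
    expect_lt(max(tr$pressures[right_swing, paste0("R", 1:9)]), 0.01 * peak)
    left_swing <- s > tr$events$lto_frame + 1 & s < tr$events$lhs_frame - 1
    expect_lt(max(tr$pressures[left_swing, paste0("L", 1:9)]), 0.01 * peak)
  }
})

test_that("cohort generation counts and group structure are exact", {
  cohort <- generate_cohort(15, 15, 3, seed = 1, noise_scale = 0)
  expect_length(cohort$trials, 90)
  expect_equal(sum(cohort$manifest$group == "young"), 45)
  expect_equal(sum(cohort$manifest$group == "old"), 45)

  c2 <- generate_cohort(13, 13, 3, seed = 2, noise_scale = 0)
  expect_length(c2$trials, 78)

  # deterministic given seed
  c3 <- generate_cohort(13, 13, 3, seed = 2, noise_scale = 0)
  expect_identical(c2$trials[[40]], c3$trials[[40]])
})

test_that("group ML sway difference matches the configured defaults", {
  cohort <- generate_cohort(15, 15, 3, seed = 8, noise_scale = 0)
  pv <- vapply(cohort$trials, function(tr) diff(range(tr$cg_global[, "y"])),
               numeric(1))
  young <- pv[cohort$manifest$group == "young"]
  old <- pv[cohort$manifest$group == "old"]
  # configured means differ by 64.32 - 45.25 = 19.07 mm
  expect_equal(mean(old) - mean(young), 19.07, tolerance = 0.2)
  expect_lt(t.test(old, young)$p.value, 0.05)
})

test_that("cohorts round-trip bit-exactly through the CSV + manifest format", {
  cohort <- generate_cohort(2, 2, 2, seed = 5)
  dir <- tempfile("cohort_")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back$trials, length(cohort$trials))
  for (i in seq_along(cohort$trials)) {
    expect_identical(back$trials[[i]]$pressures, cohort$trials[[i]]$pressures)
    expect_identical(back$trials[[i]]$cg_global, cohort$trials[[i]]$cg_global)
    expect_identical(unclass(back$trials[[i]]$events),
                     unclass(cohort$trials[[i]]$events))
  }
  unlink(dir, recursive = TRUE)
})

test_that("invalid profiles and counts are rejected", {
  expect_error(subject_profile("young", weight = -1), "positive")
  expect_error(generate_cohort(0, 1, 1), ">= 1")
  expect_error(generate_trial(subject_profile("young"), 1, n_raw_frames = 20),
               "at least 50")
})
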