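test_that("the zero-phase lowpass passes DC and low frequencies, blocks high", {
  # DC
  x <- rep(5, 100)
  expect_equal(lowpass_filter(x, 100, 7), x, tolerance = 1e-8)

  tt <- (0:499) / 100
  low <- sin(2 * pi * 1 * tt)
  out <- lowpass_filter(low, 100, 7)
  mid <- 100:400
  expect_lt(abs(max(abs(out[mid])) - 1), 0.01)

  high <- sin(2 * pi * 30 * tt)
  out_h <- lowpass_filter(high, 100, 7)
  expect_lt(max(abs(out_h[mid])), 0.05)

  expect_error(lowpass_filter(low, 100, 60), "Nyquist")
})

test_that("cycle extraction is half-open and tiles the recording", {
  x <- matrix(seq_len(240), ncol = 2)
  seg <- extract_cycle(x, c(1, 101))
  expect_equal(nrow(seg), 100)
  expect_equal(seg, x[1:100, ])
  expect_equal(nrow(extract_cycle(x, c(11, 21))), 10)
  # consecutive cycles reconstruct the original span
  joined <- rbind(extract_cycle(x, c(1, 41)), extract_cycle(x, c(41, 93)),
                  extract_cycle(x, c(93, 121)))
  expect_identical(joined, x[1:120, ])
  expect_error(extract_cycle(x, c(50, 40)), "after the first")
})

test_that("time normalization yields exactly 100 frames with preserved endpoints", {
  x <- seq(0, 1, length.out = 113)
  out <- time_normalize(x)
  expect_length(out, 100)
  expect_equal(out[c(1, 100)], c(0, 1))
  # a linear ramp stays linear under linear interpolation
  expect_lt(max(abs(out - seq(0, 1, length.out = 100))), 1e-9)

  # identity when the length already matches
  y <- rnorm(100)
  expect_equal(time_normalize(y), y)

  for (n in c(87, 104, 131)) {
    m <- matrix(rnorm(2 * n), ncol = 2)
    tn <- time_normalize(m)
    expect_equal(nrow(tn), 100)
    expect_equal(tn[1, ], m[1, ])
    expect_equal(tn[100, ], m[n, ])
  }
  expect_error(time_normalize(1), "2 frames")
})

test_that("weight normalization divides by body-weight force", {
  w <- 70
  expect_equal(normalize_pressure_by_weight(matrix(w * 9.81), w), matrix(1))
  expect_equal(normalize_pressure_by_weight(matrix(0, 2, 2), w),
               matrix(0, 2, 2))
  m <- matrix(runif(10), 5)
  expect_equal(normalize_pressure_by_weight(m, 2 * w),
               normalize_pressure_by_weight(m, w) / 2)
  expect_error(normalize_pressure_by_weight(m, 0), "positive")
})

test_that("the local gait frame is orthonormal and correctly placed", {
  org <- c(10, 20, 0)
  expect_equal(as.vector(cg_to_local_frame(matrix(org, 1), org, c(1, 0, 0))),
               c(0, 0, 0))
  expect_equal(as.vector(cg_to_local_frame(matrix(org + c(1, 0, 0), 1), org,
                                           c(1, 0, 0))),
               c(1, 0, 0))
  # right-handed: walking +x, vertical +z gives y pointing left (+y global)
  expect_equal(as.vector(cg_to_local_frame(matrix(org + c(0, 2, 0), 1), org,
                                           c(1, 0, 0))),
               c(0, 2, 0))
  # translating the input equals translating through the rotation only
  set.seed(2)
  cg <- matrix(rnorm(30), 10, 3)
  shift <- c(5, -3, 2)
  a <- cg_to_local_frame(cg + rep(shift, each = 10), org, c(1, 1, 0))
  b <- cg_to_local_frame(cg, org - shift, c(1, 1, 0))
  expect_equal(a, b)
  expect_error(cg_to_local_frame(cg, org, c(0, 0, 1)), "parallel")
})

test_that("leg-length normalization is exact and keeps the raw trajectory", {
  cg <- matrix(c(900, 0, 450), 1)
  out <- normalize_cg_by_leg_length(cg, 900)
  expect_equal(as.vector(out), c(1, 0, 0.5))
  expect_equal(attr(out, "raw_mm"), cg)
  expect_error(normalize_cg_by_leg_length(cg, -1), "positive")
})

test_that("preprocessing a noise-free trial barely changes the CG excursions", {
  tr <- generate_trial(subject_profile("young", seed = 31), trial_seed = 4,
                       noise_scale = 0)
  cy <- preprocess_trial(tr)
  raw <- attr(cy$cg, "raw_mm")
  for (axis in c("ml", "pd")) {
    pv_in <- diff(range(tr$cg_global[, if (axis == "ml") "y" else "z"]))
    pv_out <- diff(range(raw[, axis]))
    expect_lt(abs(pv_out - pv_in) / pv_in, 0.02)
  }
  # deterministic
  expect_identical(preprocess_trial(tr)$pressures, cy$pressures)
})
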