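test_that("window statistics of a constant series take their degenerate values", {
  x <- matrix(3, 60, 1, dimnames = list(NULL, "p1"))
  fm <- extract_window_features(x)
  expect_equal(unique(fm[, "p1.avg"]), 3)
  expect_equal(unique(fm[, "p1.max"]), 3)
  expect_equal(unique(fm[, "p1.min"]), 3)
  expect_equal(unique(fm[, "p1.raw"]), 3)
  expect_equal(unique(fm[, "p1.range"]), 0)
  expect_equal(unique(fm[, "p1.mad"]), 0)
  expect_equal(unique(fm[, "p1.kurt"]), 0)
  expect_equal(unique(fm[, "p1.skew"]), 0)
})

test_that("a 30-parameter cycle yields exactly 240 candidates", {
  fm <- extract_window_features(clean_cycles()[[1]]$x)
  expect_equal(ncol(fm), 240)
  expect_equal(nrow(fm), 100)
  expect_equal(sum(grepl("\\.raw$", colnames(fm))), 30)
})

test_that("every windowed statistic matches a brute-force recomputation", {
  set.seed(11)
  x <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  fm <- extract_window_features(x, window = 5)
  for (t in c(1, 3, 50, 100)) {
    w <- x[pmax((t - 4):t, 1), "b"]
    mu <- mean(w)
    m2 <- mean((w - mu)^2)
    expect_equal(unname(fm[t, "b.avg"]), mu)
    expect_equal(unname(fm[t, "b.max"]), max(w))
    expect_equal(unname(fm[t, "b.min"]), min(w))
    expect_equal(unname(fm[t, "b.range"]), max(w) - min(w))
    expect_equal(unname(fm[t, "b.mad"]), mean(abs(w - mu)))
    if (m2 > 0) {
      expect_equal(unname(fm[t, "b.kurt"]), mean((w - mu)^4) / m2^2 - 3)
      expect_equal(unname(fm[t, "b.skew"]), mean((w - mu)^3) / m2^1.5)
    } else {
      # degenerate (replicated) window convention
      expect_equal(unname(fm[t, "b.kurt"]), 0)
      expect_equal(unname(fm[t, "b.skew"]), 0)
    }
    expect_equal(unname(fm[t, "b.raw"]), unname(x[t, "b"]))
  }
  expect_error(extract_window_features(x, window = 1), "at least 2")
})

test_that("the MI estimator evaluates the discrete formula exactly", {
  # symmetric 2x2 joint table with p(0,0) = p(1,1) = 0.5 -> exactly 1 bit
  x <- rep(c(0, 1), 50)
  mi <- mutual_information(x, x, n_bins = 2)
  expect_equal(mi$mi, 1)
  expect_equal(sum(mi$joint), 1)
  expect_equal(sum(mi$px), 1)

  # y = x gives the entropy of the binned variable
  set.seed(4)
  z <- rnorm(200)
  mi2 <- mutual_information(z, z, n_bins = 10)
  h <- -sum(mi2$px * log2(mi2$px))
  expect_equal(mi2$mi, h)

  # independence: permuted pairing at n = 10,000 is close to zero
  set.seed(8)
  a <- rnorm(10000)
  b <- sample(rnorm(10000))
  expect_lt(mutual_information(a, b, 10)$mi, 0.05)

  expect_warning(mutual_information(rep(1, 50), rnorm(50)), "degenerate")
  expect_error(mutual_information(1:5, 1:6), "lengths differ")
})

test_that("MI and the ranking are invariant to affine candidate rescaling", {
  set.seed(6)
  x <- rnorm(300)
  y <- x + rnorm(300, sd = 0.5)
  expect_equal(mutual_information(x, y, 10)$mi,
               mutual_information(5 * x - 2, y, 10)$mi)
})

test_that("per-phase ranking scores are scaled and a planted copy wins", {
  set.seed(13)
  n <- 400
  phases <- rep(1:4, each = n / 4)
  cg <- cbind(ap = cumsum(runif(n)), ml = sin(seq_len(n) / 20),
              pd = cos(seq_len(n) / 15))
  feats <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
  feats[, 3] <- cg[, "ap"]                 # exact copy of the AP axis
  sel <- rank_features_per_phase(feats, cg, phases, n_bins = 8)
  for (p in names(sel$phases)) {
    expect_equal(sel$phases[[p]]$ranking[1], "f3")
    expect_true(all(sel$phases[[p]]$scores >= 0 & sel$phases[[p]]$scores <= 1))
  }
  expect_error(rank_features_per_phase(feats[1:20, ], cg[1:20, ],
                                       rep(1:4, each = 5), n_bins = 10),
               "fewer frames")
})

test_that("feature-count optimization returns the argmin of its curve", {
  set.seed(21)
  n <- 600
  phases <- rep(1, n)
  mk <- function(n) {
    x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("c", 1:8)))
    # exactly 3 informative candidates
    y <- cbind(ap = x[, 1] + 0.8 * x[, 2] + 0.6 * x[, 3],
               ml = x[, 1] - x[, 2],
               pd = 0.5 * x[, 2] + x[, 3])
    list(features = x, cg = y, phases = rep(1L, n))
  }
  train <- mk(n)
  val <- mk(300)
  sel <- rank_features_per_phase(train$features, train$cg, train$phases)
  opt <- optimize_feature_count(sel, train, val, k_grid = 1:5)
  expect_gte(opt$k[["1"]], 3)
  curve <- opt$curves[["1"]]$rrmse
  expect_true(all(diff(curve[1:3]) <= 0))
  expect_equal(min(curve), curve[match(opt$k[["1"]], opt$curves[["1"]]$k)])

  # a single-candidate range is returned as-is
  opt1 <- optimize_feature_count(sel, train, val, k_grid = 4)
  expect_equal(unname(opt1$k), 4)
  expect_error(optimize_feature_count(sel, train, val, k_grid = integer(0)),
               "empty")
})

test_that("selection results persist as JSON", {
  set.seed(2)
  feats <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  cg <- cbind(ap = rnorm(100), ml = rnorm(100), pd = rnorm(100))
  sel <- rank_features_per_phase(feats, cg, rep(1:2, each = 50), n_bins = 5)
  path <- tempfile(fileext = ".json")
  write_feature_selection(sel, path = path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$ranking[[1]], sel$phases[["1"]]$ranking)
  unlink(path)
})
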