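test_that("trajectory metrics have their closed-form values", {
  set.seed(1)
  ref <- cbind(ap = cumsum(runif(100)), ml = 20 * sin(1:100 / 16),
               pd = 15 * cos(1:100 / 12))
  m <- trajectory_metrics(ref, ref)
  expect_equal(m$r, rep(1, 3))
  expect_equal(m$rmse, rep(0, 3))
  expect_equal(m$rrmse, rep(0, 3))

  shifted <- trajectory_metrics(ref + 5, ref)
  expect_equal(shifted$r, rep(1, 3))
  expect_equal(shifted$rmse, rep(5, 3))
  expect_equal(shifted$rrmse,
               unname(100 * 5 / apply(ref, 2, function(x) diff(range(x)))))

  # adopted definition: RMSE 6.485 mm on a 50 mm reference range -> 12.97%
  ref50 <- cbind(seq(0, 50, length.out = 100))
  pred <- ref50 + 6.485
  expect_equal(trajectory_metrics(pred, ref50)$rrmse, 12.97)

  # zero-range reference flags rRMSE as undefined
  flat <- cbind(rep(1, 100))
  expect_true(is.na(trajectory_metrics(flat + 1, flat)$rrmse))
})

test_that("rRMSE is invariant to leg-length normalization, RMSE scales", {
  set.seed(2)
  ref <- cbind(a = 30 * sin(1:100 / 10), b = cumsum(runif(100)), c = rnorm(100))
  pred <- ref + matrix(rnorm(300), 100)
  m_mm <- trajectory_metrics(pred, ref)
  m_norm <- trajectory_metrics(pred / 900, ref / 900)
  expect_equal(m_norm$rrmse, m_mm$rrmse)
  expect_equal(m_norm$r, m_mm$r)
  expect_equal(m_norm$rmse * 900, m_mm$rmse)
})

test_that("PV range is the global excursion", {
  t <- seq(0, 2 * pi, length.out = 200)
  expect_equal(pv_range(3.5 * sin(t)), 7, tolerance = 1e-4)
  expect_equal(pv_range(rep(2, 50)), 0)
  expect_error(pv_range(numeric(0)), "empty")
})

test_that("young-default ML trajectories reproduce the configured PV range", {
  tr <- generate_trial(subject_profile("young", seed = 2), trial_seed = 7,
                       noise_scale = 0)
  cy <- preprocess_trial(tr)
  expect_equal(pv_range(attr(cy$cg, "raw_mm")[, "ml"]), 45.25,
               tolerance = 0.05 * 45.25)
})

test_that("the group test reports direction and symmetry correctly", {
  g <- c(10, 11, 12, 10.5)
  same <- group_difference_test(g, g)
  expect_equal(same$direction, "none")
  expect_gt(same$p_value, 0.99)

  set.seed(3)
  young <- rnorm(15, 45, 2.5)
  old <- rnorm(15, 64, 2.9)
  res <- group_difference_test(young, old)
  expect_equal(res$direction, "old>young")
  expect_lt(res$p_value, 0.05)
  flipped <- group_difference_test(old, young)
  expect_equal(flipped$direction, "young>old")
  expect_equal(flipped$p_value, res$p_value)
  # degenerate variance: exact equality check
  expect_equal(group_difference_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(group_difference_test(c(1, 1), c(2, 2))$p_value, 0)
})

test_that("whole-cycle selectors behave at their degenerate settings", {
  cycles <- clean_cycles()
  pool <- list(
    features = do.call(rbind, lapply(cycles[1:4], function(c)
      extract_window_features(c$x))),
    cg = do.call(rbind, lapply(cycles[1:4], function(c) c$y)))
  # RFE with k = 240 keeps the full candidate set (the none baseline)
  expect_identical(insoleCG:::rfe_select(pool$features, pool$cg, 240),
                   colnames(pool$features))
  sel_rfe <- insoleCG:::rfe_select(pool$features, pool$cg, 12, max_frames = 200)
  expect_length(sel_rfe, 12)
  sel_mi <- insoleCG:::mi_select(pool$features, pool$cg, 15)
  expect_length(sel_mi, 15)
  sel_ela <- insoleCG:::elastic_net_select(pool$features, pool$cg, seed = 1)
  expect_gt(length(sel_ela), 0)
})

test_that("a single-method comparative run emits one report entry", {
  cohort <- generate_cohort(3, 3, 2, seed = 17)
  rep <- run_comparative_study(cohort, methods = "proposed", seed = 1,
                               epochs = 2, k_grid = c(6, 10))
  expect_named(rep$reports, "proposed")
  expect_false(rep$reports$proposed$failed)
  smry <- rep$reports$proposed$summary
  expect_true(all(c("young", "old", "pooled") %in% smry$group))
  expect_true(all(smry$rrmse_mean >= 0))
  expect_true(all(abs(smry$r_mean) <= 1))
  dir <- tempfile("eval_")
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  unlink(dir, recursive = TRUE)
})
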