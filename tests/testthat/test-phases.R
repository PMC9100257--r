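test_that("phase labels form the expected contiguous blocks", {
  ev <- gait_event_schedule(12, 30, 50, 80)
  labs <- label_phases(ev)
  expect_equal(as.vector(table(labs)), c(30, 20, 30, 20))
  expect_equal(length(unique(labs)), 4)
  # blocks are contiguous and ordered
  expect_true(all(diff(labs) >= 0))
  # phase 1 spans both the initial double support (before LTO) and single support
  expect_true(ev$lto_frame < sum(labs == 1))
  expect_true(labs[ev$lto_frame] == 1 && labs[ev$lto_frame + 2] == 1)
})

test_that("a degenerate grid fits directly and records its hyperparameters", {
  cycles <- clean_cycles()
  X <- do.call(rbind, lapply(cycles[1:4], function(c) extract_window_features(c$x)))
  y <- unlist(lapply(cycles[1:4], function(c) c$phases))
  clf <- train_phase_classifier(X, y)
  expect_equal(clf$hyperparameters$C, 1)
  expect_equal(clf$hyperparameters$kernel, "radial")
  expect_equal(clf$hyperparameters$gamma, 0.1)
  expect_error(train_phase_classifier(X, rep(1, length(y))), "single class")
})

test_that("grid search selects over subject-level folds", {
  cycles <- clean_cycles()
  X <- do.call(rbind, lapply(cycles, function(c) extract_window_features(c$x)))
  y <- unlist(lapply(cycles, function(c) c$phases))
  subj <- rep(vapply(cycles, function(c) c$subject, numeric(1)), each = 100)
  grid <- data.frame(C = c(1, 1), kernel = "radial", degree = 3,
                     gamma = c(0.1, 1e-6))
  clf <- train_phase_classifier(X, y, subjects = subj, grid = grid,
                                n_folds = 3)
  expect_equal(clf$hyperparameters$gamma, 0.1)   # the informative setting wins
  expect_false(is.na(clf$cv_accuracy))
})

test_that("classification plus repair reproduces clean labels per cycle", {
  cycles <- clean_cycles()
  X <- do.call(rbind, lapply(cycles, function(c) extract_window_features(c$x)))
  y <- unlist(lapply(cycles, function(c) c$phases))
  clf <- train_phase_classifier(X, y)
  # training cycles classify back to their ground truth (allowing the odd
  # boundary frame)
  for (i in c(1, 5)) {
    pred <- classify_phases(clf, extract_window_features(cycles[[i]]$x))
    expect_gte(mean(pred == cycles[[i]]$phases), 0.97)
    # output is always four contiguous blocks
    expect_equal(length(unique(pred)), 4)
    expect_true(all(diff(pred) >= 0))
  }
  # schema mismatch is rejected
  bad <- X[, c(2, 1, 3:240)]
  expect_error(classify_phases(clf, bad), "schema")
})

test_that("the repair pass smooths isolated flips and enforces contiguity", {
  expect_equal(majority_smooth(c(1, 1, 1, 2, 1, 1, 1), 5), rep(1, 7))
  messy <- c(rep(1, 28), 2, 1, rep(2, 18), 3, rep(3, 29), rep(4, 22))
  fixed <- insoleCG:::enforce_contiguous_phases(messy)
  expect_true(all(diff(fixed) >= 0))
  expect_equal(sort(unique(fixed)), 1:4)
  expect_error(majority_smooth(1:4, 4), "odd")
})

test_that("classification metrics match an independent tally", {
  expect_report <- phase_classification_report(rep(1:4, each = 25),
                                               rep(1:4, each = 25))
  expect_true(all(expect_report$per_class$f1 == 1))
  expect_true(all(diag(expect_report$confusion) == 25))
  expect_equal(expect_report$accuracy, 1)

  # all-wrong two-class swap
  swap <- phase_classification_report(rep(c(2, 1), 10), rep(c(1, 2), 10))
  expect_true(all(swap$per_class$precision == 0))
  expect_true(all(swap$per_class$recall == 0))

  set.seed(5)
  truth <- sample(1:4, 100, replace = TRUE)
  pred <- sample(1:4, 100, replace = TRUE)
  rep <- phase_classification_report(pred, truth)
  for (k in 1:4) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    expect_equal(rep$per_class$precision[k], if (tp + fp) tp / (tp + fp) else 0)
    expect_equal(rep$per_class$recall[k], if (tp + fn) tp / (tp + fn) else 0)
  }
})

test_that("classifiers persist with their hyperparameters", {
  cycles <- clean_cycles()
  X <- extract_window_features(cycles[[1]]$x)
  clf <- train_phase_classifier(X, cycles[[1]]$phases)
  path <- tempfile(fileext = ".rds")
  save_phase_classifier(clf, path)
  back <- load_phase_classifier(path)
  expect_equal(back$hyperparameters, clf$hyperparameters)
  expect_equal(classify_phases(back, X), classify_phases(clf, X))
  unlink(path)
})
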