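make_toy_samples <- function(n, ks = c(3, 4, 3, 2),
                             lens = c(30, 20, 30, 20), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    branches <- lapply(seq_along(ks), function(p)
      matrix(runif(lens[p] * ks[p]), lens[p], ks[p]))
    tt <- seq_len(sum(lens))
    y <- cbind(0.5 + 0.3 * sin(tt / 12 + i / n), 0.5 + 0.2 * cos(tt / 9),
               0.2 + 0.6 * tt / max(tt))
    list(branches = branches, y = y)
  })
}

test_that("model specs validate and reflect the per-phase feature counts", {
  spec <- build_cg_model(c(10, 13, 14, 15))
  expect_equal(spec$feature_counts, c(10L, 13L, 14L, 15L))
  expect_equal(spec$n_branches, 4)
  expect_equal(spec$hidden_branch, c(64L, 32L))
  expect_equal(spec$hidden_trunk, c(32L, 32L))
  params <- insoleCG:::init_cg_params(spec, seed = 1)
  for (p in 1:4)
    expect_equal(ncol(params[[sprintf("br%d.l1.f.W", p)]]),
                 spec$feature_counts[p])
  expect_error(build_cg_model(c(0, 3)), "at least one")
})

test_that("the forward pass is shaped, bounded and deterministic", {
  spec <- build_cg_model(c(3, 4, 3, 2), hidden_branch = c(8, 6),
                         hidden_trunk = c(6, 5))
  params <- insoleCG:::init_cg_params(spec, seed = 2)
  batch <- make_toy_samples(3)
  # zero inputs still give finite sigmoid-bounded outputs
  zero_batch <- lapply(batch, function(s) {
    s$branches <- lapply(s$branches, function(b) b * 0); s
  })
  fw0 <- insoleCG:::cg_forward(params, spec, zero_batch)
  for (pr in fw0$preds) {
    expect_equal(dim(pr), c(100, 3))
    expect_true(all(is.finite(pr)) && all(pr >= 0 & pr <= 1))
  }
  fw1 <- insoleCG:::cg_forward(params, spec, batch)
  fw2 <- insoleCG:::cg_forward(params, spec, batch)
  expect_identical(fw1$preds, fw2$preds)
})

test_that("min-max normalization is exact, invertible and unclipped", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4)
  nm <- minmax_normalize(x)
  expect_equal(apply(nm$x, 2, min), rep(0, 4))
  expect_equal(apply(nm$x, 2, max), rep(1, 4))
  back <- minmax_denormalize(nm$x, nm$constants)
  expect_lt(max(abs(back - x)), 1e-12)
  # out-of-range values map outside [0, 1]
  out <- minmax_normalize(matrix(max(x[, 1]) + 1, 1, 4), nm$constants)$x
  expect_gt(out[1, 1], 1)
  # constant channels are flagged and mapped to zero
  cst <- minmax_normalize(matrix(7, 10, 1))
  expect_true(cst$constants$constant)
  expect_true(all(cst$x == 0))
})

test_that("training reduces the loss, is seed-reproducible and stops early", {
  spec <- build_cg_model(c(3, 4, 3, 2), hidden_branch = c(8, 6),
                         hidden_trunk = c(6, 5))
  train <- make_toy_samples(12, seed = 3)
  val <- make_toy_samples(3, seed = 4)
  net <- train_cg_network(train, val, spec, seed = 9, epochs = 12,
                          batch_size = 4)
  expect_lt(net$history$train_loss[10], net$history$train_loss[1])
  net2 <- train_cg_network(train, val, spec, seed = 9, epochs = 12,
                           batch_size = 4)
  expect_identical(net$params, net2$params)
  expect_equal(net$stop_epoch, net2$stop_epoch)

  # a trivially learnable mean plus irreducible target noise puts a floor
  # under the validation loss, so early stopping must fire before the cap
  set.seed(8)
  triv <- lapply(make_toy_samples(8, seed = 5), function(s) {
    s$y <- matrix(0.5 + rnorm(length(s$y), sd = 0.05), nrow(s$y), 3); s
  })
  net3 <- train_cg_network(triv[1:6], triv[7:8], spec, seed = 1, epochs = 400,
                           early_stop_patience = 15)
  expect_lt(net3$stop_epoch, 400)
  expect_lte(net3$best_epoch, net3$stop_epoch)
})

test_that("a small model fits a deterministic mapping and predicts stably", {
  cycles <- clean_cycles()
  chosen <- rep(list(c("R_copx.raw", "R_total.raw", "L_copx.raw",
                       "L_total.raw", "R_front.avg", "L_front.avg")), 4)
  model <- fit_cg_model(cycles[1:8], cycles[9:10], chosen, seed = 2,
                        epochs = 60)
  pred <- predict(model, cycles[[1]], leg_length = cycles[[1]]$leg_length)
  expect_equal(dim(pred), c(100, 3))
  expect_equal(dim(attr(pred, "raw_mm")), c(100, 3))
  # self-fit sanity: the anterior axis of a training trial is captured
  expect_gt(cor(pred[, "ap"], cycles[[1]]$y[, "ap"]), 0.99)
  # inference is deterministic
  expect_identical(pred, predict(model, cycles[[1]],
                                 leg_length = cycles[[1]]$leg_length))
})

test_that("model archives round-trip", {
  cycles <- clean_cycles()
  chosen <- rep(list(c("R_copx.raw", "L_copx.raw")), 4)
  model <- fit_cg_model(cycles[1:3], cycles[4:5], chosen, seed = 1, epochs = 2)
  path <- tempfile(fileext = ".rds")
  save_cg_model(model, path)
  back <- load_cg_model(path)
  expect_identical(predict(back, cycles[[1]]), predict(model, cycles[[1]]))
  unlink(path)
})
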