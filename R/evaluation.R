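# ---------------------------------------------------------------------------
# Evaluation: trajectory metrics (correlation, RMSE, relative RMSE,
# peak-to-valley range), group-difference analysis, and the comparative
# harness running the whole-cycle feature-selection baselines (none / RFE /
# MI / elastic net) against the phase-branched model.
# ---------------------------------------------------------------------------

#' Per-axis trajectory agreement metrics
#'
#' Pearson correlation, RMSE (in the units of the input, typically mm) and
#' relative RMSE per CG axis. rRMSE is `100 * RMSE / (max - min)` of the
#' reference axis over the cycle (range-normalized; the per-axis excursions
#' differ by an order of magnitude, so a common normalizer would be
#' meaningless); set `rrmse_norm = "mean"` to divide by the reference mean
#' magnitude instead. rRMSE is flagged `NA` on a zero-range reference.
#'
#' @param predicted,reference frames x 3 matrices (same frame count).
#' @param rrmse_norm `"range"` (default) or `"mean"`.
#' @return data.frame with one row per axis: `axis`, `r`, `rmse`, `rrmse`.
#' @export
trajectory_metrics <- function(predicted, reference,
                               rrmse_norm = c("range", "mean")) {
  rrmse_norm <- match.arg(rrmse_norm)
  predicted <- as.matrix(predicted); reference <- as.matrix(reference)
  if (nrow(predicted) != nrow(reference)) stop("frame counts differ")
  axes <- colnames(reference)
  if (is.null(axes)) axes <- paste0("axis", seq_len(ncol(reference)))
  out <- NULL
  for (a in seq_len(ncol(reference))) {
    err <- predicted[, a] - reference[, a]
    rmse <- sqrt(mean(err^2))
    denom <- if (rrmse_norm == "range") diff(range(reference[, a])) else
      mean(abs(reference[, a]))
    rr <- if (denom > 0) 100 * rmse / denom else NA_real_
    r <- if (sd(predicted[, a]) > 0 && sd(reference[, a]) > 0)
      cor(predicted[, a], reference[, a]) else NA_real_
    out <- rbind(out, data.frame(axis = axes[a], r = r, rmse = rmse,
                                 rrmse = rr))
  }
  out
}

#' Peak-to-valley range of a trajectory axis
#'
#' Global maximum minus global minimum over the cycle.
#' @param x numeric series (one axis).
#' @return nonnegative scalar.
#' @export
pv_range <- function(x) {
  if (!length(x)) stop("empty series")
  max(x) - min(x)
}

#' Two-group comparison of peak-to-valley ranges
#'
#' Welch two-sample t-test with the direction of the mean difference. When
#' both groups are (numerically) constant the test degenerates to an exact
#' equality check.
#'
#' @param pv_young,pv_old PV-range values per group (>= 2 each).
#' @return list with `p_value`, `direction` (`"old>young"`, `"young>old"` or
#'   `"none"`), `mean_young`, `mean_old`, `diff` (old minus young).
#' @export
group_difference_test <- function(pv_young, pv_old) {
  if (length(pv_young) < 2 || length(pv_old) < 2)
    stop("at least 2 values per group are required")
  d <- mean(pv_old) - mean(pv_young)
  if (sd(pv_young) == 0 && sd(pv_old) == 0) {
    p <- if (d == 0) 1 else 0
  } else {
    p <- t.test(pv_old, pv_young)$p.value
  }
  direction <- if (abs(d) < .Machine$double.eps^0.5) "none" else
    if (d > 0) "old>young" else "young>old"
  list(p_value = p, direction = direction,
       mean_young = mean(pv_young), mean_old = mean(pv_old), diff = d)
}

#' Peak-to-valley group analysis of a cohort
#'
#' Preprocesses every trial, computes the medial/lateral and proximal/distal
#' PV ranges of the reference CG trajectory (mm) per trial, summarizes them
#' per group, and tests the old-vs-young difference per axis.
#'
#' @param cohort an `insole_cohort`.
#' @param config preprocessing configuration.
#' @return list per axis (`ml`, `pd`): `summary` data.frame (group, mean,
#'   sd, n) and the [group_difference_test()] result.
#' @export
pv_group_analysis <- function(cohort, config = preprocess_config()) {
  cycles <- preprocess_cohort(cohort, config)
  groups <- cohort$manifest$group
  res <- list()
  for (a in c("ml", "pd")) {
    pv <- vapply(cycles, function(cy) pv_range(attr(cy$cg, "raw_mm")[, a]),
                 numeric(1))
    smry <- do.call(rbind, lapply(c("young", "old"), function(g)
      data.frame(group = g, mean = mean(pv[groups == g]),
                 sd = sd(pv[groups == g]), n = sum(groups == g))))
    res[[a]] <- list(summary = smry,
                     test = group_difference_test(pv[groups == "young"],
                                                  pv[groups == "old"]))
  }
  res
}

# --- whole-cycle feature-selection baselines ---------------------------------

# Linear-SVR importance backed recursive feature elimination: repeatedly fit
# one linear SVR per CG axis, score features by the mean |weight|, and drop
# the lowest-scoring ~20% until k features remain.
rfe_select <- function(features, cg, k, max_frames = 600, svr_cost = 1) {
  if (k >= ncol(features)) return(colnames(features))
  rows <- round(seq(1, nrow(features), length.out = min(max_frames, nrow(features))))
  x <- features[rows, , drop = FALSE]
  y <- cg[rows, , drop = FALSE]
  keep <- seq_len(ncol(features))
  while (length(keep) > k) {
    imp <- rep(0, length(keep))
    xs <- scale(x[, keep, drop = FALSE])
    xs[!is.finite(xs)] <- 0
    for (a in seq_len(ncol(y))) {
      ya <- y[, a]
      ys <- if (sd(ya) > 0) (ya - mean(ya)) / sd(ya) else ya
      m <- e1071::svm(x = xs, y = ys, type = "eps-regression",
                      kernel = "linear", cost = svr_cost, scale = FALSE)
      w <- as.vector(t(m$coefs) %*% m$SV)
      imp <- imp + abs(w) / max(abs(w))
    }
    drop_n <- max(1L, min(length(keep) - k, ceiling(0.2 * length(keep))))
    keep <- keep[order(imp, decreasing = TRUE)][seq_len(length(keep) - drop_n)]
    keep <- sort(keep)
  }
  colnames(features)[keep]
}

# Whole-cycle MI ranking (single phase) -> top-k feature names.
mi_select <- function(features, cg, k, n_bins = 10) {
  sel <- rank_features_per_phase(features, cg, rep(1L, nrow(features)),
                                 n_bins = n_bins)
  sel$phases[["1"]]$ranking[seq_len(k)]
}

# Elastic-net selection: cross-validated glmnet (L1/L2 mixing alpha) per CG
# axis; features with a nonzero coefficient on any axis are kept.
elastic_net_select <- function(features, cg, alpha = 0.5, max_frames = 2000,
                               seed = 1L) {
  rows <- round(seq(1, nrow(features), length.out = min(max_frames, nrow(features))))
  x <- as.matrix(features[rows, , drop = FALSE])
  keep <- logical(ncol(x))
  set.seed(as.integer(seed))
  for (a in seq_len(ncol(cg))) {
    cvfit <- glmnet::cv.glmnet(x, cg[rows, a], alpha = alpha, nfolds = 5)
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.1se"))[-1, 1]
    keep <- keep | cf != 0
  }
  if (!any(keep)) keep[1] <- TRUE
  colnames(features)[keep]
}

# --- comparative harness ------------------------------------------------------

# Convert preprocessed pressure_cycle objects into model-ready cycles.
cycles_for_model <- function(pcycles, layout = default_sensor_layout()) {
  lapply(pcycles, function(cy) {
    list(x = compute_parameters(cy, layout),
         y = unclass(cy$cg)[, , drop = FALSE],
         y_mm = attr(cy$cg, "raw_mm"),
         phases = label_phases(cy$events),
         subject = cy$subject,
         group = cy$profile$group,
         leg_length = cy$profile$leg_length)
  })
}

# Deterministic subject-level split: per group, the first n - n_val - n_test
# subjects train, then validation, then test.
split_subjects <- function(manifest, n_val_per_group = 1, n_test_per_group = 1) {
  split <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in unique(manifest$group)) {
    subs <- unique(manifest$subject[manifest$group == g])
    n <- length(subs)
    if (n < n_val_per_group + n_test_per_group + 1)
      stop("not enough subjects in group ", g)
    n_tr <- n - n_val_per_group - n_test_per_group
    split$train <- c(split$train, subs[seq_len(n_tr)])
    split$val <- c(split$val, subs[n_tr + seq_len(n_val_per_group)])
    split$test <- c(split$test, subs[n_tr + n_val_per_group +
                                       seq_len(n_test_per_group)])
  }
  split
}

#' Run the comparative CG-prediction study on a cohort
#'
#' Shared protocol for all methods: subject-level train/validation/test
#' split, preprocessing, 30-parameter derivation, 4-fold augmentation of the
#' training cycles, network training with one common seed and budget, and
#' evaluation on the held-out test cycles. Methods differ only in feature
#' engineering: `proposed` runs the phase-based protocol (per-phase MI
#' ranking + SVR feature-count optimization, phase-branched network);
#' `none` feeds all 240 whole-cycle candidates to an unbranched network;
#' `rfe`, `mi` and `ela` select whole-cycle features by recursive feature
#' elimination, MI ranking, and cross-validated elastic net
#' (L1/L2 mixing 0.5) respectively, also on the unbranched network.
#'
#' @param cohort an `insole_cohort`.
#' @param methods subset of `c("proposed", "none", "rfe", "mi", "ela")`.
#' @param seed common seed for all methods.
#' @param epochs training epoch cap.
#' @param k_grid candidate counts for the per-phase optimization.
#' @param k_baseline feature count for the rfe / mi baselines.
#' @param n_val_per_group,n_test_per_group subjects per group held out.
#' @param augment apply 4-fold augmentation to the training cycles.
#' @param config preprocessing configuration.
#' @param verbose print progress.
#' @return a `comparative_report`: list with per-method `reports` (per-trial
#'   metrics, per-group and pooled summaries, chosen features, training
#'   history) and the `split`. A method that fails is reported as failed and
#'   the others continue.
#' @export
run_comparative_study <- function(cohort,
                                  methods = c("proposed", "none", "rfe", "mi", "ela"),
                                  seed = 1L, epochs = 100, k_grid = 5:30,
                                  k_baseline = 15,
                                  n_val_per_group = 1, n_test_per_group = 1,
                                  augment = TRUE,
                                  config = preprocess_config(),
                                  verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  pcycles <- preprocess_cohort(cohort, config)
  cycles <- cycles_for_model(pcycles)
  split <- split_subjects(cohort$manifest, n_val_per_group, n_test_per_group)
  sub_of <- vapply(cycles, function(c) c$subject, numeric(1))
  tr_cycles <- cycles[sub_of %in% split$train]
  va_cycles <- cycles[sub_of %in% split$val]
  te_cycles <- cycles[sub_of %in% split$test]

  # pooled training / validation frames for feature selection
  pool <- function(cyc_list) {
    list(features = do.call(rbind, lapply(cyc_list, function(c)
      extract_window_features(c$x))),
      cg = do.call(rbind, lapply(cyc_list, function(c) c$y)),
      phases = unlist(lapply(cyc_list, function(c) c$phases)))
  }
  tr_pool <- pool(tr_cycles)
  va_pool <- pool(va_cycles)

  tr_aug <- if (augment) build_training_set(tr_cycles, seed = seed) else tr_cycles

  run_method <- function(method) {
    if (verbose) message("method: ", method)
    if (method == "proposed") {
      sel <- rank_features_per_phase(tr_pool$features, tr_pool$cg, tr_pool$phases)
      opt <- optimize_feature_count(sel, tr_pool, va_pool, k_grid = k_grid)
      chosen <- opt$chosen
    } else {
      chosen <- list(switch(method,
        none = colnames(tr_pool$features),
        rfe = rfe_select(tr_pool$features, tr_pool$cg, k_baseline),
        mi = mi_select(tr_pool$features, tr_pool$cg, k_baseline),
        ela = elastic_net_select(tr_pool$features, tr_pool$cg, seed = seed)))
      opt <- NULL
    }
    model <- fit_cg_model(tr_aug, va_cycles, chosen, seed = seed,
                          epochs = epochs)
    trial_metrics <- NULL
    for (i in seq_along(te_cycles)) {
      cyc <- te_cycles[[i]]
      pred <- predict(model, cyc, leg_length = cyc$leg_length)
      m <- trajectory_metrics(attr(pred, "raw_mm"), cyc$y_mm)
      m$trial <- i; m$group <- cyc$group; m$subject <- cyc$subject
      trial_metrics <- rbind(trial_metrics, m)
    }
    list(method = method, chosen = chosen, optimization = opt,
         metrics = trial_metrics,
         summary = summarize_eval(trial_metrics),
         history = model$network$history,
         best_epoch = model$network$best_epoch, model = model,
         failed = FALSE)
  }

  reports <- lapply(methods, function(m)
    tryCatch(run_method(m), error = function(e)
      list(method = m, failed = TRUE, error = conditionMessage(e))))
  names(reports) <- methods
  structure(list(reports = reports, split = split, seed = seed,
                 epochs = epochs), class = "comparative_report")
}

#' Summarize per-trial trajectory metrics into an evaluation report
#'
#' Correlations are summarized as mean with (max-min) range across trials;
#' RMSE and rRMSE as mean and standard deviation; per group and pooled.
#'
#' @param trial_metrics rows from [trajectory_metrics()] with `group`.
#' @return data.frame: group x axis with `r_mean`, `r_min`, `r_max`,
#'   `rmse_mean`, `rmse_sd`, `rrmse_mean`, `rrmse_sd`, `n_trials`.
#' @export
summarize_eval <- function(trial_metrics) {
  groups <- c(unique(trial_metrics$group), "pooled")
  out <- NULL
  for (g in groups) {
    sub <- if (g == "pooled") trial_metrics else
      trial_metrics[trial_metrics$group == g, ]
    for (a in unique(sub$axis)) {
      sa <- sub[sub$axis == a, ]
      out <- rbind(out, data.frame(
        group = g, axis = a, r_mean = mean(sa$r), r_min = min(sa$r),
        r_max = max(sa$r), rmse_mean = mean(sa$rmse), rmse_sd = sd(sa$rmse),
        rrmse_mean = mean(sa$rrmse), rrmse_sd = sd(sa$rrmse),
        n_trials = nrow(sa)))
    }
  }
  out
}

#' @export
print.comparative_report <- function(x, ...) {
  for (rep in x$reports) {
    if (isTRUE(rep$failed)) {
      cat(sprintf("%-9s FAILED: %s\n", rep$method, rep$error))
      next
    }
    pooled <- rep$summary[rep$summary$group == "pooled", ]
    cat(sprintf("%-9s rRMSE %%: %s | r: %s\n", rep$method,
                paste(sprintf("%s %.2f", pooled$axis, pooled$rrmse_mean),
                      collapse = ", "),
                paste(sprintf("%.3f", pooled$r_mean), collapse = ", ")))
  }
  invisible(x)
}

#' Write a comparative report to JSON and CSV
#'
#' @param report a `comparative_report`.
#' @param dir output directory.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rep in report$reports) {
    if (isTRUE(rep$failed)) next
    write.csv(rep$summary, file.path(dir, sprintf("summary_%s.csv", rep$method)),
              row.names = FALSE)
  }
  smry <- lapply(report$reports, function(rep) {
    if (isTRUE(rep$failed)) list(method = rep$method, failed = TRUE,
                                 error = rep$error)
    else list(method = rep$method, failed = FALSE, summary = rep$summary,
              k = if (!is.null(rep$optimization)) unname(rep$optimization$k)
              else length(rep$chosen[[1]]))
  })
  jsonlite::write_json(smry, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
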