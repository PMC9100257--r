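# ---------------------------------------------------------------------------
# Windowed feature engineering and mutual-information feature selection.
# 30 insole parameters x 7 window statistics (average, max, min, range, mean
# absolute deviation, kurtosis, skewness) over a trailing 5-frame window
# = 210 windowed features, plus the 30 raw values at the window's last frame
# = 240 candidates.
# ---------------------------------------------------------------------------

window_stat_names <- function() {
  c("avg", "max", "min", "range", "mad", "kurt", "skew")
}

#' Names of the 240 feature candidates
#' @param param_names names of the input parameters (default the 30 insole
#'   parameters).
#' @return character vector: for each parameter its 7 windowed statistics,
#'   then all raw columns.
#' @export
feature_names <- function(param_names = parameter_names()) {
  c(as.vector(t(outer(param_names, window_stat_names(), paste, sep = "."))),
    paste0(param_names, ".raw"))
}

#' Extract windowed feature candidates from a parameter series
#'
#' For each frame t, statistics are computed over the trailing window
#' `[t - window + 1, t]`; the first `window - 1` frames replicate frame 1 so
#' the output keeps the input frame count. Kurtosis (excess) and skewness
#' use population moments and are defined as 0 for zero-variance windows
#' (constant swing-phase signals).
#'
#' @param params frames x p matrix (typically a `parameter_series`).
#' @param window window length in frames (default 5).
#' @return a frames x (8 p) `feature_matrix`: 7 windowed statistics per
#'   parameter plus the raw value at the window's last frame.
#' @export
extract_window_features <- function(params, window = 5) {
  if (window < 2) stop("window must be at least 2")
  params <- unclass(as.matrix(params))
  n <- nrow(params)
  if (n < window) stop("series shorter than the window")
  p <- ncol(params)
  pn <- colnames(params)
  if (is.null(pn)) pn <- paste0("p", seq_len(p))

  # index matrix of the trailing windows with left replicate padding
  idx <- outer(seq_len(n), (window - 1):0, function(t, k) pmax(t - k, 1L))

  stats_one <- function(x) {
    wm <- matrix(x[idx], nrow = n)           # n x window values
    mu <- rowMeans(wm)
    mx <- do.call(pmax, as.data.frame(wm))
    mn <- do.call(pmin, as.data.frame(wm))
    dev <- wm - mu
    m2 <- rowMeans(dev^2)
    m3 <- rowMeans(dev^3)
    m4 <- rowMeans(dev^4)
    kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
    skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
    cbind(mu, mx, mn, mx - mn, rowMeans(abs(dev)), kurt, skew)
  }

  windowed <- do.call(cbind, lapply(seq_len(p), function(j) stats_one(params[, j])))
  out <- cbind(windowed, params)
  colnames(out) <- feature_names(pn)
  class(out) <- c("feature_matrix", class(out))
  out
}

# ---------------------------------------------------------------------------
# Mutual information, computed exactly from a discretized joint histogram:
#   I(X,Y) = sum_{x,y} p(x,y) log2( p(x,y) / (p(x) p(y)) )
# ---------------------------------------------------------------------------

equal_frequency_bins <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Mutual information between two series
#'
#' Both series are discretized into equal-frequency bins and the mutual
#' information of the resulting joint histogram is evaluated exactly with a
#' base-2 logarithm, so the value is in bits. A constant series yields 0
#' bits with a degenerate-bin warning.
#'
#' @param x,y equal-length numeric series.
#' @param n_bins number of equal-frequency bins (default 10).
#' @return an `mi_estimate`: list with `mi` (bits), `joint` p(x,y), `px`,
#'   `py`, `n_bins_used`.
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < n_bins) stop("series shorter than the number of bins")
  bx <- equal_frequency_bins(x, n_bins)
  by <- equal_frequency_bins(y, n_bins)
  if (length(unique(bx)) < 2 || length(unique(by)) < 2)
    warning("degenerate binning (constant series): MI is 0")
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
  structure(list(mi = max(mi, 0), joint = joint, px = px, py = py,
                 n_bins_used = c(x = length(px), y = length(py))),
            class = "mi_estimate")
}

#' Rank the feature candidates of each gait phase by mutual information
#'
#' For each phase and CG axis, the MI between every candidate and the axis
#' is computed over the phase's pooled frames; per axis the 240 MI values
#' are min-max scaled to `[0, 1]`, and the candidate score is the mean of the
#' three scaled values. Candidates are sorted by descending score with ties
#' broken by column index.
#'
#' @param features pooled frames x 240 matrix.
#' @param cg pooled frames x 3 CG matrix (same row order).
#' @param phases integer phase label per row.
#' @param n_bins MI discretization bins.
#' @return a `phase_feature_selection`: per phase a list with `ranking`
#'   (ordered candidate names), `scores` (aligned with `ranking`),
#'   `mi_raw` (3 x 240 per-axis MI), plus `feature_names`.
#' @export
rank_features_per_phase <- function(features, cg, phases, n_bins = 10) {
  features <- as.matrix(features)
  cg <- as.matrix(cg)
  fn <- colnames(features)
  phases_u <- sort(unique(phases))
  per_phase <- list()
  for (p in phases_u) {
    rows <- which(phases == p)
    if (length(rows) < n_bins) stop("phase ", p, " has fewer frames than bins")
    mi_raw <- matrix(0, nrow = ncol(cg), ncol = ncol(features),
                     dimnames = list(colnames(cg), fn))
    for (a in seq_len(ncol(cg))) {
      ya <- cg[rows, a]
      mi_raw[a, ] <- vapply(seq_len(ncol(features)), function(j)
        suppressWarnings(mutual_information(features[rows, j], ya, n_bins)$mi),
        numeric(1))
    }
    scaled <- t(apply(mi_raw, 1, function(v) {
      r <- range(v)
      if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
    }))
    score <- colMeans(scaled)
    ord <- order(-score, seq_along(score))
    per_phase[[as.character(p)]] <- list(ranking = fn[ord],
                                         ranking_idx = ord,
                                         scores = score[ord],
                                         mi_raw = mi_raw)
  }
  structure(list(phases = per_phase, feature_names = fn, n_bins = n_bins),
            class = "phase_feature_selection")
}

# rRMSE of an SVR prediction, averaged over the 3 CG axes
svr_phase_rrmse <- function(xtr, ytr, xva, yva, svr_cost = 1, svr_epsilon = 0.1) {
  errs <- vapply(seq_len(ncol(ytr)), function(a) {
    m <- e1071::svm(x = xtr, y = ytr[, a], type = "eps-regression",
                    kernel = "radial", cost = svr_cost, epsilon = svr_epsilon,
                    scale = TRUE)
    pred <- predict(m, xva)
    ref_range <- diff(range(yva[, a]))
    if (ref_range == 0) return(NA_real_)
    100 * sqrt(mean((pred - yva[, a])^2)) / ref_range
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

#' Optimize the number of selected features per phase
#'
#' For each candidate count k, one support vector regressor per CG axis is
#' fitted on the phase's top-k candidates over the training frames and the
#' mean 3-axis relative RMSE on the validation frames is the objective; the
#' k with the smallest error wins (smallest k on ties). The full k-to-error
#' curve is retained.
#'
#' @param selection a `phase_feature_selection` built on the training pool.
#' @param train list with `features`, `cg`, `phases` (pooled training rows).
#' @param val list with the same fields for validation subjects (disjoint
#'   at subject level).
#' @param k_grid candidate counts to evaluate (default 5 to 30).
#' @param max_train_frames training frames are subsampled (deterministically,
#'   evenly spaced) to at most this many rows per phase to bound the SVR
#'   cost.
#' @param svr_cost,svr_epsilon SVR hyperparameters (RBF kernel).
#' @return list: `k` (named integer per phase), `curves` (per phase a
#'   data.frame k/error), `chosen` (per phase the selected feature names).
#' @export
optimize_feature_count <- function(selection, train, val, k_grid = 5:30,
                                   max_train_frames = 600,
                                   svr_cost = 1, svr_epsilon = 0.1) {
  if (!length(k_grid)) stop("empty candidate count range")
  k_grid <- sort(unique(as.integer(k_grid)))
  phases_u <- names(selection$phases)
  ks <- integer(0); curves <- list(); chosen <- list()
  for (p in phases_u) {
    sel <- selection$phases[[p]]
    tr_rows <- which(train$phases == as.integer(p))
    va_rows <- which(val$phases == as.integer(p))
    if (length(tr_rows) > max_train_frames)
      tr_rows <- tr_rows[round(seq(1, length(tr_rows),
                                   length.out = max_train_frames))]
    errs <- vapply(k_grid, function(k) {
      cols <- sel$ranking_idx[seq_len(k)]
      svr_phase_rrmse(train$features[tr_rows, cols, drop = FALSE],
                      train$cg[tr_rows, , drop = FALSE],
                      val$features[va_rows, cols, drop = FALSE],
                      val$cg[va_rows, , drop = FALSE],
                      svr_cost, svr_epsilon)
    }, numeric(1))
    best <- k_grid[which.min(errs)]
    ks[p] <- best
    curves[[p]] <- data.frame(k = k_grid, rrmse = errs)
    chosen[[p]] <- sel$ranking[seq_len(best)]
  }
  list(k = ks, curves = curves, chosen = chosen)
}

#' Persist a feature selection result as JSON
#'
#' Per phase: the ranked candidate names with scores and (when available)
#' the chosen count and feature list.
#'
#' @param selection a `phase_feature_selection`.
#' @param opt optional result of [optimize_feature_count()].
#' @param path output JSON path.
#' @export
write_feature_selection <- function(selection, opt = NULL, path) {
  out <- lapply(names(selection$phases), function(p) {
    sel <- selection$phases[[p]]
    entry <- list(phase = as.integer(p), ranking = sel$ranking,
                  scores = unname(sel$scores))
    if (!is.null(opt)) {
      entry$k <- unname(opt$k[p])
      entry$chosen <- opt$chosen[[p]]
    }
    entry
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
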