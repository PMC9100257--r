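# ---------------------------------------------------------------------------
# Four-phase gait segmentation. Phases, delimited by heel strikes and
# mid-stance events (the vertical-CG peaks):
#   1: right heel strike  -> right mid-stance
#   2: right mid-stance   -> left heel strike
#   3: left heel strike   -> left mid-stance
#   4: left mid-stance    -> next right heel strike
# Plus the SVM classifier that recovers the labels from insole features when
# no kinematic event detection is available.
# ---------------------------------------------------------------------------

#' Label the frames of a normalized cycle with their gait phase
#'
#' Event frames are on the 0-100 normalized scale; frame f (1-based) covers
#' normalized time `[f-1, f)`, so with the default schedule (mid-stances at
#' 30 and 80, LHS at 50) the four blocks have lengths 30, 20, 30, 20.
#'
#' @param events a [gait_event_schedule()].
#' @param n_frames frames per cycle (default 100).
#' @return integer vector of phase labels in 1..4, one per frame.
#' @export
label_phases <- function(events, n_frames = 100) {
  if (!inherits(events, "gait_events")) stop("events must be a gait_events schedule")
  b <- c(events$r_midstance_frame, events$lhs_frame, events$l_midstance_frame)
  b <- round(b / 100 * n_frames)
  labels <- integer(n_frames)
  labels[1:b[1]] <- 1L
  labels[(b[1] + 1):b[2]] <- 2L
  labels[(b[2] + 1):b[3]] <- 3L
  labels[(b[3] + 1):n_frames] <- 4L
  labels
}

#' Full SVM hyperparameter candidate grid
#'
#' The grid-search candidates for the phase classifier: C in
#' \{0.1, 1, 100, 1000\}, kernels rbf/poly/sigmoid/linear, polynomial degrees
#' 1-6, gamma in \{1, 0.1, 0.01, 0.001, 0.0001\}. Degree only applies to the
#' polynomial kernel and gamma does not apply to the linear kernel, so
#' redundant combinations are collapsed.
#'
#' @return data.frame with columns `C`, `kernel`, `degree`, `gamma`.
#' @export
svm_candidate_grid <- function() {
  Cs <- c(0.1, 1, 100, 1000)
  gammas <- c(1, 0.1, 0.01, 0.001, 0.0001)
  g <- rbind(
    expand.grid(C = Cs, kernel = "radial", degree = 3, gamma = gammas),
    expand.grid(C = Cs, kernel = "polynomial", degree = 1:6, gamma = gammas),
    expand.grid(C = Cs, kernel = "sigmoid", degree = 3, gamma = gammas),
    expand.grid(C = Cs, kernel = "linear", degree = 3, gamma = 0.1))
  g$kernel <- as.character(g$kernel)
  g
}

#' Hyperparameters selected in the reference protocol
#' @return one-row grid: C = 1, RBF kernel, gamma = 0.1.
#' @export
svm_selected_grid <- function() {
  data.frame(C = 1, kernel = "radial", degree = 3, gamma = 0.1)
}

#' Train the SVM gait-phase classifier
#'
#' Fits a multi-class SVM mapping per-frame feature vectors to phase labels.
#' With a multi-row `grid`, hyperparameters are selected by subject-level
#' cross-validation (folds partition subjects, never frames, so no cycle
#' leaks between training and validation); with a single-row grid the model
#' is fitted directly.
#'
#' @param features frames x p numeric matrix (rows pooled over cycles).
#' @param labels integer phase labels, one per row.
#' @param subjects subject id per row (required when `grid` has > 1 row).
#' @param grid data.frame of candidates (columns C, kernel, degree, gamma);
#'   defaults to the single selected combination C = 1, rbf, gamma = 0.1.
#' @param n_folds cross-validation folds over subjects.
#' @return a `phase_classifier`: list with the fitted `model`,
#'   `hyperparameters` actually used, `feature_names`, `cv_accuracy`.
#' @export
train_phase_classifier <- function(features, labels, subjects = NULL,
                                   grid = svm_selected_grid(), n_folds = 5) {
  features <- as.matrix(features)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  if (nrow(features) != length(labels)) stop("features and labels misaligned")

  fit_one <- function(x, y, hp) {
    e1071::svm(x = x, y = factor(y, levels = sort(unique(labels))),
               type = "C-classification", kernel = hp$kernel, cost = hp$C,
               degree = hp$degree, gamma = hp$gamma, scale = TRUE)
  }

  cv_acc <- NA_real_
  if (nrow(grid) > 1) {
    if (is.null(subjects)) stop("subject ids are required for grid search")
    subj <- unique(subjects)
    folds <- split(subj, rep_len(seq_len(n_folds), length(subj)))
    accs <- vapply(seq_len(nrow(grid)), function(i) {
      hp <- grid[i, ]
      mean(vapply(folds, function(hold) {
        tr <- !(subjects %in% hold)
        m <- fit_one(features[tr, , drop = FALSE], labels[tr], hp)
        mean(predict(m, features[!tr, , drop = FALSE]) == labels[!tr])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(accs)
    grid <- grid[best, , drop = FALSE]
    cv_acc <- accs[best]
  }
  hp <- grid[1, ]
  model <- fit_one(features, labels, hp)
  structure(list(model = model,
                 hyperparameters = list(C = hp$C, kernel = hp$kernel,
                                        degree = hp$degree, gamma = hp$gamma),
                 feature_names = colnames(features), cv_accuracy = cv_acc),
            class = "phase_classifier")
}

# Project an arbitrary label sequence onto the nearest valid phase sequence:
# four contiguous, non-empty blocks 1-2-3-4. Dynamic program maximizing
# agreement with the input labels.
enforce_contiguous_phases <- function(labels, n_phases = 4) {
  n <- length(labels)
  agree <- sapply(seq_len(n_phases), function(p) as.numeric(labels == p))
  # best[t, p]: max agreement over frames 1..t with frame t in phase p and
  # phases 1..p all non-empty
  best <- matrix(-Inf, n, n_phases)
  from <- matrix(0L, n, n_phases)
  best[1, 1] <- agree[1, 1]
  for (t in 2:n) {
    for (p in seq_len(n_phases)) {
      stay <- best[t - 1, p]
      adv <- if (p > 1) best[t - 1, p - 1] else -Inf
      if (stay >= adv) {
        best[t, p] <- stay + agree[t, p]; from[t, p] <- p
      } else {
        best[t, p] <- adv + agree[t, p]; from[t, p] <- p - 1L
      }
    }
  }
  out <- integer(n)
  out[n] <- n_phases
  for (t in n:2) out[t - 1] <- from[t, out[t]]
  out
}

#' Classify the gait phase of each frame and repair contiguity
#'
#' Per-frame SVM prediction followed by a repair pass: a 5-frame
#' majority-vote smoothing removes isolated flips, then the sequence is
#' projected onto the nearest monotone 1-2-3-4 block structure, so the
#' output always consists of four contiguous non-empty phases.
#'
#' @param classifier a `phase_classifier`.
#' @param features frames x p matrix with the training feature schema.
#' @param repair_window odd smoothing window (default 5).
#' @return integer phase labels (1..4).
#' @export
classify_phases <- function(classifier, features, repair_window = 5) {
  features <- as.matrix(features)
  if (!is.null(classifier$feature_names) &&
      !identical(colnames(features), classifier$feature_names))
    stop("feature schema does not match the classifier's training schema")
  raw <- as.integer(as.character(predict(classifier$model, features)))
  sm <- majority_smooth(raw, repair_window)
  enforce_contiguous_phases(sm)
}

#' Majority-vote label smoothing
#' @param labels integer labels.
#' @param window odd window size.
#' @return smoothed labels.
#' @export
majority_smooth <- function(labels, window = 5) {
  if (window %% 2 == 0) stop("window must be odd")
  h <- (window - 1) / 2
  n <- length(labels)
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    tab <- table(labels[lo:hi])
    winners <- names(tab)[tab == max(tab)]
    # keep the current label on ties, otherwise take the majority
    out[i] <- if (as.character(labels[i]) %in% winners) labels[i] else
      as.integer(winners[1])
  }
  out
}

#' Precision, recall, F1 and confusion matrix for phase classification
#'
#' @param predicted,truth equal-length label vectors.
#' @return list with `confusion` (rows = truth, columns = predicted),
#'   `per_class` data.frame (precision, recall, f1, support), `accuracy`.
#' @export
phase_classification_report <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  lev <- sort(unique(c(predicted, truth)))
  cm <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  dimnames(cm) <- list(truth = lev, predicted = lev)
  per <- data.frame(class = lev, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, support = as.integer(rowSums(cm)))
  for (i in seq_along(lev)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$precision[i] <- prec
    per$recall[i] <- rec
    per$f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  list(confusion = cm, per_class = per,
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Persist / restore a phase classifier
#'
#' The SVM model, its hyperparameters and the feature schema are stored in a
#' versioned RDS archive.
#'
#' @param classifier a `phase_classifier`.
#' @param path archive path.
#' @export
save_phase_classifier <- function(classifier, path) {
  saveRDS(list(format_version = 1L, classifier = classifier), path)
  invisible(path)
}

#' @rdname save_phase_classifier
#' @export
load_phase_classifier <- function(path) {
  arc <- readRDS(path)
  if (is.null(arc$format_version)) stop("not a phase classifier archive")
  arc$classifier
}
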