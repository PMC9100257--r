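# ---------------------------------------------------------------------------
# Pipeline orchestration: simulate -> preprocess -> features/phases ->
# augment -> train -> evaluate, with stage artifacts on disk so runs are
# inspectable and partially repeatable.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Nested configuration for a full run. The `"study"` scale mirrors the
#' reference experiment (15 + 15 subjects, 3 trials each, 13 + 13 training
#' subjects); the `"desk"` scale is a small smoke-test setting (3 + 3
#' subjects, short training) for quick end-to-end runs.
#'
#' @param scale `"study"` or `"desk"`, or override fields directly.
#' @param seed master seed.
#' @param n_young,n_old,trials_per_subject cohort composition.
#' @param epochs training epoch cap.
#' @param methods comparative methods to run.
#' @param k_grid per-phase feature-count candidates.
#' @param noise_scale generator noise multiplier.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scale = c("study", "desk"), seed = 1L,
                            n_young = NULL, n_old = NULL,
                            trials_per_subject = 3, epochs = NULL,
                            methods = c("proposed", "none"),
                            k_grid = NULL, noise_scale = 1) {
  scale <- match.arg(scale)
  d <- if (scale == "study")
    list(n_young = 15, n_old = 15, epochs = 100, k_grid = 5:30) else
    list(n_young = 3, n_old = 3, epochs = 5, k_grid = c(5, 10))
  cfg <- list(scale = scale, seed = as.integer(seed),
              n_young = if (is.null(n_young)) d$n_young else n_young,
              n_old = if (is.null(n_old)) d$n_old else n_old,
              trials_per_subject = trials_per_subject,
              epochs = if (is.null(epochs)) d$epochs else epochs,
              methods = methods,
              k_grid = if (is.null(k_grid)) d$k_grid else k_grid,
              noise_scale = noise_scale,
              preprocess = preprocess_config(),
              augmentation = augmentation_config())
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(scale = cfg$scale %||% "desk")
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the CG-prediction pipeline
#'
#' Executes the requested stages in protocol order; each stage writes its
#' artifacts under `outdir` and later stages consume them. A resolved copy
#' of the configuration and its content hash are written next to the
#' outputs, and identical config + seed reproduce identical metric files.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "preprocess", "features",
#'   "phases", "evaluate")` (evaluate covers augmentation, training and
#'   metric reporting, which share one harness).
#' @param outdir run directory.
#' @param verbose print progress.
#' @return `outdir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config("desk"),
                         stages = c("simulate", "preprocess", "features",
                                    "phases", "evaluate"),
                         outdir = tempfile("insolecg_run_"),
                         verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  writeLines(as.character(tools::md5sum(cfg_path)),
             file.path(outdir, "config.md5"))
  log <- function(...) if (verbose) message(sprintf(...))

  sim_dir <- file.path(outdir, "simulated")
  if ("simulate" %in% stages) {
    log("stage simulate: %d + %d subjects x %d trials", config$n_young,
        config$n_old, config$trials_per_subject)
    cohort <- generate_cohort(config$n_young, config$n_old,
                              config$trials_per_subject, seed = config$seed,
                              noise_scale = config$noise_scale)
    write_cohort(cohort, sim_dir)
  }
  if (identical(stages, "simulate") || !any(stages != "simulate"))
    return(invisible(outdir))

  if (!file.exists(file.path(sim_dir, "manifest.json")))
    stop("missing simulated data: run the 'simulate' stage first")
  cohort <- read_cohort(sim_dir)

  cycles <- NULL
  if (any(c("preprocess", "features", "phases", "evaluate") %in% stages)) {
    log("stage preprocess: %d trials", length(cohort$trials))
    pcycles <- preprocess_cohort(cohort, config$preprocess)
    cycles <- cycles_for_model(pcycles)
    if ("preprocess" %in% stages) {
      pp_dir <- file.path(outdir, "preprocessed")
      dir.create(pp_dir, showWarnings = FALSE)
      for (i in seq_along(cycles)) {
        df <- data.frame(frame = seq_len(nrow(cycles[[i]]$x)),
                         phase = cycles[[i]]$phases)
        df <- cbind(df, as.data.frame(unclass(cycles[[i]]$x)),
                    as.data.frame(cycles[[i]]$y_mm))
        write.csv(df, file.path(pp_dir, sprintf("cycle_%04d.csv", i)),
                  row.names = FALSE)
      }
    }
  }

  if ("features" %in% stages) {
    log("stage features: per-phase MI ranking")
    pool_tr <- list(
      features = do.call(rbind, lapply(cycles, function(c)
        extract_window_features(c$x))),
      cg = do.call(rbind, lapply(cycles, function(c) c$y)),
      phases = unlist(lapply(cycles, function(c) c$phases)))
    sel <- rank_features_per_phase(pool_tr$features, pool_tr$cg, pool_tr$phases)
    write_feature_selection(sel, path = file.path(outdir, "feature_ranking.json"))
  }

  if ("phases" %in% stages) {
    log("stage phases: SVM classifier")
    feats <- do.call(rbind, lapply(cycles, function(c)
      extract_window_features(c$x)))
    labs <- unlist(lapply(cycles, function(c) c$phases))
    clf <- train_phase_classifier(feats, labs)
    save_phase_classifier(clf, file.path(outdir, "phase_classifier.rds"))
    pred <- classify_phases(clf, feats)
    rep <- phase_classification_report(pred, labs)
    write.csv(rep$per_class, file.path(outdir, "phase_report.csv"),
              row.names = FALSE)
  }

  if ("evaluate" %in% stages) {
    log("stage evaluate: comparative study (%s)",
        paste(config$methods, collapse = ", "))
    report <- run_comparative_study(cohort, methods = config$methods,
                                    seed = config$seed, epochs = config$epochs,
                                    k_grid = config$k_grid, verbose = verbose)
    write_eval_report(report, file.path(outdir, "evaluation"))
    pv <- pv_group_analysis(cohort, config$preprocess)
    jsonlite::write_json(
      list(ml = list(summary = pv$ml$summary, p = pv$ml$test$p_value,
                     direction = pv$ml$test$direction),
           pd = list(summary = pv$pd$summary, p = pv$pd$test$p_value,
                     direction = pv$pd$test$direction)),
      file.path(outdir, "pv_group_analysis.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
  }
  invisible(outdir)
}
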