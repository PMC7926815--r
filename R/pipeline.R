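# End-to-end orchestration: simulate -> segment -> extract -> select ->
# train/predict (parameter models, KNN curves, LSTM curves) -> evaluate.

LSTM_INPUTS <- c("accel_forward", "accel_lateral", "accel_vertical",
                 "gyro_x", "gyro_y", "gyro_z")

#' Pipeline configuration
#'
#' All stage-level parameters with their standard defaults: correlation
#' thresholds 0.9 (feature-feature) and 0.3 (feature-target), bagged trees
#' with minimum leaf size 8 and 30 learners, 6 principal components, K = 8
#' neighbors, a 400-sample window at 400 Hz for the LSTM and the 0.5 label
#' threshold. The configuration round-trips through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed integer master seed (mandatory)
#' @param n_strides_train,n_strides_test stride counts of the simulated
#'   training and held-out sessions
#' @param walk_frac walking fraction of each session
#' @param sensor_noise_sd,artifact_scale simulator noise and insole swing
#'   artifact settings
#' @param fs_sensor,fs_insole sampling rates, Hz
#' @param r_features,r_targets correlation-selection thresholds
#' @param min_leaf_size,n_learners,pca_components bagged-tree settings
#' @param knn_k neighbor count for curve synthesis
#' @param lstm_window,lstm_hidden,lstm_epochs,lstm_batch LSTM settings
#' @param stages character vector of stage toggles, a subset of
#'   `c("params", "knn", "lstm")` (simulation, segmentation, extraction and
#'   selection always run)
#' @param out_dir run directory for the report files, or NULL to skip writing
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed,
                            n_strides_train = 200L, n_strides_test = 60L,
                            walk_frac = 0.894,
                            sensor_noise_sd = 0.05, artifact_scale = 0.10,
                            fs_sensor = 400, fs_insole = 50,
                            r_features = 0.9, r_targets = 0.3,
                            min_leaf_size = 8L, n_learners = 30L,
                            pca_components = 6L, knn_k = 8L,
                            lstm_window = 400L, lstm_hidden = c(64L, 64L),
                            lstm_epochs = 5L, lstm_batch = 256L,
                            stages = c("params", "knn"),
                            out_dir = NULL) {
  if (missing(seed)) stopf("pipeline_config requires a seed")
  fields <- as.list(environment())
  unknown <- setdiff(stages, c("params", "knn", "lstm"))
  if (length(unknown))
    stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))
  structure(fields, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @param path YAML file path
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Evaluate predictions against reference values
#'
#' NRMSE (percent) per shared numeric column.
#'
#' @param predictions,reference row-aligned data.frames
#' @return data.frame with columns `target`, `nrmse`
#' @export
evaluate_predictions <- function(predictions, reference) {
  if (is.null(reference)) stopf("missing reference values")
  cols <- intersect(colnames(predictions), colnames(reference))
  if (!length(cols)) stopf("no shared columns to evaluate")
  data.frame(target = cols,
             nrmse = vapply(cols, function(cn)
               nrmse(predictions[[cn]], reference[[cn]]), numeric(1)),
             row.names = NULL)
}

#' Run the full estimation pipeline on synthetic sessions
#'
#' Simulates a training and a held-out test session, segments the test
#' session from its sensor stream alone, extracts features and insole
#' targets, runs the correlation-based selection, then (per enabled stage)
#' trains the three bagged-tree model configurations and reports held-out
#' NRMSE per target, synthesizes vGRF curves by KNN from predicted time
#' parameters, and trains the LSTM curve/label models. Deterministic for a
#' fixed config seed.
#'
#' @param config a [pipeline_config()]
#' @return list of class `gait_report`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  profile <- subject_profile(sensor_noise_sd = config$sensor_noise_sd,
                             insole_swing_artifact_scale = config$artifact_scale)
  report <- list(config = config, stages = list())
  t_all <- Sys.time()

  sim_one <- function(n, seed_off) {
    plan <- gait_plan_walk_run(n, walk_frac = config$walk_frac,
                               seed = seed + seed_off, profile = profile)
    simulate_session(profile, plan, fs_sensor = config$fs_sensor,
                     fs_insole = config$fs_insole, seed = seed + seed_off + 1L)
  }
  train_s <- sim_one(config$n_strides_train, 0L)
  test_s <- sim_one(config$n_strides_test, 1000L)

  # segmentation runs on the sensor stream alone; training uses truth strides
  seg <- segment_strides(test_s$sensor)
  report$segmentation <- list(
    n_detected = nrow(seg), n_true = nrow(test_s$strides),
    median_boundary_error_ms = stats::median(vapply(seg$start_idx, function(e)
      min(abs(test_s$strides$start_idx - e)), numeric(1))) / config$fs_sensor * 1000)

  ex_tr <- extract_session(train_s$sensor, train_s$insole, train_s$strides,
                           profile$body_weight)
  ex_te <- extract_session(test_s$sensor, test_s$insole, test_s$strides,
                           profile$body_weight)
  targets_model <- setdiff(target_names(), "TOR")
  sel <- select_features(ex_tr$features, ex_tr$targets[, targets_model],
                         config$r_features, config$r_targets)
  report$selection <- sel

  if ("params" %in% config$stages) {
    modes <- c("six_optimal", "pca6", "all27")
    per_mode <- lapply(modes, function(md) {
      cfg <- regression_config(md, min_leaf_size = config$min_leaf_size,
                               n_learners = config$n_learners,
                               seed = seed + 7L,
                               pca_components = config$pca_components,
                               selected_features = sel$kept_features)
      bundle <- train_gait_models(ex_tr$features,
                                  ex_tr$targets[, sel$kept_targets],
                                  cfg, profile$body_weight)
      pred <- predict(bundle, ex_te$features, profile$body_weight)
      ev <- evaluate_predictions(pred, ex_te$targets)
      list(bundle = bundle, pred = pred, nrmse = ev)
    })
    names(per_mode) <- modes
    nr <- data.frame(target = per_mode[[1L]]$nrmse$target)
    for (md in modes) nr[[md]] <- per_mode[[md]]$nrmse$nrmse
    report$param_nrmse <- nr
    report$stages$params <- "run"
  } else {
    report$stages$params <- "skipped"
  }

  if ("knn" %in% config$stages) {
    slices_tr <- lapply(seq_len(nrow(train_s$strides)), function(i)
      slice_insole(train_s$insole, train_s$strides[i, ], 0, config$fs_sensor))
    lib <- build_curve_library(slices_tr, ex_tr$targets,
                               train_s$strides$duration, profile$body_weight)
    # time-parameter keys: durations are measured; TOL/GCTL/GCTR come from
    # dedicated six-feature models (the selection's target pruning may drop
    # them from the main model set)
    key_cfg <- regression_config("six_optimal",
                                 min_leaf_size = config$min_leaf_size,
                                 n_learners = config$n_learners,
                                 seed = seed + 8L,
                                 selected_features = sel$kept_features)
    key_bundle <- train_gait_models(ex_tr$features,
                                    ex_tr$targets[, c("TOL", "GCTL", "GCTR")],
                                    key_cfg, profile$body_weight)
    key_src <- predict(key_bundle, ex_te$features, profile$body_weight)
    keys_l <- cbind(test_s$strides$duration, key_src$TOL, key_src$GCTL)
    keys_r <- cbind(test_s$strides$duration, key_src$GCTR)
    cl <- query_curves(lib, keys_l, "left", k = config$knn_k)
    cr <- query_curves(lib, keys_r, "right", k = config$knn_k)
    n_s <- nrow(test_s$sensor)
    bw_n <- profile$body_weight * GRAVITY
    gi <- round(test_s$truth$gait_interval * config$fs_sensor)
    rng <- (gi[1L] + 1L):gi[2L]
    knn_nrmse <- c(
      vgrfL = nrmse(assemble_continuous(cl, test_s$strides,
                                        profile$body_weight, config$fs_sensor,
                                        n_s)[rng],
                    test_s$truth$force_left_bw[rng] * bw_n),
      vgrfR = nrmse(assemble_continuous(cr, test_s$strides,
                                        profile$body_weight, config$fs_sensor,
                                        n_s)[rng],
                    test_s$truth$force_right_bw[rng] * bw_n))
    report$knn_nrmse <- knn_nrmse
    report$stages$knn <- "run"
  } else {
    report$stages$knn <- "skipped"
  }

  if ("lstm" %in% config$stages) {
    x_tr <- as.matrix(train_s$sensor[, LSTM_INPUTS])
    x_te <- as.matrix(test_s$sensor[, LSTM_INPUTS])
    sc <- scale_channels(x_tr)
    x_te_sc <- scale_channels(x_te, sc$stats)$scaled
    w <- config$lstm_window
    y_gct <- cbind(as.integer(train_s$truth$contact_left),
                   as.integer(train_s$truth$contact_right))
    y_vgrf <- cbind(train_s$truth$force_left_bw, train_s$truth$force_right_bw)
    m_gct <- train_curve_model(
      make_sequences(sc$scaled, y_gct, w),
      lstm_spec("gct", hidden = config$lstm_hidden, epochs = config$lstm_epochs,
                batch_size = config$lstm_batch, window = w, seed = seed + 21L))
    m_vgrf <- train_curve_model(
      make_sequences(sc$scaled, y_vgrf, w),
      lstm_spec("vgrf", hidden = config$lstm_hidden, epochs = config$lstm_epochs,
                batch_size = config$lstm_batch, window = w, seed = seed + 22L))
    lab <- binarize_labels(predict_curves(m_gct, x_te_sc))
    pf <- predict_curves(m_vgrf, x_te_sc)
    keep <- w:nrow(x_te)
    truth_lab <- cbind(as.integer(test_s$truth$contact_left),
                       as.integer(test_s$truth$contact_right))[keep, ]
    truth_f <- cbind(test_s$truth$force_left_bw,
                     test_s$truth$force_right_bw)[keep, ]
    report$lstm <- list(
      gct_accuracy = c(left = label_accuracy(lab[, 1L], truth_lab[, 1L]),
                       right = label_accuracy(lab[, 2L], truth_lab[, 2L])),
      vgrf_nrmse = c(left = nrmse(pf[, 1L], truth_f[, 1L]),
                     right = nrmse(pf[, 2L], truth_f[, 2L])),
      swing_zero_frac = c(left = mean(pf[truth_f[, 1L] == 0, 1L] == 0),
                          right = mean(pf[truth_f[, 2L] == 0, 2L] == 0)),
      loss_initial = c(gct = m_gct$loss_initial, vgrf = m_vgrf$loss_initial),
      loss_final = c(gct = m_gct$loss_final, vgrf = m_vgrf$loss_final))
    report$stages$lstm <- "run"
  } else {
    report$stages$lstm <- "skipped"
  }

  report$elapsed_s <- as.numeric(Sys.time() - t_all, units = "secs")
  class(report) <- "gait_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

report_numbers <- function(report) {
  out <- list(segmentation = report$segmentation,
              kept_features = report$selection$kept_features,
              dropped_targets = report$selection$dropped_targets,
              stages = report$stages)
  if (!is.null(report$param_nrmse)) out$param_nrmse <- report$param_nrmse
  if (!is.null(report$knn_nrmse)) out$knn_nrmse <- as.list(report$knn_nrmse)
  if (!is.null(report$lstm)) out$lstm <- lapply(report$lstm, as.list)
  out
}

write_report <- function(report, out_dir) {
  run_dir <- file.path(out_dir,
                       format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_numbers(report),
                       file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(run_dir)
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  cat(sprintf("  segmentation: %d/%d strides, median boundary error %.1f ms\n",
              x$segmentation$n_detected, x$segmentation$n_true,
              x$segmentation$median_boundary_error_ms))
  cat(sprintf("  selection: %d features kept (%s)\n",
              length(x$selection$kept_features),
              paste(x$selection$kept_features, collapse = ", ")))
  if (length(x$selection$dropped_targets))
    cat("  dropped targets:",
        paste(x$selection$dropped_targets, collapse = ", "), "\n")
  if (!is.null(x$param_nrmse)) {
    cat("  held-out NRMSE (%) per target:\n")
    print(x$param_nrmse, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$knn_nrmse))
    cat(sprintf("  KNN session NRMSE: left %.2f%%, right %.2f%%\n",
                x$knn_nrmse[["vgrfL"]], x$knn_nrmse[["vgrfR"]]))
  if (!is.null(x$lstm)) {
    cat(sprintf("  LSTM GCT accuracy: left %.2f%%, right %.2f%%\n",
                x$lstm$gct_accuracy[["left"]], x$lstm$gct_accuracy[["right"]]))
    cat(sprintf("  LSTM vGRF NRMSE: left %.2f%%, right %.2f%%; swing-zero %.0f%%/%.0f%%\n",
                x$lstm$vgrf_nrmse[["left"]], x$lstm$vgrf_nrmse[["right"]],
                100 * x$lstm$swing_zero_frac[["left"]],
                100 * x$lstm$swing_zero_frac[["right"]]))
  }
  for (st in names(x$stages)) if (x$stages[[st]] == "skipped")
    cat(sprintf("  stage %s: skipped\n", st))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
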