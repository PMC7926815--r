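# Bagged regression-tree models for the per-stride gait parameters, with
# body-weight normalization of force-like targets, and the NRMSE metric.

FORCE_TARGETS <- c("peak_vgrfL", "peak_vgrfR", "impulseL", "impulseR")

#' Configuration of a bagged-tree gait parameter model
#'
#' Three input modes are supported: `six_optimal` (the features retained by
#' the correlation-based selection, passed via `selected_features`), `pca6`
#' (principal components of the selected features, `pca_components` of them)
#' and `all27` (every input feature). Trees are grown with a minimum leaf
#' size of 8 and bagged over 30 bootstrap learners by default; bagging uses
#' resampling with replacement at bag fraction 1 and all features available
#' at every split.
#'
#' @param input_mode one of `"six_optimal"`, `"pca6"`, `"all27"`
#' @param min_leaf_size minimum observations per tree leaf
#' @param n_learners number of bagged trees per target
#' @param seed integer RNG seed (reproducible ensembles)
#' @param pca_components number of principal components in `pca6` mode
#' @param selected_features character vector of feature names for
#'   `six_optimal`/`pca6` modes (e.g. `kept_features` of a selection report)
#' @return object of class `regression_config`
#' @export
regression_config <- function(input_mode = c("six_optimal", "pca6", "all27"),
                              min_leaf_size = 8L, n_learners = 30L, seed = 1L,
                              pca_components = 6L, selected_features = NULL) {
  input_mode <- match.arg(input_mode)
  stopifnot(min_leaf_size >= 1L, n_learners >= 1L, pca_components >= 1L)
  if (input_mode %in% c("six_optimal", "pca6") && is.null(selected_features))
    stopf("input_mode '%s' needs selected_features", input_mode)
  structure(list(input_mode = input_mode,
                 min_leaf_size = as.integer(min_leaf_size),
                 n_learners = as.integer(n_learners),
                 seed = as.integer(seed),
                 pca_components = as.integer(pca_components),
                 selected_features = selected_features),
            class = "regression_config")
}

#' Train bagged-tree models for gait parameter targets
#'
#' Fits one bagged ensemble of regression trees per target column. Force-like
#' targets (peak vGRFs and impulses) are divided by the subject's body weight
#' in newtons (`body_weight * g`) before fitting, so the models transfer
#' across subjects; [predict.gait_model_bundle()] multiplies them back by the
#' query subject's weight. Time targets are fitted unchanged.
#'
#' @param features data.frame of per-stride input features
#' @param targets data.frame of target parameters, row-aligned; defaults to
#'   training every supplied column
#' @param config a [regression_config()]
#' @param body_weight training subject mass, kg
#' @return object of class `gait_model_bundle`
#' @export
train_gait_models <- function(features, targets, config, body_weight) {
  stopifnot(inherits(config, "regression_config"), body_weight > 0)
  if (nrow(features) != nrow(targets))
    stopf("features and targets must be row-aligned")
  if (nrow(features) < 50L)
    stopf("need at least 50 strides to train (got %d)", nrow(features))

  input_names <- switch(config$input_mode,
    six_optimal = config$selected_features,
    pca6 = config$selected_features,
    all27 = colnames(features))
  miss <- setdiff(input_names, colnames(features))
  if (length(miss))
    stopf("config error: missing feature column(s): %s",
          paste(miss, collapse = ", "))
  x <- features[, input_names, drop = FALSE]

  pca <- NULL
  if (config$input_mode == "pca6") {
    pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    k <- min(config$pca_components, ncol(pca$x))
    pca$rotation <- pca$rotation[, seq_len(k), drop = FALSE]
    pca$x <- pca$x[, seq_len(k), drop = FALSE]
    x <- as.data.frame(pca$x)
  }

  bw_n <- body_weight * GRAVITY
  normalized <- colnames(targets) %in% FORCE_TARGETS
  names(normalized) <- colnames(targets)

  ctrl <- rpart::rpart.control(minbucket = config$min_leaf_size,
                               minsplit = 2L * config$min_leaf_size,
                               cp = 0, xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  n <- nrow(x)
  models <- vector("list", ncol(targets))
  names(models) <- colnames(targets)
  set.seed(config$seed)
  for (tn in colnames(targets)) {
    y <- targets[[tn]]
    if (anyNA(y)) stopf("config error: target %s contains NA", tn)
    if (normalized[[tn]]) y <- y / bw_n
    dat <- cbind(x, .y = y)
    models[[tn]] <- lapply(seq_len(config$n_learners), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE], control = ctrl)
    })
  }
  structure(list(models = models, input_features = input_names, pca = pca,
                 config = config, train_bw = body_weight,
                 normalized = normalized),
            class = "gait_model_bundle")
}

#' Predict gait parameters from a fitted bundle
#'
#' Ensemble predictions are the mean of the bagged learners. Body-weight
#' normalized targets are re-multiplied by the query subject's weight in
#' newtons; time targets pass through unchanged.
#'
#' @param object a `gait_model_bundle`
#' @param features data.frame containing the bundle's input features
#' @param body_weight query subject mass, kg
#' @param ... unused
#' @return data.frame of per-stride predictions, one column per target
#' @export
predict.gait_model_bundle <- function(object, features, body_weight, ...) {
  miss <- setdiff(object$input_features, colnames(features))
  if (length(miss))
    stopf("schema error: missing feature column(s): %s",
          paste(miss, collapse = ", "))
  x <- features[, object$input_features, drop = FALSE]
  if (!is.null(object$pca))
    x <- as.data.frame(stats::predict(object$pca, x)[,
           seq_len(ncol(object$pca$rotation)), drop = FALSE])
  bw_n <- body_weight * GRAVITY
  out <- lapply(names(object$models), function(tn) {
    preds <- vapply(object$models[[tn]],
                    function(m) stats::predict(m, x), numeric(nrow(x)))
    p <- if (is.matrix(preds)) rowMeans(preds) else mean(preds)
    if (object$normalized[[tn]]) p <- p * bw_n
    p
  })
  names(out) <- names(object$models)
  as.data.frame(out)
}

#' Normalized root-mean-square error, in percent
#'
#' `100 * RMSE(pred, ref) / mean(ref)` by default (so at a reference mean of
#' 2.5 xBW, an NRMSE of 2.7 percent corresponds to an absolute error of
#' 0.0675 xBW); `normalizer = "range"` divides by `max(ref) - min(ref)`
#' instead.
#'
#' @param pred,ref equal-length numeric vectors
#' @param normalizer `"mean"` (default) or `"range"`
#' @return NRMSE in percent
#' @export
nrmse <- function(pred, ref, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  if (length(pred) != length(ref) || !length(ref))
    stopf("pred and ref must have equal positive length")
  denom <- if (normalizer == "mean") mean(ref) else diff(range(ref))
  if (denom == 0) stopf("undefined metric: reference %s is zero", normalizer)
  100 * sqrt(mean((pred - ref)^2)) / denom
}
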