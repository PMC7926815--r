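# Two-stage correlation-based feature and target pruning:
# (1) of any feature pair with absolute Pearson correlation above 0.9, the
#     later one in canonical order is dropped;
# (2) features whose absolute correlation with every target is at most 0.3
#     are dropped, then targets weakly correlated (<= 0.3) with all surviving
#     features are dropped.

#' Pearson correlation matrix across stride variables
#'
#' Symmetric with unit diagonal. Constant columns (undefined correlation) are
#' flagged with a warning and treated as correlation 0 against every other
#' variable.
#'
#' @param table data.frame or matrix, strides x variables, >= 3 rows
#' @return correlation matrix
#' @export
correlation_matrix <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 3L) stopf("need at least 3 strides to correlate")
  const <- apply(x, 2, function(col) stats::sd(col) == 0 || !is.finite(stats::sd(col)))
  if (any(const))
    warnf("constant column(s) treated as correlation 0: %s",
          paste(colnames(x)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

new_selection_report <- function(kept_features, dropped, dropped_targets,
                                 kept_targets, cor_ff = NULL, cor_ft = NULL) {
  structure(list(kept_features = kept_features,
                 dropped_features = dropped,
                 dropped_targets = dropped_targets,
                 kept_targets = kept_targets,
                 cor_features = cor_ff, cor_feature_target = cor_ft),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d features kept, %d dropped; %d targets dropped\n",
              length(x$kept_features), nrow(x$dropped_features),
              length(x$dropped_targets)))
  if (length(x$kept_features))
    cat("  kept:", paste(x$kept_features, collapse = ", "), "\n")
  if (nrow(x$dropped_features))
    for (r in unique(x$dropped_features$reason))
      cat(sprintf("  dropped (%s): %s\n", r,
                  paste(x$dropped_features$name[x$dropped_features$reason == r],
                        collapse = ", ")))
  if (length(x$dropped_targets))
    cat("  dropped targets:", paste(x$dropped_targets, collapse = ", "), "\n")
  invisible(x)
}

#' Drop intercorrelated input features (stage 1)
#'
#' Scans feature pairs in canonical (column) order; whenever a surviving pair
#' has `|r| > threshold`, the later-listed member is dropped. No surviving
#' pair exceeds the threshold afterwards.
#'
#' @param features data.frame of per-stride input features
#' @param threshold absolute-correlation cut, default 0.9 (strict inequality)
#' @return a `selection_report`
#' @export
prune_intercorrelated <- function(features, threshold = 0.9) {
  r <- correlation_matrix(features)
  nm <- colnames(features)
  kept <- rep(TRUE, length(nm))
  for (i in seq_along(nm)) {
    if (!kept[i]) next
    for (j in seq_along(nm)) {
      if (j <= i || !kept[j]) next
      if (abs(r[i, j]) > threshold) kept[j] <- FALSE
    }
  }
  dropped <- data.frame(name = nm[!kept],
                        reason = rep("intercorrelated", sum(!kept)),
                        stringsAsFactors = FALSE)
  new_selection_report(nm[kept], dropped, character(0), character(0),
                       cor_ff = r)
}

#' Drop weakly target-correlated features, then orphan targets (stage 2)
#'
#' A feature is dropped when its absolute correlation with *every* target is
#' at most `threshold`; afterwards a target is dropped when its absolute
#' correlation with every surviving feature is at most `threshold`.
#'
#' @param features data.frame of features already pruned for intercorrelation
#' @param targets data.frame of target parameters, row-aligned with features
#' @param threshold weak-correlation cut, default 0.3 (inclusive)
#' @return a `selection_report`
#' @export
prune_weak <- function(features, targets, threshold = 0.3) {
  if (nrow(features) != nrow(targets))
    stopf("features and targets must be row-aligned")
  r <- correlation_matrix(cbind(features, targets))
  fn <- colnames(features); tn <- colnames(targets)
  ft <- r[fn, tn, drop = FALSE]
  keep_f <- apply(abs(ft), 1, max) > threshold
  if (!any(keep_f))
    stopf("selection failure: no feature correlates with any target above %.2f",
          threshold)
  keep_t <- apply(abs(ft[keep_f, , drop = FALSE]), 2, max) > threshold
  dropped <- data.frame(name = fn[!keep_f],
                        reason = rep("weak-target-correlation", sum(!keep_f)),
                        stringsAsFactors = FALSE)
  new_selection_report(fn[keep_f], dropped, tn[!keep_t], tn[keep_t],
                       cor_ft = ft)
}

#' Two-stage correlation-based selection
#'
#' Runs [prune_intercorrelated()] then [prune_weak()] and merges the reports.
#'
#' @inheritParams prune_weak
#' @param r_features stage-1 threshold (default 0.9)
#' @param r_targets stage-2 threshold (default 0.3)
#' @return a `selection_report`
#' @export
select_features <- function(features, targets, r_features = 0.9,
                            r_targets = 0.3) {
  s1 <- prune_intercorrelated(features, r_features)
  s2 <- prune_weak(features[, s1$kept_features, drop = FALSE], targets,
                   r_targets)
  new_selection_report(
    s2$kept_features,
    rbind(s1$dropped_features, s2$dropped_features),
    s2$dropped_targets, s2$kept_targets,
    cor_ff = s1$cor_features, cor_ft = s2$cor_feature_target)
}
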