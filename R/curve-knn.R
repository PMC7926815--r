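# K-nearest-neighbor vGRF curve synthesis: per-foot libraries of
# body-weight-normalized stride curves on a normalized-time grid, indexed by
# time-parameter key vectors (left foot: stride duration, TOL, GCTL; right
# foot: stride duration, GCTR), queried by Euclidean distance.

#' Build a per-foot library of normalized vGRF stride curves
#'
#' Each training stride's per-foot force is divided by body weight (in
#' newtons) and resampled onto a common normalized-time grid covering 0-100%
#' of the stride. Key vectors are taken from the stride's target parameters:
#' `(stride_duration, TOL, GCTL)` for the left foot and
#' `(stride_duration, GCTR)` for the right (touch-down of the left foot and
#' right toe-off are excluded, being poorly predictable; peak vGRF is
#' excluded for living on a different scale than the time parameters).
#' Zero-contact strides are excluded with a warning.
#'
#' @param insole_slices list of per-stride insole slices (data.frames with
#'   `t`, `vgrf_left`, `vgrf_right`; `t` relative to stride start)
#' @param targets row-aligned data.frame holding `GCTL`, `TOL`, `GCTR`
#' @param stride_durations per-stride durations, s
#' @param body_weight training subject mass, kg
#' @param grid_length number of normalized-time grid points (default 101)
#' @return object of class `curve_library`
#' @export
build_curve_library <- function(insole_slices, targets, stride_durations,
                                body_weight, grid_length = 101L) {
  n <- length(insole_slices)
  stopifnot(n >= 1L, nrow(targets) == n, length(stride_durations) == n,
            body_weight > 0, grid_length >= 2L)
  bw_n <- body_weight * GRAVITY
  grid <- seq(0, 1, length.out = grid_length)
  resample <- function(slice, col, dur) {
    u <- (slice$t - slice$t[1L]) / dur
    stats::approx(u, slice[[col]] / bw_n, xout = grid, rule = 2)$y
  }
  ok_l <- !is.na(targets$TOL) & targets$GCTL > 0
  ok_r <- !is.na(targets$TDR) & targets$GCTR > 0
  if (any(!ok_l | !ok_r))
    warnf("excluding %d zero-contact stride(s) from the curve library",
          sum(!ok_l | !ok_r))
  curves_l <- t(vapply(which(ok_l), function(i)
    resample(insole_slices[[i]], "vgrf_left", stride_durations[i]),
    numeric(grid_length)))
  curves_r <- t(vapply(which(ok_r), function(i)
    resample(insole_slices[[i]], "vgrf_right", stride_durations[i]),
    numeric(grid_length)))
  keys_l <- cbind(stride_duration = stride_durations[ok_l],
                  TOL = targets$TOL[ok_l], GCTL = targets$GCTL[ok_l])
  keys_r <- cbind(stride_duration = stride_durations[ok_r],
                  GCTR = targets$GCTR[ok_r])
  structure(list(
    left = list(curves = curves_l, keys = keys_l, ids = which(ok_l)),
    right = list(curves = curves_r, keys = keys_r, ids = which(ok_r)),
    grid = grid, body_weight = body_weight),
    class = "curve_library")
}

#' @export
print.curve_library <- function(x, ...) {
  cat(sprintf("<curve_library> %d left / %d right strides, %d-point grid\n",
              nrow(x$left$curves), nrow(x$right$curves), length(x$grid)))
  invisible(x)
}

# ---- neighbor search ---------------------------------------------------------

# Exhaustive K nearest rows of `keys` to `query` (Euclidean); ties broken by
# row index. The correctness oracle for the kd-tree route.
knn_exhaustive <- function(keys, query, k) {
  d2 <- colSums((t(keys) - query)^2)
  order(d2, seq_len(nrow(keys)))[seq_len(k)]
}

# Minimal kd-tree over the key rows; splits cycle through dimensions at the
# median. Search is branch-and-bound with (distance, index) lexicographic
# tie-breaking so results match the exhaustive route exactly.
kdtree_build <- function(keys, idx = seq_len(nrow(keys)), depth = 0L) {
  if (!length(idx)) return(NULL)
  if (length(idx) <= 8L) return(list(leaf = TRUE, idx = idx))
  dim <- depth %% ncol(keys) + 1L
  ord <- idx[order(keys[idx, dim], idx)]
  m <- (length(ord) + 1L) %/% 2L
  list(leaf = FALSE, dim = dim, split = keys[ord[m], dim],
       left = kdtree_build(keys, ord[seq_len(m)], depth + 1L),
       right = kdtree_build(keys, ord[-seq_len(m)], depth + 1L))
}

kdtree_search <- function(tree, keys, query, k) {
  best_d2 <- rep(Inf, k); best_i <- rep(NA_integer_, k)
  consider <- function(i) {
    d2 <- sum((keys[i, ] - query)^2)
    w <- k  # position of the current worst
    if (d2 > best_d2[w] || (d2 == best_d2[w] && !is.na(best_i[w]) && i > best_i[w]))
      return(invisible())
    # insert keeping (d2, index) lexicographic order
    pos <- which(d2 < best_d2 | (d2 == best_d2 & (is.na(best_i) | i < best_i)))[1L]
    if (is.na(pos)) return(invisible())
    if (pos < k) {
      best_d2[(pos + 1L):k] <<- best_d2[pos:(k - 1L)]
      best_i[(pos + 1L):k] <<- best_i[pos:(k - 1L)]
    }
    best_d2[pos] <<- d2; best_i[pos] <<- i
  }
  recurse <- function(node) {
    if (is.null(node)) return(invisible())
    if (node$leaf) {
      for (i in node$idx) consider(i)
      return(invisible())
    }
    near_first <- query[node$dim] <= node$split
    first <- if (near_first) node$left else node$right
    second <- if (near_first) node$right else node$left
    recurse(first)
    if ((query[node$dim] - node$split)^2 <= best_d2[k] || anyNA(best_i))
      recurse(second)
  }
  recurse(tree)
  best_i
}

#' Query the curve library: averaged K-nearest-neighbor stride curves
#'
#' For each query key vector, finds the `K` most similar training strides by
#' Euclidean distance in the foot's time-parameter space and returns the
#' pointwise mean of their normalized curves on the library grid.
#'
#' @param library a [build_curve_library()] result
#' @param keys matrix/data.frame of query key vectors (columns as the foot's
#'   library keys)
#' @param foot `"left"` or `"right"`
#' @param k neighbor count, default 8; clamped (with a warning) to the
#'   library size
#' @param method `"exhaustive"` (reference) or `"kdtree"` (accelerated;
#'   identical results)
#' @return matrix, queries x grid points, of xBW curves; attribute
#'   `neighbors` holds the selected stride indices
#' @export
query_curves <- function(library, keys, foot = c("left", "right"), k = 8L,
                         method = c("exhaustive", "kdtree")) {
  foot <- match.arg(foot); method <- match.arg(method)
  side <- library[[foot]]
  n_lib <- nrow(side$curves)
  if (!n_lib) stopf("empty curve library for the %s foot", foot)
  keys <- as.matrix(keys)
  if (ncol(keys) != ncol(side$keys))
    stopf("query keys need %d columns (%s)", ncol(side$keys),
          paste(colnames(side$keys), collapse = ", "))
  if (anyNA(keys) || any(!is.finite(keys))) stopf("query keys must be finite")
  if (k < 1L) stopf("k must be at least 1")
  if (k > n_lib) {
    warnf("k = %d exceeds library size %d; clamping", k, n_lib)
    k <- n_lib
  }
  tree <- if (method == "kdtree") kdtree_build(side$keys) else NULL
  nb <- matrix(NA_integer_, nrow(keys), k)
  out <- matrix(0, nrow(keys), ncol(side$curves))
  for (q in seq_len(nrow(keys))) {
    idx <- if (method == "exhaustive") {
      knn_exhaustive(side$keys, keys[q, ], k)
    } else {
      kdtree_search(tree, side$keys, keys[q, ], k)
    }
    nb[q, ] <- idx
    out[q, ] <- colMeans(side$curves[idx, , drop = FALSE])
  }
  attr(out, "neighbors") <- nb
  out
}

#' Assemble per-stride curves into a continuous session curve
#'
#' Warps each stride's normalized-grid curve to its stride duration, converts
#' from xBW to newtons, and places it on the sensor-rate session grid; samples
#' outside any stride are zero.
#'
#' @param stride_curves matrix (strides x grid) of xBW curves, as returned by
#'   [query_curves()]
#' @param strides a `stride_table` (0-based half-open indices)
#' @param body_weight query subject mass, kg (NULL keeps xBW units)
#' @param fs_sensor sensor rate, Hz
#' @param n_samples output length; defaults to the last stride's end
#' @return numeric vector: the continuous per-foot force curve
#' @export
assemble_continuous <- function(stride_curves, strides, body_weight = NULL,
                                fs_sensor = 400, n_samples = NULL) {
  stopifnot(nrow(stride_curves) == nrow(strides))
  if (nrow(strides) > 1L &&
      any(strides$start_idx[-1L] < strides$end_idx[-nrow(strides)]))
    stopf("assembly error: overlapping strides")
  n_samples <- n_samples %||% max(strides$end_idx)
  out <- numeric(n_samples)
  grid <- seq(0, 1, length.out = ncol(stride_curves))
  scale <- if (is.null(body_weight)) 1 else body_weight * GRAVITY
  for (i in seq_len(nrow(strides))) {
    rows <- (strides$start_idx[i] + 1L):min(strides$end_idx[i], n_samples)
    u <- (seq_along(rows) - 1L) / (length(rows))
    out[rows] <- stats::approx(grid, stride_curves[i, ], xout = u,
                               rule = 2)$y * scale
  }
  out
}
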