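#' @title Feature weights and subspaces
#' @description Selector outputs are `feature_weights` objects (a score per
#'   column plus the method tag and its orientation) and `feature_subspace`
#'   objects (an ordered set of selected column indices).
#' @param weights Numeric vector of per-column scores, all finite.
#' @param method Tag: `"variance"`, `"fisher"`, `"laplacian"` or `"jlfwl"`.
#' @param higher_is_better Orientation of the score (`FALSE` for the
#'   Laplacian score, where smaller means more locality-preserving).
#' @return A `feature_weights` object.
#' @export
new_feature_weights <- function(weights, method, higher_is_better = TRUE) {
  stopifnot(is.numeric(weights), all(is.finite(weights)))
  weights <- as.numeric(unname(weights))
  structure(list(weights = weights, method = method,
                 higher_is_better = higher_is_better),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights: %s over %d columns (%s is better)>\n",
              x$method, length(x$weights),
              if (x$higher_is_better) "higher" else "lower"))
  invisible(x)
}

#' @export
tidy.feature_weights <- function(x, ...) {
  tibble::tibble(column = seq_along(x$weights), weight = x$weights,
                 method = x$method)
}

new_feature_subspace <- function(indices, method) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, k = length(indices), method = method),
            class = "feature_subspace")
}

#' @export
print.feature_subspace <- function(x, ...) {
  cat(sprintf("<feature_subspace: %d columns via %s>\n", x$k, x$method))
  invisible(x)
}

as_feature_mat <- function(X) {
  if (inherits(X, "feature_matrix")) X$x else as.matrix(X)
}

feature_labels <- function(X, y = NULL) {
  if (!is.null(y)) return(as.integer(y))
  if (inherits(X, "feature_matrix") && !is.null(X$labels)) return(X$labels)
  abort("labels are required but absent", class = "vitabind_label_error")
}

# A large finite sentinel used where a degenerate 0/0 score must be forced to
# the worst (or, for Fisher perfect separators, the best) rank while keeping
# every weight finite.
WORST_SENTINEL <- 1e300

#' Per-column data variance
#'
#' Sample variance (denominator M - 1) of every feature column; an
#' unsupervised relevance score where larger spread ranks higher.
#'
#' @param X A `feature_matrix` or numeric matrix with at least 2 rows.
#' @return A `feature_weights` object with `higher_is_better = TRUE`.
#' @export
variance_score <- function(X) {
  x <- as_feature_mat(X)
  if (nrow(x) < 2) {
    abort("variance requires at least 2 samples", class = "vitabind_input_error")
  }
  new_feature_weights(apply(x, 2, var), "variance", higher_is_better = TRUE)
}

#' Two-class Fisher score
#'
#' For feature j with class means mu_cj, biased within-class variances
#' s2_cj and class sizes n_c, the score is
#' sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c s2_cj. Columns that are constant
#' within each class but separate the classes receive a large finite
#' sentinel so that perfect separators outrank every finite-scored column;
#' columns with neither spread nor separation score 0.
#'
#' @param X A labelled `feature_matrix`, or numeric matrix.
#' @param y Optional 0/1 labels (taken from `X` when omitted).
#' @return A `feature_weights` object with `higher_is_better = TRUE`.
#' @export
fisher_score <- function(X, y = NULL) {
  x <- as_feature_mat(X)
  y <- feature_labels(X, y)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    abort("Fisher score requires both classes", class = "vitabind_label_error")
  }
  mu <- colMeans(x)
  num <- den <- numeric(ncol(x))
  for (cl in classes) {
    xc <- x[y == cl, , drop = FALSE]
    nc <- nrow(xc)
    muc <- colMeans(xc)
    s2c <- colMeans(sweep(xc, 2, muc)^2)    # biased per-class variance
    num <- num + nc * (muc - mu)^2
    den <- den + nc * s2c
  }
  w <- ifelse(den > 0, num / den,
              ifelse(num > 0, pmin(num / .Machine$double.eps, WORST_SENTINEL), 0))
  new_feature_weights(w, "fisher", higher_is_better = TRUE)
}

# kNN heat-kernel similarity graph. Neighbours are the knn nearest other
# samples by Euclidean distance, ties broken by lower index; the graph is
# symmetrised by union. heat_t defaults to the mean squared pairwise distance.
knn_similarity <- function(x, knn, heat_t = NULL) {
  m <- nrow(x)
  if (knn >= m || knn < 1) {
    abort("knn must satisfy 1 <= knn < number of samples",
          class = "vitabind_input_error")
  }
  rs <- rowSums(x^2)
  d2 <- outer(rs, rep(1, m)) + outer(rep(1, m), rs) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0   # floating-point cancellation guard
  diag(d2) <- 0
  if (is.null(heat_t)) {
    heat_t <- mean(d2[upper.tri(d2)])
    if (!is.finite(heat_t) || heat_t <= 0) heat_t <- 1
  }
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    ord <- order(d2[i, ], seq_len(m))
    ord <- ord[ord != i]
    adj[i, ord[seq_len(knn)]] <- TRUE
  }
  adj <- adj | t(adj)
  s <- exp(-d2 / heat_t) * adj
  diag(s) <- 0
  s
}

laplacian_scores_from_graph <- function(x, s) {
  dvec <- rowSums(s)
  dsum <- sum(dvec)
  wmean <- colSums(x * dvec) / dsum
  fc <- sweep(x, 2, wmean)          # mean-centred under the degree measure
  num <- colSums(fc * (dvec * fc - s %*% fc))   # t(f~) (D - S) f~, all columns
  den <- colSums(fc^2 * dvec)
  degenerate <- den <= .Machine$double.eps * pmax(1, colSums(x^2))
  # constant features carry no locality information: worst rank;
  # clamp tiny negative values from floating-point cancellation
  ifelse(degenerate, WORST_SENTINEL, pmax(num / den, 0))
}

#' Laplacian score
#'
#' Builds a kNN heat-kernel similarity graph S over the samples, with degree
#' matrix D and Laplacian L = D - S, and scores each feature f by
#' t(f~) L f~ / t(f~) D f~ where f~ is f mean-centred under the degree
#' measure. Lower scores indicate features that better preserve the local
#' sample geometry, so `higher_is_better = FALSE`. Constant features, which
#' carry no locality information, receive a large finite sentinel (worst
#' rank).
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param knn Number of nearest neighbours for the graph (default 5).
#' @param heat_t Heat-kernel width; defaults to the mean squared pairwise
#'   distance.
#' @return A `feature_weights` object with `higher_is_better = FALSE`.
#' @export
laplacian_score <- function(X, knn = 5, heat_t = NULL) {
  x <- as_feature_mat(X)
  s <- knn_similarity(x, knn, heat_t)
  new_feature_weights(laplacian_scores_from_graph(x, s), "laplacian",
                      higher_is_better = FALSE)
}

#' Joint Laplacian feature-weights learning with automatic subspace sizing
#'
#' Learns nonnegative feature weights jointly rather than feature-by-feature:
#' starting from uniform weights, each iteration (i) builds a kNN heat-kernel
#' graph over the samples in the currently weighted feature metric, (ii)
#' rescores every feature by its Laplacian locality score under that graph,
#' and (iii) proposes new weights w_j proportional to max(0, 1 - score_j).
#' A proposal is accepted only while the weighted mean locality objective
#' sum_j w_j * score_j / sum_j w_j decreases, so the recorded objective trace
#' is non-increasing by construction; on non-convergence within `max_iter`
#' the best iterate is returned with `converged = FALSE` rather than an
#' error. The sparsity parameter `epsilon` then soft-thresholds the converged
#' weights at `epsilon * mean(w)`, driving small weights to exact zero; the
#' subspace is the set of columns with positive thresholded weight, so its
#' size is determined automatically (and is non-increasing in `epsilon`)
#' rather than supplied by the user. The procedure involves no randomness, so
#' results are bit-reproducible for fixed inputs.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param epsilon Sparsity control, >= 0; default 0.5.
#' @param knn Graph neighbourhood size (default 5).
#' @param max_iter Maximum joint-reweighting iterations (default 10).
#' @param tol Minimum objective decrease to continue iterating.
#' @return A list with `weights` (a `feature_weights` object over the
#'   thresholded weights), `subspace` (a `feature_subspace`), `converged`,
#'   `iterations` and `objective` (the accepted-objective trace).
#' @export
jlfwl <- function(X, epsilon = 0.5, knn = 5, max_iter = 10, tol = 1e-4) {
  x <- as_feature_mat(X)
  if (nrow(x) < 2) {
    abort("jlfwl requires at least 2 samples", class = "vitabind_input_error")
  }
  if (epsilon < 0) {
    abort("epsilon must be >= 0", class = "vitabind_input_error")
  }
  # standardise columns so the weighted metric is scale-free; zero-spread
  # columns stay identically zero and drop out of the graph metric
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  xs <- sweep(x, 2, mu)
  pos <- sdv > 0
  xs[, pos] <- sweep(xs[, pos, drop = FALSE], 2, sdv[pos], "/")

  w <- rep(1, ncol(x))
  graph_scores <- function(wv) {
    xw <- sweep(xs, 2, sqrt(wv), "*")
    s <- knn_similarity(xw, knn)
    laplacian_scores_from_graph(xs, s)
  }
  scores <- graph_scores(w)
  objective <- sum(w * pmin(scores, 2)) / sum(w)
  trace <- objective
  best_w <- w
  converged <- FALSE
  iterations <- 0
  for (it in seq_len(max_iter)) {
    w_new <- pmax(0, 1 - scores)
    if (max(w_new) <= 0) { converged <- TRUE; break }
    w_new <- w_new / max(w_new)
    scores_new <- graph_scores(w_new)
    obj_new <- sum(w_new * pmin(scores_new, 2)) / sum(w_new)
    if (obj_new < objective - tol) {
      w <- w_new; scores <- scores_new; objective <- obj_new
      best_w <- w; trace <- c(trace, obj_new)
      iterations <- it
    } else {
      converged <- TRUE
      break
    }
  }
  w_final <- pmax(0, best_w - epsilon * mean(best_w))
  selected <- which(w_final > 1e-12)
  list(weights = new_feature_weights(w_final, "jlfwl", higher_is_better = TRUE),
       subspace = new_feature_subspace(selected, "jlfwl"),
       converged = converged, iterations = iterations, objective = trace)
}

#' Select the top-k columns of a feature weighting
#'
#' @param weights A `feature_weights` object.
#' @param k Number of columns to keep, 1 <= k <= D.
#' @return A `feature_subspace` with the k best columns under the method's
#'   orientation; score ties are broken in favour of the lower column index.
#' @export
select_top_k <- function(weights, k) {
  stopifnot(inherits(weights, "feature_weights"))
  d <- length(weights$weights)
  if (k < 1 || k > d) {
    abort(sprintf("k must lie in [1, %d]", d), class = "vitabind_input_error")
  }
  key <- if (weights$higher_is_better) -weights$weights else weights$weights
  ord <- order(key, seq_len(d))
  new_feature_subspace(ord[seq_len(k)], weights$method)
}
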