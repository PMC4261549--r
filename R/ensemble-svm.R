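#' @title Heterogeneous subspace SVM ensemble
#' @description One C-SVM with a radial-basis kernel is trained per selected
#'   feature subspace; the ensemble score of a residue is the unweighted mean
#'   of the members' calibrated scores, and a decision threshold turns scores
#'   into binary calls.
#' @name ensemble_svm
NULL

# Fit an RBF C-SVM and a Platt-style logistic calibration of its decision
# values, so member scores are comparable probabilities in [0,1] before
# averaging. The calibration is fit in-package on the training decision
# values (deterministically), rather than through libsvm's internal
# cross-validated sigmoid fit, which shuffles with an unseeded RNG.
fit_rbf_svm <- function(x, y, cost, gamma) {
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(x = x, y = yf, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dv <- decision_values(fit, x)
  calib <- suppressWarnings(glm(y ~ dv, family = binomial()))
  list(svm = fit, calib = unname(stats::coef(calib)))
}

decision_values <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (identical(lab, "1")) dv[, 1] else -dv[, 1]
}

svm_scores <- function(model, x) {
  dv <- decision_values(model$svm, x)
  sc <- plogis(model$calib[1] + model$calib[2] * dv)
  pmin(pmax(sc, 0), 1)
}

#' Grid search for RBF C-SVM hyperparameters
#'
#' Evaluates every (cost, gamma) pair on an inner k-fold cross-validation of
#' the training data and returns the pair with the largest pooled inner-CV
#' AUC. Ties are broken towards the smaller cost and then the smaller gamma
#' (the smoother model). A 1 x 1 grid is returned directly without any inner
#' CV.
#'
#' @param x Numeric training matrix (already subspace-reduced).
#' @param y 0/1 labels.
#' @param C_grid,gamma_grid Candidate values; defaults follow the customary
#'   libsvm grid, coarsened: cost 2^(-5, -3, ..., 15), gamma 2^(-15, -13,
#'   ..., 3).
#' @param inner_folds Number of inner CV folds (default 3).
#' @param seed Seed for the inner fold assignment.
#' @return A list with `cost`, `gamma` and `auc` (inner-CV AUC, `NA` for a
#'   1 x 1 grid).
#' @export
grid_search_svm <- function(x, y, C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            inner_folds = 3, seed = 1) {
  if (length(unique(y)) < 2) {
    abort("grid search requires both classes", class = "vitabind_label_error")
  }
  if (length(C_grid) == 0 || length(gamma_grid) == 0) {
    abort("hyperparameter grids must be nonempty", class = "vitabind_input_error")
  }
  if (length(C_grid) == 1 && length(gamma_grid) == 1) {
    return(list(cost = C_grid, gamma = gamma_grid, auc = NA_real_))
  }
  folds <- withr::with_seed(seed, {
    f <- rep(seq_len(inner_folds), length.out = length(y))
    # stratified shuffle so every fold sees both classes when possible
    idx <- c(sample(which(y == 1)), sample(which(y == 0)))
    f[order(idx)] <- f
    f
  })
  grid <- expand.grid(cost = C_grid, gamma = gamma_grid)
  aucs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- numeric(length(y))
    ok <- TRUE
    for (k in seq_len(inner_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2) { ok <- FALSE; break }
      m <- fit_rbf_svm(x[tr, , drop = FALSE], y[tr], grid$cost[g], grid$gamma[g])
      sc[!tr] <- svm_scores(m, x[!tr, , drop = FALSE])
    }
    aucs[g] <- if (ok) roc_auc(sc, y) else -Inf
  }
  best <- order(-aucs, grid$cost, grid$gamma)[1]
  list(cost = grid$cost[best], gamma = grid$gamma[best], auc = aucs[best])
}

#' Train one subspace SVM
#'
#' Fits an RBF C-SVM on the subspace-restricted columns of the feature
#' matrix, with a logistic calibration mapping decision values to scores in
#' \[0,1\].
#'
#' @param X A labelled `feature_matrix` (or numeric matrix with `y`).
#' @param subspace A `feature_subspace` valid for `X`.
#' @param hyperparams List with `cost` and `gamma`, e.g. from
#'   [grid_search_svm()].
#' @param y Optional 0/1 labels.
#' @param seed Recorded in the training metadata (the fit itself is
#'   deterministic).
#' @return A `subspace_model` object.
#' @export
train_subspace_svm <- function(X, subspace, hyperparams, y = NULL, seed = 1) {
  x <- as_feature_mat(X)
  y <- feature_labels(X, y)
  if (length(unique(y)) < 2) {
    abort("training requires both classes", class = "vitabind_label_error")
  }
  stopifnot(inherits(subspace, "feature_subspace"))
  if (max(subspace$indices) > ncol(x)) {
    abort("subspace indices exceed feature dimension", class = "vitabind_input_error")
  }
  xr <- x[, subspace$indices, drop = FALSE]
  fit <- fit_rbf_svm(xr, y, hyperparams$cost, hyperparams$gamma)
  structure(list(subspace = subspace, svm = fit$svm, calib = fit$calib,
                 hyperparams = list(cost = hyperparams$cost, gamma = hyperparams$gamma),
                 training_meta = list(n_pos = sum(y == 1), n_neg = sum(y == 0),
                                      seed = seed)),
            class = "subspace_model")
}

#' @export
print.subspace_model <- function(x, ...) {
  cat(sprintf("<subspace_model: %s (k=%d), cost=%g gamma=%g, %d+/%d- training residues>\n",
              x$subspace$method, x$subspace$k, x$hyperparams$cost,
              x$hyperparams$gamma, x$training_meta$n_pos, x$training_meta$n_neg))
  invisible(x)
}

#' Score new residues with one subspace model
#'
#' @param model A `subspace_model`.
#' @param X A `feature_matrix` or numeric matrix with the full training
#'   feature dimension (the model applies its own subspace restriction).
#' @return Numeric scores in \[0,1\].
#' @export
score_model <- function(model, X) {
  x <- as_feature_mat(X)
  if (max(model$subspace$indices) > ncol(x)) {
    abort("feature dimension smaller than the model's subspace",
          class = "vitabind_input_error")
  }
  svm_scores(model, x[, model$subspace$indices, drop = FALSE])
}

resolve_selector <- function(X, selector, y, k, epsilon, knn, jlfwl_cache) {
  switch(selector,
    jlfwl = jlfwl_cache$subspace,
    fisher = select_top_k(fisher_score(X, y), k),
    laplacian = select_top_k(laplacian_score(X, knn = knn), k),
    variance = select_top_k(variance_score(X), k),
    abort(sprintf("unknown selector '%s'", selector), class = "vitabind_input_error")
  )
}

#' Train the heterogeneous subspace SVM ensemble
#'
#' Runs each requested feature selector on the training matrix, trains one
#' RBF C-SVM per selected subspace (with an optional inner grid search for
#' cost and gamma), and bundles the members into an ensemble whose prediction
#' is the unweighted mean of member scores. The subspace size for the
#' fixed-size selectors (variance, Fisher, Laplacian) defaults to the size
#' the joint Laplacian learner determines automatically on the same matrix,
#' mirroring the coupling used to set all subspaces to one common size.
#'
#' @param X A labelled `feature_matrix` (or numeric matrix plus `y`).
#' @param selectors Character vector from `c("jlfwl", "fisher", "laplacian",
#'   "variance")`; default the heterogeneous trio `jlfwl, fisher, laplacian`.
#'   Repeated selectors are allowed.
#' @param y Optional 0/1 labels.
#' @param k Subspace size for the fixed-size selectors; `NULL` (default)
#'   couples it to the jlfwl size.
#' @param epsilon Sparsity control for the joint learner (default 0.5).
#' @param knn Graph neighbourhood size for the Laplacian-based selectors.
#' @param C_grid,gamma_grid,inner_folds Hyperparameter search settings; pass
#'   length-1 grids to fix the hyperparameters without any inner CV.
#' @param seed Seed for the inner-CV fold assignment.
#' @return A `vita_ensemble` with unset threshold (see
#'   [calibrate_threshold()]).
#' @export
train_ensemble <- function(X, selectors = c("jlfwl", "fisher", "laplacian"),
                           y = NULL, k = NULL, epsilon = 0.5, knn = 5,
                           C_grid = 2^seq(-5, 15, 2), gamma_grid = 2^seq(-15, 3, 2),
                           inner_folds = 3, seed = 1) {
  if (length(selectors) < 1) {
    abort("at least one selector is required", class = "vitabind_input_error")
  }
  x <- as_feature_mat(X)
  y <- feature_labels(X, y)
  jl <- NULL
  if ("jlfwl" %in% selectors || is.null(k)) {
    jl <- jlfwl(x, epsilon = epsilon, knn = knn)
    if (jl$subspace$k == 0) {
      # epsilon pruned everything; fall back to the full space so downstream
      # members remain trainable
      jl$subspace <- new_feature_subspace(seq_len(ncol(x)), "jlfwl")
    }
  }
  if (is.null(k)) k <- jl$subspace$k
  members <- purrr::map(seq_along(selectors), function(i) {
    sub <- resolve_selector(x, selectors[i], y, k, epsilon, knn, jl)
    hp <- grid_search_svm(x[, sub$indices, drop = FALSE], y,
                          C_grid = C_grid, gamma_grid = gamma_grid,
                          inner_folds = inner_folds, seed = seed + i - 1)
    train_subspace_svm(x, sub, hp, y = y, seed = seed)
  })
  structure(list(members = members, selectors = selectors,
                 threshold = NA_real_, strategy = "none",
                 n_features = ncol(x), seed = seed),
            class = "vita_ensemble")
}

#' @export
print.vita_ensemble <- function(x, ...) {
  cat(sprintf("<vita_ensemble: %d member(s) [%s] over %d features; threshold %s (%s)>\n",
              length(x$members), paste(x$selectors, collapse = ", "),
              x$n_features,
              if (is.na(x$threshold)) "unset" else format(x$threshold),
              x$strategy))
  invisible(x)
}

#' Ensemble scores by unweighted member averaging
#'
#' @param ensemble A `vita_ensemble`.
#' @param X A `feature_matrix` or numeric matrix with the training feature
#'   dimension.
#' @return Numeric vector of per-residue scores in \[0,1\] (arithmetic mean
#'   of the member scores, no member weighting).
#' @export
predict_scores <- function(ensemble, X) {
  x <- as_feature_mat(X)
  if (ncol(x) != ensemble$n_features) {
    abort(sprintf("feature dimension %d does not match training dimension %d",
                  ncol(x), ensemble$n_features),
          class = "vitabind_input_error")
  }
  member_scores <- purrr::map(ensemble$members, score_model, X = x)
  rowMeans(do.call(cbind, member_scores))
}

#' Threshold scores into binary calls
#'
#' A residue is called binding iff its score is strictly greater than the
#' threshold.
#'
#' @param scores Numeric scores in \[0,1\].
#' @param threshold Decision threshold T.
#' @return Integer 0/1 vector.
#' @export
classify <- function(scores, threshold) {
  as.integer(scores > threshold)
}

#' Set the ensemble decision threshold from scored training data
#'
#' @param ensemble A `vita_ensemble`.
#' @param scores Scores for labelled residues (typically the training set).
#' @param truth 0/1 labels aligned with `scores`.
#' @param strategy `"balanced"` (threshold equalising sensitivity and
#'   specificity), `"maxmcc"` (threshold maximising MCC), or `"fixed"`.
#' @param threshold Threshold value when `strategy = "fixed"`.
#' @return The ensemble with `threshold` and `strategy` set.
#' @export
calibrate_threshold <- function(ensemble, scores, truth,
                                strategy = c("balanced", "maxmcc", "fixed"),
                                threshold = 0.5) {
  strategy <- match.arg(strategy)
  t_opt <- switch(strategy,
    balanced = balanced_threshold(scores, truth)$threshold,
    maxmcc = maxmcc_threshold(scores, truth)$threshold,
    fixed = threshold)
  ensemble$threshold <- t_opt
  ensemble$strategy <- strategy
  ensemble
}

#' @export
tidy.vita_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    tibble::tibble(member = i, selector = m$subspace$method,
                   subspace_size = m$subspace$k,
                   cost = m$hyperparams$cost, gamma = m$hyperparams$gamma,
                   n_pos = m$training_meta$n_pos, n_neg = m$training_meta$n_neg)
  })
}

#' @export
glance.vita_ensemble <- function(x, ...) {
  tibble::tibble(n_members = length(x$members), n_features = x$n_features,
                 threshold = x$threshold, strategy = x$strategy)
}
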