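#' Train a vitamin-binding residue predictor end to end
#'
#' Estimates the binding-propensity table from the labelled training
#' records, builds the windowed feature matrix, trains the subspace SVM
#' ensemble and calibrates its decision threshold on the training scores.
#'
#' @inheritParams run_cv
#' @param strategy Threshold strategy (`"balanced"`, `"maxmcc"` or
#'   `"fixed"`).
#' @param threshold Threshold when `strategy = "fixed"`.
#' @param vitamin_class Tag stored with the propensity table.
#' @return A `vita_model`: list with the trained `ensemble`, the
#'   `propensities` table, `window`, and the package `version`.
#' @export
train_predictor <- function(records, profiles, ss,
                            selectors = c("jlfwl", "fisher", "laplacian"),
                            strategy = c("balanced", "maxmcc", "fixed"),
                            threshold = 0.5, W = 17, epsilon = 0.5, knn = 5,
                            k = NULL, C_grid = 1, gamma_grid = NULL,
                            inner_folds = 3, seed = 1,
                            vitamin_class = "generic") {
  strategy <- match.arg(strategy)
  if (is.null(gamma_grid)) gamma_grid <- 1 / (24 * W)
  prop <- compute_binding_propensities(records, vitamin_class)
  fm <- build_feature_matrix(records, profiles, ss, prop, W = W)
  ens <- train_ensemble(fm, selectors = selectors, k = k, epsilon = epsilon,
                        knn = knn, C_grid = C_grid, gamma_grid = gamma_grid,
                        inner_folds = inner_folds, seed = seed)
  train_scores <- predict_scores(ens, fm)
  ens <- calibrate_threshold(ens, train_scores, fm$labels, strategy, threshold)
  structure(list(ensemble = ens, propensities = prop, window = W,
                 version = as.character(utils::packageVersion("vitabind"))),
            class = "vita_model")
}

#' @export
print.vita_model <- function(x, ...) {
  cat(sprintf("<vita_model v%s: W=%d>\n", x$version, x$window))
  print(x$ensemble)
  invisible(x)
}

#' Predict binding residues for new sequences
#'
#' @param model A `vita_model` from [train_predictor()] or [load_model()].
#' @param records Record tibble (labels not required).
#' @param profiles,ss Named lists of profile and secondary-structure
#'   matrices for the records.
#' @param threshold Optional override of the stored decision threshold;
#'   changes the calls, never the scores.
#' @return A tibble with columns `sequence_id`, `position`, `residue`,
#'   `score`, `call`, ordered by input record then position.
#' @export
predict_residues <- function(model, records, profiles, ss, threshold = NULL) {
  stopifnot(inherits(model, "vita_model"))
  if (nrow(records) == 0) {
    return(tibble::tibble(sequence_id = character(), position = integer(),
                          residue = character(), score = numeric(),
                          call = integer()))
  }
  fm <- build_feature_matrix(records, profiles, ss, model$propensities,
                             W = model$window)
  scores <- predict_scores(model$ensemble, fm)
  t_use <- if (is.null(threshold)) model$ensemble$threshold else threshold
  dplyr::bind_cols(fm$index,
                   tibble::tibble(score = scores, call = classify(scores, t_use)))
}

#' Save / load a trained predictor
#'
#' The archive bundles subspace indices, hyperparameters, the propensity
#' table and the serialised SVMs, stamped with the package version; loading
#' an archive written by a different package version raises an explicit
#' error rather than risking a silently incompatible model.
#'
#' @param model A `vita_model`.
#' @param path Archive path.
#' @return `path` (save) or the restored `vita_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vita_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vita_model")) {
    abort("archive does not contain a vitabind model", class = "vitabind_format_error")
  }
  current <- as.character(utils::packageVersion("vitabind"))
  if (!identical(model$version, current)) {
    abort(sprintf("model archive written by vitabind %s; this is vitabind %s",
                  model$version, current),
          class = "vitabind_version_error")
  }
  model
}
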