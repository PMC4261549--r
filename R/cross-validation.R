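#' Build a k-fold cross-validation plan
#'
#' Partitions the evaluation units — whole sequences (`level = "sequence"`)
#' or individual residues (`level = "residue"`) — into k folds whose sizes
#' differ by at most one unit. Sequence-level folds keep all residues of a
#' sequence in the same test fold and are the leakage-free protocol;
#' residue-level folds allow residues of one sequence to appear in both
#' training and test splits, which over-estimates performance on homologous
#' residues.
#'
#' @param records Labelled record tibble.
#' @param level `"sequence"` or `"residue"`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the random partition.
#' @return A `cv_plan`: list with `level`, `k`, `seed` and `assignment` (a
#'   tibble mapping each unit to its fold).
#' @export
make_cv_folds <- function(records, level = c("sequence", "residue"), k = 5,
                          seed = 1) {
  level <- match.arg(level)
  if (k < 2) {
    abort("k must be at least 2", class = "vitabind_input_error")
  }
  assignment <- if (level == "sequence") {
    if (nrow(records) < k) {
      abort(sprintf("only %d sequences for %d folds", nrow(records), k),
            class = "vitabind_input_error")
    }
    fold <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = nrow(records))))
    tibble::tibble(sequence_id = records$id, fold = fold)
  } else {
    idx <- tidyr::unnest(
      dplyr::mutate(records, position = purrr::map(.data$sequence,
                                                   ~seq_len(nchar(.x)))),
      "position")[, c("id", "position")]
    names(idx)[1] <- "sequence_id"
    if (nrow(idx) < k) {
      abort(sprintf("only %d residues for %d folds", nrow(idx), k),
            class = "vitabind_input_error")
    }
    idx$fold <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = nrow(idx))))
    idx
  }
  structure(list(level = level, k = k, seed = seed, assignment = assignment),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan: %d-fold %s-level, seed %d, %d units>\n", x$k, x$level,
              x$seed, nrow(x$assignment)))
  invisible(x)
}

propensities_from_residues <- function(letters_all, labels_all,
                                       vitamin_class = "generic") {
  rec <- tibble::tibble(id = "pooled",
                        sequence = paste(letters_all, collapse = ""),
                        labels = list(as.integer(labels_all)))
  compute_binding_propensities(rec, vitamin_class)
}

residue_fold_vector <- function(records, plan) {
  lens <- nchar(records$sequence)
  if (plan$level == "sequence") {
    lut <- setNames(plan$assignment$fold, plan$assignment$sequence_id)
    rep(unname(lut[records$id]), times = lens)
  } else {
    key_plan <- paste(plan$assignment$sequence_id, plan$assignment$position)
    key_res <- paste(rep(records$id, times = lens),
                     unlist(lapply(lens, seq_len)))
    lut <- setNames(plan$assignment$fold, key_plan)
    unname(lut[key_res])
  }
}

#' Run k-fold cross-validation of the full pipeline
#'
#' For every fold, the binding-propensity table is estimated from the
#' training residues only, the feature selectors are run on the training
#' feature matrix only, the subspace SVM ensemble is trained, and the test
#' residues are scored. Test scores are pooled over all folds and a single
#' global threshold is chosen on the pooled scores by each requested
#' strategy, so the report carries whole-dataset confusion counts.
#'
#' @param records Labelled record tibble.
#' @param profiles Named list of `profile_matrix` objects.
#' @param ss Named list of secondary-structure probability matrices.
#' @param plan A `cv_plan` from [make_cv_folds()].
#' @param selectors Selector list for [train_ensemble()].
#' @param strategy Character vector of threshold strategies to report
#'   (subset of `"balanced"`, `"maxmcc"`).
#' @param W Window size (default 17).
#' @param epsilon,knn,k,C_grid,gamma_grid,inner_folds Passed to
#'   [train_ensemble()].
#' @param seed Base seed for per-fold training.
#' @return A `vita_cv` object: list with `reports` (one `vita_report` per
#'   strategy), `scores` (tibble of pooled per-residue scores with per-member
#'   columns), `auc` (pooled ensemble AUC), `member_auc`, and `plan`.
#' @export
run_cv <- function(records, profiles, ss, plan,
                   selectors = c("jlfwl", "fisher", "laplacian"),
                   strategy = c("balanced", "maxmcc"), W = 17, epsilon = 0.5,
                   knn = 5, k = NULL, C_grid = 1, gamma_grid = NULL,
                   inner_folds = 3, seed = 1) {
  stopifnot(inherits(plan, "cv_plan"))
  if (any(purrr::map_lgl(records$labels, is.null))) {
    abort("run_cv requires labelled records", class = "vitabind_label_error")
  }
  strategy <- match.arg(strategy, several.ok = TRUE)
  fold_of_residue <- residue_fold_vector(records, plan)
  letters_all <- unlist(strsplit(records$sequence, ""))
  labels_all <- unlist(records$labels)
  if (is.null(gamma_grid)) gamma_grid <- 1 / (24 * W)

  pooled <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr_mask <- fold_of_residue != f
    if (length(unique(labels_all[tr_mask])) < 2) {
      abort(sprintf("training split of fold %d lacks a class", f),
            class = "vitabind_label_error")
    }
    prop <- propensities_from_residues(letters_all[tr_mask], labels_all[tr_mask])
    if (plan$level == "sequence") {
      tr_ids <- plan$assignment$sequence_id[plan$assignment$fold != f]
      te_ids <- plan$assignment$sequence_id[plan$assignment$fold == f]
      fm_tr <- build_feature_matrix(records[records$id %in% tr_ids, ],
                                    profiles, ss, prop, W = W)
      fm_te <- build_feature_matrix(records[records$id %in% te_ids, ],
                                    profiles, ss, prop, W = W)
    } else {
      fm_all <- build_feature_matrix(records, profiles, ss, prop, W = W)
      fm_tr <- subset_rows(fm_all, tr_mask)
      fm_te <- subset_rows(fm_all, !tr_mask)
    }
    ens <- train_ensemble(fm_tr, selectors = selectors, k = k, epsilon = epsilon,
                          knn = knn, C_grid = C_grid, gamma_grid = gamma_grid,
                          inner_folds = inner_folds, seed = seed + f)
    member_scores <- do.call(cbind, purrr::map(ens$members, score_model, X = fm_te$x))
    colnames(member_scores) <- paste0("member_", seq_along(ens$members))
    pooled[[f]] <- dplyr::bind_cols(
      fm_te$index,
      tibble::tibble(truth = fm_te$labels, fold = f,
                     score = rowMeans(member_scores)),
      tibble::as_tibble(member_scores))
  }
  scores_tbl <- dplyr::bind_rows(pooled)
  reports <- purrr::map(strategy, function(st) {
    res <- switch(st,
      balanced = balanced_threshold(scores_tbl$score, scores_tbl$truth, plan$level),
      maxmcc = maxmcc_threshold(scores_tbl$score, scores_tbl$truth, plan$level))
    res$report
  })
  names(reports) <- strategy
  member_cols <- grep("^member_", names(scores_tbl), value = TRUE)
  member_auc <- vapply(member_cols, function(cn) {
    roc_auc(scores_tbl[[cn]], scores_tbl$truth)
  }, numeric(1))
  structure(list(reports = reports, scores = scores_tbl,
                 auc = roc_auc(scores_tbl$score, scores_tbl$truth),
                 member_auc = member_auc, selectors = selectors, plan = plan),
            class = "vita_cv")
}

#' @export
print.vita_cv <- function(x, ...) {
  cat(sprintf("<vita_cv: %d-fold %s-level, pooled AUC %.3f>\n", x$plan$k,
              x$plan$level, x$auc))
  for (r in x$reports) print(r)
  invisible(x)
}

#' @export
tidy.vita_cv <- function(x, ...) {
  purrr::map_dfr(names(x$reports), function(st) {
    dplyr::mutate(glance(x$reports[[st]]), strategy = st)
  })
}

#' @export
glance.vita_cv <- function(x, ...) {
  tibble::tibble(cv_level = x$plan$level, k = x$plan$k, auc = x$auc,
                 best_member_auc = max(x$member_auc),
                 n_residues = nrow(x$scores))
}

#' ROC curve of a cross-validation run
#'
#' @param object A `vita_cv` object.
#' @param ... Unused.
#' @return A ggplot of the pooled ROC curve.
#' @export
autoplot.vita_cv <- function(object, ...) {
  pts <- roc_points(object$scores$score, object$scores$truth)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Pooled %s-level CV ROC (AUC %.3f)",
                                  object$plan$level, object$auc)) +
    ggplot2::theme_minimal()
}

#' Propensity-table bar plot
#'
#' @param object A `propensity_table`.
#' @param ... Unused.
#' @return A ggplot of per-amino-acid binding propensities.
#' @export
autoplot.propensity_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$aa, -.data$propensity),
                                   y = .data$propensity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Amino acid", y = "Binding propensity",
                  title = sprintf("Vitamin-binding propensities (%s)",
                                  attr(object, "vitamin_class"))) +
    ggplot2::theme_minimal()
}
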