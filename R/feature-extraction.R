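#' Logistic normalisation of a raw PSSM
#'
#' Maps every log-odds element x to 1 / (1 + exp(-x)), so all values lie
#' strictly in (0,1) and a log-odds of zero maps to 0.5.
#'
#' @param profile A raw `profile_matrix` from [read_psiblast_pssm()].
#' @return A `profile_matrix` with `normalized = TRUE`.
#' @export
logistic_normalize <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  if (profile$normalized) {
    abort("profile is already normalized", class = "vitabind_state_error")
  }
  new_profile_matrix(plogis(profile$values), residues = profile$residues,
                     normalized = TRUE)
}

#' Estimate amino-acid binding propensities from labelled residues
#'
#' For each of the 20 standard amino acids, the propensity is the fraction of
#' training residues of that type labelled as binding. Letters that never
#' occur in the training set receive the mean propensity over observed
#' letters, as do ambiguity codes (X, B, Z, U) at lookup time. Propensities
#' must only ever be computed from training residues; [run_cv()] re-estimates
#' them inside every training split.
#'
#' @param records Labelled record tibble (see [attach_labels()]).
#' @param vitamin_class Free-text tag for the vitamin class the labels
#'   describe (e.g. `"generic"`, `"A"`, `"B6"`).
#' @return A `propensity_table`: tibble with columns `aa`, `n_binding`,
#'   `n_total`, `propensity`, plus attributes `vitamin_class` and
#'   `mean_propensity`.
#' @export
#' @examples
#' rec <- tibble::tibble(id = "p1", sequence = "AAAC",
#'                       labels = list(c(1L, 1L, 0L, 0L)))
#' compute_binding_propensities(rec)
compute_binding_propensities <- function(records, vitamin_class = "generic") {
  if (nrow(records) == 0) {
    abort("cannot estimate propensities from an empty record set",
          class = "vitabind_input_error")
  }
  if (any(purrr::map_lgl(records$labels, is.null))) {
    abort("all records must carry labels", class = "vitabind_label_error")
  }
  letters_all <- unlist(strsplit(records$sequence, ""))
  labels_all <- unlist(records$labels)
  stopifnot(length(letters_all) == length(labels_all))
  keep <- letters_all %in% AA_ORDER
  tab <- tibble::tibble(aa = factor(letters_all[keep], levels = AA_ORDER),
                        label = labels_all[keep]) |>
    dplyr::group_by(.data$aa, .drop = FALSE) |>
    dplyr::summarise(n_binding = sum(.data$label), n_total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(aa = as.character(.data$aa),
                  propensity = ifelse(.data$n_total > 0,
                                      .data$n_binding / .data$n_total, NA_real_))
  mean_prop <- mean(tab$propensity, na.rm = TRUE)
  tab$propensity[is.na(tab$propensity)] <- mean_prop
  structure(tab, class = c("propensity_table", class(tab)),
            vitamin_class = vitamin_class, mean_propensity = mean_prop)
}

#' Look up per-letter propensities for a sequence
#'
#' @param table A `propensity_table`.
#' @param sequence A protein sequence string.
#' @return Numeric vector of length `nchar(sequence)`; ambiguity codes and
#'   unknown letters receive the table's mean propensity.
#' @export
propensity_profile <- function(table, sequence) {
  stopifnot(inherits(table, "propensity_table"))
  lut <- setNames(table$propensity, table$aa)
  letters_i <- strsplit(sequence, "")[[1]]
  p <- unname(lut[letters_i])
  p[is.na(p)] <- attr(table, "mean_propensity")
  p
}

#' Extract a sliding-window feature vector for one residue
#'
#' Concatenates the rows of an L x K per-residue matrix for a window of odd
#' size `W` centred on `position`; rows falling outside the sequence are
#' replaced by a constant row of `pad_value`.
#'
#' @param matrix L x K numeric matrix (rows = residues).
#' @param position 1-based residue position.
#' @param W Odd window size (default 17).
#' @param pad_value Value used for out-of-range rows.
#' @return Numeric vector of length `W * K`.
#' @export
window_features <- function(matrix, position, W = 17, pad_value = 0) {
  if (W %% 2 != 1) {
    abort("window size W must be odd", class = "vitabind_input_error")
  }
  L <- nrow(matrix)
  K <- ncol(matrix)
  stopifnot(position >= 1, position <= L)
  half <- (W - 1) / 2
  rows <- (position - half):(position + half)
  out <- matrix(pad_value, nrow = W, ncol = K)
  inside <- rows >= 1 & rows <= L
  out[inside, ] <- matrix[rows[inside], , drop = FALSE]
  as.vector(t(out))
}

block_spans <- function(W) {
  list(pssm = seq_len(20 * W),
       pss  = 20 * W + seq_len(3 * W),
       vbp  = 23 * W + seq_len(W))
}

#' Build the per-residue feature matrix
#'
#' Produces one feature row per residue over all records by serially
#' combining three windowed blocks: the logistic-normalised PSSM window
#' (`20 * W` columns), the predicted secondary-structure window (`3 * W`
#' columns), and the binding-propensity window (`W` columns). With the
#' default `W = 17` this yields the 340 + 51 + 17 = 408-dimensional
#' representation. Out-of-range window rows are padded with the neutral
#' element of each block: 0.5 for the PSSM (the logistic image of a zero
#' log-odds), 1/3 per state for secondary structure, and the propensity
#' table's mean for the propensity block.
#'
#' @param records Record tibble; `labels`, when present, are copied through.
#' @param profiles Named list of `profile_matrix` objects (raw or
#'   normalised), one per record id.
#' @param ss Named list of L x 3 secondary-structure probability matrices.
#' @param propensities A `propensity_table` from
#'   [compute_binding_propensities()].
#' @param W Odd window size; default 17.
#' @return A `feature_matrix` object: list with `x` (M x D numeric matrix),
#'   `index` (tibble of `sequence_id`, `position`, `residue` per row),
#'   `labels` (integer vector or `NULL`), `blocks` (column spans of the
#'   three blocks) and `window`.
#' @export
build_feature_matrix <- function(records, profiles, ss, propensities, W = 17) {
  if (nrow(records) == 0) {
    abort("no records supplied", class = "vitabind_input_error")
  }
  if (W %% 2 != 1) {
    abort("window size W must be odd", class = "vitabind_input_error")
  }
  missing_p <- setdiff(records$id, names(profiles))
  if (length(missing_p) > 0) {
    abort(sprintf("missing profile for record(s): %s", paste(missing_p, collapse = ", ")),
          class = "vitabind_input_error")
  }
  missing_s <- setdiff(records$id, names(ss))
  if (length(missing_s) > 0) {
    abort(sprintf("missing secondary-structure matrix for record(s): %s",
                  paste(missing_s, collapse = ", ")),
          class = "vitabind_input_error")
  }
  mean_prop <- attr(propensities, "mean_propensity")
  per_record <- purrr::pmap(list(records$id, records$sequence, records$labels),
                            function(id, seq, lab) {
    L <- nchar(seq)
    prof <- profiles[[id]]
    if (!prof$normalized) prof <- logistic_normalize(prof)
    if (nrow(prof$values) != L) {
      abort(sprintf("profile rows (%d) != sequence length (%d) for '%s'",
                    nrow(prof$values), L, id),
            class = "vitabind_input_error")
    }
    ssm <- ss[[id]]
    if (nrow(ssm) != L) {
      abort(sprintf("ss2 rows (%d) != sequence length (%d) for '%s'",
                    nrow(ssm), L, id),
            class = "vitabind_input_error")
    }
    if (!is.null(prof$residues)) {
      seq_letters <- strsplit(seq, "")[[1]]
      std <- seq_letters %in% AA_ORDER
      if (any(prof$residues[std] != seq_letters[std])) {
        warn(sprintf("profile residue letters disagree with FASTA for '%s'; trusting FASTA", id))
      }
    }
    vbp <- base::matrix(propensity_profile(propensities, seq), ncol = 1)
    x <- base::matrix(NA_real_, nrow = L, ncol = 24 * W)
    for (i in seq_len(L)) {
      x[i, ] <- c(window_features(prof$values, i, W, pad_value = 0.5),
                  window_features(ssm, i, W, pad_value = 1 / 3),
                  window_features(vbp, i, W, pad_value = mean_prop))
    }
    list(x = x,
         index = tibble::tibble(sequence_id = id, position = seq_len(L),
                                residue = strsplit(seq, "")[[1]]),
         labels = lab)
  })
  x <- do.call(rbind, purrr::map(per_record, "x"))
  index <- dplyr::bind_rows(purrr::map(per_record, "index"))
  labs <- purrr::map(per_record, "labels")
  labels <- if (any(purrr::map_lgl(labs, is.null))) NULL else as.integer(unlist(labs))
  new_feature_matrix(x, index, labels, W)
}

new_feature_matrix <- function(x, index, labels, W) {
  stopifnot(nrow(x) == nrow(index))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(x))
  structure(list(x = x, index = index, labels = labels,
                 blocks = block_spans(W), window = W),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d residues x %d features (W=%d; blocks %s)%s>\n",
              nrow(x$x), ncol(x$x), x$window,
              paste(purrr::map_int(x$blocks, length), collapse = "/"),
              if (is.null(x$labels)) "" else sprintf("; %d positives", sum(x$labels))))
  invisible(x)
}

#' Restrict a feature matrix to a subset of its rows
#'
#' @param fm A `feature_matrix`.
#' @param rows Integer or logical row index.
#' @return A `feature_matrix` over the selected residues.
#' @export
subset_rows <- function(fm, rows) {
  stopifnot(inherits(fm, "feature_matrix"))
  new_feature_matrix(fm$x[rows, , drop = FALSE], fm$index[rows, , drop = FALSE],
                     if (is.null(fm$labels)) NULL else fm$labels[rows], fm$window)
}
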