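#' Read a FASTA file into a protein record tibble
#'
#' Parses a plain-text FASTA file into one row per sequence. Sequence ids are
#' taken as the first whitespace-delimited token after `>`; sequences are
#' uppercased. Binding labels are absent after reading and can be added with
#' [attach_labels()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `sequence` (character) and
#'   `labels` (list column of integer vectors, all `NULL` after reading).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "ghik"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("FASTA file '%s' is empty", path), class = "vitabind_format_error")
  }
  hdr <- startsWith(trimws(lines), ">")
  if (!hdr[1]) {
    abort(sprintf("FASTA file '%s' does not start with a '>' header", path),
          class = "vitabind_format_error")
  }
  grp <- cumsum(hdr)
  ids <- vapply(trimws(lines[hdr]), function(h) {
    strsplit(sub("^>", "", h), "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("FASTA header with empty id", class = "vitabind_format_error")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s) in '%s': %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "vitabind_format_error")
  }
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(x) {
    toupper(gsub("\\s+", "", paste(x, collapse = "")))
  }, character(1))
  seqs <- seqs[as.character(seq_along(ids))]
  if (anyNA(seqs) || any(!nzchar(seqs))) {
    abort(sprintf("FASTA record without sequence body in '%s'", path),
          class = "vitabind_format_error")
  }
  new_protein_records(ids, unname(seqs))
}

new_protein_records <- function(ids, sequences, labels = NULL) {
  if (is.null(labels)) labels <- vector("list", length(ids))
  tibble::tibble(id = ids, sequence = sequences, labels = labels)
}

#' Write protein records to a FASTA file
#'
#' @param records A record tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  out <- unlist(purrr::map2(records$id, records$sequence, function(id, s) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the modern PSI-BLAST ASCII PSSM layout (two header lines, then one
#' row per residue carrying position, residue letter, 20 log-odds integers and
#' 20 weighted-percentage columns, then trailing statistics lines). Only the
#' first 20 numeric columns — the log-odds block — are consumed.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A `profile_matrix` object: list with `values` (L x 20 numeric
#'   matrix, columns in PSI-BLAST amino-acid order), `residues` (character
#'   vector of the per-row residue letters, for cross-checking against the
#'   FASTA sequence) and `normalized = FALSE`.
#' @export
read_psiblast_pssm <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  row_like <- grepl("^\\s*[0-9]+\\s+[A-Za-z]", lines)
  if (!any(row_like)) {
    abort(sprintf("'%s' contains no PSSM rows", path), class = "vitabind_format_error")
  }
  idx <- which(row_like)
  vals <- matrix(NA_real_, nrow = length(idx), ncol = 20,
                 dimnames = list(NULL, AA_ORDER))
  residues <- character(length(idx))
  positions <- integer(length(idx))
  for (i in seq_along(idx)) {
    ln <- idx[i]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 22) {
      abort(sprintf("truncated PSSM row at line %d of '%s'", ln, path),
            class = "vitabind_format_error")
    }
    num <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(num)) {
      abort(sprintf("non-numeric PSSM cell at line %d of '%s'", ln, path),
            class = "vitabind_format_error")
    }
    positions[i] <- as.integer(tok[1])
    residues[i] <- toupper(tok[2])
    vals[i, ] <- num
  }
  if (!identical(positions, seq_along(positions))) {
    abort(sprintf("PSSM positions in '%s' are not consecutive from 1 (declared %d rows)",
                  path, length(positions)),
          class = "vitabind_format_error")
  }
  new_profile_matrix(vals, residues = residues, normalized = FALSE)
}

#' Construct a profile matrix object
#'
#' @param values L x 20 numeric matrix of per-position scores.
#' @param residues Optional character vector of residue letters per row.
#' @param normalized Logical; `TRUE` once values have been mapped into (0,1)
#'   by [logistic_normalize()].
#' @return A `profile_matrix` object.
#' @export
new_profile_matrix <- function(values, residues = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != 20) {
    abort("profile matrix must have 20 columns", class = "vitabind_format_error")
  }
  dimnames(values) <- list(NULL, AA_ORDER)
  if (!is.null(residues) && length(residues) != nrow(values)) {
    abort("residue letters do not match profile row count",
          class = "vitabind_format_error")
  }
  if (normalized && (any(values <= 0) || any(values >= 1))) {
    abort("normalized profile values must lie strictly in (0,1)",
          class = "vitabind_format_error")
  }
  structure(list(values = values, residues = residues, normalized = normalized),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix: %d residues x 20, %s>\n", nrow(x$values),
              if (x$normalized) "logistic-normalized" else "raw log-odds"))
  invisible(x)
}

#' Read a PSIPRED ss2 secondary-structure probability file
#'
#' Parses the `# PSIPRED VFORMAT` dialect: a header line, a blank line, then
#' one row per residue with (index, residue, state, pC, pH, pE). Probabilities
#' are consumed as emitted; rows are not renormalised.
#'
#' @param path Path to an `.ss2` file.
#' @return An L x 3 numeric matrix with columns `C`, `H`, `E` (coil, helix,
#'   strand) and a `residues` attribute carrying the per-row letters.
#' @export
read_psipred_ss2 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^# PSIPRED", lines))) {
    warn(sprintf("'%s' lacks a '# PSIPRED' header; attempting to parse anyway", path))
  }
  rows <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s+[A-Za-z]", lines, value = FALSE)
  if (length(rows) == 0) {
    abort(sprintf("'%s' contains no ss2 rows", path), class = "vitabind_format_error")
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = 3,
                dimnames = list(NULL, c("C", "H", "E")))
  residues <- character(length(rows))
  for (i in seq_along(rows)) {
    tok <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    if (length(tok) < 6) {
      abort(sprintf("truncated ss2 row at line %d of '%s'", rows[i], path),
            class = "vitabind_format_error")
    }
    p <- suppressWarnings(as.numeric(tok[4:6]))
    if (anyNA(p)) {
      abort(sprintf("non-numeric ss2 probability at line %d of '%s'", rows[i], path),
            class = "vitabind_format_error")
    }
    if (any(p < 0 | p > 1)) {
      abort(sprintf("ss2 probability outside [0,1] at line %d of '%s'", rows[i], path),
            class = "vitabind_format_error")
    }
    residues[i] <- toupper(tok[2])
    mat[i, ] <- p
  }
  attr(mat, "residues") <- residues
  mat
}

#' Read per-sequence binding labels
#'
#' Reads a two-column text file: sequence id, then a string of `0`/`1`
#' characters marking non-binding/binding residues.
#'
#' @param path Path to the label file.
#' @return A named list of integer vectors.
#' @export
read_labels <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2) {
      abort(sprintf("label line %d is not 'id 01-string'", i),
            class = "vitabind_format_error")
    }
    if (grepl("[^01]", tok[2])) {
      abort(sprintf("label string for '%s' contains characters other than 0/1", tok[1]),
            class = "vitabind_format_error")
    }
    out[[tok[1]]] <- as.integer(strsplit(tok[2], "")[[1]])
  }
  out
}

#' Attach binding labels to protein records
#'
#' @param records Record tibble from [read_fasta()].
#' @param labels Named list of integer 0/1 vectors, as from [read_labels()].
#' @return The record tibble with its `labels` list column filled.
#' @export
attach_labels <- function(records, labels) {
  records$labels <- purrr::map2(records$id, records$sequence, function(id, s) {
    lab <- labels[[id]]
    if (is.null(lab)) {
      abort(sprintf("no labels for sequence '%s'", id), class = "vitabind_label_error")
    }
    if (length(lab) != nchar(s)) {
      abort(sprintf("label length %d != sequence length %d for '%s'",
                    length(lab), nchar(s), id),
            class = "vitabind_label_error")
    }
    as.integer(lab)
  })
  records
}

#' Write per-residue predictions to a TSV file
#'
#' @param predictions A tibble with columns `sequence_id`, `position`
#'   (1-based), `residue`, `score` and `call`, as produced by
#'   [predict_residues()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("sequence_id", "position", "residue", "score", "call")
  if (!all(need %in% names(predictions))) {
    abort(paste("predictions must have columns", paste(need, collapse = ", ")),
          class = "vitabind_format_error")
  }
  if (nrow(predictions) > 0 && (any(predictions$score < 0) || any(predictions$score > 1))) {
    abort("prediction scores must lie in [0,1]", class = "vitabind_format_error")
  }
  df <- as.data.frame(predictions[, need])
  df$score <- sprintf("%.6f", df$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(need, collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path Path to a prediction TSV.
#' @return A tibble with the prediction columns.
#' @export
read_predictions <- function(path) {
  df <- read.csv(path, sep = "\t", colClasses = c("character", "integer", "character",
                                                  "numeric", "integer"))
  tibble::as_tibble(df)
}
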