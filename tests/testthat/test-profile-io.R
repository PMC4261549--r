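test_that("FASTA reading uppercases, preserves order, and rejects bad input", {
  tf <- write_temp_fasta(c(">p1", "acde", ">p2 some description", "GHIK", "LMNP"))
  rec <- read_fasta(tf)
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$sequence, c("ACDE", "GHIKLMNP"))
  expect_true(all(vapply(rec$labels, is.null, logical(1))))

  empty <- write_temp_fasta(character(0))
  expect_error(read_fasta(empty), class = "vitabind_format_error")

  dup <- write_temp_fasta(c(">p1", "ACDE", ">p1", "GHIK"))
  expect_error(read_fasta(dup), "p1", class = "vitabind_format_error")
})

test_that("PSSM reader round-trips fixture files and flags malformed rows", {
  ds <- tiny_dataset(seed = 11, n = 3)
  dir <- withr::local_tempdir()
  write_fixture_tree(ds, dir)
  for (id in ds$records$id) {
    prof <- read_psiblast_pssm(file.path(dir, "pssm", paste0(id, ".pssm")))
    expect_identical(prof$values, ds$profiles[[id]]$values)
    expect_false(prof$normalized)
    expect_equal(paste(prof$residues, collapse = ""),
                 ds$records$sequence[ds$records$id == id])
  }

  # truncated row names the offending line
  path <- file.path(dir, "pssm", paste0(ds$records$id[1], ".pssm"))
  lines <- readLines(path)
  lines[5] <- substr(lines[5], 1, 20)
  bad <- tempfile(fileext = ".pssm")
  writeLines(lines, bad)
  expect_error(read_psiblast_pssm(bad), "line 5", class = "vitabind_format_error")

  # non-numeric cell
  lines <- readLines(path)
  lines[4] <- sub(" {2}([0-9-])", "  x", lines[4])
  writeLines(lines, bad)
  expect_error(read_psiblast_pssm(bad), class = "vitabind_format_error")
})

test_that("all-zero PSSM fixture reads back as a zero matrix", {
  prof <- new_profile_matrix(matrix(0, 3, 20), residues = c("A", "C", "D"))
  lines <- vitabind:::format_pssm_file("z", prof)
  tf <- tempfile(fileext = ".pssm")
  writeLines(lines, tf)
  back <- read_psiblast_pssm(tf)
  expect_identical(back$values, prof$values)
  expect_false(back$normalized)
})

test_that("ss2 reader parses probabilities as emitted, without renormalising", {
  tf <- tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "",
               "   1 A C   1.000  0.000  0.000",
               "   2 C H   0.000  1.000  0.000"), tf)
  m <- read_psipred_ss2(tf)
  expect_equal(unname(m[, ]), rbind(c(1, 0, 0), c(0, 1, 0)), ignore_attr = TRUE)
  expect_equal(colnames(m), c("C", "H", "E"))

  # rows that do not sum to 1 pass through unchanged
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "",
               "   1 A C   0.500  0.270  0.200"), tf)
  m2 <- read_psipred_ss2(tf)
  expect_equal(sum(m2[1, ]), 0.97)

  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", ""), tf)
  expect_error(read_psipred_ss2(tf), class = "vitabind_format_error")

  writeLines(c("   1 A C   0.500  0.300  0.200"), tf)
  expect_warning(read_psipred_ss2(tf), "header")

  writeLines(c("# PSIPRED VFORMAT", "", "   1 A C   1.500  0.000  0.000"), tf)
  expect_error(read_psipred_ss2(tf), class = "vitabind_format_error")
})

test_that("label files parse to 0/1 vectors and attach with length checks", {
  tf <- tempfile()
  writeLines(c("p1 0110", "p2 0000"), tf)
  labs <- read_labels(tf)
  expect_equal(labs$p1, c(0L, 1L, 1L, 0L))
  expect_equal(sum(labs$p2), 0L)

  rec <- new_protein_records(c("p1", "p2"), c("ACDE", "GHIK"))
  rec <- attach_labels(rec, labs)
  expect_equal(rec$labels[[1]], c(0L, 1L, 1L, 0L))

  writeLines("p1 01x0", tf)
  expect_error(read_labels(tf), class = "vitabind_format_error")

  writeLines(c("p1 01", "p2 0000"), tf)
  expect_error(attach_labels(rec, read_labels(tf)), "p1",
               class = "vitabind_label_error")
})

test_that("prediction TSVs are deterministic and round-trip", {
  pred <- tibble::tibble(sequence_id = c("p1", "p1"), position = 1:2,
                         residue = c("A", "C"), score = c(0.25, 0.75),
                         call = c(0L, 1L))
  tf <- tempfile(fileext = ".tsv")
  write_predictions(pred, tf)
  lines <- readLines(tf)
  expect_equal(length(lines), 3)
  expect_equal(lines[1], "sequence_id\tposition\tresidue\tscore\tcall")
  back <- read_predictions(tf)
  expect_equal(back$score, pred$score)

  # empty prediction set -> header-only file
  write_predictions(pred[0, ], tf)
  expect_equal(readLines(tf), "sequence_id\tposition\tresidue\tscore\tcall")

  expect_error(write_predictions(dplyr::mutate(pred, score = score + 1), tf),
               class = "vitabind_format_error")
})
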