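test_that("confusion counts and the four indexes follow their definitions", {
  expect_equal(confusion(c(1, 1, 1), c(1, 1, 1)),
               c(tp = 3L, fp = 0L, tn = 0L, fn = 0L))
  expect_equal(confusion(c(0, 1), c(1, 0)), c(tp = 0L, fp = 1L, tn = 0L, fn = 1L))
  ct <- confusion(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(ct, c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_equal(sensitivity(ct), 50)
  expect_equal(specificity(ct), 50)
  expect_equal(accuracy(ct), 50)
  expect_equal(mcc(ct), 0)
  expect_error(confusion(c(1, 0), c(1, 0, 0)), class = "vitabind_input_error")

  # published-counts spot checks (full replay lives in the acceptance suite)
  big <- c(tp = 2342, fp = 12325, tn = 49797, fn = 674)
  expect_equal(round_half_up(sensitivity(big)), 77.65)
  expect_equal(round_half_up(specificity(big)), 80.16)
  expect_equal(round_half_up(accuracy(big)), 80.04)
  expect_equal(round_half_up(mcc(big)), 0.29)
  expect_equal(round_half_up(mcc(c(tp = 183, tn = 5880, fp = 55, fn = 63))), 0.75)

  # zero-denominator conventions
  expect_true(is.na(sensitivity(c(tp = 0, fp = 1, tn = 1, fn = 0))))
  expect_equal(mcc(c(tp = 0, fp = 0, tn = 2, fn = 0)), 0)
  expect_equal(mcc(c(tp = 1, fp = 0, tn = 1, fn = 0)), 1)
})

test_that("rank-statistic AUC handles perfect, inverted and tied rankings", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)  # all ties
  expect_true(is.na(roc_auc(c(0.2, 0.4), c(1, 1))))
  # invariance under strictly monotone transforms
  set.seed(5)
  sc <- runif(50); tr <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(plogis(8 * sc - 3), tr), roc_auc(sc, tr))
  # agreement with an independent ROC implementation
  expect_equal(roc_auc(sc, tr),
               as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("threshold strategies are argmin/argmax over the candidate scan", {
  sc <- c(0.1, 0.4, 0.6, 0.9); tr <- c(0, 0, 1, 1)
  bal <- balanced_threshold(sc, tr)
  expect_gt(bal$threshold, 0.4); expect_lt(bal$threshold, 0.6)
  expect_equal(bal$report$sn, bal$report$sp)
  mm <- maxmcc_threshold(sc, tr)
  expect_equal(mm$report$mcc, 1)

  # a score exactly at the threshold is called negative (strict inequality)
  expect_equal(classify(c(0.3, 0.5, 0.7), 0.5), c(0L, 0L, 1L))
  expect_equal(classify(c(0.2, 1), 1), c(0L, 0L))

  # argmin/argmax contracts over every scanned candidate
  set.seed(9)
  sc <- round(runif(60), 2); tr <- rbinom(60, 1, 0.3)
  cands <- threshold_candidates(sc)
  bal <- balanced_threshold(sc, tr)
  gaps <- vapply(cands, function(t) {
    ct <- confusion(classify(sc, t), tr); abs(sensitivity(ct) - specificity(ct))
  }, numeric(1))
  ct_bal <- confusion(classify(sc, bal$threshold), tr)
  expect_lte(abs(sensitivity(ct_bal) - specificity(ct_bal)), min(gaps) + 1e-9)
  mm <- maxmcc_threshold(sc, tr)
  mccs <- vapply(cands, function(t) mcc(confusion(classify(sc, t), tr)), numeric(1))
  expect_gte(mm$report$mcc, max(mccs) - 1e-9)
  # smaller-threshold tie rule
  ties <- which(abs(mccs - max(mccs)) < 1e-12)
  expect_equal(mm$threshold, cands[min(ties)])

  expect_error(balanced_threshold(c(0.2, 0.8), c(1, 1)),
               class = "vitabind_label_error")
})

test_that("TP+FN and TN+FP are threshold-invariant", {
  set.seed(2)
  sc <- runif(40); tr <- rbinom(40, 1, 0.25)
  for (t in c(0, 0.3, 0.7, 1)) {
    ct <- confusion(classify(sc, t), tr)
    expect_equal(ct[["tp"]] + ct[["fn"]], sum(tr == 1))
    expect_equal(ct[["tn"]] + ct[["fp"]], sum(tr == 0))
  }
})

test_that("report accessors expose counts and metrics coherently", {
  rep <- evaluate_predictions(c(0.2, 0.8, 0.6, 0.3), c(0, 1, 1, 0), 0.5,
                              strategy = "fixed")
  g <- glance(rep)
  expect_equal(g$tp, 2); expect_equal(g$tn, 2)
  expect_equal(g$sn, 100); expect_equal(g$mcc, 1)
  td <- tidy(rep)
  expect_equal(td$value[td$metric == "auc"], 1)
  js <- jsonlite::fromJSON(report_json(rep))
  expect_equal(js$mcc, 1)
})

test_that("cross-validation folds partition units evenly and reproducibly", {
  ds <- tiny_dataset(seed = 5, n = 10)
  plan <- make_cv_folds(ds$records, "sequence", k = 5, seed = 3)
  expect_equal(unname(table(plan$assignment$fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(plan$assignment,
                   make_cv_folds(ds$records, "sequence", k = 5, seed = 3)$assignment)

  # sequence-level: all residues of a sequence share one fold
  fold_res <- vitabind:::residue_fold_vector(ds$records, plan)
  per_seq <- split(fold_res, rep(ds$records$id, nchar(ds$records$sequence)))
  expect_true(all(vapply(per_seq, function(f) length(unique(f)) == 1, logical(1))))

  plan_r <- make_cv_folds(ds$records, "residue", k = 5, seed = 3)
  sizes <- table(plan_r$assignment$fold)
  expect_lte(max(sizes) - min(sizes), 1)

  expect_error(make_cv_folds(ds$records[1:3, ], "sequence", k = 5),
               class = "vitabind_input_error")
  expect_error(make_cv_folds(ds$records, "sequence", k = 1),
               class = "vitabind_input_error")
})

test_that("cross-validation scores every residue once and is seed-stable", {
  ds <- tiny_dataset(seed = 8, n = 4, length_range = c(20, 24))
  plan <- make_cv_folds(ds$records, "sequence", k = 2, seed = 8)
  cv <- run_cv(ds$records, ds$profiles, ds$ss, plan, selectors = "fisher",
               k = 50, seed = 8)
  expect_equal(nrow(cv$scores), sum(nchar(ds$records$sequence)))
  expect_equal(anyDuplicated(cv$scores[, c("sequence_id", "position")]), 0L)
  # pooled counts cover the whole dataset
  g <- glance(cv$reports$balanced)
  expect_equal(g$tp + g$fn, sum(unlist(ds$records$labels)))
  expect_equal(g$tn + g$fp, sum(unlist(ds$records$labels) == 0))
  expect_equal(names(cv$reports), c("balanced", "maxmcc"))
  expect_equal(cv$reports$balanced$cv_level, "sequence")

  cv2 <- run_cv(ds$records, ds$profiles, ds$ss, plan, selectors = "fisher",
                k = 50, seed = 8)
  expect_identical(cv$scores, cv2$scores)
  expect_identical(glance(cv$reports$maxmcc), glance(cv2$reports$maxmcc))
})
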