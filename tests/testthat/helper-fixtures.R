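# Shared in-code fixtures: small datasets are generated, never stored.

tiny_dataset <- function(seed = 1, n = 6, length_range = c(20, 30), ...) {
  generate_dataset(generator_config(n_sequences = n, length_range = length_range,
                                    seed = seed, ...))
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# Brute-force oracles, deliberately naive and independent of the package's
# vectorised implementations.

oracle_variance <- function(x) {
  apply(x, 2, function(f) sum((f - mean(f))^2) / (length(f) - 1))
}

oracle_fisher <- function(x, y) {
  vapply(seq_len(ncol(x)), function(j) {
    f <- x[, j]
    num <- den <- 0
    for (cl in unique(y)) {
      fc <- f[y == cl]
      num <- num + length(fc) * (mean(fc) - mean(f))^2
      den <- den + length(fc) * mean((fc - mean(fc))^2)
    }
    if (den > 0) num / den else if (num > 0) Inf else 0
  }, numeric(1))
}

# Dense-matrix Laplacian score: explicit S, D, L = D - S with the same kNN
# rule (k nearest by Euclidean distance, index tie-break, symmetrised by
# union; heat kernel with t = mean squared pairwise distance).
oracle_laplacian <- function(x, knn) {
  m <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  t_heat <- mean(d2[upper.tri(d2)])
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    ord <- order(d2[i, ], seq_len(m))
    ord <- ord[ord != i]
    adj[i, ord[seq_len(knn)]] <- TRUE
  }
  adj <- adj | t(adj)
  s <- exp(-d2 / t_heat) * adj
  diag(s) <- 0
  dmat <- diag(rowSums(s))
  lap <- dmat - s
  ones <- rep(1, m)
  vapply(seq_len(ncol(x)), function(j) {
    f <- x[, j]
    fc <- f - as.numeric((t(f) %*% dmat %*% ones) / (t(ones) %*% dmat %*% ones)) * ones
    den <- as.numeric(t(fc) %*% dmat %*% fc)
    if (den < 1e-12) return(NA_real_)
    as.numeric(t(fc) %*% lap %*% fc) / den
  }, numeric(1))
}

# AUC by explicit pair counting over all positive-negative pairs.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold scan over a fine grid (finer than the midpoint set).
oracle_best_threshold <- function(scores, truth, objective) {
  grid <- sort(unique(c(0, 1, scores, (head(sort(scores), -1) + tail(sort(scores), -1)) / 2,
                        seq(0, 1, by = 0.001))))
  vals <- vapply(grid, function(t) objective(confusion(as.integer(scores > t), truth)),
                 numeric(1))
  max(vals)
}
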