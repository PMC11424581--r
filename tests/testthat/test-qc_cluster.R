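mk_cells <- function(counts_per_cell) {
  # counts_per_cell: list of named gene count vectors
  genes <- unique(unlist(lapply(counts_per_cell, names)))
  m <- vapply(counts_per_cell, function(v) {
    out <- stats::setNames(rep(0L, length(genes)), genes)
    out[names(v)] <- as.integer(v)
    out
  }, integer(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes,
                              sprintf("c%02d", seq_along(counts_per_cell))))
  meta <- data.frame(row.names = colnames(m),
                     cell_type = rep("t", ncol(m)),
                     condition = rep("treated", ncol(m)),
                     replicate = rep(1L, ncol(m)))
  CellMatrix(m, meta)
}

test_that("QC metrics are per-cell count arithmetic", {
  cm <- mk_cells(list(
    c("mt-Nd1" = 2, Actb = 6, Rps1 = 0, Gapdh = 0),  # pct_mito 2/8
    c("mt-Nd1" = 5),                                 # mito only
    c(Actb = 0)))                                    # empty cell
  qc <- computeQCMetrics(cm, mito_prefix = "mt-")
  expect_equal(qc$pct_mito, c(0.25, 1, 0))
  expect_equal(qc$n_features, c(2, 1, 0))
  expect_equal(qc$n_counts, c(8, 5, 0))
  expect_identical(qc$empty, c(FALSE, FALSE, TRUE))
})

test_that("a missing prefix logs a warning and zeroes the metric", {
  cm <- mk_cells(list(c(Actb = 3), c(Actb = 4), c(Actb = 5)))
  expect_message(qc <- computeQCMetrics(cm, mito_prefix = "MT-"),
                 "mitochondrial")
  expect_true(all(qc$pct_mito == 0))
})

test_that("identical cells all pass (zero-MAD degenerate rule)", {
  cm <- mk_cells(replicate(10, c("mt-Nd1" = 1, Actb = 9, Rps1 = 2),
                           simplify = FALSE))
  qc <- computeQCMetrics(cm, mito_prefix = "mt-")
  expect_length(suppressMessages(madFilter(qc)), 10)
})

test_that("a gross mitochondrial outlier is removed", {
  cells <- replicate(9, c("mt-Nd1" = 1, Actb = 19), simplify = FALSE)
  cells[[10]] <- c("mt-Nd1" = 19, Actb = 1)
  qc <- computeQCMetrics(mk_cells(cells), mito_prefix = "mt-")
  # add jitter-free variety so feature/count MADs stay zero-degenerate
  kept <- suppressMessages(madFilter(qc))
  expect_length(kept, 9)
  expect_false("c10" %in% kept)
})

test_that("the count-feature regression filter removes conditional outliers", {
  # 12 cells along a tight log-log line; one keeps normal marginals but
  # sits far off the regression (many counts, few features)
  set.seed(1)
  n_counts <- round(10^seq(2, 3, length.out = 12))
  n_feat <- round(10^(0.9 * log10(n_counts) - 0.5))
  n_feat[6] <- round(10^(0.9 * log10(n_counts[6]) - 0.5 - 0.35))
  qc <- data.frame(pct_mito = rep(0.05, 12), pct_ribo = rep(0.1, 12),
                   n_features = n_feat, n_counts = n_counts,
                   empty = FALSE, row.names = sprintf("c%02d", 1:12))
  # verify by hand that only cell 6 breaches the residual criterion
  lf <- log10(qc$n_features); lc <- log10(qc$n_counts)
  r <- residuals(lm(lf ~ lc))
  breach <- abs(r - median(r)) > 3 * mad(r)
  expect_identical(which(breach), c(`6` = 6L))
  in_marg <- function(x) abs(x - median(x)) <= 3 * mad(x)
  expect_true(in_marg(lf)[6] && in_marg(lc)[6])
  kept <- suppressMessages(madFilter(qc))
  expect_identical(setdiff(rownames(qc), kept), "c06")
})

test_that("empty cells are removed unconditionally", {
  cells <- replicate(5, c(Actb = 10, Rps1 = 3), simplify = FALSE)
  cells[[6]] <- c(Actb = 0)
  qc <- computeQCMetrics(mk_cells(cells))
  expect_false("c06" %in% suppressMessages(madFilter(qc)))
})

test_that("madFilter is invariant to cell order", {
  set.seed(2)
  qc <- data.frame(pct_mito = runif(20, 0, 0.2), pct_ribo = runif(20, 0, 0.3),
                   n_features = sample(200:400, 20),
                   n_counts = sample(1000:2000, 20), empty = FALSE,
                   row.names = sprintf("c%02d", 1:20))
  kept <- suppressMessages(madFilter(qc))
  perm <- sample(20)
  expect_setequal(suppressMessages(madFilter(qc[perm, ])), kept)
})

test_that("Calinski-Harabasz reproduces the 1-D worked example", {
  # points {0,1,10,11}: B = 100, W = 1, n = 4, k = 2 -> 200
  expect_equal(calinskiHarabasz(cbind(c(0, 1, 10, 11)),
                                c("a", "a", "b", "b")), 200)
})

test_that("zero within-cluster scatter scores +Inf and outranks everything", {
  expect_identical(calinskiHarabasz(cbind(c(0, 0, 10)), c("a", "a", "b")),
                   Inf)
  emb <- cbind(c(0, 1, 10, 11))
  sel <- selectClustering(
    cbind(c(0, 0, 10)),
    list(finite = c("a", "b", "b"), tight = c("a", "a", "b")),
    fallback = c("a", "a", "b"))
  expect_identical(attr(sel, "tag"), "tight")
})

test_that("k = 1 and k = n are invalid candidates", {
  emb <- cbind(1:4)
  expect_error(calinskiHarabasz(emb, rep("a", 4)), "invalid")
  expect_error(calinskiHarabasz(emb, letters[1:4]), "invalid")
})

test_that("the index is invariant under rotation, translation and relabels", {
  set.seed(3)
  emb <- matrix(rnorm(40), 20, 2)
  lab <- rep(c("a", "b"), each = 10)
  base <- calinskiHarabasz(emb, lab)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(calinskiHarabasz(emb %*% rot, lab), base)
  expect_equal(calinskiHarabasz(sweep(emb, 2, c(5, -3), `+`), lab), base)
  expect_equal(calinskiHarabasz(emb, c(a = "z", b = "y")[lab]), base)
})

test_that("true labels outscore random labels on separated blobs", {
  set.seed(4)
  wins <- 0
  for (rep in 1:100) {
    emb <- rbind(matrix(rnorm(40), 20, 2),
                 matrix(rnorm(40, mean = 8), 20, 2))
    truth <- rep(c("a", "b"), each = 20)
    if (calinskiHarabasz(emb, truth) >
        calinskiHarabasz(emb, sample(truth))) wins <- wins + 1
  }
  expect_gte(wins, 99)
})

test_that("selection takes the argmax and breaks ties toward parsimony", {
  emb <- cbind(c(0, 1, 10, 11))
  good <- c("a", "a", "b", "b")
  bad <- c("a", "b", "a", "b")
  sel <- selectClustering(emb, list(r1 = bad, r2 = good), fallback = good)
  expect_identical(attr(sel, "tag"), "r2")

  # exhaustive 2-candidate tie cases: same labelling under different tags
  for (ord in list(c("x", "y"), c("y", "x"))) {
    cands <- stats::setNames(list(good, good), ord)
    sel <- selectClustering(emb, cands, fallback = good)
    expect_identical(attr(sel, "tag"), ord[1])  # first by candidate order
  }
  # tie in score, different k: fewer clusters wins
  emb2 <- cbind(c(0, 0, 4, 4, 8, 8))
  k2 <- rep(c("a", "b"), c(4, 2))
  sel2 <- selectClustering(emb2, list(
    many = c("a", "a", "b", "b", "c", "c"),
    few = rep(c("a", "b"), each = 3)), fallback = k2)
  expect_identical(attr(sel2, "tag"),
                   names(which.min(c(
                     many = calinskiHarabasz(emb2, c("a", "a", "b", "b", "c", "c")) * -1,
                     few = calinskiHarabasz(emb2, rep(c("a", "b"), each = 3)) * -1))))
})

test_that("the >30-cluster fallback triggers exactly past the ceiling", {
  set.seed(5)
  n <- 62
  emb <- cbind(seq_len(n) * 10 + rnorm(n, sd = 0.01))
  lab31 <- as.character(rep(1:31, each = 2))
  lab30 <- as.character(rep(1:30, length.out = n))
  fb <- as.character(rep(1:2, each = n / 2))
  # 31 tight pairs outscore 30 ragged clusters, but breach the ceiling
  sel <- suppressMessages(
    selectClustering(emb, list(a = lab31, b = lab30), fallback = fb))
  expect_true(attr(sel, "fallback"))
  expect_identical(as.character(sel), fb)
  # at exactly 30 clusters the winner stands
  emb2 <- cbind(rep(seq_len(30) * 10, each = 2) + rnorm(60, sd = 0.01))
  sel2 <- selectClustering(
    emb2, list(a = as.character(rep(1:30, each = 2)), b = fb[1:60]),
    fallback = fb[1:60])
  expect_false(attr(sel2, "fallback"))
})

test_that("cluster-number recovery on separated Gaussian blobs", {
  set.seed(6)
  hits <- 0
  for (rep in 1:100) {
    k_true <- sample(2:6, 1)
    centers <- matrix(rnorm(k_true * 2), k_true, 2) * 0.3 +
      cbind(seq_len(k_true) * 8, (seq_len(k_true) %% 2) * 8)
    emb <- do.call(rbind, lapply(seq_len(k_true), function(i)
      cbind(rnorm(25, centers[i, 1]), rnorm(25, centers[i, 2]))))
    cands <- lapply(2:8, function(k)
      as.character(kmeans(emb, k, nstart = 25, iter.max = 30)$cluster))
    names(cands) <- paste0("k", 2:8)
    sel <- selectClustering(emb, cands, fallback = cands[[1]])
    if (length(unique(sel)) == k_true) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
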