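test_that("activation propagates signs along determined regulators", {
  # plain activating chain
  trn <- make_trn(data.frame(source = c("A", "B"), target = c("B", "C"),
                             sign = 1))
  expect_identical(simulateActivation(trn, "A"), c(A = 1L, B = 1L, C = 1L))

  # undetermined inhibitor does not veto a determined activator
  trn <- make_trn(data.frame(source = c("A", "C"), target = c("B", "B"),
                             sign = c(1, -1)))
  expect_identical(simulateActivation(trn, "A")[["B"]], 1L)

  # sign handling on a fork
  trn <- make_trn(data.frame(source = "A", target = c("B", "C"),
                             sign = c(1, -1)))
  expect_identical(simulateActivation(trn, "A"),
                   c(A = 1L, B = 1L, C = 0L))

  # a determined active inhibitor dominates any number of activators
  trn <- make_trn(data.frame(source = c("A", "A", "B"),
                             target = c("B", "C", "C"), sign = c(1, 1, -1)))
  expect_identical(simulateActivation(trn, "A")[["C"]], 0L)
})

test_that("activation agrees with a naive oracle on all 3-node digraphs", {
  pairs3 <- subset(expand.grid(source = c("A", "B", "C"),
                               target = c("A", "B", "C"),
                               stringsAsFactors = FALSE), source != target)
  signs <- c(0, 1, -1)  # absent / activating / inhibiting per ordered pair
  grid <- do.call(expand.grid, rep(list(1:3), 6))
  fp_checked <- 0
  for (r in seq_len(nrow(grid))) {
    sg <- signs[as.integer(grid[r, ])]
    e <- pairs3[sg != 0, , drop = FALSE]
    if (!nrow(e)) next
    e$sign <- sg[sg != 0]
    trn <- make_trn(e)
    for (tf in nodes(trn)) {
      got <- simulateActivation(trn, tf)
      want <- oracle_activation(e, tf)
      expect_identical(got, want[names(got)], ignore_attr = TRUE)
      # converged results must be fixed points of the clamped update map
      if (attr(want, "converged") && r %% 37 == 0) {
        fps <- oracle_fixed_points(e, tf)
        expect_true(any(vapply(fps, function(f)
          identical(unname(f), unname(got)), logical(1))))
        fp_checked <- fp_checked + 1
      }
    }
  }
  expect_gte(fp_checked, 20)
})

test_that("activation agrees with the oracle on random 4-node digraphs", {
  set.seed(19)
  for (rep in 1:150) {
    e <- random_signed_digraph(4, p_edge = 0.4)
    if (!nrow(e)) next
    trn <- make_trn(e)
    tf <- sample(nodes(trn), 1)
    expect_identical(simulateActivation(trn, tf),
                     oracle_activation(e, tf)[names(simulateActivation(trn, tf))],
                     ignore_attr = TRUE)
  }
})

test_that("scores honour the printed corner cases", {
  # root of a fully hierarchical consistent network scores 1.0
  pn <- simulatePlantedTRN(n_tfs = 3, n_targets = 4, seed = 1)
  trn <- prunePKN(pn@pkn, pn@profile)
  expect_identical(tfScore(trn, plantedMR(pn)), 1)

  # an end node with state 1 scores exactly 1/N, for every N in 2..20
  for (n in 2:20) {
    chain <- data.frame(source = paste0("n", seq_len(n - 1)),
                        target = paste0("n", seq_len(n - 1) + 1), sign = 1)
    st <- stats::setNames(rep(1L, n), paste0("n", 1:n))
    trn <- make_trn(chain, st)
    expect_identical(networkSize(trn), as.integer(n))
    expect_equal(tfScore(trn, paste0("n", n)), 1 / n)
  }

  # a TF whose booleanized state is 0 scores 0, whatever its reach
  trn <- make_trn(data.frame(source = "A", target = c("B", "C"), sign = 1),
                  c(A = 0L, B = 1L, C = 1L))
  expect_identical(tfScore(trn, "A"), 0)
})

test_that("flipped profile states subtract exactly from the root score", {
  pn <- simulatePlantedTRN(n_tfs = 3, n_targets = 4, branching = 2,
                           noise_fraction = 0.3, seed = 5)
  # 2 of 6 non-root nodes flipped: on the intact tree the root's activation
  # still determines every node, so it matches exactly the unflipped 5 of 7
  expect_equal(explainedFraction(pn), 5 / 7)
  trn <- TRN(edges(pn), pn@profile)
  expect_equal(tfScore(trn, plantedMR(pn)), 5 / 7)
})

test_that("scores lie in [0,1] and are bounded by reachability", {
  set.seed(23)
  for (rep in 1:30) {
    e <- random_signed_digraph(sample(4:6, 1), p_edge = 0.4)
    if (!nrow(e)) next
    nd <- sort(unique(c(e$source, e$target)))
    st <- stats::setNames(sample(0:1, length(nd), replace = TRUE), nd)
    trn <- make_trn(e, st)
    g <- igraph::graph_from_data_frame(e[c("source", "target")],
                                       vertices = nd)
    for (tf in unique(e$source)) {
      sc <- tfScore(trn, tf)
      expect_gte(sc, 0)
      expect_lte(sc, 1)
      reach <- sum(is.finite(igraph::distances(g, v = tf, mode = "out"))) - 1
      expect_lte(sc, (1 + reach) / networkSize(trn))
    }
  }
})

test_that("scores are invariant to node-order permutation of the edges", {
  set.seed(31)
  e <- random_signed_digraph(6, p_edge = 0.4)
  nd <- sort(unique(c(e$source, e$target)))
  st <- stats::setNames(sample(0:1, length(nd), replace = TRUE), nd)
  base <- scoreAllTFs(make_trn(e, st))
  for (rep in 1:5) {
    perm <- e[sample(nrow(e)), , drop = FALSE]
    expect_equal(scoreAllTFs(make_trn(perm, st)), base)
  }
})

test_that("master-regulator classification is inclusive at the threshold", {
  tab <- data.frame(tf = c("a", "b", "c"), score = c(0.35, 0.30, 0.10))
  expect_identical(classifyMasterRegulators(tab), c("a", "b"))
})

test_that("score table flags MRs and reports determined counts over N", {
  pn <- simulatePlantedTRN(n_tfs = 3, n_targets = 4, seed = 2)
  trn <- prunePKN(pn@pkn, pn@profile)
  tab <- scoreAllTFs(trn)
  expect_identical(tab$tf[1], plantedMR(pn))
  expect_true(all(tab$n == networkSize(trn)))
  expect_equal(tab$score, tab$determined / tab$n)
  expect_identical(tab$is_mr, tab$score >= 0.30)
})

test_that("aggregation treats absent TFs as zero and ranks by mean score", {
  t1 <- data.frame(tf = c("a", "b"), score = c(1.0, 0.4))
  t2 <- data.frame(tf = "b", score = 0.6)
  agg <- aggregateTopTFs(list(x = t1, y = t2), k = 30)
  expect_equal(agg$matrix["a", "y"], 0)
  expect_equal(agg$ranking$mean_score[agg$ranking$tf == "a"], 0.5)
  expect_equal(agg$ranking$mean_score[agg$ranking$tf == "b"], 0.5)

  # TF present once with score 1.0 across 10 conditions averages 0.1
  many <- c(list(t1), replicate(9, data.frame(tf = "z", score = 0.2),
                                simplify = FALSE))
  agg2 <- aggregateTopTFs(many)
  expect_equal(agg2$ranking$mean_score[agg2$ranking$tf == "a"], 0.1)

  # k beyond the TF universe returns everything without padding
  expect_identical(nrow(aggregateTopTFs(list(t1), k = 10)$ranking), 2L)
})

test_that("the planted master regulator is recovered across seeds", {
  top_hit <- logical(60)
  for (i in seq_along(top_hit)) {
    n_tf <- sample(3:10, 1)
    n_tg <- sample(6:30, 1)
    br <- ceiling((n_tf + n_tg - 1) / n_tf)
    pn <- simulatePlantedTRN(n_tf, n_tg, branching = br,
                             inhibitor_fraction = 0.25,
                             noise_fraction = 0.08, seed = 1000 + i)
    trn <- prunePKN(pn@pkn, pn@profile)
    tab <- scoreAllTFs(trn)
    top_hit[i] <- tab$tf[1] == plantedMR(pn)
  }
  expect_gte(mean(top_hit), 0.9)
})
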