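test_that("top_k_similar matches a full-sort oracle and the tie rule", {
  withr::with_seed(8, {
    ref <- matrix(runif(8 * 3), nrow = 8)
    query <- matrix(runif(3 * 3), nrow = 3)
  })
  got <- top_k_similar(ref, query, k = 4)
  for (q in 1:3) {
    expect_equal(got[q, ], oracle_top_k(ref, query[q, ], 4))
  }
  # identical query to reference row 3, orthogonal-ish others, k = 1
  ident <- matrix(ref[3, ], nrow = 1)
  expect_equal(top_k_similar(ref, ident, k = 1)[1, 1], 3L)
  # all-tied correlations: smallest indices win
  const_ref <- matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)
  q1 <- matrix(c(1, 2, 3), nrow = 1)
  expect_equal(top_k_similar(const_ref, q1, k = 2)[1, ], c(1L, 2L))
  expect_error(top_k_similar(ref, query, k = 8), "candidate")
})

test_that("M1, M2 and N match double-loop oracles on random toys", {
  toy <- toy_instance(n_bins = 12, n_genes = 5, n_cells = 6, seed = 17)
  genes <- colnames(toy$atlas)
  k <- 3
  expect_equal(metric_m1(toy$atlas, toy$geometry, genes, k),
               oracle_m1(toy$atlas, toy$geometry, genes, k))
  expect_equal(metric_m2(toy$atlas, toy$cells, toy$geometry, genes, k),
               oracle_m2(toy$atlas, toy$cells, toy$geometry, genes, k))
  gold_bins <- withr::with_seed(9, sample.int(12, 6, replace = TRUE))
  gold <- data.frame(cell = rownames(toy$cells), bin = gold_bins)
  expect_equal(metric_n(toy$cells, gold, toy$geometry, genes, k),
               oracle_n(toy$cells, gold_bins, toy$geometry, genes, k))
  # subsets too
  sub <- genes[c(2, 4, 5)]
  expect_equal(metric_m1(toy$atlas, toy$geometry, sub, k),
               oracle_m1(toy$atlas, toy$geometry, sub, k))
  expect_equal(metric_m2(toy$atlas, toy$cells, toy$geometry, sub, k),
               oracle_m2(toy$atlas, toy$cells, toy$geometry, sub, k))
})

test_that("metrics are invariant under rigid motions and scale with coordinates", {
  toy <- toy_instance(n_bins = 10, n_genes = 4, n_cells = 5, seed = 23)
  genes <- colnames(toy$atlas)
  k <- 3
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3)
  moved <- toy$geometry %*% rot + matrix(c(5, -2, 7), nrow = 10, ncol = 3, byrow = TRUE)
  m1 <- metric_m1(toy$atlas, toy$geometry, genes, k)
  expect_equal(metric_m1(toy$atlas, moved, genes, k), m1)
  expect_equal(metric_m1(toy$atlas, toy$geometry * 2.5, genes, k), 2.5 * m1)
  m2 <- metric_m2(toy$atlas, toy$cells, toy$geometry, genes, k)
  expect_equal(metric_m2(toy$atlas, toy$cells, moved, genes, k), m2)
  # gene order within the signature is irrelevant
  expect_equal(metric_m1(toy$atlas, toy$geometry, rev(genes), k), m1)
  expect_equal(metric_m2(toy$atlas, toy$cells, toy$geometry, rev(genes), k), m2)
})

test_that("M2 limiting and constructed cases behave as derived", {
  # k = 1: only the self term survives, M2 = 0
  toy <- toy_instance(n_bins = 8, n_genes = 4, n_cells = 3, seed = 31)
  expect_equal(metric_m2(toy$atlas, toy$cells, toy$geometry, colnames(toy$atlas), k = 1), 0)

  # all cells sharing one gold bin make N = 0
  gold <- data.frame(cell = rownames(toy$cells), bin = rep(4L, 3))
  expect_equal(metric_n(toy$cells, gold, toy$geometry, colnames(toy$atlas), k = 2), 0)

  # two expression-identical cells with gold bins at distance d, k = 1: N = d
  cells2 <- toy$cells[c(1, 1), ]
  rownames(cells2) <- c("a", "b")
  geom_line <- cbind(x = 0:7, y = 0, z = 0)
  gold2 <- data.frame(cell = c("a", "b"), bin = c(1L, 6L))
  expect_equal(metric_n(cells2, gold2, geom_line, colnames(toy$atlas), k = 1), 5)
})

test_that("backward elimination is greedy-exact at each step", {
  toy <- toy_instance(n_bins = 10, n_genes = 6, n_cells = 5, seed = 29)
  obj <- unsupervised_objective(toy$atlas, toy$cells, toy$geometry, k = 3)
  trace <- backward_eliminate(obj, colnames(toy$atlas), target_size = 3)
  expect_s3_class(trace, "elimination_trace")
  expect_equal(nrow(trace$steps), 3)
  expect_equal(length(trace$final), 3)
  # replay: every recorded removal matches the exhaustive single-step oracle
  current <- colnames(toy$atlas)
  for (s in seq_len(nrow(trace$steps))) {
    expect_equal(trace$steps$removed_gene[s], oracle_elimination_step(obj, current))
    current <- setdiff(current, trace$steps$removed_gene[s])
  }
  expect_setequal(current, trace$final)

  # no-op when target_size equals the start size
  noop <- backward_eliminate(obj, colnames(toy$atlas), 6)
  expect_equal(nrow(noop$steps), 0)
  expect_equal(noop$final, colnames(toy$atlas))

  # constant objective: removal order is lexicographic by gene name
  const_trace <- backward_eliminate(function(g) 1, c("gb", "ga", "gc"), 1)
  expect_equal(const_trace$steps$removed_gene, c("ga", "gb"))

  expect_error(backward_eliminate(function(g) stop("boom"), c("a", "b"), 1),
               "objective failed when removing 'a'")
})

test_that("unsupervised selection retains planted signal genes", {
  fx <- prepared_fixture(fixture_spec(n_bins = 60, n_genes = 12, n_signal_genes = 8,
                                      n_cells = 40, noise_flip_rate = 0.05, seed = 19))
  sel <- select_genes(fx$atlas, fx$normalized, fx$geometry, "unsupervised",
                      target_size = 8, k = 5)
  expect_gte(mean(grepl("^sig", sel$final)), 0.8)
})

test_that("supervised selection uses the gold standard and supports per-fold runs", {
  fx <- prepared_fixture(fixture_spec(n_bins = 40, n_genes = 8, n_signal_genes = 6,
                                      n_cells = 30, noise_flip_rate = 0.02, seed = 37))
  folds <- make_cv_folds(nrow(fx$normalized), n_folds = 3, seed = 2)
  sel <- select_genes(fx$atlas, fx$normalized, fx$geometry, "supervised",
                      target_size = 5, gold = fx$gold_true, folds = folds, k = 4)
  expect_length(sel$final, 5)
  expect_length(sel$fold_signatures, 3)
  for (sig in sel$fold_signatures) expect_length(sig, 5)
  expect_error(select_genes(fx$atlas, fx$normalized, fx$geometry, "supervised",
                            target_size = 5), "gold standard")
})
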