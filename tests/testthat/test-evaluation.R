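# Small hand-checkable instances for the challenge scores.
make_pred <- function(bins, scores = NULL) {
  if (is.null(scores)) {
    scores <- matrix(rev(seq_len(ncol(bins))) / ncol(bins),
                     nrow = nrow(bins), ncol = ncol(bins), byrow = TRUE)
  }
  structure(list(bins = bins, scores = scores, k = ncol(bins)),
            class = "location_prediction")
}

test_that("location quality forms the d84/dk ratios with the zero-distance rule", {
  geom <- cbind(x = 0:7, y = 0, z = 0)
  gold <- data.frame(cell = c("a", "b"), bin = c(2L, 5L))
  ref <- make_pred(rbind(c(1L, 3L), c(4L, 6L)))   # both cells: distances {1,1}
  pred <- make_pred(rbind(c(4L, 8L), c(3L, 7L)))  # distances {2,6}/2=4 and {2,2}
  lq <- location_quality(pred, ref, gold, geom)
  expect_equal(lq$d_ref, c(1, 1))
  expect_equal(lq$d_k, c(4, 2))
  expect_equal(lq$p, c(0.25, 0.5))
  # s2 is the mean ratio; halved distances give s2 = 0.5 exactly
  pred2 <- make_pred(rbind(c(4L, 8L), c(3L, 7L)))
  expect_equal(score_s2(pred2, ref, gold, geom), 0.375)
  # a cell with d_k = 0 receives the maximum finite ratio
  pred3 <- make_pred(rbind(c(2L, 2L), c(3L, 7L)))
  lq3 <- location_quality(pred3, ref, gold, geom)
  expect_equal(lq3$p[1], max(lq3$p[is.finite(lq3$p)]))
})

test_that("s1 matches a term-by-term oracle and its perfect-prediction limit", {
  withr::with_seed(71, {
    atlas <- matrix(rbinom(8 * 4, 1, 0.5), nrow = 8,
                    dimnames = list(NULL, paste0("g", 1:4)))
  })
  geom <- cbind(x = 0:7, y = 0, z = 0)
  gold <- data.frame(cell = c("a", "b", "c"), bin = c(2L, 5L, 7L))
  ref <- make_pred(rbind(c(1L, 3L), c(4L, 6L), c(6L, 8L)))
  pred <- make_pred(rbind(c(3L, 4L), c(5L, 2L), c(7L, 1L)))
  genes <- colnames(atlas)
  got <- score_s1(pred, ref, gold, atlas, geom, genes)
  # term-by-term oracle
  d <- oracle_dist(geom)
  p <- vapply(1:3, function(c_) {
    mean(d[gold$bin[c_], ref$bins[c_, ]]) / mean(d[gold$bin[c_], pred$bins[c_, ]])
  }, numeric(1))
  mccs <- vapply(1:3, function(c_) {
    oracle_mcc(atlas[pred$bins[c_, 1], ], atlas[gold$bin[c_], ])
  }, numeric(1))
  expect_equal(got, sum(p / sum(p) * mccs))
  # predictions identical to gold with identical top-k geometry: s1 = 1
  perfect <- make_pred(cbind(gold$bin, gold$bin))
  # ensure non-degenerate profiles at the gold bins for an exact 1
  expect_equal(score_s1(perfect, perfect, gold, atlas, geom, genes), 1)
})

test_that("s3 matches a term-by-term oracle under both weight interpretations", {
  withr::with_seed(73, {
    atlas <- matrix(rbinom(8 * 4, 1, 0.5), nrow = 8,
                    dimnames = list(NULL, paste0("g", 1:4)))
    cells_bin <- matrix(rbinom(6 * 4, 1, 0.5), nrow = 6,
                        dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
    gold <- data.frame(cell = paste0("c", 1:6),
                       bin = sample.int(8, 6, replace = TRUE))
    pred <- make_pred(cbind(sample.int(8, 6, replace = TRUE),
                            sample.int(8, 6, replace = TRUE)))
    ref <- make_pred(cbind(sample.int(8, 6, replace = TRUE),
                           sample.int(8, 6, replace = TRUE)))
  })
  genes <- colnames(atlas)
  s3_oracle <- function(weight_bin_vec) {
    wts <- vapply(genes, function(g) {
      oracle_mcc(cells_bin[, g], atlas[cbind(weight_bin_vec, match(g, genes))])
    }, numeric(1))
    terms <- vapply(genes, function(g) {
      oracle_mcc(cells_bin[, g], atlas[cbind(pred$bins[, 1], match(g, genes))])
    }, numeric(1))
    sum(wts / sum(wts) * terms)
  }
  expect_equal(score_s3(pred, gold, cells_bin, atlas, genes), s3_oracle(gold$bin))
  expect_equal(score_s3(pred, gold, cells_bin, atlas, genes,
                        weight_bins = "ref84", ref_pred = ref),
               s3_oracle(ref$bins[, 1]))
  # top-1 predictions equal to gold: score terms equal weight terms
  perfect <- make_pred(cbind(gold$bin, gold$bin))
  wts <- vapply(genes, function(g) {
    oracle_mcc(cells_bin[, g], atlas[cbind(gold$bin, match(g, genes))])
  }, numeric(1))
  expect_equal(score_s3(perfect, gold, cells_bin, atlas, genes),
               sum(wts / sum(wts) * wts))
})

test_that("jaccard and its expectation behave as counted and enumerated", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("a"), c("a")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 1)
  jm <- jaccard_matrix(list(A = c("a", "b"), B = c("b", "c"), C = c("a", "b")))
  expect_equal(jm["A", "C"], 1)
  expect_equal(jm["A", "B"], 1 / 3)
  expect_equal(jm, t(jm))

  # E(J): full-set case and two-element enumeration
  expect_equal(expected_jaccard(10, 10), 1)
  expect_equal(expected_jaccard(2, 1), 0.5)
  # Monte-Carlo oracle at the challenge scale
  expect_equal(expected_jaccard(84, 20),
               oracle_expected_jaccard_mc(84, 20, nrep = 2e5, seed = 100),
               tolerance = 1e-3)
  # monotone in m at n = 84 (stability gap grows for smaller panels)
  ej <- vapply(c(20, 40, 60), expected_jaccard, numeric(1), n = 84)
  expect_true(all(diff(ej) > 0))
  expect_error(expected_jaccard(5, 6), "m must satisfy")
})

test_that("overlap p-value equals enumeration and the one-sided Fisher test", {
  expect_equal(fisher_overlap_pvalue(6, 3, 3, 2), oracle_fisher_enum(6, 3, 3, 2))
  expect_equal(fisher_overlap_pvalue(10, 4, 5, 0), 1)
  # cross-check against stats::fisher.test on the 2x2 overlap table
  p <- fisher_overlap_pvalue(84, 20, 20, 11)
  ft <- fisher.test(matrix(c(11, 9, 9, 55), 2), alternative = "greater")
  expect_equal(p, ft$p.value, tolerance = 1e-10)
  # non-increasing in the overlap
  ps <- vapply(0:8, function(ov) fisher_overlap_pvalue(30, 10, 10, ov), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(fisher_overlap_pvalue(10, 4, 4, 5), "overlap")
})

test_that("cv folds are near-equal, seeded and reproducible", {
  f <- make_cv_folds(20, 10, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 10))
  f2 <- make_cv_folds(23, 10, seed = 3)
  expect_equal(sort(as.integer(table(f2))), c(rep(2L, 7), rep(3L, 3)))
  expect_identical(make_cv_folds(23, 10, seed = 3), f2)
  expect_false(identical(make_cv_folds(23, 10, seed = 4), f2))
  expect_error(make_cv_folds(5, 10), "more folds than cells")
})

test_that("pattern reconstruction is the positive-score weighted average", {
  P <- rbind(c(0.5, 0.5, 0), c(-1, 2, 2), c(0, 0, 0), c(3, -2, 1))
  cells <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
                  dimnames = list(paste0("c", 1:3), c("gA", "gB")))
  got <- reconstruct_pattern(P, cells, "gA")
  manual <- c((0.5 * 1 + 0.5 * 3) / 1, (2 * 3 + 2 * 5) / 4, 0, (3 * 1 + 1 * 5) / 4)
  expect_equal(got, manual)
  # single positive-scoring cell: pattern is that cell's value everywhere scored
  P1 <- cbind(c(2, 1, 4, 3))
  expect_equal(reconstruct_pattern(P1, cells[1, , drop = FALSE], "gB"),
               rep(2, 4))
  # perfect one-to-one matching returns the matched cells' expression
  Pm <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(reconstruct_pattern(Pm, cells, "gA"), c(1, 5, 3))
  expect_error(reconstruct_pattern(P, cells, "nope"), "absent")

  expect_equal(pattern_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pattern_correlation(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(pattern_correlation(c(1, 1, 1), c(1, 2, 3)), 0)
  withr::with_seed(81, {
    a <- runif(20); b <- runif(20)
    expect_equal(pattern_correlation(a, b), cor(a, b))
  })
})
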