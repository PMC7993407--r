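# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: correlations go through stats::cor on scalar pairs,
# neighborhoods through full sorts, metrics through explicit double loops.

# Pearson correlation of two vectors with the zero-variance -> 0 convention.
oracle_pcc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

oracle_mcc <- function(x, y) {
  tp <- sum(x == 1 & y == 1); tn <- sum(x == 0 & y == 0)
  fp <- sum(x == 1 & y == 0); fn <- sum(x == 0 & y == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
}

# Top-k reference indices for one query vector, by full sort. Similarities
# are rounded to the same 10-decimal tie tolerance the package documents, so
# exact ties between binary profiles resolve by index here too.
oracle_top_k <- function(ref_mat, query_vec, k, exclude = NULL) {
  sims <- round(apply(ref_mat, 1, oracle_pcc, b = query_vec), 10)
  ord <- order(-sims, seq_along(sims))
  if (!is.null(exclude)) ord <- ord[ord != exclude]
  ord[seq_len(k)]
}

oracle_dist <- function(geometry) {
  d <- as.matrix(stats::dist(geometry))
  dimnames(d) <- NULL
  d
}

oracle_m1 <- function(atlas, geometry, genes, k) {
  w <- atlas[, genes, drop = FALSE]
  d <- oracle_dist(geometry)
  n <- nrow(w)
  total <- 0
  for (i in seq_len(n)) {
    nb <- oracle_top_k(w, w[i, ], k, exclude = i)
    for (j in nb) total <- total + d[i, j]
  }
  total / (k * n)
}

oracle_m2 <- function(atlas, cells, geometry, genes, k) {
  w <- atlas[, genes, drop = FALSE]
  y <- cells[, genes, drop = FALSE]
  d <- oracle_dist(geometry)
  total <- 0
  for (c_ in seq_len(nrow(y))) {
    nb <- oracle_top_k(w, y[c_, ], k)
    for (j in nb) total <- total + d[nb[1], j]
  }
  total / (k * nrow(y))
}

oracle_n <- function(cells, gold_bins, geometry, genes, k) {
  y <- cells[, genes, drop = FALSE]
  d <- oracle_dist(geometry)
  total <- 0
  for (c_ in seq_len(nrow(y))) {
    nb <- oracle_top_k(y, y[c_, ], k, exclude = c_)
    for (j in nb) total <- total + d[gold_bins[c_], gold_bins[j]]
  }
  total / (k * nrow(y))
}

oracle_m3 <- function(weights, genes, cells, atlas, geometry, gold_bins, k) {
  w <- sweep(atlas[, genes, drop = FALSE], 2, weights, "*")
  y <- sweep(cells[, genes, drop = FALSE], 2, weights, "*")
  d <- oracle_dist(geometry)
  total <- 0
  for (c_ in seq_len(nrow(y))) {
    nb <- oracle_top_k(w, y[c_, ], k)
    for (j in nb) total <- total + d[gold_bins[c_], j]
  }
  total / (k * nrow(y))
}

oracle_d_star <- function(geometry) {
  d <- oracle_dist(geometry)
  nearest <- vapply(seq_len(nrow(d)), function(i) min(d[i, -i]), numeric(1))
  stats::median(nearest)
}

# Monte-Carlo expected Jaccard of two independent uniform m-subsets of n.
oracle_expected_jaccard_mc <- function(n, m, nrep, seed) {
  withr::with_seed(seed, {
    mean(replicate(nrep, {
      k <- length(intersect(sample.int(n, m), sample.int(n, m)))
      k / (2 * m - k)
    }))
  })
}

# Exhaustive overlap tail probability over all pairs of subsets (tiny n).
oracle_fisher_enum <- function(n, m1, m2, overlap) {
  s1 <- utils::combn(n, m1, simplify = FALSE)
  s2 <- utils::combn(n, m2, simplify = FALSE)
  hits <- 0
  for (a in s1) for (b in s2) {
    if (length(intersect(a, b)) >= overlap) hits <- hits + 1
  }
  hits / (length(s1) * length(s2))
}

# One exhaustive backward-elimination step: the gene whose removal minimizes
# the objective (ties -> smallest gene name).
oracle_elimination_step <- function(objective, genes) {
  vals <- vapply(seq_along(genes), function(i) objective(genes[-i]), numeric(1))
  genes[order(vals, genes)[1]]
}
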