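# Challenge-style evaluation: the three consortium scores s1-s3, gene-set
# stability (Jaccard, expected Jaccard under random subsets, hypergeometric
# overlap test), cross-validation folds, and virtual in situ pattern
# reconstruction from the bin-cell score matrix.

#' Per-cell location quality d_K and weights p_K
#'
#' `d_K(c)` is the mean Euclidean distance between cell c's gold-standard
#' bin and its top-k predicted bins under the evaluated signature; `p_K(c) =
#' d_ref(c) / d_K(c)` where `d_ref` comes from the reference prediction made
#' with the full marker panel and uniform weights. A cell with `d_K = 0`
#' (all predictions at the gold bin) gets the maximum finite `p_K` over
#' cells, rewarding perfection without infinities; if no cell has a finite
#' ratio the weights are all 1.
#'
#' @param pred evaluated `location_prediction`.
#' @param ref_pred reference (full-panel, uniform-weight) prediction.
#' @param gold gold-standard assignment data.frame.
#' @param geometry bins x 3 coordinate matrix.
#' @return data.frame with one row per cell: `cell`, `d_k`, `d_ref`, `p`.
#' @export
location_quality <- function(pred, ref_pred, gold, geometry) {
  m <- nrow(pred$bins)
  if (nrow(ref_pred$bins) != m || nrow(gold) != m) {
    stopf("prediction, reference and gold standard must cover the same cells")
  }
  d <- bin_distances(geometry)
  mean_dist <- function(p) {
    vapply(seq_len(m), function(c_) mean(d[gold$bin[c_], p$bins[c_, ]]), numeric(1))
  }
  d_k <- mean_dist(pred)
  d_ref <- mean_dist(ref_pred)
  p <- ifelse(d_k > 0, d_ref / d_k, NA_real_)
  if (anyNA(p)) {
    finite_max <- suppressWarnings(max(p[is.finite(p)], na.rm = TRUE))
    p[is.na(p)] <- if (is.finite(finite_max)) finite_max else 1
  }
  data.frame(cell = gold$cell, d_k = d_k, d_ref = d_ref, p = p,
             stringsAsFactors = FALSE)
}

#' Score s1: p-weighted MCC between predicted and gold in situ profiles
#'
#' `s1 = sum_c [p(c)/sum(p)] * MCC(f_top1(c), f_gold(c))` where `f` is the
#' atlas profile restricted to the evaluated signature (set
#' `mcc_genes = colnames(atlas)` to compare full profiles instead).
#'
#' @inheritParams location_quality
#' @param atlas bins x genes binary atlas.
#' @param genes evaluated gene signature (defines K).
#' @param mcc_genes genes over which the profile MCC is taken (default: the
#'   evaluated signature).
#' @return a number in [-1, 1].
#' @export
score_s1 <- function(pred, ref_pred, gold, atlas, geometry, genes,
                     mcc_genes = genes) {
  lq <- location_quality(pred, ref_pred, gold, geometry)
  w <- restrict_genes(atlas, mcc_genes, "atlas")
  mccs <- vapply(seq_len(nrow(lq)), function(c_) {
    mcc(w[pred$bins[c_, 1], ], w[gold$bin[c_], ])
  }, numeric(1))
  sum(lq$p / sum(lq$p) * mccs)
}

#' Score s2: mean distance-ratio to the full-panel reference prediction
#'
#' `s2 = mean_c p(c)`; equals 1 when the evaluated prediction reproduces the
#' reference top-k distances cell-wise, and exceeds 1 when it is closer to
#' the gold bins than the reference.
#'
#' @inheritParams location_quality
#' @return a nonnegative number.
#' @export
score_s2 <- function(pred, ref_pred, gold, geometry) {
  mean(location_quality(pred, ref_pred, gold, geometry)$p)
}

#' Score s3: gene-wise expression-recovery MCC
#'
#' For each signature gene s, `MCC_c` is taken across cells between the
#' binarized scRNA value `t_cs` and the atlas value at a per-cell bin:
#' the top-1 predicted bin for the score term, and (by default) the
#' gold-standard bin for the weight term. Weights are normalized over the
#' signature: `s3 = sum_s u_s * MCC_c(t_.s, f_top1(.),s)` with
#' `u_s = MCC_c(t_.s, f_gold(.),s) / sum_i MCC_c(t_.i, f_gold(.),i)`.
#' `weight_bins = "ref84"` instead draws the weight-term bins from the
#' full-panel reference prediction's top-1 bins (the second reading of the
#' consortium formula).
#'
#' @param pred evaluated `location_prediction`.
#' @param gold gold-standard assignment.
#' @param cells_binarized cells x genes binary matrix covering `genes`.
#' @param atlas bins x genes binary atlas.
#' @param genes evaluated signature.
#' @param weight_bins `"gold"` (default) or `"ref84"`.
#' @param ref_pred required when `weight_bins = "ref84"`.
#' @return a number.
#' @export
score_s3 <- function(pred, gold, cells_binarized, atlas, genes,
                     weight_bins = c("gold", "ref84"), ref_pred = NULL) {
  weight_bins <- match.arg(weight_bins)
  t_ <- restrict_genes(cells_binarized, genes, "binarized expression")
  w <- restrict_genes(atlas, genes, "atlas")
  check_expression(t_, binary = TRUE)
  top1 <- pred$bins[, 1]
  wb <- switch(weight_bins,
               gold = gold$bin,
               ref84 = {
                 if (is.null(ref_pred)) stopf("weight_bins = 'ref84' needs ref_pred")
                 ref_pred$bins[, 1]
               })
  gene_mcc <- function(bins_per_cell, s) mcc(t_[, s], w[bins_per_cell, s])
  weights_raw <- vapply(seq_along(genes), function(s) gene_mcc(wb, s), numeric(1))
  terms <- vapply(seq_along(genes), function(s) gene_mcc(top1, s), numeric(1))
  norm <- sum(weights_raw)
  if (norm == 0) stopf("s3 weight normalizer is zero")
  sum(weights_raw / norm * terms)
}

#' Jaccard similarity of two gene sets
#'
#' `|A n B| / |A u B|`; two empty sets are defined as identical (J = 1).
#'
#' @param a,b character vectors (treated as sets).
#' @return a number in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over a list of gene sets
#'
#' @param sets list of character vectors (e.g. per-fold signatures).
#' @return symmetric matrix of Jaccard similarities with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) out[i, j] <- out[j, i] <- jaccard(sets[[i]], sets[[j]])
  }
  dimnames(out) <- list(names(sets), names(sets))
  out
}

#' Expected Jaccard similarity of two random m-subsets of n items
#'
#' Closed form `E(J) = sum_{k=0}^{m} [k/(2m-k)] * C(m,k) C(n-m, m-k) / C(n,m)`
#' (the intersection size of two independent uniform m-subsets is
#' hypergeometric).
#'
#' @param n total number of items (e.g. 84 markers).
#' @param m subset size (1 <= m <= n).
#' @return a number in [0, 1].
#' @export
expected_jaccard <- function(n, m) {
  if (m < 1 || m > n) stopf("m must satisfy 1 <= m <= n")
  k <- 0:m
  probs <- exp(lchoose(m, k) + lchoose(n - m, m - k) - lchoose(n, m))
  probs[m - k > n - m] <- 0
  sum(k / (2 * m - k) * probs)
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability that two independent uniform subsets of sizes `m1` and `m2`
#' drawn from `n` items share at least `overlap` elements (a one-sided
#' enrichment test, equivalent to a one-sided Fisher exact test on the
#' overlap table).
#'
#' @param n universe size.
#' @param m1,m2 subset sizes.
#' @param overlap observed intersection size.
#' @return a probability in (0, 1].
#' @export
fisher_overlap_pvalue <- function(n, m1, m2, overlap) {
  if (m1 > n || m2 > n) stopf("subset sizes cannot exceed the universe size")
  if (overlap > min(m1, m2) || overlap < 0) {
    stopf("overlap must lie in [0, min(m1, m2)]")
  }
  stats::phyper(overlap - 1, m1, n - m1, m2, lower.tail = FALSE)
}

#' Seeded cross-validation folds
#'
#' Random partition of `n_cells` into `n_folds` near-equal folds (sizes
#' differ by at most one); the same seed always gives the same partition.
#'
#' @param n_cells number of cells.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:n_folds`, one per cell.
#' @export
make_cv_folds <- function(n_cells, n_folds = 10, seed = 1) {
  if (n_folds > n_cells) stopf("more folds than cells")
  withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(n_folds), length.out = n_cells))
  })
}

#' Virtual in situ reconstruction of one gene's spatial pattern
#'
#' Per bin, a weighted average of the gene's expression over cells, with
#' weights `max(p_bc, 0)` normalized to sum 1 within the bin; bins whose
#' scores are all nonpositive get 0.
#'
#' @param P bins x cells score matrix (raw or smoothed).
#' @param cells cells x genes expression matrix.
#' @param gene gene name to reconstruct.
#' @return numeric vector of length `nrow(P)` (one value per bin).
#' @export
reconstruct_pattern <- function(P, cells, gene) {
  if (!gene %in% colnames(cells)) stopf("gene '%s' absent from expression matrix", gene)
  if (ncol(P) != nrow(cells)) {
    stopf("P has %d cells but expression has %d", ncol(P), nrow(cells))
  }
  w <- pmax(P, 0)
  rs <- rowSums(w)
  vals <- as.numeric(w %*% cells[, gene])
  ifelse(rs > 0, vals / rs, 0)
}

#' Pearson correlation between two spatial patterns
#'
#' Zero-variance patterns correlate as 0.
#'
#' @param reconstructed,reference numeric vectors of equal length.
#' @return a number in [-1, 1].
#' @export
pattern_correlation <- function(reconstructed, reference) {
  if (length(reconstructed) != length(reference)) stopf("pattern lengths differ")
  as.numeric(row_pcc(matrix(reconstructed, nrow = 1), matrix(reference, nrow = 1)))
}

#' All three challenge scores at once
#'
#' @inheritParams score_s1
#' @inheritParams score_s3
#' @return list with `s1`, `s2`, `s3` and `K` (signature size).
#' @export
challenge_scores <- function(pred, ref_pred, gold, cells_binarized, atlas,
                             geometry, genes) {
  list(s1 = score_s1(pred, ref_pred, gold, atlas, geometry, genes),
       s2 = score_s2(pred, ref_pred, gold, geometry),
       s3 = score_s3(pred, gold, cells_binarized, atlas, genes),
       K = length(genes))
}
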