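# Gold-standard bin assignment: Matthews correlation between each cell's
# binarized marker profile and every bin's in situ profile; each cell is
# assigned the bin maximizing the MCC.

#' Matthews correlation coefficient of two binary vectors
#'
#' Computed from the 2x2 contingency table as
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention that the result is 0 whenever a marginal is zero (constant
#' vector).
#'
#' @param x,y binary vectors of equal length.
#' @return a number in [-1, 1].
#' @export
mcc <- function(x, y) {
  if (length(x) != length(y)) {
    stopf("mcc: vector lengths differ (%d vs %d)", length(x), length(y))
  }
  if (length(x) == 0) stopf("mcc: empty vectors")
  if (!is_binary(x) || !is_binary(y)) stopf("mcc: entries must be 0 or 1")
  tp <- sum(x == 1 & y == 1)
  tn <- sum(x == 0 & y == 0)
  fp <- sum(x == 1 & y == 0)
  fn <- sum(x == 0 & y == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' MCC between every bin profile and every cell profile
#'
#' Vectorized over all bin-cell pairs via the contingency-table identities
#' (`TP = W t(T)` etc.); zero-marginal pairs score 0.
#'
#' @param cells cells x genes binary matrix (binarized expression).
#' @param atlas bins x genes binary reference atlas.
#' @param genes gene signature; must be present in both matrices.
#' @return bins x cells matrix of MCC values.
#' @export
mcc_matrix <- function(cells, atlas, genes = colnames(atlas)) {
  check_atlas(atlas)
  check_expression(cells, binary = TRUE)
  w <- restrict_genes(atlas, genes, "atlas")
  t_ <- restrict_genes(cells, genes, "expression matrix")
  tp <- tcrossprod(w, t_)
  fp <- tcrossprod(w, 1 - t_)
  fn <- tcrossprod(1 - w, t_)
  tn <- tcrossprod(1 - w, 1 - t_)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- (tp * tn - fp * fn) / sqrt(ifelse(den > 0, den, 1))
  out[den == 0] <- 0
  dimnames(out) <- list(rownames(w), rownames(t_))
  out
}

#' Assign each cell its gold-standard bin
#'
#' Per cell, the bin with the maximum MCC score; ties broken toward the
#' smallest bin index so assignments are reproducible.
#'
#' @param scores bins x cells score matrix (e.g. from [mcc_matrix()]).
#' @return data.frame with one row per cell: `cell` (label or index),
#'   `bin` (1-based bin index) and `score` (the attained maximum).
#' @export
assign_gold_standard <- function(scores) {
  if (length(scores) == 0) stopf("empty score matrix")
  bin <- apply(scores, 2, which.max)  # which.max: first maximum = smallest index
  score <- scores[cbind(bin, seq_len(ncol(scores)))]
  cells <- if (!is.null(colnames(scores))) colnames(scores) else as.character(seq_len(ncol(scores)))
  data.frame(cell = cells, bin = as.integer(bin), score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' Full gold-standard pipeline from binarized cells
#'
#' Convenience wrapper: [mcc_matrix()] then [assign_gold_standard()].
#'
#' @inheritParams mcc_matrix
#' @return as [assign_gold_standard()].
#' @export
gold_standard <- function(cells, atlas, genes = colnames(atlas)) {
  assign_gold_standard(mcc_matrix(cells, atlas, genes))
}
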