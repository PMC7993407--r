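# Internal numeric helpers shared across the pipeline.

#' Pearson correlation between the rows of two matrices
#'
#' Computes the full Pearson correlation matrix between every row of `x` and
#' every row of `y`, with the convention -- used throughout the pipeline --
#' that a zero-variance vector has correlation 0 with everything. This
#' convention matters because atlas profiles are binary and can be constant
#' over a small gene signature.
#'
#' @param x numeric matrix, one observation vector per row.
#' @param y numeric matrix with the same number of columns as `x`.
#' @return `nrow(x)` x `nrow(y)` matrix of correlations in [-1, 1].
#' @keywords internal
row_pcc <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) {
    stop("row_pcc: feature dimensions differ (", ncol(x), " vs ", ncol(y), ")")
  }
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  xn <- sqrt(rowSums(xc^2))
  yn <- sqrt(rowSums(yc^2))
  num <- tcrossprod(xc, yc)
  den <- outer(xn, yn)
  r <- num / ifelse(den > 0, den, 1)
  r[outer(xn == 0, yn == 0, "|")] <- 0
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- NULL
  r
}

# Column-wise Pearson correlation of one matrix with itself, zero-variance
# columns correlating as 0.
col_pcc <- function(x) row_pcc(t(x), t(x))

# Index order for descending score with smallest-index tie break.
order_desc_ties_first <- function(scores) order(-scores, seq_along(scores))

# Similarities are rounded before ranking so that exact ties (common between
# binary profiles) are resolved by the index rule rather than by float noise,
# keeping neighbor sets identical across algebraically equivalent routes.
RANK_DIGITS <- 10L
rank_round <- function(x) round(x, RANK_DIGITS)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_binary <- function(x) all(x %in% c(0, 1))

# --- validators for the three core containers ------------------------------

check_atlas <- function(atlas) {
  if (!is.matrix(atlas) || !is.numeric(atlas)) {
    stopf("atlas must be a numeric matrix (bins x genes)")
  }
  if (is.null(colnames(atlas))) stopf("atlas must carry gene names as colnames")
  if (anyDuplicated(colnames(atlas))) stopf("atlas gene names must be unique")
  if (!is_binary(atlas)) stopf("atlas entries must all be 0 or 1")
  invisible(atlas)
}

check_geometry <- function(geometry, n_bins = NULL) {
  if (!is.matrix(geometry) || !is.numeric(geometry) || ncol(geometry) != 3) {
    stopf("geometry must be a numeric matrix with 3 columns (x, y, z)")
  }
  if (!all(is.finite(geometry))) stopf("geometry coordinates must be finite")
  if (!is.null(n_bins) && nrow(geometry) != n_bins) {
    stopf("geometry has %d rows but the atlas has %d bins", nrow(geometry), n_bins)
  }
  invisible(geometry)
}

check_expression <- function(cells, binary = FALSE) {
  if (!is.matrix(cells) || !is.numeric(cells)) {
    stopf("cell expression must be a numeric matrix (cells x genes)")
  }
  if (is.null(colnames(cells))) stopf("cell expression must carry gene names as colnames")
  if (anyDuplicated(colnames(cells))) stopf("expression gene names must be unique")
  if (binary && !is_binary(cells)) stopf("binarized expression entries must all be 0 or 1")
  invisible(cells)
}

# Restrict a labelled matrix to a gene signature, preserving signature order.
restrict_genes <- function(mat, genes, what = "matrix") {
  genes <- as.character(genes)
  if (length(genes) == 0) stopf("empty gene signature")
  if (anyDuplicated(genes)) stopf("gene signature contains duplicates")
  missing <- setdiff(genes, colnames(mat))
  if (length(missing) > 0) {
    stopf("%s is missing gene(s): %s", what, paste(missing, collapse = ", "))
  }
  mat[, genes, drop = FALSE]
}

# Pairwise Euclidean distance matrix between bin coordinates.
bin_distances <- function(geometry) {
  d <- as.matrix(stats::dist(geometry))
  dimnames(d) <- NULL
  d
}
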