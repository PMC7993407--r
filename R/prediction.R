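# Cell-to-bin scoring and neighbor-weighted prediction. The raw bin-cell
# association matrix C holds the (optionally gene-weighted) Pearson
# correlation between every bin's in situ profile and every cell's
# expression profile. Smoothing multiplies C by the affinity matrix
# A_ij = exp(-d_ij / d*), upweighting locations whose spatial neighbors also
# score highly; d* is the median nearest-bin distance.

#' Raw bin-cell association matrix C
#'
#' `C_ij` = Pearson correlation between bin i's atlas profile and cell j's
#' expression over the signature, both multiplied entry-wise by the gene
#' weights first. Zero-variance vectors correlate as 0. With uniform weights
#' this is plain profile correlation; rescaling the weight vector by a
#' positive constant leaves C unchanged up to that scheme's PCC invariance.
#'
#' @param cells cells x genes expression matrix.
#' @param atlas bins x genes binary atlas.
#' @param genes gene signature.
#' @param weights per-gene weight vector of length `length(genes)`, or
#'   `NULL` for uniform weights.
#' @return bins x cells numeric matrix (stage: raw C).
#' @export
score_cells <- function(cells, atlas, genes = colnames(atlas), weights = NULL) {
  w_mat <- restrict_genes(atlas, genes, "atlas")
  y_mat <- restrict_genes(cells, genes, "expression matrix")
  if (!is.null(weights)) {
    if (length(weights) != length(genes)) {
      stopf("weights length %d does not match signature size %d",
            length(weights), length(genes))
    }
    if (!all(is.finite(weights))) stopf("weights must be finite")
    w_mat <- sweep(w_mat, 2, weights, "*")
    y_mat <- sweep(y_mat, 2, weights, "*")
  }
  row_pcc(w_mat, y_mat)
}

#' Neighborhood scale d*: median nearest-bin distance
#'
#' @param geometry bins x 3 coordinate matrix with no duplicated points.
#' @return positive number; the median over bins of the distance to each
#'   bin's nearest other bin (even counts: midpoint of the central pair).
#' @export
compute_d_star <- function(geometry) {
  check_geometry(geometry)
  if (nrow(geometry) < 2) stopf("d* needs at least 2 bins")
  d <- bin_distances(geometry)
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  if (any(nearest == 0)) {
    stopf("duplicate bin coordinates found; deduplicate the geometry first")
  }
  stats::median(nearest)
}

#' Exponential-decay bin affinity matrix
#'
#' `A_ij = exp(-d_ij / d_star)`; the diagonal is exactly 1 and entries decay
#' with distance so that only near neighbors meaningfully contribute.
#'
#' @param geometry bins x 3 coordinate matrix.
#' @param d_star positive decay scale (default [compute_d_star()]).
#' @return bins x bins symmetric matrix with unit diagonal.
#' @export
build_affinity <- function(geometry, d_star = compute_d_star(geometry)) {
  if (!is.numeric(d_star) || length(d_star) != 1 || d_star <= 0) {
    stopf("d_star must be a single positive number")
  }
  exp(-bin_distances(geometry) / d_star)
}

#' Neighbor-weighted smoothing P = A x C
#'
#' Plain matrix product: each bin's final score for a cell is its own raw
#' score plus the affinity-weighted scores of all other bins.
#'
#' @param C bins x cells raw association matrix.
#' @param A bins x bins affinity matrix.
#' @return bins x cells smoothed score matrix.
#' @export
neighbor_reweight <- function(C, A) {
  if (nrow(A) != ncol(A)) stopf("affinity matrix must be square")
  if (ncol(A) != nrow(C)) {
    stopf("shape mismatch: affinity is %dx%d but C has %d bins",
          nrow(A), ncol(A), nrow(C))
  }
  A %*% C
}

#' Top-k locations per cell
#'
#' @param P bins x cells score matrix.
#' @param k locations reported per cell (default 10); ties broken toward the
#'   smaller bin index.
#' @return object of class `location_prediction`: list with `bins` and
#'   `scores`, both cells x k matrices (scores non-increasing within a row),
#'   and `k`.
#' @export
top_locations <- function(P, k = 10) {
  if (k > nrow(P)) stopf("k = %d exceeds the number of bins (%d)", k, nrow(P))
  m <- ncol(P)
  bins <- matrix(0L, nrow = m, ncol = k)
  scores <- matrix(0, nrow = m, ncol = k)
  for (j in seq_len(m)) {
    ord <- order_desc_ties_first(P[, j])[seq_len(k)]
    bins[j, ] <- ord
    scores[j, ] <- P[ord, j]
  }
  rownames(bins) <- rownames(scores) <- colnames(P)
  structure(list(bins = bins, scores = scores, k = k), class = "location_prediction")
}

#' @export
print.location_prediction <- function(x, ...) {
  cat(sprintf("Location prediction: %d cell(s), top-%d bins each\n",
              nrow(x$bins), x$k))
  invisible(x)
}

#' End-to-end location prediction
#'
#' [score_cells()], optionally [neighbor_reweight()] with the affinity built
#' from the geometry, then [top_locations()]. The `preset` argument mirrors
#' the three challenge configurations: `"sc1"` = learned weights + neighbor
#' weighting (60 genes), `"sc2"` = uniform weights + neighbor weighting
#' (40 genes), `"sc3"` = learned weights, no neighbor weighting (20 genes).
#' A preset only toggles `weights`/`neighbor_weighting` defaults; explicit
#' arguments win.
#'
#' @inheritParams score_cells
#' @param geometry bins x 3 coordinate matrix.
#' @param neighbor_weighting smooth C with the affinity matrix first?
#' @param k locations per cell.
#' @param preset optional `"sc1"`, `"sc2"` or `"sc3"`.
#' @return a `location_prediction` (see [top_locations()]), with the raw and
#'   smoothed score matrices attached as attributes `C` and `P`.
#' @export
predict_locations <- function(cells, atlas, geometry, genes = colnames(atlas),
                              weights = NULL, neighbor_weighting = TRUE, k = 10,
                              preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sc1", "sc2", "sc3"))
    if (preset == "sc2") weights <- NULL
    if (preset == "sc3") neighbor_weighting <- FALSE
  }
  check_geometry(geometry, nrow(atlas))
  C <- score_cells(cells, atlas, genes, weights)
  P <- if (neighbor_weighting) neighbor_reweight(C, build_affinity(geometry)) else C
  pred <- top_locations(P, k)
  attr(pred, "C") <- C
  attr(pred, "P") <- P
  pred
}
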