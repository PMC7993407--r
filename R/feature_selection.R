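# Topological-consistency gene selection. Three metrics measure how well a
# gene signature G keeps expression-similar items geometrically close:
#   M1 (unsupervised, atlas only): mean distance from each bin to its k most
#       correlation-similar bins;
#   M2 (unsupervised, atlas + cells): mean distance from each cell's best-
#       matching bin to the cell's k most similar bins (self included);
#   N  (supervised): mean distance between gold-standard bins of each cell
#       and its k most expression-similar cells.
# All three are searched by greedy stepwise backward elimination.

#' Indices of the k most correlation-similar reference vectors per query
#'
#' Similarity is Pearson correlation between rows (zero-variance rows
#' correlate as 0); ties are broken toward the smaller reference index.
#'
#' @param reference_vectors matrix, one candidate vector per row.
#' @param query_vectors matrix with the same number of columns.
#' @param k neighbors retained per query.
#' @param exclude_self if `TRUE` and query `i` is reference `i` (same matrix),
#'   the self index is skipped.
#' @return `nrow(query_vectors)` x `k` matrix of reference indices.
#' @export
top_k_similar <- function(reference_vectors, query_vectors, k, exclude_self = FALSE) {
  n_ref <- nrow(reference_vectors)
  if (k >= n_ref) {  # with self-exclusion k = n_ref - 1 uses every other item
    stopf("k = %d but only %d candidate item(s)", k, n_ref)
  }
  sim <- rank_round(row_pcc(query_vectors, reference_vectors))
  out <- matrix(0L, nrow = nrow(sim), ncol = k)
  for (i in seq_len(nrow(sim))) {
    ord <- order_desc_ties_first(sim[i, ])
    if (exclude_self) ord <- ord[ord != i]
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' Unsupervised metric M1: spatial spread of expression-similar bins
#'
#' `M1 = sum_i sum_{j in L_k(i)} D_ij / (k n)` where `L_k(i)` holds the k
#' bins whose atlas profiles over `genes` correlate best with bin `i`'s
#' (self excluded) and `D` is the Euclidean bin distance matrix.
#'
#' @param atlas bins x genes binary atlas.
#' @param geometry bins x 3 coordinate matrix.
#' @param genes gene signature.
#' @param k neighborhood size (default 10).
#' @return nonnegative number.
#' @export
metric_m1 <- function(atlas, geometry, genes = colnames(atlas), k = 10) {
  check_geometry(geometry, nrow(atlas))
  w <- restrict_genes(atlas, genes, "atlas")
  n <- nrow(w)
  if (n < k + 1) stopf("M1 needs at least k + 1 = %d bins, have %d", k + 1, n)
  d <- bin_distances(geometry)
  nn <- top_k_similar(w, w, k, exclude_self = TRUE)
  total <- sum(d[cbind(rep(seq_len(n), each = k), as.vector(t(nn)))])
  total / (k * n)
}

#' Unsupervised metric M2: spatial spread of a cell's best-matching bins
#'
#' For each cell, the k bins whose atlas profiles correlate best with the
#' cell's expression over `genes` are found (the single best bin `l_c` is
#' among them, contributing a zero distance); M2 is the mean distance from
#' `l_c` to those k bins.
#'
#' @inheritParams metric_m1
#' @param cells cells x genes expression matrix (normalized by default; the
#'   metric accepts binarized input equally).
#' @return nonnegative number.
#' @export
metric_m2 <- function(atlas, cells, geometry, genes = colnames(atlas), k = 10) {
  check_geometry(geometry, nrow(atlas))
  w <- restrict_genes(atlas, genes, "atlas")
  y <- restrict_genes(cells, genes, "expression matrix")
  if (nrow(w) < k + 1) stopf("M2 needs at least k + 1 = %d bins, have %d", k + 1, nrow(w))
  d <- bin_distances(geometry)
  nn <- top_k_similar(w, y, k, exclude_self = FALSE)
  best <- nn[, 1]  # highest-correlation bin; ties already resolved to smallest index
  total <- 0
  for (c_ in seq_len(nrow(y))) total <- total + sum(d[best[c_], nn[c_, ]])
  total / (k * nrow(y))
}

#' Supervised metric N: gold-bin spread of expression-similar cells
#'
#' `N = sum_c sum_{j in T_k(c)} D_{l*_c, l*_j} / (k m)` where `T_k(c)` holds
#' the k cells most correlation-similar to cell `c` over `genes` (self
#' excluded) and `l*` the gold-standard bin of each cell.
#'
#' @inheritParams metric_m2
#' @param gold gold-standard assignment data.frame (from [gold_standard()]),
#'   one row per cell in the order of `cells`.
#' @return nonnegative number.
#' @export
metric_n <- function(cells, gold, geometry, genes, k = 10) {
  y <- restrict_genes(cells, genes, "expression matrix")
  m <- nrow(y)
  if (nrow(gold) != m) stopf("gold standard covers %d cells, expression has %d", nrow(gold), m)
  if (m < k + 1) stopf("N needs at least k + 1 = %d cells, have %d", k + 1, m)
  check_geometry(geometry)
  d <- bin_distances(geometry)
  nn <- top_k_similar(y, y, k, exclude_self = TRUE)
  gb <- gold$bin
  total <- 0
  for (c_ in seq_len(m)) total <- total + sum(d[gb[c_], gb[nn[c_, ]]])
  total / (k * m)
}

#' Greedy stepwise backward elimination over gene signatures
#'
#' Starting from `start`, each step evaluates every single-gene removal,
#' keeps the subset minimizing `objective` (ties broken by removing the
#' lexicographically smallest gene name) and repeats until `target_size`
#' genes remain. Greedy: no optimality guarantee.
#'
#' @param objective function(character vector of genes) -> single number.
#' @param start character vector, the initial signature.
#' @param target_size final signature size (>= 1).
#' @return object of class `elimination_trace`: list with `steps`
#'   (data.frame step/removed_gene/objective) and `final` (character vector).
#' @export
backward_eliminate <- function(objective, start, target_size) {
  start <- as.character(start)
  if (anyDuplicated(start)) stopf("start signature contains duplicates")
  if (target_size < 1 || target_size > length(start)) {
    stopf("target_size must be in [1, %d]", length(start))
  }
  current <- start
  steps <- list()
  while (length(current) > target_size) {
    cand_obj <- vapply(seq_along(current), function(i) {
      val <- tryCatch(objective(current[-i]), error = function(e) {
        stopf("objective failed when removing '%s': %s", current[i], conditionMessage(e))
      })
      as.numeric(val)
    }, numeric(1))
    pick <- order(cand_obj, current)[1]  # min objective, ties -> smallest gene name
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, removed_gene = current[pick],
      objective = cand_obj[pick], stringsAsFactors = FALSE)
    current <- current[-pick]
  }
  steps_df <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), removed_gene = character(), objective = numeric())
  structure(list(steps = steps_df, final = current), class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("Backward elimination: %d step(s), final signature of %d gene(s)\n",
              nrow(x$steps), length(x$final)))
  if (nrow(x$steps) > 0) {
    cat(sprintf("  final objective %.4f\n", x$steps$objective[nrow(x$steps)]))
  }
  invisible(x)
}

#' Objective closures for gene selection
#'
#' `unsupervised_objective` returns `M1 + M2` (the two terms are distances in
#' the same coordinate units, summed unweighted); `supervised_objective`
#' returns `N`. Both close over their data so they can be handed to
#' [backward_eliminate()].
#'
#' @inheritParams metric_m2
#' @inheritParams metric_n
#' @return function(genes) -> number.
#' @export
unsupervised_objective <- function(atlas, cells, geometry, k = 10) {
  force(atlas); force(cells); force(geometry); force(k)
  function(genes) {
    metric_m1(atlas, geometry, genes, k) + metric_m2(atlas, cells, geometry, genes, k)
  }
}

#' @rdname unsupervised_objective
#' @export
supervised_objective <- function(cells, gold, geometry, k = 10) {
  force(cells); force(gold); force(geometry); force(k)
  function(genes) metric_n(cells, gold, geometry, genes, k)
}

#' Select a gene signature by backward elimination
#'
#' High-level driver. Unsupervised mode minimizes `M1 + M2` on the full data.
#' Supervised mode minimizes `N`; when `folds` is given it additionally runs
#' the elimination once per cross-validation fold (training cells only),
#' returning the per-fold signatures for stability analysis alongside the
#' full-data signature.
#'
#' @inheritParams metric_m2
#' @param mode `"unsupervised"` or `"supervised"`.
#' @param target_size final number of genes.
#' @param gold required in supervised mode.
#' @param folds optional integer fold-id vector (supervised mode), e.g. from
#'   [make_cv_folds()].
#' @param k neighborhood size.
#' @return list with `trace` (full-data [backward_eliminate()] result),
#'   `final` (character vector) and, when folds were given, `fold_signatures`
#'   (list of character vectors).
#' @export
select_genes <- function(atlas, cells, geometry, mode = c("unsupervised", "supervised"),
                         target_size, gold = NULL, folds = NULL, k = 10) {
  mode <- match.arg(mode)
  start <- colnames(atlas)
  if (mode == "unsupervised") {
    obj <- unsupervised_objective(atlas, cells, geometry, k)
    trace <- backward_eliminate(obj, start, target_size)
    return(list(trace = trace, final = trace$final))
  }
  if (is.null(gold)) stopf("supervised selection requires a gold standard")
  trace <- backward_eliminate(supervised_objective(cells, gold, geometry, k), start, target_size)
  out <- list(trace = trace, final = trace$final)
  if (!is.null(folds)) {
    out$fold_signatures <- lapply(sort(unique(folds)), function(f) {
      idx <- which(folds != f)  # train on all cells outside fold f
      obj <- supervised_objective(cells[idx, , drop = FALSE], gold[idx, , drop = FALSE],
                                  geometry, k)
      backward_eliminate(obj, start, target_size)$final
    })
  }
  out
}
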