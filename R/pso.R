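# Particle swarm optimization of per-gene weights. Each agent carries a
# candidate weight vector; fitness is M3, the mean distance between each
# training cell's gold-standard bin and the k bins most similar to the
# cell's weighted expression pattern. The update rule has no velocity
# memory:
#   w_i <- w_i + alpha * r1 o (Pbest_i - w_i) + beta * r2 o (Gbest - w_i)
# with r1, r2 fresh uniform(0,1) vectors per agent per iteration.

#' PSO configuration
#'
#' Defaults follow the full-scale setting (`alpha = beta = 0.2`, 200 agents,
#' 40 iterations); scale `n_agents`/`max_iter` down for small problems.
#'
#' @param alpha,beta nonnegative acceleration (trust) coefficients.
#' @param n_agents swarm size.
#' @param max_iter number of update iterations (0 = evaluate the initial
#'   swarm only).
#' @param seed integer seed driving initialization and all r-draws.
#' @param init_range length-2 numeric, uniform initialization box per entry.
#' @return list of class `pso_config`.
#' @export
pso_config <- function(alpha = 0.2, beta = 0.2, n_agents = 200, max_iter = 40,
                       seed = 1, init_range = c(0, 1)) {
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be nonnegative")
  if (n_agents < 1) stopf("need at least one agent")
  if (max_iter < 0) stopf("max_iter must be nonnegative")
  structure(list(alpha = alpha, beta = beta, n_agents = as.integer(n_agents),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 init_range = as.numeric(init_range)),
            class = "pso_config")
}

#' M3 fitness: distance of weighted-PCC top-k bins to the gold bin
#'
#' `M3 = sum_c sum_{j in S_k(c)} D_{l*_c, j} / (k m)` where `S_k(c)` are the
#' k bins whose (weighted) atlas profiles correlate best with cell c's
#' (weighted) expression, and `l*_c` is the cell's gold-standard bin. Both
#' profiles are multiplied entry-wise by `weights` before the correlation,
#' so positive rescaling of the weight vector leaves M3 unchanged.
#'
#' @param weights per-gene weight vector (length of `genes`).
#' @inheritParams metric_m2
#' @param gold gold-standard assignment for the rows of `cells`.
#' @return nonnegative number.
#' @export
fitness_m3 <- function(weights, genes, cells, atlas, geometry, gold, k = 10) {
  if (nrow(gold) != nrow(cells)) {
    stopf("gold standard covers %d cells, expression has %d", nrow(gold), nrow(cells))
  }
  check_geometry(geometry, nrow(atlas))
  C <- score_cells(cells, atlas, genes, weights)  # bins x cells
  d <- bin_distances(geometry)
  if (nrow(C) < k) stopf("M3 needs at least k = %d bins", k)
  Cr <- rank_round(C)
  total <- 0
  for (c_ in seq_len(ncol(C))) {
    topk <- order_desc_ties_first(Cr[, c_])[seq_len(k)]
    total <- total + sum(d[gold$bin[c_], topk])
  }
  total / (k * ncol(C))
}

# Evaluate all agent rows; error on non-finite fitness naming the agent.
eval_swarm <- function(positions, fitness) {
  fits <- vapply(seq_len(nrow(positions)), function(i) {
    f <- fitness(positions[i, ])
    if (!is.finite(f)) stopf("non-finite fitness for agent %d", i)
    f
  }, numeric(1))
  fits
}

#' Initialize a particle swarm
#'
#' Positions are uniform over `init_range` per entry; personal bests start
#' at the initial positions and the global best is the fittest agent.
#' Consumes the RNG stream (seed management belongs to the caller; see
#' [pso_optimize()]).
#'
#' @param n_dim weight-vector length.
#' @param config a [pso_config()].
#' @param fitness function(numeric vector) -> single finite number.
#' @return list of class `pso_state` with `positions`, `pbest`, `pbest_fit`,
#'   `gbest`, `gbest_fit`, `history`.
#' @export
pso_init <- function(n_dim, config, fitness) {
  lo <- config$init_range[1]; hi <- config$init_range[2]
  positions <- matrix(stats::runif(config$n_agents * n_dim, lo, hi),
                      nrow = config$n_agents, ncol = n_dim, byrow = TRUE)
  fits <- eval_swarm(positions, fitness)
  best <- which.min(fits)
  structure(list(positions = positions, pbest = positions, pbest_fit = fits,
                 gbest = positions[best, ], gbest_fit = fits[best],
                 history = fits[best]),
            class = "pso_state")
}

#' One synchronous PSO iteration
#'
#' All agents move using the previous iteration's personal/global bests
#' (draw order: agent 1's r1 then r2, agent 2's r1 then r2, ...), then all
#' fitnesses are evaluated and bests updated on strict improvement, so the
#' global-best fitness never increases.
#'
#' @param state a `pso_state`.
#' @inheritParams pso_init
#' @return the updated `pso_state`.
#' @export
pso_step <- function(state, config, fitness) {
  n_dim <- ncol(state$positions)
  newpos <- state$positions
  for (i in seq_len(nrow(newpos))) {
    r1 <- stats::runif(n_dim)
    r2 <- stats::runif(n_dim)
    wi <- state$positions[i, ]
    newpos[i, ] <- wi +
      config$alpha * r1 * (state$pbest[i, ] - wi) +
      config$beta * r2 * (state$gbest - wi)
  }
  fits <- eval_swarm(newpos, fitness)
  improved <- fits < state$pbest_fit
  state$positions <- newpos
  state$pbest[improved, ] <- newpos[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fits[improved]
  best <- which.min(state$pbest_fit)
  state$gbest <- state$pbest[best, ]
  state$gbest_fit <- state$pbest_fit[best]
  state$history <- c(state$history, state$gbest_fit)
  state
}

#' Run PSO to completion
#'
#' Seeds a private RNG stream from `config$seed` (the caller's RNG state is
#' untouched), initializes the swarm and runs `max_iter` steps. Identical
#' seeds give identical results.
#'
#' @inheritParams pso_init
#' @return list of class `pso_fit`: `weights` (global best), `fitness`
#'   (its fitness) and `history` (global-best fitness per iteration,
#'   non-increasing, length `max_iter + 1` including the initial swarm).
#' @export
pso_optimize <- function(n_dim, config, fitness) {
  state <- withr::with_seed(config$seed, {
    s <- pso_init(n_dim, config, fitness)
    for (it in seq_len(config$max_iter)) s <- pso_step(s, config, fitness)
    s
  })
  structure(list(weights = state$gbest, fitness = state$gbest_fit,
                 history = state$history),
            class = "pso_fit")
}

#' @export
print.pso_fit <- function(x, ...) {
  cat(sprintf("PSO fit: %d weights, final fitness %.4f (initial %.4f, %d iterations)\n",
              length(x$weights), x$fitness, x$history[1], length(x$history) - 1L))
  invisible(x)
}

#' Learn gene weights by PSO against the M3 fitness
#'
#' Convenience wrapper binding [fitness_m3()] to [pso_optimize()] for one
#' training set of cells.
#'
#' @inheritParams fitness_m3
#' @param config a [pso_config()].
#' @return a `pso_fit`; `weights` is named by `genes`.
#' @export
optimize_gene_weights <- function(genes, cells, atlas, geometry, gold,
                                  config = pso_config(), k = 10) {
  fit <- pso_optimize(length(genes), config,
                      function(w) fitness_m3(w, genes, cells, atlas, geometry, gold, k))
  names(fit$weights) <- genes
  fit
}

#' Cross-validated gene-weight learning
#'
#' For each fold, weights are learned on the other folds' cells (fold seeds
#' are `config$seed + fold`, keeping folds independent but reproducible).
#'
#' @inheritParams optimize_gene_weights
#' @param folds integer fold-id vector over the rows of `cells`, e.g. from
#'   [make_cv_folds()].
#' @return list of `pso_fit` objects, one per fold id (sorted).
#' @export
optimize_gene_weights_cv <- function(genes, cells, atlas, geometry, gold, folds,
                                     config = pso_config(), k = 10) {
  lapply(sort(unique(folds)), function(f) {
    idx <- which(folds != f)
    cfg <- config
    cfg$seed <- config$seed + f
    optimize_gene_weights(genes, cells[idx, , drop = FALSE], atlas, geometry,
                          gold[idx, , drop = FALSE], cfg, k)
  })
}
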