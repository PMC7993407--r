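# Synthetic embryo fixtures: bin geometry, a spatially coherent binary
# atlas, and noisy Poisson-count cells with known origin bins, so every
# pipeline stage is testable end to end with a known ground truth.
#
# RNG discipline: each generator seeds its own stream from the fixture seed
# plus a fixed offset (geometry +0, atlas +1, cells +2), so the three pieces
# are individually and jointly reproducible.

#' Specification for a synthetic fixture
#'
#' Defaults give the standard test-scale fixture: 150 bins on a half
#' ellipsoid shell, 30 genes of which 20 carry spatial signal, 100 cells,
#' 5% condition-flip noise, no dropout, Poisson emission rates 10 (on) and
#' 0.5 (off).
#'
#' @param n_bins number of location bins (>= 2).
#' @param n_genes total genes in the atlas.
#' @param n_signal_genes genes with spatially coherent patterns (the rest
#'   are independent coin-flip noise genes).
#' @param n_cells number of cells.
#' @param noise_flip_rate probability in [0, 0.5) that a cell/gene entry
#'   emits from the wrong atlas state (on<->off swap of Poisson rates).
#' @param dropout_rate probability in [0, 1) that an observed count is
#'   zeroed (capture failure).
#' @param geometry_shape `"line"`, `"grid"` or `"ellipsoid_shell"`.
#' @param seed integer master seed.
#' @param lambda_high,lambda_low Poisson emission rates where the origin
#'   bin's atlas entry is 1 / 0.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_bins = 150, n_genes = 30, n_signal_genes = 20,
                         n_cells = 100, noise_flip_rate = 0.05,
                         dropout_rate = 0,
                         geometry_shape = c("ellipsoid_shell", "line", "grid"),
                         seed = 1, lambda_high = 10, lambda_low = 0.5) {
  geometry_shape <- match.arg(geometry_shape)
  if (n_signal_genes > n_genes) stopf("n_signal_genes cannot exceed n_genes")
  if (noise_flip_rate < 0 || noise_flip_rate >= 0.5) stopf("noise_flip_rate must be in [0, 0.5)")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  if (n_bins < 2) stopf("need at least 2 bins")
  structure(list(n_bins = as.integer(n_bins), n_genes = as.integer(n_genes),
                 n_signal_genes = as.integer(n_signal_genes),
                 n_cells = as.integer(n_cells),
                 noise_flip_rate = noise_flip_rate, dropout_rate = dropout_rate,
                 geometry_shape = geometry_shape, seed = as.integer(seed),
                 lambda_high = lambda_high, lambda_low = lambda_low),
            class = "fixture_spec")
}

#' Generate synthetic bin geometry
#'
#' `line`: bins at (0, 0, 0), (1, 0, 0), ...; `grid`: a near-square planar
#' lattice with unit spacing; `ellipsoid_shell`: seeded quasi-uniform points
#' on the upper half of an ellipsoid surface with semi-axes (2, 1, 1) -- a
#' half-embryo-like shell.
#'
#' @param spec a [fixture_spec()].
#' @return bins x 3 coordinate matrix.
#' @export
make_geometry <- function(spec) {
  n <- spec$n_bins
  coords <- switch(spec$geometry_shape,
    line = cbind(x = 0:(n - 1), y = 0, z = 0),
    grid = {
      side <- ceiling(sqrt(n))
      g <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))
      cbind(x = g$x[seq_len(n)], y = g$y[seq_len(n)], z = 0)
    },
    ellipsoid_shell = withr::with_seed(spec$seed, {
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      u[, 3] <- abs(u[, 3])  # keep the upper half-shell
      sweep(u, 2, c(2, 1, 1), "*")
    })
  )
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  coords
}

# Median nearest-neighbor spacing, used to set stripe periods.
nn_spacing <- function(geometry) {
  d <- bin_distances(geometry)
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Generate a spatially coherent binary atlas over a geometry
#'
#' Signal genes cycle through three pattern families, each thresholded at
#' its median so roughly half the bins express each gene:
#' gradients (random spatial direction), stripes (periodic bands along the
#' principal axis with period `2 s` nearest-neighbor spacings for the s-th
#' stripe gene -- the hard, segmentation-like case), and radial fields
#' (distance from a randomly chosen bin). Noise genes are independent fair
#' coin flips per bin. Signal genes are named `sig01, ...`, noise genes
#' `rnd01, ...`.
#'
#' @param geometry bins x 3 coordinate matrix.
#' @param spec a [fixture_spec()].
#' @return bins x genes binary matrix.
#' @export
make_atlas <- function(geometry, spec) {
  n <- nrow(geometry)
  spacing <- if (n > 1) nn_spacing(geometry) else 1
  # principal axis = coordinate with the largest spread
  axis <- which.max(apply(geometry, 2, function(v) diff(range(v))))
  kinds <- rep(c("gradient", "stripe", "radial"), length.out = spec$n_signal_genes)
  n_stripes_seen <- 0L
  withr::with_seed(spec$seed + 1L, {
    signal <- vapply(seq_len(spec$n_signal_genes), function(g) {
      kind <- kinds[g]
      if (kind == "gradient") {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        v <- as.numeric(geometry %*% dir)
        (v > stats::median(v)) * 1
      } else if (kind == "stripe") {
        n_stripes_seen <<- n_stripes_seen + 1L
        period <- 2 * n_stripes_seen * spacing
        v <- geometry[, axis] - min(geometry[, axis])
        (floor(v / (period / 2)) %% 2 == 0) * 1
      } else {
        center <- geometry[sample.int(n, 1), ]
        v <- sqrt(colSums((t(geometry) - center)^2))
        (v < stats::median(v)) * 1
      }
    }, numeric(n))
    n_noise <- spec$n_genes - spec$n_signal_genes
    noise <- if (n_noise > 0) {
      matrix(stats::rbinom(n * n_noise, 1, 0.5), nrow = n)
    } else {
      matrix(0, nrow = n, ncol = 0)
    }
    atlas <- cbind(signal, noise)
    colnames(atlas) <- c(sprintf("sig%02d", seq_len(spec$n_signal_genes)),
                         if (n_noise > 0) sprintf("rnd%02d", seq_len(n_noise)))
    atlas
  })
}

#' Generate noisy cells with known origin bins
#'
#' Each cell draws a uniform origin bin; each gene's raw count is Poisson
#' with rate `lambda_high` where the origin bin's atlas entry is 1 and
#' `lambda_low` where it is 0. With probability `noise_flip_rate` the two
#' rates are swapped for that cell/gene (condition-flip noise); observed
#' counts are then zeroed independently at `dropout_rate`.
#' Draw order: origins, then the flip mask, then counts, then dropout.
#'
#' @param atlas bins x genes binary matrix.
#' @param geometry bins x 3 coordinate matrix (carried for shape checks).
#' @param spec a [fixture_spec()].
#' @return list with `counts` (cells x genes raw counts, cells named
#'   `cell001, ...`) and `true_origin` (integer bin index per cell).
#' @export
make_cells <- function(atlas, geometry, spec) {
  check_geometry(geometry, nrow(atlas))
  n_cells <- spec$n_cells
  n_genes <- ncol(atlas)
  withr::with_seed(spec$seed + 2L, {
    origin <- sample.int(nrow(atlas), n_cells, replace = TRUE)
    state <- atlas[origin, , drop = FALSE]
    flip <- matrix(stats::runif(n_cells * n_genes) < spec$noise_flip_rate,
                   nrow = n_cells)
    state[flip] <- 1 - state[flip]
    lam <- ifelse(state == 1, spec$lambda_high, spec$lambda_low)
    counts <- matrix(stats::rpois(n_cells * n_genes, lam), nrow = n_cells)
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_cells * n_genes) < spec$dropout_rate,
                     nrow = n_cells)
      counts[drop] <- 0L
    }
    dimnames(counts) <- list(sprintf("cell%03d", seq_len(n_cells)), colnames(atlas))
    list(counts = counts, true_origin = origin)
  })
}

#' Generate a complete synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture`: `atlas`, `geometry`, `cells_raw`,
#'   `true_origin`, `signal_genes`, `spec`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  geometry <- make_geometry(spec)
  atlas <- make_atlas(geometry, spec)
  cells <- make_cells(atlas, geometry, spec)
  structure(list(atlas = atlas, geometry = geometry, cells_raw = cells$counts,
                 true_origin = cells$true_origin,
                 signal_genes = grep("^sig", colnames(atlas), value = TRUE),
                 spec = spec),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic fixture: %d bins (%s), %d genes (%d signal), %d cells, flip %.2f, dropout %.2f, seed %d\n",
    x$spec$n_bins, x$spec$geometry_shape, x$spec$n_genes, x$spec$n_signal_genes,
    x$spec$n_cells, x$spec$noise_flip_rate, x$spec$dropout_rate, x$spec$seed))
  invisible(x)
}
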