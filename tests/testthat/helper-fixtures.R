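# Small deterministic fixtures built in code.

# Random binary atlas + geometry + continuous cells at a given toy scale.
toy_instance <- function(n_bins = 12, n_genes = 5, n_cells = 6, seed = 42,
                         shape = c("scatter", "line")) {
  shape <- match.arg(shape)
  withr::with_seed(seed, {
    atlas <- matrix(rbinom(n_bins * n_genes, 1, 0.5), nrow = n_bins,
                    dimnames = list(NULL, sprintf("g%02d", seq_len(n_genes))))
    geometry <- if (shape == "line") {
      cbind(x = 0:(n_bins - 1), y = 0, z = 0)
    } else {
      matrix(runif(n_bins * 3, 0, 10), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    }
    cells <- matrix(runif(n_cells * n_genes, 0, 5), nrow = n_cells,
                    dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                                    colnames(atlas)))
    list(atlas = atlas, geometry = geometry, cells = cells)
  })
}

# Fixture with zero-total cells removed, normalized, with true-origin gold.
prepared_fixture <- function(spec) {
  fx <- make_fixture(spec)
  keep <- rowSums(fx$cells_raw) > 0
  fx$cells_raw <- fx$cells_raw[keep, , drop = FALSE]
  fx$true_origin <- fx$true_origin[keep]
  fx$normalized <- normalize_counts(fx$cells_raw)
  fx$gold_true <- data.frame(cell = rownames(fx$cells_raw),
                             bin = fx$true_origin, score = 1,
                             stringsAsFactors = FALSE)
  fx
}
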