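# Reading, writing, normalization and quantile-matched binarization of the
# three pipeline inputs: binary reference atlas W (bins x genes), bin
# geometry L (bins x 3) and scRNA-seq expression Y (cells x genes).

# Read a delimited file into lines, dropping leading provenance comments
# ("#" lines emitted by the CLI) and auto-detecting the delimiter when not
# given (comma vs tab, whichever splits the header into more fields).
read_body_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("file is empty: %s", path)
  lines
}

detect_delimiter <- function(header_line) {
  n_comma <- lengths(regmatches(header_line, gregexpr(",", header_line, fixed = TRUE)))
  n_tab <- lengths(regmatches(header_line, gregexpr("\t", header_line, fixed = TRUE)))
  if (n_tab > n_comma) "\t" else ","
}

#' Read a labelled numeric matrix from delimited text
#'
#' Core reader behind [read_atlas()] and [read_expression()]. The first row
#' is a mandatory header of column labels; an optional leading row-label
#' column is detected when the first body field is non-numeric. Ragged rows,
#' duplicate labels and non-numeric body cells are hard errors that name the
#' offending row/column.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator; `NULL` auto-detects comma vs tab.
#' @return numeric matrix with `dimnames` taken from the file.
#' @export
read_labeled_matrix <- function(path, delimiter = NULL) {
  lines <- read_body_lines(path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1]])
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  if (length(body) == 0) stopf("no data rows in %s", path)

  widths <- lengths(body)
  has_rownames <- all(widths == length(header) + 1) ||
    (all(widths == length(header)) && is.na(suppressWarnings(as.numeric(body[[1]][1]))))
  if (has_rownames && all(widths == length(header))) {
    # header covers the row-label column too; first header field labels rows
    header <- header[-1]
  }
  expected <- length(header) + as.integer(has_rownames)
  bad <- which(widths != expected)
  if (length(bad) > 0) {
    stopf("ragged row %d in %s: %d fields, expected %d",
          bad[1] + 1L, path, widths[bad[1]], expected)
  }
  if (anyDuplicated(header)) {
    stopf("duplicate column label(s) in %s: %s", path,
          paste(unique(header[duplicated(header)]), collapse = ", "))
  }

  rlab <- NULL
  if (has_rownames) {
    rlab <- vapply(body, `[[`, character(1), 1L)
    body <- lapply(body, `[`, -1L)
    if (anyDuplicated(rlab)) {
      stopf("duplicate row label(s) in %s: %s", path,
            paste(unique(rlab[duplicated(rlab)]), collapse = ", "))
    }
  }
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(length(header))))
  vals <- matrix(vals, nrow = length(body), ncol = length(header), byrow = TRUE)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stopf("non-numeric value in %s at data row %d, column '%s'",
          path, idx[["row"]], header[idx[["col"]]])
  }
  dimnames(vals) <- list(rlab, header)
  vals
}

#' Read a binary in situ reference atlas
#'
#' @param path delimited text file with a gene-name header.
#' @param orientation `"rows_are_bins"` (canonical) or `"rows_are_genes"`
#'   (transposed on read).
#' @param delimiter field separator; `NULL` auto-detects.
#' @return bins x genes matrix of 0/1 with gene names as colnames.
#' @export
read_atlas <- function(path, orientation = c("rows_are_bins", "rows_are_genes"),
                       delimiter = NULL) {
  orientation <- match.arg(orientation)
  m <- read_labeled_matrix(path, delimiter)
  if (orientation == "rows_are_genes") m <- t(m)
  check_atlas(m)
}

#' Read a cells x genes expression matrix
#'
#' @inheritParams read_atlas
#' @param orientation `"rows_are_cells"` (canonical) or `"rows_are_genes"`.
#' @return cells x genes numeric matrix.
#' @export
read_expression <- function(path, orientation = c("rows_are_cells", "rows_are_genes"),
                            delimiter = NULL) {
  orientation <- match.arg(orientation)
  m <- read_labeled_matrix(path, delimiter)
  if (orientation == "rows_are_genes") m <- t(m)
  check_expression(m)
}

#' Read bin geometry (x, y, z coordinates)
#'
#' Accepts three numeric columns with an optional `x,y,z` header.
#'
#' @inheritParams read_atlas
#' @return bins x 3 numeric matrix with colnames `x`, `y`, `z`.
#' @export
read_geometry <- function(path, delimiter = NULL) {
  lines <- read_body_lines(path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1]])
  first <- strsplit(lines[[1]], delimiter, fixed = TRUE)[[1]]
  skip_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (skip_header) lines <- lines[-1]
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  if (any(lengths(fields) != 3)) {
    stopf("geometry file %s must have exactly 3 columns", path)
  }
  vals <- suppressWarnings(t(vapply(fields, as.numeric, numeric(3))))
  if (anyNA(vals)) stopf("non-numeric coordinate in %s", path)
  colnames(vals) <- c("x", "y", "z")
  check_geometry(vals)
}

#' Write a labelled matrix as delimited text
#'
#' @param x numeric matrix (row names optional).
#' @param path output path.
#' @param delimiter field separator (default comma).
#' @param header_lines optional character vector of provenance lines written
#'   first, each prefixed with `#`.
#' @export
write_labeled_matrix <- function(x, path, delimiter = ",", header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(paste0("# ", header_lines), con)
  has_rn <- !is.null(rownames(x))
  header <- paste(c(if (has_rn) "id", colnames(x)), collapse = delimiter)
  writeLines(header, con)
  body <- apply(x, 1, paste, collapse = delimiter)
  if (has_rn) body <- paste(rownames(x), body, sep = delimiter)
  writeLines(body, con)
  invisible(path)
}

#' Normalize raw UMI counts
#'
#' Per-cell library-size normalization followed by a pseudo-count of 1 and a
#' natural-log transform: `ln(1 + raw/T_c * S)` where `T_c` is the cell's
#' total count and `S` the scale factor. Zeros map to zero.
#'
#' @param raw cells x genes matrix of nonnegative counts.
#' @param scale `"median_total"` (S = median of per-cell totals) or a single
#'   positive number used as a fixed S.
#' @return cells x genes normalized matrix, same dimnames.
#' @export
normalize_counts <- function(raw, scale = "median_total") {
  check_expression(raw)
  if (any(raw < 0)) stopf("raw counts must be nonnegative")
  totals <- rowSums(raw)
  if (any(totals == 0)) {
    bad <- which(totals == 0)[1]
    lab <- if (!is.null(rownames(raw))) rownames(raw)[bad] else as.character(bad)
    stopf("zero-total cell: %s", lab)
  }
  S <- if (identical(scale, "median_total")) stats::median(totals) else {
    if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
      stopf("scale must be 'median_total' or a single positive number")
    }
    as.numeric(scale)
  }
  log1p(raw / totals * S)
}

# RMSE between two gene-gene correlation matrices over distinct gene pairs.
cor_rmse <- function(c1, c2) {
  ut <- upper.tri(c1)
  sqrt(mean((c1[ut] - c2[ut])^2))
}

#' Binarize expression by correlation-matched quantile search
#'
#' Restricts the expression matrix to the atlas genes, then for each
#' candidate quantile `q` thresholds every gene at its own `q`-quantile
#' (strictly greater than the threshold maps to 1). The `q` whose binarized
#' gene-gene Pearson correlation matrix is closest (RMSE over distinct gene
#' pairs) to the atlas's correlation matrix is selected. Zero-variance
#' columns correlate as 0.
#'
#' @param normalized cells x genes matrix (normalized expression).
#' @param atlas bins x genes binary reference atlas; atlas genes must be a
#'   subset of the expression genes.
#' @param quantile_grid candidate quantiles in (0, 1); ties in the minimum
#'   RMSE are broken toward the smaller quantile.
#' @return object of class `binarization_result`: list with `binarized`
#'   (cells x atlas-genes 0/1 matrix), `chosen_quantile`, and
#'   `rmse_by_quantile` (data.frame quantile/rmse).
#' @export
binarize_by_quantile_match <- function(normalized, atlas,
                                       quantile_grid = seq(0.05, 0.95, by = 0.05)) {
  check_expression(normalized)
  check_atlas(atlas)
  if (any(quantile_grid <= 0 | quantile_grid >= 1)) {
    stopf("quantile_grid values must lie strictly within (0, 1)")
  }
  genes <- colnames(atlas)
  if (length(intersect(genes, colnames(normalized))) == 0) {
    stopf("no genes shared between atlas and expression matrix")
  }
  expr <- restrict_genes(normalized, genes, "expression matrix")
  atlas_cor <- col_pcc(atlas)

  quantile_grid <- sort(quantile_grid)
  results <- lapply(quantile_grid, function(q) {
    thr <- apply(expr, 2, stats::quantile, probs = q, names = FALSE)
    b <- (expr > rep(thr, each = nrow(expr))) * 1
    list(binarized = b, rmse = cor_rmse(col_pcc(b), atlas_cor))
  })
  rmses <- vapply(results, `[[`, numeric(1), "rmse")
  if (all(!is.finite(rmses))) stopf("RMSE undefined for every quantile in the grid")
  best <- which.min(rmses)  # ties -> first, i.e. smaller quantile
  structure(
    list(binarized = results[[best]]$binarized,
         chosen_quantile = quantile_grid[best],
         rmse_by_quantile = data.frame(quantile = quantile_grid, rmse = rmses)),
    class = "binarization_result"
  )
}

#' @export
print.binarization_result <- function(x, ...) {
  cat(sprintf("Quantile-matched binarization: %d cells x %d genes\n",
              nrow(x$binarized), ncol(x$binarized)))
  cat(sprintf("  chosen quantile %.2f (correlation RMSE %.4f)\n",
              x$chosen_quantile,
              x$rmse_by_quantile$rmse[x$rmse_by_quantile$quantile == x$chosen_quantile]))
  invisible(x)
}
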