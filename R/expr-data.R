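#' Labeled cells-by-genes expression container
#'
#' A light wrapper around a dense numeric matrix of normalized, non-negative
#' expression values (cells in rows, genes in columns) plus one population
#' label per cell. This is the input container for gene filtering,
#' downsampling, model training and perturbation.
#'
#' @param x Numeric matrix, cells in rows and genes in columns. Row names are
#'   cell IDs and column names are gene names; both must be unique.
#' @param labels Character vector of population labels, one per row of `x`.
#' @return An object of class `cell_expr`: a list with elements `x` (the
#'   matrix) and `labels` (character, named by cell ID).
#' @examples
#' m <- matrix(abs(rnorm(20)), 4, 5,
#'   dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
#' ce <- cell_expr(m, c("A", "A", "B", "B"))
#' ce
#' @export
cell_expr <- function(x, labels) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (cells x genes)", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("cell", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    stop("`x` must have gene names as column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate gene names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate cell IDs", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop("length(labels) [", length(labels), "] != number of cells [",
         nrow(x), "]", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("expression values must be non-negative (normalized expression)",
         call. = FALSE)
  }
  names(labels) <- rownames(x)
  structure(list(x = x, labels = labels), class = "cell_expr")
}

#' @export
print.cell_expr <- function(x, ...) {
  tab <- table(x$labels)
  cat("<cell_expr> ", nrow(x$x), " cells x ", ncol(x$x), " genes\n", sep = "")
  cat("populations: ",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.cell_expr <- function(x) dim(x$x)

#' Subset a cell_expr by cells and/or genes
#'
#' @param x A [cell_expr()] object.
#' @param i,j Cell and gene indices (any form accepted by matrix subsetting).
#' @param ... Ignored.
#' @export
`[.cell_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  cell_expr(x$x[i, j, drop = FALSE], x$labels[i])
}

#' @rdname cell_expr
#' @param data A `cell_expr` object.
#' @export
as_tibble_cell_expr <- function(data) {
  stopifnot(inherits(data, "cell_expr"))
  dplyr::bind_cols(
    tibble::tibble(cell_id = rownames(data$x), population = unname(data$labels)),
    tibble::as_tibble(data$x)
  )
}

# internal: accept cell_expr or bare matrix, return matrix
expr_matrix <- function(data) {
  if (inherits(data, "cell_expr")) data$x
  else if (is.matrix(data)) data
  else stop("expected a cell_expr or a numeric matrix", call. = FALSE)
}

#' Read a labeled expression matrix from disk
#'
#' Supports the MatrixMarket triplet dialect (`matrix.mtx` plus `genes.tsv`
#' and `barcodes.tsv` sidecars, 1-based coordinates as per the MatrixMarket
#' standard, genes in rows by convention) and dense delimited text with an
#' explicit orientation flag. Labels come from a separate two-column TSV
#' (cell_id, population), or default to a single population.
#'
#' @param path For `dialect = "mtx"`, the `.mtx` file (sidecars are looked up
#'   next to it unless given); for `"delimited"`, the table file.
#' @param dialect `"mtx"` or `"delimited"`.
#' @param labels_path Optional two-column TSV of (cell_id, population).
#' @param genes_path,barcodes_path Optional explicit sidecar paths (mtx only).
#' @param orientation For delimited input: `"cells_by_genes"` (rows are cells,
#'   first column cell IDs) or `"genes_by_cells"` (transposed on read). MTX
#'   input is always genes-by-cells, per the 10x convention.
#' @param delim Field delimiter for delimited input.
#' @return A [cell_expr()] object.
#' @export
read_expression <- function(path,
                            dialect = c("mtx", "delimited"),
                            labels_path = NULL,
                            genes_path = NULL,
                            barcodes_path = NULL,
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            delim = "\t") {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (dialect == "mtx") {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- readLines(barcodes_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecars (", length(genes), " genes, ",
           length(cells), " barcodes)", call. = FALSE)
    }
    dimnames(m) <- list(genes, cells)
    m <- t(m)
  } else {
    tab <- utils::read.table(path, sep = delim, header = TRUE,
                             row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    if (orientation == "genes_by_cells") m <- t(m)
  }
  labels <- if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                             col.names = c("cell_id", "population"),
                             colClasses = "character")
    missing <- setdiff(rownames(m), lab$cell_id)
    if (length(missing) > 0) {
      stop("labels missing for ", length(missing), " cells (e.g. ",
           missing[1], ")", call. = FALSE)
    }
    lab$population[match(rownames(m), lab$cell_id)]
  } else {
    rep("all", nrow(m))
  }
  cell_expr(m, labels)
}

#' Write a labeled expression matrix to disk
#'
#' Inverse of [read_expression()]: writes either the MatrixMarket triplet
#' (genes-by-cells `matrix.mtx` + `genes.tsv` + `barcodes.tsv`) or a dense
#' cells-by-genes TSV, plus a `labels.tsv` sidecar in both dialects.
#'
#' @param data A [cell_expr()] object.
#' @param dir Output directory (created if absent).
#' @param dialect `"mtx"` or `"delimited"`.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(data, dir, dialect = c("mtx", "delimited")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(data, "cell_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, "labels.tsv"))
  utils::write.table(
    data.frame(cell_id = rownames(data$x), population = unname(data$labels)),
    paths[["labels"]],
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (dialect == "mtx") {
    paths <- c(paths,
               matrix = file.path(dir, "matrix.mtx"),
               genes = file.path(dir, "genes.tsv"),
               barcodes = file.path(dir, "barcodes.tsv"))
    Matrix::writeMM(Matrix::Matrix(t(data$x), sparse = TRUE), paths[["matrix"]])
    writeLines(colnames(data$x), paths[["genes"]])
    writeLines(rownames(data$x), paths[["barcodes"]])
  } else {
    paths <- c(paths, matrix = file.path(dir, "expression.tsv"))
    utils::write.table(
      data.frame(cell_id = rownames(data$x), data$x, check.names = FALSE),
      paths[["matrix"]],
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
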