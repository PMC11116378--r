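#' Filter genes by per-population expression rate
#'
#' A gene's expression rate in a population is the fraction of that
#' population's cells in which the gene is detected (value strictly greater
#' than zero). A gene is kept when its rate reaches `min_rate` in at least one
#' population (the union rule), which preserves genes expressed only in small
#' populations. With `global = TRUE` the rate is computed once over all cells
#' and the union rule degenerates to a single global threshold.
#'
#' @param data A [cell_expr()] object.
#' @param min_rate Minimum detection rate in (0, 1); genes below it in every
#'   population are removed. Default 0.10.
#' @param global If `TRUE`, ignore population structure and filter on the
#'   overall detection rate.
#' @return A `gene_filter_report`: list with `kept_genes` (character, input
#'   order) and `rates` (tibble of gene, population, rate).
#' @examples
#' m <- matrix(c(1, 0, 0, 0, 2, 2, 0, 0), 4, 2,
#'   dimnames = list(paste0("c", 1:4), c("rare", "common")))
#' filter_genes(cell_expr(m, c("P1", "P1", "P2", "P2")), min_rate = 0.5)
#' @export
filter_genes <- function(data, min_rate = 0.10, global = FALSE) {
  stopifnot(inherits(data, "cell_expr"))
  if (!(min_rate > 0 && min_rate < 1)) {
    stop("`min_rate` must lie in (0, 1)", call. = FALSE)
  }
  labels <- if (global) rep("all", nrow(data$x)) else data$labels
  pops <- unique(labels)
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("empty population: ", names(counts)[counts == 0][1], call. = FALSE)
  }
  # detection rate per gene within each population
  rate_mat <- vapply(pops, function(p) {
    colMeans(data$x[labels == p, , drop = FALSE] > 0)
  }, numeric(ncol(data$x)))
  if (is.null(dim(rate_mat))) rate_mat <- matrix(rate_mat, nrow = 1)
  rownames(rate_mat) <- colnames(data$x)
  keep <- rowSums(rate_mat >= min_rate) > 0
  if (!any(keep)) {
    stop("no gene reaches a detection rate of ", min_rate,
         " in any population", call. = FALSE)
  }
  rates <- tibble::tibble(
    gene = rep(colnames(data$x), times = length(pops)),
    population = rep(pops, each = ncol(data$x)),
    rate = as.vector(rate_mat)
  )
  structure(
    list(kept_genes = colnames(data$x)[keep], rates = rates,
         min_rate = min_rate),
    class = "gene_filter_report"
  )
}

#' @export
print.gene_filter_report <- function(x, ...) {
  cat("<gene_filter_report> kept ", length(x$kept_genes), " of ",
      length(unique(x$rates$gene)), " genes at min_rate = ", x$min_rate,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_filter_report <- function(x, ...) {
  dplyr::mutate(x$rates, kept = .data$gene %in% x$kept_genes)
}

#' Restrict an expression matrix to the genes a filter kept
#'
#' @param data A [cell_expr()] object.
#' @param report A `gene_filter_report` from [filter_genes()], or a character
#'   vector of gene names.
#' @return A [cell_expr()] with only the kept genes, in input order.
#' @export
apply_gene_filter <- function(data, report) {
  keep <- if (inherits(report, "gene_filter_report")) report$kept_genes
          else as.character(report)
  data[, intersect(colnames(data$x), keep)]
}

#' Downsample cells per population
#'
#' Draws up to `n_per_population` cells from each population without
#' replacement, reproducibly for a given seed. Populations smaller than the
#' request are kept whole (with a warning). Cells listed in `exclude` are
#' never drawn, which is how disjoint train/test splits are built.
#'
#' @param data A [cell_expr()] object.
#' @param n_per_population Cells to draw per population.
#' @param seed Integer RNG seed.
#' @param exclude Character vector of cell IDs to leave out of the draw.
#' @return A [cell_expr()] with the sampled cells, grouped by population in
#'   first-appearance order.
#' @export
downsample <- function(data, n_per_population, seed, exclude = character()) {
  stopifnot(inherits(data, "cell_expr"), n_per_population >= 1)
  pops <- unique(data$labels)
  picked <- withr::with_seed(as.integer(seed), {
    unlist(lapply(pops, function(p) {
      ids <- setdiff(names(data$labels)[data$labels == p], exclude)
      if (length(ids) < n_per_population) {
        warning("population '", p, "' has only ", length(ids),
                " available cells (< ", n_per_population, "); taking all",
                call. = FALSE)
        ids
      } else {
        sort(sample(ids, n_per_population))
      }
    }))
  })
  data[picked, ]
}

#' Disjoint train/test split by population
#'
#' Two successive [downsample()] draws: `n_train` cells per population for
#' training, then `n_test` per population from the remainder.
#'
#' @param data A [cell_expr()] object.
#' @param n_train,n_test Cells per population for each split. Defaults 200
#'   and 100.
#' @param seed Integer RNG seed (the test draw uses `seed + 1`).
#' @return List with elements `train` and `test`, both [cell_expr()].
#' @export
split_train_test <- function(data, n_train = 200, n_test = 100, seed = 1) {
  train <- downsample(data, n_train, seed)
  test <- downsample(data, n_test, seed + 1L, exclude = rownames(train$x))
  list(train = train, test = test)
}

#' Assemble the ordered TF list that fixes the latent dimension
#'
#' Intersects a TF universe with the kept genes, preserving kept-gene order
#' and dropping duplicates. The length of the result is the latent dimension
#' of the anchored VAE.
#'
#' @param kept_genes Ordered character vector of retained gene names.
#' @param tf_universe Character vector of TF names (duplicates tolerated).
#' @return Character vector: `tf_universe` ∩ `kept_genes` in kept order.
#' @export
assemble_tf_list <- function(kept_genes, tf_universe) {
  if (length(tf_universe) == 0) stop("`tf_universe` is empty", call. = FALSE)
  out <- kept_genes[kept_genes %in% unique(tf_universe)]
  if (length(out) == 0) {
    stop("no TF in `tf_universe` survives the gene filter; the latent ",
         "space would be empty", call. = FALSE)
  }
  out
}
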