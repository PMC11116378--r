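#' Configuration for the synthetic lineage simulator
#'
#' Describes a simulated dataset in which every cell's transcriptome is a
#' noisy, sparse function of its TF activity — the generative structure the
#' anchored VAE assumes. The default scenario is a lineage bifurcation:
#' a Start population and two end populations (EndA, EndB) whose TF profiles
#' differ in a pair of antagonistic driver TFs (d1 high / d2 low in EndA,
#' mirrored in EndB) and, more weakly, in one secondary TF activated by each
#' driver; all other TFs share their means across populations. A small
#' signed TF network (d1 -| d2, d2 -| d1, d1 -> s1, d2 -> s2) is emitted
#' alongside, consistent with those shifts.
#'
#' @param n_genes Total genes, TFs included. Default 200.
#' @param n_tfs TFs, embedded as the first `n_tfs` gene columns. Default 20.
#' @param n_cells_per_pop Cells per population. Default 300.
#' @param noise_sd Gaussian noise SD on TF activity and gene expression.
#'   Default 0.25.
#' @param weight_sparsity Fraction of nonzero TF-to-gene weights. Default
#'   0.3.
#' @param dropout_rate Probability that any measured entry is zeroed
#'   (technical dropout). Default 0.1.
#' @param seed Integer seed. Default 0.
#' @param populations Optional custom design: a list of
#'   `list(label =, n_cells =, tf_means =)` entries, each `tf_means` of
#'   length `n_tfs`. When supplied, no driver/network truth is attached.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_tfs = 20, n_cells_per_pop = 300,
                       noise_sd = 0.25, weight_sparsity = 0.3,
                       dropout_rate = 0.1, seed = 0, populations = NULL) {
  stopifnot(n_tfs <= n_genes, n_tfs >= 4 || !is.null(populations),
            noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1,
            weight_sparsity > 0, weight_sparsity <= 1)
  if (!is.null(populations)) {
    ok <- vapply(populations, function(p) {
      length(p$tf_means) == n_tfs && p$n_cells >= 1
    }, logical(1))
    if (!all(ok)) {
      stop("every population needs `n_cells` >= 1 and a `tf_means` vector ",
           "of length n_tfs", call. = FALSE)
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
         n_cells_per_pop = as.integer(n_cells_per_pop), noise_sd = noise_sd,
         weight_sparsity = weight_sparsity, dropout_rate = dropout_rate,
         seed = as.integer(seed), populations = populations),
    class = "sim_config"
  )
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Simulate a labeled expression dataset with a known lineage bifurcation
#'
#' Per cell, TF activity is drawn as Normal(population TF mean, `noise_sd`)
#' clipped at zero. Non-TF gene expression is `softplus(W tf + b)` plus
#' Gaussian noise (clipped at zero), with `W` a sparse signed weight matrix.
#' Every measured entry — TF columns included — is then zeroed independently
#' with probability `dropout_rate`. The default bifurcation design plants
#' driver TFs `TF1`/`TF2` and secondary targets `TF3`/`TF4` (see
#' [sim_config()]); the returned `truth` records population TF means, `W`,
#' `b` and the driver duo, and `network` is the matching signed TF graph.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_lineage` with `expression` ([cell_expr()]),
#'   `tf_names`, `truth` (list: `tf_means` matrix populations x TFs,
#'   `W`, `b`, `drivers`, `secondary`, `activity` — the pre-dropout TF
#'   activity) and `network` (a [reg_network()], `NULL` for custom
#'   populations).
#' @export
simulate_lineage <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_tfs <- config$n_tfs
  tf_names <- paste0("TF", seq_len(n_tfs))
  gene_names <- c(tf_names,
                  sprintf("G%03d", seq_len(config$n_genes - n_tfs)))
  withr::with_seed(config$seed, {
    if (is.null(config$populations)) {
      baseline <- stats::runif(n_tfs, 0.5, 2.0)
      # every TF's activity is population-specific (mild multiplicative
      # jitter), as in real lineages; the driver/secondary TFs are then
      # overridden with the planted bifurcation profile
      mk <- function(d1, d2, s1, s2) {
        m <- baseline * stats::runif(n_tfs, 0.7, 1.3)
        m[1:4] <- c(d1, d2, s1, s2)
        m
      }
      # TF1/TF2: antagonistic drivers; TF3/TF4: their activated targets
      pops <- list(
        list(label = "Start", n_cells = config$n_cells_per_pop,
             tf_means = mk(1.25, 1.25, 1.0, 1.0)),
        list(label = "EndA", n_cells = config$n_cells_per_pop,
             tf_means = mk(3.0, 0.1, 1.8, 0.6)),
        list(label = "EndB", n_cells = config$n_cells_per_pop,
             tf_means = mk(0.1, 3.0, 0.6, 1.8)))
      truth_extra <- list(
        drivers = c(up = "TF1", down = "TF2"),
        secondary = c(up = "TF3", down = "TF4"))
      network <- reg_network(tibble::tibble(
        from = c("TF1", "TF2", "TF1", "TF2"),
        to = c("TF2", "TF1", "TF3", "TF4"),
        sign = c(-1L, -1L, 1L, 1L)))
    } else {
      pops <- config$populations
      truth_extra <- list(drivers = NULL, secondary = NULL)
      network <- NULL
    }

    n_out <- config$n_genes - n_tfs
    W <- matrix(0, n_out, n_tfs)
    nz <- matrix(stats::runif(n_out * n_tfs) < config$weight_sparsity,
                 n_out, n_tfs)
    W[nz] <- stats::runif(sum(nz), 0.3, 1) *
      sample(c(-1, 1), sum(nz), replace = TRUE)
    b <- stats::runif(n_out, -0.5, 1.5)

    per_pop <- lapply(pops, function(p) {
      act <- matrix(stats::rnorm(p$n_cells * n_tfs,
                                 mean = rep(p$tf_means, each = p$n_cells),
                                 sd = config$noise_sd),
                    p$n_cells, n_tfs)
      act <- pmax(act, 0)
      genes <- if (n_out > 0) {
        base <- t(t(act %*% t(W)) + b)
        pmax(softplus(base) +
               matrix(stats::rnorm(p$n_cells * n_out, sd = config$noise_sd),
                      p$n_cells, n_out), 0)
      } else NULL
      list(label = p$label, activity = act,
           x = cbind(act, genes))
    })

    x <- do.call(rbind, lapply(per_pop, `[[`, "x"))
    activity <- do.call(rbind, lapply(per_pop, `[[`, "activity"))
    labels <- unlist(lapply(per_pop, function(p) rep(p$label, nrow(p$x))))
    if (config$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(x)) < config$dropout_rate,
                     nrow(x), ncol(x))
      x[mask] <- 0
    }
    dimnames(x) <- list(sprintf("cell%04d", seq_len(nrow(x))), gene_names)
    colnames(activity) <- tf_names
    rownames(activity) <- rownames(x)

    tf_means <- do.call(rbind, lapply(pops, `[[`, "tf_means"))
    rownames(tf_means) <- vapply(pops, `[[`, character(1), "label")
    colnames(tf_means) <- tf_names

    structure(
      list(expression = cell_expr(x, labels),
           tf_names = tf_names,
           truth = c(list(tf_means = tf_means, W = W, b = b,
                          activity = activity), truth_extra),
           network = network),
      class = "sim_lineage")
  })
}

#' @export
print.sim_lineage <- function(x, ...) {
  cat("<sim_lineage>\n")
  print(x$expression)
  cat(length(x$tf_names), " TFs embedded as the first gene columns",
      if (!is.null(x$truth$drivers))
        paste0("; driver duo ", x$truth$drivers[["up"]], " (up) / ",
               x$truth$drivers[["down"]], " (down)"),
      "\n", sep = "")
  invisible(x)
}

#' Shuffle each TF column independently across cells
#'
#' Destroys the cell-wise association between TF expression and
#' transcriptome while preserving every column's marginal distribution
#' exactly — the negative control for latent anchoring: a model anchored to
#' shuffled TF profiles should reconstruct transcriptomes worse.
#'
#' @param tf_matrix Matrix (cells x TFs).
#' @param seed Integer seed.
#' @return Matrix of the same shape, each column a permutation of the
#'   original.
#' @export
shuffle_tf_columns <- function(tf_matrix, seed = 1) {
  m <- as.matrix(tf_matrix)
  if (length(m) == 0) stop("empty matrix", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(m))) {
      m[, j] <- m[sample.int(nrow(m)), j]
    }
  })
  m
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits the MatrixMarket triplet plus labels, the TF list, the signed
#' network as TRRUST-dialect TSV, and the ground truth as YAML.
#'
#' @param sim A [simulate_lineage()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_lineage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, dir, dialect = "mtx")
  writeLines(sim$tf_names, file.path(dir, "tf_list.tsv"))
  if (!is.null(sim$network)) {
    ed <- sim$network$edges
    utils::write.table(
      data.frame(ed$from, ed$to,
                 ifelse(ed$sign == 1, "Activation", "Repression"),
                 "simulated"),
      file.path(dir, "network.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  truth <- list(
    drivers = as.list(sim$truth$drivers),
    secondary = as.list(sim$truth$secondary),
    tf_means = apply(sim$truth$tf_means, 1, as.list, simplify = FALSE))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
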