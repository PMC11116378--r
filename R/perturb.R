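#' Specify an in silico TF perturbation
#'
#' Names the TFs to push up and down, and the quantile fraction `q` used when
#' resampling their latent values from a reference: up-regulated TFs draw
#' from the top-`q` tail of the reference distribution, down-regulated TFs
#' from the bottom-`q` tail. The default `q = 0.01` (1%) deliberately uses
#' only extreme, but observed, values so the adjusted latent space stays
#' biologically legitimate.
#'
#' @param up,down Character vectors of TF names (disjoint).
#' @param q Quantile fraction in (0, 0.5]. Default 0.01.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(up = character(), down = character(), q = 0.01) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0) {
    stop("TFs cannot be both up- and down-regulated: ",
         paste(intersect(up, down), collapse = ", "), call. = FALSE)
  }
  if (!(q > 0 && q <= 0.5)) stop("`q` must lie in (0, 0.5]", call. = FALSE)
  structure(list(up = up, down = down, q = q), class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("<perturbation_spec> q = ", x$q,
      "\n  up:   ", if (length(x$up)) paste(x$up, collapse = ", ") else "(none)",
      "\n  down: ", if (length(x$down)) paste(x$down, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Read / write a perturbation spec as YAML
#'
#' The YAML carries fields `up:`, `down:` and `q:`.
#'
#' @param path YAML file path.
#' @param spec A [perturbation_spec()].
#' @return `read_perturbation_spec` returns a [perturbation_spec()].
#' @export
read_perturbation_spec <- function(path) {
  y <- yaml::read_yaml(path)
  perturbation_spec(up = unlist(y$up), down = unlist(y$down),
                    q = if (is.null(y$q)) 0.01 else y$q)
}

#' @rdname read_perturbation_spec
#' @export
write_perturbation_spec <- function(spec, path) {
  yaml::write_yaml(list(up = as.list(spec$up), down = as.list(spec$down),
                        q = spec$q), path)
  invisible(path)
}

#' Extreme-quantile sampling pool of a reference column
#'
#' The pool is rank-based: the `ceiling(q * n)` largest (`tail = "top"`) or
#' smallest (`tail = "bottom"`) values, extended by any values tied with the
#' boundary rank. Rank-based pools are never empty and sidestep
#' quantile-interpolation ambiguity.
#'
#' @param reference_column Numeric vector of reference expression values for
#'   one TF.
#' @param q Quantile fraction in (0, 0.5].
#' @param tail `"top"` or `"bottom"`.
#' @return Numeric vector of pool values (with multiplicity as observed).
#' @examples
#' quantile_pool(1:100, 0.01, "top")    # 100
#' quantile_pool(1:100, 0.01, "bottom") # 1
#' @export
quantile_pool <- function(reference_column, q, tail = c("top", "bottom")) {
  tail <- match.arg(tail)
  v <- as.numeric(reference_column)
  if (length(v) == 0) stop("reference column is empty", call. = FALSE)
  if (anyNA(v)) stop("reference column contains NA", call. = FALSE)
  k <- ceiling(q * length(v))
  sorted <- sort(v, decreasing = (tail == "top"))
  boundary <- sorted[k]
  if (tail == "top") v[v >= boundary] else v[v <= boundary]
}

# internal: coerce a reference to a cells x TFs matrix aligned to tf_names
reference_matrix <- function(reference, tf_names) {
  ref <- expr_matrix(reference)
  if (!is.null(colnames(ref)) && all(tf_names %in% colnames(ref))) {
    ref <- ref[, tf_names, drop = FALSE]
  } else if (ncol(ref) != length(tf_names)) {
    stop("reference has ", ncol(ref), " columns but ", length(tf_names),
         " TFs are required, and TF names are not resolvable from its ",
         "column names", call. = FALSE)
  }
  ref
}

#' Adjust latent TF profiles according to a perturbation spec
#'
#' For every cell independently, entries of up-regulated TFs are replaced by
#' draws with replacement from that TF's top-`q` reference pool, entries of
#' down-regulated TFs by draws from the bottom-`q` pool, and all other
#' entries are left untouched.
#'
#' @param base Matrix (cells x TFs) of latent profiles, columns in TF-list
#'   order (TF names as column names).
#' @param spec A [perturbation_spec()].
#' @param reference Reference expression: a [cell_expr()], or a matrix whose
#'   columns cover the TFs (aligned by name when names are present).
#' @param seed Integer seed making the draws reproducible.
#' @return Matrix of the same shape as `base`.
#' @export
adjust_latent <- function(base, spec, reference, seed = 1) {
  stopifnot(inherits(spec, "perturbation_spec"))
  base <- as.matrix(base)
  tf_names <- colnames(base)
  if (is.null(tf_names)) stop("`base` must have TF column names", call. = FALSE)
  absent <- setdiff(c(spec$up, spec$down), tf_names)
  if (length(absent) > 0) {
    stop("perturbation names TFs absent from the latent space: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ref <- reference_matrix(reference, tf_names)
  out <- base
  withr::with_seed(as.integer(seed), {
    for (tf in spec$up) {
      pool <- quantile_pool(ref[, tf], spec$q, "top")
      out[, tf] <- pool[sample.int(length(pool), nrow(base), replace = TRUE)]
    }
    for (tf in spec$down) {
      pool <- quantile_pool(ref[, tf], spec$q, "bottom")
      out[, tf] <- pool[sample.int(length(pool), nrow(base), replace = TRUE)]
    }
  })
  out
}

#' Predict transcriptomes after an in silico TF perturbation
#'
#' The latent profile of each start cell is its measured TF expression
#' (consistent with the anchored latent space); candidate TF entries are
#' resampled from the reference tails per `spec`, and the adjusted profiles
#' are decoded into whole transcriptomes. With `use_encoder = TRUE` the base
#' latent profiles are the encoder posterior means instead.
#'
#' @param model A trained [train_tfvae()] model.
#' @param start A [cell_expr()] (or matrix with the model's genes): the cells
#'   to perturb.
#' @param spec A [perturbation_spec()]; an empty spec decodes the measured
#'   TF profiles unchanged.
#' @param reference Reference for the quantile pools; defaults in practice to
#'   the full training expression matrix.
#' @param seed Integer seed for the latent draws.
#' @param use_encoder If `TRUE`, base latent values come from
#'   `encode(model, start, deterministic = TRUE)`.
#' @return Matrix (start cells x genes) of predicted expression, row order
#'   preserved.
#' @export
perturb <- function(model, start, spec, reference, seed = 1,
                    use_encoder = FALSE) {
  stopifnot(inherits(model, "tfvae"), inherits(spec, "perturbation_spec"))
  base <- if (use_encoder) {
    encode(model, start, deterministic = TRUE)$z_star
  } else {
    model_input(model, start)[, model$tf_names, drop = FALSE]
  }
  ref <- expr_matrix(reference)
  if (!is.null(colnames(ref)) && all(model$gene_names %in% colnames(ref))) {
    ref <- ref[, model$tf_names, drop = FALSE]
    if (model$config$log_input) ref <- log1p(ref)
  }
  decode(model, adjust_latent(base, spec, ref, seed = seed))
}
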