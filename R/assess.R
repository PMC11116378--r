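#' Correlation triad between perturbed, start and end populations
#'
#' Summarizes where perturbed cells landed: each perturbed cell is correlated
#' (Pearson, over all shared genes) against the End-population centroid and
#' the Start-population centroid, and each start cell against the End
#' centroid. Centroids are per-gene means. The three vectors —
#' r(Perturb, End), r(Start, End), r(Perturb, Start) — feed [assess()].
#'
#' @param perturb Matrix of predicted (perturbed) expression, cells x genes.
#' @param start,end Matrices (or [cell_expr()]) of the start and target
#'   populations, sharing the gene axis with `perturb`.
#' @param genes Optional character vector restricting the correlations to a
#'   gene subset (e.g. highly variable genes); default: all shared genes.
#' @return A list of class `correlation_triad` with vectors `r_perturb_end`,
#'   `r_start_end`, `r_perturb_start`.
#' @export
correlation_triad <- function(perturb, start, end, genes = NULL) {
  pm <- as.matrix(expr_matrix(perturb))
  sm <- as.matrix(expr_matrix(start))
  em <- as.matrix(expr_matrix(end))
  if (!is.null(genes)) {
    pick <- function(m) {
      missing <- setdiff(genes, colnames(m))
      if (length(missing) > 0) {
        stop("genes not present in all inputs: ",
             paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
      }
      m[, genes, drop = FALSE]
    }
    pm <- pick(pm); sm <- pick(sm); em <- pick(em)
  }
  if (ncol(pm) != ncol(sm) || ncol(pm) != ncol(em)) {
    stop("perturb, start and end must share the gene axis", call. = FALSE)
  }
  if (nrow(pm) < 2 || nrow(sm) < 2 || nrow(em) < 2) {
    stop("each input needs at least 2 cells", call. = FALSE)
  }
  end_centroid <- colMeans(em)
  start_centroid <- colMeans(sm)
  if (stats::sd(end_centroid) == 0 || stats::sd(start_centroid) == 0) {
    stop("constant centroid: correlation undefined", call. = FALSE)
  }
  row_cor <- function(m, centroid) {
    apply(m, 1, function(row) {
      if (stats::sd(row) == 0) {
        stop("constant cell profile: correlation undefined", call. = FALSE)
      }
      stats::cor(row, centroid)
    })
  }
  structure(
    list(r_perturb_end = unname(row_cor(pm, end_centroid)),
         r_start_end = unname(row_cor(sm, end_centroid)),
         r_perturb_start = unname(row_cor(pm, start_centroid))),
    class = "correlation_triad"
  )
}

#' @export
tidy.correlation_triad <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(comparison = "perturb_end", r = x$r_perturb_end),
    tibble::tibble(comparison = "start_end", r = x$r_start_end),
    tibble::tibble(comparison = "perturb_start", r = x$r_perturb_start))
}

#' Label a perturbation Ideal, Under or N.S.
#'
#' Two t-statistics summarize the triad. The progress statistic is a Welch
#' two-sample t of r(Perturb, End) against r(Start, End): did perturbed cells
#' move toward the target? The identity statistic is a one-sample t on the
#' per-cell paired differences r(Perturb, End) - r(Perturb, Start): are
#' perturbed cells now more End-like than Start-like? Both tests are
#' one-sided (greater). A perturbation is `Ideal` when both are significant,
#' `Under` when only progress is (cells moved the right way but remain
#' Start-like), and `N.S.` otherwise. Optionally correlations are Fisher
#' z-transformed first.
#'
#' @param triad A [correlation_triad()].
#' @param sig_level One-sided significance level. Default 0.05.
#' @param fisher_z If `TRUE`, apply `atanh` to the correlations before
#'   testing.
#' @return A list of class `perturbation_assessment` with `t_progress`,
#'   `p_progress`, `t_identity`, `p_identity`, `label`, `sig_level`.
#' @export
assess <- function(triad, sig_level = 0.05, fisher_z = FALSE) {
  stopifnot(inherits(triad, "correlation_triad"))
  rpe <- triad$r_perturb_end
  rse <- triad$r_start_end
  rps <- triad$r_perturb_start
  if (length(rpe) < 2 || length(rse) < 2) {
    stop("need at least 2 cells per group to assess", call. = FALSE)
  }
  if (fisher_z) {
    clamp <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    rpe <- clamp(rpe); rse <- clamp(rse); rps <- clamp(rps)
  }
  if (stats::sd(rpe) == 0 && stats::sd(rse) == 0) {
    stop("zero-variance correlation vectors: t-statistics undefined",
         call. = FALSE)
  }
  progress <- stats::t.test(rpe, rse, alternative = "greater",
                            var.equal = FALSE)
  diffs <- rpe - rps
  if (stats::sd(diffs) == 0) {
    stop("zero-variance paired differences: t-statistic undefined",
         call. = FALSE)
  }
  identity <- stats::t.test(diffs, alternative = "greater")
  p_prog <- progress$p.value
  p_ident <- identity$p.value
  label <- if (p_prog < sig_level && p_ident < sig_level) "Ideal"
           else if (p_prog < sig_level) "Under"
           else "N.S."
  structure(
    list(t_progress = unname(progress$statistic),
         p_progress = p_prog,
         t_identity = unname(identity$statistic),
         p_identity = p_ident,
         label = label, sig_level = sig_level),
    class = "perturbation_assessment"
  )
}

#' @export
print.perturbation_assessment <- function(x, ...) {
  cat(sprintf(
    "<perturbation_assessment> %s\n  progress: t = %.3f (p = %.3g)\n  identity: t = %.3f (p = %.3g)\n",
    x$label, x$t_progress, x$p_progress, x$t_identity, x$p_identity))
  invisible(x)
}

#' @export
glance.perturbation_assessment <- function(x, ...) {
  tibble::tibble(t_progress = x$t_progress, p_progress = x$p_progress,
                 t_identity = x$t_identity, p_identity = x$p_identity,
                 label = x$label, sig_level = x$sig_level)
}

#' Per-TF volcano statistics between two cell groups
#'
#' For each TF, the d-value is the difference of group mean expression
#' (group1 minus group2) and the p-value a two-sided Mann-Whitney U test:
#' exact when the combined sample size is at most 25 and tie-free, a normal
#' approximation with tie and continuity correction otherwise. Groups where
#' every value is tied give p = 1 (no evidence), not an error.
#'
#' @param group1,group2 Matrices (cells x TFs) with columns aligned to
#'   `tf_names`, or [cell_expr()] objects covering those genes.
#' @param tf_names Character vector naming the TF columns to test.
#' @return Tibble with columns `tf`, `d_value`, `p_value`.
#' @export
diff_tf_stats <- function(group1, group2, tf_names) {
  m1 <- as.matrix(expr_matrix(group1))
  m2 <- as.matrix(expr_matrix(group2))
  pick <- function(m) {
    if (!is.null(colnames(m)) && all(tf_names %in% colnames(m))) {
      m[, tf_names, drop = FALSE]
    } else if (ncol(m) == length(tf_names)) m
    else stop("group columns do not cover `tf_names`", call. = FALSE)
  }
  m1 <- pick(m1); m2 <- pick(m2)
  if (nrow(m1) < 1 || nrow(m2) < 1) {
    stop("each group needs at least one cell", call. = FALSE)
  }
  tibble::tibble(
    tf = tf_names,
    d_value = unname(colMeans(m1) - colMeans(m2)),
    p_value = vapply(seq_along(tf_names), function(j) {
      u_test_p(m1[, j], m2[, j])
    }, numeric(1)))
}

# two-sided U-test p-value used by diff_tf_stats
u_test_p <- function(g1, g2, exact_max_n = 25) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && (n1 + n2) <= exact_max_n) {
    # exact, tie-free: U follows the Wilcoxon rank-sum null distribution
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  mu_u <- n1 * n2 / 2
  tie_tab <- table(pooled)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # everything tied: no evidence either way
  z <- (u - mu_u - sign(u - mu_u) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' PCA coordinates for start, end and perturbed cells
#'
#' Fits a standard PCA on the start and end cells and projects the perturbed
#' cells into it, so perturbation trajectories can be drawn in a fixed
#' 2-D reference frame.
#'
#' @param start,end,perturb Matrices (or [cell_expr()]) sharing the gene
#'   axis.
#' @param n_pcs Number of components to keep. Default 2.
#' @return Tibble with columns `cell_id`, `set` (start/end/perturb) and one
#'   column per component.
#' @export
pca_coords <- function(start, end, perturb, n_pcs = 2) {
  sm <- as.matrix(expr_matrix(start))
  em <- as.matrix(expr_matrix(end))
  pm <- as.matrix(expr_matrix(perturb))
  fit <- stats::prcomp(rbind(sm, em), center = TRUE, scale. = FALSE,
                       rank. = n_pcs)
  coords <- function(m, set) {
    sc <- stats::predict(fit, m)[, seq_len(n_pcs), drop = FALSE]
    out <- tibble::as_tibble(sc)
    dplyr::bind_cols(
      tibble::tibble(cell_id = rownames(m) %||% paste0(set, seq_len(nrow(m))),
                     set = set),
      out)
  }
  dplyr::bind_rows(coords(sm, "start"), coords(em, "end"),
                   coords(pm, "perturb"))
}
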