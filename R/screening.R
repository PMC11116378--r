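#' Top-k most highly expressed TFs in a population
#'
#' TFs ranked by mean expression within the named population, descending,
#' ties broken alphabetically.
#'
#' @param expr A [cell_expr()] object.
#' @param population Population label to rank within.
#' @param tf_names Candidate TF gene names.
#' @param k How many to return. Default 5.
#' @return Character vector of length `k`.
#' @export
top_expressed_tfs <- function(expr, population, tf_names, k = 5) {
  stopifnot(inherits(expr, "cell_expr"), k >= 1, k <= length(tf_names))
  if (!population %in% expr$labels) {
    stop("unknown population: ", population, call. = FALSE)
  }
  missing <- setdiff(tf_names, colnames(expr$x))
  if (length(missing) > 0) {
    stop("TF(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- expr$x[expr$labels == population, tf_names, drop = FALSE]
  means <- colMeans(sub)
  ord <- order(-means, tf_names)
  tf_names[ord][seq_len(k)]
}

#' Enumerate all up/down TF duo perturbations
#'
#' The full cross-product of one up-candidate with one down-candidate, in
#' up-major order. A duo whose two members coincide is kept but flagged
#' degenerate (with a warning), since candidate lists may share TFs.
#'
#' @param up_candidates,down_candidates Ordered character vectors.
#' @param q Quantile fraction for every spec. Default 0.01.
#' @return Tibble of class `duo_set` with columns `up`, `down`, `q`,
#'   `degenerate`.
#' @examples
#' enumerate_duos(c("A", "B"), c("C", "D"))
#' @export
enumerate_duos <- function(up_candidates, down_candidates, q = 0.01) {
  if (length(up_candidates) == 0 || length(down_candidates) == 0) {
    stop("candidate lists must be non-empty", call. = FALSE)
  }
  out <- tibble::tibble(
    up = rep(up_candidates, each = length(down_candidates)),
    down = rep(down_candidates, times = length(up_candidates)),
    q = q)
  out$degenerate <- out$up == out$down
  if (any(out$degenerate)) {
    warning(sum(out$degenerate), " degenerate duo(s) where up == down; ",
            "kept and flagged", call. = FALSE)
  }
  class(out) <- c("duo_set", class(out))
  out
}

#' Screen TF perturbation duos and rank them by effectiveness
#'
#' Runs every duo through (optional) network expansion, [perturb()],
#' [correlation_triad()] and [assess()], then ranks: `Ideal` before `Under`
#' before `N.S.` (errors last), and within a label class by identity
#' t-statistic, then progress t-statistic, descending. Ties keep input
#' order. The same seed drives every duo's latent draws, so the ranking does
#' not depend on the order specs are supplied in.
#'
#' @param model A trained [train_tfvae()] model.
#' @param start,end [cell_expr()] objects (or matrices): cells to perturb
#'   and the target population.
#' @param duos A [enumerate_duos()] tibble, or any data frame with `up`,
#'   `down` (and optionally `q`) columns.
#' @param reference Reference matrix for the quantile pools (typically the
#'   full training expression).
#' @param network Optional [reg_network()]; when given, each duo is expanded
#'   with [expand_spec()] before perturbing.
#' @param radius Expansion radius. Default 6.
#' @param sig_level Significance level for [assess()]. Default 0.05.
#' @param seed Integer seed for the latent draws.
#' @return Tibble of class `tf_screen`: `rank`, `up`, `down`, `expanded_up`,
#'   `expanded_down` (comma-joined), `t_progress`, `t_identity`,
#'   `p_progress`, `p_identity`, `label`.
#' @export
run_screen <- function(model, start, end, duos, reference, network = NULL,
                       radius = 6, sig_level = 0.05, seed = 1) {
  duos <- tibble::as_tibble(duos)
  stopifnot(all(c("up", "down") %in% names(duos)))
  if (!"q" %in% names(duos)) duos$q <- 0.01
  rows <- purrr::map(seq_len(nrow(duos)), function(i) {
    res <- tryCatch({
      spec <- perturbation_spec(up = duos$up[i], down = duos$down[i],
                                q = duos$q[i])
      if (!is.null(network)) {
        spec <- suppressWarnings(expand_spec(network, spec, radius = radius))
      }
      pred <- perturb(model, start, spec, reference, seed = seed)
      a <- assess(correlation_triad(pred, expr_matrix(start),
                                    expr_matrix(end)),
                  sig_level = sig_level)
      tibble::tibble(
        up = duos$up[i], down = duos$down[i],
        expanded_up = paste(spec$up, collapse = ","),
        expanded_down = paste(spec$down, collapse = ","),
        t_progress = a$t_progress, t_identity = a$t_identity,
        p_progress = a$p_progress, p_identity = a$p_identity,
        label = a$label)
    }, error = function(e) {
      tibble::tibble(up = duos$up[i], down = duos$down[i],
                     expanded_up = NA_character_,
                     expanded_down = NA_character_,
                     t_progress = NA_real_, t_identity = NA_real_,
                     p_progress = NA_real_, p_identity = NA_real_,
                     label = "error")
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  label_class <- match(out$label, c("Ideal", "Under", "N.S.", "error"))
  ord <- order(label_class, -out$t_identity, -out$t_progress,
               seq_len(nrow(out)), na.last = TRUE)
  out <- out[ord, ]
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  class(out) <- c("tf_screen", class(out))
  out
}

#' @export
autoplot.tf_screen <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$t_progress, .data$t_identity,
                               colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "progress t (toward End)",
                  y = "identity t (End-like vs Start-like)",
                  colour = NULL)
}
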