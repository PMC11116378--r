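#' Construct a signed TF regulatory network
#'
#' A directed graph of TF -> TF edges, each with a sign (+1 activation, -1
#' repression). Self-loops are rejected; at most one edge per ordered
#' (source, target) pair.
#'
#' @param edges Tibble/data frame with columns `from`, `to`, `sign`
#'   (values +1 or -1).
#' @return A list of class `reg_network` with `edges` (tibble) and `nodes`
#'   (character).
#' @export
reg_network <- function(edges) {
  edges <- tibble::as_tibble(edges)[, c("from", "to", "sign")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) > 0) {
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge signs must be +1 or -1", call. = FALSE)
    }
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    if (anyDuplicated(edges[, c("from", "to")])) {
      stop("duplicate (source, target) pairs", call. = FALSE)
    }
  }
  structure(list(edges = edges, nodes = unique(c(edges$from, edges$to))),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat("<reg_network> ", length(x$nodes), " TFs, ", nrow(x$edges),
      " signed edges (", sum(x$edges$sign == 1), " activating, ",
      sum(x$edges$sign == -1), " repressing)\n", sep = "")
  invisible(x)
}

#' @export
tidy.reg_network <- function(x, ...) x$edges

#' Parse a TRRUST-dialect signed regulatory network
#'
#' Reads the 4-column, header-free TSV dialect used by the TRRUST database
#' (TF, target, mode, references) and cleans it up: `Activation` becomes
#' +1, `Repression` -1, `Unknown` rows are dropped; self-loops are dropped;
#' exact duplicate rows collapse to one edge; a (source, target) pair
#' annotated with both signs is dropped entirely with a warning, since its
#' direction cannot be trusted.
#'
#' @param path Path to the TSV file.
#' @return A [reg_network()].
#' @export
parse_trrust <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    stop("malformed row at line ", bad[1], ": expected 4 tab-separated ",
         "columns (TF, target, mode, references)", call. = FALSE)
  }
  mode <- vapply(fields, `[[`, character(1), 3)
  unknown_mode <- !mode %in% c("Activation", "Repression", "Unknown")
  if (any(unknown_mode)) {
    stop("malformed row at line ", which(unknown_mode)[1],
         ": mode must be Activation, Repression or Unknown", call. = FALSE)
  }
  df <- tibble::tibble(
    from = vapply(fields, `[[`, character(1), 1),
    to = vapply(fields, `[[`, character(1), 2),
    sign = ifelse(mode == "Activation", 1L,
                  ifelse(mode == "Repression", -1L, NA_integer_)))
  df <- df[!is.na(df$sign) & df$from != df$to, ]
  df <- dplyr::distinct(df)
  key <- paste(df$from, df$to, sep = "\r")
  conflicted <- unique(key[duplicated(key)])
  if (length(conflicted) > 0) {
    warning(length(conflicted), " TF pair(s) annotated with both signs ",
            "dropped: ",
            paste(utils::head(gsub("\r", " -> ", conflicted), 5),
                  collapse = ", "),
            call. = FALSE)
    df <- df[!key %in% conflicted, ]
  }
  reg_network(df)
}

#' Propagate a perturbation direction along a signed path
#'
#' The direction a perturbation imposes on the far end of a regulatory chain
#' is the seed direction times the product of edge signs — equivalently an
#' XNOR chain on the binary encoding (up/activation = 1, down/repression
#' = 0): each repression flips the direction, each activation preserves it.
#'
#' @param edge_signs Vector of +1/-1 edge signs along the path, in order.
#' @param seed_direction +1 (up) or -1 (down) for the perturbed seed TF.
#' @return +1 or -1.
#' @examples
#' path_direction(c(1, 1), 1)   # activation chain preserves "up"
#' path_direction(c(1, -1), 1)  # one repression flips it
#' @export
path_direction <- function(edge_signs, seed_direction) {
  stopifnot(length(edge_signs) >= 1,
            all(edge_signs %in% c(-1, 1)),
            seed_direction %in% c(-1, 1))
  as.integer(seed_direction * prod(edge_signs))
}

# internal: igraph object with the sign edge attribute
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE)
}

#' Find downstream TF targets of a perturbation module
#'
#' Expands seed TFs into the downstream TFs they reach on the signed
#' network, under three rules: targets must lie within `radius` steps of a
#' seed (graph distance rule); only minimum-length paths contribute
#' (shortest path rule); each path's direction is the seed direction
#' propagated through [path_direction()] (direction chain rule). When
#' several shortest paths (possibly from several seeds) reach one target,
#' their directions are averaged; a target whose path directions cancel
#' exactly is excluded — opposing regulation with equal support gives no
#' usable call. The cancellation test is on the integer sum of path scores,
#' so it is exact.
#'
#' @param network A [reg_network()].
#' @param seeds Tibble/data frame with columns `tf` and `direction` (+1/-1),
#'   or a named integer vector.
#' @param radius Maximum graph distance from a seed. Default 6.
#' @return Tibble of target calls: `tf`, `direction`, `distance` (minimum
#'   over seeds), `n_paths` (shortest paths pooled over seeds),
#'   `mean_direction`.
#' @export
find_targets <- function(network, seeds, radius = 6) {
  stopifnot(inherits(network, "reg_network"))
  if (!is.data.frame(seeds)) {
    seeds <- tibble::tibble(tf = names(seeds), direction = as.integer(seeds))
  }
  seeds <- tibble::as_tibble(seeds)
  stopifnot(all(c("tf", "direction") %in% names(seeds)),
            all(seeds$direction %in% c(-1L, 1L)))
  absent <- setdiff(seeds$tf, network$nodes)
  if (length(absent) > 0) {
    stop("seed TF(s) not in the network: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(network$edges) == 0) {
    return(tibble::tibble(tf = character(), direction = integer(),
                          distance = integer(), n_paths = integer(),
                          mean_direction = double()))
  }
  g <- as_igraph(network)
  acc <- list()
  for (i in seq_len(nrow(seeds))) {
    seed_tf <- seeds$tf[i]
    seed_dir <- seeds$direction[i]
    d <- igraph::distances(g, v = seed_tf, mode = "out")[1, ]
    targets <- names(d)[is.finite(d) & d >= 1 & d <= radius]
    targets <- setdiff(targets, seeds$tf)  # seeds keep their stated direction
    for (tgt in targets) {
      asp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = seed_tf, to = tgt,
                                   mode = "out"))
      scores <- vapply(asp$res, function(vp) {
        signs <- igraph::E(g, path = vp)$sign
        path_direction(signs, seed_dir)
      }, integer(1))
      acc[[length(acc) + 1]] <- tibble::tibble(
        tf = tgt, distance = as.integer(d[tgt]),
        score_sum = sum(scores), n = length(scores))
    }
  }
  if (length(acc) == 0) {
    return(tibble::tibble(tf = character(), direction = integer(),
                          distance = integer(), n_paths = integer(),
                          mean_direction = double()))
  }
  pooled <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(acc), .data$tf),
    distance = min(.data$distance),
    n_paths = sum(.data$n),
    score_sum = sum(.data$score_sum),
    .groups = "drop")
  pooled <- pooled[pooled$score_sum != 0L, ]  # exact integer cancellation
  out <- tibble::tibble(
    tf = pooled$tf,
    direction = as.integer(sign(pooled$score_sum)),
    distance = pooled$distance,
    n_paths = pooled$n_paths,
    mean_direction = pooled$score_sum / pooled$n_paths)
  dplyr::arrange(out, .data$distance, .data$tf)
}

#' Expand a perturbation spec with its network-derived downstream targets
#'
#' Runs [find_targets()] on the spec's TFs and folds the resulting calls
#' into the up/down sets. Seeds keep their stated directions. Seed TFs
#' absent from the network are kept in the spec but cannot seed expansion
#' (warning).
#'
#' @param network A [reg_network()].
#' @param spec A [perturbation_spec()].
#' @param radius Maximum graph distance. Default 6.
#' @return A new [perturbation_spec()] including the derived targets.
#' @export
expand_spec <- function(network, spec, radius = 6) {
  stopifnot(inherits(network, "reg_network"),
            inherits(spec, "perturbation_spec"))
  seed_tfs <- c(spec$up, spec$down)
  present <- seed_tfs %in% network$nodes
  if (any(!present)) {
    warning("spec TF(s) absent from the network, not expanded: ",
            paste(seed_tfs[!present], collapse = ", "), call. = FALSE)
  }
  seeds <- tibble::tibble(
    tf = seed_tfs[present],
    direction = c(rep(1L, length(spec$up)),
                  rep(-1L, length(spec$down)))[present])
  if (nrow(seeds) == 0) return(spec)
  calls <- find_targets(network, seeds, radius = radius)
  calls <- calls[!calls$tf %in% seed_tfs, ]  # seed direction wins
  perturbation_spec(up = c(spec$up, calls$tf[calls$direction == 1L]),
                    down = c(spec$down, calls$tf[calls$direction == -1L]),
                    q = spec$q)
}
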