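# independent brute-force oracle: hand-written DFS over an adjacency list,
# enumerating all simple paths up to the radius, keeping minimum-length ones
brute_targets <- function(net, seeds, radius) {
  adj <- split(seq_len(nrow(net$edges)), net$edges$from)
  paths <- list()  # per (seed, target): list of sign vectors
  for (i in seq_len(nrow(seeds))) {
    dfs <- function(node, visited, signs) {
      if (length(signs) > 0) {
        key <- node
        paths[[key]] <<- c(paths[[key]], list(
          list(seed_idx = i, seed = seeds$direction[i], signs = signs)))
      }
      if (length(signs) >= radius) return()
      for (e in adj[[node]]) {
        nxt <- net$edges$to[e]
        if (!nxt %in% visited) {
          dfs(nxt, c(visited, nxt), c(signs, net$edges$sign[e]))
        }
      }
    }
    dfs(seeds$tf[i], seeds$tf[i], integer())
  }
  out <- list()
  for (tgt in setdiff(names(paths), seeds$tf)) {
    lens <- vapply(paths[[tgt]], function(p) length(p$signs), integer(1))
    # shortest-path rule is per seed: keep each seed's minimum-length paths
    seeds_of <- vapply(paths[[tgt]], function(p) p$seed_idx, integer(1))
    keep <- rep(FALSE, length(lens))
    for (sd in unique(seeds_of)) {
      idx <- which(seeds_of == sd)
      keep[idx[lens[idx] == min(lens[idx])]] <- TRUE
    }
    kept <- paths[[tgt]][keep]
    scores <- vapply(kept, function(p) p$seed * prod(p$signs), numeric(1))
    if (sum(scores) == 0) next
    out[[tgt]] <- tibble::tibble(
      tf = tgt, direction = as.integer(sign(sum(scores))),
      distance = as.integer(min(lens)), n_paths = length(scores),
      mean_direction = sum(scores) / length(scores))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  res[order(res$distance, res$tf), ]
}
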