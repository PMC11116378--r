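write_trrust <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

test_that("parse_trrust applies sign mapping, loop/dup/conflict cleanup", {
  p <- write_trrust(list(
    c("A", "B", "Activation", "1"),
    c("B", "C", "Repression", "2"),
    c("A", "A", "Activation", "3"),
    c("D", "E", "Unknown", "4")))
  net <- parse_trrust(p)
  expect_equal(net$edges,
               tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                              sign = c(1L, -1L)))

  p2 <- write_trrust(list(
    c("A", "B", "Activation", "1"),
    c("A", "B", "Activation", "2")))
  expect_equal(nrow(parse_trrust(p2)$edges), 1)

  p3 <- write_trrust(list(
    c("A", "B", "Activation", "1"),
    c("A", "B", "Repression", "2"),
    c("B", "C", "Activation", "3")))
  expect_warning(net3 <- parse_trrust(p3), "both signs")
  expect_equal(net3$edges$from, "B")

  p4 <- write_trrust(list(c("A", "B", "Activation", "1"),
                          c("oops")))
  expect_error(parse_trrust(p4), "line 2")
})

test_that("path_direction equals seed times sign product and the XNOR oracle", {
  expect_equal(path_direction(c(1, 1), 1), 1)
  expect_equal(path_direction(c(1, -1), 1), -1)
  expect_equal(path_direction(c(-1, -1), -1), -1)

  # bit-level XNOR-chain oracle: encode up/positive as 1, down/negative as 0
  xnor <- function(a, b) as.integer(a == b)
  oracle <- function(signs, seed_dir) {
    bit <- as.integer(seed_dir == 1)
    for (s in signs) bit <- xnor(bit, as.integer(s == 1))
    if (bit == 1) 1L else -1L
  }
  for (k in 1:6) {
    combos <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    for (i in seq_len(nrow(combos))) {
      for (seed_dir in c(-1, 1)) {
        expect_identical(path_direction(combos[i, ], seed_dir),
                         oracle(combos[i, ], seed_dir))
      }
    }
  }
})

test_that("find_targets handles chains and exact diamond cancellation", {
  chain <- reg_network(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                      sign = c(1L, -1L)))
  out <- find_targets(chain, tibble::tibble(tf = "A", direction = 1L))
  expect_equal(out$tf, c("B", "C"))
  expect_equal(out$direction, c(1L, -1L))
  expect_equal(out$distance, c(1L, 2L))

  diamond <- reg_network(tibble::tibble(
    from = c("A", "B", "A", "C"), to = c("B", "D", "C", "D"),
    sign = c(1L, 1L, -1L, 1L)))
  out2 <- find_targets(diamond, tibble::tibble(tf = "A", direction = 1L))
  # D reached by two equal-length paths with opposite directions: excluded
  expect_false("D" %in% out2$tf)
  expect_setequal(out2$tf, c("B", "C"))

  expect_error(
    find_targets(chain, tibble::tibble(tf = "Z", direction = 1L)), "Z")
})

test_that("radius bounds distances and growing it never drops near targets", {
  long <- reg_network(tibble::tibble(
    from = paste0("N", 1:8), to = paste0("N", 2:9), sign = rep(1L, 8)))
  seeds <- tibble::tibble(tf = "N1", direction = 1L)
  r3 <- find_targets(long, seeds, radius = 3)
  r6 <- find_targets(long, seeds, radius = 6)
  expect_true(all(r3$distance <= 3))
  expect_true(all(r6$distance <= 6))
  expect_true(all(r3$tf %in% r6$tf))
  expect_equal(r3, r6[r6$tf %in% r3$tf, ])
})

test_that("find_targets matches the all-simple-paths oracle on random DAGs", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    nodes <- paste0("T", seq_len(n))
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    pick <- pairs[runif(nrow(pairs)) < 0.35, , drop = FALSE]
    if (nrow(pick) == 0) next
    net <- reg_network(tibble::tibble(
      from = nodes[pick[, 1]], to = nodes[pick[, 2]],
      sign = sample(c(-1L, 1L), nrow(pick), replace = TRUE)))
    n_seeds <- sample(1:2, 1)
    seeds <- tibble::tibble(
      tf = sample(intersect(nodes, net$nodes), n_seeds),
      direction = sample(c(-1L, 1L), n_seeds, replace = TRUE))
    radius <- sample(2:6, 1)
    got <- find_targets(net, seeds, radius = radius)
    want <- brute_targets(net, seeds, radius)
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
    }
  }
})

test_that("expand_spec folds derived targets into the spec, seeds win", {
  chain <- reg_network(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                      sign = c(1L, -1L)))
  sp <- expand_spec(chain, perturbation_spec(up = "A"))
  expect_setequal(sp$up, c("A", "B"))
  expect_setequal(sp$down, "C")

  # a derived direction conflicting with a stated seed direction is ignored,
  # and C's pooled paths (down via A-up, up via B-down) cancel exactly
  sp2 <- expand_spec(chain, perturbation_spec(up = "A", down = "B"))
  expect_setequal(sp2$up, "A")
  expect_setequal(sp2$down, "B")
  expect_false("C" %in% c(sp2$up, sp2$down))

  empty <- reg_network(tibble::tibble(from = character(), to = character(),
                                      sign = integer()))
  expect_warning(sp3 <- expand_spec(empty, perturbation_spec(up = "A")),
                 "absent")
  expect_equal(sp3$up, "A")

  # equal and opposite derivations from two seeds cancel: target excluded
  conflict <- reg_network(tibble::tibble(
    from = c("A", "B"), to = c("X", "X"), sign = c(1L, 1L)))
  sp4 <- expand_spec(conflict, perturbation_spec(up = "A", down = "B"))
  expect_false("X" %in% c(sp4$up, sp4$down))
})

test_that("reg_network rejects malformed edge sets", {
  expect_error(reg_network(tibble::tibble(from = "A", to = "A", sign = 1L)),
               "self-loop")
  expect_error(reg_network(tibble::tibble(from = "A", to = "B", sign = 2L)),
               "sign")
  expect_error(reg_network(tibble::tibble(from = c("A", "A"),
                                          to = c("B", "B"),
                                          sign = c(1L, -1L))),
               "duplicate")
})
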