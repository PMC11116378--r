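test_that("the simulator is deterministic and honours degenerate noise", {
  cfg <- sim_config(n_genes = 40, n_tfs = 6, n_cells_per_pop = 30, seed = 5)
  s1 <- simulate_lineage(cfg)
  s2 <- simulate_lineage(cfg)
  expect_identical(s1$expression$x, s2$expression$x)
  expect_identical(s1$truth$W, s2$truth$W)

  # zero noise, zero dropout: every cell sits exactly at its population mean
  s0 <- simulate_lineage(sim_config(n_genes = 40, n_tfs = 6,
                                    n_cells_per_pop = 10, noise_sd = 0,
                                    dropout_rate = 0, seed = 1))
  for (p in rownames(s0$truth$tf_means)) {
    sub <- s0$expression$x[s0$expression$labels == p, s0$tf_names]
    expect_equal(sub, matrix(rep(pmax(s0$truth$tf_means[p, ], 0),
                                 each = nrow(sub)),
                             nrow(sub), 6, dimnames = dimnames(sub)))
  }
})

test_that("the TF sub-matrix equals simulated activity after dropout", {
  sim <- small_sim()
  obs <- sim$expression$x[, sim$tf_names]
  act <- sim$truth$activity
  # entries are either the pre-dropout activity or zeroed
  match_or_zero <- obs == act | obs == 0
  expect_true(all(match_or_zero))
  # dropout rate on TF entries is near the configured 10%
  dropped <- mean(obs == 0 & act > 0)
  expect_gt(dropped, 0.05)
  expect_lt(dropped, 0.16)
})

test_that("per-gene regression on TF activity recovers the planted signs", {
  sim <- default_sim()
  act <- sim$truth$activity
  W <- sim$truth$W
  n_tfs <- length(sim$tf_names)
  genes <- sim$expression$x[, -seq_len(n_tfs)]
  hits <- 0; total <- 0
  for (g in seq_len(ncol(genes))) {
    nz <- which(W[g, ] != 0)
    if (length(nz) == 0) next
    fit <- stats::lm.fit(cbind(1, act[, nz, drop = FALSE]), genes[, g])
    est <- fit$coefficients[-1]
    hits <- hits + sum(sign(est) == sign(W[g, nz]))
    total <- total + length(nz)
  }
  expect_gt(hits / total, 0.9)
})

test_that("the default fixture survives gene filtering", {
  sim <- default_sim()
  rep <- filter_genes(sim$expression, min_rate = 0.10)
  expect_gt(length(rep$kept_genes), 0)
  expect_true(all(sim$tf_names %in% rep$kept_genes))
})

test_that("the truth network is consistent with the planted TF shifts", {
  sim <- default_sim()
  net <- sim$network
  mu <- sim$truth$tf_means
  up <- sim$truth$drivers[["up"]]; down <- sim$truth$drivers[["down"]]
  # expansion of the driver duo calls the secondary TFs in the directions
  # their population means actually shift between Start and EndA
  sp <- expand_spec(net, perturbation_spec(up = up, down = down))
  delta <- mu["EndA", ] - mu["Start", ]
  for (tf in setdiff(sp$up, c(up, down))) expect_gt(delta[tf], 0)
  for (tf in setdiff(sp$down, c(up, down))) expect_lt(delta[tf], 0)
})

test_that("shuffling TF columns preserves marginals and kills correlation", {
  sim <- default_sim()
  tfm <- sim$expression$x[, sim$tf_names]
  sh <- shuffle_tf_columns(tfm, seed = 3)
  for (j in seq_len(ncol(tfm))) {
    expect_equal(sort(as.vector(sh[, j])), sort(as.vector(tfm[, j])))
  }
  expect_identical(sh, shuffle_tf_columns(tfm, seed = 3))
  expect_false(identical(sh, shuffle_tf_columns(tfm, seed = 4)))

  off_diag <- function(m) {
    cc <- cor(m)
    mean(abs(cc[upper.tri(cc)]))
  }
  expect_lt(off_diag(cbind(tfm[, 1:4], sh[, 5:8])) , off_diag(tfm[, 1:8]))
  # cross-TF structure collapses: mean |r| at least halved after shuffling
  expect_lt(off_diag(sh), off_diag(tfm) / 2)
})

test_that("custom population designs are honoured and carry no truth network", {
  pops <- list(
    list(label = "X", n_cells = 12, tf_means = c(1, 2, 3, 4)),
    list(label = "Y", n_cells = 8, tf_means = c(4, 3, 2, 1)))
  sim <- simulate_lineage(sim_config(n_genes = 20, n_tfs = 4,
                                     populations = pops, seed = 2))
  expect_equal(as.vector(table(sim$expression$labels)[c("X", "Y")]),
               c(12, 8))
  expect_null(sim$network)
  expect_error(sim_config(n_genes = 10, n_tfs = 4, populations = list(
    list(label = "X", n_cells = 5, tf_means = c(1, 2)))), "tf_means")
})

test_that("write_sim emits a loadable fixture directory", {
  sim <- simulate_lineage(sim_config(n_genes = 25, n_tfs = 5,
                                     n_cells_per_pop = 15, seed = 9))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_expression(file.path(dir, "matrix.mtx"), dialect = "mtx",
                          labels_path = file.path(dir, "labels.tsv"))
  expect_equal(back$x, sim$expression$x)
  expect_equal(unname(back$labels), unname(sim$expression$labels))
  expect_equal(readLines(file.path(dir, "tf_list.tsv")), sim$tf_names)
  net <- parse_trrust(file.path(dir, "network.tsv"))
  expect_equal(net$edges, sim$network$edges)
})
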