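toy_mats <- function(seed = 1, n = 5, g = 10) {
  set.seed(seed)
  list(perturb = matrix(rnorm(n * g, 2), n, g),
       start = matrix(rnorm(n * g, 1), n, g),
       end = matrix(rnorm(n * g, 3), n, g))
}

test_that("correlation triad matches a brute-force per-cell loop", {
  m <- toy_mats()
  triad <- correlation_triad(m$perturb, m$start, m$end)
  end_c <- colMeans(m$end); start_c <- colMeans(m$start)
  for (i in 1:5) {
    expect_equal(triad$r_perturb_end[i], brute_cor(m$perturb[i, ], end_c))
    expect_equal(triad$r_start_end[i], brute_cor(m$start[i, ], end_c))
    expect_equal(triad$r_perturb_start[i], brute_cor(m$perturb[i, ], start_c))
  }
})

test_that("degenerate triads: centroid self-correlation and identical inputs", {
  m <- toy_mats(2)
  end_c <- colMeans(m$end)
  at_end <- matrix(rep(end_c, each = 3), 3, ncol(m$end))
  triad <- correlation_triad(at_end, m$start, m$end)
  expect_equal(triad$r_perturb_end, rep(1, 3))

  same <- correlation_triad(m$start, m$start, m$end)
  expect_equal(same$r_perturb_end, same$r_start_end)

  flat <- matrix(1, 3, ncol(m$end))
  expect_error(correlation_triad(flat, m$start, m$end), "constant")
  expect_error(correlation_triad(m$perturb, m$start, flat), "constant")
})

test_that("assess labels Ideal, Under and N.S. perturbations", {
  set.seed(5)
  mk <- function(rpe, rse, rps) {
    structure(list(r_perturb_end = rpe, r_start_end = rse,
                   r_perturb_start = rps), class = "correlation_triad")
  }
  n <- 30
  ideal <- assess(mk(0.95 + rnorm(n, 0, 0.01), 0.3 + rnorm(n, 0, 0.05),
                     0.3 + rnorm(n, 0, 0.05)))
  expect_equal(ideal$label, "Ideal")
  expect_gt(ideal$t_progress, 0)
  expect_gt(ideal$t_identity, 0)

  # no movement at all: progress t ~ 0
  rse <- 0.4 + rnorm(n, 0, 0.05)
  ns <- assess(mk(rse, rse[sample(n)], 0.9 + rnorm(n, 0, 0.02)))
  expect_equal(ns$label, "N.S.")

  # moved toward End but still closer to Start
  under <- assess(mk(0.55 + rnorm(n, 0, 0.03), 0.4 + rnorm(n, 0, 0.03),
                     0.85 + rnorm(n, 0, 0.03)))
  expect_equal(under$label, "Under")
  expect_gt(under$t_progress, 0)
  expect_lt(under$t_identity, 0)
})

test_that("a 'halfway' perturbation on simulated cells is labelled Under", {
  set.seed(11)
  g <- 40
  start <- matrix(rnorm(25 * g, rep(runif(g, 0, 4), each = 25), 0.3), 25, g)
  end <- matrix(rnorm(25 * g, rep(runif(g, 0, 4), each = 25), 0.3), 25, g)
  end_c <- colMeans(end)
  moved <- start + 0.3 * (matrix(rep(end_c, each = 25), 25, g) - start)
  res <- assess(correlation_triad(moved, start, end))
  expect_equal(res$label, "Under")
})

test_that("assess is invariant to within-group cell permutations and", {
  m <- toy_mats(3, n = 12, g = 20)
  t1 <- assess(correlation_triad(m$perturb, m$start, m$end))
  set.seed(1)
  t2 <- assess(correlation_triad(m$perturb[sample(12), ],
                                 m$start[sample(12), ],
                                 m$end[sample(12), ]))
  expect_equal(t1$t_progress, t2$t_progress)
  expect_equal(t1$t_identity, t2$t_identity)
  expect_equal(t1$label, t2$label)
})

test_that("identity t is antisymmetric in the Start/End roles", {
  m <- toy_mats(4, n = 15, g = 25)
  fwd <- assess(correlation_triad(m$perturb, m$start, m$end))
  # swapping roles swaps the two correlation vectors in the paired diff
  swapped <- assess(correlation_triad(m$perturb, m$end, m$start))
  expect_equal(fwd$t_identity, -swapped$t_identity)
})

test_that("null perturbations reject at close to the nominal rate", {
  set.seed(2026)
  n_sim <- 200
  rejections <- 0
  for (s in seq_len(n_sim)) {
    g <- 50
    mu_s <- runif(g, 0, 4); mu_e <- runif(g, 0, 4)
    start <- matrix(rnorm(30 * g, rep(mu_s, each = 30), 0.5), 30, g)
    end <- matrix(rnorm(30 * g, rep(mu_e, each = 30), 0.5), 30, g)
    null_perturb <- matrix(rnorm(30 * g, rep(mu_s, each = 30), 0.5), 30, g)
    res <- assess(correlation_triad(null_perturb, start, end))
    if (res$p_progress < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("U-test exact p-values match full enumeration for n1+n2 <= 8", {
  enum_p <- function(g1, g2) {
    # enumerate all assignments of the pooled values to group 1
    pooled <- c(g1, g2); n1 <- length(g1)
    u_of <- function(idx) {
      r <- rank(pooled)
      sum(r[idx]) - n1 * (n1 + 1) / 2
    }
    obs <- u_of(seq_len(n1))
    all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
    mu <- mean(all_u)
    # two-sided: double the smaller tail (exact distribution is symmetric)
    min(1, 2 * min(mean(all_u <= obs), mean(all_u >= obs)))
  }
  set.seed(8)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    if (n1 + n2 > 8) next
    repeat { # tie-free integer samples
      vals <- sample(1:50, n1 + n2)
      if (!anyDuplicated(vals)) break
    }
    g1 <- vals[seq_len(n1)]; g2 <- vals[-seq_len(n1)]
    m1 <- matrix(g1, ncol = 1, dimnames = list(NULL, "tf"))
    m2 <- matrix(g2, ncol = 1, dimnames = list(NULL, "tf"))
    got <- diff_tf_stats(m1, m2, "tf")
    expect_equal(got$p_value, enum_p(g1, g2), tolerance = 1e-12)
    expect_equal(got$d_value, mean(g1) - mean(g2))
  }
})

test_that("the {1,2,3} vs {4,5,6} case gives exact p = 0.1 and d = -3", {
  m1 <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "tf"))
  m2 <- matrix(c(4, 5, 6), ncol = 1, dimnames = list(NULL, "tf"))
  got <- diff_tf_stats(m1, m2, "tf")
  expect_equal(got$p_value, 0.1)
  expect_equal(got$d_value, -3)
})

test_that("diff_tf_stats symmetry and tie handling", {
  set.seed(3)
  m1 <- matrix(rpois(12, 4), 6, 2, dimnames = list(NULL, c("a", "b")))
  m2 <- matrix(rpois(8, 6), 4, 2, dimnames = list(NULL, c("a", "b")))
  fwd <- diff_tf_stats(m1, m2, c("a", "b"))
  rev <- diff_tf_stats(m2, m1, c("a", "b"))
  expect_equal(fwd$d_value, -rev$d_value)
  expect_equal(fwd$p_value, rev$p_value)

  # identical groups: d = 0; all-tied tiny samples: p = 1, not an error
  same <- diff_tf_stats(m1, m1, c("a", "b"))
  expect_equal(same$d_value, c(0, 0))
  tied1 <- matrix(5, 3, 1, dimnames = list(NULL, "a"))
  tied2 <- matrix(5, 2, 1, dimnames = list(NULL, "a"))
  expect_equal(diff_tf_stats(tied1, tied2, "a")$p_value, 1)
})

test_that("pca_coords returns a frame fitted on start+end cells", {
  m <- toy_mats(6, n = 10, g = 15)
  rownames(m$start) <- paste0("s", 1:10)
  rownames(m$end) <- paste0("e", 1:10)
  rownames(m$perturb) <- paste0("p", 1:10)
  co <- pca_coords(m$start, m$end, m$perturb)
  expect_equal(nrow(co), 30)
  expect_true(all(c("PC1", "PC2") %in% names(co)))
  expect_equal(sort(unique(co$set)), c("end", "perturb", "start"))
  # projection of the training cells matches prcomp scores directly
  fit <- prcomp(rbind(m$start, m$end), center = TRUE, rank. = 2)
  expect_equal(unname(as.matrix(co[co$set == "start", c("PC1", "PC2")])),
               unname(fit$x[1:10, 1:2]))
})
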