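# Shared fixtures, built once per test run and cached, so the heavier
# training-based checks do not retrain per test block.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small, fast fixture for contract-level tests
small_sim <- function() {
  cached("small_sim",
         simulate_lineage(sim_config(n_genes = 60, n_tfs = 8,
                                     n_cells_per_pop = 80, seed = 3)))
}

small_model <- function() {
  cached("small_model", {
    sim <- small_sim()
    train_tfvae(sim$expression, sim$tf_names,
                train_config(n_epochs = 80, seed = 2))
  })
}

# the default bifurcation fixture and the models trained on it, used by the
# end-to-end and acceptance-level checks
default_sim <- function() {
  cached("default_sim", simulate_lineage(sim_config()))
}

default_model <- function() {
  cached("default_model", {
    sim <- default_sim()
    train_tfvae(sim$expression, sim$tf_names, train_config(seed = 1))
  })
}

alpha0_model <- function() {
  cached("alpha0_model", {
    sim <- default_sim()
    train_tfvae(sim$expression, sim$tf_names,
                train_config(alpha = 0, seed = 1))
  })
}

shuffled_model <- function() {
  cached("shuffled_model", {
    sim <- default_sim()
    tfm <- sim$expression$x[, sim$tf_names, drop = FALSE]
    train_tfvae(sim$expression, sim$tf_names, train_config(seed = 1),
                tf_targets = shuffle_tf_columns(tfm, seed = 7))
  })
}

# population slices of the default fixture
sim_population <- function(sim, label) {
  sim$expression[sim$expression$labels == label, ]
}

# independent brute-force Pearson correlation (explicit sums)
brute_cor <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}
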