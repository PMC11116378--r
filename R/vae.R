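#' Training configuration for the TF-anchored VAE
#'
#' Bundles every hyper-parameter of the model and its optimizer. The latent
#' dimension is never set here: it always equals the length of the TF list
#' passed to [train_tfvae()], which is what anchors the latent space to TF
#' expression. The loss weights follow
#' \deqn{L = (1-\alpha)\{(1-\beta) L_R + \beta D_{KL}\} + \alpha L_r}
#' where \eqn{L_R} is the transcriptome reconstruction MSE, \eqn{D_{KL}} the
#' KL divergence of the posterior against N(0, 1), and \eqn{L_r} the MSE
#' between the reparameterized latent sample and measured TF expression.
#'
#' @param alpha Weight of the TF-anchoring loss, in \[0, 1\]. Default 0.8.
#' @param beta Weight of the KL term inside the VAE part, in \[0, 1\].
#'   Default 5e-5.
#' @param n_layers Fully connected layers in each of encoder trunk and
#'   decoder. Default 3.
#' @param hidden_width Nodes per hidden layer; `NULL` (default) means the
#'   number of genes.
#' @param learning_rate Peak Adam learning rate. Default 5e-3.
#' @param n_epochs Training epochs. Default 500.
#' @param batch_size Minibatch size. Default 128.
#' @param seed Integer seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @param lr_decay If `TRUE` (default), the learning rate follows a cosine
#'   decay from `learning_rate` to zero across the epochs, which settles the
#'   late-training plateau of the anchoring loss.
#' @param log_input If `TRUE`, apply `log1p` to expression before the model
#'   (and to the TF anchoring targets). Default `FALSE`: inputs are assumed
#'   already on a normalized (typically log) scale.
#' @return A list of class `train_config`.
#' @export
train_config <- function(alpha = 0.8, beta = 5e-5, n_layers = 3,
                         hidden_width = NULL, learning_rate = 5e-3,
                         n_epochs = 500, batch_size = 128, seed = 1,
                         lr_decay = TRUE, log_input = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            n_layers >= 1, n_epochs >= 0, batch_size >= 1)
  structure(
    list(alpha = alpha, beta = beta, n_layers = as.integer(n_layers),
         hidden_width = if (is.null(hidden_width)) NULL
                        else as.integer(hidden_width),
         learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         lr_decay = isTRUE(lr_decay), log_input = isTRUE(log_input)),
    class = "train_config"
  )
}

# ---- low-level network plumbing ---------------------------------------------

affine <- function(h, layer) t(t(h %*% layer$W) + layer$b)

he_layer <- function(n_in, n_out, b_init = 0) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(b_init, n_out))
}

# square hidden layers start at the identity (shifted into the linear regime
# of the leaky units); rectangular layers use He. Identity initialization
# keeps every input coordinate readable by the heads from step one, which is
# what the anchoring loss ultimately needs, while gradient descent remains
# free to move the trunk anywhere
hidden_layer <- function(n_in, n_out, shift = 2) {
  if (n_in == n_out) list(W = diag(n_out), b = rep(shift, n_out))
  else he_layer(n_in, n_out)
}

init_params <- function(n_genes, n_tfs, n_layers, width) {
  enc <- vector("list", n_layers)
  d_in <- n_genes
  for (i in seq_len(n_layers)) { enc[[i]] <- hidden_layer(d_in, width); d_in <- width }
  dec <- vector("list", n_layers)
  d_in <- n_tfs
  for (i in seq_len(n_layers)) { dec[[i]] <- hidden_layer(d_in, width); d_in <- width }
  # the log-variance head starts low so early reparameterization noise does
  # not drown the anchoring signal; training still adapts it freely
  list(enc = enc,
       mu = he_layer(width, n_tfs),
       logvar = he_layer(width, n_tfs, b_init = -4),
       dec = dec,
       out = he_layer(width, n_genes))
}

LEAKY_SLOPE <- 0.1

# forward through a leaky-ReLU stack; returns post-activation values per layer
relu_forward <- function(x, layers) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  for (i in seq_along(layers)) {
    a <- affine(acts[[i]], layers[[i]])
    acts[[i + 1]] <- pmax(a, 0) + LEAKY_SLOPE * pmin(a, 0)
  }
  acts
}

# backward through the stack; returns list(grads per layer, grad wrt input).
# leaky ReLU preserves sign, so the derivative mask is recoverable from the
# stored post-activation values
relu_backward <- function(delta, layers, acts) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    delta <- delta * ifelse(acts[[i + 1]] > 0, 1, LEAKY_SLOPE)
    grads[[i]] <- list(W = crossprod(acts[[i]], delta), b = colSums(delta))
    delta <- delta %*% t(layers[[i]]$W)
  }
  list(grads = grads, dinput = delta)
}

encoder_forward <- function(params, x) {
  acts <- relu_forward(x, params$enc)
  h <- acts[[length(acts)]]
  list(acts = acts,
       mu = affine(h, params$mu),
       logvar = affine(h, params$logvar))
}

decoder_forward <- function(params, z) {
  acts <- relu_forward(z, params$dec)
  list(acts = acts, x_hat = affine(acts[[length(acts)]], params$out))
}

# ---- loss -------------------------------------------------------------------

#' KL divergence of a diagonal Gaussian posterior against N(0, 1)
#'
#' Closed form, summed over latent dimensions and averaged over cells:
#' \eqn{\frac{1}{n}\sum_i \frac{1}{2}\sum_d (e^{lv_{id}} + \mu_{id}^2 - 1 - lv_{id})}.
#'
#' @param mu,logvar Matrices (cells x latent dims) of posterior means and log
#'   variances; shapes must match.
#' @return A single non-negative number.
#' @examples
#' kl_divergence(matrix(0, 2, 3), matrix(0, 2, 3)) # 0
#' kl_divergence(matrix(1, 1, 1), matrix(0, 1, 1)) # 0.5
#' @export
kl_divergence <- function(mu, logvar) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  if (!all(dim(mu) == dim(logvar))) {
    stop("`mu` and `logvar` shapes differ: ", paste(dim(mu), collapse = "x"),
         " vs ", paste(dim(logvar), collapse = "x"), call. = FALSE)
  }
  mean(0.5 * rowSums(exp(logvar) + mu^2 - 1 - logvar))
}

mse <- function(a, b) mean((a - b)^2)

#' Composite anchored-VAE loss
#'
#' Computes the four components and the weighted total
#' `(1 - alpha) * ((1 - beta) * recon + beta * kl) + alpha * tf_recon`.
#' `recon` is the MSE between input and reconstruction, `kl` the Gaussian KL
#' against N(0, 1), and `tf_recon` the MSE between the reparameterized latent
#' sample and the measured TF expression — the term that anchors the latent
#' space.
#'
#' @param x,x_hat Input and reconstructed expression (cells x genes).
#' @param enc An encoded state as returned by [encode()]: list with `mu`,
#'   `logvar`, `z_star`.
#' @param tf Measured TF expression (cells x TFs), aligned to `enc$z_star`.
#' @param alpha,beta Loss weights in \[0, 1\].
#' @return A list of class `loss_breakdown` with `total`, `recon`, `kl`,
#'   `tf_recon`.
#' @export
vae_loss <- function(x, x_hat, enc, tf, alpha = 0.8, beta = 5e-5) {
  if (!all(dim(x) == dim(x_hat))) {
    stop("`x` and `x_hat` shapes differ", call. = FALSE)
  }
  if (!all(dim(enc$z_star) == dim(tf))) {
    stop("`enc$z_star` and `tf` shapes differ", call. = FALSE)
  }
  recon <- mse(x, x_hat)
  kl <- kl_divergence(enc$mu, enc$logvar)
  tf_recon <- mse(enc$z_star, tf)
  structure(
    list(total = (1 - alpha) * ((1 - beta) * recon + beta * kl) +
           alpha * tf_recon,
         recon = recon, kl = kl, tf_recon = tf_recon),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.6g (recon %.6g, kl %.6g, tf_recon %.6g)\n",
              x$total, x$recon, x$kl, x$tf_recon))
  invisible(x)
}

# ---- training ---------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

# global gradient-norm clipping, the usual guard against unstable steps
clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(unlist(rapply(grads, function(g) sum(g^2),
                                  how = "unlist"))))
  if (is.finite(total) && total > max_norm) {
    grads <- rapply(grads, function(g) g * (max_norm / total),
                    how = "replace")
  }
  grads
}

adam_step <- function(params, grads, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    for (nm in names(p)) {
      if (is.list(p[[nm]])) {
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      } else {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mh <- m[[nm]] / (1 - b1^t)
        vh <- v[[nm]] / (1 - b2^t)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  walk(params, grads, m, v)
}

#' Train a TF-anchored variational autoencoder
#'
#' Fits a VAE whose latent dimension equals the number of TFs and whose
#' reparameterized latent sample is pulled toward the measured TF expression
#' of each cell by the anchoring loss term (weight `alpha`). The trained
#' decoder then maps (possibly edited) TF-space profiles to whole
#' transcriptomes.
#'
#' Encoder and decoder are mirror-image fully connected ReLU stacks of
#' `config$n_layers` layers, `config$hidden_width` nodes each (default: one
#' node per gene), with linear heads for the posterior mean/log-variance and
#' for the decoded expression. Optimization is minibatch Adam; all
#' randomness (initialization, shuffling, reparameterization noise) is
#' governed by `config$seed`.
#'
#' @param data A [cell_expr()] object (cells x genes, normalized).
#' @param tf_names Ordered character vector of TF gene names; must be a
#'   subset of the gene names. Fixes the latent dimension.
#' @param config A [train_config()].
#' @param tf_targets Optional cells x TFs matrix to use as the anchoring
#'   target instead of the TF sub-matrix of `data` (used e.g. for
#'   shuffled-anchor negative controls).
#' @return An object of class `tfvae`: model parameters, the config, gene and
#'   TF name lists, and a per-epoch loss history tibble.
#' @seealso [encode()], [decode()], [perturb()]
#' @export
train_tfvae <- function(data, tf_names, config = train_config(),
                        tf_targets = NULL) {
  stopifnot(inherits(data, "cell_expr"), inherits(config, "train_config"))
  gene_names <- colnames(data$x)
  missing <- setdiff(tf_names, gene_names)
  if (length(missing) > 0) {
    stop("TFs absent from the gene list: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- data$x
  if (config$log_input) x <- log1p(x)
  tf <- if (is.null(tf_targets)) x[, tf_names, drop = FALSE] else {
    stopifnot(nrow(tf_targets) == nrow(x), ncol(tf_targets) == length(tf_names))
    as.matrix(tf_targets)
  }
  n <- nrow(x); n_genes <- ncol(x); n_tfs <- length(tf_names)
  width <- if (is.null(config$hidden_width)) n_genes else config$hidden_width
  alpha <- config$alpha; beta <- config$beta
  w_rec <- (1 - alpha) * (1 - beta)
  w_kl <- (1 - alpha) * beta

  # the encoder reads per-gene standardized input (better conditioned for
  # the ReLU trunk); reconstruction and anchoring targets stay on the
  # original expression scale, so the loss semantics are unchanged
  center <- colMeans(x)
  scale_ <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- t((t(x) - center) / scale_)

  history <- vector("list", config$n_epochs)
  params <- withr::with_seed(config$seed, {
    params <- init_params(n_genes, n_tfs, config$n_layers, width)
    m <- adam_init(params); v <- adam_init(params); step <- 0L
    warmup <- max(1, ceiling(0.1 * config$n_epochs))
    for (epoch in seq_len(config$n_epochs)) {
      # linear warmup into a cosine decay: the warmup protects the early
      # epochs (when the decoder is far from scale) from destabilizing
      # steps, the decay settles the late-training plateau
      lr_epoch <- config$learning_rate *
        if (!config$lr_decay) 1
        else if (epoch <= warmup) epoch / warmup
        else 0.5 * (1 + cos(pi * (epoch - warmup) /
                              max(1, config$n_epochs - warmup)))
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep <- c(total = 0, recon = 0, kl = 0, tf_recon = 0)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        xsb <- xs[idx, , drop = FALSE]
        tfb <- tf[idx, , drop = FALSE]
        nb <- length(idx)

        ef <- encoder_forward(params, xsb)
        eps_b <- matrix(stats::rnorm(nb * n_tfs), nb, n_tfs)
        sd_b <- exp(ef$logvar / 2)
        z <- ef$mu + eps_b * sd_b
        df <- decoder_forward(params, z)

        lb <- vae_loss(xb, df$x_hat,
                       list(mu = ef$mu, logvar = ef$logvar, z_star = z),
                       tfb, alpha, beta)
        if (!is.finite(lb$total)) {
          stop("non-finite loss at epoch ", epoch,
               "; lower the learning rate", call. = FALSE)
        }
        ep <- ep + nb * c(lb$total, lb$recon, lb$kl, lb$tf_recon)

        # gradients
        g_xhat <- w_rec * 2 * (df$x_hat - xb) / (nb * n_genes)
        g_out <- list(W = crossprod(df$acts[[length(df$acts)]], g_xhat),
                      b = colSums(g_xhat))
        bdec <- relu_backward(g_xhat %*% t(params$out$W), params$dec, df$acts)
        g_z <- bdec$dinput + alpha * 2 * (z - tfb) / (nb * n_tfs)
        g_mu <- g_z + w_kl * ef$mu / nb
        g_lv <- g_z * (0.5 * eps_b * sd_b) +
          w_kl * 0.5 * (exp(ef$logvar) - 1) / nb
        h_top <- ef$acts[[length(ef$acts)]]
        g_muh <- list(W = crossprod(h_top, g_mu), b = colSums(g_mu))
        g_lvh <- list(W = crossprod(h_top, g_lv), b = colSums(g_lv))
        benc <- relu_backward(g_mu %*% t(params$mu$W) +
                                g_lv %*% t(params$logvar$W),
                              params$enc, ef$acts)
        grads <- list(enc = benc$grads, mu = g_muh, logvar = g_lvh,
                      dec = bdec$grads, out = g_out)
        grads <- clip_grads(grads, max_norm = 5)

        step <- step + 1L
        upd <- adam_step(params, grads, m, v, lr_epoch, step)
        params <- upd$p; m <- upd$m; v <- upd$v
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, total = ep[["total"]] / n, recon = ep[["recon"]] / n,
        kl = ep[["kl"]] / n, tf_recon = ep[["tf_recon"]] / n)
    }
    params
  })

  structure(
    list(params = params, config = config, gene_names = gene_names,
         tf_names = tf_names, center = center, scale = scale_,
         history = if (config$n_epochs > 0) dplyr::bind_rows(history)
                   else tibble::tibble(epoch = integer(), total = double(),
                                       recon = double(), kl = double(),
                                       tf_recon = double()),
         format_version = 1L),
    class = "tfvae"
  )
}

#' @export
print.tfvae <- function(x, ...) {
  cat("<tfvae> ", length(x$gene_names), " genes, ", length(x$tf_names),
      " latent TFs, ", x$config$n_layers, "-layer encoder/decoder\n", sep = "")
  cat("trained ", nrow(x$history), " epochs (alpha = ", x$config$alpha,
      ", beta = ", x$config$beta, ")\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final losses: total %.4g, recon %.4g, kl %.4g, tf_recon %.4g\n",
                last$total, last$recon, last$kl, last$tf_recon))
  }
  invisible(x)
}

#' @export
tidy.tfvae <- function(x, ...) x$history

#' @export
glance.tfvae <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else
    tibble::tibble(total = NA_real_, recon = NA_real_, kl = NA_real_,
                   tf_recon = NA_real_)
  tibble::tibble(
    n_genes = length(x$gene_names), n_tfs = length(x$tf_names),
    n_layers = x$config$n_layers, alpha = x$config$alpha,
    beta = x$config$beta, n_epochs = nrow(x$history),
    total = last$total, recon = last$recon, kl = last$kl,
    tf_recon = last$tf_recon)
}

# internal: check input genes against the model, return the (transformed) matrix
model_input <- function(model, data) {
  x <- expr_matrix(data)
  if (is.null(colnames(x)) || !identical(colnames(x), model$gene_names)) {
    missing <- setdiff(model$gene_names, colnames(x))
    stop("input genes do not match the model's gene list",
         if (length(missing) > 0)
           paste0("; missing: ", paste(utils::head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..."),
         call. = FALSE)
  }
  if (model$config$log_input) log1p(x) else x
}

#' Encode expression profiles into the TF-anchored latent space
#'
#' @param model A trained [train_tfvae()] model.
#' @param data A [cell_expr()] or matrix with exactly the model's genes.
#' @param deterministic If `TRUE`, `z_star` is the posterior mean (no
#'   reparameterization noise).
#' @param seed Seed for the reparameterization draw when
#'   `deterministic = FALSE`.
#' @return A list of class `encoded_state` with matrices `mu`, `logvar` and
#'   `z_star` (cells x TFs, TF names as columns).
#' @export
encode <- function(model, data, deterministic = FALSE, seed = 1) {
  stopifnot(inherits(model, "tfvae"))
  x <- model_input(model, data)
  xs <- t((t(x) - model$center) / model$scale)
  ef <- encoder_forward(model$params, xs)
  z_star <- if (deterministic) ef$mu else {
    eps <- withr::with_seed(as.integer(seed),
                            matrix(stats::rnorm(length(ef$mu)), nrow(ef$mu)))
    ef$mu + eps * exp(ef$logvar / 2)
  }
  dn <- list(rownames(x), model$tf_names)
  dimnames(ef$mu) <- dn; dimnames(ef$logvar) <- dn; dimnames(z_star) <- dn
  structure(list(mu = ef$mu, logvar = ef$logvar, z_star = z_star),
            class = "encoded_state")
}

#' Decode latent TF-space profiles into transcriptomes
#'
#' A pure function of the decoder parameters: identical latent rows decode to
#' identical expression rows.
#'
#' @param model A trained [train_tfvae()] model.
#' @param z Matrix (cells x TFs) of latent profiles; width must equal the
#'   model's latent dimension.
#' @return Matrix (cells x genes) of predicted expression, gene names as
#'   columns. If the model was trained with `log_input = TRUE` the output is
#'   on the log1p scale.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "tfvae"))
  z <- as.matrix(z)
  if (ncol(z) != length(model$tf_names)) {
    stop("latent width ", ncol(z), " != model latent dimension ",
         length(model$tf_names), call. = FALSE)
  }
  out <- decoder_forward(model$params, z)$x_hat
  dimnames(out) <- list(rownames(z), model$gene_names)
  out
}

#' Reconstruct expression through the anchored latent space
#'
#' Shorthand for `decode(model, encode(model, data, deterministic = TRUE)$z_star)`.
#'
#' @inheritParams encode
#' @return Matrix (cells x genes) of reconstructed expression.
#' @export
reconstruct <- function(model, data) {
  decode(model, encode(model, data, deterministic = TRUE)$z_star)
}

#' Per-cell reconstruction correlations
#'
#' Pearson correlation between each cell's observed and reconstructed
#' transcriptome — the standard summary of how well the decoder reproduces
#' expression from the anchored latent space.
#'
#' @inheritParams encode
#' @return Tibble with columns `cell_id` and `r`.
#' @export
reconstruction_cor <- function(model, data) {
  x <- model_input(model, data)
  xh <- reconstruct(model, data)
  tibble::tibble(
    cell_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    r = vapply(seq_len(nrow(x)), function(i) {
      stats::cor(x[i, ], xh[i, ])
    }, numeric(1)))
}

#' Per-TF latent anchoring correlations
#'
#' Pearson correlation, across cells, between each TF's reparameterized
#' latent value and its measured expression. High values mean the anchoring
#' loss succeeded in making the latent space readable as TF expression.
#'
#' @inheritParams encode
#' @param seed Seed for the reparameterization draw.
#' @return Tibble with columns `tf` and `r`.
#' @export
anchoring_cor <- function(model, data, seed = 1) {
  x <- model_input(model, data)
  z <- encode(model, data, deterministic = FALSE, seed = seed)$z_star
  tf_obs <- x[, model$tf_names, drop = FALSE]
  tibble::tibble(
    tf = model$tf_names,
    r = vapply(seq_along(model$tf_names), function(j) {
      stats::cor(z[, j], tf_obs[, j])
    }, numeric(1)))
}

#' @export
autoplot.tfvae <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL)
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a trained model checkpoint
#'
#' The checkpoint stores parameters, config, gene and TF name lists and a
#' format version; loading a checkpoint written by an incompatible version,
#' or a file that is not a checkpoint, fails with a clear error.
#'
#' @param model A `tfvae` model.
#' @param path File path for the checkpoint.
#' @return `save_tfvae` returns `path` invisibly; `load_tfvae` returns the
#'   model.
#' @export
save_tfvae <- function(model, path) {
  stopifnot(inherits(model, "tfvae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tfvae
#' @export
load_tfvae <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("not a readable checkpoint: ", path, call. = FALSE)
  })
  if (!inherits(model, "tfvae") || is.null(model$format_version)) {
    stop("file is not a tfvae checkpoint: ", path, call. = FALSE)
  }
  if (model$format_version != 1L) {
    stop("checkpoint format version ", model$format_version,
         " not supported by this package (supports 1)", call. = FALSE)
  }
  model
}
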