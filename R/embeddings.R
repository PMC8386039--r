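#' Specify an embedding model
#'
#' Encoder-decoder models that compress cells to a low-dimensional latent
#' representation and reconstruct counts under a negative-binomial
#' likelihood with an exponential inverse-link (decoded means are strictly
#' positive). Kinds:
#' \describe{
#'   \item{linear}{a linear encoder and linear decoder (a matrix
#'     factorization fitted by the NB likelihood)}
#'   \item{nmf}{non-negative matrix factorization of the transformed
#'     matrix, fitted by multiplicative updates; scored with the NB
#'     likelihood like all other kinds}
#'   \item{ae}{dense autoencoder with selu activations and batch
#'     normalisation between dense layers (default hidden sizes
#'     512-64-512, the middle entry being the bottleneck)}
#'   \item{vae}{variational autoencoder with a unit-Gaussian prior on the
#'     latent space; the loss adds the KL divergence of the encoder
#'     posterior from the prior to the NB reconstruction term}
#'   \item{random_projection}{sparse random-projection baseline; see
#'     [random_projection_baseline()]}
#' }
#'
#' The encoder consumes [transform_counts()] values; the likelihood is
#' evaluated against the raw counts, with each cell's size factor
#' re-applied to the decoded per-10^4 rate.
#'
#' @param kind model kind
#' @param input_genes ordered gene ids
#' @param hidden hidden sizes for ae/vae as `c(encoder..., latent,
#'   decoder...)` (odd length; default `c(512, 64, 512)`)
#' @param latent_dim bottleneck size for linear/nmf/random_projection
#'   (default 64); for ae/vae it is the middle entry of `hidden`
#' @param batchnorm batch-normalise hidden layers (ae/vae only; default on)
#' @param dispersion `"per_gene"` (one trained dispersion per gene) or
#'   `"per_cell_gene"` (a decoder head emits one dispersion per cell and
#'   gene)
#' @param kl_weight weight of the VAE KL term (default 1)
#' @param l2 L2 penalty on dense weights
#' @return an `embedding_spec`
#' @seealso [fit_embedding()], [embed()], [reconstruct_and_score()]
#' @export
embedding_spec <- function(kind = c("linear", "nmf", "ae", "vae", "random_projection"),
                           input_genes,
                           hidden = c(512L, 64L, 512L),
                           latent_dim = 64L,
                           batchnorm = TRUE,
                           dispersion = c("per_gene", "per_cell_gene"),
                           kl_weight = 1, l2 = 0) {
  kind <- match.arg(kind)
  dispersion <- match.arg(dispersion)
  input_genes <- as.character(input_genes)
  J <- length(input_genes)
  if (kind %in% c("ae", "vae")) {
    if (length(hidden) %% 2L != 1L) {
      oz_stop("domain_error", "hidden must have odd length (encoder, latent, decoder)")
    }
    mid <- (length(hidden) + 1L) %/% 2L
    enc_hidden <- as.integer(hidden[seq_len(mid - 1L)])
    latent_dim <- as.integer(hidden[mid])
    dec_hidden <- as.integer(hidden[-seq_len(mid)])
  } else {
    enc_hidden <- integer(); dec_hidden <- integer()
    latent_dim <- as.integer(latent_dim)
    batchnorm <- FALSE
  }
  if (latent_dim >= J) {
    oz_stop("domain_error", "latent_dim (%d) must be smaller than the number of genes (%d)",
            latent_dim, J)
  }
  structure(
    list(kind = kind, input_genes = input_genes, enc_hidden = enc_hidden,
         dec_hidden = dec_hidden, latent_dim = latent_dim,
         activation = "selu", batchnorm = batchnorm,
         dispersion = dispersion, kl_weight = kl_weight, l2 = l2),
    class = "embedding_spec"
  )
}

init_embedding_params <- function(spec) {
  J <- length(spec$input_genes)
  d <- spec$latent_dim
  bn <- isTRUE(spec$batchnorm)
  stack <- function(sizes, out_linear_dim = NULL, bn_hidden = bn) {
    layers <- list()
    prev <- sizes[1L]
    for (h in sizes[-1L]) {
      layers[[length(layers) + 1L]] <- c(new_dense_layer(prev, h, batchnorm = bn_hidden),
                                         list(act = spec$activation))
      prev <- h
    }
    list(layers = layers, out_dim = prev)
  }
  p <- list()
  if (spec$kind == "linear") {
    p$enc <- list(c(new_dense_layer(J, d), list(act = "linear")))
    p$dec <- list()
    p$out_head <- c(new_dense_layer(d, J), list(act = "linear"))
    dec_top <- d
  } else if (spec$kind %in% c("ae", "vae")) {
    es <- stack(c(J, spec$enc_hidden))
    p$enc <- es$layers
    if (spec$kind == "ae") {
      p$enc[[length(p$enc) + 1L]] <- c(new_dense_layer(es$out_dim, d), list(act = "linear"))
    } else {
      p$mu_head <- c(new_dense_layer(es$out_dim, d), list(act = "linear"))
      p$lv_head <- c(new_dense_layer(es$out_dim, d), list(act = "linear"))
    }
    ds <- stack(c(d, spec$dec_hidden))
    p$dec <- ds$layers
    p$out_head <- c(new_dense_layer(ds$out_dim, J), list(act = "linear"))
    dec_top <- ds$out_dim
  } else if (spec$kind == "nmf") {
    p$H <- matrix(stats::runif(d * J, 0.1, 1), d, J)
    return(p)
  } else if (spec$kind == "random_projection") {
    p$P <- sparse_projection_matrix(d, J)
    return(p)
  }
  if (spec$dispersion == "per_gene") {
    p$rho <- numeric(J)                      # phi = exp(rho), start at 1
  } else {
    p$phi_head <- c(new_dense_layer(dec_top, J), list(act = "linear"))
  }
  p
}

# Sparse random projection components (latent_dim x J): Achlioptas-style
# +/- sqrt(1/density)/sqrt(latent_dim) entries with density 1/sqrt(J).
sparse_projection_matrix <- function(latent_dim, J) {
  density <- 1 / sqrt(J)
  scale <- sqrt(1 / density) / sqrt(latent_dim)
  u <- stats::runif(latent_dim * J)
  vals <- ifelse(u < density / 2, -scale, ifelse(u < density, scale, 0))
  matrix(vals, latent_dim, J)
}

run_stack <- function(layers, A, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    caches[[i]] <- dense_forward(layers[[i]], A, layers[[i]]$act, training = training)
    A <- caches[[i]]$out
  }
  list(out = A, caches = caches)
}

back_stack <- function(layers, caches, dOut, prefix, g, l2 = 0) {
  dA <- dOut
  for (i in rev(seq_along(layers))) {
    bp <- dense_backward(layers[[i]], caches[[i]], dA, layers[[i]]$act)
    g[[sprintf("%s.%d.W", prefix, i)]] <- bp$W + l2 * layers[[i]]$W
    g[[sprintf("%s.%d.b", prefix, i)]] <- bp$b
    if (!is.null(bp$bn_gamma)) {
      g[[sprintf("%s.%d.bn.gamma", prefix, i)]] <- bp$bn_gamma
      g[[sprintf("%s.%d.bn.beta", prefix, i)]] <- bp$bn_beta
    }
    dA <- bp$dA
  }
  list(g = g, dA = dA)
}

embedding_forward <- function(spec, params, Xt, training = FALSE, noise = NULL) {
  fw <- list()
  if (spec$kind == "vae") {
    enc <- run_stack(params$enc, Xt, training)
    muh <- dense_forward(params$mu_head, enc$out, "linear")
    lvh <- dense_forward(params$lv_head, enc$out, "linear")
    z_mu <- muh$out
    logvar <- pmin(pmax(lvh$out, -10), 10)
    if (training) {
      eps <- noise %||% matrix(stats::rnorm(length(z_mu)), nrow(z_mu), ncol(z_mu))
      z <- z_mu + exp(0.5 * logvar) * eps
      fw$eps <- eps
    } else {
      z <- z_mu
    }
    fw <- c(fw, list(enc = enc, muh = muh, lvh = lvh, z_mu = z_mu,
                     logvar = logvar, z = z))
  } else {
    enc <- run_stack(params$enc, Xt, training)
    fw$enc <- enc
    fw$z <- enc$out
  }
  dec <- run_stack(params$dec, fw$z, training)
  outh <- dense_forward(params$out_head, dec$out, "linear")
  fw$dec <- dec
  fw$outh <- outh
  fw$eta <- outh$out
  if (spec$dispersion == "per_cell_gene") {
    fw$phih <- dense_forward(params$phi_head, dec$out, "linear")
    fw$eta_phi <- pmin(pmax(fw$phih$out, -15), 15)
    fw$phi <- exp(fw$eta_phi)
  } else {
    fw$phi <- exp(params$rho)
  }
  fw
}

embedding_grads <- function(spec, params, fw, x_raw, sf) {
  B <- nrow(x_raw)
  mu_raw <- sf * exp(pmin(fw$eta, 30))
  mu <- pmax(mu_raw, 1e-12)                 # consistent with nb_nll's clip
  phi <- if (spec$dispersion == "per_cell_gene") fw$phi
         else matrix(fw$phi, B, ncol(x_raw), byrow = TRUE)
  g <- list()
  active <- (mu_raw > 1e-12) & (fw$eta < 30)
  dEta <- nb_nll_grad_eta(x_raw, mu, phi) * active / B
  if (spec$dispersion == "per_cell_gene") {
    active_phi <- abs(fw$phih$out) < 15     # clip in the forward pass
    dEtaPhi <- nb_nll_grad_rho(x_raw, mu, phi) * active_phi / B
    bp_phi <- dense_backward(params$phi_head, fw$phih, dEtaPhi, "linear")
    g[["phi_head.W"]] <- bp_phi$W; g[["phi_head.b"]] <- bp_phi$b
    dDecTop_phi <- bp_phi$dA
  } else {
    g[["rho"]] <- colSums(nb_nll_grad_rho(x_raw, mu, phi)) / B
    dDecTop_phi <- 0
  }
  bp_out <- dense_backward(params$out_head, fw$outh, dEta, "linear")
  g[["out_head.W"]] <- bp_out$W + spec$l2 * params$out_head$W
  g[["out_head.b"]] <- bp_out$b
  dec_res <- back_stack(params$dec, fw$dec$caches, bp_out$dA + dDecTop_phi,
                        "dec", g, spec$l2)
  g <- dec_res$g
  dZ <- dec_res$dA
  if (spec$kind == "vae") {
    sigma <- exp(0.5 * fw$logvar)
    dMu <- dZ + spec$kl_weight * fw$z_mu / B
    dLogvar <- dZ * fw$eps * 0.5 * sigma +
      spec$kl_weight * 0.5 * (exp(fw$logvar) - 1) / B
    bp_mu <- dense_backward(params$mu_head, fw$muh, dMu, "linear")
    bp_lv <- dense_backward(params$lv_head, fw$lvh, dLogvar, "linear")
    g[["mu_head.W"]] <- bp_mu$W; g[["mu_head.b"]] <- bp_mu$b
    g[["lv_head.W"]] <- bp_lv$W; g[["lv_head.b"]] <- bp_lv$b
    enc_res <- back_stack(params$enc, fw$enc$caches, bp_mu$dA + bp_lv$dA, "enc", g, spec$l2)
  } else {
    enc_res <- back_stack(params$enc, fw$enc$caches, dZ, "enc", g, spec$l2)
  }
  enc_res$g
}

vae_kl <- function(z_mu, logvar) {
  -0.5 * sum(1 + logvar - z_mu^2 - exp(logvar))
}

embedding_loss <- function(spec, params, fw, x_raw, sf) {
  mu <- sf * exp(pmin(fw$eta, 30))
  if (!all(is.finite(mu)) || !all(is.finite(fw$phi))) return(NaN)
  mu <- pmax(mu, 1e-12)
  nll <- nb_nll(x_raw, mu, fw$phi)$total
  loss <- nll / nrow(x_raw)
  if (spec$kind == "vae") {
    loss <- loss + spec$kl_weight * vae_kl(fw$z_mu, fw$logvar) / nrow(x_raw)
  }
  loss
}

#' Fit an embedding model
#'
#' Gradient-based kinds (linear, ae, vae) are trained by minibatch Adam on
#' the negative-binomial reconstruction NLL (plus the KL term for the VAE).
#' `nmf` runs multiplicative updates on the transformed matrix; `epochs` is
#' its iteration count. `random_projection` draws its projection matrix
#' under `seed` and involves no optimisation. All randomness is governed by
#' `seed`; refitting with identical inputs reproduces the model.
#'
#' @param spec an [embedding_spec()]
#' @param counts a [count_matrix()] (raw counts; the transform is applied
#'   internally)
#' @param epochs training epochs / NMF iterations; `0` returns the
#'   initialisation
#' @param lr Adam step size
#' @param batch_size minibatch size
#' @param seed integer seed
#' @return an `ontozoo_embedding` with `spec`, `params`, `history`
#'   (data.frame of end-of-epoch full-data loss in evaluation mode) and
#'   `seed`
#' @export
fit_embedding <- function(spec, counts, epochs = 100L, lr = 1e-3,
                          batch_size = 128L, seed = 1L) {
  stopifnot(inherits(spec, "embedding_spec"))
  cm <- as_count_matrix(counts)
  check_feature_space(spec$input_genes, cm$gene_ids)
  x_raw <- cm$counts
  tm <- transform_counts(cm)
  Xt <- tm$values
  sf <- size_factors(x_raw)
  set.seed(seed)
  params <- init_embedding_params(spec)
  history <- data.frame(epoch = integer(), loss = numeric())

  if (spec$kind == "nmf") {
    if (epochs > 0L) {
      res <- fit_nmf(params$H, Xt, epochs)
      params$H <- res$H
      params$W_train <- res$W
      # per-gene dispersion estimated post hoc by profiling the NB NLL
      mu <- nmf_decode_mu(res$W, params$H, sf)
      params$rho <- log(profile_phi(x_raw, mu))
      history <- res$history
    } else {
      params$rho <- 0
    }
  } else if (spec$kind == "random_projection") {
    # no training: the projection is data-independent
  } else {
    n <- nrow(Xt)
    flat <- flatten_params(params)
    state <- adam_init(flat)
    if (epochs > 0L) {
      for (ep in seq_len(epochs)) {
        for (batch in minibatches(n, batch_size)) {
          fw <- embedding_forward(spec, params, Xt[batch, , drop = FALSE],
                                  training = TRUE)
          g <- embedding_grads(spec, params, fw, x_raw[batch, , drop = FALSE],
                               sf[batch])
          upd <- adam_step(flat, g, state, lr = lr)
          flat <- upd$params; state <- upd$state
          params <- unflatten_params(flat, params)
          params$enc <- bn_update_stack(params$enc, fw$enc$caches)
          params$dec <- bn_update_stack(params$dec, fw$dec$caches)
        }
        fw_all <- embedding_forward(spec, params, Xt, training = FALSE)
        loss <- embedding_loss(spec, params, fw_all, x_raw, sf)
        check_finite_loss(loss, ep)
        history[ep, ] <- list(ep, loss)
      }
    }
  }
  structure(
    list(spec = spec, params = params, history = history, seed = seed),
    class = "ontozoo_embedding"
  )
}

bn_update_stack <- function(layers, caches) {
  for (i in seq_along(layers)) layers[[i]] <- update_bn_running(layers[[i]], caches[[i]])
  layers
}

fit_nmf <- function(H, Xt, iters, W = NULL, update_H = TRUE, eps = 1e-9) {
  d <- nrow(H)
  if (is.null(W)) W <- matrix(stats::runif(nrow(Xt) * d, 0.1, 1), nrow(Xt), d)
  history <- data.frame(epoch = integer(), loss = numeric())
  for (it in seq_len(iters)) {
    W <- W * (Xt %*% t(H)) / (W %*% H %*% t(H) + eps)
    if (update_H) H <- H * (t(W) %*% Xt) / (t(W) %*% W %*% H + eps)
    if (update_H) history[it, ] <- list(it, mean((Xt - W %*% H)^2))
  }
  list(W = W, H = H, history = history)
}

nmf_decode_mu <- function(W, H, sf, floor = 1e-10) {
  pmax(expm1(pmax(W %*% H, 0)) * sf, floor)
}

# Global NB dispersion by profiling the likelihood over log-phi.
profile_phi <- function(x, mu, lower = -6, upper = 10) {
  f <- function(rho) nb_nll(x, mu, exp(rho))$total
  exp(stats::optimize(f, c(lower, upper))$minimum)
}

#' @export
print.ontozoo_embedding <- function(x, ...) {
  cat(sprintf("<ontozoo_embedding> kind=%s, %d genes -> %d latent dims\n",
              x$spec$kind, length(x$spec$input_genes), x$spec$latent_dim))
  if (nrow(x$history)) {
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                x$history$loss[nrow(x$history)], nrow(x$history)))
  }
  invisible(x)
}

#' Embed cells into the latent space
#'
#' Deterministic for every model kind; the VAE returns the posterior mean
#' (the log-variances are attached as attribute `"logvar"`).
#'
#' @param object an [fit_embedding()] result
#' @param data a [count_matrix()], [transform_counts()] result, or matrix
#'   of transformed values in the model's gene space
#' @return cells x latent_dim matrix
#' @export
embed <- function(object, data) {
  UseMethod("embed")
}

#' @export
embed.ontozoo_embedding <- function(object, data) {
  spec <- object$spec
  Xt <- as_transformed_values(data, spec$input_genes)
  if (spec$kind == "nmf") {
    # deterministic constant initialisation so embedding is reproducible
    W0 <- matrix(1, nrow(Xt), nrow(object$params$H))
    res <- fit_nmf(object$params$H, Xt, iters = 200L, W = W0, update_H = FALSE)
    return(res$W)
  }
  if (spec$kind == "random_projection") {
    return(Xt %*% t(object$params$P))
  }
  fw <- embedding_forward(spec, object$params, Xt, training = FALSE)
  z <- fw$z
  if (spec$kind == "vae") attr(z, "logvar") <- fw$logvar
  z
}

as_transformed_values <- function(data, input_genes) {
  if (inherits(data, "transformed_matrix")) {
    check_feature_space(input_genes, data$gene_ids)
    data$values
  } else if (inherits(data, "count_matrix")) {
    check_feature_space(input_genes, data$gene_ids)
    transform_counts(data)$values
  } else if (is.matrix(data)) {
    if (!is.null(colnames(data))) check_feature_space(input_genes, colnames(data))
    else if (ncol(data) != length(input_genes)) {
      oz_stop("feature_space_error", "data has %d genes, model expects %d",
              ncol(data), length(input_genes))
    }
    data
  } else {
    oz_stop("domain_error", "unsupported data type for embedding")
  }
}

#' Decode latent coordinates to negative-binomial means
#'
#' @param object an `ontozoo_embedding`
#' @param z cells x latent_dim matrix
#' @param sf per-cell size factors (total counts / 1e4); default 1 decodes
#'   per-10^4 rates
#' @return cells x genes matrix of strictly positive NB means
#' @export
decode_latent <- function(object, z, sf = 1) {
  spec <- object$spec
  if (spec$kind == "nmf") return(nmf_decode_mu(z, object$params$H, sf))
  if (spec$kind == "random_projection") {
    rec <- z %*% object$params$P
    return(pmax(expm1(pmax(rec, 0)) * sf, 1e-10))
  }
  dec <- run_stack(object$params$dec, z, training = FALSE)
  eta <- dense_forward(object$params$out_head, dec$out, "linear")$out
  sf * exp(pmin(eta, 30))
}

#' Reconstruction metrics on held-out data
#'
#' Embeds and decodes `counts`, then reports the negative-binomial NLL
#' (mean per entry and per cell) and the mean squared error of the decoded
#' means against the raw counts.
#'
#' @param object an `ontozoo_embedding`
#' @param counts a [count_matrix()] in the model's gene space
#' @return list with `nb_nll` (mean per entry), `nb_nll_per_cell`,
#'   `mse` and `n_cells`
#' @export
reconstruct_and_score <- function(object, counts) {
  cm <- as_count_matrix(counts)
  if (nrow(cm$counts) == 0L) oz_stop("empty_eval_error", "no cells to score")
  check_feature_space(object$spec$input_genes, cm$gene_ids)
  sf <- size_factors(cm$counts)
  z <- embed(object, cm)
  mu <- decode_latent(object, z, sf)
  phi <- reconstruction_phi(object, z)
  res <- nb_nll(cm$counts, mu, phi)
  list(nb_nll = res$mean_per_entry,
       nb_nll_per_cell = res$per_cell,
       mse = mean((cm$counts - mu)^2),
       n_cells = nrow(cm$counts))
}

reconstruction_phi <- function(object, z) {
  spec <- object$spec
  if (spec$kind == "random_projection") return(1)
  if (spec$dispersion == "per_cell_gene" && !is.null(object$params$phi_head)) {
    dec <- run_stack(object$params$dec, z, training = FALSE)
    return(exp(pmin(pmax(dense_forward(object$params$phi_head, dec$out, "linear")$out,
                         -15), 15)))
  }
  exp(object$params$rho)
}

#' Random-projection reconstruction baseline
#'
#' Contextualises trained embedding models: a sparse random projection is
#' drawn on the training data's gene space, test cells are projected to
#' `latent_dim` dimensions and reconstructed by multiplying the reduced
#' data with the projection components. Reconstructed values that are
#' negative or zero are replaced by `1e-10`, and the reconstruction is
#' scored by mean squared error and the negative-binomial NLL with a
#' constant scale (dispersion) of 1.0.
#'
#' @param train a [count_matrix()] used to fit (dimension) the projection
#' @param test a [count_matrix()] in the same gene space
#' @param latent_dim projection dimension (default 64)
#' @param seed integer seed for the projection draw
#' @return list with `nb_nll`, `nb_nll_per_cell`, `mse`, `reconstruction`
#'   (count-scale means after clipping) and `model` (the
#'   `ontozoo_embedding` wrapper)
#' @export
random_projection_baseline <- function(train, test, latent_dim = 64L, seed = 1L) {
  train <- as_count_matrix(train)
  test <- as_count_matrix(test)
  if (!identical(train$gene_ids, test$gene_ids)) {
    oz_stop("feature_space_error", "train and test gene spaces differ")
  }
  J <- ncol(train$counts)
  if (latent_dim >= J) {
    oz_stop("domain_error", "latent_dim (%d) must be smaller than the number of genes (%d)",
            latent_dim, J)
  }
  spec <- embedding_spec("random_projection", train$gene_ids,
                         latent_dim = latent_dim)
  model <- fit_embedding(spec, train, seed = seed)
  z <- embed(model, test)
  sf <- size_factors(test$counts)
  mu <- decode_latent(model, z, sf)       # clipped at 1e-10 inside
  res <- nb_nll(test$counts, mu, 1)
  list(nb_nll = res$mean_per_entry, nb_nll_per_cell = res$per_cell,
       mse = mean((test$counts - mu)^2), reconstruction = mu, model = model)
}
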