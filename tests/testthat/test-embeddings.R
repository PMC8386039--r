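test_that("linear model: decode(encode(x)) equals the explicit matrix product", {
  d <- rank2_counts(n = 60, J = 12, seed = 31)
  spec <- embedding_spec("linear", d$cm$gene_ids, latent_dim = 3)
  fit <- fit_embedding(spec, d$cm, epochs = 5, seed = 31)
  tm <- transform_counts(d$cm)
  z <- embed(fit, tm)
  # encoder is one linear layer
  We <- fit$params$enc[[1]]$W; be <- fit$params$enc[[1]]$b
  expect_lt(max(abs(z - sweep(tm$values %*% We, 2, be, "+"))), 1e-8)
  # decoded mean is exp of the explicit two-matrix product (sf = 1)
  Wd <- fit$params$out_head$W; bd <- fit$params$out_head$b
  mu <- decode_latent(fit, z)
  expect_lt(max(abs(mu - exp(sweep(z %*% Wd, 2, bd, "+")))), 1e-8)
  expect_true(all(mu > 0))
  # duplicate cells map to identical latent rows
  X2 <- tm$values[c(1, 1, 2), ]
  z2 <- embed(fit, X2)
  expect_identical(z2[1, ], z2[2, ])
})

test_that("trained linear embedding approaches the NLL at the generating means", {
  d <- rank2_counts(n = 400, J = 50, seed = 1)
  spec <- embedding_spec("linear", d$cm$gene_ids, latent_dim = 2)
  fit <- fit_embedding(spec, d$cm, epochs = 2000, lr = 3e-3, seed = 1)
  sc <- reconstruct_and_score(fit, d$cm)
  oracle <- nb_nll(d$cm$counts, d$mu, d$phi)$mean_per_entry
  expect_lt((sc$nb_nll - oracle) / abs(oracle), 0.05)
  # internal consistency: scoring the training data reproduces the recorded
  # end-of-training loss (per-cell mean NLL)
  expect_equal(mean(sc$nb_nll_per_cell),
               fit$history$loss[nrow(fit$history)], tolerance = 1e-6)
})

test_that("NMF factors are non-negative and reconstruct on the transformed scale", {
  d <- rank2_counts(n = 80, J = 15, seed = 33)
  spec <- embedding_spec("nmf", d$cm$gene_ids, latent_dim = 4)
  fit <- fit_embedding(spec, d$cm, epochs = 80, seed = 33)
  expect_true(all(fit$params$H >= 0))
  expect_true(all(fit$params$W_train >= 0))
  z <- embed(fit, d$cm)
  expect_true(all(z >= 0))
  sc <- reconstruct_and_score(fit, d$cm)
  expect_true(is.finite(sc$nb_nll))
})

test_that("VAE: KL is non-negative, zero only at the prior, and beats nothing for free", {
  oz <- asNamespace("ontozoo")
  set.seed(34)
  z_mu <- matrix(rnorm(20), 5, 4)
  lv <- matrix(rnorm(20, sd = 0.3), 5, 4)
  expect_gte(oz$vae_kl(z_mu, lv), 0)
  expect_equal(oz$vae_kl(matrix(0, 5, 4), matrix(0, 5, 4)), 0)

  # with KL weight 0 and matched architecture, the VAE's final NLL is not
  # worse than the AE's beyond tolerance on the same fixture and seed
  d <- rank2_counts(n = 150, J = 20, seed = 34)
  hid <- c(10L, 4L, 10L)
  ae <- fit_embedding(embedding_spec("ae", d$cm$gene_ids, hidden = hid),
                      d$cm, epochs = 60, seed = 34)
  vae0 <- fit_embedding(embedding_spec("vae", d$cm$gene_ids, hidden = hid,
                                       kl_weight = 0),
                        d$cm, epochs = 60, seed = 34)
  nll_ae <- reconstruct_and_score(ae, d$cm)$nb_nll
  nll_vae <- reconstruct_and_score(vae0, d$cm)$nb_nll
  expect_lt(nll_vae, nll_ae + 0.25 * abs(nll_ae))
})

test_that("random projection: clipping contract, finite NLL, loses to a trained model", {
  train <- rank2_counts(n = 300, J = 20, seed = 35)$cm
  test <- rank2_counts(n = 100, J = 20, seed = 351)$cm
  rp <- random_projection_baseline(train, test, latent_dim = 2, seed = 35)
  expect_true(all(rp$reconstruction >= 1e-10))
  expect_true(is.finite(rp$nb_nll))
  expect_true(any(test$counts == 0))  # zeros present, NLL still finite

  expect_error(random_projection_baseline(train, test, latent_dim = 20),
               class = "ontozoo_domain_error")

  wins <- vapply(1:5, function(seed) {
    d <- rank2_counts(n = 250, J = 20, seed = seed + 100)
    tr <- count_matrix(d$cm$counts[1:200, ], gene_ids = d$cm$gene_ids)
    te <- count_matrix(d$cm$counts[201:250, ], gene_ids = d$cm$gene_ids)
    fit <- fit_embedding(embedding_spec("linear", tr$gene_ids, latent_dim = 2),
                         tr, epochs = 250, lr = 3e-3, seed = seed)
    lin <- reconstruct_and_score(fit, te)$nb_nll
    rpb <- random_projection_baseline(tr, te, latent_dim = 2, seed = seed)$nb_nll
    lin < rpb
  }, logical(1))
  expect_true(all(wins))
})

test_that("fit is reproducible under a seed and flags divergence", {
  d <- rank2_counts(n = 60, J = 10, seed = 36)
  spec <- embedding_spec("linear", d$cm$gene_ids, latent_dim = 2)
  f1 <- fit_embedding(spec, d$cm, epochs = 10, seed = 7)
  f2 <- fit_embedding(spec, d$cm, epochs = 10, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_error(fit_embedding(spec, d$cm, epochs = 10, lr = 1e6, seed = 7),
               class = "ontozoo_training_diverged_error")
})

test_that("per-cell-and-gene dispersion mode trains and scores", {
  d <- rank2_counts(n = 100, J = 12, seed = 37)
  spec <- embedding_spec("linear", d$cm$gene_ids, latent_dim = 2,
                         dispersion = "per_cell_gene")
  fit <- fit_embedding(spec, d$cm, epochs = 40, seed = 37)
  sc <- reconstruct_and_score(fit, d$cm)
  expect_true(is.finite(sc$nb_nll))
  z <- embed(fit, d$cm)
  phi <- asNamespace("ontozoo")$reconstruction_phi(fit, z)
  expect_identical(dim(phi), dim(d$cm$counts))
  expect_true(all(phi > 0))
})
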