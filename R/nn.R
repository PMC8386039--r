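# Dense-network internals shared by the classifier and embedding models.
# All gradients are derived analytically and verified against central
# finite differences in the test suite; there is no external autodiff
# backend.

SELU_LAMBDA <- 1.0507009873554804934193349852946
SELU_ALPHA <- 1.6732632423543772848170429916717

selu <- function(x) {
  ifelse(x > 0, SELU_LAMBDA * x, SELU_LAMBDA * SELU_ALPHA * (exp(x) - 1))
}
selu_grad <- function(x) {
  ifelse(x > 0, SELU_LAMBDA, SELU_LAMBDA * SELU_ALPHA * exp(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Lecun-normal initial weights: sd = 1/sqrt(fan_in), the standard pairing
# with selu activations.
lecun_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = 1 / sqrt(fan_in)), fan_in, fan_out)
}

new_dense_layer <- function(fan_in, fan_out, batchnorm = FALSE) {
  l <- list(W = lecun_init(fan_in, fan_out), b = numeric(fan_out))
  if (batchnorm) {
    l$bn <- list(gamma = rep(1, fan_out), beta = numeric(fan_out),
                 rmean = numeric(fan_out), rvar = rep(1, fan_out))
  }
  l
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Forward pass of one dense layer. activation: "selu", "linear".
# Returns activations and the cache needed for the backward pass.
dense_forward <- function(layer, A, activation, training = FALSE) {
  S <- sweep(A %*% layer$W, 2L, layer$b, "+")
  cache <- list(A = A, S = S)
  if (!is.null(layer$bn)) {
    bn <- layer$bn
    if (training) {
      m <- colMeans(S)
      v <- colMeans(sweep(S, 2L, m)^2)
      cache$bn_m <- m; cache$bn_v <- v
    } else {
      m <- bn$rmean; v <- bn$rvar
      cache$bn_m <- m; cache$bn_v <- v
    }
    Shat <- sweep(sweep(S, 2L, m), 2L, sqrt(v + BN_EPS), "/")
    cache$Shat <- Shat
    S <- sweep(sweep(Shat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  }
  cache$pre <- S
  out <- switch(activation, selu = selu(S), linear = S,
                oz_stop("domain_error", "unknown activation '%s'", activation))
  cache$out <- out
  cache
}

# Backward pass matching dense_forward. dOut is the gradient at the layer
# output; returns grads for W, b (and bn) plus dA for the layer input.
dense_backward <- function(layer, cache, dOut, activation, training = TRUE) {
  dPre <- switch(activation,
                 selu = dOut * selu_grad(cache$pre),
                 linear = dOut)
  g <- list()
  if (!is.null(layer$bn)) {
    n <- nrow(dPre)
    g$bn_gamma <- colSums(dPre * cache$Shat)
    g$bn_beta <- colSums(dPre)
    dShat <- sweep(dPre, 2L, layer$bn$gamma, "*")
    inv_sd <- 1 / sqrt(cache$bn_v + BN_EPS)
    if (training) {
      dS <- sweep(
        dShat - matrix(colMeans(dShat), n, ncol(dShat), byrow = TRUE) -
          cache$Shat * matrix(colMeans(dShat * cache$Shat), n, ncol(dShat), byrow = TRUE),
        2L, inv_sd, "*")
    } else {
      dS <- sweep(dShat, 2L, inv_sd, "*")
    }
  } else {
    dS <- dPre
  }
  g$W <- crossprod(cache$A, dS)
  g$b <- colSums(dS)
  g$dA <- dS %*% t(layer$W)
  g
}

update_bn_running <- function(layer, cache) {
  if (is.null(layer$bn)) return(layer)
  layer$bn$rmean <- BN_MOMENTUM * layer$bn$rmean + (1 - BN_MOMENTUM) * cache$bn_m
  layer$bn$rvar <- BN_MOMENTUM * layer$bn$rvar + (1 - BN_MOMENTUM) * cache$bn_v
  layer
}

# --- Adam over a flat named list of arrays -------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Minibatch index generator: shuffled, last batch may be short.
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

check_finite_loss <- function(loss, epoch) {
  if (!is.finite(loss)) {
    oz_stop("training_diverged_error",
            "non-finite training loss at epoch %d", epoch)
  }
}

# --- nested <-> flat parameter lists -------------------------------------
# Trainable arrays are addressed by dotted paths ("layers.1.W"); batchnorm
# running statistics (rmean/rvar) are tracked outside the optimizer.

flatten_params <- function(x, prefix = "") {
  out <- list()
  nms <- names(x) %||% as.character(seq_along(x))
  for (i in seq_along(x)) {
    nm <- nms[i]
    if (nm %in% c("rmean", "rvar")) next
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(x[[i]])) out <- c(out, flatten_params(x[[i]], key))
    else if (is.numeric(x[[i]])) out[[key]] <- x[[i]]
  }
  out
}

unflatten_params <- function(flat, template, prefix = "") {
  nms <- names(template) %||% as.character(seq_along(template))
  for (i in seq_along(template)) {
    nm <- nms[i]
    if (nm %in% c("rmean", "rvar")) next
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(template[[i]])) {
      template[[i]] <- unflatten_params(flat, template[[i]], key)
    } else if (is.numeric(template[[i]]) && !is.null(flat[[key]])) {
      template[[i]] <- flat[[key]]
    }
  }
  template
}
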