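#' Specify a cell-type classifier
#'
#' Three model kinds share a softmax output over the label-space leaves and
#' are trained with the aggregated cross-entropy ([cce_agg()]):
#' \describe{
#'   \item{linear}{multinomial logistic regression on the transformed
#'     expression values}
#'   \item{mlp}{a dense feed-forward network with selu activations (default
#'     one hidden layer of 128 units)}
#'   \item{marker}{a marker-gene model: each gene is first squashed through
#'     its own sigmoid `sigmoid(a_j x_j + b_j)`, modelling an on/off
#'     expression threshold, and a dense pooling layer combines the
#'     per-gene marker states into class logits}
#' }
#'
#' @param kind `"linear"`, `"mlp"` or `"marker"`
#' @param input_genes ordered character vector of gene ids the model consumes
#' @param label_space a [build_label_space()] result; the output classes are
#'   its leaves
#' @param hidden integer vector of hidden-layer sizes (mlp only; default 128)
#' @param l1,l2 penalty weights on dense weights (default 0)
#' @param marker_prior optional list `(a, b, weight)` penalising the marker
#'   stage's slopes/offsets toward prior means (L2-toward-prior); `NULL`
#'   (default) disables it
#' @return a `classifier_spec`
#' @seealso [fit_classifier()]
#' @export
classifier_spec <- function(kind = c("linear", "mlp", "marker"),
                            input_genes, label_space,
                            hidden = if (kind == "mlp") 128L else integer(),
                            l1 = 0, l2 = 0, marker_prior = NULL) {
  kind <- match.arg(kind)
  if (kind != "mlp") hidden <- integer()
  stopifnot(inherits(label_space, "label_space"), length(input_genes) > 0)
  structure(
    list(kind = kind, hidden = as.integer(hidden), activation = "selu",
         l1 = l1, l2 = l2, input_genes = as.character(input_genes),
         label_space = label_space, marker_prior = marker_prior),
    class = "classifier_spec"
  )
}

check_feature_space <- function(input_genes, gene_ids) {
  if (is.null(gene_ids)) {
    return(invisible(TRUE))
  }
  if (length(gene_ids) != length(input_genes)) {
    oz_stop("feature_space_error", "data has %d genes, model expects %d",
            length(gene_ids), length(input_genes))
  }
  bad <- which(gene_ids != input_genes)
  if (length(bad)) {
    oz_stop("feature_space_error",
            "gene space mismatch at position %d (model expects '%s', data has '%s')",
            bad[1L], input_genes[bad[1L]], gene_ids[bad[1L]])
  }
  invisible(TRUE)
}

as_feature_matrix <- function(x, input_genes) {
  if (inherits(x, "transformed_matrix")) {
    check_feature_space(input_genes, x$gene_ids)
    x$values
  } else {
    x <- as.matrix(x)
    if (!is.null(colnames(x))) {
      check_feature_space(input_genes, colnames(x))
    } else if (ncol(x) != length(input_genes)) {
      oz_stop("feature_space_error", "data has %d genes, model expects %d",
              ncol(x), length(input_genes))
    }
    x
  }
}

init_classifier_params <- function(spec) {
  J <- length(spec$input_genes)
  K <- length(spec$label_space$leaves)
  if (spec$kind == "marker") {
    list(a = rep(1, J), b = numeric(J), pool = new_dense_layer(J, K))
  } else {
    sizes <- c(J, spec$hidden, K)
    list(layers = lapply(seq_len(length(sizes) - 1L), function(i) {
      new_dense_layer(sizes[i], sizes[i + 1L])
    }))
  }
}

classifier_forward <- function(spec, params, X) {
  if (spec$kind == "marker") {
    pre <- sweep(sweep(X, 2L, params$a, "*"), 2L, params$b, "+")
    H <- sigmoid(pre)
    pool <- dense_forward(params$pool, H, "linear")
    list(p = softmax(pool$out), logits = pool$out,
         caches = list(X = X, H = H, pool = pool))
  } else {
    A <- X
    n_l <- length(params$layers)
    caches <- vector("list", n_l)
    for (i in seq_len(n_l)) {
      act <- if (i < n_l) spec$activation else "linear"
      caches[[i]] <- dense_forward(params$layers[[i]], A, act)
      A <- caches[[i]]$out
    }
    list(p = softmax(A), logits = A, caches = caches)
  }
}

# Gradient of the mean aggregated CE w.r.t. the logits:
# d/dlogit_nj [-log s_n] = p_nj - y_nj p_nj / s_n, with s_n = sum_k y_nk p_nk.
cce_agg_grad_logits <- function(p, y, eps = 1e-12) {
  s <- pmax(rowSums(p * y), eps)
  (p - (y * p) / s) / nrow(p)
}

classifier_grads <- function(spec, params, fw, dlogits) {
  g <- list()
  pen <- function(W) spec$l2 * W + spec$l1 * sign(W)
  if (spec$kind == "marker") {
    bp <- dense_backward(params$pool, fw$caches$pool, dlogits, "linear")
    g[["pool.W"]] <- bp$W + pen(params$pool$W)
    g[["pool.b"]] <- bp$b
    H <- fw$caches$H
    dpre <- bp$dA * H * (1 - H)
    g[["a"]] <- colSums(dpre * fw$caches$X)
    g[["b"]] <- colSums(dpre)
    if (!is.null(spec$marker_prior)) {
      w <- spec$marker_prior$weight %||% 0
      g[["a"]] <- g[["a"]] + w * (params$a - (spec$marker_prior$a %||% 0))
      g[["b"]] <- g[["b"]] + w * (params$b - (spec$marker_prior$b %||% 0))
    }
  } else {
    dA <- dlogits
    n_l <- length(params$layers)
    for (i in rev(seq_len(n_l))) {
      act <- if (i < n_l) spec$activation else "linear"
      bp <- dense_backward(params$layers[[i]], fw$caches[[i]], dA, act)
      g[[sprintf("layers.%d.W", i)]] <- bp$W + pen(params$layers[[i]]$W)
      g[[sprintf("layers.%d.b", i)]] <- bp$b
      dA <- bp$dA
    }
  }
  g
}

#' Fit a cell-type classifier with the aggregated cross-entropy
#'
#' Trains the model of a [classifier_spec()] by minibatch gradient descent
#' with adaptive moments (Adam, step `1e-3`, batch 128 by default) on the
#' aggregated cross-entropy, so cells may carry coarse (internal-node)
#' labels. A validation fraction (default 0.1, stratified by dataset when
#' `datasets` is supplied) is split off for per-epoch monitoring of
#' [cce_agg()] and [acc_agg()]. All randomness (initial weights, shuffles,
#' validation split) is governed by `seed`.
#'
#' @param spec a [classifier_spec()]
#' @param x a [transform_counts()] result (or plain matrix in the spec's
#'   gene space)
#' @param labels per-cell ontology term ids (character) or a
#'   [map_labels()] result
#' @param epochs training epochs; `0` returns the initialisation unchanged
#' @param lr Adam step size
#' @param batch_size minibatch size
#' @param validation_fraction share of cells monitored, not trained on
#' @param datasets optional per-cell dataset ids for stratified validation
#' @param seed integer seed
#' @return an `ontozoo_classifier`: list with `spec`, `params`, `history`
#'   (data.frame epoch/train_cce/val_cce/val_acc) and `seed`
#' @examples
#' sim <- simulate_corpus(sim_spec(n_datasets = 1, cells_per_dataset = 300,
#'                                 n_genes = 30, seed = 1))
#' xt <- transform_counts(sim$matrices[[1]])
#' spc <- classifier_spec("linear", xt$gene_ids, sim$label_space)
#' fit <- fit_classifier(spc, xt, sim$matrices[[1]]$labels, epochs = 50, seed = 1)
#' head(predict(fit, xt))
#' @export
fit_classifier <- function(spec, x, labels, epochs = 100L, lr = 1e-3,
                           batch_size = 128L, validation_fraction = 0.1,
                           datasets = NULL, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_feature_matrix(x, spec$input_genes)
  lm <- if (inherits(labels, "label_matrix")) labels
        else map_labels(labels, spec$label_space)
  Y <- lm$y
  if (nrow(Y) != nrow(X)) oz_stop("domain_error", "labels and data disagree in cell count")

  set.seed(seed)
  params <- init_classifier_params(spec)
  n <- nrow(X)
  val_idx <- pick_validation(n, validation_fraction, datasets)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) oz_stop("domain_error", "no training cells left")
  flat <- flatten_params(params)
  state <- adam_init(flat)
  history <- data.frame(epoch = integer(), train_cce = numeric(),
                        val_cce = numeric(), val_acc = numeric())
  if (epochs > 0L) {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      for (batch in minibatches(length(tr_idx), batch_size)) {
        idx <- tr_idx[batch]
        fw <- classifier_forward(spec, params, X[idx, , drop = FALSE])
        loss <- cce_agg(fw$p, Y[idx, , drop = FALSE])
        check_finite_loss(loss, ep)
        g <- classifier_grads(spec, params, fw,
                              cce_agg_grad_logits(fw$p, Y[idx, , drop = FALSE]))
        upd <- adam_step(flat, g, state, lr = lr)
        flat <- upd$params; state <- upd$state
        params <- unflatten_params(flat, params)
        ep_loss <- ep_loss + loss * length(idx)
      }
      if (length(val_idx)) {
        pv <- classifier_forward(spec, params, X[val_idx, , drop = FALSE])$p
        yv <- Y[val_idx, , drop = FALSE]
        history[ep, ] <- list(ep, ep_loss / length(tr_idx), cce_agg(pv, yv),
                              acc_agg(pv, yv))
      } else {
        history[ep, ] <- list(ep, ep_loss / length(tr_idx), NA_real_, NA_real_)
      }
    }
  }
  structure(
    list(spec = spec, params = params, history = history, seed = seed),
    class = "ontozoo_classifier"
  )
}

pick_validation <- function(n, fraction, datasets = NULL) {
  if (fraction <= 0) return(integer())
  if (is.null(datasets)) {
    sample.int(n, size = max(1L, round(fraction * n)))
  } else {
    unlist(lapply(split(seq_len(n), datasets), function(ix) {
      sample(ix, size = max(1L, round(fraction * length(ix))))
    }), use.names = FALSE)
  }
}

#' Predict class probabilities over the label-space leaves
#'
#' @param object an [fit_classifier()] result
#' @param newdata a [transform_counts()] result or matrix in the model's
#'   gene space
#' @param ... unused
#' @return cells x leaves probability matrix (rows sum to 1)
#' @export
predict.ontozoo_classifier <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$spec$input_genes)
  p <- classifier_forward(object$spec, object$params, X)$p
  colnames(p) <- object$spec$label_space$leaves
  if (inherits(newdata, "transformed_matrix")) rownames(p) <- newdata$cell_ids
  p
}

#' @export
print.ontozoo_classifier <- function(x, ...) {
  cat(sprintf("<ontozoo_classifier> kind=%s, %d genes -> %d leaves\n",
              x$spec$kind, length(x$spec$input_genes),
              length(x$spec$label_space$leaves)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final val cce_agg %.4f, acc_agg %.4f\n",
                last$epoch, last$val_cce, last$val_acc))
  } else {
    cat("  untrained (initialisation only)\n")
  }
  invisible(x)
}

#' @export
coef.ontozoo_classifier <- function(object, ...) {
  if (object$spec$kind == "linear") {
    W <- object$params$layers[[1L]]$W
    dimnames(W) <- list(object$spec$input_genes, object$spec$label_space$leaves)
    list(weights = W, bias = stats::setNames(object$params$layers[[1L]]$b,
                                             object$spec$label_space$leaves))
  } else {
    object$params
  }
}

#' Evaluate a classifier on labelled cells
#'
#' Aggregated metrics ([cce_agg()], [acc_agg()]) are computed on all cells;
#' per-leaf F1 scores are computed from an argmax confusion matrix on the
#' subset of cells whose label is itself a leaf (coarse-labelled cells have
#' no single true leaf and are excluded from F1).
#'
#' @param object an `ontozoo_classifier`
#' @param x test expression ([transform_counts()] result or matrix)
#' @param labels per-cell term ids or a [map_labels()] result
#' @return list with `acc_agg`, `cce_agg`, `f1` (named per-leaf vector,
#'   `NaN` for leaves absent from both truth and prediction) and
#'   `n_cells` / `n_leaf_labelled`
#' @export
evaluate_classifier <- function(object, x, labels) {
  lm <- if (inherits(labels, "label_matrix")) labels
        else map_labels(labels, object$spec$label_space)
  if (nrow(lm$y) == 0L) oz_stop("empty_eval_error", "empty test set")
  p <- predict(object, x)
  leaves <- object$spec$label_space$leaves
  out <- list(acc_agg = acc_agg(p, lm), cce_agg = cce_agg(p, lm),
              n_cells = nrow(lm$y))
  src <- lm$source_terms %||% ifelse(rowSums(lm$y) == 1L,
                                     leaves[max.col(lm$y)], NA_character_)
  leafcells <- which(src %in% leaves)
  out$n_leaf_labelled <- length(leafcells)
  f1 <- stats::setNames(rep(NaN, length(leaves)), leaves)
  if (length(leafcells)) {
    truth <- factor(src[leafcells], levels = leaves)
    pred <- factor(leaves[max.col(p[leafcells, , drop = FALSE])], levels = leaves)
    cm <- table(truth, pred)
    tp <- diag(cm)
    prec <- tp / pmax(colSums(cm), 0)
    rec <- tp / pmax(rowSums(cm), 0)
    f1 <- 2 * prec * rec / (prec + rec)
    f1[is.na(f1) & (rowSums(cm) + colSums(cm)) > 0] <- 0
  }
  out$f1 <- f1
  out
}
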