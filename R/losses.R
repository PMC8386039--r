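#' Negative-binomial negative log-likelihood
#'
#' Reconstruction loss of the embedding models. For counts `x`, mean `mu`
#' and dispersion `phi` the per-entry log-likelihood is
#' \deqn{\log\Gamma(x+\varphi) - \log\Gamma(x+1) - \log\Gamma(\varphi)
#'   + x(\log\mu - \log(\mu+\varphi))
#'   + \varphi(\log\varphi - \log(\mu+\varphi)),}
#' the standard NB parameterisation with variance
#' \eqn{\mu + \mu^2/\varphi}; as \eqn{\varphi \to \infty} it approaches the
#' Poisson log-likelihood at `mu`. Two dispersion modes are supported: a
#' per-gene vector (recycled across cells) or a full cells x genes matrix
#' (one dispersion per cell and gene).
#'
#' @param x cells x genes matrix of non-negative counts
#' @param mu positive means, same shape as `x`
#' @param phi positive dispersions: length-`ncol(x)` vector or matrix
#'   shaped like `x`
#' @param eps lower clip applied inside logarithms (numerical guard)
#' @return list with `total` (summed NLL), `per_cell` (vector of per-cell
#'   sums) and `mean_per_entry` (total / number of entries)
#' @examples
#' nb_nll(matrix(0), matrix(1), 1)$total  # log 2: P(0) = 0.5 at mu = phi = 1
#' @export
nb_nll <- function(x, mu, phi, eps = 1e-12) {
  x <- as.matrix(x); mu <- as.matrix(mu)
  if (!all(dim(x) == dim(mu))) oz_stop("domain_error", "x and mu shapes differ")
  if (any(mu <= 0)) oz_stop("domain_error", "mu must be positive")
  if (any(phi <= 0)) oz_stop("domain_error", "phi must be positive")
  if (is.matrix(phi)) {
    if (!all(dim(phi) == dim(x))) {
      oz_stop("domain_error", "matrix phi must match the shape of x")
    }
  } else if (length(phi) == 1L) {
    phi <- matrix(phi, nrow(x), ncol(x))
  } else if (length(phi) == ncol(x)) {
    phi <- matrix(phi, nrow(x), ncol(x), byrow = TRUE)
  } else {
    oz_stop("domain_error", "phi must be scalar, per-gene, or per-cell-and-gene")
  }
  mu <- pmax(mu, eps)
  ll <- lgamma(x + phi) - lgamma(x + 1) - lgamma(phi) +
    x * (log(mu) - log(mu + phi)) +
    phi * (log(phi) - log(mu + phi))
  list(total = -sum(ll),
       per_cell = -rowSums(ll),
       mean_per_entry = -sum(ll) / length(ll))
}

# Gradient of the summed NB NLL w.r.t. eta (mu = exp(eta) * sf, sf constant)
# and w.r.t. rho (phi = exp(rho)). Shapes follow x.
nb_nll_grad_eta <- function(x, mu, phi) {
  mu * (x + phi) / (mu + phi) - x
}
nb_nll_grad_rho <- function(x, mu, phi) {
  dll_dphi <- digamma(x + phi) - digamma(phi) +
    log(phi) + 1 - log(mu + phi) - (x + phi) / (mu + phi)
  -dll_dphi * phi
}

#' Map ontology labels onto a label space
#'
#' Converts per-cell ontology term ids into a binary cells x leaves
#' indicator matrix: entry (n, k) is 1 iff leaf k is in the positive leaf
#' set K+ of cell n's label. A leaf-labelled cell yields a one-hot row; a
#' coarse label (internal ontology term) yields a multi-hot row over its
#' descendant leaves, which is what lets the aggregated loss consume
#' datasets annotated at different granularities.
#'
#' @param source_terms character vector of per-cell term ids
#' @param label_space a [build_label_space()] result
#' @return a `label_matrix`: list with `y` (binary matrix, columns named by
#'   leaf) and `source_terms`
#' @export
map_labels <- function(source_terms, label_space) {
  source_terms <- as.character(source_terms)
  leaves <- label_space$leaves
  y <- matrix(0, length(source_terms), length(leaves),
              dimnames = list(NULL, leaves))
  for (term in unique(source_terms)) {
    ps <- positive_set(label_space, term)
    y[source_terms == term, match(ps, leaves)] <- 1
  }
  structure(list(y = y, source_terms = source_terms), class = "label_matrix")
}

as_label_matrix <- function(y) {
  if (inherits(y, "label_matrix")) return(y)
  y <- as.matrix(y)
  if (any(rowSums(y) < 1)) {
    oz_stop("unmappable_label_error", "label matrix has an all-zero row")
  }
  structure(list(y = y, source_terms = NULL), class = "label_matrix")
}

check_probs <- function(p, y) {
  p <- as.matrix(p)
  if (!all(dim(p) == dim(y))) {
    oz_stop("domain_error", "probability and label matrices have different shapes")
  }
  p
}

#' Aggregated cross-entropy
#'
#' Cross-entropy on the predicted probability mass summed over the positive
#' leaf set K+ of each cell's label:
#' \deqn{-\sum_n \log \sum_{k \in K^+_n} p_{nk}.}
#' When every row of `y` is one-hot this is exactly the multi-class
#' cross-entropy; with coarse (multi-hot) rows, any distribution of mass
#' among the leaves below the coarse term is accepted, so coarsely
#' annotated datasets still constrain the boundary between K+ and the rest.
#'
#' @param p cells x leaves probability matrix (rows on the simplex)
#' @param y a `label_matrix` from [map_labels()] or a binary matrix
#' @param reduction `"mean"` (default, per-cell average) or `"sum"`
#' @param eps lower clip on the aggregated mass before the log
#' @return scalar loss
#' @examples
#' p <- matrix(c(.3, .5, .2), 1)
#' y <- matrix(c(1, 1, 0), 1)   # coarse label covering leaves 1 and 2
#' cce_agg(p, y)                # -log(0.8)
#' @export
cce_agg <- function(p, y, reduction = c("mean", "sum"), eps = 1e-12) {
  reduction <- match.arg(reduction)
  y <- as_label_matrix(y)$y
  p <- check_probs(p, y)
  mass <- rowSums(p * y)
  loss <- -sum(log(pmax(mass, eps)))
  if (reduction == "mean") loss / nrow(y) else loss
}

#' Aggregated accuracy
#'
#' The fraction of cells whose probability mass aggregated over the
#' positive leaf set K+ strictly exceeds the largest single-leaf
#' probability in the complement K-. Ties count as incorrect. A cell whose
#' label covers every leaf (K- empty, e.g. the subgraph root) counts as
#' correct.
#'
#' @inheritParams cce_agg
#' @return scalar in `[0, 1]`
#' @export
acc_agg <- function(p, y) {
  y <- as_label_matrix(y)$y
  p <- check_probs(p, y)
  mass <- rowSums(p * y)
  neg <- p
  neg[y == 1] <- -Inf
  best_neg <- apply(neg, 1L, max)            # -Inf when K- is empty
  mean(mass > best_neg)
}
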