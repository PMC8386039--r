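#' Cell-type-wise gradient map of an embedding
#'
#' Computes, for every cell, the Jacobian of the latent (bottleneck)
#' activations with respect to the input features, aggregates it over the
#' latent dimensions (sum of absolute partial derivatives by default, or
#' the L2 norm), averages within each cell type, and normalises each
#' cell-type row to maximum 1. For a linear encoder the Jacobian is
#' input-independent, so the map is the same function of the encoder weight
#' matrix for every cell type — the analogue of inspecting PCA loadings.
#'
#' @param object a differentiable [fit_embedding()] result (`linear`,
#'   `ae` or `vae`; the random projection and NMF have no encoder
#'   Jacobian and are rejected)
#' @param data cells ([count_matrix()], [transform_counts()] result or
#'   matrix of transformed values)
#' @param labels per-cell cell-type labels (character)
#' @param aggregate `"sum_abs"` (default) or `"l2"` aggregation over latent
#'   dimensions
#' @param normalize divide each cell-type row by its maximum (default)
#' @return a `gradient_map`: list with `g` (cell types x genes, normalised),
#'   `raw` (before row normalisation), `aggregate`, `cell_types`, `genes`
#' @seealso [gradient_correlation()]
#' @export
gradient_map <- function(object, data, labels,
                         aggregate = c("sum_abs", "l2"), normalize = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(object, "ontozoo_embedding"))
  if (object$spec$kind %in% c("random_projection", "nmf")) {
    oz_stop("unsupported_model_error",
            "gradient maps require a differentiable encoder; kind '%s' has none",
            object$spec$kind)
  }
  Xt <- as_transformed_values(data, object$spec$input_genes)
  labels <- as.character(labels)
  if (length(labels) != nrow(Xt)) {
    oz_stop("domain_error", "labels and data disagree in cell count")
  }
  genes <- object$spec$input_genes
  types <- sort(unique(labels))
  agg_fun <- if (aggregate == "sum_abs") {
    function(Jc) rowSums(abs(Jc))
  } else {
    function(Jc) sqrt(rowSums(Jc^2))
  }
  if (object$spec$kind == "linear") {
    # Jacobian is the encoder weight matrix for every input
    Jc <- encoder_jacobian(object, Xt[1L, , drop = FALSE])
    row <- agg_fun(Jc)
    raw <- matrix(row, length(types), length(genes), byrow = TRUE,
                  dimnames = list(types, genes))
  } else {
    per_cell <- matrix(0, nrow(Xt), length(genes))
    for (i in seq_len(nrow(Xt))) {
      per_cell[i, ] <- agg_fun(encoder_jacobian(object, Xt[i, , drop = FALSE]))
    }
    raw <- do.call(rbind, lapply(types, function(ct) {
      colMeans(per_cell[labels == ct, , drop = FALSE])
    }))
    dimnames(raw) <- list(types, genes)
  }
  g <- raw
  if (normalize) {
    mx <- apply(raw, 1L, max)
    ok <- mx > 0
    g[ok, ] <- raw[ok, , drop = FALSE] / mx[ok]
  }
  structure(list(g = g, raw = raw, aggregate = aggregate,
                 cell_types = types, genes = genes, normalized = normalize),
            class = "gradient_map")
}

# Jacobian dz/dx (genes x latent) of the encoder at one cell, evaluated in
# inference mode (batchnorm uses running statistics, so each layer
# contributes an affine per-unit scale).
encoder_jacobian <- function(object, x_row) {
  params <- object$params
  spec <- object$spec
  M <- diag(length(spec$input_genes))
  A <- x_row
  propagate <- function(M, layer, A) {
    cache <- dense_forward(layer, A, layer$act %||% "linear", training = FALSE)
    factor <- rep(1, ncol(layer$W))
    if (!is.null(layer$bn)) factor <- layer$bn$gamma / sqrt(layer$bn$rvar + BN_EPS)
    if ((layer$act %||% "linear") == "selu") {
      factor <- factor * as.numeric(selu_grad(cache$pre))
    }
    list(M = M %*% sweep(layer$W, 2L, factor, "*"), A = cache$out)
  }
  for (layer in params$enc) {
    st <- propagate(M, layer, A)
    M <- st$M; A <- st$A
  }
  if (spec$kind == "vae") {
    st <- propagate(M, params$mu_head, A)
    M <- st$M
  }
  M
}

#' @export
print.gradient_map <- function(x, ...) {
  cat(sprintf("<gradient_map> %d cell types x %d genes (%s aggregation%s)\n",
              length(x$cell_types), length(x$genes), x$aggregate,
              if (x$normalized) ", row-normalised" else ""))
  invisible(x)
}

#' Correlation and hierarchical clustering of a gradient map
#'
#' Pearson correlation across genes between the cell-type rows of a
#' gradient map, followed by average-linkage hierarchical clustering on the
#' correlation distance `1 - r`. Similar cell types (similar feature sets
#' driving their embedding) cluster together.
#'
#' @param map a [gradient_map()]
#' @return list with `correlation` (cell types x cell types), `order`
#'   (dendrogram leaf order, character), and `hclust`
#' @export
gradient_correlation <- function(map) {
  stopifnot(inherits(map, "gradient_map"))
  m <- map$g
  if (nrow(m) < 2L) {
    oz_stop("domain_error", "need at least 2 cell types to correlate")
  }
  r <- stats::cor(t(m))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(correlation = r, order = rownames(r)[hc$order], hclust = hc)
}

#' Heatmap of a gradient correlation matrix
#'
#' @param x a [gradient_map()]
#' @param ... passed to the heatmap backend
#' @return invisibly, the [gradient_correlation()] result
#' @export
plot.gradient_map <- function(x, ...) {
  gc <- gradient_correlation(x)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(gc$correlation, clustering_method = "average", ...)
  } else {
    stats::heatmap(gc$correlation, ...)
  }
  invisible(gc)
}

#' Write a gradient map and its correlation matrix as TSV
#'
#' @param map a [gradient_map()]
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_gradient_map <- function(map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "gradient_map.tsv")
  utils::write.table(map$g, p1, sep = "\t", quote = FALSE, col.names = NA)
  p2 <- file.path(dir, "gradient_correlation.tsv")
  utils::write.table(gradient_correlation(map)$correlation, p2, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(c(p1, p2))
}
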