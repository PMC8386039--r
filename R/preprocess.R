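#' Per-cell size-factor scaling and log transform
#'
#' The common input transform prepended to every model: each cell's counts
#' are linearly scaled so the cell totals 10,000, then log-transformed. The
#' transform of a cell depends only on that cell, so it is independent of
#' batch composition and can be applied to any subset of the data.
#'
#' Zeros dominate single-cell count matrices and `log(0)` is `-Inf`, so the
#' default applies `log1p` to the scaled value. `strict = TRUE` instead
#' evaluates the plain `log(x / total * 1e4)` with zero counts mapped to 0
#' by convention, for auditing against the plain-log definition.
#'
#' @param counts a [count_matrix()] or a cells x genes numeric matrix of
#'   non-negative counts
#' @param scale_factor per-cell target total (default `1e4`)
#' @param strict use plain `log` with zeros mapped to 0 instead of `log1p`
#' @return a `transformed_matrix`: list with `values` (cells x genes),
#'   `scale_factor`, `log_base` (`"natural"`), `strict`, `cell_ids`,
#'   `gene_ids`
#' @examples
#' m <- matrix(c(1, 9999, 5000, 5000), nrow = 2, byrow = TRUE)
#' transform_counts(m)$values
#' @export
transform_counts <- function(counts, scale_factor = 1e4, strict = FALSE) {
  cm <- as_count_matrix(counts)
  x <- cm$counts
  totals <- rowSums(x)
  if (any(totals <= 0)) {
    bad <- cm$cell_ids[totals <= 0]
    oz_stop("zero_library_error", "cells with zero total count: %s",
            paste(utils::head(bad, 5L), collapse = ", "))
  }
  scaled <- x / totals * scale_factor
  values <- if (strict) {
    v <- log(scaled)
    v[x == 0] <- 0
    v
  } else {
    log1p(scaled)
  }
  dimnames(values) <- list(cm$cell_ids, cm$gene_ids)
  structure(
    list(values = values, scale_factor = scale_factor, log_base = "natural",
         strict = strict, cell_ids = cm$cell_ids, gene_ids = cm$gene_ids),
    class = "transformed_matrix"
  )
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("<transformed_matrix> %d cells x %d genes (scale %g, %s log%s)\n",
              nrow(x$values), ncol(x$values), x$scale_factor, x$log_base,
              if (x$strict) ", strict" else ", log1p"))
  invisible(x)
}

# Per-cell size factors: total counts / scale_factor. Decoded means are
# per-scale_factor rates; multiplying by the size factor puts them back on
# the observed count scale for the NB likelihood.
size_factors <- function(counts, scale_factor = 1e4) {
  rowSums(counts) / scale_factor
}
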