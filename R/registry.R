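#' Cell x gene count matrix container
#'
#' @param counts cells x genes matrix of non-negative integers (dense or
#'   `Matrix` sparse; stored dense)
#' @param cell_ids unique per-cell ids (default from rownames or generated)
#' @param gene_ids unique gene ids (default from colnames or generated)
#' @param labels optional per-cell ontology term ids
#' @param feature_space list with `assembly` and `subset` tags describing
#'   the gene space (the assembly name is carried as metadata only)
#' @return a `count_matrix`
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         labels = NULL,
                         feature_space = list(assembly = "unspecified",
                                              subset = "all")) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) oz_stop("domain_error", "counts must be non-negative")
  cell_ids <- as.character(cell_ids %||% rownames(counts) %||%
                             sprintf("cell_%d", seq_len(nrow(counts))))
  gene_ids <- as.character(gene_ids %||% colnames(counts) %||%
                             sprintf("gene_%d", seq_len(ncol(counts))))
  if (anyDuplicated(cell_ids)) oz_stop("schema_error", "duplicate cell ids")
  if (anyDuplicated(gene_ids)) oz_stop("schema_error", "duplicate gene ids")
  stopifnot(length(cell_ids) == nrow(counts), length(gene_ids) == ncol(counts))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == nrow(counts))
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 labels = labels, feature_space = feature_space),
            class = "count_matrix")
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes (%s/%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              x$feature_space$assembly, x$feature_space$subset,
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

#' Dataset metadata card
#'
#' An ontology-constrained metadata record with a lazy handle to its count
#' matrix: the matrix is only read when [load_matrix()] is called.
#'
#' @param dataset_id unique dataset id
#' @param organism organism name (e.g. `"mouse"`)
#' @param organ anatomy term id; validated against `anatomy` when supplied
#' @param assay assay name (e.g. `"10x"`)
#' @param disease disease state (default `"healthy"`)
#' @param n_cells declared number of cells; checked against the matrix on
#'   load
#' @param matrix_handle a `count_matrix` held inline, a directory written
#'   by [write_count_matrix()], an `.h5` file, or a zero-argument function
#' @param feature_space list with `assembly` and `subset`
#' @param anatomy optional [onto_dag()] to validate `organ` against
#' @return a `dataset_card`
#' @export
dataset_card <- function(dataset_id, organism, organ, assay,
                         disease = "healthy", n_cells = NA_integer_,
                         matrix_handle = NULL,
                         feature_space = list(assembly = "unspecified",
                                              subset = "all"),
                         anatomy = NULL) {
  if (!is.null(anatomy)) check_term(anatomy, organ)
  structure(list(dataset_id = dataset_id, organism = organism, organ = organ,
                 assay = assay, disease = disease,
                 n_cells = as.integer(n_cells),
                 matrix_handle = matrix_handle, feature_space = feature_space),
            class = "dataset_card")
}

#' @export
print.dataset_card <- function(x, ...) {
  cat(sprintf("<dataset_card> %s: %s %s (%s, %s), %s cells\n",
              x$dataset_id, x$organism, x$organ, x$assay, x$disease,
              ifelse(is.na(x$n_cells), "?", x$n_cells)))
  invisible(x)
}

# Process-wide matrix cache: each card's matrix is read at most once per
# process and can be released on demand.
.matrix_cache <- new.env(parent = emptyenv())

#' Resolve a card's count matrix
#'
#' @param card a [dataset_card()]
#' @return the `count_matrix`
#' @export
load_matrix <- function(card) {
  h <- card$matrix_handle
  key <- if (is.character(h)) normalizePath(h, mustWork = FALSE) else NULL
  if (!is.null(key) && !is.null(.matrix_cache[[key]])) {
    return(.matrix_cache[[key]])
  }
  cm <- if (inherits(h, "count_matrix")) {
    h
  } else if (is.function(h)) {
    as_count_matrix(h())
  } else if (is.character(h) && dir.exists(h)) {
    read_count_matrix(h)
  } else if (is.character(h) && grepl("\\.h5$", h)) {
    read_count_matrix_h5(h)
  } else {
    oz_stop("schema_error", "card '%s' has no resolvable matrix handle",
            card$dataset_id)
  }
  if (!is.na(card$n_cells) && nrow(cm$counts) != card$n_cells) {
    oz_stop("schema_error", "card '%s' declares %d cells but matrix has %d",
            card$dataset_id, card$n_cells, nrow(cm$counts))
  }
  if (!is.null(key)) .matrix_cache[[key]] <- cm
  cm
}

#' @rdname load_matrix
#' @export
release_matrix <- function(card) {
  h <- card$matrix_handle
  if (is.character(h)) {
    key <- normalizePath(h, mustWork = FALSE)
    if (!is.null(.matrix_cache[[key]])) rm(list = key, envir = .matrix_cache)
  }
  invisible(NULL)
}

CARD_KEYS <- c("dataset_id", "organism", "organ", "assay", "disease")

#' Relational subsetting of dataset cards
#'
#' Filters a card collection by metadata equality, with ontology expansion
#' for the `organ` field: when an anatomy DAG is supplied, a query organ
#' matches cards annotated with that term or any of its descendants (so
#' "lung" matches sub-tissues of lung). No matrices are loaded.
#'
#' @param cards list of [dataset_card()]s
#' @param ... named filters over `dataset_id`, `organism`, `organ`,
#'   `assay`, `disease`
#' @param anatomy optional [onto_dag()] enabling ontology expansion of
#'   `organ`
#' @return the matching sublist (possibly empty), in input order
#' @export
subset_cards <- function(cards, ..., anatomy = NULL) {
  query <- list(...)
  unknown <- setdiff(names(query), CARD_KEYS)
  if (length(unknown)) {
    oz_stop("schema_error", "unknown metadata key '%s'", unknown[1L])
  }
  keep <- vapply(cards, function(card) {
    for (key in names(query)) {
      want <- query[[key]]
      have <- card[[key]]
      ok <- if (key == "organ" && !is.null(anatomy)) {
        have %in% descendants(anatomy, want, include_self = TRUE)
      } else {
        have %in% want
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1L))
  cards[keep]
}

# Assemble per-cell rows (dataset, organ, cell_type, one column per gene)
# across a card collection, on the preprocessed or raw scale.
collect_cells <- function(cards, genes, preprocessed = TRUE) {
  out <- lapply(cards, function(card) {
    cm <- load_matrix(card)
    miss <- setdiff(genes, cm$gene_ids)
    if (length(miss)) {
      oz_stop("missing_feature_error", "gene '%s' absent from dataset '%s'",
              miss[1L], card$dataset_id)
    }
    if (is.null(cm$labels)) {
      oz_stop("schema_error", "dataset '%s' has no cell labels", card$dataset_id)
    }
    vals <- if (preprocessed) {
      transform_counts(cm)$values[, genes, drop = FALSE]
    } else {
      cm$counts[, genes, drop = FALSE]
    }
    data.frame(dataset_id = card$dataset_id, organ = card$organ,
               cell_type = cm$labels, vals, check.names = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Grouped summary statistic of a gene's expression
#'
#' Mean (or another statistic) of a gene's preprocessed expression per
#' (organ, cell type) group across a card collection; groups with zero
#' cells are omitted. With `weighting = "dataset"`, per-dataset group means
#' are averaged instead of pooling cells, so large datasets do not dominate.
#'
#' @param cards list of [dataset_card()]s whose matrices carry labels
#' @param gene gene id (must be present in every card's feature space)
#' @param stat summary function (default [mean()])
#' @param preprocessed use [transform_counts()] values (default) or raw
#'   counts
#' @param weighting `"cell"` (pool cells, default) or `"dataset"`
#' @return data.frame with `organ`, `cell_type`, `value`, `n_cells`
#' @export
grouped_gene_stat <- function(cards, gene, stat = mean, preprocessed = TRUE,
                              weighting = c("cell", "dataset")) {
  weighting <- match.arg(weighting)
  df <- collect_cells(cards, gene, preprocessed)
  expr <- df[[gene]]
  if (weighting == "cell") {
    agg <- stats::aggregate(expr, by = list(organ = df$organ,
                                            cell_type = df$cell_type),
                            FUN = stat)
  } else {
    per_ds <- stats::aggregate(expr,
                               by = list(organ = df$organ,
                                         cell_type = df$cell_type,
                                         dataset_id = df$dataset_id),
                               FUN = stat)
    agg <- stats::aggregate(per_ds$x, by = list(organ = per_ds$organ,
                                                cell_type = per_ds$cell_type),
                            FUN = mean)
  }
  n <- stats::aggregate(rep(1L, nrow(df)),
                        by = list(organ = df$organ, cell_type = df$cell_type),
                        FUN = sum)
  out <- merge(agg, n, by = c("organ", "cell_type"),
               suffixes = c("", "_n"))
  names(out) <- c("organ", "cell_type", "value", "n_cells")
  out[order(out$organ, out$cell_type), , drop = FALSE]
}

#' Per-group Pearson correlation between two genes
#'
#' Pearson correlation of the preprocessed expression of two genes within
#' each (dataset, cell type) group. Groups with fewer than 2 cells or zero
#' variance in either gene are reported with a missing correlation and a `reason`, never
#' as a correlation of 0.
#'
#' @param cards list of [dataset_card()]s
#' @param gene_a,gene_b gene ids
#' @param preprocessed use transformed values (default)
#' @return data.frame with `dataset_id`, `organ`, `cell_type`, `r`, `n_cells`,
#'   `reason` (`NA` for valid groups)
#' @export
gene_gene_correlation <- function(cards, gene_a, gene_b, preprocessed = TRUE) {
  df <- collect_cells(cards, unique(c(gene_a, gene_b)), preprocessed)
  groups <- split(df, list(df$dataset_id, df$cell_type), drop = TRUE)
  rows <- lapply(groups, function(g) {
    a <- g[[gene_a]]; b <- g[[gene_b]]
    reason <- NA_character_; r <- NA_real_
    if (nrow(g) < 2L) {
      reason <- "fewer than 2 cells"
    } else if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      reason <- "zero variance"
    } else {
      r <- stats::cor(a, b)
    }
    data.frame(dataset_id = g$dataset_id[1L], organ = g$organ[1L],
               cell_type = g$cell_type[1L], r = r, n_cells = nrow(g),
               reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$dataset_id, out$cell_type), , drop = FALSE]
}

#' Fraction of cells of a type (descendants included) per dataset
#'
#' A cell counts toward the target term if its label is the target or any
#' ontology descendant of it, so querying "lymphocyte" includes cells
#' labelled "T cell".
#'
#' @param cards list of [dataset_card()]s
#' @param target target ontology term id
#' @param dag the cell-type [onto_dag()]
#' @return data.frame with `dataset_id`, `fraction`, `n_cells`
#' @export
cell_type_fraction <- function(cards, target, dag) {
  hits <- descendants(dag, target, include_self = TRUE)
  rows <- lapply(cards, function(card) {
    cm <- load_matrix(card)
    if (is.null(cm$labels)) {
      oz_stop("schema_error", "dataset '%s' has no cell labels", card$dataset_id)
    }
    data.frame(dataset_id = card$dataset_id,
               fraction = mean(cm$labels %in% hits),
               n_cells = length(cm$labels))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Train/test splits
#'
#' Two schemes: `"holdout"` places all cells of one named dataset in the
#' test set (requires at least 2 datasets); `"fraction"` samples
#' `round(fraction * n)` cells (round half away from zero) without
#' replacement under `seed`. Identical inputs reproduce identical splits.
#'
#' @param cards list of [dataset_card()]s
#' @param scheme `"holdout"` or `"fraction"`
#' @param holdout_dataset_id dataset held out (holdout scheme)
#' @param fraction test fraction (default 0.2)
#' @param seed integer seed (fraction scheme)
#' @return a `split` object: lists `train` and `test` of
#'   `(dataset_id, cells)` index vectors, plus `scheme` and `seed`
#' @export
make_split <- function(cards, scheme = c("holdout", "fraction"),
                       holdout_dataset_id = NULL, fraction = 0.2, seed = 1L) {
  scheme <- match.arg(scheme)
  ids <- vapply(cards, `[[`, "", "dataset_id")
  sizes <- vapply(cards, function(c) nrow(load_matrix(c)$counts), 0L)
  names(sizes) <- ids
  if (scheme == "holdout") {
    if (length(cards) < 2L) {
      oz_stop("split_scheme_error",
              "holdout split requires >= 2 datasets; use scheme = 'fraction'")
    }
    if (is.null(holdout_dataset_id) || !holdout_dataset_id %in% ids) {
      oz_stop("split_scheme_error", "holdout dataset '%s' not in collection",
              holdout_dataset_id %||% "<missing>")
    }
    train <- lapply(ids[ids != holdout_dataset_id],
                    function(d) list(dataset_id = d, cells = seq_len(sizes[[d]])))
    test <- list(list(dataset_id = holdout_dataset_id,
                      cells = seq_len(sizes[[holdout_dataset_id]])))
  } else {
    set.seed(seed)
    train <- list(); test <- list()
    for (d in ids) {
      n <- sizes[[d]]
      n_test <- round_half_away(fraction * n)
      idx <- sort(sample.int(n, n_test))
      test[[length(test) + 1L]] <- list(dataset_id = d, cells = idx)
      train[[length(train) + 1L]] <- list(dataset_id = d,
                                          cells = setdiff(seq_len(n), idx))
    }
  }
  structure(list(train = train, test = test, scheme = scheme, seed = seed),
            class = "ontozoo_split")
}

#' @export
print.ontozoo_split <- function(x, ...) {
  n_tr <- sum(vapply(x$train, function(s) length(s$cells), 0L))
  n_te <- sum(vapply(x$test, function(s) length(s$cells), 0L))
  cat(sprintf("<split> scheme=%s: %d train cells, %d test cells (seed %d)\n",
              x$scheme, n_tr, n_te, x$seed))
  invisible(x)
}

# --- on-disk formats ------------------------------------------------------

#' Read and write count matrices
#'
#' The directory layout is MatrixMarket `matrix.mtx` with `cells.tsv` and
#' `genes.tsv` sidecars (one id per line), an optional `labels.tsv`
#' (`cell_id<TAB>term_id`), and a `feature_space.json` tag. The single-file
#' HDF5 layout (`/X` CSR triplet, `/obs/cell_id`, `/obs/label`,
#' `/var/gene_id`) requires the rhdf5 package.
#'
#' @param cm a [count_matrix()]
#' @param dir directory to write to / read from
#' @return `write_count_matrix` returns `dir` invisibly;
#'   `read_count_matrix` returns a `count_matrix`
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(cm$counts), "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(cm$cell_ids, file.path(dir, "cells.tsv"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  if (!is.null(cm$labels)) {
    utils::write.table(data.frame(cell_id = cm$cell_ids, term_id = cm$labels),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cm$feature_space, file.path(dir, "feature_space.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) oz_stop("schema_error", "no matrix.mtx under %s", dir)
  counts <- as.matrix(Matrix::readMM(mtx))
  cell_ids <- readLines(file.path(dir, "cells.tsv"))
  gene_ids <- readLines(file.path(dir, "genes.tsv"))
  labels <- NULL
  lf <- file.path(dir, "labels.tsv")
  if (file.exists(lf)) {
    lt <- utils::read.table(lf, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            quote = "")
    labels <- lt$term_id[match(cell_ids, lt$cell_id)]
  }
  fs <- list(assembly = "unspecified", subset = "all")
  fj <- file.path(dir, "feature_space.json")
  if (file.exists(fj)) fs <- jsonlite::read_json(fj, simplifyVector = TRUE)
  count_matrix(counts, cell_ids, gene_ids, labels, fs)
}

#' @rdname write_count_matrix
#' @param path `.h5` file path
#' @export
write_count_matrix_h5 <- function(cm, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    oz_stop("schema_error", "the rhdf5 package is required for HDF5 I/O")
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  sp <- methods::as(Matrix::Matrix(cm$counts), "RsparseMatrix")  # CSR
  rhdf5::h5createGroup(path, "X")
  rhdf5::h5write(sp@x, path, "X/data")
  rhdf5::h5write(sp@j, path, "X/indices")
  rhdf5::h5write(sp@p, path, "X/indptr")
  rhdf5::h5write(dim(cm$counts), path, "X/shape")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(cm$cell_ids, path, "obs/cell_id")
  if (!is.null(cm$labels)) rhdf5::h5write(cm$labels, path, "obs/label")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(cm$gene_ids, path, "var/gene_id")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    oz_stop("schema_error", "the rhdf5 package is required for HDF5 I/O")
  }
  shape <- rhdf5::h5read(path, "X/shape")
  sp <- methods::new("dgRMatrix",
                     x = as.numeric(rhdf5::h5read(path, "X/data")),
                     j = as.integer(rhdf5::h5read(path, "X/indices")),
                     p = as.integer(rhdf5::h5read(path, "X/indptr")),
                     Dim = as.integer(shape))
  cell_ids <- as.character(rhdf5::h5read(path, "obs/cell_id"))
  gene_ids <- as.character(rhdf5::h5read(path, "var/gene_id"))
  labels <- tryCatch(as.character(rhdf5::h5read(path, "obs/label")),
                     error = function(e) NULL)
  rhdf5::h5closeAll()
  count_matrix(as.matrix(sp), cell_ids, gene_ids, labels)
}

#' Read and write dataset cards as YAML
#'
#' @param card a [dataset_card()]
#' @param path YAML file path
#' @param matrix_dir directory holding the matrix (stored as the card's
#'   handle)
#' @return `write_card` returns `path` invisibly; `read_card` a
#'   `dataset_card`
#' @export
write_card <- function(card, path, matrix_dir = NULL) {
  rec <- card[c("dataset_id", "organism", "organ", "assay", "disease",
                "n_cells", "feature_space")]
  rec$matrix_handle <- matrix_dir %||%
    (if (is.character(card$matrix_handle)) card$matrix_handle else NULL)
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname write_card
#' @param anatomy optional anatomy DAG for organ validation
#' @export
read_card <- function(path, anatomy = NULL) {
  rec <- yaml::read_yaml(path)
  handle <- rec$matrix_handle
  if (!is.null(handle) && !grepl("^(/|[A-Za-z]:)", handle)) {
    handle <- file.path(dirname(path), handle)
  }
  dataset_card(rec$dataset_id, rec$organism, rec$organ, rec$assay,
               rec$disease %||% "healthy", rec$n_cells %||% NA_integer_,
               matrix_handle = handle,
               feature_space = rec$feature_space %||%
                 list(assembly = "unspecified", subset = "all"),
               anatomy = anatomy)
}
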