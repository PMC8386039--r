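# Synthetic fixtures: a toy immune-cell ontology, a toy anatomy DAG, and a
# negative-binomial corpus generator with mixed-granularity labels. These
# make every other module testable fully offline.

toy_immune_edges <- function() {
  rbind(
    c("leukocyte", "cell"),
    c("epithelial cell", "cell"),
    c("stromal cell", "cell"),
    c("lymphocyte", "leukocyte"),
    c("myeloid leukocyte", "leukocyte"),
    c("T cell", "lymphocyte"),
    c("B cell", "lymphocyte"),
    c("natural killer cell", "lymphocyte"),
    c("CD4 T cell", "T cell"),
    c("CD8 T cell", "T cell"),
    c("regulatory T cell", "T cell"),
    c("gamma-delta T cell", "T cell"),
    c("naive B cell", "B cell"),
    c("memory B cell", "B cell"),
    c("plasma cell", "B cell"),
    c("monocyte", "myeloid leukocyte"),
    c("macrophage", "myeloid leukocyte"),
    c("dendritic cell", "myeloid leukocyte"),
    c("neutrophil", "myeloid leukocyte"),
    c("basophil", "myeloid leukocyte"),
    c("eosinophil", "myeloid leukocyte"),
    c("alveolar macrophage", "macrophage"),
    c("inflammatory macrophage", "macrophage"),
    c("classical monocyte", "monocyte"),
    c("non-classical monocyte", "monocyte"),
    c("secretory cell", "epithelial cell"),
    c("ciliated cell", "epithelial cell"),
    c("fibroblast", "stromal cell"),
    c("endothelial cell", "stromal cell")
  )
}

#' Toy ontologies shipped with the package
#'
#' `toy_ontology()` is a 30-term, 4-level immune-centric cell-type DAG;
#' `toy_anatomy()` is a small anatomy DAG used to validate and
#' ontology-expand the `organ` metadata field. Both are constructed in
#' code; the same immune ontology also ships under `inst/extdata` in OBO
#' and edge-list form (see [write_toy_ontology_files()]).
#'
#' @return an [onto_dag()]
#' @export
toy_ontology <- function() {
  onto_dag(toy_immune_edges(), version = "toy-immune-1.0")
}

#' @rdname toy_ontology
#' @export
toy_anatomy <- function() {
  edges <- rbind(
    c("lymphoid organ", "organ"),
    c("spleen", "lymphoid organ"),
    c("thymus", "lymphoid organ"),
    c("bone marrow", "lymphoid organ"),
    c("lung", "organ"),
    c("pancreas", "organ")
  )
  onto_dag(edges, version = "toy-anatomy-1.0")
}

#' Write the toy immune ontology as OBO and edge-list files
#'
#' @param dir output directory
#' @return invisibly, the two file paths
#' @export
write_toy_ontology_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- toy_immune_edges()
  tsv <- file.path(dir, "toy_immune_edges.tsv")
  writeLines(paste(edges[, 1L], edges[, 2L], sep = "\t"), tsv)
  terms <- sort(unique(c(edges)))
  obo_lines <- c("format-version: 1.2", "data-version: toy-immune-1.0", "")
  for (t in terms) {
    parents <- edges[edges[, 1L] == t, 2L]
    obo_lines <- c(obo_lines, "[Term]", paste0("id: ", t), paste0("name: ", t),
                   if (length(parents)) paste0("is_a: ", parents), "")
  }
  obo <- file.path(dir, "toy_immune.obo")
  writeLines(obo_lines, obo)
  invisible(c(tsv, obo))
}

#' Simulation specification
#'
#' Defines a multi-dataset corpus of negative-binomial counts with
#' cell-type-specific mean profiles and mixed-granularity labels. Per-gene
#' baseline means are log-normal draws shared across types; each type
#' additionally upregulates its own block of marker genes `marker_fold`
#' times, so marker-driven classifiers have signal to find. A
#' `coarse_label_fraction` of cells report the ontology parent of their
#' true leaf type (as when a study annotates only "lymphocyte"), while the
#' ground-truth leaf is kept separately for evaluation.
#'
#' @param n_datasets number of datasets (cards)
#' @param cells_per_dataset cells per dataset
#' @param n_genes genes in the shared feature space
#' @param cell_types leaf terms of [toy_ontology()] to simulate
#' @param n_markers marker genes per type
#' @param marker_fold fold-change of a type's markers over baseline
#' @param base_meanlog,base_sdlog log-normal parameters of baseline gene
#'   means
#' @param phi NB dispersion (variance `mu + mu^2/phi`)
#' @param library_size expected total counts per cell
#' @param coarse_label_fraction share of cells labelled at the parent term
#' @param organism,assay metadata written to the cards
#' @param seed integer seed
#' @return a `sim_spec`
#' @export
sim_spec <- function(n_datasets = 3L, cells_per_dataset = 500L, n_genes = 60L,
                     cell_types = c("T cell", "B cell", "natural killer cell",
                                    "macrophage", "monocyte"),
                     n_markers = 3L, marker_fold = 5,
                     base_meanlog = log(1.5), base_sdlog = 0.6,
                     phi = 2, library_size = 2000,
                     coarse_label_fraction = 0.5,
                     organism = "mouse", assay = "10x", seed = 1L) {
  if (n_datasets < 1L || cells_per_dataset < 1L || n_genes < 1L) {
    oz_stop("domain_error", "datasets, cells and genes must all be positive")
  }
  if (coarse_label_fraction < 0 || coarse_label_fraction > 1) {
    oz_stop("domain_error", "coarse_label_fraction must be in [0, 1]")
  }
  if (n_markers * length(cell_types) > n_genes) {
    oz_stop("domain_error", "not enough genes for %d markers per type",
            n_markers)
  }
  if (phi <= 0) oz_stop("domain_error", "phi must be positive")
  structure(
    list(n_datasets = as.integer(n_datasets),
         cells_per_dataset = as.integer(cells_per_dataset),
         n_genes = as.integer(n_genes), cell_types = cell_types,
         n_markers = as.integer(n_markers), marker_fold = marker_fold,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         phi = phi, library_size = library_size,
         coarse_label_fraction = coarse_label_fraction,
         organism = organism, assay = assay, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Simulate a multi-dataset corpus with mixed-granularity labels
#'
#' @param spec a [sim_spec()]
#' @return list with `cards` (dataset cards with inline matrices),
#'   `matrices` (named list of [count_matrix()], labels = observed terms),
#'   `labels` (data.frame: dataset_id, cell_id, observed, truth),
#'   `profiles` (types x genes NB means), `markers` (named list of marker
#'   genes per type), `ontology`, `anatomy`, `label_space` (built from the
#'   observed terms) and `spec`
#' @export
simulate_corpus <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  dag <- toy_ontology()
  anatomy <- toy_anatomy()
  check_term(dag, spec$cell_types)
  set.seed(spec$seed)
  J <- spec$n_genes
  genes <- sprintf("gene_%03d", seq_len(J))
  types <- spec$cell_types
  baseline <- stats::rlnorm(J, spec$base_meanlog, spec$base_sdlog)
  markers <- list()
  profiles <- matrix(rep(baseline, each = length(types)), length(types), J,
                     dimnames = list(types, genes))
  for (i in seq_along(types)) {
    mg <- ((i - 1L) * spec$n_markers + 1L):(i * spec$n_markers)
    markers[[types[i]]] <- genes[mg]
    profiles[i, mg] <- profiles[i, mg] * spec$marker_fold
  }
  # scale each type's profile to the target library size
  profiles <- profiles / rowSums(profiles) * spec$library_size

  parent_of <- vapply(types, function(t) dag$parents[[t]][1L], "")
  organs <- rep(c("spleen", "lung", "bone marrow"),
                length.out = spec$n_datasets)
  cards <- list(); matrices <- list(); label_rows <- list()
  for (d in seq_len(spec$n_datasets)) {
    ds_id <- sprintf("sim_ds%02d", d)
    n <- spec$cells_per_dataset
    truth <- sample(types, n, replace = TRUE)
    counts <- matrix(0L, n, J)
    for (t in types) {
      ix <- which(truth == t)
      if (!length(ix)) next
      counts[ix, ] <- matrix(
        stats::rnbinom(length(ix) * J,
                       mu = rep(profiles[t, ], each = length(ix)),
                       size = spec$phi),
        length(ix), J)
    }
    coarse <- stats::runif(n) < spec$coarse_label_fraction
    observed <- ifelse(coarse, parent_of[truth], truth)
    cell_ids <- sprintf("%s_cell_%04d", ds_id, seq_len(n))
    cm <- count_matrix(counts, cell_ids, genes, labels = observed,
                       feature_space = list(assembly = "synthetic",
                                            subset = "sim"))
    matrices[[ds_id]] <- cm
    cards[[ds_id]] <- dataset_card(
      ds_id, spec$organism, organs[d], spec$assay, "healthy", n,
      matrix_handle = cm,
      feature_space = cm$feature_space, anatomy = anatomy)
    label_rows[[ds_id]] <- data.frame(dataset_id = ds_id, cell_id = cell_ids,
                                      observed = observed, truth = truth)
  }
  labels <- do.call(rbind, label_rows)
  rownames(labels) <- NULL
  list(cards = unname(cards), matrices = matrices, labels = labels,
       profiles = profiles, markers = markers, ontology = dag,
       anatomy = anatomy,
       label_space = build_label_space(dag, unique(labels$observed)),
       spec = spec)
}

#' Write a simulated corpus in the registry's on-disk formats
#'
#' One subdirectory per dataset (MatrixMarket matrix with TSV sidecars and
#' labels) plus a `card.yaml`, and the toy ontology in both formats at the
#' top level.
#'
#' @param sim a [simulate_corpus()] result
#' @param dir output directory
#' @return invisibly, `dir`
#' @export
write_corpus <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (card in sim$cards) {
    ds_dir <- file.path(dir, card$dataset_id)
    write_count_matrix(sim$matrices[[card$dataset_id]], ds_dir)
    write_card(card, file.path(ds_dir, "card.yaml"), matrix_dir = ".")
  }
  write_toy_ontology_files(dir)
  utils::write.table(sim$labels, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read back a corpus written by [write_corpus()]
#'
#' @param dir corpus directory
#' @return list with `cards`, `ontology` and (when present) `truth`
#' @export
read_corpus <- function(dir) {
  anatomy <- toy_anatomy()
  card_files <- sort(list.files(dir, pattern = "^card\\.yaml$",
                                recursive = TRUE, full.names = TRUE))
  cards <- lapply(card_files, read_card, anatomy = anatomy)
  onto <- load_ontology(file.path(dir, "toy_immune_edges.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.table(truth_path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "")
  }
  list(cards = cards, ontology = onto, truth = truth)
}
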