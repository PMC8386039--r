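#' Load a cell-type (or anatomy) ontology as a DAG
#'
#' Reads an ontology from either a minimal OBO file (only `[Term]` stanzas
#' with `id`, `name` and `is_a` lines are honoured; every other relationship
#' type is ignored with a warning) or a two-column tab-separated edge list
#' `child_id<TAB>parent_id`. The result is a validated directed acyclic
#' graph of is-a relations supporting descendant/ancestor queries and
#' label-space construction.
#'
#' @param source path to the ontology file
#' @param format `"obo"` or `"edge_list"`; guessed from the file extension
#'   (`.obo` vs anything else) when missing
#' @param version free-text ontology version tag; when `NULL`, taken from
#'   the OBO `data-version` header if present, otherwise the file name
#' @return an object of class `onto_dag` with elements `terms` (character
#'   ids), `names` (display names, named by id), `parents` / `children`
#'   (adjacency lists, named by id), `edges` (two-column matrix
#'   child,parent) and `version`
#' @examples
#' f <- system.file("extdata", "toy_immune_edges.tsv", package = "ontozoo")
#' dag <- load_ontology(f)
#' descendants(dag, "lymphocyte")
#' @seealso [build_label_space()], [descendants()], [ancestors()]
#' @export
load_ontology <- function(source, format = c("auto", "obo", "edge_list"),
                          version = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) {
    oz_stop("schema_error", "ontology file not found: %s", source)
  }
  if (format == "auto") {
    format <- if (grepl("\\.obo$", source, ignore.case = TRUE)) "obo" else "edge_list"
  }
  if (format == "obo") {
    parsed <- parse_obo(source)
    if (is.null(version)) version <- parsed$version %||% basename(source)
    onto_dag(parsed$edges, names = parsed$names, version = version,
             isolated = parsed$isolated)
  } else {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      oz_stop("schema_error",
              "edge list must have exactly 2 tab-separated columns (line %d)",
              which(lengths(parts) != 2L)[1L])
    }
    edges <- do.call(rbind, parts)
    colnames(edges) <- c("child", "parent")
    onto_dag(edges, version = version %||% basename(source))
  }
}

#' Construct an ontology DAG from an edge table
#'
#' @param edges two-column character matrix or data.frame of child -> parent
#'   is-a pairs
#' @param names optional named character vector of display names; ids
#'   missing from it display as themselves
#' @param version free-text version tag
#' @param isolated additional term ids that appear without any edge
#' @return an `onto_dag`
#' @export
onto_dag <- function(edges, names = NULL, version = "unversioned",
                     isolated = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) oz_stop("schema_error", "edges must have 2 columns")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("child", "parent")
  terms <- lex_sort(unique(c(edges[, 1L], edges[, 2L], isolated)))
  if (!is.null(names)) {
    unknown <- setdiff(base::names(names), terms)
    if (length(unknown)) {
      oz_stop("schema_error", "edge references undeclared term: %s",
              unknown[1L])
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- g + igraph::vertices(setdiff(terms, igraph::V(g)$name))
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle_member(edges)
    oz_stop("cycle_error", "ontology contains a cycle through term '%s'", cyc)
  }
  display <- stats::setNames(terms, terms)
  if (!is.null(names)) display[base::names(names)] <- names
  parents <- split(edges[, "parent"], factor(edges[, "child"], levels = terms))
  children <- split(edges[, "child"], factor(edges[, "parent"], levels = terms))
  structure(
    list(terms = terms, names = display, edges = edges,
         parents = lapply(parents, unique), children = lapply(children, unique),
         graph = g, version = version),
    class = "onto_dag"
  )
}

# Locale-independent ordering: case-insensitive, ties broken bytewise.
# Radix ordering ignores the session collation, so classifier output
# columns are identical across platforms and locales.
lex_sort <- function(x) x[order(tolower(x), x, method = "radix")]

# One vertex on a directed cycle, by iteratively stripping sinks and
# sources: only vertices on cycles survive both prunings.
find_cycle_member <- function(edges) {
  nodes <- unique(c(edges))
  repeat {
    keep <- nodes %in% edges[, 1L] & nodes %in% edges[, 2L]
    if (all(keep) || !any(keep)) break
    nodes <- nodes[keep]
    edges <- edges[edges[, 1L] %in% nodes & edges[, 2L] %in% nodes, , drop = FALSE]
  }
  if (length(nodes)) lex_sort(nodes)[1L] else "<unknown>"
}

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  version <- NULL
  hdr <- grep("^data-version:", lines, value = TRUE)
  if (length(hdr)) version <- trimws(sub("^data-version:", "", hdr[1L]))
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  if (!length(term_starts)) oz_stop("schema_error", "no [Term] stanzas in %s", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(); nms <- character(); edges <- NULL
  skipped_rel <- 0L
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    id <- trimws(sub("^id:", "", grep("^id:", block, value = TRUE)[1L]))
    if (is.na(id)) oz_stop("schema_error", "[Term] stanza without id in %s", path)
    nm <- grep("^name:", block, value = TRUE)
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) trimws(sub("^name:", "", nm[1L])) else id)
    isa <- grep("^is_a:", block, value = TRUE)
    for (line in isa) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      edges <- rbind(edges, c(id, parent))
    }
    skipped_rel <- skipped_rel + length(grep("^relationship:", block))
  }
  if (skipped_rel > 0L) {
    oz_warn("ignored %d non-is_a relationship line(s); only the is-a hierarchy is used",
            skipped_rel)
  }
  unknown <- setdiff(unique(edges[, 2L]), ids)
  if (length(unknown)) {
    oz_stop("schema_error", "is_a target '%s' has no [Term] stanza", unknown[1L])
  }
  list(edges = edges, names = stats::setNames(nms, ids),
       isolated = setdiff(ids, unique(c(edges))), version = version)
}

#' @export
print.onto_dag <- function(x, ...) {
  n_leaves <- sum(lengths(x$children) == 0L)
  cat(sprintf("<onto_dag> %d terms, %d is-a edges, %d leaves (version: %s)\n",
              length(x$terms), nrow(x$edges), n_leaves, x$version))
  invisible(x)
}

check_term <- function(dag, term) {
  missing <- setdiff(term, dag$terms)
  if (length(missing)) {
    oz_stop("unknown_term_error", "term '%s' is not in the ontology", missing[1L])
  }
}

#' Descendant and ancestor queries
#'
#' Transitive closure over is-a edges. By default the query term itself is
#' excluded; set `include_self = TRUE` for the reflexive closure (the form
#' used when aggregating label probability mass over a term's subtree).
#'
#' @param dag an [onto_dag()]
#' @param term a single term id
#' @param include_self include `term` in the result (default `FALSE`)
#' @return character vector of term ids, sorted
#' @export
descendants <- function(dag, term, include_self = FALSE) {
  check_term(dag, term)
  out <- igraph::subcomponent(dag$graph, term, mode = "in")$name
  if (!include_self) out <- setdiff(out, term)
  lex_sort(out)
}

#' @rdname descendants
#' @export
ancestors <- function(dag, term, include_self = FALSE) {
  check_term(dag, term)
  out <- igraph::subcomponent(dag$graph, term, mode = "out")$name
  if (!include_self) out <- setdiff(out, term)
  lex_sort(out)
}

#' Build a leaf-node label space from observed terms
#'
#' The classifier's output classes are the finest-grained terms observed in
#' the data: within the ancestor-closed subgraph induced by the observed
#' terms, the leaves are the observed terms that have no other observed term
#' among their descendants. Every term of the subgraph is mapped to its
#' positive leaf set — the leaves that are the term itself or one of its
#' descendants — which is what the aggregated cross-entropy sums predicted
#' probability mass over. When observed terms are ancestrally related
#' (e.g. one study reports "lymphocyte" and another "T cell"), the union of
#' observations is taken before leaf extraction, so the coarse term becomes
#' an internal node.
#'
#' @param dag an [onto_dag()]
#' @param observed_terms character vector of term ids observed in data
#' @return an object of class `label_space` with elements `leaves` (ordered
#'   lexicographically, the output classes K), `positive_sets` (named list:
#'   term id -> character vector of leaves, K+), `terms` (all subgraph
#'   terms) and `dag_version`
#' @examples
#' f <- system.file("extdata", "toy_immune_edges.tsv", package = "ontozoo")
#' dag <- load_ontology(f)
#' ls <- build_label_space(dag, c("lymphocyte", "T cell", "B cell", "macrophage"))
#' ls$leaves
#' ls$positive_sets[["lymphocyte"]]
#' @export
build_label_space <- function(dag, observed_terms) {
  observed_terms <- unique(as.character(observed_terms))
  if (!length(observed_terms)) {
    oz_stop("empty_label_space_error", "no observed terms to build a label space from")
  }
  check_term(dag, observed_terms)
  subgraph <- unique(unlist(lapply(observed_terms, ancestors,
                                   dag = dag, include_self = TRUE)))
  desc <- lapply(stats::setNames(subgraph, subgraph), descendants, dag = dag)
  is_leaf <- vapply(observed_terms, function(t) {
    !any(observed_terms %in% desc[[t]])
  }, logical(1L))
  leaves <- lex_sort(observed_terms[is_leaf])
  positive_sets <- lapply(stats::setNames(subgraph, subgraph), function(t) {
    lex_sort(intersect(leaves, c(t, desc[[t]])))
  })
  if (any(lengths(positive_sets) == 0L)) {
    # cannot happen for an ancestor-closed subgraph; guard the invariant
    bad <- names(positive_sets)[lengths(positive_sets) == 0L][1L]
    oz_stop("unmappable_label_error", "term '%s' has an empty positive leaf set", bad)
  }
  structure(
    list(leaves = leaves, positive_sets = positive_sets,
         terms = lex_sort(subgraph), dag_version = dag$version),
    class = "label_space"
  )
}

#' @export
print.label_space <- function(x, ...) {
  cat(sprintf("<label_space> %d leaves over a %d-term subgraph (ontology: %s)\n",
              length(x$leaves), length(x$terms), x$dag_version))
  cat("  leaves:", paste(utils::head(x$leaves, 8L), collapse = ", "),
      if (length(x$leaves) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Positive leaf set of a term
#'
#' @param label_space a [build_label_space()] result
#' @param term a term id inside the label-space subgraph
#' @return character vector of leaves (K+)
#' @export
positive_set <- function(label_space, term) {
  ps <- label_space$positive_sets[[term]]
  if (is.null(ps)) {
    oz_stop("unmappable_label_error",
            "term '%s' is outside the label-space subgraph", term)
  }
  ps
}
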