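# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the package's own code paths (plain-R BFS, dnbinom, two-pass loops).

# Case-insensitive, locale-independent ordering (mirrors the package's
# documented leaf ordering so identical sets compare as identical vectors).
ci_sort <- function(x) x[order(tolower(x), x, method = "radix")]

# Independent reflexive-transitive closure over child -> parent edges by
# breadth-first expansion; returns descendants-or-self of `term`.
bfs_desc_or_self <- function(edges, term) {
  out <- term
  repeat {
    kids <- edges[edges[, 2L] %in% out, 1L]
    new <- setdiff(kids, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  ci_sort(out)
}

bfs_anc_or_self <- function(edges, term) {
  out <- term
  repeat {
    parents <- edges[edges[, 1L] %in% out, 2L]
    new <- setdiff(parents, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  ci_sort(out)
}

toy_edges <- function() {
  f <- system.file("extdata", "toy_immune_edges.tsv", package = "ontozoo")
  m <- do.call(rbind, strsplit(readLines(f), "\t", fixed = TRUE))
  colnames(m) <- c("child", "parent")
  m
}

toy_dag <- function() {
  load_ontology(system.file("extdata", "toy_immune_edges.tsv",
                            package = "ontozoo"))
}

# Small labelled count matrix with two well-separated types.
tiny_labelled_counts <- function(n = 40, J = 10, seed = 1) {
  set.seed(seed)
  types <- rep(c("T cell", "B cell"), length.out = n)
  half <- max(1L, J %/% 2L)
  mu <- matrix(3, n, J)
  mu[types == "T cell", seq_len(half)] <- 15
  mu[types == "B cell", (half + 1L):J] <- 15
  counts <- matrix(rnbinom(n * J, mu = mu, size = 3), n, J)
  counts[rowSums(counts) == 0, 1] <- 1
  count_matrix(counts, gene_ids = sprintf("g%02d", seq_len(J)), labels = types)
}

# Counts whose log-mean matrix has rank 2 (one latent factor plus per-gene
# offsets), so a latent-2 linear NB model can represent the truth.
rank2_counts <- function(n = 400, J = 50, phi = 5, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  v <- rnorm(J, sd = 0.5)
  b <- rnorm(J, mean = log(50), sd = 0.7)
  mu <- exp(outer(u, v) + matrix(b, n, J, byrow = TRUE))
  counts <- matrix(rnbinom(n * J, mu = mu, size = phi), n, J)
  stopifnot(all(rowSums(counts) > 0))
  list(cm = count_matrix(counts, gene_ids = sprintf("g%03d", seq_len(J))),
       mu = mu, phi = phi)
}

# Relative-error finite-difference comparison helper.
rel_err <- function(a, b, floor = 1) abs(a - b) / pmax(floor, abs(b))
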