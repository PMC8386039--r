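three_card_fixture <- function() {
  anatomy <- toy_anatomy()
  mk <- function(id, organ, organism, seed) {
    cm <- tiny_labelled_counts(n = 20, J = 6, seed = seed)
    dataset_card(id, organism, organ, "10x", n_cells = 20,
                 matrix_handle = cm, anatomy = anatomy)
  }
  list(mk("d1", "spleen", "mouse", 1),
       mk("d2", "thymus", "mouse", 2),
       mk("d3", "lung", "human", 3))
}

test_that("cards validate the organ term and check declared cell counts", {
  anatomy <- toy_anatomy()
  expect_error(dataset_card("x", "mouse", "gizzard", "10x", anatomy = anatomy),
               class = "ontozoo_unknown_term_error")
  cm <- tiny_labelled_counts(n = 10, J = 4, seed = 4)
  card <- dataset_card("x", "mouse", "spleen", "10x", n_cells = 99,
                       matrix_handle = cm, anatomy = anatomy)
  expect_error(load_matrix(card), class = "ontozoo_schema_error")
})

test_that("subset queries expand organ terms over the anatomy DAG", {
  cards <- three_card_fixture()
  anatomy <- toy_anatomy()
  # 'lymphoid organ' matches spleen and thymus via descendants
  hit <- subset_cards(cards, organ = "lymphoid organ", anatomy = anatomy)
  expect_setequal(vapply(hit, `[[`, "", "dataset_id"), c("d1", "d2"))
  # exact string fields
  expect_length(subset_cards(cards, organism = "human"), 1L)
  # vacuous match is an empty list, not an error
  expect_length(subset_cards(cards, organism = "axolotl"), 0L)
  # unknown key fails loudly
  expect_error(subset_cards(cards, tissue = "spleen"),
               class = "ontozoo_schema_error")
  # stability under card reordering
  hit_rev <- subset_cards(rev(cards), organ = "lymphoid organ",
                          anatomy = anatomy)
  expect_setequal(vapply(hit_rev, `[[`, "", "dataset_id"),
                  vapply(hit, `[[`, "", "dataset_id"))
})

test_that("grouped gene statistics agree with a naive two-pass loop", {
  cards <- three_card_fixture()
  out <- grouped_gene_stat(cards, "g01")
  # naive recomputation
  for (i in seq_len(nrow(out))) {
    vals <- c()
    for (card in cards) {
      cm <- load_matrix(card)
      if (card$organ != out$organ[i]) next
      tv <- transform_counts(cm)$values[, "g01"]
      vals <- c(vals, tv[cm$labels == out$cell_type[i]])
    }
    expect_equal(out$value[i], mean(vals), tolerance = 1e-12)
    expect_equal(out$n_cells[i], length(vals))
  }
  # constant matrix: identical value in every group
  const <- count_matrix(matrix(5, 12, 4), gene_ids = paste0("g", 1:4),
                        labels = rep(c("T cell", "B cell"), 6))
  ccard <- dataset_card("c", "mouse", "spleen", "10x", n_cells = 12,
                        matrix_handle = const)
  cout <- grouped_gene_stat(list(ccard), "g1")
  expect_equal(length(unique(cout$value)), 1L)
  # missing gene names the offending card
  err <- expect_error(grouped_gene_stat(cards, "nope"),
                      class = "ontozoo_missing_feature_error")
  expect_match(conditionMessage(err), "d1")
})

test_that("dataset-weighted grouped statistics average per-dataset means", {
  anatomy <- toy_anatomy()
  mk <- function(id, value, n) {
    cm <- count_matrix(cbind(rep(value, n), rep(1, n)),
                       cell_ids = sprintf("%s_%d", id, 1:n),
                       gene_ids = c("gA", "gB"),
                       labels = rep("T cell", n))
    dataset_card(id, "mouse", "spleen", "10x", n_cells = n,
                 matrix_handle = cm, anatomy = anatomy)
  }
  cards <- list(mk("big", 9, 30), mk("small", 1, 3))
  pooled <- grouped_gene_stat(cards, "gA", preprocessed = FALSE)
  by_ds <- grouped_gene_stat(cards, "gA", preprocessed = FALSE,
                             weighting = "dataset")
  expect_equal(pooled$value, (9 * 30 + 1 * 3) / 33)
  expect_equal(by_ds$value, (9 + 1) / 2)
})

test_that("gene-gene correlation handles perfect, degenerate and noisy groups", {
  anatomy <- toy_anatomy()
  set.seed(61)
  # duplicated column: r = 1 in every valid group
  base <- matrix(rpois(40 * 2, 8) + 1, 40, 2)
  cm <- count_matrix(cbind(base, base[, 1]), gene_ids = c("a", "b", "adup"),
                     labels = rep(c("T cell", "B cell"), 20))
  card <- dataset_card("dd", "mouse", "spleen", "10x", n_cells = 40,
                       matrix_handle = cm, anatomy = anatomy)
  out <- gene_gene_correlation(list(card), "a", "adup")
  expect_true(all(abs(out$r - 1) < 1e-12))

  # two-cell group with opposite ranks: r = -1 (raw counts avoid the
  # per-cell rescaling)
  cm2 <- count_matrix(rbind(c(1, 5), c(5, 1)), gene_ids = c("a", "b"),
                      labels = c("T cell", "T cell"))
  card2 <- dataset_card("d2", "mouse", "spleen", "10x", n_cells = 2,
                        matrix_handle = cm2, anatomy = anatomy)
  out2 <- gene_gene_correlation(list(card2), "a", "b", preprocessed = FALSE)
  expect_equal(out2$r, -1)

  # single-cell and zero-variance groups are missing with a reason
  cm3 <- count_matrix(rbind(c(1, 2), c(3, 2), c(3, 2)), gene_ids = c("a", "b"),
                      labels = c("T cell", "B cell", "B cell"))
  card3 <- dataset_card("d3", "mouse", "spleen", "10x", n_cells = 3,
                        matrix_handle = cm3, anatomy = anatomy)
  out3 <- gene_gene_correlation(list(card3), "a", "b", preprocessed = FALSE)
  expect_true(all(is.na(out3$r)))
  expect_setequal(out3$reason, c("fewer than 2 cells", "zero variance"))
})

test_that("correlated NB pairs recover the latent correlation within 0.1", {
  # bivariate counts built from a shared log-normal factor; the oracle is
  # the direct Pearson formula on the same draws
  set.seed(62)
  n <- 2000
  latent <- rnorm(n)
  mu_a <- exp(1.2 + 0.8 * latent)
  mu_b <- exp(1.0 + 0.8 * latent)
  a <- rnbinom(n, mu = mu_a, size = 8)
  b <- rnbinom(n, mu = mu_b, size = 8)
  cm <- count_matrix(cbind(a = a, b = b, pad = rpois(n, 5) + 1),
                     gene_ids = c("a", "b", "pad"),
                     labels = rep("T cell", n))
  card <- dataset_card("cc", "mouse", "spleen", "10x", n_cells = n,
                       matrix_handle = cm, anatomy = toy_anatomy())
  out <- gene_gene_correlation(list(card), "a", "b", preprocessed = FALSE)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(out$r, oracle, tolerance = 1e-12)
  expect_lt(abs(out$r - 0.6), 0.25)  # latent correlation regime, not 0 or 1
})

test_that("cell-type fractions expand over ontology descendants", {
  dag <- toy_dag()
  cm <- count_matrix(matrix(1, 100, 2), gene_ids = c("a", "b"),
                     labels = c(rep("T cell", 30), rep("B cell", 70)))
  card <- dataset_card("f1", "mouse", "spleen", "10x", n_cells = 100,
                       matrix_handle = cm, anatomy = toy_anatomy())
  expect_equal(cell_type_fraction(list(card), "lymphocyte", dag)$fraction, 1)
  expect_equal(cell_type_fraction(list(card), "T cell", dag)$fraction, 0.3)
  expect_equal(cell_type_fraction(list(card), "macrophage", dag)$fraction, 0)
  expect_error(cell_type_fraction(list(card), "unicorn", dag),
               class = "ontozoo_unknown_term_error")
})

test_that("splits partition cells, reproduce under seeds, and round half away", {
  cards <- three_card_fixture()
  sp <- make_split(cards, "holdout", holdout_dataset_id = "d2")
  expect_setequal(vapply(sp$train, `[[`, "", "dataset_id"), c("d1", "d3"))
  expect_identical(sp$test[[1]]$dataset_id, "d2")

  one <- cards[1]
  expect_error(make_split(one, "holdout", holdout_dataset_id = "d1"),
               class = "ontozoo_split_scheme_error")

  big <- count_matrix(matrix(1, 1000, 2), gene_ids = c("a", "b"))
  bcard <- dataset_card("big", "mouse", "spleen", "10x", n_cells = 1000,
                        matrix_handle = big)
  s1 <- make_split(list(bcard), "fraction", fraction = 0.2, seed = 7)
  s2 <- make_split(list(bcard), "fraction", fraction = 0.2, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$test[[1]]$cells, 200L)
  expect_length(intersect(s1$test[[1]]$cells, s1$train[[1]]$cells), 0L)
  expect_setequal(c(s1$test[[1]]$cells, s1$train[[1]]$cells), 1:1000)

  nine <- count_matrix(matrix(1, 9, 2), gene_ids = c("a", "b"))
  ncard <- dataset_card("nine", "mouse", "spleen", "10x", n_cells = 9,
                        matrix_handle = nine)
  s9 <- make_split(list(ncard), "fraction", fraction = 0.2, seed = 1)
  expect_length(s9$test[[1]]$cells, 2L)  # round(1.8) half away from zero
})

test_that("count matrices round-trip through MTX directories and cards", {
  cm <- tiny_labelled_counts(n = 15, J = 7, seed = 63)
  dir <- withr::local_tempdir()
  write_count_matrix(cm, dir)
  back <- read_count_matrix(dir)
  expect_equal(back$counts, cm$counts)
  expect_identical(back$cell_ids, cm$cell_ids)
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_identical(back$labels, cm$labels)

  card <- dataset_card("rt", "mouse", "spleen", "10x", n_cells = 15,
                       matrix_handle = dir, anatomy = toy_anatomy())
  yml <- file.path(dir, "card.yaml")
  write_card(card, yml, matrix_dir = ".")
  card2 <- read_card(yml, anatomy = toy_anatomy())
  expect_identical(card2$dataset_id, "rt")
  m <- load_matrix(card2)
  expect_equal(m$counts, cm$counts)
  release_matrix(card2)
})

test_that("count matrices round-trip through the single-file HDF5 layout", {
  skip_if_not_installed("rhdf5")
  cm <- tiny_labelled_counts(n = 12, J = 5, seed = 64)
  path <- withr::local_tempfile(fileext = ".h5")
  write_count_matrix_h5(cm, path)
  back <- read_count_matrix_h5(path)
  expect_equal(back$counts, cm$counts, ignore_attr = TRUE)
  expect_identical(back$cell_ids, cm$cell_ids)
  expect_identical(back$labels, cm$labels)
})
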