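make_spec <- function(kind, genes, lsp, ...) {
  classifier_spec(kind, genes, lsp, ...)
}

test_that("forward contracts: uniform softmax at zero weights, determinism, gene checks", {
  dag <- toy_dag()
  lsp <- build_label_space(dag, c("T cell", "B cell", "macrophage"))
  genes <- sprintf("g%02d", 1:6)
  spec <- make_spec("linear", genes, lsp)
  fit0 <- fit_classifier(spec, matrix(rnorm(30), 5, 6,
                                      dimnames = list(NULL, genes)),
                         rep("T cell", 5), epochs = 0L, seed = 1)
  # zero out the initial weights: softmax must be uniform
  fit0$params$layers[[1]]$W[] <- 0
  fit0$params$layers[[1]]$b[] <- 0
  p <- predict(fit0, matrix(rnorm(12), 2, 6, dimnames = list(NULL, genes)))
  expect_equal(unname(p), matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_identical(colnames(p), lsp$leaves)

  # repeated forward passes are bitwise identical
  spec_mlp <- make_spec("mlp", genes, lsp, hidden = 4L)
  fitm <- fit_classifier(spec_mlp, matrix(rnorm(60), 10, 6,
                                          dimnames = list(NULL, genes)),
                         rep(c("T cell", "B cell"), 5), epochs = 2L, seed = 3)
  X <- matrix(rnorm(18), 3, 6, dimnames = list(NULL, genes))
  expect_identical(predict(fitm, X), predict(fitm, X))

  bad <- matrix(0, 2, 6, dimnames = list(NULL, rev(genes)))
  err <- expect_error(predict(fitm, bad), class = "ontozoo_feature_space_error")
  expect_match(conditionMessage(err), "g06")
})

test_that("marker model: monotone gene stage and concentration on a marked leaf", {
  dag <- toy_dag()
  lsp <- build_label_space(dag, c("T cell", "B cell"))
  genes <- c("markerT", "markerB")
  spec <- make_spec("marker", genes, lsp)
  fit <- fit_classifier(spec, matrix(1, 2, 2, dimnames = list(NULL, genes)),
                        c("T cell", "B cell"), epochs = 0L, seed = 1)
  # steep slope on each marker, identity pooling onto the matching leaf
  fit$params$a <- c(50, 50)
  fit$params$b <- c(-25, -25)
  fit$params$pool$W <- matrix(c(0, 8, 8, 0), 2, 2)  # markerT -> T cell col 2
  fit$params$pool$b <- c(0, 0)
  X <- rbind(c(2, 0), c(0, 2))
  colnames(X) <- genes
  p <- predict(fit, X)
  expect_gt(p[1, "T cell"], 0.99)
  expect_gt(p[2, "B cell"], 0.99)

  # gene-wise sigmoid stage is monotone in its input (positive slope)
  oz <- asNamespace("ontozoo")
  xs <- seq(-3, 3, length.out = 25)
  h <- oz$sigmoid(fit$params$a[1] * xs + fit$params$b[1])
  expect_true(all(diff(h) >= 0))
})

test_that("training with one-hot labels matches plain cross-entropy training", {
  # with exclusively leaf labels the aggregated loss *is* multi-class CE,
  # so the recorded loss trajectory must match an independent CE computed
  # on the same predictions
  dag <- toy_dag()
  lsp <- build_label_space(dag, c("T cell", "B cell"))
  cm <- tiny_labelled_counts(n = 60, seed = 5)
  tm <- transform_counts(cm)
  spec <- make_spec("linear", tm$gene_ids, lsp)
  fit <- fit_classifier(spec, tm, cm$labels, epochs = 20, seed = 2,
                        validation_fraction = 0)
  p <- predict(fit, tm)
  y <- map_labels(cm$labels, lsp)$y
  idx <- cbind(seq_len(nrow(y)), max.col(y))
  ce_ref <- -mean(log(p[idx]))
  expect_lt(abs(cce_agg(p, y) - ce_ref), 1e-10)
})

test_that("zero epochs returns the initialisation; training fits separable data", {
  dag <- toy_dag()
  lsp <- build_label_space(dag, c("T cell", "B cell"))
  cm <- tiny_labelled_counts(n = 80, seed = 6)
  tm <- transform_counts(cm)
  spec <- make_spec("linear", tm$gene_ids, lsp)
  f0a <- fit_classifier(spec, tm, cm$labels, epochs = 0L, seed = 9)
  f0b <- fit_classifier(spec, tm, cm$labels, epochs = 0L, seed = 9)
  expect_identical(f0a$params, f0b$params)
  expect_identical(nrow(f0a$history), 0L)

  # fully separable two-type construction: disjoint strong marker blocks
  set.seed(10)
  types <- rep(c("T cell", "B cell"), each = 50)
  mu_sep <- matrix(0.2, 100, 10)
  mu_sep[types == "T cell", 1:5] <- 40
  mu_sep[types == "B cell", 6:10] <- 40
  counts <- matrix(rnbinom(1000, mu = mu_sep, size = 10), 100, 10)
  counts[rowSums(counts) == 0, 1] <- 1
  sep <- count_matrix(counts, gene_ids = sprintf("g%02d", 1:10), labels = types)
  tms <- transform_counts(sep)
  fit <- fit_classifier(classifier_spec("linear", tms$gene_ids, lsp),
                        tms, sep$labels, epochs = 200, seed = 9,
                        validation_fraction = 0)
  p <- predict(fit, tms)
  expect_gte(acc_agg(p, map_labels(sep$labels, lsp)), 0.98)
})

test_that("training on coarse labels improves leaf recovery over discarding them", {
  sim <- simulate_corpus(sim_spec(n_datasets = 1, cells_per_dataset = 1200,
                                  coarse_label_fraction = 0.5, seed = 41))
  cm <- sim$matrices[[1]]
  truth <- sim$labels$truth
  tm <- transform_counts(cm)
  lsp <- sim$label_space
  split <- make_split(sim$cards, "fraction", fraction = 0.2, seed = 41)
  te <- split$test[[1]]$cells
  tr <- split$train[[1]]$cells
  spec <- make_spec("linear", tm$gene_ids, lsp)
  acc_of <- function(idx) {
    fit <- fit_classifier(spec, tm$values[idx, ], cm$labels[idx],
                          epochs = 120, seed = 41, validation_fraction = 0)
    p <- predict(fit, tm$values[te, ])
    mean(colnames(p)[max.col(p)] == truth[te])
  }
  acc_all <- acc_of(tr)
  acc_leaf_only <- acc_of(tr[cm$labels[tr] %in% lsp$leaves])
  expect_gt(acc_all, acc_leaf_only)
})

test_that("evaluation metrics match an independent confusion-matrix computation", {
  dag <- toy_dag()
  lsp <- build_label_space(dag, c("T cell", "B cell"))
  cm <- tiny_labelled_counts(n = 100, seed = 7)
  tm <- transform_counts(cm)
  spec <- make_spec("linear", tm$gene_ids, lsp)
  fit <- fit_classifier(spec, tm, cm$labels, epochs = 60, seed = 3,
                        validation_fraction = 0)
  m <- evaluate_classifier(fit, tm, cm$labels)
  p <- predict(fit, tm)
  pred <- colnames(p)[max.col(p)]
  for (leaf in lsp$leaves) {
    tp <- sum(pred == leaf & cm$labels == leaf)
    fp <- sum(pred == leaf & cm$labels != leaf)
    fn <- sum(pred != leaf & cm$labels == leaf)
    f1_ref <- if (2 * tp + fp + fn == 0) NaN else 2 * tp / (2 * tp + fp + fn)
    expect_equal(unname(m$f1[leaf]), f1_ref, info = leaf)
  }
  expect_equal(m$acc_agg, acc_agg(p, map_labels(cm$labels, lsp)))
  expect_error(evaluate_classifier(fit, tm$values[0, , drop = FALSE],
                                   character()),
               class = "ontozoo_empty_eval_error")

  # degenerate all-one-class predictor on balanced two-class data
  fit$params$layers[[1]]$W[] <- 0
  fit$params$layers[[1]]$b <- c(10, 0)
  m2 <- evaluate_classifier(fit, tm, cm$labels)
  expect_equal(unname(m2$f1[1]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m2$f1[2]), 0)
})

test_that("class-wise F1 increases with class size on imbalanced fixtures", {
  # five types with strongly imbalanced frequencies: rank correlation
  # between class size and F1 positive for most seeds
  cors <- vapply(1:5, function(seed) {
    set.seed(seed)
    sim <- simulate_corpus(sim_spec(n_datasets = 1, cells_per_dataset = 600,
                                    coarse_label_fraction = 0, marker_fold = 2.2,
                                    seed = seed))
    cm <- sim$matrices[[1]]
    n <- nrow(cm$counts)
    # thin the last three types to make classes imbalanced
    keep_prob <- c(1, 1, 0.25, 0.15, 0.1)[match(cm$labels,
                                                sort(unique(cm$labels)))]
    keep <- runif(n) < keep_prob
    cm2 <- count_matrix(cm$counts[keep, ], cm$cell_ids[keep], cm$gene_ids,
                        labels = cm$labels[keep])
    tm <- transform_counts(cm2)
    lsp <- build_label_space(sim$ontology, unique(cm2$labels))
    fit <- fit_classifier(classifier_spec("linear", tm$gene_ids, lsp),
                          tm, cm2$labels, epochs = 40, seed = seed,
                          validation_fraction = 0)
    m <- evaluate_classifier(fit, tm, cm2$labels)
    sizes <- table(factor(cm2$labels, levels = lsp$leaves))
    suppressWarnings(cor(as.numeric(sizes), m$f1, method = "spearman"))
  }, 0)
  expect_gt(mean(cors > 0), 0.5)
  expect_gt(mean(cors), 0)
})
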