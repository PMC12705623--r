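test_that("prediction head softmax behaves to closed form", {
  # zero logits -> (0.5, 0.5)
  expect_equal(herbnet:::softmax_rows(matrix(0, 1, 2)), matrix(0.5, 1, 2))
  # logits (1, 0)
  expect_equal(round(herbnet:::softmax_rows(matrix(c(1, 0), 1)), 5),
               matrix(c(0.73106, 0.26894), 1))
  withr::local_seed(1)
  R <- matrix(rnorm(40), 10, 4)
  P <- predict_head(R, matrix(rnorm(8), 4, 2))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-7)
})

test_that("classification takes the argmax with a conservative tie-break", {
  expect_equal(classify(rbind(c(0.7, 0.3), c(0.3, 0.7))), c(0L, 1L))
  expect_equal(classify(c(0.5, 0.5)), 0L)
  # invariant to positive rescaling
  expect_equal(classify(rbind(c(0.2, 0.6)) * 3), classify(rbind(c(0.2, 0.6))))
})

test_that("binary cross-entropy has its closed-form values and clamp", {
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_lte(bce_loss(0, 1), -log(1e-7) + 1e-9)
  expect_gte(bce_loss(0, 1), 0)
})

test_that("metrics agree with brute-force and reference implementations", {
  y <- c(1, 0, 1, 0); s <- c(0.9, 0.8, 0.4, 0.1)
  expect_equal(evaluate_scores(y, s)[["auc"]], 0.75)
  expect_equal(evaluate_scores(y, s)[["auc"]], pairwise_auc(y, s))
  # perfect separation
  e <- evaluate_scores(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(e[["auc"]], 1); expect_equal(e[["aupr"]], 1)
  # all-positive predictions on balanced labels
  e2 <- evaluate_scores(c(1, 0, 1, 0), c(0.9, 0.9, 0.9, 0.9))
  expect_equal(e2[["recall"]], 1); expect_equal(e2[["precision"]], 0.5)
  # rank-based AUC against pROC and the all-pairs oracle on random data
  withr::local_seed(4)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.4); s <- round(runif(40), 2)  # ties included
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(y, s), pairwise_auc(y, s))
    expect_equal(auc_score(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))))
  }
})

test_that("stratified folds partition every prescription exactly once", {
  fx <- tiny_graph(seed = 45, n_prescriptions = 83)
  ids <- fx$graph$nodes$prescription$id
  y <- fx$graph$labels[ids, "planted"]
  f1 <- stratified_folds(ids, y, 10, seed = 3)
  f2 <- stratified_folds(ids, y, 10, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(diff(sort(table(f1))) <= 2))  # sizes differ by <= 1 per class
  expect_equal(sum(table(f1)), length(ids))
  for (cl in 0:1)
    expect_true(all(diff(sort(table(f1[y == cl]))) <= 1))
})

test_that("training loss decreases on average over early epochs", {
  fx <- tiny_graph(seed = 47, n_prescriptions = 120)
  g <- fx$graph
  ids <- g$nodes$prescription$id
  y <- g$labels[ids, "planted"]
  fold <- stratified_folds(ids, y, 10, 1)
  cfg <- train_config(epochs = 20, patience = 20, seed = 2,
                      rgat = rgat_config(hidden_dim = 16,
                                         attention_heads = 2,
                                         relation_heads = 2,
                                         relation_dim = 8))
  m <- fit_rgat(g, "planted", ids[fold <= 8], ids[fold == 9], cfg)
  tr <- m$trace$loss
  expect_lt(mean(tail(tr, 5)), mean(head(tr, 5)))
  # checkpoint round trip preserves scores and attention
  ck <- file.path(withr::local_tempdir(), "model.rds")
  save_rgat_model(m, ck)
  m2 <- load_rgat_model(ck)
  expect_identical(m2$scores, m$scores)
  expect_identical(m2$attention, m$attention)
})

test_that("cross-validation isolates folds and reports summary rows", {
  fx <- tiny_graph(seed = 49, n_prescriptions = 100)
  cfg <- train_config(folds = 5, epochs = 8, patience = 8, seed = 3,
                      rgat = rgat_config(hidden_dim = 16,
                                         attention_heads = 2,
                                         relation_heads = 2,
                                         relation_dim = 8))
  rep <- crossvalidate(fx$graph, "planted", cfg)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep), 7L)  # 5 folds + mean + sd
  m <- report_means(rep)
  expect_true(all(m[c("auc", "aupr", "accuracy")] >= 0 &
                    m[c("auc", "aupr", "accuracy")] <= 1))
  dir <- withr::local_tempdir()
  write_metrics(rep, file.path(dir, "m.csv"))
  back <- read.csv(file.path(dir, "m.csv"))
  expect_equal(nrow(back), 7L)
})

test_that("ablation variants transform the graph as specified", {
  fx <- tiny_graph(seed = 51)
  g <- fx$graph
  cfg <- train_config(max_herbs = 7)
  gR <- herbnet:::apply_variant(g, "R", cfg)
  expect_identical(names(gR$nodes), c("prescription", "herb"))
  expect_true(all(gR$edges$relation %in%
                    c("prescription-herb", "herb-prescription")))
  # R on a graph without metabolites is the identity
  ds <- fx$dataset
  g0 <- build_graph(ds$prescriptions, ds$herbs)
  expect_identical(herbnet:::apply_variant(g0, "R", cfg), g0)
  # H: concatenated herb features with fixed width
  gH <- herbnet:::apply_variant(g, "H", cfg)
  expect_equal(ncol(gH$features$prescription), 7L * 22L)
  # E: metabolite/target features change, everything else fixed
  gE <- herbnet:::apply_variant(g, "E", cfg)
  expect_false(isTRUE(all.equal(gE$features$metabolite,
                                g$features$metabolite)))
  expect_identical(gE$features$herb, g$features$herb)
  expect_identical(gE$edges, g$edges)
})

test_that("the tabular baseline runs through the same protocol", {
  fx <- tiny_graph(seed = 53, n_prescriptions = 100, positive_share = 0.3)
  cfg <- train_config(folds = 5, seed = 4, variant = "S", augmentation = TRUE)
  rep <- crossvalidate(fx$graph, "planted", cfg)
  m <- report_means(rep)
  expect_gt(m[["auc"]], 0.5)
})
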