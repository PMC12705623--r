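# End-to-end training, cross-validated evaluation, and ablation variants.

#' Training configuration
#'
#' @param folds Number of cross-validation folds (default 10; folds rotate
#'   as 8 training folds, 1 validation fold, 1 test fold).
#' @param epochs Maximum training epochs per fold.
#' @param lr Adam learning rate for the classifier.
#' @param patience Early-stopping patience on validation AUC.
#' @param min_epochs Epochs to run before early stopping may fire (model
#'   selection still tracks the best validation epoch).
#' @param seed Master seed: fold assignment, initialization and every
#'   stochastic step derive from it.
#' @param augmentation Whether to fit the adversarial augmenter on the
#'   training folds and merge generated nodes (training folds only).
#' @param variant Ablation variant: `"full"`, `"R"` (metabolite/target
#'   relations removed), `"E"` (alternate sequence encoder), `"H"`
#'   (prescription features concatenated instead of summed), `"S"`
#'   (graph bypassed: SMOTE oversampling + random forest).
#' @param rgat An [rgat_config()].
#' @param gan A [gan_config()] used when `augmentation = TRUE`.
#' @param forbidden Optional forbidden herb-pair table for pruning.
#' @param max_herbs Herb slots for the `"H"` concatenation variant.
#' @return A list of class `train_config`.
#' @export
train_config <- function(folds = 10L, epochs = 40L, lr = 1e-3,
                         patience = 8L, min_epochs = 0L, seed = 1L,
                         augmentation = FALSE,
                         variant = c("full", "R", "E", "H", "S"),
                         rgat = rgat_config(hidden_dim = 32L,
                                            attention_heads = 2L,
                                            relation_heads = 2L,
                                            relation_dim = 8L),
                         gan = gan_config(epochs = 150L),
                         forbidden = NULL, max_herbs = 12L) {
  variant <- match.arg(variant)
  structure(list(folds = as.integer(folds), epochs = as.integer(epochs),
                 lr = lr, patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 seed = as.integer(seed), augmentation = augmentation,
                 variant = variant, rgat = rgat, gan = gan,
                 forbidden = forbidden, max_herbs = as.integer(max_herbs)),
            class = "train_config")
}

presc_global_rows <- function(idx, graph, ids) {
  idx$offsets[["prescription"]] + match(ids, graph$nodes$prescription$id)
}

#' Fit the relational graph attention classifier for one efficacy
#'
#' Full-batch Adam training of the whole stack (input projections,
#' attention layers, relation embeddings, prediction head) with the
#' cross-entropy of the two-class softmax head on the training
#' prescriptions, early-stopped on validation AUC.
#'
#' @param graph A `hetero_graph` whose label table contains `efficacy`.
#' @param efficacy Efficacy name (column of the label table).
#' @param train_ids,val_ids Prescription id partitions.
#' @param config A [train_config()].
#' @return An `rgat_model`: parameters at the best validation epoch,
#'   per-prescription positive-class `scores`, `attention` records of the
#'   final forward pass, and the training `trace`.
#' @export
fit_rgat <- function(graph, efficacy, train_ids, val_ids,
                     config = train_config()) {
  idx <- graph_index(graph)
  rcfg <- config$rgat
  rcfg$seed <- config$seed
  params <- rgat_init(rcfg, idx$type_dims, idx$rel_levels)
  tr_rows <- presc_global_rows(idx, graph, train_ids)
  va_rows <- presc_global_rows(idx, graph, val_ids)
  y_tr <- graph$labels[train_ids, efficacy]
  y_va <- graph$labels[val_ids, efficacy]
  opt <- make_adam(lr = config$lr)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_auc = numeric(0))
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      tape <- new_tape()
      pn <- ad_params(tape, params)
      fw <- ad_rgat_forward(tape, graph$features, idx, pn, rcfg,
                            training = TRUE)
      P <- ad_gather_rows(tape, fw$H, c(tr_rows, va_rows))
      logits <- ad_add(tape, ad_mm(tape, ad_layernorm(tape, P), pn$head.W),
                       pn$head.b)
      tr_slice <- ad_push(tape, logits$value[seq_along(tr_rows), , drop = FALSE],
                          list(logits), function(g) {
                            G <- matrix(0, nrow(logits$value), 2)
                            G[seq_along(tr_rows), ] <- g
                            list(G)
                          })
      loss <- ad_cross_entropy(tape, tr_slice, y_tr + 1L)
      ad_backward(tape, loss)
      params <- opt(params, ad_grads(pn))
      pv <- softmax_rows(ad_value(logits))
      va_auc <- auc_score(y_va, pv[length(tr_rows) + seq_along(va_rows), 2])
      trace <- rbind(trace, data.frame(epoch = ep,
                                       loss = ad_value(loss)[1, 1],
                                       val_auc = va_auc))
      if (!is.na(va_auc) && va_auc > best$auc + 1e-6) {
        best <- list(auc = va_auc, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience && ep >= (config$min_epochs %||% 0L)) break
      }
    }
  })
  # final deterministic forward with the selected parameters
  fw <- rgat_forward(graph, rcfg, params = best$params)
  all_ids <- graph$nodes$prescription$id
  rows <- presc_global_rows(fw$index, graph, all_ids)
  probs <- predict_head(fw$H[rows, , drop = FALSE], best$params$head.W,
                        best$params$head.b)
  scores <- stats::setNames(probs[, 2], all_ids)
  structure(list(params = best$params, rgat = rcfg, efficacy = efficacy,
                 scores = scores, attention = fw$attention,
                 index = fw$index, trace = trace,
                 best_epoch = best$epoch, val_auc = best$auc),
            class = "rgat_model")
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single archive holding the configuration, the
#' parameter matrices, per-prescription scores and the attention records,
#' so interpretation tools can run without retraining.
#'
#' @param model An `rgat_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `rgat_model` (load).
#' @export
save_rgat_model <- function(model, path) {
  stopifnot(inherits(model, "rgat_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rgat_model
#' @export
load_rgat_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rgat_model"))
  model
}

# ---- ablation transforms ---------------------------------------------------

# Apply an ablation variant to a graph copy before training.
apply_variant <- function(graph, variant, config) {
  if (variant %in% c("full", "S")) return(graph)
  if (variant == "R") {
    keep <- intersect(names(graph$nodes), c("prescription", "herb"))
    graph$nodes <- graph$nodes[keep]
    graph$features <- graph$features[keep]
    graph$edges <- graph$edges[
      graph$edges$src_type %in% keep & graph$edges$dst_type %in% keep, ,
      drop = FALSE]
    return(graph)
  }
  if (variant == "E") {
    dim <- graph$meta$embedding_dim %||% 64L
    alt <- kmer_encoder(dim, k = 2L, seed = 9090L)
    spec <- sequence_embedding_spec(dim = dim)
    if (!is.null(graph$nodes$metabolite)) {
      sq <- graph$nodes$metabolite$sequenced
      m <- graph$features$metabolite
      if (any(sq)) m[sq, ] <- embed_sequences(graph$nodes$metabolite$smiles[sq],
                                              spec, alt)
      graph$features$metabolite <- m
    }
    if (!is.null(graph$nodes$target) && !is.null(graph$nodes$target$sequence)) {
      sq <- graph$nodes$target$sequenced
      m <- graph$features$target
      if (any(sq)) m[sq, ] <- embed_sequences(graph$nodes$target$sequence[sq],
                                              spec, alt)
      graph$features$target <- m
    }
    return(graph)
  }
  if (variant == "H") {
    hmat <- graph$features$herb
    n <- ncol(hmat); mh <- config$max_herbs
    conc <- t(vapply(graph$herb_sets[graph$nodes$prescription$id], function(hs) {
      hs <- utils::head(hs, mh)
      v <- as.vector(t(hmat[hs, , drop = FALSE]))
      c(v, numeric(mh * n - length(v)))
    }, numeric(mh * n)))
    rownames(conc) <- graph$nodes$prescription$id
    graph$features$prescription <- conc
    return(graph)
  }
  graph
}

# Minimal SMOTE: synthesize minority rows by interpolating towards one of
# the point's nearest minority neighbors.
smote_oversample <- function(X, y, count, k = 5L, seed = 1L) {
  minority <- X[y == 1, , drop = FALSE]
  if (nrow(minority) < 2 || count <= 0)
    return(list(X = X, y = y))
  with_seed(seed, {
    D <- as.matrix(stats::dist(minority))
    diag(D) <- Inf
    synth <- t(vapply(seq_len(count), function(i) {
      a <- sample(nrow(minority), 1)
      nb <- order(D[a, ])[seq_len(min(k, nrow(minority) - 1))]
      b <- nb[sample(length(nb), 1)]
      u <- stats::runif(1)
      minority[a, ] + u * (minority[b, ] - minority[a, ])
    }, numeric(ncol(X))))
    list(X = rbind(X, synth), y = c(y, rep(1L, count)))
  })
}

# Tabular baseline for the S variant: SMOTE oversampling of prescription
# features plus a random forest, evaluated on the same fold partitions.
rf_fold_scores <- function(X, y, train_rows, test_rows, oversample, seed) {
  Xtr <- X[train_rows, , drop = FALSE]; ytr <- y[train_rows]
  if (oversample) {
    deficit <- sum(ytr == 0) - sum(ytr == 1)
    os <- smote_oversample(Xtr, ytr, deficit, seed = seed)
    Xtr <- os$X; ytr <- os$y
  }
  with_seed(seed, {
    rf <- randomForest::randomForest(x = Xtr, y = factor(ytr, c(0, 1)),
                                     ntree = 200)
    stats::predict(rf, X[test_rows, , drop = FALSE], type = "prob")[, "1"]
  })
}

#' Stratified fold assignment
#'
#' Ids of each class are shuffled and dealt round-robin, so fold sizes
#' differ by at most one per class and every class is present in every
#' fold whenever it has at least `folds` members.
#'
#' @param ids Identifiers to partition.
#' @param y Class labels aligned with `ids`.
#' @param folds Number of folds.
#' @param seed Seed making the assignment reproducible.
#' @return Integer fold index (1..folds) per id.
#' @export
stratified_folds <- function(ids, y, folds, seed) {
  fold <- integer(length(ids))
  with_seed(seed, {
    for (cl in unique(y)) {
      rows <- which(y == cl)
      fold[rows[sample(length(rows))]] <- rep_len(seq_len(folds), length(rows))
    }
  })
  if (any(vapply(split(y, fold), function(v) length(unique(v)) < 2, TRUE)))
    warning("some folds lack a class; metrics for them may be NA")
  fold
}

#' Cross-validated evaluation of prescription efficacy prediction
#'
#' Stratified k-fold protocol with rotating roles: fold t is the test set,
#' fold t+1 (mod k) the validation set, the remainder trains -- an 8:1:1
#' split at the default 10 folds. When augmentation is on, the adversarial
#' augmenter is fitted on the training folds only and generated nodes
#' never enter validation or test sets.
#'
#' @param graph A `hetero_graph` with labels.
#' @param efficacy Efficacy column to predict.
#' @param config A [train_config()].
#' @return A `metrics_report`: per-fold metrics plus mean and sd rows.
#' @export
crossvalidate <- function(graph, efficacy, config = train_config()) {
  graph <- apply_variant(graph, config$variant, config)
  real <- graph$nodes$prescription$id[
    graph$nodes$prescription$provenance == "original"]
  y <- graph$labels[real, efficacy]
  real <- real[!is.na(y)]; y <- y[!is.na(y)]
  if (sum(y == 1) < config$folds || sum(y == 0) < config$folds)
    stop("need at least `folds` prescriptions of each class")
  fold <- stratified_folds(real, y, config$folds, config$seed)
  per_fold <- vector("list", config$folds)
  for (t in seq_len(config$folds)) {
    v <- t %% config$folds + 1L
    test_ids <- real[fold == t]
    val_ids <- real[fold == v]
    train_ids <- real[fold != t & fold != v]
    if (config$variant == "S") {
      X <- graph$features$prescription[real, , drop = FALSE]
      sc <- rf_fold_scores(X, y, which(fold != t & fold != v),
                           which(fold == t), oversample = config$augmentation,
                           seed = config$seed + t)
      per_fold[[t]] <- evaluate_scores(y[fold == t], sc)
      next
    }
    g_t <- graph
    fit_train <- train_ids
    if (config$augmentation) {
      gcfg <- config$gan
      gcfg$seed <- config$seed + 97L * t
      aug <- augment_prescriptions(graph, efficacy, train_ids, gcfg,
                                   forbidden = config$forbidden)
      if (length(aug$records)) {
        g_t <- merge_generated(graph, aug$records, efficacy)
        gen_ids <- g_t$nodes$prescription$id[
          g_t$nodes$prescription$provenance == "generated"]
        fit_train <- c(train_ids, gen_ids)
      }
    }
    cfg_t <- config
    cfg_t$seed <- config$seed + 1000L * t
    model <- fit_rgat(g_t, efficacy, fit_train, val_ids, cfg_t)
    per_fold[[t]] <- evaluate_scores(graph$labels[test_ids, efficacy],
                                     model$scores[test_ids])
  }
  m <- do.call(rbind, per_fold)
  report <- data.frame(fold = c(as.character(seq_len(config$folds)),
                                "mean", "sd"),
                       rbind(m, colMeans(m, na.rm = TRUE),
                             apply(m, 2, stats::sd, na.rm = TRUE)))
  class(report) <- c("metrics_report", "data.frame")
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Mean row of a metrics report as a named vector
#' @param report A `metrics_report`.
#' @return Named numeric vector of mean metrics.
#' @export
report_means <- function(report) {
  r <- as.data.frame(report)
  unlist(r[r$fold == "mean", -1])
}

#' Run an ablation variant under the shared evaluation protocol
#'
#' `"R"` removes metabolite/target (and fingerprint) nodes and relations
#' before training; `"E"` swaps the sequence encoder backend; `"H"`
#' replaces the summed prescription feature by fixed-length concatenation
#' of herb features; `"S"` bypasses the graph entirely (SMOTE + random
#' forest on prescription features).
#'
#' @param variant One of `"full"`, `"R"`, `"E"`, `"H"`, `"S"`.
#' @param graph A `hetero_graph`.
#' @param efficacy Efficacy to predict.
#' @param config A [train_config()] (its `variant` field is overridden).
#' @return A `metrics_report`.
#' @export
run_ablation <- function(variant, graph, efficacy, config = train_config()) {
  config$variant <- match.arg(variant, c("full", "R", "E", "H", "S"))
  crossvalidate(graph, efficacy, config)
}

#' Write a metrics report as CSV (one row per fold plus summary rows)
#'
#' @param report A `metrics_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round(v, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
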