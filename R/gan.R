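# Adversarial generation of synthetic prescription nodes.
#
# One generator/discriminator pair is trained per (efficacy, label)
# stratum on rows [feature || prescription-herb adjacency]. The
# discriminator maximizes E log D(x) + E log(1 - D(G(z))); the generator
# is updated with the non-saturating form of the same objective. The
# generator's output head is identity on the feature slice (standardized
# features are unbounded) and sigmoid on the adjacency slice.

#' Configuration of the adversarial augmenter
#'
#' @param noise_dim Generator input noise dimension.
#' @param hidden_dim Width of the single hidden layer of both networks.
#' @param lr_discriminator Discriminator Adam learning rate (default 1e-5).
#' @param lr_ratio Generator/discriminator learning-rate ratio (default
#'   30, so the generator trains at 3e-4).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param per_class_counts Optional named vector of generation counts per
#'   label stratum; `NULL` means "generate enough minority records to
#'   balance the classes".
#' @param binarization `"threshold"` or `"top_k"` rule for turning soft
#'   adjacency rows into herb sets.
#' @param threshold Threshold for the `"threshold"` rule.
#' @param seed Integer seed; training is deterministic given it.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(noise_dim = 64L, hidden_dim = 128L,
                       lr_discriminator = 1e-5, lr_ratio = 30,
                       epochs = 500L, batch_size = 64L,
                       per_class_counts = NULL,
                       binarization = c("threshold", "top_k"),
                       threshold = 0.5, seed = 1L) {
  binarization <- match.arg(binarization)
  stopifnot(lr_ratio > 0, lr_discriminator > 0, epochs >= 0, noise_dim >= 1)
  if (!is.null(per_class_counts)) stopifnot(all(per_class_counts >= 0))
  structure(list(noise_dim = as.integer(noise_dim),
                 hidden_dim = as.integer(hidden_dim),
                 lr_discriminator = lr_discriminator, lr_ratio = lr_ratio,
                 lr_generator = lr_discriminator * lr_ratio,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 per_class_counts = per_class_counts,
                 binarization = binarization, threshold = threshold,
                 seed = as.integer(seed)),
            class = "gan_config")
}

gan_init <- function(config, data_dim) {
  h <- config$hidden_dim; nz <- config$noise_dim
  list(G.W1 = glorot(nz, h), G.b1 = matrix(0, 1, h),
       G.W2 = glorot(h, data_dim), G.b2 = matrix(0, 1, data_dim),
       D.W1 = glorot(data_dim, h), D.b1 = matrix(0, 1, h),
       D.W2 = glorot(h, 1), D.b2 = matrix(0, 1, 1))
}

# Generator forward on a tape; feature slice identity, adjacency sigmoid.
ad_generator <- function(tape, z, pn, feature_dim, adj_dim) {
  h <- ad_relu(tape, ad_add(tape, ad_mm(tape, z, pn$G.W1), pn$G.b1))
  raw <- ad_add(tape, ad_mm(tape, h, pn$G.W2), pn$G.b2)
  if (adj_dim == 0) return(raw)
  if (feature_dim == 0) return(ad_sigmoid(tape, raw))
  d <- feature_dim + adj_dim
  # split, activate adjacency, re-concatenate
  feat <- ad_push(tape, raw$value[, seq_len(feature_dim), drop = FALSE],
                  list(raw), function(g) {
                    G <- matrix(0, nrow(g), d); G[, seq_len(feature_dim)] <- g
                    list(G)
                  })
  adj <- ad_push(tape, raw$value[, feature_dim + seq_len(adj_dim), drop = FALSE],
                 list(raw), function(g) {
                   G <- matrix(0, nrow(g), d)
                   G[, feature_dim + seq_len(adj_dim)] <- g
                   list(G)
                 })
  ad_cbind(tape, list(feat, ad_sigmoid(tape, adj)))
}

ad_discriminator_logits <- function(tape, x, pn) {
  h <- ad_relu(tape, ad_add(tape, ad_mm(tape, x, pn$D.W1), pn$D.b1))
  ad_add(tape, ad_mm(tape, h, pn$D.W2), pn$D.b2)
}

#' Train a generative adversarial pair on prescription rows
#'
#' Alternating minimax updates on rows `[feature || adjacency]`. The
#' discriminator output is a sigmoid, strictly inside (0, 1); the loss
#' trace is checked finite each epoch and training aborts with a
#' diagnostic of the last batch on NaN.
#'
#' @param features Real feature matrix (n x f); may have zero columns.
#' @param adjacency Real soft/binary adjacency matrix (n x H) or `NULL`.
#' @param config A [gan_config()].
#' @return List of class `gan_model`: parameter list, slice dims, per-epoch
#'   `trace` (data.frame of discriminator/generator losses), and the
#'   config.
#' @export
train_gan <- function(features, adjacency = NULL, config = gan_config()) {
  features <- as.matrix(features)
  if (is.null(adjacency)) adjacency <- matrix(0, nrow(features), 0)
  adjacency <- as.matrix(adjacency)
  n <- nrow(features)
  if (n == 0) stop("empty real data")
  stopifnot(nrow(adjacency) == n)
  fdim <- ncol(features); adim <- ncol(adjacency)
  X <- cbind(features, adjacency)
  with_seed(config$seed, {
    params <- gan_init(config, fdim + adim)
    # warm start: generator output bias at the real stratum's marginal
    # statistics (feature means; adjacency log-odds), so adversarial
    # refinement starts from the right neighborhood of data space
    warm <- c(if (fdim) colMeans(features),
              if (adim) stats::qlogis(pmin(pmax(colMeans(adjacency), 0.02), 0.98)))
    params$G.b2 <- matrix(warm, 1)
    optD <- make_adam(lr = config$lr_discriminator)
    optG <- make_adam(lr = config$lr_generator)
    dn <- c("D.W1", "D.b1", "D.W2", "D.b2")
    gn <- c("G.W1", "G.b1", "G.W2", "G.b2")
    trace <- data.frame(epoch = integer(0), d_loss = numeric(0),
                        g_loss = numeric(0))
    if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      bs <- min(config$batch_size, n)
      dl <- gl <- 0; nb <- 0L
      for (start in seq(1, n, by = bs)) {
        batch <- X[ord[start:min(start + bs - 1, n)], , drop = FALSE]
        m <- nrow(batch)
        z <- matrix(stats::rnorm(m * config$noise_dim), m)
        # --- discriminator step (generator frozen) ---
        tape <- new_tape()
        pn <- ad_params(tape, params)
        for (nm in gn) pn[[nm]]$track <- FALSE
        fake <- ad_generator(tape, ad_input(tape, z), pn, fdim, adim)
        logits <- ad_rbind(tape, list(
          ad_discriminator_logits(tape, ad_input(tape, batch), pn),
          ad_discriminator_logits(tape, fake, pn)))
        dloss <- ad_bce_logits(tape, logits, c(rep(1, m), rep(0, m)))
        ad_backward(tape, dloss)
        gD <- ad_grads(pn[dn])
        params[dn] <- optD(params[dn], gD)
        # --- generator step (discriminator frozen) ---
        z <- matrix(stats::rnorm(m * config$noise_dim), m)
        tape <- new_tape()
        pn <- ad_params(tape, params)
        for (nm in dn) pn[[nm]]$track <- FALSE
        fake <- ad_generator(tape, ad_input(tape, z), pn, fdim, adim)
        glogit <- ad_discriminator_logits(tape, fake, pn)
        gloss <- ad_bce_logits(tape, glogit, rep(1, m))
        ad_backward(tape, gloss)
        params[gn] <- optG(params[gn], ad_grads(pn[gn]))
        dv <- ad_value(dloss)[1, 1]; gv <- ad_value(gloss)[1, 1]
        if (!is.finite(dv) || !is.finite(gv))
          stop(sprintf("NaN in GAN loss at epoch %d (batch starting %d)",
                       ep, start))
        dl <- dl + dv; gl <- gl + gv; nb <- nb + 1L
      }
      trace <- rbind(trace, data.frame(epoch = ep, d_loss = dl / nb,
                                       g_loss = gl / nb))
    }
    structure(list(params = params, feature_dim = fdim, adj_dim = adim,
                   trace = trace, config = config),
              class = "gan_model")
  })
}

#' Discriminator scores for data rows
#'
#' @param model A trained `gan_model`.
#' @param x Data matrix (features and adjacency concatenated).
#' @return Vector of probabilities, strictly in (0, 1).
#' @export
discriminate <- function(model, x) {
  tape <- new_tape()
  pn <- ad_params(tape, model$params)
  as.vector(ad_value(ad_sigmoid(tape, ad_discriminator_logits(
    tape, ad_input(tape, as.matrix(x)), pn))))
}

#' Sample synthetic rows from a trained generator
#'
#' @param model A trained `gan_model`.
#' @param count Number of rows.
#' @param seed Seed for the noise draw.
#' @return List with `features` and soft `adjacency` matrices.
#' @export
gan_sample <- function(model, count, seed = 1L) {
  if (count < 0) stop("count must be >= 0")
  d <- model$feature_dim + model$adj_dim
  if (count == 0) return(list(features = matrix(0, 0, model$feature_dim),
                              adjacency = matrix(0, 0, model$adj_dim)))
  with_seed(seed, {
    z <- matrix(stats::rnorm(count * model$config$noise_dim), count)
    tape <- new_tape()
    pn <- ad_params(tape, model$params)
    out <- ad_value(ad_generator(tape, ad_input(tape, z), pn,
                                 model$feature_dim, model$adj_dim))
    list(features = out[, seq_len(model$feature_dim), drop = FALSE],
         adjacency = out[, model$feature_dim + seq_len(model$adj_dim),
                         drop = FALSE])
  })
}

#' Binarize a soft adjacency row into a herb index set
#'
#' `"threshold"` keeps indices strictly above the threshold; `"top_k"`
#' keeps the k largest entries. An empty result falls back to the single
#' largest entry (first index on ties), so the returned set is never
#' empty.
#'
#' @param soft_row Numeric vector with entries in `[0, 1]`.
#' @param rule `"threshold"` or `"top_k"`.
#' @param threshold Cutoff for the threshold rule.
#' @param k Set size for the top-k rule.
#' @return Integer vector of kept indices (1-based), non-empty.
#' @export
binarize_adjacency <- function(soft_row, rule = c("threshold", "top_k"),
                               threshold = 0.5, k = NULL) {
  rule <- match.arg(rule)
  if (any(soft_row < 0 | soft_row > 1))
    stop("soft adjacency entries must lie in [0, 1]")
  idx <- if (rule == "threshold") {
    which(soft_row > threshold)
  } else {
    if (is.null(k)) stop("top_k rule requires k")
    k <- min(max(1L, as.integer(k)), length(soft_row))
    order(soft_row, decreasing = TRUE)[seq_len(k)]
  }
  if (!length(idx)) idx <- which.max(soft_row)
  sort(as.integer(idx))
}

#' Generate synthetic prescription records for one efficacy stratum
#'
#' Draws `count` rows from a trained generator and binarizes each soft
#' adjacency row into a non-empty herb set. Records carry the stratum
#' label, the generated feature vector, the soft adjacency row, and
#' `provenance = "generated"`.
#'
#' @param model A trained `gan_model` whose adjacency slice spans
#'   `herb_ids`.
#' @param efficacy Efficacy name the stratum belongs to.
#' @param label 0/1 label of the stratum.
#' @param count Number of records to generate (before pruning).
#' @param herb_ids Character vector naming the herb universe (adjacency
#'   columns).
#' @param binarization,threshold,k Passed to [binarize_adjacency()]; for
#'   `"top_k"`, `k` may be a vector of candidate sizes (e.g. the empirical
#'   herbs-per-prescription counts) sampled per record.
#' @param seed Seed for generation.
#' @return List of synthetic prescription records.
#' @export
generate_prescriptions <- function(model, efficacy, label, count, herb_ids,
                                   binarization = model$config$binarization,
                                   threshold = model$config$threshold,
                                   k = NULL, seed = 1L) {
  if (count < 0) stop("count must be >= 0")
  if (count == 0) return(list())
  stopifnot(length(herb_ids) == model$adj_dim)
  smp <- gan_sample(model, count, seed = seed)
  ks <- if (!is.null(k)) {
    if (length(k) == 1L) rep(k, count)
    else with_seed(seed + 1L, sample(k, count, replace = TRUE))
  }
  lapply(seq_len(count), function(i) {
    idx <- binarize_adjacency(smp$adjacency[i, ], binarization,
                              threshold = threshold, k = ks[i])
    list(label = as.integer(label), efficacy = efficacy,
         feature = smp$features[i, ], soft_adjacency = smp$adjacency[i, ],
         herb_ids = herb_ids[idx], provenance = "generated")
  })
}

#' Remove generated prescriptions containing forbidden herb pairs
#'
#' A record is removed iff its herb set contains both members of any
#' forbidden pair; matching is order-insensitive. Pairs referencing ids
#' absent from the herb universe are skipped with a warning.
#'
#' @param items List of synthetic prescription records.
#' @param pairs Data.frame with columns `herb_id_a`, `herb_id_b`.
#' @param herb_ids Optional herb universe used to validate the pair table.
#' @return List with `kept` (surviving records) and `removed` (count).
#' @export
prune_incompatible <- function(items, pairs, herb_ids = NULL) {
  if (is.null(pairs) || !nrow(pairs)) return(list(kept = items, removed = 0L))
  if (!is.null(herb_ids)) {
    known <- pairs$herb_id_a %in% herb_ids & pairs$herb_id_b %in% herb_ids
    if (any(!known)) {
      warning(sum(!known), " forbidden pair(s) reference unknown herb ids; skipped")
      pairs <- pairs[known, , drop = FALSE]
    }
  }
  if (!nrow(pairs)) return(list(kept = items, removed = 0L))
  hit <- vapply(items, function(r) {
    hs <- r$herb_ids
    any(pairs$herb_id_a %in% hs & pairs$herb_id_b %in% hs)
  }, logical(1))
  list(kept = items[!hit], removed = sum(hit))
}

#' Fit the augmenter on training prescriptions and generate the shortfall
#'
#' High-level convenience wrapper used by cross-validation: trains one GAN
#' per minority stratum of the requested efficacy on the supplied training
#' prescriptions only, generates enough records to balance the classes (or
#' the explicitly configured counts), binarizes with a top-k rule driven by
#' the empirical herbs-per-prescription distribution, and prunes forbidden
#' pairs. A post-pruning shortfall is accepted and reported.
#'
#' @param graph A `hetero_graph` (features and herb sets supply the real
#'   rows).
#' @param efficacy Efficacy name to rebalance.
#' @param train_ids Prescription ids the augmenter may see.
#' @param config A [gan_config()].
#' @param forbidden Optional forbidden-pair data.frame.
#' @return List with `records`, the per-stratum `requested` and `pruned`
#'   counts, and the trained `models`.
#' @export
augment_prescriptions <- function(graph, efficacy, train_ids,
                                  config = gan_config(),
                                  forbidden = NULL) {
  labs <- graph$labels[train_ids, efficacy]
  train_ids <- train_ids[!is.na(labs)]
  labs <- labs[!is.na(labs)]
  herb_ids <- graph$nodes$herb$id
  adj <- t(vapply(graph$herb_sets[train_ids],
                  function(hs) as.numeric(herb_ids %in% hs),
                  numeric(length(herb_ids))))
  feats <- graph$features$prescription[train_ids, , drop = FALSE]
  tab <- table(factor(labs, c(0, 1)))
  counts <- config$per_class_counts
  if (is.null(counts)) {
    counts <- c("0" = max(0L, tab[["1"]] - tab[["0"]]),
                "1" = max(0L, tab[["0"]] - tab[["1"]]))
  }
  kk <- lengths(graph$herb_sets[train_ids])
  records <- list(); models <- list()
  requested <- 0L; pruned <- 0L
  for (lab in c("0", "1")) {
    cnt <- counts[[lab]] %||% 0L
    if (is.na(cnt) || cnt <= 0) next
    rows <- labs == as.integer(lab)
    if (!any(rows)) next
    model <- train_gan(feats[rows, , drop = FALSE], adj[rows, , drop = FALSE],
                       config)
    recs <- generate_prescriptions(model, efficacy, as.integer(lab), cnt,
                                   herb_ids, binarization = "top_k",
                                   k = kk, seed = config$seed + as.integer(lab))
    pr <- prune_incompatible(recs, forbidden, herb_ids)
    records <- c(records, pr$kept)
    requested <- requested + cnt
    pruned <- pruned + pr$removed
    models[[lab]] <- model
  }
  list(records = records, requested = requested, pruned = pruned,
       models = models)
}
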