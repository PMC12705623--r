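# Shared fixtures and independent oracles.

# Small synthetic dataset -> cleaned hetero graph, one call.
tiny_graph <- function(seed = 3L, n_prescriptions = 60L, n_herbs = 20L,
                       n_metabolites = 30L, n_targets = 30L, ...) {
  cfg <- synth_config(n_prescriptions = n_prescriptions, n_herbs = n_herbs,
                      n_metabolites = n_metabolites, n_targets = n_targets,
                      seed = seed, ...)
  ds <- generate_synthetic_dataset(cfg)
  g <- build_graph(ds$prescriptions, ds$herbs, ds$metabolites, ds$targets,
                   ds$herb_metabolite, ds$metabolite_target,
                   embedding_spec = sequence_embedding_spec(dim = 16L))
  list(graph = drop_unsequenced(g), dataset = ds)
}

# Random dense small graph for layer-level tests: n nodes, every node has a
# self loop plus random edges over `n_rel` relation types.
random_small_graph <- function(n, n_rel = 2L, d = 6L, seed = 1L,
                               p_edge = 0.5) {
  withr::local_seed(seed)
  rels <- c(paste0("rel", seq_len(n_rel)), "self")
  src <- integer(0); dst <- integer(0); rel <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (runif(1) < p_edge) {
      src <- c(src, j); dst <- c(dst, i)
      rel <- c(rel, sample(rels[seq_len(n_rel)], 1))
    }
  }
  src <- c(src, seq_len(n)); dst <- c(dst, seq_len(n))
  rel <- c(rel, rep("self", n))
  list(features = matrix(rnorm(n * d), n, d),
       edges = data.frame(src = src, dst = dst, relation = rel,
                          stringsAsFactors = FALSE),
       relations = rels)
}

# Independent dense reference implementation of one relational attention
# layer: explicit per-node loops, full softmax, no shared code with the
# package's segment-based path.
dense_rgat_layer <- function(features, edges, params, config, layer = 1L) {
  n <- nrow(features)
  K <- config$attention_heads; M <- config$relation_heads
  h_att <- NULL
  for (k in seq_len(K)) {
    Wq <- params[[sprintf("L%d.att%d.Wq", layer, k)]]
    Wk <- params[[sprintf("L%d.att%d.Wk", layer, k)]]
    Wv <- params[[sprintf("L%d.att%d.Wv", layer, k)]]
    Q <- features %*% Wq; Kx <- features %*% Wk; V <- features %*% Wv
    out <- matrix(0, n, ncol(Wv))
    for (i in seq_len(n)) {
      nb <- edges$src[edges$dst == i]
      s <- vapply(nb, function(j) sum(Q[i, ] * Kx[j, ]), 0) / sqrt(ncol(Wq))
      a <- exp(s - max(s)); a <- a / sum(a)
      for (t in seq_along(nb)) out[i, ] <- out[i, ] + a[t] * V[nb[t], ]
    }
    h_att <- cbind(h_att, out)
  }
  h_rel <- NULL
  for (m in seq_len(M)) {
    W1 <- params[[sprintf("L%d.rel%d.W1", layer, m)]]
    b1 <- params[[sprintf("L%d.rel%d.b1", layer, m)]]
    W2 <- params[[sprintf("L%d.rel%d.W2", layer, m)]]
    b2 <- params[[sprintf("L%d.rel%d.b2", layer, m)]]
    Wv <- params[[sprintf("L%d.rel%d.Wv", layer, m)]]
    V <- features %*% Wv
    out <- matrix(0, n, ncol(Wv))
    for (i in seq_len(n)) {
      rows <- which(edges$dst == i)
      g <- vapply(rows, function(e) {
        r <- params$rel_emb[edges$relation[e], , drop = FALSE]
        inner <- pmax(r %*% W1 + as.vector(b1), 0)
        1 / (1 + exp(-(inner %*% W2 + as.vector(b2))))
      }, 0)
      b <- exp(g - max(g)); b <- b / sum(b)
      for (t in seq_along(rows))
        out[i, ] <- out[i, ] + b[t] * V[edges$src[rows[t]], ]
    }
    h_rel <- cbind(h_rel, out)
  }
  x <- cbind(h_att, h_rel)
  W <- params[[sprintf("L%d.out.W", layer)]]
  b <- params[[sprintf("L%d.out.b", layer)]]
  pmax(sweep(x %*% W, 2, as.vector(b), "+"), 0)
}

# Layer parameters for an arbitrary relation set (projections included so
# rgat_init's contract is satisfied).
layer_params <- function(config, d, relations) {
  rgat_init(config, type_dims = list(x = d), relations = relations)
}

# Brute-force all-pairs AUC (concordant-pair fraction, ties 0.5).
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
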