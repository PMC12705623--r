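# Relational graph attention message passing.
#
# Each layer combines (a) multi-head scaled-dot attention over a node's
# in-neighborhood -- per head a convex combination of transformed neighbor
# features, heads concatenated -- and (b) relation attention, where every
# edge's relation type has a learned embedding scored by a two-layer
# transform (relu inner, sigmoid outer), normalized over the neighborhood
# and used to weight per-relation-head transformed neighbor features. The
# two blocks are concatenated and projected through relu. Self-loops (their
# own relation type) make every neighborhood non-empty.

#' Configuration of the relational graph attention network
#'
#' @param num_layers Number of stacked layers (default 2).
#' @param hidden_dim Hidden width (default 512); must be divisible by both
#'   head counts.
#' @param attention_heads Number of node-attention heads K (default 4).
#' @param relation_heads Number of relation-attention heads M (default 4).
#' @param relation_dim Dimension of the learned relation embeddings.
#' @param dropout Dropout rate applied to layer inputs during training.
#' @param seed Seed for parameter initialization.
#' @return A list of class `rgat_config`.
#' @export
rgat_config <- function(num_layers = 2L, hidden_dim = 512L,
                        attention_heads = 4L, relation_heads = 4L,
                        relation_dim = 32L, dropout = 0, seed = 1L) {
  stopifnot(num_layers >= 1, hidden_dim >= 1, attention_heads >= 1,
            relation_heads >= 1)
  if (hidden_dim %% attention_heads != 0)
    stop("hidden_dim must be divisible by attention_heads")
  if (hidden_dim %% relation_heads != 0)
    stop("hidden_dim must be divisible by relation_heads")
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 attention_heads = as.integer(attention_heads),
                 relation_heads = as.integer(relation_heads),
                 relation_dim = as.integer(relation_dim),
                 dropout = dropout, seed = as.integer(seed)),
            class = "rgat_config")
}

# Flatten a hetero_graph into global index arrays for message passing.
# Self-loop edges (relation "self") are appended for every node.
graph_index <- function(graph) {
  types <- names(graph$nodes)
  sizes <- vapply(types, function(t) nrow(graph$nodes[[t]]), integer(1))
  offsets <- c(0L, cumsum(sizes))[seq_along(types)]
  names(offsets) <- types
  gid <- function(type, id) {
    offsets[type] + match(id, graph$nodes[[type]]$id)
  }
  e <- graph$edges
  src_g <- integer(nrow(e)); dst_g <- integer(nrow(e))
  for (t in types) {
    is_s <- e$src_type == t
    src_g[is_s] <- offsets[t] + match(e$src[is_s], graph$nodes[[t]]$id)
    is_d <- e$dst_type == t
    dst_g[is_d] <- offsets[t] + match(e$dst[is_d], graph$nodes[[t]]$id)
  }
  if (anyNA(src_g) || anyNA(dst_g)) stop("edge endpoint missing from node tables")
  n <- sum(sizes)
  src <- c(src_g, seq_len(n))
  dst <- c(dst_g, seq_len(n))
  rel <- c(e$relation, rep("self", n))
  rel_levels <- sort(unique(rel))
  list(types = types, sizes = sizes, offsets = offsets, n = n,
       src = src, dst = dst, rel = factor(rel, rel_levels),
       rel_levels = rel_levels, gid = gid,
       type_dims = lapply(graph$features, ncol))
}

#' Initialize RGAT parameters
#'
#' Creates per-type input projections (linear, no bias), relation
#' embeddings, and per-layer attention, relation-attention and output
#' projection weights, all glorot-initialized from `config$seed`.
#'
#' @param config An [rgat_config()].
#' @param type_dims Named list of input feature dimensions per node type.
#' @param relations Character vector of relation type names (including
#'   `"self"`).
#' @return Flat named list of parameter matrices.
#' @export
rgat_init <- function(config, type_dims, relations) {
  h <- config$hidden_dim
  K <- config$attention_heads; M <- config$relation_heads
  dh <- h %/% K; dm <- h %/% M; dr <- config$relation_dim
  with_seed(config$seed, {
    p <- list()
    for (t in names(type_dims)) p[[paste0("proj.", t)]] <- glorot(type_dims[[t]], h)
    p$rel_emb <- matrix(stats::rnorm(length(relations) * dr, sd = 0.1),
                        length(relations), dr,
                        dimnames = list(relations, NULL))
    for (l in seq_len(config$num_layers)) {
      for (k in seq_len(K)) {
        p[[sprintf("L%d.att%d.Wq", l, k)]] <- glorot(h, dh)
        p[[sprintf("L%d.att%d.Wk", l, k)]] <- glorot(h, dh)
        p[[sprintf("L%d.att%d.Wv", l, k)]] <- glorot(h, dh)
      }
      for (m in seq_len(M)) {
        p[[sprintf("L%d.rel%d.W1", l, m)]] <- glorot(dr, dr)
        p[[sprintf("L%d.rel%d.b1", l, m)]] <- matrix(0, 1, dr)
        p[[sprintf("L%d.rel%d.W2", l, m)]] <- glorot(dr, 1)
        p[[sprintf("L%d.rel%d.b2", l, m)]] <- matrix(0, 1, 1)
        p[[sprintf("L%d.rel%d.Wv", l, m)]] <- glorot(h, dm)
      }
      p[[sprintf("L%d.out.W", l)]] <- glorot(2L * h, h)
      p[[sprintf("L%d.out.b", l)]] <- matrix(0, 1, h)
    }
    p$head.W <- glorot(h, 2L)
    p$head.b <- matrix(0, 1, 2)
    p
  })
}

# ---- layer blocks (autodiff) ----------------------------------------------

# Multi-head node attention: returns list(node = N x hidden AD node,
# alpha = list of per-head weight vectors over edges).
ad_node_attention <- function(tape, H, src, dst, n, pn, layer, K) {
  heads <- vector("list", K); alphas <- vector("list", K)
  for (k in seq_len(K)) {
    Wq <- pn[[sprintf("L%d.att%d.Wq", layer, k)]]
    Wk <- pn[[sprintf("L%d.att%d.Wk", layer, k)]]
    Wv <- pn[[sprintf("L%d.att%d.Wv", layer, k)]]
    dh <- ncol(Wq$value)
    Q <- ad_mm(tape, H, Wq); Kx <- ad_mm(tape, H, Wk); V <- ad_mm(tape, H, Wv)
    s <- ad_scale(tape, ad_rowdot(tape, ad_gather_rows(tape, Q, dst),
                                  ad_gather_rows(tape, Kx, src)), 1 / sqrt(dh))
    a <- ad_segment_softmax(tape, s, dst, n)
    msg <- ad_scale_rows(tape, ad_gather_rows(tape, V, src), a)
    heads[[k]] <- ad_segment_sum(tape, msg, dst, n)
    alphas[[k]] <- as.vector(ad_value(a))
  }
  list(node = ad_cbind(tape, heads), alpha = alphas)
}

# Relation attention: scores every edge from its relation embedding via the
# two-layer transform, softmax over neighborhoods, weights per-relation-head
# transformed neighbor features.
ad_relation_attention <- function(tape, H, src, dst, rel_idx, rel_emb_node,
                                  n, pn, layer, M) {
  r_e <- ad_gather_rows(tape, rel_emb_node, rel_idx)
  heads <- vector("list", M); betas <- vector("list", M)
  for (m in seq_len(M)) {
    W1 <- pn[[sprintf("L%d.rel%d.W1", layer, m)]]
    b1 <- pn[[sprintf("L%d.rel%d.b1", layer, m)]]
    W2 <- pn[[sprintf("L%d.rel%d.W2", layer, m)]]
    b2 <- pn[[sprintf("L%d.rel%d.b2", layer, m)]]
    Wv <- pn[[sprintf("L%d.rel%d.Wv", layer, m)]]
    inner <- ad_relu(tape, ad_add(tape, ad_mm(tape, r_e, W1), b1))
    gsc <- ad_sigmoid(tape, ad_add(tape, ad_mm(tape, inner, W2), b2))
    b <- ad_segment_softmax(tape, gsc, dst, n)
    msg <- ad_scale_rows(tape, ad_gather_rows(tape, ad_mm(tape, H, Wv), src), b)
    heads[[m]] <- ad_segment_sum(tape, msg, dst, n)
    betas[[m]] <- as.vector(ad_value(b))
  }
  list(node = ad_cbind(tape, heads), beta = betas)
}

# One full layer: concat(node attention, relation attention) -> linear -> relu
ad_rgat_layer <- function(tape, H, idx, pn, layer, config) {
  att <- ad_node_attention(tape, H, idx$src, idx$dst, idx$n, pn, layer,
                           config$attention_heads)
  rel <- ad_relation_attention(tape, H, idx$src, idx$dst,
                               as.integer(idx$rel), pn$rel_emb, idx$n, pn,
                               layer, config$relation_heads)
  x <- ad_cbind(tape, list(att$node, rel$node))
  out <- ad_relu(tape, ad_add(tape, ad_mm(tape, x, pn[[sprintf("L%d.out.W", layer)]]),
                              pn[[sprintf("L%d.out.b", layer)]]))
  if (!all(is.finite(ad_value(out))))
    stop("non-finite activations at layer ", layer)
  list(out = out, alpha = att$alpha, beta = rel$beta)
}

# Project per-type input features to the common hidden dimension and stack
# them in global node order.
ad_project_inputs <- function(tape, feats, idx, pn) {
  rows <- vector("list", length(idx$types))
  for (i in seq_along(idx$types)) {
    t <- idx$types[i]
    Ft <- ad_input(tape, feats[[t]])
    rows[[i]] <- ad_mm(tape, Ft, pn[[paste0("proj.", t)]])
  }
  # vertical stacking via gather on a block matrix is wasteful; build by
  # concatenating backward-aware: stack with a dedicated node
  ad_rbind(tape, rows)
}

# Full forward pass; returns the final representation node plus attention
# records for every layer and head.
ad_rgat_forward <- function(tape, feats, idx, pn, config, training = FALSE) {
  H <- ad_project_inputs(tape, feats, idx, pn)
  records <- list()
  for (l in seq_len(config$num_layers)) {
    if (training && config$dropout > 0) H <- ad_dropout(tape, H, config$dropout)
    res <- ad_rgat_layer(tape, H, idx, pn, l, config)
    H <- res$out
    for (k in seq_along(res$alpha))
      records[[length(records) + 1L]] <- data.frame(
        src = idx$src, dst = idx$dst, relation = as.character(idx$rel),
        layer = l, head = k, kind = "node", weight = res$alpha[[k]],
        stringsAsFactors = FALSE)
    for (m in seq_along(res$beta))
      records[[length(records) + 1L]] <- data.frame(
        src = idx$src, dst = idx$dst, relation = as.character(idx$rel),
        layer = l, head = m, kind = "relation", weight = res$beta[[m]],
        stringsAsFactors = FALSE)
  }
  list(H = H, attention = do.call(rbind, records))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`; every softmax row sums to one.
#'
#' @param Q n x d_k query matrix.
#' @param K m x d_k key matrix.
#' @param V m x d_v value matrix.
#' @return n x d_v matrix.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have matching rows")
  if (ncol(Q) == 0) stop("key dimension must be positive")
  softmax_rows(Q %*% t(K) / sqrt(ncol(Q))) %*% V
}

#' Multi-head node attention over explicit neighborhoods
#'
#' Reference entry point for the node-attention block on a plain edge list:
#' per head, each destination's update is a convex combination of its
#' in-neighbors' value-transformed features with scaled-dot weights; head
#' outputs are concatenated. Destinations without an in-edge are an error
#' (the full network adds self-loops so the situation never arises there).
#'
#' @param features N x d node feature matrix.
#' @param edges Data.frame with integer columns `src`, `dst` (1-based).
#' @param params List of K per-head lists with matrices `Wq`, `Wk`, `Wv`.
#' @return List with `h_att` (N x sum of head dims) and `alpha`
#'   (edge weights per head).
#' @export
node_attention_aggregate <- function(features, edges, params) {
  n <- nrow(features)
  if (!all(seq_len(n) %in% edges$dst))
    stop("every node needs at least one in-neighbor (add self-loops)")
  tape <- new_tape()
  H <- ad_input(tape, features)
  pn <- list()
  for (k in seq_along(params)) {
    pn[[sprintf("L1.att%d.Wq", k)]] <- ad_input(tape, params[[k]]$Wq)
    pn[[sprintf("L1.att%d.Wk", k)]] <- ad_input(tape, params[[k]]$Wk)
    pn[[sprintf("L1.att%d.Wv", k)]] <- ad_input(tape, params[[k]]$Wv)
  }
  res <- ad_node_attention(tape, H, edges$src, edges$dst, n, pn, 1L,
                           length(params))
  list(h_att = ad_value(res$node), alpha = res$alpha)
}

#' Relation attention over explicit neighborhoods
#'
#' Scores each edge purely from its relation-type embedding through the
#' two-layer transform (relu inner, sigmoid outer), normalizes the scores
#' over each destination's neighborhood, and aggregates per-relation-head
#' value-transformed neighbor features.
#'
#' @param features N x d node feature matrix.
#' @param edges Data.frame with `src`, `dst` (integer) and `relation`
#'   (character).
#' @param rel_emb Relation embedding matrix with relation names as
#'   rownames.
#' @param params List of M per-head lists with `W1`, `b1`, `W2`, `b2`,
#'   `Wv`.
#' @return List with `h_rel` and per-head `beta` edge weights.
#' @export
relation_attention <- function(features, edges, rel_emb, params) {
  n <- nrow(features)
  miss <- setdiff(unique(edges$relation), rownames(rel_emb))
  if (length(miss)) stop("missing relation embedding for: ",
                         paste(miss, collapse = ", "))
  if (!all(seq_len(n) %in% edges$dst))
    stop("every node needs at least one in-neighbor (add self-loops)")
  tape <- new_tape()
  H <- ad_input(tape, features)
  pn <- list(rel_emb = ad_input(tape, rel_emb))
  for (m in seq_along(params)) {
    for (nm in c("W1", "b1", "W2", "b2", "Wv"))
      pn[[sprintf("L1.rel%d.%s", m, nm)]] <- ad_input(tape, params[[m]][[nm]])
  }
  ridx <- match(edges$relation, rownames(rel_emb))
  res <- ad_relation_attention(tape, H, edges$src, edges$dst, ridx,
                               pn$rel_emb, n, pn, 1L, length(params))
  list(h_rel = ad_value(res$node), beta = res$beta)
}

#' Apply one full relational graph attention layer
#'
#' @param features N x hidden matrix (already projected to the layer
#'   width).
#' @param edges Data.frame with `src`, `dst`, `relation`.
#' @param params Flat parameter list as produced by [rgat_init()] (layer 1
#'   entries are used).
#' @param config An [rgat_config()].
#' @param layer Which layer's parameters to apply.
#' @return List with the updated `features` and the per-head `alpha` and
#'   `beta` edge weights.
#' @export
rgat_layer <- function(features, edges, params, config, layer = 1L) {
  n <- nrow(features)
  tape <- new_tape()
  pn <- lapply(params, function(p) ad_input(tape, p))
  idx <- list(src = edges$src, dst = edges$dst,
              rel = factor(edges$relation, rownames(params$rel_emb)),
              n = n)
  H <- ad_input(tape, features)
  res <- ad_rgat_layer(tape, H, idx, pn, layer, config)
  list(features = ad_value(res$out), alpha = res$alpha, beta = res$beta)
}

#' Project heterogeneous per-type features to a common dimension
#'
#' One learned linear projection (no bias) per node type; types are stacked
#' in the graph's global node order.
#'
#' @param features Named list of per-type feature matrices.
#' @param params Flat parameter list containing `proj.<type>` matrices.
#' @return Stacked numeric matrix.
#' @export
project_inputs <- function(features, params) {
  do.call(rbind, lapply(names(features), function(t) {
    W <- params[[paste0("proj.", t)]]
    if (is.null(W)) stop("no projection for node type: ", t)
    unname(features[[t]] %*% W)
  }))
}

#' Run the relational graph attention network over a heterogeneous graph
#'
#' Deterministic given `config$seed` (parameters) and the graph; returns
#' the final node representations together with all attention records,
#' which downstream interpretation tools consume.
#'
#' @param graph A `hetero_graph` with features attached.
#' @param config An [rgat_config()].
#' @param params Optional pre-trained parameters (defaults to a fresh
#'   [rgat_init()]).
#' @return List with `H` (all node representations, global order),
#'   `attention` (data.frame of src/dst/relation/layer/head/kind/weight),
#'   `index` (the global node index) and `params`.
#' @export
rgat_forward <- function(graph, config = rgat_config(), params = NULL) {
  idx <- graph_index(graph)
  if (is.null(params))
    params <- rgat_init(config, idx$type_dims, idx$rel_levels)
  tape <- new_tape()
  pn <- lapply(params, function(p) ad_input(tape, p))
  res <- ad_rgat_forward(tape, graph$features, idx, pn, config)
  list(H = ad_value(res$H), attention = res$attention, index = idx,
       params = params)
}
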