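test_that("scaled dot attention matches hand arithmetic", {
  # single key-value pair: output is V's row for every query
  Q <- matrix(rnorm(6), 3, 2)
  out <- scaled_dot_attention(Q, matrix(c(1, 0), 1), matrix(c(3, 7), 1))
  expect_equal(out, matrix(rep(c(3, 7), each = 3), 3))
  # identical keys: uniform weights, output = column mean of V
  K <- matrix(1, 4, 2); V <- matrix(1:8, 4, 2)
  expect_equal(scaled_dot_attention(matrix(c(1, 2), 1), K, V),
               matrix(colMeans(V), 1))
  # hand-computed two-key case
  out <- scaled_dot_attention(matrix(c(1, 0), 1),
                              rbind(c(1, 0), c(0, 1)), matrix(c(1, 0), 2))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(out[1, 1], w1, tolerance = 1e-5)
  expect_equal(round(out[1, 1], 5), 0.66976)
})

test_that("node attention is convex over neighbors", {
  cfg <- rgat_config(num_layers = 1, hidden_dim = 4, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 2)
  p <- layer_params(cfg, 4, c("rel1", "self"))
  heads <- lapply(1:2, function(k) list(
    Wq = p[[sprintf("L1.att%d.Wq", k)]],
    Wk = p[[sprintf("L1.att%d.Wk", k)]],
    Wv = p[[sprintf("L1.att%d.Wv", k)]]))
  X <- matrix(rnorm(12), 3, 4)
  # node 1's single neighbor is node 2: per-head output = transformed
  # neighbor feature
  edges <- data.frame(src = c(2L, 1L, 2L, 3L), dst = c(1L, 2L, 3L, 3L))
  res <- node_attention_aggregate(X, edges, heads)
  expect_equal(res$h_att[1, ],
               c(X[2, ] %*% heads[[1]]$Wv, X[2, ] %*% heads[[2]]$Wv),
               tolerance = 1e-10)
  # identical neighbors behave like a single neighbor
  X2 <- X; X2[3, ] <- X2[2, ]
  edges2 <- data.frame(src = c(2L, 3L, 1L, 1L), dst = c(1L, 1L, 2L, 3L))
  res2 <- node_attention_aggregate(X2, edges2, heads)
  expect_equal(res2$h_att[1, ],
               c(X2[2, ] %*% heads[[1]]$Wv, X2[2, ] %*% heads[[2]]$Wv),
               tolerance = 1e-10)
  expect_error(node_attention_aggregate(X, data.frame(src = 1L, dst = 2L),
                                        heads), "self-loops")
})

test_that("relation attention normalizes scores over each neighborhood", {
  cfg <- rgat_config(num_layers = 1, hidden_dim = 4, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 3)
  rels <- c("rel1", "rel2", "self")
  p <- layer_params(cfg, 4, rels)
  heads <- lapply(1:2, function(m) list(
    W1 = p[[sprintf("L1.rel%d.W1", m)]], b1 = p[[sprintf("L1.rel%d.b1", m)]],
    W2 = p[[sprintf("L1.rel%d.W2", m)]], b2 = p[[sprintf("L1.rel%d.b2", m)]],
    Wv = p[[sprintf("L1.rel%d.Wv", m)]]))
  X <- matrix(rnorm(12), 3, 4)
  # all neighbors share one relation -> uniform weights
  edges <- data.frame(src = c(2L, 3L, 1L, 1L), dst = c(1L, 1L, 2L, 3L),
                      relation = "rel1", stringsAsFactors = FALSE)
  res <- relation_attention(X, edges, p$rel_emb, heads)
  expect_equal(res$beta[[1]][1:2], c(0.5, 0.5), tolerance = 1e-10)
  # single neighbor -> weight 1
  expect_equal(res$beta[[1]][3], 1, tolerance = 1e-10)
  # mixed relations: weights equal softmax of the closed-form scores
  edges2 <- edges; edges2$relation <- c("rel1", "rel2", "self", "self")
  res2 <- relation_attention(X, edges2, p$rel_emb, heads)
  g_of <- function(rel, h) {
    r <- p$rel_emb[rel, , drop = FALSE]
    inner <- pmax(r %*% h$W1 + as.vector(h$b1), 0)
    1 / (1 + exp(-(inner %*% h$W2 + as.vector(h$b2))))
  }
  g12 <- c(g_of("rel1", heads[[1]]), g_of("rel2", heads[[1]]))
  expect_equal(res2$beta[[1]][1:2], as.vector(exp(g12) / sum(exp(g12))),
               tolerance = 1e-10)
  # the spec's hand softmax: scores (0.2, 0.8)
  expect_equal(round(exp(c(0.2, 0.8)) / sum(exp(c(0.2, 0.8))), 5),
               c(0.35434, 0.64566))
  expect_error(relation_attention(X, transform(edges, relation = "nope"),
                                  p$rel_emb, heads), "missing relation")
})

test_that("a full layer matches the dense reference implementation", {
  for (n in 2:6) for (n_rel in 1:2) {
    sg <- random_small_graph(n, n_rel, d = 4, seed = 100 + 10 * n + n_rel)
    cfg <- rgat_config(num_layers = 1, hidden_dim = 4, attention_heads = 2,
                       relation_heads = 2, relation_dim = 4,
                       seed = n + n_rel)
    p <- layer_params(cfg, 4, sg$relations)
    got <- rgat_layer(sg$features, sg$edges, p, cfg)
    want <- dense_rgat_layer(sg$features, sg$edges, p, cfg)
    expect_equal(got$features, want, tolerance = 1e-5)
  }
})

test_that("layer output is zero under zero output weights and keeps width", {
  sg <- random_small_graph(4, 1, d = 6, seed = 9)
  cfg <- rgat_config(num_layers = 1, hidden_dim = 6, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 4)
  p <- layer_params(cfg, 6, sg$relations)
  p$L1.out.W[] <- 0; p$L1.out.b[] <- 0
  res <- rgat_layer(sg$features, sg$edges, p, cfg)
  expect_true(all(res$features == 0))
  p2 <- layer_params(cfg, 6, sg$relations)
  expect_equal(dim(rgat_layer(sg$features, sg$edges, p2, cfg)$features),
               c(4L, 6L))
})

test_that("stacked layers equal composed single-layer calls", {
  sg <- random_small_graph(6, 2, d = 8, seed = 21)
  cfg <- rgat_config(num_layers = 2, hidden_dim = 8, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 5)
  p <- layer_params(cfg, 8, sg$relations)
  h1 <- rgat_layer(sg$features, sg$edges, p, cfg, layer = 1)$features
  h2 <- rgat_layer(h1, sg$edges, p, cfg, layer = 2)$features
  # same computation through the stacked forward (projection = identity)
  tape <- herbnet:::new_tape()
  pn <- lapply(p, function(m) herbnet:::ad_input(tape, m))
  idx <- list(src = sg$edges$src, dst = sg$edges$dst,
              rel = factor(sg$edges$relation, rownames(p$rel_emb)),
              n = nrow(sg$features))
  H <- herbnet:::ad_input(tape, sg$features)
  r1 <- herbnet:::ad_rgat_layer(tape, H, idx, pn, 1L, cfg)
  r2 <- herbnet:::ad_rgat_layer(tape, r1$out, idx, pn, 2L, cfg)
  expect_equal(herbnet:::ad_value(r2$out), h2, tolerance = 1e-10)
})

test_that("attention weights normalize per destination, head and layer", {
  fx <- tiny_graph(seed = 15)
  cfg <- rgat_config(num_layers = 2, hidden_dim = 8, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 6)
  fw <- rgat_forward(fx$graph, cfg)
  att <- fw$attention
  sums <- stats::aggregate(weight ~ dst + layer + head + kind, data = att,
                           FUN = sum)
  expect_true(all(abs(sums$weight - 1) < 1e-6))
})

test_that("forward is deterministic and equivariant to node relabeling", {
  fx <- tiny_graph(seed = 19)
  cfg <- rgat_config(num_layers = 2, hidden_dim = 8, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 7)
  a <- rgat_forward(fx$graph, cfg)
  b <- rgat_forward(fx$graph, cfg)
  expect_identical(a$H, b$H)
  # relabel prescriptions by shuffling input rows; rows follow the ids
  ds <- fx$dataset
  withr::local_seed(3)
  pres2 <- ds$prescriptions[sample(nrow(ds$prescriptions)), ]
  g2 <- drop_unsequenced(build_graph(pres2, ds$herbs, ds$metabolites,
                                     ds$targets, ds$herb_metabolite,
                                     ds$metabolite_target,
                                     embedding_spec = sequence_embedding_spec(dim = 16L)))
  c2 <- rgat_forward(g2, cfg)
  expect_equal(c2$H, a$H, tolerance = 1e-10)
})

test_that("a self-loop-only node sees only its own feature", {
  cfg <- rgat_config(num_layers = 1, hidden_dim = 4, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 8)
  edges <- data.frame(src = c(1L, 2L, 3L, 3L, 2L),
                      dst = c(1L, 2L, 3L, 2L, 3L),
                      relation = c("self", "self", "self", "rel1", "rel1"),
                      stringsAsFactors = FALSE)
  p <- layer_params(cfg, 4, c("rel1", "self"))
  withr::local_seed(10)
  X <- matrix(rnorm(12), 3, 4)
  r1 <- rgat_layer(X, edges, p, cfg)$features
  X2 <- X; X2[2:3, ] <- rnorm(8)   # perturb everything except node 1
  r2 <- rgat_layer(X2, edges, p, cfg)$features
  expect_equal(r2[1, ], r1[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r2[2, ], r1[2, ])))
})

test_that("input projections cover every type and receive gradient", {
  feats <- list(a = matrix(1:4, 2, 2), b = matrix(1, 1, 3))
  params <- list(`proj.a` = diag(2), `proj.b` = matrix(0, 3, 2))
  out <- project_inputs(feats, params)
  expect_equal(dim(out), c(3L, 2L))
  expect_equal(out[1:2, ], unname(matrix(1:4, 2, 2)))
  expect_error(project_inputs(list(c = diag(2)), params), "node type")

  fx <- tiny_graph(seed = 25)
  cfg <- rgat_config(num_layers = 1, hidden_dim = 8, attention_heads = 2,
                     relation_heads = 2, relation_dim = 4, seed = 9)
  idx <- herbnet:::graph_index(fx$graph)
  p <- rgat_init(cfg, idx$type_dims, idx$rel_levels)
  tape <- herbnet:::new_tape()
  pn <- herbnet:::ad_params(tape, p)
  fw <- herbnet:::ad_rgat_forward(tape, fx$graph$features, idx, pn, cfg)
  loss <- herbnet:::ad_mean(tape, fw$H)
  herbnet:::ad_backward(tape, loss)
  for (t in names(idx$type_dims)) {
    g <- pn[[paste0("proj.", t)]]$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
})
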