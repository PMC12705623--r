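test_that("rare efficacies are filtered on the positive-share boundary", {
  lab <- cbind(a = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
               b = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
               c = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  # shares: a = 0.15 (boundary, kept), b = 0.2, c = 0.1 (dropped)
  expect_identical(filter_rare_efficacies(lab, 0.15), c("a", "b"))
  expect_identical(filter_rare_efficacies(lab, 0.05), c("a", "b", "c"))
  expect_error(filter_rare_efficacies(lab[0, , drop = FALSE]), "empty")
  expect_error(filter_rare_efficacies(lab, 0), "min_share")
})

test_that("graph construction deduplicates and validates ids", {
  pres <- data.frame(prescription_id = c("P2", "P1"),
                     herb_ids = c("A|B|B", "B"), eff = c(1L, 0L),
                     stringsAsFactors = FALSE)
  herbs <- data.frame(herb_id = c("B", "A"), name = c("b", "a"),
                      attributes = c("cold|sweet", "hot"),
                      stringsAsFactors = FALSE)
  g <- build_graph(pres, herbs)
  # duplicate herb entry collapses: P2 has 2 herbs, P1 has 1
  ph <- g$edges[g$edges$relation == "prescription-herb", ]
  expect_equal(nrow(ph), 3L)
  expect_identical(sort(g$herb_sets$P2), c("A", "B"))
  # every edge has its reverse dual
  rev_key <- paste(g$edges$dst_type, g$edges$dst, g$edges$src_type,
                   g$edges$src)
  fwd_key <- paste(g$edges$src_type, g$edges$src, g$edges$dst_type,
                   g$edges$dst)
  expect_true(all(rev_key %in% fwd_key))
  # dangling herb id
  bad <- pres; bad$herb_ids[1] <- "A|ZZZ"
  expect_error(build_graph(bad, herbs), "ZZZ")
})

test_that("graph construction is invariant to input row order", {
  fx <- tiny_graph(seed = 5)
  ds <- fx$dataset
  withr::local_seed(1)
  g1 <- build_graph(ds$prescriptions, ds$herbs, ds$metabolites, ds$targets,
                    ds$herb_metabolite, ds$metabolite_target,
                    embedding_spec = sequence_embedding_spec(dim = 16L))
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  g2 <- build_graph(shuf(ds$prescriptions), shuf(ds$herbs),
                    shuf(ds$metabolites), shuf(ds$targets),
                    shuf(ds$herb_metabolite), shuf(ds$metabolite_target),
                    embedding_spec = sequence_embedding_spec(dim = 16L))
  expect_identical(g1$nodes, g2$nodes)
  expect_equal(g1$features, g2$features)
  key <- function(g) sort(paste(g$edges$src, g$edges$dst, g$edges$relation))
  expect_identical(key(g1), key(g2))
})

test_that("unsequenced nodes are dropped with exact edge bookkeeping", {
  fx <- tiny_graph(seed = 7, frac_unsequenced_metabolites = 0.3,
                   frac_unsequenced_targets = 0.3)
  ds <- fx$dataset
  g0 <- build_graph(ds$prescriptions, ds$herbs, ds$metabolites, ds$targets,
                    ds$herb_metabolite, ds$metabolite_target,
                    embedding_spec = sequence_embedding_spec(dim = 16L))
  g1 <- drop_unsequenced(g0)
  # brute-force recount of surviving herb-metabolite pairs
  ok_m <- g0$nodes$metabolite$id[g0$nodes$metabolite$sequenced]
  ok_t <- g0$nodes$target$id[g0$nodes$target$sequenced]
  hm_expect <- sum(unique(ds$herb_metabolite)$metabolite_id %in% ok_m)
  mt <- unique(ds$metabolite_target)
  mt_expect <- sum(mt$metabolite_id %in% ok_m & mt$target_id %in% ok_t)
  expect_equal(sum(g1$edges$relation == "herb-metabolite"), hm_expect)
  expect_equal(sum(g1$edges$relation == "metabolite-target"), mt_expect)
  expect_equal(nrow(g1$nodes$metabolite), length(ok_m))
  # idempotent
  g2 <- drop_unsequenced(g1)
  expect_identical(g2$edges, g1$edges)
  expect_identical(g2$nodes, g1$nodes)
  # nothing unsequenced -> identity
  fx2 <- tiny_graph(seed = 8, frac_unsequenced_metabolites = 0,
                    frac_unsequenced_targets = 0)
  before <- fx2$graph$edges
  expect_identical(drop_unsequenced(fx2$graph)$edges, before)
})

test_that("virtual fingerprint nodes have degree exactly one", {
  fx <- tiny_graph(seed = 9)
  g <- attach_virtual_ecfp(fx$graph, nbits = 64)
  n_fp <- nrow(g$nodes$ecfp)
  expect_equal(n_fp, sum(g$nodes$metabolite$sequenced))
  expect_equal(sum(g$edges$relation == "metabolite-ecfp"), n_fp)
  expect_equal(sum(g$edges$relation == "ecfp-metabolite"), n_fp)
  deg <- table(c(g$edges$dst[g$edges$dst_type == "ecfp"],
                 g$edges$src[g$edges$src_type == "ecfp"]))
  expect_true(all(deg == 2))  # one in-edge plus its reverse
})

test_that("merging generated prescriptions leaves the original graph intact", {
  fx <- tiny_graph(seed = 11)
  g <- fx$graph
  expect_identical(merge_generated(g, list(), "planted"), g)
  recs <- list(
    list(label = 1L, feature = rnorm(22), herb_ids = g$nodes$herb$id[1:3]),
    list(label = 0L, feature = rnorm(22), herb_ids = g$nodes$herb$id[2:4]))
  g2 <- merge_generated(g, recs, "planted")
  expect_equal(nrow(g2$nodes$prescription), nrow(g$nodes$prescription) + 2L)
  expect_equal(nrow(g2$edges), nrow(g$edges) + 2L * (3L + 3L))
  gen <- g2$nodes$prescription$provenance == "generated"
  expect_equal(sum(gen), 2L)
  expect_false(any(g2$nodes$prescription$id[gen] %in%
                     g$nodes$prescription$id))
  # original subgraph identical after merge
  orig_ids <- g$nodes$prescription$id
  e2 <- g2$edges[!(g2$edges$src %in% g2$nodes$prescription$id[gen]) &
                   !(g2$edges$dst %in% g2$nodes$prescription$id[gen]), ]
  rownames(e2) <- NULL
  e1 <- g$edges; rownames(e1) <- NULL
  expect_identical(sort(paste(e1$src, e1$dst, e1$relation)),
                   sort(paste(e2$src, e2$dst, e2$relation)))
  expect_identical(g2$labels[orig_ids, ], g$labels[orig_ids, ])
  expect_identical(g2$labels[g2$nodes$prescription$id[gen], "planted"],
                   stats::setNames(c(1L, 0L), g2$nodes$prescription$id[gen]))
})

test_that("graph serialization round-trips", {
  fx <- tiny_graph(seed = 13)
  g <- attach_virtual_ecfp(fx$graph, nbits = 32)
  dir <- withr::local_tempdir()
  write_graph_dir(g, dir)
  g2 <- read_graph_dir(dir)
  expect_identical(lapply(g$nodes, function(n) n$id),
                   lapply(g2$nodes, function(n) n$id))
  key <- function(g) sort(paste(g$edges$src, g$edges$dst, g$edges$relation))
  expect_identical(key(g), key(g2))
  for (t in names(g$features))
    expect_equal(g2$features[[t]], g$features[[t]], tolerance = 1e-12)
  expect_identical(g2$labels, g$labels)
  # GraphML export parses back with the same edge count
  gm <- file.path(dir, "g.graphml")
  export_graphml(g, gm)
  ig <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
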