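# Heterogeneous graph data model, cleaning filters, construction and I/O.
#
# A `hetero_graph` holds typed node tables (prescription, herb, metabolite,
# target, ecfp), typed bidirectional edge lists (each direction a distinct
# relation so the message passing can learn separate relation embeddings),
# per-type feature matrices, an efficacy label table, and provenance flags.
# Edges carry no attributes.

REL_FORWARD <- c("prescription-herb", "herb-metabolite", "metabolite-target",
                 "metabolite-ecfp")

reverse_relation <- function(rel) {
  parts <- strsplit(rel, "-", fixed = TRUE)[[1]]
  paste(rev(parts), collapse = "-")
}

new_hetero_graph <- function(nodes, features, edges, labels, herb_sets,
                             vocab, meta = list()) {
  structure(list(nodes = nodes, features = features, edges = edges,
                 labels = labels, herb_sets = herb_sets, vocab = vocab,
                 meta = meta),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("<hetero_graph>\n")
  for (t in names(x$nodes))
    cat(sprintf("  %-13s %6d nodes\n", t, nrow(x$nodes[[t]])))
  tab <- table(x$edges$relation)
  for (r in names(tab)) cat(sprintf("  %-28s %6d edges\n", r, tab[[r]]))
  if (!is.null(x$labels))
    cat("  efficacies:", paste(colnames(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Keep efficacies whose positive share reaches a threshold
#'
#' Rare efficacy classes are removed before modelling: an efficacy is
#' retained iff the share of prescriptions carrying it is at least
#' `min_share` (the boundary value is retained; strictly-below is dropped).
#'
#' @param labels Binary prescription x efficacy matrix (NA rows ignored per
#'   column).
#' @param min_share Minimum positive share, in (0, 1); default 0.15.
#' @return Character vector of retained efficacy names.
#' @export
filter_rare_efficacies <- function(labels, min_share = 0.15) {
  if (min_share <= 0 || min_share >= 1) stop("min_share must be in (0, 1)")
  labels <- as.matrix(labels)
  if (!nrow(labels) || !ncol(labels)) stop("empty label table")
  shares <- colMeans(labels == 1, na.rm = TRUE)
  colnames(labels)[shares >= min_share]
}

split_ids <- function(x) strsplit(x, "|", fixed = TRUE)

#' Build the heterogeneous prescription--herb--metabolite--target graph
#'
#' Validates that every referenced id resolves (dangling ids raise an error
#' listing the offenders), de-duplicates edges and repeated herb entries
#' within a prescription, sorts node tables canonically by id, computes
#' initial features (multi-hot herb attributes, standardized prescription
#' sums, sequence embeddings for metabolites and targets), and stores both
#' directions of every relation.
#'
#' @param prescriptions Data.frame with `prescription_id`, `herb_ids`
#'   (\code{"|"}-separated) and one 0/1 column per efficacy (optionally a
#'   `provenance` column).
#' @param herbs Data.frame with `herb_id`, optional `name`, and
#'   `attributes` (\code{"|"}-separated vocabulary tokens).
#' @param metabolites Optional data.frame with `metabolite_id`, `smiles`.
#' @param targets Optional data.frame with `target_id`, `sequence`.
#' @param herb_metabolite,metabolite_target Optional edge data.frames.
#' @param vocab Attribute vocabulary; persisted in the graph.
#' @param embedding_spec Spec for the sequence encoder used on SMILES and
#'   protein sequences.
#' @param encoder Optional encoder override (see [embed_sequences()]).
#' @return A `hetero_graph`.
#' @export
build_graph <- function(prescriptions, herbs, metabolites = NULL,
                        targets = NULL, herb_metabolite = NULL,
                        metabolite_target = NULL,
                        vocab = attribute_vocabulary(),
                        embedding_spec = sequence_embedding_spec(dim = 64L),
                        encoder = NULL) {
  herbs <- herbs[order(herbs$herb_id), , drop = FALSE]
  prescriptions <- prescriptions[order(prescriptions$prescription_id), , drop = FALSE]
  if (anyDuplicated(herbs$herb_id)) stop("duplicated herb ids")
  if (anyDuplicated(prescriptions$prescription_id)) stop("duplicated prescription ids")

  herb_sets <- lapply(split_ids(prescriptions$herb_ids), unique)
  names(herb_sets) <- prescriptions$prescription_id
  dangling <- setdiff(unlist(herb_sets), herbs$herb_id)
  if (length(dangling))
    stop("prescriptions reference unknown herb ids: ",
         paste(utils::head(dangling, 10), collapse = ", "))

  nodes <- list(
    prescription = data.frame(
      id = prescriptions$prescription_id,
      provenance = prescriptions$provenance %||% rep("original", nrow(prescriptions)),
      stringsAsFactors = FALSE),
    herb = data.frame(id = herbs$herb_id, provenance = "original",
                      stringsAsFactors = FALSE))

  # features: herbs multi-hot, prescriptions standardized sums
  hmat <- t(vapply(split_ids(herbs$attributes %||% rep("", nrow(herbs))),
                   function(a) encode_herb(a[nzchar(a)], vocab),
                   numeric(vocab$n)))
  dimnames(hmat) <- list(herbs$herb_id, NULL)  # token order lives in vocab
  pmat <- t(vapply(herb_sets, function(hs)
    aggregate_prescription(hmat[hs, , drop = FALSE]), numeric(vocab$n)))
  dimnames(pmat) <- list(prescriptions$prescription_id, NULL)
  features <- list(prescription = pmat, herb = hmat)

  edges <- data.frame(
    src_type = "prescription",
    src = rep(prescriptions$prescription_id, lengths(herb_sets)),
    dst_type = "herb", dst = unlist(herb_sets),
    relation = "prescription-herb", stringsAsFactors = FALSE)

  if (!is.null(metabolites)) {
    metabolites <- metabolites[order(metabolites$metabolite_id), , drop = FALSE]
    seqd <- smiles_parses(metabolites$smiles)
    nodes$metabolite <- data.frame(id = metabolites$metabolite_id,
                                   provenance = "original",
                                   smiles = metabolites$smiles,
                                   sequenced = seqd, stringsAsFactors = FALSE)
    mfeat <- matrix(0, nrow(metabolites), embedding_spec$dim)
    if (any(seqd))
      mfeat[seqd, ] <- embed_sequences(metabolites$smiles[seqd],
                                       embedding_spec, encoder)
    rownames(mfeat) <- metabolites$metabolite_id
    features$metabolite <- mfeat
    if (!is.null(herb_metabolite)) {
      bad <- c(setdiff(herb_metabolite$herb_id, herbs$herb_id),
               setdiff(herb_metabolite$metabolite_id, metabolites$metabolite_id))
      if (length(bad))
        stop("herb-metabolite edges reference unknown ids: ",
             paste(utils::head(bad, 10), collapse = ", "))
      hm <- unique(herb_metabolite[c("herb_id", "metabolite_id")])
      edges <- rbind(edges, data.frame(
        src_type = "herb", src = hm$herb_id, dst_type = "metabolite",
        dst = hm$metabolite_id, relation = "herb-metabolite",
        stringsAsFactors = FALSE))
    }
  }

  if (!is.null(targets)) {
    targets <- targets[order(targets$target_id), , drop = FALSE]
    seqd <- !is.na(targets$sequence) & nzchar(targets$sequence)
    nodes$target <- data.frame(id = targets$target_id, provenance = "original",
                               sequence = targets$sequence,
                               sequenced = seqd, stringsAsFactors = FALSE)
    tfeat <- matrix(0, nrow(targets), embedding_spec$dim)
    if (any(seqd))
      tfeat[seqd, ] <- embed_sequences(targets$sequence[seqd],
                                       embedding_spec, encoder)
    rownames(tfeat) <- targets$target_id
    features$target <- tfeat
    if (!is.null(metabolite_target)) {
      bad <- c(setdiff(metabolite_target$metabolite_id, nodes$metabolite$id),
               setdiff(metabolite_target$target_id, targets$target_id))
      if (length(bad))
        stop("metabolite-target edges reference unknown ids: ",
             paste(utils::head(bad, 10), collapse = ", "))
      mt <- unique(metabolite_target[c("metabolite_id", "target_id")])
      edges <- rbind(edges, data.frame(
        src_type = "metabolite", src = mt$metabolite_id, dst_type = "target",
        dst = mt$target_id, relation = "metabolite-target",
        stringsAsFactors = FALSE))
    }
  }

  edges <- unique(edges)
  edges <- add_reverse_edges(edges)

  eff_cols <- setdiff(names(prescriptions),
                      c("prescription_id", "herb_ids", "provenance"))
  labels <- NULL
  if (length(eff_cols)) {
    labels <- as.matrix(prescriptions[eff_cols])
    storage.mode(labels) <- "integer"
    rownames(labels) <- prescriptions$prescription_id
  }

  new_hetero_graph(nodes, features, edges, labels, herb_sets, vocab,
                   meta = list(embedding_dim = embedding_spec$dim))
}

# Append the reverse dual of every stored forward edge (and drop any
# duplicates that would result).
add_reverse_edges <- function(edges) {
  fwd <- edges[edges$relation %in% REL_FORWARD, , drop = FALSE]
  rev <- data.frame(src_type = fwd$dst_type, src = fwd$dst,
                    dst_type = fwd$src_type, dst = fwd$src,
                    relation = vapply(fwd$relation, reverse_relation, ""),
                    stringsAsFactors = FALSE)
  out <- unique(rbind(fwd, rev))
  rownames(out) <- NULL
  out
}

#' Remove metabolites and targets that lack usable sequences
#'
#' Metabolite nodes whose SMILES does not parse and target nodes without a
#' protein sequence are removed together with all incident edges, mirroring
#' the cleaning step applied before graph learning. Idempotent; the counts
#' of removed nodes and edges are recorded in `graph$meta$cleaning`.
#'
#' @param graph A `hetero_graph`.
#' @param molecules Optional data.frame (`metabolite_id`, `smiles`)
#'   overriding the sequenced flags stored at build time.
#' @param targets Optional data.frame (`target_id`, `sequence`) likewise.
#' @return The cleaned `hetero_graph`.
#' @export
drop_unsequenced <- function(graph, molecules = NULL, targets = NULL) {
  stopifnot(inherits(graph, "hetero_graph"))
  drop_ids <- character(0)
  if (!is.null(graph$nodes$metabolite)) {
    flag <- graph$nodes$metabolite$sequenced
    if (!is.null(molecules)) {
      m <- match(graph$nodes$metabolite$id, molecules$metabolite_id)
      flag <- smiles_parses(molecules$smiles[m])
    }
    drop_ids <- c(drop_ids, graph$nodes$metabolite$id[!flag])
  }
  if (!is.null(graph$nodes$target)) {
    flag <- graph$nodes$target$sequenced
    if (!is.null(targets)) {
      m <- match(graph$nodes$target$id, targets$target_id)
      sq <- targets$sequence[m]
      flag <- !is.na(sq) & nzchar(sq)
    }
    drop_ids <- c(drop_ids, graph$nodes$target$id[!flag])
  }
  n_edges_before <- nrow(graph$edges)
  removed_nodes <- integer(0)
  for (t in c("metabolite", "target")) {
    if (is.null(graph$nodes[[t]])) next
    keep <- !(graph$nodes[[t]]$id %in% drop_ids)
    removed_nodes[t] <- sum(!keep)
    graph$nodes[[t]] <- graph$nodes[[t]][keep, , drop = FALSE]
    graph$features[[t]] <- graph$features[[t]][keep, , drop = FALSE]
  }
  keep_e <- !(graph$edges$src %in% drop_ids) & !(graph$edges$dst %in% drop_ids)
  graph$edges <- graph$edges[keep_e, , drop = FALSE]
  graph$meta$cleaning <- list(removed_nodes = as.list(removed_nodes),
                              removed_edges = n_edges_before - sum(keep_e))
  graph
}

#' Attach one virtual fingerprint node per fingerprinted metabolite
#'
#' Each metabolite with a parsable SMILES gains a degree-1 virtual node
#' whose feature is the molecule's circular fingerprint, connected to the
#' metabolite by a dedicated relation (plus its reverse). Metabolites
#' without a fingerprint get no virtual node.
#'
#' @param graph A `hetero_graph` containing metabolite nodes.
#' @param radius,nbits Fingerprint parameters (see [compute_ecfp()]).
#' @return The augmented `hetero_graph`.
#' @export
attach_virtual_ecfp <- function(graph, radius = 2L, nbits = 2048L) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (is.null(graph$nodes$metabolite)) stop("graph has no metabolite nodes")
  mm <- graph$nodes$metabolite
  res <- ecfp_matrix(mm$smiles, radius, nbits)
  keep <- res$parsed
  if (!any(keep)) return(graph)
  ids <- paste0("ecfp:", mm$id[keep])
  graph$nodes$ecfp <- data.frame(id = ids, provenance = "virtual",
                                 stringsAsFactors = FALSE)
  fmat <- res$fp[keep, , drop = FALSE]
  rownames(fmat) <- ids
  graph$features$ecfp <- fmat
  newe <- data.frame(src_type = "metabolite", src = mm$id[keep],
                     dst_type = "ecfp", dst = ids,
                     relation = "metabolite-ecfp", stringsAsFactors = FALSE)
  graph$edges <- add_reverse_edges(rbind(graph$edges, newe))
  graph
}

#' Merge generated prescriptions into the graph
#'
#' Adds the synthetic prescription nodes produced by the adversarial
#' augmenter -- flagged `generated`, never overwriting real ids -- together
#' with their prescription--herb edges, and extends the label table with
#' the targeted efficacy. All pre-existing nodes and edges are untouched.
#'
#' @param graph A `hetero_graph`.
#' @param synthetic List of synthetic prescription records (see
#'   [generate_prescriptions()]).
#' @param efficacy Efficacy name the records were generated for.
#' @return The augmented `hetero_graph`.
#' @export
merge_generated <- function(graph, synthetic, efficacy) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (!length(synthetic)) return(graph)
  base <- sum(graph$nodes$prescription$provenance == "generated")
  ids <- sprintf("gen:%s:%05d", efficacy, base + seq_along(synthetic))
  stopifnot(!any(ids %in% graph$nodes$prescription$id))
  feats <- t(vapply(synthetic, function(r) as.numeric(r$feature),
                    numeric(ncol(graph$features$prescription))))
  rownames(feats) <- ids
  graph$nodes$prescription <- rbind(
    graph$nodes$prescription,
    data.frame(id = ids, provenance = "generated", stringsAsFactors = FALSE))
  graph$features$prescription <- rbind(graph$features$prescription, feats)
  hs <- lapply(synthetic, function(r) r$herb_ids)
  names(hs) <- ids
  bad <- setdiff(unlist(hs), graph$nodes$herb$id)
  if (length(bad)) stop("generated records reference unknown herbs: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  graph$herb_sets <- c(graph$herb_sets, hs)
  newe <- data.frame(src_type = "prescription", src = rep(ids, lengths(hs)),
                     dst_type = "herb", dst = unlist(hs),
                     relation = "prescription-herb", stringsAsFactors = FALSE)
  graph$edges <- add_reverse_edges(rbind(graph$edges, newe))
  if (!is.null(graph$labels)) {
    newlab <- matrix(NA_integer_, length(ids), ncol(graph$labels),
                     dimnames = list(ids, colnames(graph$labels)))
    if (efficacy %in% colnames(graph$labels))
      newlab[, efficacy] <- vapply(synthetic, function(r) as.integer(r$label),
                                   integer(1))
    graph$labels <- rbind(graph$labels, newlab)
  }
  graph
}

# ---- serialization ---------------------------------------------------------

#' Write a heterogeneous graph as typed TSV tables plus a JSON manifest
#'
#' @param graph A `hetero_graph`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_graph_dir <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  for (t in names(graph$nodes)) wt(graph$nodes[[t]], paste0("nodes_", t, ".tsv"))
  wt(graph$edges, "edges.tsv")
  for (t in names(graph$features)) {
    m <- graph$features[[t]]
    df <- data.frame(id = rownames(m),
                     format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    wt(df, paste0("features_", t, ".tsv"))
  }
  if (!is.null(graph$labels))
    wt(data.frame(prescription_id = rownames(graph$labels), graph$labels,
                  check.names = FALSE), "labels.tsv")
  wt(data.frame(prescription_id = names(graph$herb_sets),
                herb_ids = vapply(graph$herb_sets, paste, "", collapse = "|")),
     "herb_sets.tsv")
  jsonlite::write_json(
    list(types = names(graph$nodes), vocab = graph$vocab, meta = graph$meta),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a graph directory written by [write_graph_dir()]
#'
#' @param dir Directory path.
#' @return The reconstructed `hetero_graph`.
#' @export
read_graph_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rt <- function(f, classes = NA) utils::read.table(
    file.path(dir, f), sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = classes, quote = "", comment.char = "")
  nodes <- list(); features <- list()
  for (t in man$types) {
    nodes[[t]] <- rt(paste0("nodes_", t, ".tsv"))
    nodes[[t]]$id <- as.character(nodes[[t]]$id)
    ff <- file.path(dir, paste0("features_", t, ".tsv"))
    if (file.exists(ff)) {
      df <- rt(paste0("features_", t, ".tsv"))
      m <- as.matrix(df[, -1, drop = FALSE])
      storage.mode(m) <- "double"
      dimnames(m) <- list(as.character(df$id), NULL)
      features[[t]] <- m
    }
  }
  edges <- rt("edges.tsv", "character")
  labels <- NULL
  lf <- file.path(dir, "labels.tsv")
  if (file.exists(lf)) {
    df <- rt("labels.tsv")
    labels <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(labels) <- "integer"
    rownames(labels) <- as.character(df$prescription_id)
  }
  hsdf <- rt("herb_sets.tsv", "character")
  herb_sets <- split_ids(hsdf$herb_ids)
  names(herb_sets) <- hsdf$prescription_id
  vocab <- man$vocab
  vocab$n <- as.integer(vocab$n)
  new_hetero_graph(nodes, features, edges, labels, herb_sets, vocab,
                   meta = man$meta)
}

#' Export the graph (or any weighted edge list) to GraphML
#'
#' @param graph A `hetero_graph`.
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  e <- graph$edges
  vnames <- unlist(lapply(names(graph$nodes), function(t)
    paste(t, graph$nodes[[t]]$id, sep = ":")))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste(e$src_type, e$src, sep = ":"),
               to = paste(e$dst_type, e$dst, sep = ":"),
               relation = e$relation),
    vertices = data.frame(name = vnames), directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
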