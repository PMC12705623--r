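# Extraction, binning and export of post-training attention weights.

#' Extract attention weights for one relation as a weighted edge list
#'
#' Pulls the attention records of a trained model for a single relation
#' type (default the herb-to-metabolite edges), reducing over heads at one
#' layer. Weights are neighborhood-normalized attention coefficients, so
#' each lies in `[0, 1]`.
#'
#' @param model An `rgat_model` (or any list with `attention` records and
#'   `index`) as returned by [fit_rgat()] / [rgat_forward()].
#' @param graph The `hetero_graph` the model was run on (resolves global
#'   node indices back to ids).
#' @param relation Relation type to extract (default `"herb-metabolite"`).
#' @param layer Layer to read; default the final layer present.
#' @param kind `"node"` (multi-head neighborhood attention) or
#'   `"relation"` (relation-embedding attention).
#' @param reduction `"mean"` (default) or `"max"` over heads.
#' @return Data.frame with `src`, `dst`, `relation`, `weight`.
#' @export
extract_relation_attention <- function(model, graph,
                                       relation = "herb-metabolite",
                                       layer = NULL, kind = "node",
                                       reduction = c("mean", "max")) {
  reduction <- match.arg(reduction)
  att <- model$attention
  if (is.null(att) || !nrow(att)) stop("model carries no attention records")
  if (!relation %in% att$relation)
    stop("relation absent from graph: ", relation)
  if (is.null(layer)) layer <- max(att$layer)
  sel <- att[att$relation == relation & att$layer == layer &
               att$kind == kind, , drop = FALSE]
  agg <- stats::aggregate(weight ~ src + dst, data = sel,
                          FUN = if (reduction == "mean") mean else max)
  # resolve global indices back to typed ids
  idx <- model$index
  resolve <- function(g) {
    t_i <- findInterval(g - 1L, idx$offsets)
    type <- idx$types[t_i]
    vapply(seq_along(g), function(i)
      graph$nodes[[type[i]]]$id[g[i] - idx$offsets[type[i]]], "")
  }
  out <- data.frame(src = resolve(agg$src), dst = resolve(agg$dst),
                    relation = relation, weight = agg$weight,
                    stringsAsFactors = FALSE)
  out[order(out$src, out$dst), , drop = FALSE]
}

#' Select the strongest edges within attention-weight bins
#'
#' Partitions `[0, 1]` into half-open bins of width `bin_width` (the final
#' bin is closed at 1) and keeps the `top_n` largest weights inside each
#' non-empty bin, breaking ties by source-id order.
#'
#' @param edges Data.frame with at least `src` and `weight` columns,
#'   weights in `[0, 1]`.
#' @param bin_width Bin width (default 0.1).
#' @param top_n Edges to keep per bin (default 5).
#' @return The selected rows, ordered by bin then descending weight.
#' @export
bin_top_edges <- function(edges, bin_width = 0.1, top_n = 5L) {
  if (!nrow(edges)) return(edges)
  if (any(edges$weight < 0 | edges$weight > 1))
    stop("weights must lie in [0, 1]")
  nb <- ceiling(1 / bin_width)
  # epsilon guards the half-open boundaries against float division error
  bin <- pmin(floor(edges$weight / bin_width + 1e-9), nb - 1L)
  keep <- unlist(lapply(split(seq_len(nrow(edges)), bin), function(rows) {
    o <- rows[order(-edges$weight[rows], edges$src[rows])]
    utils::head(o, top_n)
  }), use.names = FALSE)
  edges[keep, , drop = FALSE]
}

#' Export weighted attention edges as TSV or GraphML
#'
#' The TSV carries fixed columns (`src`, `dst`, `relation`, `weight`);
#' GraphML stores the weight as an edge attribute for network rendering
#' tools. A round-trip read recovers edges and weights.
#'
#' @param edges Data.frame with `src`, `dst`, `relation`, `weight`.
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_attention <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edges <- edges[, c("src", "dst", "relation", "weight"), drop = FALSE]
  if (format == "tsv") {
    edges$weight <- sprintf("%.6f", edges$weight)
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$src), to = as.character(edges$dst),
                 relation = as.character(edges$relation),
                 weight = round(edges$weight, 6)),
      directed = TRUE,
      vertices = data.frame(name = unique(c(as.character(edges$src),
                                            as.character(edges$dst)))))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read attention edges back from a TSV or GraphML file
#'
#' @param path File written by [export_attention()].
#' @param format `"tsv"` or `"graphml"`.
#' @return Data.frame with `src`, `dst`, `relation`, `weight`.
#' @export
read_attention <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "character", "numeric"))
    return(df)
  }
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  data.frame(src = el$from, dst = el$to, relation = el$relation,
             weight = el$weight, stringsAsFactors = FALSE)
}
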