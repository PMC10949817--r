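.res_label <- function(res_num, res_name) {
  one <- suppressWarnings(bio3d::aa321(res_name))
  one[is.na(one)] <- "X"
  paste0(res_num, one)
}

#' Build a residue-level stabilization-center connectivity graph
#'
#' Collapses a stability table (one row per residue-pair instance, i.e.
#' per subunit occurrence) to residue-number level, aggregating over all
#' chains into a single graph: nodes are residue labels such as "65C",
#' node weight counts the SC instances the residue participates in, edge
#' weight is the stability fraction averaged over the subunit instances
#' of that residue pair, and cysteine nodes are flagged. The handshake
#' identity holds by construction: the node weights sum to twice the
#' total number of edge instances.
#'
#' @param stability stability table from \code{\link{sc_timeseries}} (or
#'   any data.frame with columns res_a, name_a, res_b, name_b, fraction).
#' @return An object of class \code{"gj_sc_graph"}: list of \code{nodes}
#'   (label, res_num, res_name, weight, is_cys) and \code{edges} (from,
#'   to, weight, n_instances).
#' @export
build_sc_graph <- function(stability) {
  if (!nrow(stability)) {
    g <- list(nodes = data.frame(label = character(), res_num = integer(),
                                 res_name = character(), weight = integer(),
                                 is_cys = logical(), stringsAsFactors = FALSE),
              edges = data.frame(from = character(), to = character(),
                                 weight = numeric(), n_instances = integer(),
                                 stringsAsFactors = FALSE))
    class(g) <- "gj_sc_graph"
    return(g)
  }
  la <- .res_label(stability$res_a, stability$name_a)
  lb <- .res_label(stability$res_b, stability$name_b)
  swap <- stability$res_a > stability$res_b
  from <- ifelse(swap, lb, la); to <- ifelse(swap, la, lb)
  ekey <- paste(from, to, sep = "|")
  sp <- split(seq_along(ekey), factor(ekey, levels = unique(ekey)))
  edges <- do.call(rbind, lapply(sp, function(i) {
    data.frame(from = from[i[1]], to = to[i[1]],
               weight = mean(stability$fraction[i]),
               n_instances = length(i), stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  node_tab <- rbind(
    data.frame(label = la, res_num = stability$res_a,
               res_name = stability$name_a, stringsAsFactors = FALSE),
    data.frame(label = lb, res_num = stability$res_b,
               res_name = stability$name_b, stringsAsFactors = FALSE))
  spn <- split(seq_len(nrow(node_tab)),
               factor(node_tab$label, levels = unique(node_tab$label)))
  nodes <- do.call(rbind, lapply(spn, function(i) {
    data.frame(label = node_tab$label[i[1]], res_num = node_tab$res_num[i[1]],
               res_name = node_tab$res_name[i[1]], weight = length(i),
               is_cys = node_tab$res_name[i[1]] == "CYS",
               stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$res_num), ]
  rownames(nodes) <- NULL
  g <- list(nodes = nodes, edges = edges)
  class(g) <- "gj_sc_graph"
  g
}

#' @export
print.gj_sc_graph <- function(x, ...) {
  cat("<gj_sc_graph> ", nrow(x$nodes), " residues, ", nrow(x$edges),
      " SC edges (", sum(x$nodes$is_cys), " Cys nodes)\n", sep = "")
  invisible(x)
}

#' Convert an SC graph to an igraph object
#'
#' @param graph a \code{\link{build_sc_graph}} result.
#' @return An \code{igraph} graph with node/edge weights and the
#'   \code{is_cys} flag as attributes.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges,
    directed = FALSE,
    vertices = graph$nodes[, c("label", "res_num", "res_name", "weight",
                               "is_cys")])
}

#' Export an SC graph
#'
#' GraphML (round-trippable, attribute-preserving, via igraph) or a TSV
#' edge list.
#'
#' @param graph a \code{\link{build_sc_graph}} result.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import an SC graph written by \code{\link{export_graph}}
#'
#' @param path GraphML file.
#' @return A \code{\link{build_sc_graph}}-shaped object.
#' @export
import_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  v <- igraph::as_data_frame(ig, what = "vertices")
  e <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(label = v$name, res_num = as.integer(v$res_num),
                      res_name = v$res_name, weight = as.integer(v$weight),
                      is_cys = as.logical(v$is_cys), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$res_num), ]
  rownames(nodes) <- NULL
  edges <- data.frame(from = e$from, to = e$to, weight = e$weight,
                      n_instances = as.integer(e$n_instances),
                      stringsAsFactors = FALSE)
  g <- list(nodes = nodes, edges = edges)
  class(g) <- "gj_sc_graph"
  g
}

#' Connected modules of an SC graph
#'
#' Drops nodes below a participation-weight threshold and returns the
#' connected components of what remains — a plain way of delineating the
#' cysteine-centred interaction modules without committing to a
#' community-detection algorithm.
#'
#' @param graph a \code{\link{build_sc_graph}} result.
#' @param min_node_weight drop nodes with weight below this (default 1:
#'   keep all).
#' @return List of character vectors of node labels, largest first.
#' @export
sc_graph_components <- function(graph, min_node_weight = 1L) {
  ig <- as_igraph(graph)
  keep <- igraph::V(ig)[igraph::V(ig)$weight >= min_node_weight]
  ig <- igraph::induced_subgraph(ig, keep)
  comp <- igraph::components(ig)
  sp <- split(names(comp$membership), comp$membership)
  sp[order(-vapply(sp, length, 1L))]
}
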