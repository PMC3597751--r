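# Association network assembly from significant correlation pairs, and
# export for external visualization (e.g. Cytoscape).

#' Build the domain association network
#'
#' One node per retained family, one undirected edge per significant
#' pair, weighted by rho. Node attributes `category` and `is_duf`
#' (stored as 0/1) come from the category map.
#'
#' @param cres A pruned `correlation_result` (from
#'   [prune_uncorrelated()]; its `significant` mask must be present).
#' @param cmap A [category_map()] covering every retained family.
#' @return An [igraph::igraph] object (undirected, simple) with edge
#'   attribute `weight` and node attributes `category`, `is_duf`.
#' @export
build_network <- function(cres, cmap) {
  if (is.null(cres$significant)) {
    stop("correlation result has no significance mask; run prune_uncorrelated() first",
         call. = FALSE)
  }
  fams <- cres$families
  info <- .lookup_categories(fams, cmap)
  idx <- which(upper.tri(cres$significant) & cres$significant, arr.ind = TRUE)
  edges <- data.frame(from = fams[idx[, 1L]], to = fams[idx[, 2L]],
                      weight = cres$rho[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = fams,
                          category = ifelse(is.na(info$category), "NA",
                                            info$category),
                          is_duf = as.numeric(info$is_duf),
                          stringsAsFactors = FALSE))
  g
}

#' Connected components of the association network
#'
#' @param g An igraph network.
#' @return List of character vectors (node names, sorted), ordered by
#'   decreasing component size with lexicographic tie-break on the first
#'   member.
#' @export
network_components <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1L)),
               vapply(groups, `[`, character(1L), 1L))
  unname(groups[ord])
}

#' Export the association network
#'
#' GraphML and GML (Cytoscape-loadable) via igraph, or a plain edge-list
#' TSV with columns `family_a`, `family_b`, `rho`. GraphML round-trips
#' nodes, edges, weights and attributes losslessly.
#'
#' @param g An igraph network.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"gml"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "gml", "edge-tsv")) {
  format <- match.arg(format)
  if (format %in% c("graphml", "gml")) {
    igraph::write_graph(g, path, format = format)
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    d <- data.frame(family_a = el$from, family_b = el$to, rho = el$weight)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a GraphML network
#'
#' @param path Path to a GraphML file written by [export_graph()].
#' @return An igraph network.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
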