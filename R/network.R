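#' Modelable sub-networks by single-linkage clustering
#'
#' The interactions carrying a structure element form a graph; its
#' connected components are the modelable sub-networks, i.e. the maximal
#' sets of proteins for which every pair is linked through at least one
#' path of template-bearing interactions.  Components are returned sorted
#' by size (descending), then by lexicographically smallest member
#' accession, so run output is deterministic.
#'
#' @param elements List of [ppi_element()].
#' @return List of `sub_network` objects, each with `nodes` (character),
#'   `edges` (list of `list(pair_key, element)`), and `degree` (named
#'   integer: distinct neighbours per node, self-loops contributing 1).
#' @export
cluster_subnetworks <- function(elements) {
  if (length(elements) == 0) return(list())
  ea <- vapply(elements, function(e) e$interaction$acc_a, character(1))
  eb <- vapply(elements, function(e) e$interaction$acc_b, character(1))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, stringsAsFactors = FALSE),
    directed = FALSE)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  nets <- lapply(member, function(nodes) {
    nodes <- sort(nodes)
    in_comp <- ea %in% nodes | eb %in% nodes
    edges <- lapply(which(in_comp), function(i)
      list(pair = pair_key(c(ea[i], eb[i])), element = elements[[i]]))
    nbr <- lapply(setNames(nodes, nodes), function(v) {
      others <- unique(c(eb[in_comp & ea == v], ea[in_comp & eb == v]))
      others  # a self-loop leaves v itself in the set, contributing 1
    })
    degree <- vapply(nbr, length, integer(1))
    structure(list(nodes = nodes, edges = edges, degree = degree),
              class = "sub_network")
  })
  sizes <- vapply(nets, function(n) length(n$nodes), integer(1))
  firsts <- vapply(nets, function(n) n$nodes[1], character(1))
  unname(nets[order(-sizes, firsts)])
}

#' @export
print.sub_network <- function(x, ...) {
  cat(sprintf("<sub_network> %d nodes, %d element edges\n",
              length(x$nodes), length(x$edges)))
  invisible(x)
}

#' Interaction degree of a node within a sub-network
#'
#' Number of distinct interacting partners of `node` in the sub-network; a
#' homodimer self-loop contributes 1 (it names one partner, the protein
#' itself).
#'
#' @param net A `sub_network`.
#' @param node Protein accession.
#' @return Integer degree.
#' @export
degree_of <- function(net, node) {
  if (!node %in% net$nodes) stop("node ", node, " not in sub-network")
  unname(net$degree[node])
}

#' Export sub-networks as an edge-list TSV and JSON graph document
#'
#' @param nets List of `sub_network` objects.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly `NULL`.
#' @export
write_subnetworks <- function(nets, tsv_path = NULL, json_path = NULL) {
  rows <- do.call(rbind, lapply(seq_along(nets), function(i) {
    net <- nets[[i]]
    do.call(rbind, lapply(net$edges, function(e) {
      el <- e$element
      data.frame(subnetwork = i, acc_a = el$interaction$acc_a,
                 acc_b = el$interaction$acc_b,
                 template_entry = el$template_entry,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(tsv_path)) {
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    doc <- lapply(seq_along(nets), function(i) {
      net <- nets[[i]]
      list(id = i, nodes = net$nodes,
           degree = as.list(net$degree),
           edges = lapply(net$edges, function(e)
             list(acc_a = e$element$interaction$acc_a,
                  acc_b = e$element$interaction$acc_b,
                  template_entry = e$element$template_entry)))
    })
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(NULL)
}
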