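#' Reaction-network container
#'
#' A `reaction_network` holds the enzyme-centric projection of a metabolic
#' pathway: nodes are enzyme-catalysed reactions and an edge records that a
#' product metabolite of one reaction is an essential substrate of the other.
#' The object carries a node table (with the encoding genes of each enzyme
#' node, since one enzyme complex may be encoded by several genes) and an edge
#' table; it exists in a directed form (as built from substrate-product pairs)
#' and an undirected form (as used by all shortest-path analyses).
#'
#' @param nodes Tibble with columns `node_id` (character), `genes`
#'   (list-column of character vectors) and optionally `label`.
#' @param edges Tibble with columns `from`, `to` and optionally `compound`
#'   (the mediating metabolite).
#' @param directed Logical; are the edges ordered pairs?
#' @param is_lcc Logical; is this the largest connected component of an
#'   undirected projection (i.e. connected by construction)?
#'
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(nodes, edges, directed = TRUE, is_lcc = FALSE) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!all(c("node_id") %in% names(nodes))) {
    abort("`nodes` must have a `node_id` column.")
  }
  if (!"genes" %in% names(nodes)) nodes$genes <- as.list(nodes$node_id)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$node_id
  if (anyDuplicated(nodes$node_id)) abort("duplicate `node_id` in nodes.")
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have `from` and `to` columns.")
  }
  if (!"compound" %in% names(edges)) edges$compound <- NA_character_
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes$node_id)
  if (length(missing) > 0) {
    abort(paste0("edges reference unknown nodes: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  structure(
    list(nodes = nodes, edges = edges,
         directed = isTRUE(directed), is_lcc = isTRUE(is_lcc)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  kind <- if (x$directed) "directed" else "undirected"
  cat(sprintf("<reaction_network> %d nodes, %d %s edges%s\n",
              nrow(x$nodes), nrow(x$edges), kind,
              if (x$is_lcc) " (largest connected component)" else ""))
  invisible(x)
}

#' Convert a reaction network to an igraph graph
#'
#' @param network A [reaction_network()].
#' @return An [igraph::igraph] object with vertex names equal to `node_id`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")],
    directed = network$directed,
    vertices = network$nodes["node_id"]
  )
}

#' @export
tidy.reaction_network <- function(x, ...) x$edges

#' @export
glance.reaction_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    directed = x$directed,
    is_lcc = x$is_lcc
  )
}

node_degrees <- function(network) {
  g <- as_igraph(network)
  setNames(as.integer(igraph::degree(g, mode = "all")),
           igraph::V(g)$name)
}
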