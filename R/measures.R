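#' Traditional per-node network measures
#'
#' The four classic nodal measures used to ask whether chaperonin substrate
#' classes sit at structurally distinctive positions:
#' \describe{
#'   \item{degree}{number of neighbours k_i.}
#'   \item{closeness}{(N - 1) / sum over j of d(i, j): high when the node is
#'     on average close to every other node; defined on connected networks.}
#'   \item{betweenness}{sum over unordered pairs s != t (both distinct from
#'     i) of the fraction of shortest s-t paths passing through i, divided by
#'     the maximum nodal value so the most central node scores exactly 1. On
#'     a graph where no node lies interior to any shortest path (e.g. a
#'     complete graph) all values are 0.}
#'   \item{clustering}{2 M_i / [k_i (k_i - 1)], the edge density among the
#'     node's neighbours; set to 0 when k_i < 2 so per-class summaries stay
#'     total.}
#' }
#'
#' @param network An undirected connected [reaction_network()].
#' @return A tibble with columns `node_id`, `degree`, `closeness`,
#'   `betweenness`, `clustering`.
#' @export
node_measures <- function(network) {
  tibble(
    node_id = network$nodes$node_id,
    degree = degree_centrality(network),
    closeness = closeness_centrality(network),
    betweenness = betweenness_centrality(network),
    clustering = clustering_coefficient(network)
  )
}

measure_graph <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  if (network$directed) abort("measures are defined on the undirected network")
  as_igraph(network)
}

#' @rdname node_measures
#' @export
degree_centrality <- function(network) {
  g <- measure_graph(network)
  unname(as.integer(igraph::degree(g)))
}

#' @rdname node_measures
#' @export
closeness_centrality <- function(network) {
  g <- measure_graph(network)
  if (igraph::vcount(g) < 2) abort("closeness needs at least 2 nodes")
  if (!igraph::is_connected(g)) abort("closeness needs a connected network")
  unname(igraph::closeness(g, normalized = TRUE))
}

#' @rdname node_measures
#' @export
betweenness_centrality <- function(network) {
  g <- measure_graph(network)
  raw <- igraph::betweenness(g, directed = FALSE)
  m <- max(raw)
  if (m == 0) return(unname(raw))
  unname(raw / m)
}

#' @rdname node_measures
#' @export
clustering_coefficient <- function(network) {
  g <- measure_graph(network)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  unname(cc)
}

#' Competition rank of a node on a measure
#'
#' Rank 1 is the largest value; tied values share the smallest rank of the
#' tie group ("competition" ranking, so values 5, 3, 3, 1 rank 1, 2, 2, 4).
#'
#' @param node A node identifier.
#' @param values Named numeric vector (names are node identifiers) or a
#'   two-column data frame (`node_id`, value).
#' @return Integer rank in descending order of the measure.
#' @export
rank_of <- function(node, values) {
  if (is.data.frame(values)) {
    values <- setNames(values[[2]], values[[1]])
  }
  if (!node %in% names(values)) abort(sprintf("node `%s` not in values", node))
  ranks <- rank(-values, ties.method = "min")
  as.integer(ranks[[node]])
}

#' Boxplots of a node measure by substrate class
#'
#' @param measures Output of [node_measures()].
#' @param annotation Output of [annotate_nodes()].
#' @param measure Name of the measure column to plot.
#' @param log_y Show the measure on a log axis (conventional for degree and
#'   abundance-like quantities).
#' @return A ggplot object.
#' @export
plot_measure_by_class <- function(measures, annotation, measure = "degree",
                                  log_y = measure == "degree") {
  df <- annotation |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::inner_join(measures, by = "node_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                        y = .data[[measure]])) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = "chaperonin substrate class", y = measure) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
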