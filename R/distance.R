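#' Shortest-path distances from a source node
#'
#' Breadth-first (unweighted) shortest-path lengths from one source node to
#' every node of a connected undirected network.
#'
#' @param network A connected undirected [reaction_network()] (the LCC).
#' @param source A node identifier present in the network.
#' @return A tibble with columns `node_id`, `distance` (non-negative
#'   integers); `distance` is 0 at the source. Attribute `"source"` records
#'   the source node.
#' @export
bfs_distances <- function(network, source) {
  stopifnot(inherits(network, "reaction_network"))
  if (!source %in% network$nodes$node_id) {
    abort(sprintf("source node `%s` is not in the network", source))
  }
  g <- as_igraph(network)
  d <- igraph::distances(g, v = source, mode = "all")[1, ]
  out <- tibble(node_id = names(d), distance = as.numeric(d))
  attr(out, "source") <- source
  out
}

#' Pick the central (source) node
#'
#' The center of the distance analysis is the enzyme node encoded by a
#' configured gene set; the default is pyruvate kinase (pykF `b1676`, pykA
#' `b1854`), the classic hub next to pyruvate at the crossroads of
#' glycolysis, the citrate cycle and amino-acid metabolism. When several
#' nodes match, the one with the highest degree wins; remaining ties break on
#' the lexicographically smallest node identifier.
#'
#' @param network A [reaction_network()].
#' @param center_genes Character vector of gene identifiers that mark the
#'   center enzyme.
#' @return A single node identifier.
#' @export
select_center <- function(network, center_genes = c("b1676", "b1854")) {
  stopifnot(inherits(network, "reaction_network"))
  center_genes <- normalize_gene_ids(center_genes)
  hit <- network$nodes$node_id[
    purrr::map_lgl(network$nodes$genes, function(g) any(g %in% center_genes))
  ]
  if (length(hit) == 0) {
    abort(paste0("no node carries a center gene (looked for: ",
                 paste(center_genes, collapse = ", "), ")"))
  }
  if (length(hit) == 1) return(hit)
  deg <- node_degrees(network)[hit]
  hit <- hit[deg == max(deg)]
  sort(hit)[1]
}

new_distance_profile <- function(distances, kind) {
  distances <- as.numeric(distances)
  histogram <- tibble(h = sort(unique(distances))) |>
    dplyr::mutate(
      n = purrr::map_int(.data$h, function(hh) sum(distances == hh)),
      proportion = .data$n / length(distances)
    )
  structure(
    list(histogram = histogram,
         n = length(distances),
         mean = mean(distances),
         median = median(distances),
         distances = distances,
         kind = kind),
    class = "distance_profile"
  )
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile: %s> n = %d, mean = %.3f, median = %g\n",
              x$kind, x$n, x$mean, x$median))
  print(x$histogram)
  invisible(x)
}

#' @export
tidy.distance_profile <- function(x, ...) x$histogram

#' @export
glance.distance_profile <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, median = x$median, kind = x$kind)
}

#' @export
autoplot.distance_profile <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$h, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "shortest path length h", y = "proportion",
                  title = object$kind) +
    ggplot2::theme_minimal()
}

#' Distance-from-center profile of a node set
#'
#' For a class C of enzymes, the profile gives the proportion P(h) of members
#' separated by shortest-path length h from the central node o:
#' P(h) = (1/|C|) * sum over x in C of delta(d(o, x) - h), where delta is the
#' Kronecker delta. h = 0 is a legal bin (the center may itself belong to the
#' class).
#'
#' @param dmap Distance map from [bfs_distances()].
#' @param members Character vector of member node identifiers (subset of the
#'   distance map's nodes, non-empty).
#' @return A `distance_profile` (histogram over h plus `n`, `mean`,
#'   `median`).
#' @export
distance_from_center_profile <- function(dmap, members) {
  members <- unique(members)
  if (length(members) == 0) abort("`members` is empty")
  missing <- setdiff(members, dmap$node_id)
  if (length(missing) > 0) {
    abort(paste0("members not in distance map: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  d <- dmap$distance[match(members, dmap$node_id)]
  new_distance_profile(d, kind = "distance from center")
}

#' Within-class pairwise distance profile
#'
#' The proportion of unordered member pairs \{x, y\} separated by shortest
#' path length h; self-pairs are excluded, so a class of size m yields
#' m(m-1)/2 pair distances.
#'
#' @param network A connected undirected [reaction_network()].
#' @param members Character vector of at least two node identifiers.
#' @return A `distance_profile` over the pair distances.
#' @export
pairwise_class_distance_profile <- function(network, members) {
  stopifnot(inherits(network, "reaction_network"))
  members <- unique(members)
  if (length(members) < 2) abort("need at least 2 members for pair distances")
  missing <- setdiff(members, network$nodes$node_id)
  if (length(missing) > 0) {
    abort(paste0("members not in network: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  g <- as_igraph(network)
  dm <- igraph::distances(g, v = members, to = members, mode = "all")
  dm <- dm[sort(members), sort(members), drop = FALSE]
  d <- dm[upper.tri(dm)]
  new_distance_profile(d, kind = "within-class pair distance")
}
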