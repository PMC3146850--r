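#' Build the directed reaction-adjacency network
#'
#' Projects reaction entries onto a graph whose nodes are enzyme-catalysed
#' reactions and whose directed edges follow metabolite flow: an edge A -> B
#' is drawn when at least one product of A is an essential substrate of B,
#' judged only against the curated substrate-product pairs of each reaction.
#' Because currency metabolites (ATP, NADH, water, ...) do not appear in
#' those pairs, they cannot create shortcut edges between otherwise unrelated
#' reactions. Reversible reactions contribute their pairs in both
#' orientations. Reactions sharing a `reaction_id` across pathway documents
#' are merged into a single node (gene sets and pair sets are unioned).
#' Self-edges are dropped.
#'
#' @param entries A tibble of reaction entries as returned by [parse_kgml()]
#'   (columns `reaction_id`, `genes`, `pairs`, `reversible`); entries from
#'   several pathway files can be row-bound first.
#' @return A directed [reaction_network()]; each edge row records the
#'   mediating `compound`.
#' @export
build_reaction_network <- function(entries) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0) abort("no reactions with curated pairs")

  merged <- entries |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(
      genes = list(sort(unique(unlist(.data$genes)))),
      pairs = list(dplyr::distinct(dplyr::bind_rows(.data$pairs))),
      reversible = any(.data$reversible),
      order = min(dplyr::cur_group_rows())
    ) |>
    dplyr::arrange(.data$order) |>
    dplyr::select(-"order")

  oriented <- merged |>
    dplyr::mutate(pairs = purrr::map2(.data$pairs, .data$reversible, function(p, rev) {
      if (rev) {
        dplyr::distinct(dplyr::bind_rows(
          p, tibble(substrate = p$product, product = p$substrate)))
      } else {
        p
      }
    })) |>
    dplyr::select("reaction_id", "pairs") |>
    tidyr::unnest("pairs")

  if (nrow(oriented) == 0) abort("no reactions with curated pairs")

  producers <- dplyr::select(oriented, from = "reaction_id", compound = "product")
  consumers <- dplyr::select(oriented, to = "reaction_id", compound = "substrate")
  edges <- dplyr::inner_join(producers, consumers, by = "compound",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct(.data$from, .data$to, .data$compound)

  nodes <- tibble(
    node_id = merged$reaction_id,
    genes = merged$genes,
    label = purrr::map_chr(merged$genes, function(g) {
      if (length(g) > 0) g[[1]] else NA_character_
    })
  )
  reaction_network(nodes, edges, directed = TRUE, is_lcc = FALSE)
}

#' Reduce to the undirected largest connected component
#'
#' Drops edge direction (A -> B and B -> A collapse to one edge, parallel
#' edges through different metabolites collapse to one unweighted edge) and
#' keeps the connected component with the most nodes, so that a shortest path
#' exists between every node pair. Ties between equally large components are
#' broken in favour of the one containing the lexicographically smallest node
#' identifier.
#'
#' @param network A [reaction_network()] with at least one node.
#' @return An undirected, connected [reaction_network()] with `is_lcc = TRUE`.
#' @export
to_undirected_lcc <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  if (nrow(network$nodes) == 0) abort("network has no nodes")

  edges <- network$edges |>
    dplyr::mutate(a = pmin(.data$from, .data$to),
                  b = pmax(.data$from, .data$to)) |>
    dplyr::filter(.data$a != .data$b) |>
    dplyr::distinct(.data$a, .data$b, .keep_all = TRUE) |>
    dplyr::select(from = "a", to = "b", "compound")

  und <- reaction_network(network$nodes, edges, directed = FALSE)
  g <- as_igraph(und)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    smallest_member <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(smallest_member)][1]
  }
  keep <- igraph::V(g)$name[comp$membership == best]

  reaction_network(
    nodes = dplyr::filter(und$nodes, .data$node_id %in% keep),
    edges = dplyr::filter(und$edges, .data$from %in% keep & .data$to %in% keep),
    directed = FALSE, is_lcc = TRUE
  )
}
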