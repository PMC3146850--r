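#' Annotate enzyme nodes with chaperonin substrate classes
#'
#' Attaches substrate-class labels to network nodes through their encoding
#' genes: a node receives label L when at least one of its genes carries L
#' under the chosen scheme. An enzyme complex whose subunit genes share the
#' same class is counted once for that class (per-gene counting would be
#' redundant). A node whose genes span *different* classes within one scheme
#' keeps all of them (one row each) and a warning is raised, since mixed
#' complexes are ambiguous.
#'
#' @param network A [reaction_network()].
#' @param classes A class table from [read_class_table()] / [as_class_table()].
#' @param scheme `"kerner"` (Class I/II/III) or `"fujiwara"`
#'   (Class I/II'/IV, plus III-).
#' @return A tibble with columns `node_id`, `class` -- one row per node-label;
#'   unclassified nodes appear once with `class = NA`, so the full node
#'   universe (the "all enzymes" background population) is preserved.
#' @export
annotate_nodes <- function(network, classes, scheme = c("kerner", "fujiwara")) {
  stopifnot(inherits(network, "reaction_network"))
  scheme <- match.arg(scheme)
  classes <- as_tibble(classes)
  if (nrow(classes) == 0) abort("empty class table")
  col <- paste0(scheme, "_class")
  if (!col %in% names(classes)) abort(sprintf("class table lacks `%s`", col))
  lut <- setNames(classes[[col]], classes$gene_id)

  ann <- network$nodes |>
    dplyr::mutate(class = purrr::map(.data$genes, function(g) {
      labs <- unique(stats::na.omit(unname(lut[g])))
      if (length(labs) == 0) NA_character_ else sort(labs)
    })) |>
    dplyr::select("node_id", "class") |>
    tidyr::unnest("class")

  mixed <- ann |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::count(.data$node_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    warn(sprintf("%d node(s) carry more than one class within the %s scheme: %s",
                 nrow(mixed), scheme,
                 paste(utils::head(mixed$node_id, 5), collapse = ", ")))
  }
  attr(ann, "scheme") <- scheme
  ann
}

#' Count nodes per substrate class
#'
#' @param annotation Output of [annotate_nodes()].
#' @return A tibble with columns `class`, `n` (number of enzyme nodes carrying
#'   that label; a multi-label node contributes to each of its labels).
#' @export
class_counts <- function(annotation) {
  annotation |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::arrange(.data$class)
}

#' Node sets per class
#'
#' Convenience accessor used by the distance profiles: the node identifiers
#' carrying a given label, or all nodes when `class = NULL` (the background
#' population of all metabolic enzymes).
#'
#' @param annotation Output of [annotate_nodes()].
#' @param class A class label, or `NULL` for every node.
#' @return Character vector of node identifiers.
#' @export
class_members <- function(annotation, class = NULL) {
  if (is.null(class)) return(unique(annotation$node_id))
  unique(annotation$node_id[!is.na(annotation$class) &
                              annotation$class == class])
}
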