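#' Degree of conservation of genes across species
#'
#' The degree of conservation of gene i is S_i / S_total, where S_i is the
#' number of surveyed species possessing at least one ortholog of i and
#' S_total is the total number of species in the ortholog survey (a property
#' of the snapshot, taken from the table itself rather than hard-coded).
#' Well-conserved genes are read as evolutionarily old; species-specific ones
#' as late arrivals.
#'
#' @param orthologs Ortholog-presence table from [read_ortholog_table()] (or
#'   any tibble with columns `gene_id`, `species`, optionally carrying the
#'   species universe in attribute `"species"`).
#' @param genes Genes to score; defaults to every gene in the table. Asking
#'   for a gene absent from the table is an error.
#' @param s_total Override for the species universe size (e.g. when the
#'   survey's zero-presence species are not represented in a long-format
#'   file).
#' @return A tibble with columns `gene_id`, `s_i`, `s_total`, `ratio`.
#' @export
conservation_degree <- function(orthologs, genes = NULL, s_total = NULL) {
  orthologs <- dplyr::distinct(as_tibble(orthologs))
  universe <- attr(orthologs, "species")
  if (is.null(s_total)) {
    s_total <- if (!is.null(universe)) length(universe)
               else dplyr::n_distinct(orthologs$species)
  }
  if (s_total <= 0) abort("species universe is empty (S_total = 0)")
  known <- attr(orthologs, "genes") %||% sort(unique(orthologs$gene_id))
  if (is.null(genes)) {
    genes <- known
  } else {
    genes <- normalize_gene_ids(genes)
    unknown <- setdiff(genes, known)
    if (length(unknown) > 0) {
      abort(paste0("gene(s) not in ortholog table: ",
                   paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  counts <- orthologs |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::count(.data$gene_id, name = "s_i")
  tibble(gene_id = genes) |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::mutate(
      s_i = dplyr::coalesce(.data$s_i, 0L),
      s_total = as.integer(s_total),
      ratio = .data$s_i / .data$s_total
    )
}

#' Compare the degree of conservation across substrate classes
#'
#' Groups conservation ratios by chaperonin substrate class and tests for a
#' difference with the Kruskal-Wallis test; class medians are reported in
#' class order so the monotone trend (conservation decreasing with chaperonin
#' requirement) can be read off directly. Two populations are meaningful:
#' only the substrate genes that are metabolic enzymes of the network
#' (`genes` = the network's gene set), or all chaperonin substrates
#' (`genes = NULL`). Under the revised scheme, Class III- is omitted by
#' default because its chaperonin requirement is unclear; set
#' `include_ambiguous = TRUE` to keep it as a fourth group.
#'
#' @param records Conservation records from [conservation_degree()].
#' @param classes A class table ([read_class_table()] / [as_class_table()]).
#' @param scheme `"kerner"` or `"fujiwara"`.
#' @param genes Optional gene universe restriction (e.g.
#'   [network_genes()] for the enzymes-only population).
#' @param include_ambiguous Keep Class III- under the Fujiwara scheme?
#' @return An object of class `conservation_by_class`: the per-gene samples
#'   (`$data`), class medians in class order (`$medians`) and the
#'   Kruskal-Wallis result (`$test`).
#' @export
conservation_by_class <- function(records, classes,
                                  scheme = c("kerner", "fujiwara"),
                                  genes = NULL, include_ambiguous = FALSE) {
  scheme <- match.arg(scheme)
  col <- paste0(scheme, "_class")
  order <- if (scheme == "kerner") c("I", "II", "III") else c("I", "II'", "IV")
  if (scheme == "fujiwara" && include_ambiguous) order <- c(order, "III-")

  df <- as_tibble(classes) |>
    dplyr::select("gene_id", class = dplyr::all_of(col)) |>
    dplyr::filter(.data$class %in% order) |>
    dplyr::inner_join(records, by = "gene_id")
  if (!is.null(genes)) {
    df <- dplyr::filter(df, .data$gene_id %in% normalize_gene_ids(genes))
  }
  for (cl in order) {
    if (!cl %in% df$class) abort(sprintf("class %s has no conservation records", cl))
  }
  df$class <- factor(df$class, levels = order)
  medians <- df |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(.data$ratio),
                     mean = mean(.data$ratio))
  structure(
    list(data = df, medians = medians,
         test = kruskal_wallis(df, "ratio", "class")),
    class = "conservation_by_class"
  )
}

#' @export
print.conservation_by_class <- function(x, ...) {
  cat("<conservation_by_class>\n")
  print(x$medians)
  cat(sprintf("Kruskal-Wallis: H = %.3f, p = %.4g\n",
              x$test$statistic, x$test$p_value))
  invisible(x)
}

#' @export
tidy.conservation_by_class <- function(x, ...) x$data

#' @export
glance.conservation_by_class <- function(x, ...) x$test

#' @export
autoplot.conservation_by_class <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$class, y = .data$ratio)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = "chaperonin substrate class",
                  y = expression(S[i] / S[total])) +
    ggplot2::theme_minimal()
}

#' Gene universe of a network
#'
#' All gene identifiers attached to the nodes of a reaction network -- the
#' "metabolic enzymes" population for conservation comparisons.
#'
#' @param network A [reaction_network()].
#' @return Character vector of gene identifiers.
#' @export
network_genes <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  sort(unique(unlist(network$nodes$genes)))
}
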