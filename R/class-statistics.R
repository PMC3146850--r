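#' Nonparametric and parametric group comparisons
#'
#' Thin tidy wrappers around the classical tests used throughout the
#' analysis, returning one-row tibbles so results bind into reports. All
#' take a data frame first with tidy-eval column selection.
#'
#' `kruskal_wallis()` is the tie-corrected Kruskal-Wallis H test with a
#' chi-square reference distribution on (number of groups - 1) degrees of
#' freedom; shortest-path distances are small integers, so the tie correction
#' always matters. When every observation is identical the statistic is 0 and
#' p = 1 by convention (the chi-square form is 0/0 there).
#'
#' `wilcoxon_rank_sum()` is the two-sided two-sample Wilcoxon (Mann-Whitney)
#' test; the exact null enumeration is used when both groups have at most 10
#' untied observations, otherwise the tie-corrected normal approximation.
#'
#' `student_t()` is the classical pooled-variance (not Welch) two-sample
#' t-test. With zero pooled variance the p-value degenerates to 1 for equal
#' means and 0 otherwise.
#'
#' @param data A data frame.
#' @param value Column holding the measured values.
#' @param group Column holding the group labels (2 for the two-sample tests).
#' @return A one-row tibble: `method`, `statistic`, `df` (KW only,
#'   `NA` otherwise), `p_value`, `n_per_group` (list of named group sizes).
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  grp <- as.character(dplyr::pull(data, {{ group }}))
  sizes <- table(grp)
  if (length(sizes) < 2) abort("Kruskal-Wallis needs at least 2 groups")
  if (any(sizes == 0)) abort("empty group")
  if (length(unique(v)) == 1) {
    return(test_row("kruskal_wallis", statistic = 0,
                    df = length(sizes) - 1, p_value = 1, sizes = sizes))
  }
  fit <- stats::kruskal.test(v, factor(grp))
  test_row("kruskal_wallis", statistic = unname(fit$statistic),
           df = unname(fit$parameter), p_value = fit$p.value, sizes = sizes)
}

#' @rdname kruskal_wallis
#' @export
wilcoxon_rank_sum <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  grp <- as.character(dplyr::pull(data, {{ group }}))
  lev <- sort(unique(grp))
  if (length(lev) != 2) abort("Wilcoxon rank-sum needs exactly 2 groups")
  a <- v[grp == lev[1]]
  b <- v[grp == lev[2]]
  if (length(a) == 0 || length(b) == 0) abort("empty sample")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  test_row("wilcoxon_rank_sum", statistic = unname(fit$statistic),
           df = NA_real_, p_value = min(1, fit$p.value),
           sizes = table(grp))
}

#' @rdname kruskal_wallis
#' @export
student_t <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  grp <- as.character(dplyr::pull(data, {{ group }}))
  lev <- sort(unique(grp))
  if (length(lev) != 2) abort("Student's t needs exactly 2 groups")
  a <- v[grp == lev[1]]
  b <- v[grp == lev[2]]
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    return(test_row("student_t", statistic = stat, df = NA_real_,
                    p_value = p, sizes = table(grp)))
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  test_row("student_t", statistic = unname(fit$statistic),
           df = unname(fit$parameter), p_value = fit$p.value,
           sizes = table(grp))
}

test_row <- function(method, statistic, df, p_value, sizes) {
  tibble(
    method = method,
    statistic = as.numeric(statistic),
    df = as.numeric(df),
    p_value = as.numeric(p_value),
    n_per_group = list(setNames(as.integer(sizes), names(sizes)))
  )
}

#' Kruskal-Wallis comparison of every network measure across classes
#'
#' For each of degree, closeness, betweenness and clustering coefficient,
#' tests whether the distribution differs among the substrate classes of the
#' chosen scheme (Kerner: I/II/III; Fujiwara: I/II'/IV -- Class III- is not
#' part of the revised scheme proper and is left out).
#'
#' @param measures Output of [node_measures()].
#' @param annotation Output of [annotate_nodes()] on the same node universe.
#' @param classes Class labels to compare; defaults to the scheme the
#'   annotation was made with.
#' @return A tibble with one row per measure (columns as [kruskal_wallis()]
#'   plus `measure`).
#' @export
measures_by_class <- function(measures, annotation, classes = NULL) {
  if (is.null(classes)) {
    scheme <- attr(annotation, "scheme") %||% "kerner"
    classes <- if (scheme == "fujiwara") c("I", "II'", "IV") else c("I", "II", "III")
  }
  df <- annotation |>
    dplyr::filter(.data$class %in% classes) |>
    dplyr::inner_join(measures, by = "node_id")
  for (cl in classes) {
    if (!cl %in% df$class) abort(sprintf("class %s has no nodes", cl))
  }
  purrr::map_dfr(c("degree", "closeness", "betweenness", "clustering"),
                 function(m) {
                   dplyr::mutate(kruskal_wallis(df, !!rlang::sym(m), "class"),
                                 measure = m, .before = 1)
                 })
}

#' Does protein abundance vary with distance from the center?
#'
#' Groups per-gene abundances (emPAI-like values) by the integer shortest
#' path length of the encoding enzyme node from the central node and applies
#' the Kruskal-Wallis test across the distance bins. Genes without abundance
#' values and abundances without a network gene are dropped by intersection.
#' The test is rank-based, so log-transforming the abundances (as done for
#' display) cannot change the result.
#'
#' @param abundance Tibble with columns `gene_id`, `abundance`.
#' @param dmap Distance map from [bfs_distances()].
#' @param network The [reaction_network()] the distance map was computed on
#'   (supplies the gene lists of the nodes).
#' @return A one-row tibble as [kruskal_wallis()], with attribute `"data"`
#'   holding the gene-level tibble (`gene_id`, `distance`, `abundance`).
#' @export
abundance_vs_distance <- function(abundance, dmap, network) {
  stopifnot(inherits(network, "reaction_network"))
  gene_dist <- network$nodes |>
    dplyr::select("node_id", "genes") |>
    tidyr::unnest_longer("genes", values_to = "gene_id") |>
    dplyr::inner_join(dmap, by = "node_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(distance = min(.data$distance))
  df <- dplyr::inner_join(gene_dist, abundance, by = "gene_id") |>
    dplyr::filter(!is.na(.data$abundance))
  if (dplyr::n_distinct(df$distance) < 2) {
    abort("need at least 2 distance bins with abundance values")
  }
  out <- kruskal_wallis(df, "abundance", "distance")
  attr(out, "data") <- df
  out
}

#' Scatter of protein abundance against distance from the center
#'
#' @param result Output of [abundance_vs_distance()].
#' @return A ggplot object (abundance on a log10 axis).
#' @export
plot_abundance_vs_distance <- function(result) {
  df <- attr(result, "data")
  if (is.null(df)) abort("result carries no data; use abundance_vs_distance()")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$distance),
                                   y = .data$abundance)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from center", y = "protein abundance (emPAI)") +
    ggplot2::theme_minimal()
}
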