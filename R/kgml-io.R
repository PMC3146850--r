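#' Parse a KGML pathway document into reaction entries
#'
#' Reads a KEGG pathway XML (KGML) document and returns one row per reaction
#' element that carries at least one essential substrate-product pair and is
#' linked to at least one gene entry. KGML lists, for every reaction, the
#' curated substrates and products that take part in the actual chemical
#' transformation; ubiquitous currency metabolites (ATP, NADH, water, ...) are
#' absent from those lists, which is what makes the downstream
#' reaction-adjacency projection biologically meaningful. Each retained
#' reaction contributes all substrate x product combinations as its pairs.
#'
#' Gene identifiers are normalised to lower-case b-numbers: an organism prefix
#' such as `eco:` is stripped. The reversibility flag is recorded verbatim
#' from the reaction `type` attribute; reversible reactions contribute both
#' orientations of their pairs later, at network-build time, so parsing stays
#' lossless.
#'
#' @param x Path to a KGML file, or a length-1 character scalar holding the
#'   XML text itself.
#'
#' @return A tibble with one row per retained reaction, in document order:
#'   \describe{
#'     \item{reaction_id}{the KGML reaction `name` attribute, verbatim}
#'     \item{genes}{list-column of normalised gene identifiers}
#'     \item{pairs}{list-column of tibbles with columns `substrate`,
#'       `product` (KEGG compound identifiers)}
#'     \item{reversible}{logical}
#'   }
#' @export
#' @examples
#' kgml <- paste0(
#'   '<pathway name="path:syn00001" org="syn" number="00001">',
#'   '<entry id="1" name="syn:b0001" type="gene" reaction="rn:R1"/>',
#'   '<reaction name="rn:R1" type="irreversible">',
#'   '<substrate name="cpd:C1"/><product name="cpd:C2"/>',
#'   '</reaction></pathway>'
#' )
#' parse_kgml(kgml)
parse_kgml <- function(x) {
  doc <- xml2::read_xml(x)

  entries <- xml2::xml_find_all(doc, ".//entry[@reaction]")
  reaction_genes <- list()
  for (e in entries) {
    rxns <- strsplit(xml2::xml_attr(e, "reaction"), "\\s+")[[1]]
    genes <- normalize_gene_ids(strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]])
    for (r in rxns) {
      reaction_genes[[r]] <- union(reaction_genes[[r]], genes)
    }
  }

  rxn_nodes <- xml2::xml_find_all(doc, ".//reaction")
  rows <- purrr::map(rxn_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "name")
    subs <- xml2::xml_attr(xml2::xml_find_all(rx, "./substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(rx, "./product"), "name")
    if (length(subs) == 0 || length(prods) == 0) {
      warn(sprintf("reaction %s has no substrate-product pair; skipped", rid))
      return(NULL)
    }
    genes <- reaction_genes[[rid]]
    if (is.null(genes) || length(genes) == 0) {
      warn(sprintf("reaction %s is not referenced by any gene entry; skipped", rid))
      return(NULL)
    }
    pairs <- tidyr::expand_grid(substrate = subs, product = prods)
    tibble(
      reaction_id = rid,
      genes = list(sort(genes)),
      pairs = list(pairs),
      reversible = identical(xml2::xml_attr(rx, "type"), "reversible")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(reaction_id = character(), genes = list(),
                  pairs = list(), reversible = logical())
  }
  out
}

normalize_gene_ids <- function(x) {
  tolower(sub("^[A-Za-z]+:", "", x))
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

kerner_labels <- c("I", "II", "III")
fujiwara_labels <- c("I", "II'", "IV", "III-")

#' Read a chaperonin substrate-class table
#'
#' The table maps gene identifiers (b-numbers) to substrate classes under the
#' two classification schemes in use for GroEL/GroES requirement: the original
#' three-class scheme (Class I chaperonin-independent, Class II partially
#' dependent, Class III obligate candidates) and the in-vivo revised scheme
#' (Class I, II', IV, plus the ambiguous III- subset that is soluble without
#' the chaperonin). Empty cells mean "not classified under that scheme".
#'
#' @param path TSV or CSV file with columns `gene_id`, `kerner_class`,
#'   `fujiwara_class` (either class column may be omitted).
#' @return A tibble (`class_table`) with columns `gene_id`, `kerner_class`,
#'   `fujiwara_class`; unclassified entries are `NA`.
#' @export
read_class_table <- function(path) {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!"gene_id" %in% names(raw)) abort("class table needs a `gene_id` column.")
  for (col in c("kerner_class", "fujiwara_class")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
    raw[[col]][!is.na(raw[[col]]) & raw[[col]] == ""] <- NA_character_
  }
  as_class_table(raw[, c("gene_id", "kerner_class", "fujiwara_class")])
}

#' Assemble and validate a class table
#'
#' @param x Data frame with columns `gene_id`, `kerner_class`,
#'   `fujiwara_class`.
#' @return A validated tibble of class memberships.
#' @export
as_class_table <- function(x) {
  x <- as_tibble(x)
  x$gene_id <- normalize_gene_ids(x$gene_id)
  check_labels <- function(values, allowed, scheme) {
    bad <- setdiff(stats::na.omit(unique(values)), allowed)
    if (length(bad) > 0) {
      abort(sprintf("unknown %s class label(s) %s; allowed: %s",
                    scheme, paste(bad, collapse = ", "),
                    paste(allowed, collapse = ", ")))
    }
  }
  check_labels(x$kerner_class, kerner_labels, "Kerner")
  check_labels(x$fujiwara_class, fujiwara_labels, "Fujiwara")
  x <- dplyr::distinct(x)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("conflicting class assignments for gene(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  x
}

#' Read an ortholog-presence table
#'
#' Accepts either a wide binary matrix (first column `gene_id`, one 0/1 column
#' per surveyed species) or a long pair list (columns `gene_id`, `species`,
#' one row per gene-species presence). Duplicated pairs are collapsed. The
#' species universe -- the denominator of the conservation ratio -- is the set
#' of species columns in the wide form and the set of distinct species seen in
#' the long form.
#'
#' @param path TSV or CSV file.
#' @return A tibble with columns `gene_id`, `species` (one row per presence)
#'   carrying the full species universe in attribute `"species"`.
#' @export
read_ortholog_table <- function(path) {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!"gene_id" %in% names(raw)) abort("ortholog table needs a `gene_id` column.")
  if (identical(sort(names(raw)), sort(c("gene_id", "species")))) {
    long <- dplyr::distinct(raw[, c("gene_id", "species")])
    species <- sort(unique(long$species))
  } else {
    species <- setdiff(names(raw), "gene_id")
    long <- raw |>
      tidyr::pivot_longer(-"gene_id", names_to = "species",
                          values_to = "present") |>
      dplyr::filter(.data$present %in% c("1", "TRUE", "true")) |>
      dplyr::distinct(.data$gene_id, .data$species)
  }
  long$gene_id <- normalize_gene_ids(long$gene_id)
  attr(long, "species") <- species
  # genes with zero presences have no long rows; keep the full universe
  attr(long, "genes") <- sort(unique(normalize_gene_ids(raw$gene_id)))
  long
}

#' Read a protein-abundance table
#'
#' Abundances are expected on the scale of exponentially modified protein
#' abundance indices (emPAI), i.e. positive values spanning orders of
#' magnitude; downstream comparisons are rank-based so the scale only affects
#' plotting.
#'
#' @param path TSV or CSV with columns `gene_id`, `abundance`.
#' @return A tibble with columns `gene_id` (character), `abundance` (double).
#' @export
read_abundance_table <- function(path) {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c("gene_id", "abundance") %in% names(raw))) {
    abort("abundance table needs `gene_id` and `abundance` columns.")
  }
  tibble(gene_id = normalize_gene_ids(raw$gene_id),
         abundance = as.numeric(raw$abundance))
}

#' Read / write a plain-text edge list
#'
#' The edge list is the interchange format for the undirected analysis
#' network: one tab-separated `from  to` pair per line with a header row.
#' Reading reconstructs an undirected network whose node set is the union of
#' the two columns; node gene lists default to the node identifier itself
#' (the convention when nodes are named by b-numbers).
#'
#' @param path File path.
#' @param directed Logical; interpret rows as ordered pairs?
#' @return `read_edge_list()` returns a [reaction_network()];
#'   `write_edge_list()` invisibly returns `path`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  edges <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(edges) < 2) abort("edge list needs two node columns.")
  names(edges)[1:2] <- c("from", "to")
  ids <- sort(unique(c(edges$from, edges$to)))
  reaction_network(
    nodes = tibble(node_id = ids, genes = as.list(ids)),
    edges = edges[, c("from", "to")],
    directed = directed
  )
}

#' @param network A [reaction_network()].
#' @rdname read_edge_list
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  readr::write_tsv(network$edges[, c("from", "to")], path, progress = FALSE)
  invisible(path)
}
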