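# Small in-code fixtures shared across test files.

# a KGML document assembled from reaction specs:
# list(id=, genes=, subs=, prods=, type=)
make_kgml <- function(reactions, orphan_reactions = character()) {
  entries <- character(0)
  rxns <- character(0)
  eid <- 0
  for (r in reactions) {
    if (length(r$genes) > 0) {
      eid <- eid + 1
      entries <- c(entries, sprintf(
        '<entry id="%d" name="%s" type="gene" reaction="%s"/>',
        eid, paste0("eco:", r$genes, collapse = " "), r$id))
    }
    type <- if (isTRUE(r$reversible)) "reversible" else "irreversible"
    body <- c(
      sprintf('<substrate name="%s"/>', r$subs),
      sprintf('<product name="%s"/>', r$prods)
    )
    rxns <- c(rxns, sprintf('<reaction name="%s" type="%s">%s</reaction>',
                            r$id, type, paste(body, collapse = "")))
  }
  paste0('<pathway name="path:eco00010" org="eco" number="00010">',
         paste(entries, collapse = ""), paste(rxns, collapse = ""),
         "</pathway>")
}

rxn <- function(id, genes, subs, prods, reversible = FALSE) {
  list(id = id, genes = genes, subs = subs, prods = prods,
       reversible = reversible)
}

# reaction entries tibble built directly (bypassing XML)
make_entries <- function(...) {
  specs <- list(...)
  dplyr::bind_rows(purrr::map(specs, function(r) {
    tibble::tibble(
      reaction_id = r$id,
      genes = list(r$genes),
      pairs = list(tibble::tibble(substrate = r$subs, product = r$prods)),
      reversible = isTRUE(r$reversible)
    )
  }))
}

# undirected network from "A-B" edge strings
make_net <- function(...) {
  parts <- strsplit(c(...), "-", fixed = TRUE)
  edges <- tibble::tibble(from = vapply(parts, `[[`, "", 1),
                          to = vapply(parts, `[[`, "", 2))
  ids <- sort(unique(c(edges$from, edges$to)))
  reaction_network(tibble::tibble(node_id = ids), edges, directed = FALSE)
}

complete_network <- function(n) {
  ids <- LETTERS[seq_len(n)]
  e <- utils::combn(ids, 2)
  reaction_network(tibble::tibble(node_id = ids),
                   tibble::tibble(from = e[1, ], to = e[2, ]),
                   directed = FALSE)
}
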