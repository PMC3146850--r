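test_that("a single-reaction document parses to one entry with its pair", {
  kgml <- make_kgml(list(
    rxn("rn:R1", "b0001", "cpd:C1", "cpd:C2")
  ))
  out <- parse_kgml(kgml)
  expect_equal(nrow(out), 1)
  expect_equal(out$reaction_id, "rn:R1")
  expect_equal(out$genes[[1]], "b0001")
  expect_equal(out$pairs[[1]],
               tibble::tibble(substrate = "cpd:C1", product = "cpd:C2"))
  expect_false(out$reversible[[1]])
})

test_that("gene ids are normalised and multi-gene entries attach to one reaction", {
  kgml <- make_kgml(list(
    rxn("rn:R1", c("B0001", "b0002"), "cpd:C1", "cpd:C2", reversible = TRUE)
  ))
  out <- parse_kgml(kgml)
  expect_equal(out$genes[[1]], c("b0001", "b0002"))
  expect_true(out$reversible[[1]])
})

test_that("reactions without pairs or without a gene entry are skipped with a warning", {
  no_pair <- make_kgml(list(
    rxn("rn:R1", "b0001", "cpd:C1", "cpd:C2"),
    rxn("rn:R2", "b0002", character(0), "cpd:C3")
  ))
  expect_warning(out <- parse_kgml(no_pair), "no substrate-product pair")
  expect_equal(out$reaction_id, "rn:R1")

  orphan <- make_kgml(list(
    rxn("rn:R1", "b0001", "cpd:C1", "cpd:C2"),
    rxn("rn:R9", character(0), "cpd:C5", "cpd:C6")
  ))
  expect_warning(out2 <- parse_kgml(orphan), "not referenced by any gene")
  expect_equal(out2$reaction_id, "rn:R1")
})

test_that("parsing is deterministic and preserves document order", {
  kgml <- make_kgml(list(
    rxn("rn:R2", "b0002", "cpd:C2", "cpd:C3"),
    rxn("rn:R1", "b0001", "cpd:C1", "cpd:C2")
  ))
  a <- parse_kgml(kgml)
  b <- parse_kgml(kgml)
  expect_identical(a, b)
  expect_equal(a$reaction_id, c("rn:R2", "rn:R1"))
})

test_that("malformed XML raises a parse error", {
  expect_error(parse_kgml("<pathway><entry></pathway>"))
})

test_that("a synthetic KGML document round-trips to the generator's ground truth", {
  cfg <- synthetic_config(seed = 11, n_nodes = 10, edges_per_new_node = 1)
  net <- grow_network(cfg)
  path <- withr::local_tempfile(fileext = ".kgml")
  write_kgml(net, path)
  entries <- parse_kgml(path)
  expect_setequal(entries$reaction_id, net$nodes$node_id)
  genes <- setNames(entries$genes, entries$reaction_id)
  for (i in seq_len(nrow(net$nodes))) {
    expect_equal(genes[[net$nodes$node_id[[i]]]], net$nodes$genes[[i]])
  }
})

test_that("class tables read, validate labels and reject conflicts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,kerner_class,fujiwara_class",
               "b2097,I,I", "b0001,III,IV"), path)
  ct <- read_class_table(path)
  expect_equal(ct$gene_id, c("b2097", "b0001"))
  expect_equal(ct$kerner_class, c("I", "III"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,kerner_class,fujiwara_class", "b0001,V,"), bad)
  expect_error(read_class_table(bad), "allowed")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,kerner_class,fujiwara_class",
               "b0001,I,", "b0001,II,"), dup)
  expect_error(read_class_table(dup), "conflicting")
})

test_that("edge lists round-trip and a path reads as 3 nodes / 2 edges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "a\tb", "b\tc"), path)
  net <- read_edge_list(path)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_false(net$directed)

  cfg <- synthetic_config(seed = 4, n_nodes = 100)
  big <- grow_network(cfg)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(big, out)
  back <- read_edge_list(out)
  expect_setequal(back$nodes$node_id, big$nodes$node_id)
  canon <- function(e) {
    dplyr::arrange(tibble::tibble(a = pmin(e$from, e$to),
                                  b = pmax(e$from, e$to)), a, b)
  }
  expect_equal(canon(back$edges), canon(big$edges))
})

test_that("wide and long ortholog tables are equivalent", {
  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsp1\tsp2\tsp3",
               "b0001\t1\t0\t1",
               "b0002\t0\t0\t0"), wide)
  w <- read_ortholog_table(wide)
  expect_equal(attr(w, "species"), c("sp1", "sp2", "sp3"))
  expect_equal(nrow(w), 2)

  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tspecies", "b0001\tsp1", "b0001\tsp3",
               "b0001\tsp1"), long)
  l <- read_ortholog_table(long)
  expect_equal(nrow(l), 2)  # duplicate pair collapsed
  expect_setequal(l$species, c("sp1", "sp3"))
})

test_that("abundance tables read genes and numeric values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,abundance", "eco:b0001,12.5", "b0002,0.3"), path)
  ab <- read_abundance_table(path)
  expect_equal(ab$gene_id, c("b0001", "b0002"))
  expect_equal(ab$abundance, c(12.5, 0.3))
})
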