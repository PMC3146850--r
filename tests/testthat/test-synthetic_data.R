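test_that("single-edge growth yields a connected tree", {
  cfg <- synthetic_config(seed = 5, n_nodes = 10, edges_per_new_node = 1)
  net <- grow_network(cfg)
  expect_equal(nrow(net$nodes), 10)
  expect_equal(nrow(net$edges), 9)
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  expect_equal(clustering_coefficient(net), rep(0, 10))
})

test_that("a fixed seed reproduces the network byte for byte", {
  cfg <- synthetic_config(seed = 42, n_nodes = 150)
  a <- grow_network(cfg)
  b <- grow_network(cfg)
  expect_identical(a$edges, b$edges)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_edge_list(a, fa); write_edge_list(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(grow_network(cfg)); y <- runif(1)
  expect_identical(x, y)
})

test_that("mean pairwise distance grows about logarithmically with size", {
  sizes <- c(100, 200, 400, 800)
  mean_h <- vapply(sizes, function(n) {
    h <- vapply(1:3, function(s) {
      net <- grow_network(synthetic_config(seed = s, n_nodes = n))
      g <- as_igraph(net)
      igraph::mean_distance(g)
    }, numeric(1))
    mean(h)
  }, numeric(1))
  expect_true(all(diff(mean_h) > 0))
  fit <- stats::lm(mean_h ~ log(sizes))
  expect_gt(summary(fit)$r.squared, 0.8)
  # sublinear: doubling N must not come close to doubling h
  expect_lt(mean_h[4] / mean_h[1], 2)
})

test_that("class fractions are honoured and zero fractions give an empty table", {
  cfg <- synthetic_config(seed = 3, n_nodes = 600)
  ct <- assign_classes(grow_network(cfg), cfg)
  counts <- table(ct$kerner_class)
  total <- nrow(ct)
  expect_true(all(abs(counts[c("I", "II", "III")] / total -
                        cfg$class_fractions / sum(cfg$class_fractions)) < 0.02))

  none <- synthetic_config(seed = 3, n_nodes = 50,
                           class_fractions = c(I = 0, II = 0, III = 0))
  expect_equal(nrow(assign_classes(grow_network(none), none)), 0)
})

test_that("age bias zero decouples class labels from birth order", {
  set.seed(0)
  ps <- vapply(1:40, function(s) {
    cfg <- synthetic_config(seed = s, n_nodes = 300, age_bias = 0)
    net <- grow_network(cfg)
    ct <- assign_classes(net, cfg)
    df <- tibble::tibble(
      birth = net$nodes$birth_order,
      class = setNames(ct$kerner_class, ct$gene_id)[unlist(net$nodes$genes)]
    )
    kruskal_wallis(dplyr::filter(df, !is.na(class)), birth, class)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("full retention yields ratio one for every gene of that class", {
  cfg <- synthetic_config(seed = 2, n_nodes = 100,
                          retention = c(I = 1, II = 0.5, III = 0.5))
  net <- grow_network(cfg)
  ct <- assign_classes(net, cfg)
  orth <- make_ortholog_table(ct, cfg)
  rec <- conservation_degree(orth)
  class1 <- ct$gene_id[ct$kerner_class == "I"]
  expect_true(all(rec$ratio[rec$gene_id %in% class1] == 1))
})

test_that("abundance values are log-normal and independent of position", {
  cfg <- synthetic_config(seed = 13, n_nodes = 400)
  net <- grow_network(cfg)
  ab <- make_abundance(net, cfg)
  expect_equal(nrow(ab), 400)
  expect_true(all(ab$abundance > 0))
  expect_lt(abs(mean(log(ab$abundance))), 0.2)
  d <- bfs_distances(net, "R00001")
  rho <- cor(d$distance[match(net$nodes$node_id, d$node_id)],
             log(ab$abundance), method = "spearman")
  expect_lt(abs(rho), 0.15)
})

test_that("the written KGML reconstructs the grown network exactly", {
  cfg <- synthetic_config(seed = 6, n_nodes = 120)
  net <- grow_network(cfg)
  path <- withr::local_tempfile(fileext = ".kgml")
  write_kgml(net, path)
  lcc <- to_undirected_lcc(build_reaction_network(parse_kgml(path)))
  expect_setequal(lcc$nodes$node_id, net$nodes$node_id)
  canon <- function(e) {
    dplyr::arrange(tibble::tibble(a = pmin(e$from, e$to),
                                  b = pmax(e$from, e$to)), a, b)
  }
  expect_equal(canon(lcc$edges), canon(net$edges))
})

test_that("write_synthetic_inputs emits all five readable files", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 8, n_nodes = 60)
  out <- write_synthetic_inputs(cfg, dir)
  expect_true(all(file.exists(unlist(out$paths))))
  expect_equal(nrow(read_edge_list(out$paths$edges)$nodes), 60)
  expect_s3_class(read_class_table(out$paths$classes), "tbl_df")
  expect_gt(nrow(read_ortholog_table(out$paths$orthologs)), 0)
  expect_equal(nrow(read_abundance_table(out$paths$abundance)), 60)
})
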