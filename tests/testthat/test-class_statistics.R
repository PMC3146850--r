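groups_df <- function(...) {
  samples <- list(...)
  tibble::tibble(
    value = unlist(samples),
    group = rep(paste0("g", seq_along(samples)),
                vapply(samples, length, integer(1)))
  )
}

test_that("Kruskal-Wallis handles identical groups, ties and degenerate input", {
  res <- kruskal_wallis(groups_df(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)), value, group)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_per_group[[1]], c(g1 = 3L, g2 = 3L, g3 = 3L))

  allsame <- kruskal_wallis(groups_df(c(5, 5), c(5, 5, 5)), value, group)
  expect_equal(allsame$statistic, 0)
  expect_equal(allsame$p_value, 1)

  expect_error(kruskal_wallis(groups_df(c(1, 2)), value, group), "2 groups")
})

test_that("Kruskal-Wallis p agrees with the exact permutation oracle", {
  # tiny two-group case: the exact null has 20 assignments, 2 as extreme
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  expect_equal(oracle_kw_exact_p(a, b), 0.1)
  approx_p <- kruskal_wallis(groups_df(a, b), value, group)$p_value
  expect_equal(approx_p, 0.0495, tolerance = 0.001)
  # the chi-square approximation is coarse at n = 3 per group; at n = 5 it
  # tracks the exact enumeration closely
  a5 <- c(1, 2, 3, 4, 9); b5 <- c(5, 6, 7, 8, 10)
  expect_lt(abs(kruskal_wallis(groups_df(a5, b5), value, group)$p_value -
                  oracle_kw_exact_p(a5, b5)), 0.02)
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(2024)
  p <- replicate(400, {
    kruskal_wallis(groups_df(rnorm(20), rnorm(20), rnorm(20)),
                   value, group)$p_value
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("Wilcoxon rank-sum matches exact enumeration on tiny samples", {
  res <- wilcoxon_rank_sum(groups_df(c(1, 2), c(3, 4)), value, group)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$p_value, oracle_wilcoxon_exact_p(c(1, 2), c(3, 4)))

  set.seed(31)
  for (rep in 1:5) {
    a <- sample(1:50, 6); b <- sample(51:100, 7)
    got <- wilcoxon_rank_sum(groups_df(a, b), value, group)$p_value
    expect_equal(got, oracle_wilcoxon_exact_p(a, b))
  }

  same <- wilcoxon_rank_sum(groups_df(c(1, 2, 3), c(1, 2, 3)), value, group)
  expect_equal(same$p_value, 1)
})

test_that("Wilcoxon detects a two-sigma shift at n = 30 essentially always", {
  set.seed(7)
  hits <- replicate(200, {
    wilcoxon_rank_sum(groups_df(rnorm(30), rnorm(30, 2)), value, group)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.99)
})

test_that("Student's t is pooled-variance and handles zero variance", {
  same <- student_t(groups_df(c(0, 0, 1, 1), c(0, 0, 1, 1)), value, group)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const_eq <- student_t(groups_df(c(2, 2), c(2, 2, 2)), value, group)
  expect_equal(const_eq$p_value, 1)
  const_ne <- student_t(groups_df(c(1, 1), c(2, 2)), value, group)
  expect_equal(const_ne$p_value, 0)

  set.seed(11)
  a <- rnorm(8); b <- rnorm(10, 0.5)
  got <- student_t(groups_df(a, b), value, group)
  sp2 <- ((7 * var(a) + 9 * var(b)) / 16)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 10))
  expect_equal(got$statistic, t_hand)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), 16))
  expect_error(student_t(groups_df(1, c(2, 3)), value, group), "n >= 2")
})

test_that("two-group Kruskal-Wallis agrees with Wilcoxon at moderate n", {
  set.seed(3)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  kw <- kruskal_wallis(groups_df(a, b), value, group)$p_value
  wx <- wilcoxon_rank_sum(groups_df(a, b), value, group)$p_value
  expect_lt(abs(kw - wx), 0.01)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(17)
  df <- groups_df(rpois(15, 4), rpois(15, 6), rpois(15, 8))
  df2 <- dplyr::mutate(df, value = exp(value))
  expect_equal(kruskal_wallis(df, value, group)$p_value,
               kruskal_wallis(df2, value, group)$p_value)
  two <- dplyr::filter(df, group != "g3")
  two2 <- dplyr::filter(df2, group != "g3")
  expect_equal(wilcoxon_rank_sum(two, value, group)$p_value,
               wilcoxon_rank_sum(two2, value, group)$p_value)
})

test_that("measures_by_class reports all four measures and flags empty classes", {
  cfg <- synthetic_config(seed = 6, n_nodes = 150)
  net <- grow_network(cfg)
  ann <- annotate_nodes(net, assign_classes(net, cfg), "kerner")
  m <- node_measures(net)
  rep <- measures_by_class(m, ann)
  expect_equal(rep$measure, c("degree", "closeness", "betweenness", "clustering"))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_error(measures_by_class(m, ann, classes = c("I", "II", "III", "IV")),
               "has no nodes")
})

test_that("structure-independent labels give uniform p-values over replicates", {
  cfg <- synthetic_config(seed = 1, n_nodes = 150)
  net <- grow_network(cfg)
  m <- node_measures(net)
  set.seed(123)
  ps <- replicate(150, {
    lab <- rep(NA_character_, 150)
    lab[sample.int(150, 36)] <- rep(c("I", "II", "III"), each = 12)
    ann <- tibble::tibble(node_id = net$nodes$node_id, class = lab)
    # closeness is continuous, so its null p-values are very nearly uniform
    measures_by_class(m, ann, classes = c("I", "II", "III"))$p_value[2]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("abundance-distance test is null on flat input and powered on trends", {
  net <- make_net("A-B", "B-C", "C-D", "D-E")
  dmap <- bfs_distances(net, "A")
  flat <- tibble::tibble(gene_id = net$nodes$node_id,
                         abundance = 3)
  res <- abundance_vs_distance(flat, dmap, net)
  expect_equal(res$p_value, 1)

  cfg <- synthetic_config(seed = 12, n_nodes = 120)
  big <- grow_network(cfg)
  dbig <- bfs_distances(big, "R00001")
  set.seed(5)
  trended <- tibble::tibble(
    gene_id = unlist(big$nodes$genes),
    abundance = exp(dbig$distance[match(big$nodes$node_id, dbig$node_id)] +
                      rnorm(120, 0, 0.3))
  )
  expect_lt(abundance_vs_distance(trended, dbig, big)$p_value, 0.001)

  one_bin <- tibble::tibble(gene_id = "A", abundance = 1)
  expect_error(abundance_vs_distance(one_bin, dmap, net), "2 distance bins")
})
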