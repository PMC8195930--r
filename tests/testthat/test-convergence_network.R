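test_that("levenshtein matches known editing examples", {
  expect_equal(levenshtein("CASSL", "CASSL"), 0L)
  expect_equal(levenshtein("CASSL", "CASTL"), 1L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("", "abc"), 3L)
  expect_equal(levenshtein("abc", ""), 3L)
  expect_equal(levenshtein("", ""), 0L)
})

test_that("levenshtein agrees with the dynamic-programming oracle", {
  set.seed(31)
  n <- 1000
  a <- vapply(sample(0:25, n, TRUE), function(k) {
    paste0(sample(LETTERS[1:6], k, TRUE), collapse = "")
  }, character(1))
  b <- vapply(sample(0:25, n, TRUE), function(k) {
    paste0(sample(LETTERS[1:6], k, TRUE), collapse = "")
  }, character(1))
  oracle <- mapply(function(x, y) utils::adist(x, y)[1, 1], a, b,
                   USE.NAMES = FALSE)
  expect_equal(levenshtein(a, b), as.integer(oracle))
  # symmetry
  expect_equal(levenshtein(a, b), levenshtein(b, a))
})

test_that("thresholded pair set equals the dense-matrix oracle", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    s <- random_aa_strings(n, min_len = 2, max_len = 7,
                           alphabet = c("A", "C", "G"))
    max_rel <- sample(0:2, 1)
    got <- pairwise_distance_matrix(s, max_rel)
    d <- utils::adist(s)
    idx <- which(upper.tri(d) & d <= max_rel, arr.ind = TRUE)
    expect_equal(nrow(got), nrow(idx))
    if (nrow(got)) {
      got <- got[order(got$i, got$j), ]
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      expect_equal(got$i, unname(idx[, 1]))
      expect_equal(got$j, unname(idx[, 2]))
      expect_equal(got$dist, unname(d[cbind(got$i, got$j)]))
    }
  }
})

test_that("pairwise distances: single sequence and exact duplicates", {
  expect_equal(nrow(pairwise_distance_matrix("CASSL", 1)), 0L)
  dup <- pairwise_distance_matrix(c("AA", "AA"), 1)
  expect_equal(dup$dist, 0L)
  expect_equal(pairwise_distance_matrix(c("AA", "AB", "ZZ"), 1)[, c("i", "j")],
               tibble::tibble(i = 1L, j = 2L))
})

test_that("convergent groups are the single-linkage transitive closure", {
  expect_equal(convergent_groups(c("CASSL", "CASSF", "CARRW")),
               c(1L, 1L, 2L))
  # chain: AAAA-AAAB at 1, AAAB-AABB at 1, AAAA-AABB at 2 -> one cluster
  expect_equal(convergent_groups(c("AAAA", "AAAB", "AABB")), rep(1L, 3))
  expect_equal(convergent_groups(c("AAAA", "CCCC", "GGGG")), 1:3)
  expect_equal(convergent_groups(character()), integer())
})

test_that("convergent groups equal the union-find oracle on random inputs", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(2:60, 1)
    s <- random_aa_strings(n, min_len = 2, max_len = 5,
                           alphabet = c("A", "C"))
    got <- convergent_groups(s, 1)
    want <- oracle_groups(s, 1)
    # same partition: identical co-membership matrix
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("network pools timepoints with distance-0 cross-timepoint edges", {
  post <- make_rep(c("CASSL", "CASTL"), c(5, 5),
                   patient_id = "P1", timepoint = "C1D15",
                   sample_id = "P1_C1D15")
  course <- pair_timepoints(list(
    make_rep(c("CASSL", "CASSX"), c(9, 1), patient_id = "P1",
             timepoint = "C1D1"), post))$P1
  g <- build_network(course)
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(g$n_components, 1L)
  labels <- paste0(g$nodes$aa_cdr3, "@", g$nodes$timepoint)
  edge_labels <- sort(paste(pmin(labels[g$edges$i], labels[g$edges$j]),
                            pmax(labels[g$edges$i], labels[g$edges$j])))
  expect_true("CASSL@C1D1 CASSL@C1D15" %in% edge_labels)
  # distance-0 edges only join the same sequence across timepoints
  zero <- g$edges[g$edges$dist == 0, ]
  expect_true(all(g$nodes$aa_cdr3[zero$i] == g$nodes$aa_cdr3[zero$j]))
  expect_true(all(g$nodes$timepoint[zero$i] != g$nodes$timepoint[zero$j]))
})

test_that("mutually distant sequences give isolated nodes, diameter 0", {
  rep <- make_rep(c("AAAAAAA", "CCCCCCC", "DDDDDDD", "SSSSSSS"),
                  c(1, 2, 3, 4))
  g <- build_network(rep)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$n_components, 4L)
  expect_equal(g$diameter, 0L)
})

test_that("identical baseline and post repertoires mirror their structure", {
  aa <- c("CASSA", "CASSB", "CARRW")
  base <- make_rep(aa, c(1, 2, 3), patient_id = "P1", timepoint = "C1D1")
  post <- make_rep(aa, c(1, 2, 3), patient_id = "P1", timepoint = "C1D15",
                   sample_id = "P1_C1D15")
  g <- build_network(pair_timepoints(list(base, post))$P1)
  expect_equal(nrow(g$nodes), 6L)
  zero <- g$edges[g$edges$dist == 0, ]
  expect_equal(nrow(zero), 3L)  # one cross-timepoint edge per sequence
  within_base <- sum(g$nodes$timepoint[g$edges$i] == "C1D1" &
                       g$nodes$timepoint[g$edges$j] == "C1D1")
  within_post <- sum(g$nodes$timepoint[g$edges$i] == "C1D15" &
                       g$nodes$timepoint[g$edges$j] == "C1D15")
  expect_equal(within_base, within_post)
})

test_that("diameter equals the Floyd-Warshall oracle and known shapes", {
  path4 <- igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE)
  expect_equal(network_diameter(path4), 3L)
  # two components: triangle and 5-node path -> max over components = 4
  tri_path <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 7, 7, 8),
                                 directed = FALSE)
  expect_equal(network_diameter(tri_path), 4L)
  expect_equal(network_diameter(igraph::make_full_graph(5)), 1L)
  expect_equal(network_diameter(igraph::make_empty_graph(0,
                                                         directed = FALSE)),
               0L)
  expect_equal(network_diameter(path4, units = "vertices"), 4L)

  set.seed(34)
  for (i in 1:30) {
    n <- sample(2:60, 1)
    rg <- random_graph(n, p_edge = stats::runif(1, 0.03, 0.3))
    expect_equal(network_diameter(rg$graph), oracle_diameter(rg$adj))
  }
})

test_that("adding an edge never increases a connected graph's diameter", {
  set.seed(35)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    # random spanning tree keeps the graph connected
    g <- igraph::sample_tree(n)
    d0 <- network_diameter(g)
    missing <- which(!igraph::as_adjacency_matrix(g, sparse = FALSE) &
                       upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    if (!nrow(missing)) next
    pick <- missing[sample(nrow(missing), 1), ]
    g2 <- igraph::add_edges(g, pick)
    expect_lte(network_diameter(g2), d0)
  }
})

test_that("median-diameter split puts the median itself in the low group", {
  s <- dichotomize_by_median_diameter(c(10, 12, 14))
  expect_equal(s$median, 12)
  expect_equal(s$labels, c("low", "low", "high"))
  expect_warning(s2 <- dichotomize_by_median_diameter(c(5, 5, 5)),
                 "low")
  expect_equal(s2$labels, rep("low", 3))
  # even cohort: midpoint convention
  s3 <- dichotomize_by_median_diameter(c(10, 11, 13, 14))
  expect_equal(s3$median, 12)
  expect_equal(s3$labels, c("low", "low", "high", "high"))
})

test_that("edge-list export names nodes by sequence and timepoint", {
  base <- make_rep(c("CASSA", "CASSB"), c(1, 1), patient_id = "P1",
                   timepoint = "C1D1")
  g <- build_network(base)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(tab$node_a, "CASSA@C1D1")
  expect_equal(tab$distance, 1)
})
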