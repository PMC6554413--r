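test_that("node heterogeneity: stars and regular graphs give 0, P4 gives 1/8", {
  for (n in c(3, 10, 50))
    expect_equal(node_heterogeneity(fixture_graph("star", n = n)), 0)
  expect_equal(node_heterogeneity(fixture_graph("cycle", n = 7)), 0)
  expect_equal(node_heterogeneity(fixture_graph("complete", n = 6)), 0)

  p4 <- fixture_graph("path", n = 4)
  expect_equal(node_heterogeneity(p4, variance = "population"), 0.125)
  expect_equal(node_heterogeneity(p4, variance = "population"), oracle_Vn(p4))
})

test_that("node heterogeneity matches the brute-force oracle on random graphs", {
  for (seed in 1:8) {
    g <- random_test_graph(seed, n = 40)
    expect_equal(suppressWarnings(node_heterogeneity(g)), oracle_Vn(g),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(node_heterogeneity(g, variance = "sample")),
                 oracle_Vn(g, sample_var = TRUE), tolerance = 1e-12)
  }
})

test_that("relative node heterogeneity: P4 = 0.5, regular graphs undefined", {
  p4 <- fixture_graph("path", n = 4)
  expect_equal(relative_node_heterogeneity(p4, variance = "population"), 0.5)
  expect_true(is.na(relative_node_heterogeneity(fixture_graph("cycle", n = 6))))
})

test_that("neighbourhood similarity: worked examples and the self-match option", {
  expect_equal(neighbourhood_similarity(fixture_graph("cycle", n = 5)), 1)
  expect_equal(neighbourhood_similarity(fixture_graph("path", n = 3)), 2 / 3)
  # the literal double-delta formula self-matches and is identically 1
  expect_equal(neighbourhood_similarity(fixture_graph("path", n = 3),
                                        include_self = TRUE), 1)
})

test_that("S: hash grouping equals O(n^2) pairwise comparison and the oracle", {
  for (seed in 1:20) {
    g <- random_test_graph(seed)
    s_hash <- suppressWarnings(neighbourhood_similarity(g, method = "hash"))
    s_pair <- suppressWarnings(neighbourhood_similarity(g, method = "pairwise"))
    expect_identical(s_hash, s_pair)
    expect_equal(s_hash, oracle_S(g), tolerance = 1e-12)
  }
})

test_that("omega_p: literal formula, closed form and oracle agree", {
  # all identical sequences -> 0; all unique -> 1
  expect_equal(omega_p(fixture_graph("cycle", n = 6), 2), 0)
  dci <- degree_class_index(fixture_graph("path", n = 5))
  expect_equal(omega_p(dci, 2), 1 / 3)
  expect_equal(omega_p(dci, 2, method = "literal"), 1 / 3)
  expect_error(omega_p(dci, 7), "D2")

  # planted class with q = 5, multiplicities (1, 1, 3): Eq value 0.3
  g <- fixture_graph("planted_multiorder", multiplicities = c(1, 1, 3))
  expect_equal(omega_p(g, 2), 0.3)
  expect_equal(oracle_omega(g, 2), 0.3)

  for (seed in 21:35) {
    g <- random_test_graph(seed, n = 80)
    dci <- degree_class_index(suppressWarnings(sequence_table(g)))
    for (p in dci$D2) {
      expect_equal(omega_p(dci, p, method = "closed"),
                   omega_p(dci, p, method = "literal"), tolerance = 1e-12)
      expect_equal(omega_p(dci, p), oracle_omega(g, p), tolerance = 1e-12)
    }
  }
})

test_that("neighbourhood organisation: regular graphs 1, P5 = 5/6, ER low vs lattice", {
  expect_equal(neighbourhood_organisation(fixture_graph("cycle", n = 9)), 1)
  expect_equal(neighbourhood_organisation(fixture_graph("complete", n = 4)), 1)
  expect_equal(neighbourhood_organisation(fixture_graph("path", n = 5)), 5 / 6)

  lattice <- generate_graph("watts_strogatz", n = 60, k = 3, beta = 0, seed = 1)
  er <- generate_graph("erdos_renyi", n = 60, p = 0.1, seed = 1)
  expect_equal(neighbourhood_organisation(lattice), 1)
  expect_lt(neighbourhood_organisation(er), neighbourhood_organisation(lattice))
})

test_that("hierarchical complexity: P5 literal values; per-node factor; R_Omega <= R", {
  p5 <- fixture_graph("path", n = 5)
  expect_equal(hierarchical_complexity(p5, normalisation = "equation"), 1 / 12)
  expect_equal(hierarchical_complexity_corrected(p5, normalisation = "equation"),
               1 / 36)
  # per-node normalisation divides by the number of non-isolated nodes
  expect_equal(hierarchical_complexity(p5), 1 / 60)

  expect_equal(hierarchical_complexity(fixture_graph("cycle", n = 8)), 0)
  expect_equal(hierarchical_complexity_corrected(fixture_graph("cycle", n = 8)), 0)

  for (seed in 36:50) {
    g <- random_test_graph(seed, n = 70)
    r <- suppressWarnings(hierarchical_complexity(g, normalisation = "equation"))
    ro <- suppressWarnings(
      hierarchical_complexity_corrected(g, normalisation = "equation"))
    expect_equal(r, oracle_R(g), tolerance = 1e-12)
    expect_equal(ro, oracle_R(g, weighted = TRUE), tolerance = 1e-12)
    expect_lte(ro, r + 1e-12)
  }
})

test_that("disjoint doubling forces S = 1 (planar-symmetry property)", {
  for (seed in 1:50) {
    set.seed(seed)
    h <- igraph::sample_gnp(sample(4:12, 1), 0.5)
    if (igraph::ecount(h) == 0) h <- igraph::add_edges(h, c(1, 2))
    hh <- fixture_graph("symmetric_double", base = h)
    expect_equal(suppressWarnings(neighbourhood_similarity(hh)), 1)
  }
})

test_that("wl2 signatures encode (degree, sequence) pairs and refine degrees", {
  k3 <- fixture_graph("complete", n = 3)
  expect_length(unique(wl2_signature(k3)), 1)

  p3 <- fixture_graph("path", n = 3)
  sig <- wl2_signature(p3)
  expect_identical(sig[[1]], sig[[3]])
  expect_false(identical(sig[[1]], sig[[2]]))
  expect_error(wl2_signature(p3, "zzz"), "unknown node")

  for (seed in c(3, 14, 15)) {
    g <- random_test_graph(seed, n = 60)
    tab <- suppressWarnings(sequence_table(g))
    sig <- suppressWarnings(wl2_signature(g))
    manual <- vapply(tab$labels, function(l)
      paste0(tab$degree[[l]], "|", paste(tab$seqs[[l]], collapse = ",")),
      character(1))
    expect_equal(sort(sig), sort(manual))
    # equal tokens imply equal degrees
    split_deg <- split(tab$degree, sig)
    expect_true(all(vapply(split_deg, function(d) length(unique(d)) == 1,
                           logical(1))))
  }
})

test_that("compute_all populates all indices with undefined-value flags", {
  rep5 <- compute_all(fixture_graph("cycle", n = 5))
  expect_equal(rep5$S, 1)
  expect_equal(rep5$V_n, 0)
  expect_equal(rep5$Omega, 1)
  expect_equal(rep5$R, 0)
  expect_equal(rep5$R_Omega, 0)
  expect_true(is.na(rep5$V_hat_n))
  expect_match(paste(rep5$flags, collapse = " "), "V_hat_n")

  repP5 <- compute_all(fixture_graph("path", n = 5),
                       normalisation = "equation")
  expect_equal(repP5$Omega, 5 / 6)
  expect_equal(repP5$R, 1 / 12)
  expect_equal(repP5$R_Omega, 1 / 36)
  expect_equal(nrow(repP5$per_degree), 2)
  expect_equal(repP5$per_degree$omega_p, c(0, 1 / 3))
})
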