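toy_map <- function() {
  target_map(
    circ_to_mirna = list(circA = c("m1", "m2", "m3"),
                         circB = c("m1", "m2", "m4"),
                         circC = c("m7", "m8", "m9")),
    mirna_to_gene = list(m1 = "g1", m2 = c("g1", "g2"), m3 = "g3",
                         m4 = "g4", m7 = "g5", m8 = "g5", m9 = "g6"),
    mirna_universe = sprintf("m%d", 1:10))
}

test_that("pair p-value matches exact enumeration and its boundary cases", {
  # N=10, K=4, n=3, c=2: (C(4,2)C(6,1) + C(4,3)) / C(10,3) = 40/120
  expect_equal(cerna_pair_pvalue(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  # c = 0 spans the whole support
  expect_equal(cerna_pair_pvalue(10, 4, 3, 0), 1)
  # K = N forces complete overlap
  expect_equal(cerna_pair_pvalue(5, 5, 2, 2), 1)

  expect_error(cerna_pair_pvalue(10, 11, 3, 1), "exceed")
  expect_error(cerna_pair_pvalue(10, 4, 3, 4), "min")
})

test_that("pair p-value agrees with the exact-rational oracle on a grid", {
  for (N in c(4, 7, 12)) {
    for (K in 1:N) {
      for (n in 1:N) {
        for (c in max(0, K + n - N):min(K, n)) {
          expect_equal(cerna_pair_pvalue(N, K, n, c),
                       oracle_hyper_tail(N, K, n, c), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("pair p-value is monotone and exchangeable", {
  # strictly decreasing in c
  ps <- cerna_pair_pvalue(100, 20, 15, 0:15)
  expect_true(all(diff(ps) < 0))
  # a fixed overlap grows more surprising as the universe grows
  pn <- vapply(25:60, cerna_pair_pvalue, numeric(1), K = 10, n = 15, c = 5)
  expect_true(all(diff(pn) < 0))
  # the two MRE-set sizes are exchangeable
  expect_equal(cerna_pair_pvalue(50, 12, 7, 3),
               cerna_pair_pvalue(50, 7, 12, 3), tolerance = 1e-15)
})

test_that("pair screening filters on shared count and significance", {
  map <- toy_map()
  # circA-circB share m1, m2 (c=2, p = tail of Hypergeom(10,3,3) at 2);
  # circC is disjoint from both
  pairs <- screen_cerna_pairs(map, c("circA", "circB", "circC"),
                              p_cutoff = 0.2)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$id_a, "circA")
  expect_equal(pairs$id_b, "circB")
  expect_equal(pairs$c, 2)
  expect_setequal(pairs$common_mirnas[[1]], c("m1", "m2"))
  expect_equal(pairs$p_value, oracle_hyper_tail(10, 3, 3, 2),
               tolerance = 1e-12)

  # disjoint pairs fail the common-miRNA gate regardless of p_cutoff
  none <- screen_cerna_pairs(map, c("circA", "circC"), p_cutoff = 1,
                             min_common = 1)
  expect_equal(nrow(none), 0)

  # candidate order never changes the result
  p1 <- screen_cerna_pairs(map, c("circC", "circB", "circA"), p_cutoff = 1)
  p2 <- screen_cerna_pairs(map, c("circA", "circB", "circC"), p_cutoff = 1)
  expect_identical(p1, p2)
})

test_that("gene candidates are screened through their inverted miRNA sets", {
  map <- toy_map()
  # g1 is targeted by m1 and m2 -> shares both with circA
  pairs <- screen_cerna_pairs(map, c("circA", "g1"), p_cutoff = 1)
  expect_equal(pairs$c, 2)
  expect_equal(sort(c(pairs$id_a, pairs$id_b)), c("circA", "g1"))

  # an id with no MRE set is skipped with a warning
  expect_warning(
    out <- screen_cerna_pairs(map, c("circA", "circB", "ghost"),
                              p_cutoff = 1),
    "ghost")
  expect_equal(nrow(out), 1)
})

test_that("planted pairs are recovered and the null retains few pairs", {
  sim <- simulate_target_map(n_circ = 60, n_mirna = 10000, mre_per_circ = 5,
                             planted_pairs = 6, planted_overlap = 5,
                             seed = 12)
  pairs <- screen_cerna_pairs(sim$target_map,
                              names(sim$target_map$circ_to_mirna))
  found <- paste(pairs$id_a, pairs$id_b)
  planted <- paste(sim$truth$planted_pairs$id_a,
                   sim$truth$planted_pairs$id_b)
  expect_true(all(planted %in% found))
  expect_true(all(pairs$p_value[match(planted, found)] < 1e-10))
})

test_that("network assembly merges shared miRNAs into a tripartite graph", {
  # worked instance: 2 circRNAs sharing {m1, m2}; m1->g1, m2->{g1,g2}
  map <- target_map(
    circ_to_mirna = list(c1 = c("m1", "m2", "m5"), c2 = c("m1", "m2", "m6")),
    mirna_to_gene = list(m1 = "g1", m2 = c("g1", "g2"), m5 = "g9",
                         m6 = "g9"),
    mirna_universe = sprintf("m%d", 1:100))
  pairs <- screen_cerna_pairs(map, c("c1", "c2"), p_cutoff = 1)
  net <- build_cerna_network(pairs, map)
  expect_equal(table(net$nodes$kind),
               table(factor(c("circRNA", "circRNA", "miRNA", "miRNA",
                              "gene", "gene"))),
               ignore_attr = TRUE)
  expect_equal(sum(net$edges$kind == "circ-miRNA"), 4)
  expect_equal(sum(net$edges$kind == "miRNA-gene"), 3)
  expect_silent(assert_tripartite(net))

  # empty pair list -> empty network
  empty <- build_cerna_network(pairs[0, ], map)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
  expect_silent(assert_tripartite(empty))
})

test_that("network export round-trips and all formats are written", {
  sim <- simulate_target_map(n_circ = 30, n_mirna = 2000, mre_per_circ = 8,
                             planted_pairs = 5, planted_overlap = 4,
                             seed = 21)
  pairs <- screen_cerna_pairs(sim$target_map,
                              names(sim$target_map$circ_to_mirna))
  net <- build_cerna_network(pairs, sim$target_map)
  assert_tripartite(net)
  expect_gt(nrow(net$edges), 0)

  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "edge_tsv")
  expect_equal(read_network_edges(f), net)

  # empty network round-trips through a header-only file
  empty <- build_cerna_network(pairs[0, ], sim$target_map)
  f0 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, f0, "edge_tsv")
  expect_equal(length(readLines(f0)), 1)
  expect_equal(read_network_edges(f0), empty)

  fs <- withr::local_tempfile(fileext = ".sif")
  export_network(net, fs, "sif")
  expect_equal(length(readLines(fs)), nrow(net$edges))

  fg <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, fg, "graphml")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))

  expect_error(export_network(net, f, "dot"), "arg")
})
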