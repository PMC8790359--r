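test_that("co-occurrence counts are exact on small report sets", {
  co <- build_cooccurrence(list(c("a", "b"), c("a", "b"), c("a", "c")))
  expect_identical(co$N, 3L)
  expect_identical(co$P, c(a = 3L, b = 2L, c = 1L))
  expect_identical(co$pairs,
                   data.frame(i = c("a", "a"), j = c("b", "c"),
                              p_ij = c(2L, 1L), stringsAsFactors = FALSE))

  # single-condition report contributes to P only
  co1 <- build_cooccurrence(list(c("a", "b"), "c"))
  expect_identical(co1$P[["c"]], 1L)
  expect_identical(nrow(co1$pairs), 1L)

  # disjoint singleton reports: no edges at all
  expect_identical(nrow(build_cooccurrence(list("a", "b"))$pairs), 0L)

  expect_error(build_cooccurrence(list()), "empty")
})

test_that("co-occurrence counting matches brute-force pair enumeration", {
  set.seed(11)
  vocab <- paste0("c", 1:12)
  for (k in 1:10) {
    reports <- lapply(seq_len(40), function(i) {
      sample(vocab, sample(1:4, 1))
    })
    got <- build_cooccurrence(reports)
    ora <- oracle_pair_counts(reports)
    expect_identical(got$N, ora$N)
    expect_identical(got$P, ora$P[names(got$P)])
    expect_equal(got$pairs, ora$pairs[order(ora$pairs$i, ora$pairs$j), ],
                 ignore_attr = TRUE)
  }
})

test_that("singleton removal keeps exactly the nodes with degree >= 1", {
  edges <- data.frame(i = "a", j = "b", stringsAsFactors = FALSE)
  expect_identical(remove_singletons(c("a", "b", "c"), edges), c("a", "b"))
  tri <- data.frame(i = c("a", "a", "b"), j = c("b", "c", "c"))
  expect_identical(remove_singletons(c("a", "b", "c"), tri),
                   c("a", "b", "c"))

  reps <- generate_null_reports(60, 30, 2, seed = 4)
  co <- build_cooccurrence(reps)
  st <- edge_statistics(co)
  kept <- remove_singletons(co$conditions, st)
  deg0 <- co$conditions[!(co$conditions %in% c(st$i, st$j))]
  expect_identical(setdiff(co$conditions, kept), deg0)
})

test_that("pair association reproduces the analytic limit cases", {
  # independence: p_ij * n == p_i * p_j
  ind <- pair_association(10, 4, 5, 2)
  expect_identical(ind$rr, 1)
  expect_identical(ind$phi, 0)

  # perfect association
  per <- pair_association(10, 5, 5, 5)
  expect_identical(per$phi, 1)
  expect_identical(per$p, 0)

  # degenerate: a condition in every report
  deg <- pair_association(10, 10, 5, 5)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$phi))

  expect_error(pair_association(10, 4, 5, 6), "invalid co-occurrence")
  expect_error(pair_association(10, 9, 9, 1), "invalid co-occurrence")
})

test_that("pair association matches the 2x2 contingency oracle", {
  st <- pair_association(10, 4, 5, 3)
  expect_equal(st$rr, oracle_rr_2x2(10, 4, 5, 3), tolerance = 1e-12)
  expect_equal(st$phi, oracle_phi_2x2(10, 4, 5, 3), tolerance = 1e-12)
  expect_equal(st$sigma_ij, sqrt(1 / 3 + 1 / 20 - 1 / 10 - 1 / 100),
               tolerance = 1e-12)
  expect_equal(st$lb, st$rr * exp(-2.56 * st$sigma_ij), tolerance = 1e-12)
  expect_equal(st$ub, st$rr * exp(2.56 * st$sigma_ij), tolerance = 1e-12)
  tt <- st$phi * sqrt(8) / sqrt(1 - st$phi^2)
  expect_equal(st$t, tt, tolerance = 1e-12)
  expect_equal(st$p, 2 * stats::pt(-abs(tt), df = 8), tolerance = 1e-12)

  set.seed(5)
  for (k in 1:100) {
    n <- sample(5:40, 1)
    p_i <- sample(seq_len(n - 1), 1)
    p_j <- sample(seq_len(n - 1), 1)
    lo <- max(1, p_i + p_j - n)
    hi <- min(p_i, p_j)
    if (lo > hi) next
    p_ij <- sample(lo:hi, 1)
    st <- pair_association(n, p_i, p_j, p_ij)
    expect_equal(st$phi, oracle_phi_2x2(n, p_i, p_j, p_ij),
                 tolerance = 1e-12)
    # rr > 1 <=> phi > 0 <=> p_ij * n > p_i * p_j
    expect_identical(st$rr > 1, st$phi > 0)
    expect_identical(st$phi > 0, p_ij * n > p_i * p_j)
  }
})

test_that("edge filtering applies the conjunctive rule and is monotone in alpha", {
  reps <- generate_null_reports(200, 40, 3, seed = 8)
  st <- edge_statistics(build_cooccurrence(reps))
  # independence-like edges (phi <= 0) always fail
  expect_identical(nrow(filter_edges(st[st$phi <= 0, , drop = FALSE])), 0L)

  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  kept <- lapply(alphas, function(a) {
    ids <- filter_edges(st, alpha = a)
    paste(ids$i, ids$j)
  })
  for (k in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[k]] %in% kept[[k + 1]]))
  }

  # perfect association with large n survives the filter
  strong <- cbind(data.frame(i = "x", j = "y"),
                  pair_association(200, 40, 40, 40))
  expect_identical(nrow(filter_edges(strong)), 1L)
})

test_that("PageRank matches symmetry cases and the power-iteration oracle", {
  g2 <- igraph::graph_from_data_frame(
    data.frame(i = "a", j = "b", weight = 3), directed = FALSE)
  expect_equal(pagerank_centrality(g2), c(a = 0.5, b = 0.5),
               tolerance = 1e-12)

  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("n", 1:8)
  expect_equal(unname(pagerank_centrality(ring, weighted = FALSE)),
               rep(1 / 8, 8), tolerance = 1e-10)

  set.seed(12)
  for (k in 1:5) {
    g <- igraph::sample_gnp(60, 0.08)
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
    pr <- pagerank_centrality(g)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(pr, oracle_pagerank(g), tolerance = 1e-8)
  }
})

test_that("class mean PageRank averages correctly and flags empty classes", {
  g2 <- igraph::graph_from_data_frame(
    data.frame(i = "a", j = "b", weight = 1), directed = FALSE)
  mp <- class_mean_pagerank(g2, classes = c(a = "X", b = "Y"))
  expect_equal(mp, c(X = 0.5, Y = 0.5))

  # single class: mean equals 1/n
  mp1 <- class_mean_pagerank(g2, classes = c(a = "X", b = "X"))
  expect_equal(mp1[["X"]], 0.5)

  # empty class is undefined, not zero
  mp2 <- class_mean_pagerank(g2, classes = c(a = "TYPICAL_WAKING",
                                             b = "TYPICAL_DREAM"))
  expect_true(is.na(mp2[["EQUAL"]]))

  # planted core-periphery: EQUAL hubs hold the highest mean
  hub_edges <- do.call(rbind, lapply(1:3, function(h) {
    data.frame(i = paste0("hub", h),
               j = paste0("leaf", h, "_", 1:8), weight = 1)
  }))
  hub_edges <- rbind(hub_edges,
                     data.frame(i = "hub1", j = "hub2", weight = 1),
                     data.frame(i = "hub2", j = "hub3", weight = 1))
  gh <- igraph::graph_from_data_frame(hub_edges, directed = FALSE)
  cls <- stats::setNames(
    ifelse(grepl("hub", igraph::V(gh)$name), "EQUAL", "TYPICAL_DREAM"),
    igraph::V(gh)$name)
  mph <- class_mean_pagerank(gh, classes = cls)
  expect_gt(mph[["EQUAL"]], mph[["TYPICAL_DREAM"]])
})

test_that("attribute assortativity matches closed forms and the mixing oracle", {
  # two disconnected same-class cliques: perfectly assortative
  cl_edges <- rbind(
    expand.grid(i = paste0("a", 1:4), j = paste0("a", 1:4)),
    expand.grid(i = paste0("b", 1:4), j = paste0("b", 1:4)))
  cl_edges <- cl_edges[as.character(cl_edges$i) < as.character(cl_edges$j), ]
  g <- igraph::graph_from_data_frame(cl_edges, directed = FALSE)
  cls <- stats::setNames(substr(igraph::V(g)$name, 1, 1),
                         igraph::V(g)$name)
  expect_equal(attribute_assortativity(g, cls), 1, tolerance = 1e-12)

  # complete bipartite between two classes: r = -1 by the mixing matrix
  bip <- expand.grid(i = paste0("a", 1:3), j = paste0("b", 1:4))
  gb <- igraph::graph_from_data_frame(bip, directed = FALSE)
  clb <- stats::setNames(substr(igraph::V(gb)$name, 1, 1),
                         igraph::V(gb)$name)
  expect_equal(attribute_assortativity(gb, clb),
               oracle_assortativity(gb, clb), tolerance = 1e-12)
  expect_equal(attribute_assortativity(gb, clb), -1, tolerance = 1e-12)

  # random graphs and labels: implementation equals the mixing oracle
  set.seed(19)
  for (k in 1:10) {
    gr <- igraph::sample_gnp(25, 0.15)
    if (igraph::ecount(gr) == 0) next
    igraph::V(gr)$name <- paste0("v", 1:25)
    clr <- stats::setNames(sample(c("A", "B", "C"), 25, replace = TRUE),
                           igraph::V(gr)$name)
    got <- attribute_assortativity(gr, clr)
    if (is.na(got)) next
    expect_equal(got, oracle_assortativity(gr, clr), tolerance = 1e-10)
    expect_gte(got, -1)
    expect_lte(got, 1)
  }

  # single class among endpoints: undefined, reported as NA
  expect_warning(
    single <- attribute_assortativity(g, stats::setNames(
      rep("A", igraph::vcount(g)), igraph::V(g)$name)),
    "undefined")
  expect_true(is.na(single))
})

test_that("giant component and component sizes match a BFS oracle", {
  path <- igraph::graph_from_data_frame(
    data.frame(i = paste0("p", 1:4), j = paste0("p", 2:5)),
    directed = FALSE)
  gp <- giant_component(path)
  expect_equal(igraph::vcount(gp$graph), 5L)
  expect_identical(gp$n_components, 1L)

  two_tri <- igraph::graph_from_data_frame(
    data.frame(i = c("a1", "a2", "a3", "b1", "b2", "b3"),
               j = c("a2", "a3", "a1", "b2", "b3", "b1")),
    directed = FALSE)
  gt <- giant_component(two_tri)
  expect_identical(gt$sizes, c(3L, 3L))
  expect_identical(gt$n_components, 2L)

  set.seed(3)
  for (k in 1:5) {
    nodes <- paste0("v", 1:30)
    edges <- data.frame(i = sample(nodes, 25, replace = TRUE),
                        j = sample(nodes, 25, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$i != edges$j, ]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    got <- giant_component(g)
    ora <- oracle_components(nodes, edges)
    expect_identical(got$sizes,
                     sort(as.integer(table(ora)), decreasing = TRUE))
    expect_equal(igraph::vcount(got$graph),
                     max(as.integer(table(ora))))
  }
})

test_that("the min-degree core is a single-pass degree filter", {
  star <- igraph::graph_from_data_frame(
    data.frame(i = "hub", j = paste0("leaf", 1:6)), directed = FALSE)
  core <- extract_core(star, min_degree = 5)
  expect_equal(igraph::vcount(core), 1L)
  expect_equal(igraph::ecount(core), 0L)

  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("k", 1:6)
  core6 <- extract_core(k6, min_degree = 5)
  expect_equal(igraph::vcount(core6), 6L)
  expect_equal(igraph::ecount(core6), 15L)

  set.seed(9)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- paste0("v", 1:40)
  deg <- igraph::degree(g)
  core_g <- extract_core(g, min_degree = 3)
  expect_setequal(igraph::V(core_g)$name, names(deg)[deg >= 3])

  expect_error(extract_core(k6, min_degree = 0), "integer")
})

test_that("condition_network wires statistics, classes and bookkeeping together", {
  corp <- generate_corpora(synthetic_spec(
    n_conditions = 80, n_mentions_waking = 2000, n_reports = 800,
    report_size_mean = 3, within_cluster_prob = 0.8, n_clusters = 4,
    seed = 14))
  cl <- classify_conditions(count_frequencies(corp$waking),
                            count_frequencies(corp$reports))
  net <- condition_network(corp$reports, classes = cl)
  expect_s3_class(net, "condition_network")
  expect_lte(net$n_edges, net$n_edges_before)
  expect_lte(net$n_nodes, net$n_nodes_before)
  expect_equal(sum(net$pagerank), 1, tolerance = 1e-9)
  # every kept edge passes the conjunctive rule
  expect_true(all(net$edges$phi > 0))
  expect_true(all(net$edges$p < 0.01))
  expect_true(all(net$edges$lb > 1))
  # no singletons survive
  expect_true(all(igraph::degree(net$graph) >= 1))
  # node classes come from the classification
  expect_true(all(igraph::V(net$graph)$class %in%
                    c("TYPICAL_WAKING", "EQUAL", "TYPICAL_DREAM")))
  expect_output(print(net), "co-occurrence network")
  expect_output(print(summary(net)), "mean PageRank")

  # GraphML and edge-list writers produce parseable artifacts
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), net$n_nodes)
  expect_equal(igraph::ecount(back), net$n_edges)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  expect_identical(nrow(utils::read.delim(tsv)), net$n_edges)
})

test_that("planted co-occurrence clusters dominate the filtered network", {
  spec <- synthetic_spec(
    n_conditions = 100, zipf_exponent = 1.2, n_mentions_waking = 1000,
    n_reports = 3000, report_size_mean = 4, frac_shared = 1,
    frac_waking_only = 0, frac_dream_only = 0, frac_waking_enriched = 0,
    frac_dream_enriched = 0, n_clusters = 5, within_cluster_prob = 0.9,
    seed = 5)
  corp <- generate_corpora(spec)
  net <- condition_network(corp$reports)
  cluster <- stats::setNames(corp$truth$cluster, corp$truth$condition)
  e <- net$edges
  same <- cluster[e$i] == cluster[e$j]
  nn <- table(factor(cluster[net$nodes], levels = 1:5))
  poss_within <- sum(nn * (nn - 1) / 2)
  poss_cross <- choose(sum(nn), 2) - poss_within
  dens_within <- sum(same) / poss_within
  dens_cross <- sum(!same) / poss_cross
  expect_gt(dens_within, 5 * max(dens_cross, 1e-12))
})
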