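test_that("edge-list loading drops self-loops and duplicate edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  expect_warning(g <- load_network(f), "self-loop")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  writeLines(c("A\tB", "B\tA"), f)
  gd <- load_network(f, directed = TRUE)
  expect_equal(igraph::ecount(gd), 2)

  writeLines(c("A\tB", "oops"), f)
  expect_error(load_network(f), "malformed edge-list line 2")
})

test_that("BioGRID tab3-style files load through a column map", {
  f <- withr::local_tempfile(fileext = ".txt")
  hdr <- paste("#ID A", "ID B", "Official Symbol Interactor A",
               "Official Symbol Interactor B", "Organism A", sep = "\t")
  rows <- c("1\t2\tTP53\tMDM2\t9606",
            "3\t4\tTP53\tEP300\t9606",
            "5\t6\tMDM2\tEP300\t9606",
            "7\t8\tEGFR\tGRB2\t9606",
            "9\t10\tGRB2\tSOS1\t9606",
            "11\t12\tTP53\tMDM2\t9606",   # duplicate
            "13\t14\tEGFR\tEGFR\t9606",   # self-loop
            "15\t16\tKRAS\tBRAF\t9606",
            "17\t18\tBRAF\tMAP2K1\t9606",
            "19\t20\tKRAS\tMAP2K1\t9606")
  writeLines(c(hdr, rows), f)
  expect_warning(
    g <- load_network(f, col_map = list(
      source = "Official Symbol Interactor A",
      target = "Official Symbol Interactor B")),
    "self-loop")
  # hand count: 9 distinct symbols, 8 distinct non-loop edges
  expect_equal(igraph::vcount(g), 9)
  expect_equal(igraph::ecount(g), 8)
})

test_that("centralities are exact on graphs with known answers", {
  path <- network_from_edges(data.frame(c("A", "B"), c("B", "C")))
  ce <- centralities(path, c("degree", "betweenness", "closeness"))
  expect_equal(ce$betweenness[ce$gene == "B"], 1)
  expect_equal(ce$betweenness[ce$gene != "B"], c(0, 0))

  star <- network_from_edges(data.frame(rep("HUB", 4), paste0("L", 1:4)))
  cs <- centralities(star, c("degree", "closeness"))
  expect_equal(cs$degree[cs$gene == "HUB"], 1)
  expect_equal(cs$closeness[cs$gene == "HUB"], 1)

  expect_error(centralities(path, "in_degree"), "directed")
  expect_error(centralities(path, "nonsense"), "unknown centrality")
})

test_that("centralities match brute-force oracles on a random graph", {
  g <- network_from_edges(random_edges(30, 0.12, seed = 31))
  A <- adj_of(g)
  D <- oracle_floyd_warshall(A)
  ce <- centralities(g, c("degree", "betweenness", "closeness", "katz",
                          "eigenvector", "pagerank"), katz_alpha = 0.05)
  n <- igraph::vcount(g)
  expect_equal(ce$degree, unname(rowSums(A)) / (n - 1), tolerance = 1e-12)
  expect_equal(ce$betweenness, oracle_betweenness(g), tolerance = 1e-9)
  expect_equal(ce$closeness, oracle_closeness(D), tolerance = 1e-12)
  expect_equal(ce$katz, oracle_katz(A, alpha = 0.05), tolerance = 1e-9)
  # eigenvector: direction check against the dominant eigenvector
  ev <- eigen(A)$vectors[, 1]
  ev <- abs(ev) / max(abs(ev))
  expect_equal(ce$eigenvector, ev, tolerance = 1e-5)
  # unnormalized degree sum identity
  expect_equal(sum(ce$degree) * (n - 1), 2 * igraph::ecount(g))
})

test_that("extended centralities rank-correlate with degree/closeness", {
  s <- fixture_small()
  ce <- centralities(s$net, c("degree", "closeness", "pagerank",
                              "eigenvector", "katz"))
  expect_gt(cor(ce$degree, ce$pagerank, method = "spearman"), 0.5)
  expect_gt(cor(ce$closeness, ce$eigenvector, method = "spearman"), 0.5)
  expect_gt(cor(ce$closeness, ce$katz, method = "spearman"), 0.5)
})

test_that("class distance summaries match a Floyd-Warshall oracle", {
  # trivial cases
  g <- toy_net()  # A-B-C, C-D, C-E, D-E
  expect_equal(class_distance_summary(g, "A", "B"),
               c(avg_sp = 1, min_sp = 1))
  n <- igraph::vcount(g)
  expect_equal(class_distance_summary(g, "A", "A", exclude_self = TRUE),
               c(avg_sp = n, min_sp = n))

  gr <- network_from_edges(random_edges(50, 0.06, seed = 32))
  D <- oracle_floyd_warshall(adj_of(gr))
  nodes <- igraph::V(gr)$name
  set.seed(33)
  cls <- sample(nodes, 5)
  sentinel <- igraph::vcount(gr)
  for (v in sample(nodes, 10)) {
    got <- class_distance_summary(gr, v, cls)
    d <- D[match(v, nodes), match(setdiff(cls, v), nodes)]
    d <- d[is.finite(d)]
    want <- if (length(d)) c(avg_sp = mean(d), min_sp = min(d))
      else c(avg_sp = sentinel, min_sp = sentinel)
    expect_equal(got, want)
  }
  expect_error(class_distance_summary(gr, "NOPE", cls), "not in network")
})

test_that("min distance never exceeds average distance", {
  gr <- network_from_edges(random_edges(40, 0.08, seed = 34))
  nodes <- igraph::V(gr)$name
  set.seed(35)
  cls <- sample(nodes, 8)
  for (v in nodes[1:15]) {
    d <- class_distance_summary(gr, v, cls)
    expect_lte(d[["min_sp"]], d[["avg_sp"]])
  }
})

test_that("neighbor class ratios count overlapping labels in each class", {
  g <- network_from_edges(data.frame(rep("X", 4), c("N1", "N2", "N3", "N4")))
  cat <- gene_catalog(DTG = c("N1", "N2"), PUG = c("N2"))
  r <- neighbor_class_ratios(g, "X", cat)
  expect_equal(r[["DTG"]], 0.5)
  expect_equal(r[["PUG"]], 0.25)
  expect_equal(r[["OG"]], 0.5)      # N3, N4
  expect_gte(sum(r), 1)             # overlap makes ratios sum above 1

  none <- neighbor_class_ratios(g, "X", gene_catalog())
  expect_equal(none[["OG"]], 1)
  expect_equal(sum(none[gene_classes()]), 0)

  # brute-force check on a random graph with overlapping labels
  gr <- network_from_edges(random_edges(40, 0.1, seed = 36))
  nodes <- igraph::V(gr)$name
  set.seed(37)
  cat2 <- gene_catalog(DTG = sample(nodes, 10), DAG = sample(nodes, 12))
  for (v in nodes[1:10]) {
    nb <- setdiff(igraph::neighbors(gr, v)$name, v)
    got <- neighbor_class_ratios(gr, v, cat2)
    expect_equal(got[["DTG"]], sum(nb %in% cat2$members$DTG) / length(nb))
    expect_equal(got[["DAG"]], sum(nb %in% cat2$members$DAG) / length(nb))
  }
})

test_that("group distance analysis detects planted proximity", {
  # class A nodes wired straight into class B's neighborhood
  set.seed(38)
  base <- random_edges(60, 0.04, 38)
  nodes <- unique(c(base$from, base$to))
  a <- nodes[1:6]; b <- nodes[7:16]
  extra <- data.frame(from = rep(a, each = 3),
                      to = sample(b, 18, replace = TRUE))
  g <- network_from_edges(rbind(base, extra))
  cat <- gene_catalog(DTG = a, DAG = b)
  res <- group_distance_analysis(g, cat, "DTG", "DAG")
  expect_identical(res$direction, "closer")
  expect_lt(res$p_value, 0.05)

  # comparing the background with itself is a null comparison
  res_og <- group_distance_analysis(g, cat, "DTG", "OG")
  expect_equal(res_og$p_value, 1)

  # two singletons at hop distance 2
  g2 <- network_from_edges(data.frame(c("A", "B"), c("B", "C")))
  cat2 <- gene_catalog(DTG = "A", DAG = "C")
  res2 <- group_distance_analysis(g2, cat2, "DTG", "DAG")
  expect_equal(res2$per_node$dist_class, 2)
  expect_error(group_distance_analysis(g2, cat2, "DTG", "PUG"), "empty")
})

test_that("directed distances follow edge orientation", {
  g <- network_from_edges(data.frame(c("A", "B"), c("B", "C")),
                          directed = TRUE)
  expect_equal(class_distance_summary(g, "A", "C")[["min_sp"]], 2)
  # C cannot reach A going forward
  expect_equal(class_distance_summary(g, "C", "A")[["min_sp"]],
               igraph::vcount(g))
  ced <- centralities(g, c("in_degree", "out_degree"))
  expect_equal(sum(ced$in_degree), sum(ced$out_degree))
})
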