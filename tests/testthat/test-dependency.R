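write_dep_csv <- function(df) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, f, row.names = FALSE, quote = FALSE, na = "")
  f
}

test_that("dependency CSV loads in gene-row dialect with filtering", {
  f <- write_dep_csv(data.frame(gene = c("A", "B", "C"),
                                CL1 = 1:3, CL2 = 4:6, CL3 = 7:9,
                                CL4 = 10:12, CL5 = 13:15))
  suppressMessages({
    m <- load_dependency(f, cell_line_filter = c("CL2", "CL4"))
  })
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["B", "CL4"], 11)
  expect_error(suppressMessages(load_dependency(f, "CL9")),
               "available: CL1")
})

test_that("blank cells become missing values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,CL1,CL2", "A,0.5,", "B,-0.2,0.1"), f)
  suppressMessages(m <- load_dependency(f))
  expect_true(is.na(m["A", "CL2"]))
  expect_equal(m["B", "CL1"], -0.2)
})

test_that("DepMap gene-effect layout is transposed to the same matrix", {
  plain <- data.frame(gene = c("TP53", "KRAS"), ACH1 = c(0.1, -0.5),
                      ACH2 = c(0.2, -0.7))
  f1 <- write_dep_csv(plain)
  depmap <- data.frame(line = c("ACH1", "ACH2"),
                       `TP53 (7157)` = c(0.1, 0.2),
                       `KRAS (3845)` = c(-0.5, -0.7), check.names = FALSE)
  f2 <- write_dep_csv(depmap)
  suppressMessages({
    m1 <- load_dependency(f1)
    m2 <- load_dependency(f2)
  })
  expect_equal(m1, m2[rownames(m1), colnames(m1)])
})

test_that("gene features return raw rows and impute by column mean", {
  dep <- matrix(c(0.1, 0.2, NA, 0.4, -0.3, 0.6), 3,
                dimnames = list(c("A", "B", "C"), c("CL1", "CL2")))
  gf <- gene_dependency_features(dep, "A")
  expect_equal(gf$values, c(CL1 = 0.1, CL2 = 0.4))
  expect_false(any(gf$imputed))

  miss <- gene_dependency_features(dep, "C")
  expect_equal(unname(miss$values["CL1"]), mean(c(0.1, 0.2)))
  expect_identical(unname(miss$imputed), c(TRUE, FALSE))

  absent <- gene_dependency_features(dep, "ZZZ")
  expect_equal(absent$values, colMeans(dep, na.rm = TRUE))
  expect_true(all(absent$imputed))
})

test_that("neighbor features average scored neighbors only", {
  g <- network_from_edges(data.frame(c("X", "X", "A"), c("A", "B", "B")))
  dep <- matrix(c(0.2, -0.4, NA, 0.5, 0.1, 0.3), 3,
                dimnames = list(c("A", "B", "X"), c("CL1", "CL2")))
  nf <- neighbor_dependency_features(dep, g, "X")
  expect_equal(unname(nf$values["CL1"]), mean(c(0.2, -0.4)))  # -0.1
  one <- neighbor_dependency_features(dep, g, "A")  # neighbors X, B
  expect_equal(unname(one$values["CL1"]), -0.4)     # X unscored in CL1
  expect_error(neighbor_dependency_features(dep, g, "NOPE"), "not in network")

  # brute-force enumeration on the small fixture
  s <- fixture_small()
  nodes <- igraph::V(s$net)$name
  nbm <- neighbor_dependency_matrix(s$dep, s$net)
  for (v in nodes[c(3, 50, 120)]) {
    nb <- setdiff(igraph::neighbors(s$net, v)$name, v)
    want <- colMeans(s$dep[nb, , drop = FALSE], na.rm = TRUE)
    got <- nbm$values[v, ]
    ok <- is.finite(want)
    expect_equal(got[ok], want[ok])
    expect_equal(neighbor_dependency_features(s$dep, s$net, v)$values, got)
    # bounded by neighbor extremes
    rng <- range(s$dep[nb, ], na.rm = TRUE)
    expect_true(all(got[ok] >= rng[1] - 1e-12 & got[ok] <= rng[2] + 1e-12))
  }
})

test_that("imputation never alters observed cells", {
  s <- fixture_small()
  obs <- which(!is.na(s$dep), arr.ind = TRUE)
  pick <- obs[seq(1, nrow(obs), length.out = 25), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    gene <- rownames(s$dep)[pick[r, 1]]
    line <- colnames(s$dep)[pick[r, 2]]
    expect_equal(gene_dependency_features(s$dep, gene)$values[[line]],
                 s$dep[gene, line])
  }
})

test_that("group comparison finds planted shifts and exact micro p-values", {
  # exact micro-case: 1,2,3 vs background 4,5,6
  dep <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                dimnames = list(paste0("g", 1:6), "CL1"))
  cat <- gene_catalog(DTG = c("G1", "G2", "G3"))
  rownames(dep) <- toupper(rownames(dep))
  res <- dependency_group_comparison(dep, cat, "gene")
  row <- res[res$class == "DTG", ]
  # class vs class-plus-background: compare against the pure two-sample
  # exact enumeration on the same values
  expect_equal(row$direction, "smaller")
  expect_equal(row$p_value,
               suppressWarnings(wilcox.test(c(1, 2, 3), c(1:6))$p.value))

  # planted shift of -0.5 at n = 50 against background
  set.seed(41)
  bg <- matrix(rnorm(500), 500, 1, dimnames = list(sprintf("B%03d", 1:500), "CL1"))
  cls <- matrix(rnorm(50, -0.5), 50, 1, dimnames = list(sprintf("C%03d", 1:50), "CL1"))
  dep2 <- rbind(bg, cls)
  cat2 <- gene_catalog(PUG = rownames(cls))
  res2 <- dependency_group_comparison(dep2, cat2, "gene")
  row2 <- res2[res2$class == "PUG", ]
  expect_equal(row2$direction, "smaller")
  expect_lt(row2$p_value, 0.05)

  # a class with fewer than two scored genes is flagged not-testable
  cat3 <- gene_catalog(DRG = "B001")
  res3 <- dependency_group_comparison(dep2, cat3, "gene")
  expect_false(res3$testable[res3$class == "DRG"])
})

test_that("the exact two-sided rank-sum enumeration oracle gives 0.1 on 1:3 vs 4:6", {
  expect_equal(oracle_ranksum_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(suppressWarnings(wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value),
               0.1)
})
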