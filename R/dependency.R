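#' @title Genetic dependency (essentiality) score features
#' @description Gene x cell-line dependency scores from genome-scale
#'   loss-of-function screens (DepMap/Avana convention: lower = more
#'   essential). The matrix is a plain numeric matrix with gene symbols
#'   as row names, cell-line identifiers as column names and `NA` for
#'   missing cells.
#' @name dependency_features
NULL

#' Load a dependency score matrix from CSV
#'
#' Two dialects are auto-detected by the header:
#' \itemize{
#'   \item DepMap `gene_effect` layout — cell lines in rows, gene
#'     columns named `"SYMBOL (ENTREZ)"`; the symbol is extracted with
#'     the regex `"^(\\S+) \\(\\d+\\)$"` and the matrix transposed.
#'   \item plain gene-row layout — first column gene symbols, remaining
#'     columns cell lines.
#' }
#' Blank cells become `NA` (missing).
#'
#' @param path CSV file path.
#' @param cell_line_filter Optional character vector of cell-line
#'   identifiers to keep; an absent identifier is an error listing the
#'   available lines.
#' @return Numeric matrix (genes x cell lines, `NA` = missing).
#' @export
load_dependency <- function(path, cell_line_filter = NULL) {
  if (!file.exists(path)) stop("cannot read dependency file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)[-1]
  depmap_like <- mean(grepl("^\\S+ \\(\\d+\\)$", hdr)) > 0.5
  if (depmap_like) {
    genes <- toupper(sub("^(\\S+) \\(\\d+\\)$", "\\1", hdr))
    lines <- as.character(df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    mode(m) <- "numeric"
    dimnames(m) <- list(genes, lines)
  } else {
    genes <- toupper(trimws(as.character(df[[1]])))
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- genes
  }
  m <- m[!duplicated(rownames(m)), , drop = FALSE]
  if (!is.null(cell_line_filter)) {
    missing_cl <- setdiff(cell_line_filter, colnames(m))
    if (length(missing_cl))
      stop("cell line(s) not in file: ", paste(missing_cl, collapse = ", "),
           "; available: ", paste(colnames(m), collapse = ", "))
    m <- m[, cell_line_filter, drop = FALSE]
  }
  message("loaded dependency matrix: ", nrow(m), " genes x ",
          ncol(m), " cell lines")
  m
}

# per-cell-line mean over all scored genes: the neutral imputation value
dependency_column_means <- function(dep) {
  colMeans(dep, na.rm = TRUE)
}

#' Per-cell-line dependency scores of one gene
#'
#' Returns the gene's score in every cell line. Missing cells — and the
#' whole vector for a gene absent from the matrix — are imputed with
#' the per-cell-line mean over all scored genes, and flagged.
#'
#' @param dep Dependency matrix from [load_dependency()].
#' @param gene Gene symbol.
#' @return List with `values` (named numeric over cell lines) and
#'   `imputed` (logical vector of the same length).
#' @export
gene_dependency_features <- function(dep, gene) {
  mu <- dependency_column_means(dep)
  if (!gene %in% rownames(dep)) {
    return(list(values = mu, imputed = rep(TRUE, length(mu))))
  }
  v <- dep[gene, ]
  miss <- is.na(v)
  v[miss] <- mu[miss]
  list(values = v, imputed = miss)
}

#' Average dependency scores of a gene's network neighbors
#'
#' For every cell line, the mean score over the gene's neighbors that
#' have data in that line; unscored neighbors are skipped, not imputed.
#' A gene with no scored neighbor in a cell line falls back to the
#' per-cell-line mean, flagged.
#'
#' @param dep Dependency matrix.
#' @param net An `igraph` network containing `gene`.
#' @param gene Gene symbol.
#' @return List with `values` and `imputed`, as in
#'   [gene_dependency_features()].
#' @export
neighbor_dependency_features <- function(dep, net, gene) {
  if (!gene %in% igraph::V(net)$name) stop("gene not in network: ", gene)
  nbrs <- setdiff(unique(igraph::neighbors(net, gene, mode = "all")$name), gene)
  nbrs <- intersect(nbrs, rownames(dep))
  mu <- dependency_column_means(dep)
  if (!length(nbrs))
    return(list(values = mu, imputed = rep(TRUE, length(mu))))
  sub <- dep[nbrs, , drop = FALSE]
  v <- colMeans(sub, na.rm = TRUE)
  miss <- !is.finite(v)                  # all neighbors NA in that line
  v[miss] <- mu[miss]
  list(values = v, imputed = miss)
}

#' Neighbor-averaged dependency matrix for every network node
#'
#' Vectorized form of [neighbor_dependency_features()]: one row per
#' network node, columns the cell lines. Cells with no scored neighbor
#' are imputed with the per-cell-line mean.
#'
#' @param dep Dependency matrix.
#' @param net An `igraph` network.
#' @return List with `values` (nodes x cell lines matrix) and `imputed`
#'   (logical matrix of the same shape).
#' @export
neighbor_dependency_matrix <- function(dep, net) {
  nodes <- igraph::V(net)$name
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  if (igraph::is_directed(net)) {
    A <- A + Matrix::t(A)
    A@x[A@x > 0] <- 1
  }
  scored <- intersect(nodes, rownames(dep))
  D <- matrix(0, length(nodes), ncol(dep),
              dimnames = list(nodes, colnames(dep)))
  H <- matrix(0, length(nodes), ncol(dep), dimnames = dimnames(D))
  if (length(scored)) {
    sub <- dep[scored, , drop = FALSE]
    has <- !is.na(sub)
    sub[!has] <- 0
    D[scored, ] <- sub
    H[scored, ] <- has
  }
  S <- as.matrix(A %*% D)                # sum of scored-neighbor values
  C <- as.matrix(A %*% H)                # count of scored neighbors
  mu <- dependency_column_means(dep)
  vals <- S / C
  imputed <- C == 0
  vals[imputed] <- rep(mu, each = nrow(vals))[imputed]
  dimnames(vals) <- dimnames(imputed) <- list(nodes, colnames(dep))
  list(values = vals, imputed = imputed)
}

#' Wilcoxon comparison of class dependency scores against the background
#'
#' For each gene class and each cell line, compares the class genes'
#' scores (`mode = "gene"`) or their neighbor-averaged scores
#' (`mode = "neighbor"`) with the scores of all scored genes in that
#' cell line, by two-sided Wilcoxon rank-sum test. The class is part of
#' the background, matching a class-vs-all-genes contrast. Direction is
#' by median: `"smaller"` means the class is more essential.
#'
#' @param dep Dependency matrix.
#' @param catalog A `gene_catalog` (restricted to the network when
#'   `mode = "neighbor"`).
#' @param mode `"gene"` or `"neighbor"`.
#' @param net Required for `mode = "neighbor"`.
#' @param classes Class labels to test (default the six labels).
#' @return `data.frame`: class, cell_line, n_class, p_value, direction,
#'   testable.
#' @export
dependency_group_comparison <- function(dep, catalog,
                                        mode = c("gene", "neighbor"),
                                        net = NULL,
                                        classes = gene_classes()) {
  mode <- match.arg(mode)
  if (mode == "neighbor" && is.null(net))
    stop("mode = 'neighbor' requires a network")
  nbr <- if (mode == "neighbor") neighbor_dependency_matrix(dep, net)$values
  res <- list()
  for (line in colnames(dep)) {
    bg <- if (mode == "gene") dep[, line][!is.na(dep[, line])] else nbr[, line]
    for (lab in classes) {
      x <- if (mode == "gene") {
        g <- intersect(catalog$members[[lab]], rownames(dep))
        dep[g, line][!is.na(dep[g, line])]
      } else {
        g <- intersect(catalog$members[[lab]], rownames(nbr))
        nbr[g, line]
      }
      if (length(x) < 2L) {
        res[[length(res) + 1L]] <- data.frame(
          class = lab, cell_line = line, n_class = length(x),
          p_value = NA_real_, direction = "none", testable = FALSE)
        next
      }
      p <- if (isTRUE(all.equal(sort(x), sort(bg))) && length(x) == length(bg)) 1
        else suppressWarnings(stats::wilcox.test(x, bg)$p.value)
      md <- stats::median(x) - stats::median(bg)
      res[[length(res) + 1L]] <- data.frame(
        class = lab, cell_line = line, n_class = length(x), p_value = p,
        direction = if (md < 0) "smaller" else if (md > 0) "bigger" else "none",
        testable = TRUE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
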