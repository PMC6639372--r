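#' @title Per-gene feature assembly
#' @description Builds the gene x feature matrix fed to the one-class
#'   SVM. The primary variant has 52 features per gene:
#'   3 centralities (degree, betweenness, closeness) +
#'   14 class distances (7 classes x average and minimum shortest
#'   path) + 7 neighbor class ratios + 14 per-cell-line dependency
#'   scores of the gene + 14 per-cell-line average dependency scores
#'   of its neighbors. Variants drop or extend blocks (see
#'   [feature_names()]).
#' @name feature_assembly
NULL

FEATURE_VARIANTS <- c("primary", "no_centrality", "extended_centrality",
                      "dada_replace", "dada_append", "dada_only")

#' Feature names of a variant, in the frozen column order
#'
#' Order: centralities; then per class (DTG, DAG, PFG, PUG, URG, DRG,
#' OG) the average then minimum shortest-path distance; then the seven
#' neighbor ratios; then gene dependency scores by sorted cell line;
#' then neighbor dependency scores. DADA variants substitute/append a
#' block of seven rank-derived scores, one per seed class.
#'
#' @param variant One of `r paste(FEATURE_VARIANTS, collapse = ", ")`.
#' @param cell_lines Cell-line identifiers (sorted internally).
#' @return Character vector of column names.
#' @export
feature_names <- function(variant = "primary", cell_lines = character()) {
  variant <- match.arg(variant, FEATURE_VARIANTS)
  cl <- sort(cell_lines)
  centr <- c("degree", "betweenness", "closeness")
  centr_ext <- c(centr, "pagerank", "eigenvector", "katz")
  dist <- as.vector(rbind(paste0("avg_sp_", all_classes()),
                          paste0("min_sp_", all_classes())))
  ratio <- paste0("ratio_", all_classes())
  dep <- paste0("dep_", cl)
  nbrdep <- paste0("nbrdep_", cl)
  dada <- paste0("dada_", all_classes())
  switch(variant,
         primary = c(centr, dist, ratio, dep, nbrdep),
         no_centrality = c(dist, ratio, dep, nbrdep),
         extended_centrality = c(centr_ext, dist, ratio, dep, nbrdep),
         dada_replace = c(dada, dist, ratio, dep, nbrdep),
         dada_append = c(centr, dada, dist, ratio, dep, nbrdep),
         dada_only = dada)
}

# avg/min shortest-path features for all nodes at once, from a chunked
# distance matrix; exclude_self drops the 0 self-distance of members.
class_distance_block <- function(net, catalog, sentinel, chunk = 512L) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  memb <- class_membership_matrix(catalog, net)
  avg <- matrix(sentinel, n, length(all_classes()),
                dimnames = list(nodes, all_classes()))
  mn <- avg
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    D <- igraph::distances(net, v = rows, mode = "out")
    for (lab in all_classes()) {
      idx <- which(memb[, lab])
      if (!length(idx)) next
      sub <- D[, idx, drop = FALSE]
      # exclude self: a member's own column holds distance 0
      self_rows <- which(rows %in% idx)
      if (length(self_rows))
        sub[cbind(self_rows, match(rows[self_rows], idx))] <- Inf
      fin <- is.finite(sub)
      cnt <- rowSums(fin)
      s <- rowSums(ifelse(fin, sub, 0))
      avg[rows, lab] <- ifelse(cnt > 0, s / cnt, sentinel)
      m <- apply(sub, 1L, min)
      mn[rows, lab] <- ifelse(is.finite(m), m, sentinel)
    }
  }
  list(avg = avg, min = mn)
}

# neighbor class ratios for all nodes via sparse adjacency
neighbor_ratio_block <- function(net, catalog) {
  nodes <- igraph::V(net)$name
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  if (igraph::is_directed(net)) {
    A <- A + Matrix::t(A)
    A@x[A@x > 0] <- 1
  }
  memb <- class_membership_matrix(catalog, net)
  cnt <- as.matrix(A %*% (memb * 1))
  deg <- Matrix::rowSums(A)
  ratios <- cnt / ifelse(deg > 0, deg, 1)   # isolated nodes -> 0
  dimnames(ratios) <- list(nodes, all_classes())
  ratios
}

#' Assemble the per-gene feature table
#'
#' One row per network node, in canonical (alphabetical) node order;
#' columns per [feature_names()]. Class distances use
#' `exclude_self = TRUE` and the distance sentinel; dependency blocks
#' apply the per-cell-line mean imputation. The result has no missing
#' values.
#'
#' @param net An `igraph` network.
#' @param catalog A `gene_catalog` (restricted to `net` internally).
#' @param dep Dependency matrix from [load_dependency()].
#' @param variant Feature variant (see [feature_names()]).
#' @param dada_scores For DADA variants: a nodes x 7 numeric matrix of
#'   rank-derived scores with columns named `dada_<class>` or in
#'   [all_classes()] order, row names the gene symbols.
#' @param sentinel Distance sentinel; default `vcount(net)`.
#' @return A `feature_table`: list with `values` (matrix), `variant`,
#'   `cell_lines`, `scaling` (NULL until [scale_features()]).
#' @export
assemble_features <- function(net, catalog, dep, variant = "primary",
                              dada_scores = NULL,
                              sentinel = igraph::vcount(net)) {
  variant <- match.arg(variant, FEATURE_VARIANTS)
  catalog <- restrict_to_network(catalog, net)
  nodes <- sort(igraph::V(net)$name)
  cl <- sort(colnames(dep))
  cols <- feature_names(variant, cl)
  vals <- matrix(NA_real_, length(nodes), length(cols),
                 dimnames = list(nodes, cols))

  if (grepl("dada", variant)) {
    if (is.null(dada_scores))
      stop("variant '", variant, "' requires dada_scores")
    dada_scores <- as.matrix(dada_scores)
    if (ncol(dada_scores) != 7L)
      stop("dada_scores must have 7 columns (one per seed class)")
    if (!all(nodes %in% rownames(dada_scores)))
      stop("dada_scores must cover every network node")
    colnames(dada_scores) <- paste0("dada_", all_classes())
    vals[, colnames(dada_scores)] <- dada_scores[nodes, ]
  }

  if (variant != "dada_only") {
    centr_measures <- switch(variant,
      extended_centrality = c("degree", "betweenness", "closeness",
                              "pagerank", "eigenvector", "katz"),
      no_centrality = character(),
      dada_replace = character(),
      c("degree", "betweenness", "closeness"))
    if (length(centr_measures)) {
      ce <- centralities(net, centr_measures)
      rownames(ce) <- ce$gene
      vals[, centr_measures] <- as.matrix(ce[nodes, centr_measures])
    }
    dists <- class_distance_block(net, catalog, sentinel)
    vals[, paste0("avg_sp_", all_classes())] <- dists$avg[nodes, ]
    vals[, paste0("min_sp_", all_classes())] <- dists$min[nodes, ]
    vals[, paste0("ratio_", all_classes())] <-
      neighbor_ratio_block(net, catalog)[nodes, ]

    mu <- dependency_column_means(dep)[cl]
    gd <- matrix(rep(mu, each = length(nodes)), length(nodes),
                 dimnames = list(nodes, cl))
    present <- intersect(nodes, rownames(dep))
    if (length(present)) {
      sub <- dep[present, cl, drop = FALSE]
      miss <- is.na(sub)
      sub[miss] <- rep(mu, each = nrow(sub))[miss]
      gd[present, ] <- sub
    }
    vals[, paste0("dep_", cl)] <- gd
    nb <- neighbor_dependency_matrix(dep[, cl, drop = FALSE], net)$values
    vals[, paste0("nbrdep_", cl)] <- nb[nodes, cl]
  }

  stopifnot(!anyNA(vals))
  structure(list(values = vals, variant = variant, cell_lines = cl,
                 scaling = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> variant '", x$variant, "': ", nrow(x$values),
      " genes x ", ncol(x$values), " features",
      if (!is.null(x$scaling)) paste0(" (scaled: ", x$scaling$method, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Scale features for the classifier
#'
#' `minmax` maps every feature to `[0, 1]` (constant features to 0);
#' `zscore` centers and scales (constant features to 0). Statistics are
#' fit on `fit_rows` (default all rows) and stored so the identical
#' transform can be applied to held-out or new genes with
#' [apply_scaling()].
#'
#' @param table A `feature_table`.
#' @param method `"minmax"` or `"zscore"`.
#' @param fit_rows Optional character vector of gene names whose rows
#'   define the scaling statistics.
#' @return The scaled `feature_table` with `scaling` metadata.
#' @export
scale_features <- function(table, method = c("minmax", "zscore"),
                           fit_rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  fit <- if (is.null(fit_rows)) table$values
    else table$values[intersect(fit_rows, rownames(table$values)), , drop = FALSE]
  if (method == "minmax") {
    lo <- apply(fit, 2L, min); hi <- apply(fit, 2L, max)
    scaling <- list(method = method, center = lo,
                    scale = ifelse(hi > lo, hi - lo, 1),
                    constant = hi <= lo)
  } else {
    mu <- colMeans(fit); sd_ <- apply(fit, 2L, stats::sd)
    scaling <- list(method = method, center = mu,
                    scale = ifelse(sd_ > 0, sd_, 1), constant = sd_ <= 0)
  }
  table$values <- apply_scaling(table$values, scaling)
  table$scaling <- scaling
  table
}

#' Apply stored scaling to a feature matrix
#'
#' @param values Numeric matrix with the same feature columns.
#' @param scaling Scaling metadata from [scale_features()].
#' @return Scaled matrix.
#' @export
apply_scaling <- function(values, scaling) {
  sweep(sweep(values, 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

#' Invert stored scaling (round-trip check and export)
#'
#' @inheritParams apply_scaling
#' @return Matrix on the original feature scale. Constant features are
#'   restored to their (stored) constant value.
#' @export
unscale_features <- function(values, scaling) {
  out <- sweep(sweep(values, 2L, scaling$scale, "*"), 2L, scaling$center, "+")
  if (any(scaling$constant))
    out[, scaling$constant] <- rep(scaling$center[scaling$constant],
                                   each = nrow(out))
  out
}
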