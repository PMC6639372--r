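#' @title Interaction networks and graph-derived gene features
#' @description Loading of protein-protein interaction (PPI) or signed
#'   signaling networks from edge lists, node centralities, shortest-path
#'   proximity summaries to gene classes, and neighbor class composition.
#'   Networks are `igraph` objects whose vertices are gene symbols
#'   (vertex attribute `name`); signed networks carry an edge attribute
#'   `sign` with values in `positive`/`negative`/`physical`.
#' @name network_features
NULL

CENTRALITY_MEASURES <- c("degree", "betweenness", "closeness",
                         "pagerank", "eigenvector", "katz",
                         "in_degree", "out_degree")

#' Load an interaction network from an edge-list file
#'
#' Accepts a headerless TSV (`source<TAB>target[<TAB>sign]`) or, via
#' `col_map`, any header-ed TSV dialect such as BioGRID tab3 (name the
#' official-symbol columns). Self-loops are removed with a warning,
#' duplicate edges merged, and symbols normalized as in
#' [normalize_symbols()].
#'
#' @param path Edge-list file path.
#' @param directed Logical; directed edges (signaling network) or not
#'   (PPI).
#' @param sign_column For headerless input, `3` to read a third column
#'   of edge signs; with `col_map`, the name of the sign column. `NULL`
#'   (default) for unsigned networks.
#' @param col_map Optional `list(source=, target=)` of column names for
#'   header-ed files, e.g. BioGRID tab3:
#'   `list(source = "Official Symbol Interactor A",
#'         target = "Official Symbol Interactor B")`.
#' @return An `igraph` object.
#' @export
load_network <- function(path, directed = FALSE, sign_column = NULL,
                         col_map = NULL) {
  if (!file.exists(path)) stop("cannot read network file: ", path)
  if (is.null(col_map)) {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      bad <- which(keep)[which(nf < 2L)[1L]]
      stop("malformed edge-list line ", bad, " in ", path,
           " (need at least source<TAB>target)")
    }
    src <- vapply(fields, `[[`, "", 1L)
    tgt <- vapply(fields, `[[`, "", 2L)
    sgn <- if (!is.null(sign_column))
      vapply(fields, function(f) if (length(f) >= sign_column) f[[sign_column]] else "", "")
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    for (col in c(col_map$source, col_map$target))
      if (!col %in% names(df))
        stop("column '", col, "' not found in ", path)
    src <- as.character(df[[col_map$source]])
    tgt <- as.character(df[[col_map$target]])
    sgn <- if (!is.null(sign_column)) as.character(df[[sign_column]])
  }
  src <- toupper(trimws(src)); tgt <- toupper(trimws(tgt))
  ok <- nzchar(src) & nzchar(tgt)
  src <- src[ok]; tgt <- tgt[ok]
  if (!length(src)) stop("no edges found in ", path)
  el <- cbind(src, tgt)
  g <- igraph::graph_from_edgelist(el, directed = directed)
  if (!is.null(sign_column)) igraph::E(g)$sign <- sgn[ok]
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0L)
    warning("removed ", n_loops, " self-loop(s) from ", path)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  if (igraph::vcount(g) == 0L) stop("empty network: ", path)
  g
}

#' Build a network from an in-memory edge data.frame
#'
#' Programmatic counterpart of [load_network()] used by the simulator
#' and tests: two-column (plus optional `sign`) data.frame or matrix.
#'
#' @param edges Two- or three-column data.frame/matrix (source, target,
#'   optional sign).
#' @param directed Logical.
#' @return An `igraph` object, self-loops and duplicates removed.
#' @export
network_from_edges <- function(edges, directed = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  el <- cbind(toupper(trimws(as.character(edges[[1]]))),
              toupper(trimws(as.character(edges[[2]]))))
  g <- igraph::graph_from_edgelist(el, directed = directed)
  if (ncol(edges) >= 3L) igraph::E(g)$sign <- as.character(edges[[3]])
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Shortest-path length matrix (hops)
#'
#' Unweighted shortest paths from every node; for directed networks the
#' orientation is outgoing (`from` rows to `to` columns), matching the
#' convention that directional information is respected in signaling
#' networks. Unreachable pairs are `Inf`.
#' @noRd
distance_matrix <- function(net, from = igraph::V(net)) {
  igraph::distances(net, v = from, mode = "out")
}

#' Node centralities
#'
#' Computes per-node centrality measures:
#' \describe{
#'   \item{degree}{degree / (n - 1); total degree on directed networks}
#'   \item{betweenness}{exact shortest-path betweenness, normalized by
#'     the number of ordered/unordered non-incident pairs}
#'   \item{closeness}{reachable-set normalized closeness
#'     `((r-1)/(n-1)) * (r-1)/sum(d)` where `r` is the size of the
#'     node's reachable set — well-defined on disconnected graphs,
#'     0 for isolated nodes}
#'   \item{pagerank}{damping 0.85}
#'   \item{eigenvector}{principal-eigenvector centrality (power
#'     iteration; scaled to max 1)}
#'   \item{katz}{Katz centrality with attenuation `alpha = 0.9/lambda_max`,
#'     `beta = 1`, normalized to unit Euclidean norm}
#'   \item{in_degree / out_degree}{directed networks only, / (n - 1)}
#' }
#'
#' @param net An `igraph` network.
#' @param measures Character vector of measures (see above).
#' @param katz_alpha Katz attenuation factor; default `0.9 / lambda_max`.
#' @return `data.frame` with column `gene` plus one column per measure.
#' @export
centralities <- function(net, measures = c("degree", "betweenness", "closeness"),
                         katz_alpha = NULL) {
  stopifnot(igraph::is_igraph(net))
  bad <- setdiff(measures, CENTRALITY_MEASURES)
  if (length(bad)) stop("unknown centrality measure(s): ",
                        paste(bad, collapse = ", "))
  directed <- igraph::is_directed(net)
  if (!directed && any(c("in_degree", "out_degree") %in% measures))
    stop("in_degree/out_degree are only defined for directed networks")
  n <- igraph::vcount(net)
  out <- data.frame(gene = igraph::V(net)$name, stringsAsFactors = FALSE)
  denom <- max(1L, n - 1L)
  for (m in measures) {
    out[[m]] <- switch(
      m,
      degree = igraph::degree(net, mode = "all") / denom,
      in_degree = igraph::degree(net, mode = "in") / denom,
      out_degree = igraph::degree(net, mode = "out") / denom,
      betweenness = igraph::betweenness(net, directed = directed,
                                        normalized = TRUE),
      closeness = closeness_reachable(net),
      pagerank = igraph::page_rank(net, damping = 0.85)$vector,
      eigenvector = eigenvector_power(net),
      katz = katz_centrality(net, alpha = katz_alpha)
    )
  }
  rownames(out) <- NULL
  out
}

# Wasserman-Faust closeness on the reachable set (the NetworkX
# convention): ((r-1)/(n-1)) * (r-1)/sum(d) over the r-1 reachable
# nodes; 0 when nothing is reachable.
closeness_reachable <- function(net, chunk = 512L) {
  n <- igraph::vcount(net)
  vals <- numeric(n)
  idx <- seq_len(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- idx[start:min(start + chunk - 1L, n)]
    d <- igraph::distances(net, v = rows, mode = "out")
    fin <- is.finite(d)
    r <- rowSums(fin)                    # reachable incl. self (d=0)
    s <- rowSums(ifelse(fin, d, 0))
    vals[rows] <- ifelse(r > 1L & s > 0,
                         ((r - 1) / max(1L, n - 1L)) * ((r - 1) / s), 0)
  }
  vals
}

eigenvector_power <- function(net, tol = 1e-8, max_iter = 1000L) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  At <- Matrix::t(A)                     # x_i <- sum_j A_ji x_j
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(At %*% x)
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) stop("eigenvector centrality failed to converge ",
                       "(zero vector); consider Katz centrality")
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      return(x / max(x))
    }
    x <- x_new
  }
  stop("eigenvector centrality did not converge in ", max_iter,
       " iterations; consider Katz centrality")
}

katz_centrality <- function(net, alpha = NULL, beta = 1) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  n <- nrow(A)
  if (is.null(alpha)) {
    lam <- tryCatch(max(abs(eigen(as.matrix(A), only.values = TRUE)$values)),
                    error = function(e) NA_real_)
    if (!is.finite(lam) || lam <= 0) lam <- max(1, max(Matrix::rowSums(A)))
    alpha <- 0.9 / lam
  }
  # x = (I - alpha * A^T)^{-1} beta * 1, normalized to unit norm
  M <- Matrix::Diagonal(n) - alpha * Matrix::t(A)
  x <- as.numeric(Matrix::solve(M, rep(beta, n)))
  x / sqrt(sum(x^2))
}

#' Shortest-path proximity of one node to a gene set
#'
#' Average and minimum shortest-path length (hops) from `node` to the
#' members of `target_set`, over reachable members. When `exclude_self`
#' and the node belongs to the set, the zero self-distance is dropped.
#' An empty effective set, or one with no reachable member, yields the
#' sentinel for both values.
#'
#' @param net An `igraph` network.
#' @param node Gene symbol; must be a node of `net`.
#' @param target_set Character vector of gene symbols (silently
#'   intersected with the node set).
#' @param exclude_self Drop the node itself from the target set
#'   (default `TRUE`).
#' @param sentinel Value used when no finite distance exists; default
#'   `vcount(net)`, which exceeds any finite shortest path.
#' @return Named numeric vector `c(avg_sp=, min_sp=)`.
#' @export
class_distance_summary <- function(net, node, target_set,
                                   exclude_self = TRUE,
                                   sentinel = igraph::vcount(net)) {
  stopifnot(igraph::is_igraph(net))
  if (!node %in% igraph::V(net)$name) stop("node not in network: ", node)
  targets <- intersect(target_set, igraph::V(net)$name)
  if (exclude_self) targets <- setdiff(targets, node)
  if (!length(targets))
    return(c(avg_sp = sentinel, min_sp = sentinel))
  d <- as.numeric(igraph::distances(net, v = node, to = targets, mode = "out"))
  d <- d[is.finite(d)]
  if (!length(d)) return(c(avg_sp = sentinel, min_sp = sentinel))
  c(avg_sp = mean(d), min_sp = min(d))
}

#' Class composition of a node's neighborhood
#'
#' For each of the seven classes (six labels plus OG), the fraction of
#' the node's neighbors carrying that label. A neighbor with several
#' labels counts in each, so the ratios may sum to more than 1.
#' Directed networks use the union of in- and out-neighbors; isolated
#' nodes get all-zero ratios.
#'
#' @param net An `igraph` network.
#' @param node Gene symbol in `net`.
#' @param catalog A `gene_catalog` (restricted to `net`).
#' @return Named numeric vector over [all_classes()].
#' @export
neighbor_class_ratios <- function(net, node, catalog) {
  stopifnot(igraph::is_igraph(net), inherits(catalog, "gene_catalog"))
  if (!node %in% igraph::V(net)$name) stop("node not in network: ", node)
  nbrs <- igraph::neighbors(net, node, mode = "all")$name
  nbrs <- setdiff(unique(nbrs), node)
  out <- stats::setNames(numeric(length(all_classes())), all_classes())
  if (!length(nbrs)) return(out)
  og <- other_genes(catalog, net)
  for (lab in gene_classes())
    out[lab] <- sum(nbrs %in% catalog$members[[lab]]) / length(nbrs)
  out["OG"] <- sum(nbrs %in% og) / length(nbrs)
  out
}

#' Compare a class's proximity to another class vs the background
#'
#' For every node of `class_a`, computes the average and minimum
#' shortest-path length to `class_b` and to the OG background, then
#' contrasts the two distributions with a two-sided Wilcoxon rank-sum
#' test. The reported `direction` is `"closer"` when the median
#' distance to `class_b` is smaller than to OG, `"farther"` when
#' larger, `"none"` on ties.
#'
#' @param net An `igraph` network.
#' @param catalog A `gene_catalog` restricted to `net`.
#' @param class_a,class_b Class labels; `class_b` may also be `"OG"`.
#' @param stat `"avg"` or `"min"` — which per-node summary to test.
#' @param sentinel Distance sentinel (see [class_distance_summary()]).
#' @return List with `per_node` (data.frame: gene, dist_class,
#'   dist_og), `p_value`, `direction`, `stat`.
#' @export
group_distance_analysis <- function(net, catalog, class_a, class_b,
                                    stat = c("avg", "min"),
                                    sentinel = igraph::vcount(net)) {
  stat <- match.arg(stat)
  members_a <- if (class_a == "OG") other_genes(catalog, net) else
    intersect(catalog$members[[class_a]], igraph::V(net)$name)
  members_b <- if (class_b == "OG") other_genes(catalog, net) else
    intersect(catalog$members[[class_b]], igraph::V(net)$name)
  og <- other_genes(catalog, net)
  if (!length(members_a)) stop("class ", class_a, " is empty on this network")
  if (!length(members_b)) stop("class ", class_b, " is empty on this network")
  pick <- if (stat == "avg") "avg_sp" else "min_sp"
  d_b <- vapply(members_a, function(v)
    class_distance_summary(net, v, members_b, TRUE, sentinel)[[pick]], numeric(1))
  d_og <- vapply(members_a, function(v)
    class_distance_summary(net, v, og, TRUE, sentinel)[[pick]], numeric(1))
  p <- if (isTRUE(all.equal(d_b, d_og))) 1 else
    suppressWarnings(stats::wilcox.test(d_b, d_og)$p.value)
  med_diff <- stats::median(d_b) - stats::median(d_og)
  direction <- if (med_diff < 0) "closer" else if (med_diff > 0) "farther" else "none"
  list(per_node = data.frame(gene = members_a, dist_class = unname(d_b),
                             dist_og = unname(d_og), row.names = NULL),
       p_value = p, direction = direction, stat = stat,
       class_a = class_a, class_b = class_b)
}

#' Write per-gene network descriptors as TSV
#'
#' @param df A data.frame with a `gene` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
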