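#' @title Gene-class catalogs
#' @description A `gene_catalog` maps each of six disease-related gene
#'   classes to a set of gene symbols:
#'   \describe{
#'     \item{DTG}{drug target genes — the positive class for prediction}
#'     \item{DAG}{disease-associated genes (curated gene-disease links)}
#'     \item{PFG / PUG}{genes whose high expression is prognostically
#'       favorable / unfavorable}
#'     \item{URG / DRG}{genes up- / down-regulated in tumor vs paired
#'       normal tissue}
#'   }
#'   Classes are not mutually exclusive: a gene may carry several labels.
#'   Network nodes carrying no label form the "other genes" (OG)
#'   background, the negative/unlabeled pool.
#' @name gene_catalog
NULL

#' Class labels recognized by the catalog
#'
#' `gene_classes()` returns the six membership labels; `all_classes()`
#' appends the derived background label `"OG"` (other genes).
#'
#' @return Character vector of labels.
#' @export
gene_classes <- function() c("DTG", "DAG", "PFG", "PUG", "URG", "DRG")

#' @rdname gene_classes
#' @export
all_classes <- function() c(gene_classes(), "OG")

#' Normalize gene symbols
#'
#' Trims whitespace, uppercases, drops empty strings and `#` comment
#' lines, and deduplicates while preserving first occurrence. No alias
#' or HGNC resolution is attempted; inputs are expected to be official
#' symbols already.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of clean, unique, uppercase symbols.
#' @export
normalize_symbols <- function(x) {
  x <- trimws(as.character(x))
  x <- x[!startsWith(x, "#")]
  x <- toupper(x[nzchar(x)])
  unique(x)
}

new_gene_catalog <- function(members) {
  stopifnot(is.list(members))
  full <- stats::setNames(vector("list", length(gene_classes())), gene_classes())
  for (lab in gene_classes()) {
    full[[lab]] <- sort(unique(as.character(members[[lab]])))
  }
  structure(list(members = full), class = "gene_catalog")
}

#' Build a gene-class catalog from in-memory gene sets
#'
#' @param ... Named character vectors, one per class label (a subset of
#'   [gene_classes()]); omitted classes are empty.
#' @param pfg_pug_conflict How to resolve genes appearing in both
#'   prognostic lists: `"drop"` removes them from both (default),
#'   `"keep"` leaves them in both.
#' @return A `gene_catalog`.
#' @examples
#' gene_catalog(DTG = c("TP53", "EGFR"), DAG = "TP53")
#' @export
gene_catalog <- function(..., pfg_pug_conflict = c("drop", "keep")) {
  members <- list(...)
  if (length(members) && (is.null(names(members)) || any(!nzchar(names(members)))))
    stop("all gene sets must be named by class label")
  bad <- setdiff(names(members), gene_classes())
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(gene_classes(), collapse = ", "), ")")
  members <- lapply(members, normalize_symbols)
  members <- resolve_pfg_pug(members, match.arg(pfg_pug_conflict))
  new_gene_catalog(members)
}

resolve_pfg_pug <- function(members, policy) {
  both <- intersect(members[["PFG"]], members[["PUG"]])
  if (length(both)) {
    warning(length(both), " gene(s) appear in both PFG and PUG lists: ",
            paste(utils::head(both, 5), collapse = ", "),
            if (length(both) > 5) ", ..." else "",
            if (policy == "drop") " -- dropped from both" else " -- kept in both")
    if (policy == "drop") {
      members[["PFG"]] <- setdiff(members[["PFG"]], both)
      members[["PUG"]] <- setdiff(members[["PUG"]], both)
    }
  }
  members
}

#' Load gene-class membership lists from files
#'
#' Each file is UTF-8 text with one gene symbol per line (or a
#' single-column TSV); blank lines are skipped and lines starting with
#' `#` are comments. Symbols are trimmed, uppercased and deduplicated.
#'
#' @param paths Named character vector or list mapping class labels
#'   (subset of [gene_classes()]) to file paths.
#' @inheritParams gene_catalog
#' @return A `gene_catalog`.
#' @export
load_gene_lists <- function(paths, pfg_pug_conflict = c("drop", "keep")) {
  paths <- as.list(paths)
  bad <- setdiff(names(paths), gene_classes())
  if (length(bad) || is.null(names(paths)))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  members <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("cannot read gene list file: ", p)
    normalize_symbols(readLines(p, warn = FALSE))
  })
  members <- resolve_pfg_pug(members, match.arg(pfg_pug_conflict))
  new_gene_catalog(members)
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog>\n")
  for (lab in gene_classes())
    cat(sprintf("  %s: %d genes\n", lab, length(x$members[[lab]])))
  invisible(x)
}

#' Summarize catalog class sizes
#'
#' @param catalog A `gene_catalog`.
#' @return `data.frame` with columns `label` and `n`.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  data.frame(label = gene_classes(),
             n = vapply(catalog$members[gene_classes()], length, integer(1)),
             row.names = NULL)
}

#' Restrict a catalog to the nodes of a network
#'
#' Intersects every class set with the node set of `net`. The result
#' carries a `mapping` attribute recording input and mapped counts per
#' class (the catalog summary TSV contract).
#'
#' @param catalog A `gene_catalog`.
#' @param net An `igraph` network (see [load_network()]).
#' @return A restricted `gene_catalog`; idempotent.
#' @export
restrict_to_network <- function(catalog, net) {
  stopifnot(inherits(catalog, "gene_catalog"), igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("network is empty")
  nodes <- igraph::V(net)$name
  n_input <- vapply(catalog$members, length, integer(1))
  members <- lapply(catalog$members, intersect, y = nodes)
  out <- new_gene_catalog(members)
  attr(out, "mapping") <- data.frame(
    label = gene_classes(),
    n_input = unname(n_input[gene_classes()]),
    n_mapped = vapply(members[gene_classes()], length, integer(1)),
    row.names = NULL)
  out
}

#' Background ("other") genes of a network
#'
#' Nodes of `net` carrying none of the six class labels. Together with
#' the labeled union these partition the node set.
#'
#' @inheritParams restrict_to_network
#' @return Character vector of gene symbols (sorted).
#' @export
other_genes <- function(catalog, net) {
  stopifnot(inherits(catalog, "gene_catalog"), igraph::is_igraph(net))
  labeled <- unique(unlist(catalog$members, use.names = FALSE))
  sort(setdiff(igraph::V(net)$name, labeled))
}

#' Class membership of every network node, including OG
#'
#' Internal helper: a nodes x 7 logical matrix over
#' `all_classes()`, with `OG` true exactly when no other label is.
#'
#' @noRd
class_membership_matrix <- function(catalog, net) {
  nodes <- igraph::V(net)$name
  m <- vapply(gene_classes(),
              function(lab) nodes %in% catalog$members[[lab]],
              logical(length(nodes)))
  m <- cbind(m, OG = rowSums(m) == 0)
  rownames(m) <- nodes
  m
}

#' Write the per-class mapping summary of a restricted catalog as TSV
#'
#' @param catalog A catalog produced by [restrict_to_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_summary <- function(catalog, path) {
  m <- attr(catalog, "mapping")
  if (is.null(m))
    m <- cbind(catalog_summary(catalog), n_mapped = NA_integer_)[, c(1, 2, 3)]
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
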