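#' @title Paired differential expression calling
#' @description Calls tumor-up-regulated (URG) and down-regulated (DRG)
#'   genes from paired tumor/normal expression using a per-gene paired
#'   t-test on `log2(x + 1)` values, a linear fold change on
#'   pseudocounted means, and Benjamini-Hochberg FDR control. Defaults
#'   follow the common criteria FDR <= 0.05 and absolute fold change
#'   >= 2.
#' @name diffexpr
NULL

#' Construct a paired expression object
#'
#' @param tumor,normal Non-negative numeric matrices of identical shape
#'   (genes x pairs) with gene symbols as row names.
#' @param pairs Optional pair identifiers (default column names of
#'   `tumor` or `P1..Pn`).
#' @return A `paired_expression` object (list with `genes`, `pairs`,
#'   `tumor`, `normal`).
#' @export
paired_expression <- function(tumor, normal, pairs = NULL) {
  tumor <- as.matrix(tumor); normal <- as.matrix(normal)
  if (!identical(dim(tumor), dim(normal)))
    stop("tumor and normal matrices must have identical dimensions")
  if (is.null(rownames(tumor))) stop("tumor matrix needs gene row names")
  if (anyNA(tumor) || anyNA(normal)) stop("missing values are not allowed")
  if (any(tumor < 0) || any(normal < 0)) stop("negative expression values")
  if (is.null(pairs))
    pairs <- if (!is.null(colnames(tumor))) colnames(tumor)
      else paste0("P", seq_len(ncol(tumor)))
  genes <- toupper(rownames(tumor))
  dimnames(tumor) <- dimnames(normal) <- list(genes, pairs)
  structure(list(genes = genes, pairs = pairs, tumor = tumor,
                 normal = normal), class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("<paired_expression> ", length(x$genes), " genes x ",
      length(x$pairs), " tumor/normal pairs\n", sep = "")
  invisible(x)
}

#' Load a paired expression matrix and its pairing manifest
#'
#' The expression file is a TSV with genes in rows (first column gene
#' symbol, remaining columns samples). The manifest is a TSV with
#' columns `pair_id`, `tumor_column`, `normal_column` naming the sample
#' columns of each pair.
#'
#' @param expr_path Expression TSV path.
#' @param manifest_path Pairing manifest TSV path.
#' @return A `paired_expression` object.
#' @export
load_paired_expression <- function(expr_path, manifest_path) {
  if (!file.exists(expr_path)) stop("cannot read expression file: ", expr_path)
  if (!file.exists(manifest_path)) stop("cannot read manifest: ", manifest_path)
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  man <- utils::read.delim(manifest_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("pair_id", "tumor_column", "normal_column")
  if (!all(need %in% names(man)))
    stop("pairing manifest must have columns: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(c(man$tumor_column, man$normal_column), names(df))
  if (length(missing_cols))
    stop("manifest names sample column(s) absent from expression file: ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  paired_expression(m[, man$tumor_column, drop = FALSE],
                    m[, man$normal_column, drop = FALSE],
                    pairs = man$pair_id)
}

#' Per-gene paired t-test p-values
#'
#' Two-sided paired t-test on transformed values (default
#' `log2(x + offset)`), vectorized over genes. Degenerate genes are
#' handled by convention: zero-variance, zero-mean paired differences
#' give p = 1; zero-variance, non-zero-mean differences give a
#' machine-epsilon floor with a warning (the t statistic diverges).
#'
#' @param expr A `paired_expression` object.
#' @param log2_offset Offset added before the log2 transform (default
#'   1); `NULL` skips the transform.
#' @return Named numeric vector of p-values.
#' @export
paired_t_pvalues <- function(expr, log2_offset = 1) {
  stopifnot(inherits(expr, "paired_expression"))
  n <- length(expr$pairs)
  if (n < 2L) stop("paired t-test requires at least 2 pairs")
  tf <- if (is.null(log2_offset)) identity else function(x) log2(x + log2_offset)
  d <- tf(expr$tumor) - tf(expr$normal)
  m <- rowMeans(d)
  s2 <- rowSums((d - m)^2) / (n - 1)
  p <- rep(NA_real_, nrow(d))
  zero_var <- s2 < .Machine$double.eps * 100
  zero_mean <- abs(m) < .Machine$double.eps * 100
  p[zero_var & zero_mean] <- 1
  if (any(zero_var & !zero_mean)) {
    warning(sum(zero_var & !zero_mean),
            " gene(s) with zero-variance, non-zero-mean differences; ",
            "p floored at machine epsilon")
    p[zero_var & !zero_mean] <- .Machine$double.eps
  }
  ok <- !zero_var
  tstat <- m[ok] / sqrt(s2[ok] / n)
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 1)
  stats::setNames(p, expr$genes)
}

#' Per-gene linear fold changes
#'
#' `FC = (mean tumor + pseudocount) / (mean normal + pseudocount)`,
#' means taken across pairs on the original (linear) scale.
#'
#' @param expr A `paired_expression` object.
#' @param pseudocount Positive stabilizer (default 1).
#' @return Named numeric vector of fold changes.
#' @export
fold_changes <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "paired_expression"), pseudocount > 0)
  fc <- (rowMeans(expr$tumor) + pseudocount) /
        (rowMeans(expr$normal) + pseudocount)
  stats::setNames(fc, expr$genes)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control (wraps
#' `stats::p.adjust(method = "BH")` after validating the input range).
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return q-values, same order and names as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call up- and down-regulated genes
#'
#' URG iff `q <= alpha` and `FC >= fc_threshold`; DRG iff `q <= alpha`
#' and `FC <= 1/fc_threshold`; otherwise no call. Thresholds are
#' inclusive.
#'
#' @param fc Linear fold changes (named).
#' @param q BH q-values, aligned with `fc`.
#' @param fc_threshold Fold-change threshold (> 1, default 2).
#' @param alpha FDR level (default 0.05).
#' @param p Optional raw p-values carried into the output.
#' @return `data.frame`: gene, fc, log2fc, p, q, call (factor with
#'   levels URG, DRG, none).
#' @export
call_degs <- function(fc, q, fc_threshold = 2, alpha = 0.05, p = NA_real_) {
  if (length(fc) != length(q)) stop("fc and q must be aligned")
  call <- rep("none", length(fc))
  call[q <= alpha & fc >= fc_threshold] <- "URG"
  call[q <= alpha & fc <= 1 / fc_threshold] <- "DRG"
  data.frame(gene = if (!is.null(names(fc))) names(fc) else seq_along(fc),
             fc = unname(fc), log2fc = unname(log2(fc)),
             p = unname(p), q = unname(q),
             call = factor(call, levels = c("URG", "DRG", "none")),
             row.names = NULL)
}

#' Full differential-expression pipeline
#'
#' Convenience wrapper: [paired_t_pvalues()] + [fold_changes()] +
#' [bh_fdr()] + [call_degs()].
#'
#' @inheritParams paired_t_pvalues
#' @inheritParams fold_changes
#' @inheritParams call_degs
#' @return The [call_degs()] data.frame.
#' @export
run_deg <- function(expr, fc_threshold = 2, alpha = 0.05,
                    log2_offset = 1, pseudocount = 1) {
  p <- paired_t_pvalues(expr, log2_offset)
  fc <- fold_changes(expr, pseudocount)
  call_degs(fc, bh_fdr(p), fc_threshold, alpha, p = p)
}
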