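#' @title Evaluation statistics
#' @description Classification metrics (sensitivity, specificity,
#'   Matthews correlation coefficient), ROC/AUC, Fisher enrichment of a
#'   predicted gene set for an independent reference, evaluation
#'   against alternative negative sets, the rank-to-score transform for
#'   seed-based ranking algorithms (DADA-style), and Wilcoxon
#'   group-comparison batteries for centralities.
#' @name evaluation_stats
NULL

#' Sensitivity, specificity and MCC from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' When any factor of the MCC denominator is zero the MCC is 0 by
#' convention and the result is flagged `degenerate`.
#'
#' @param tp,fn,tn,fp Non-negative counts.
#' @return List with `Sn`, `Sp`, `MCC`, `degenerate`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  fac <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  degenerate <- any(fac == 0)
  mcc <- if (degenerate) 0 else
    (tp * tn - fn * fp) / sqrt(prod(fac))
  list(Sn = sn, Sp = sp, MCC = mcc, degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) method with midrank tie handling:
#' `AUC = P(score+ > score-) + 0.5 P(score+ = score-)`. The curve is
#' the staircase over unique thresholds.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Binary labels (1/TRUE = positive), aligned with
#'   `scores`; both classes must be present.
#' @return List with `auc` and `roc` (data.frame `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels must align")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)                       # midranks on ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  keep <- c(diff(s) != 0, TRUE)           # last point per threshold
  roc <- data.frame(fpr = c(0, fp[keep] / n0),
                    tpr = c(0, tp[keep] / n1),
                    threshold = c(Inf, s[keep]))
  list(auc = auc, roc = roc)
}

#' Enrichment of a predicted gene set for reference positives
#'
#' One-sided (greater) Fisher's exact test of the 2x2 table
#' predicted-vs-not by reference-positive-vs-not over the universe,
#' with the proportions of reference positives inside the predicted
#' set and in the rest of the universe.
#'
#' @param predicted Predicted gene set.
#' @param reference_positives Independent reference positive set.
#' @param universe All genes under consideration; `predicted` and
#'   `reference_positives` outside it are dropped with a warning.
#' @return List with `table` (2x2 matrix), `prop_predicted`,
#'   `prop_background`, `odds_ratio`, `p_value`.
#' @export
enrichment_test <- function(predicted, reference_positives, universe) {
  if (!length(predicted)) stop("predicted set is empty")
  out_pred <- setdiff(predicted, universe)
  out_ref <- setdiff(reference_positives, universe)
  if (length(out_pred) || length(out_ref)) {
    warning("dropping ", length(out_pred), " predicted and ",
            length(out_ref), " reference gene(s) outside the universe")
    predicted <- intersect(predicted, universe)
    reference_positives <- intersect(reference_positives, universe)
    if (!length(predicted)) stop("predicted set is empty within the universe")
  }
  rest <- setdiff(universe, predicted)
  a <- length(intersect(predicted, reference_positives))
  b <- length(predicted) - a
  c_ <- length(intersect(rest, reference_positives))
  d <- length(rest) - c_
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("ref_pos", "ref_neg"),
                                c("predicted", "background")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab,
       prop_predicted = a / length(predicted),
       prop_background = if (length(rest)) c_ / length(rest) else NA_real_,
       odds_ratio = unname(ft$estimate),
       p_value = ft$p.value)
}

#' Re-estimate performance against an alternative negative set
#'
#' AUC of the stored final prediction scores using a supplied negative
#' gene set (e.g. curated disease genes, known drug targets of other
#' diseases, cancer driver genes) instead of the full unlabeled
#' background. Genes in both sets are dropped from the negatives with
#' a warning.
#'
#' @param final_scores Named numeric vector of per-gene final scores.
#' @param positives Positive gene set.
#' @param negative_set Alternative negative gene set.
#' @return List with `auc`, `roc`, `n_positives`, `n_negatives`.
#' @export
alt_negative_evaluation <- function(final_scores, positives, negative_set) {
  overlap <- intersect(positives, negative_set)
  if (length(overlap)) {
    warning("dropping ", length(overlap),
            " gene(s) present in both sets from the negatives")
    negative_set <- setdiff(negative_set, positives)
  }
  pos <- intersect(positives, names(final_scores))
  neg <- intersect(negative_set, names(final_scores))
  if (!length(neg)) stop("no scored genes left in the negative set")
  if (!length(pos)) stop("no scored genes in the positive set")
  sc <- c(final_scores[pos], final_scores[neg])
  lab <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  r <- roc_auc(sc, lab)
  list(auc = r$auc, roc = r$roc, n_positives = length(pos),
       n_negatives = length(neg))
}

#' Rank-to-score transform for seed-based gene rankings
#'
#' `score = (N - rank) / N` where `N` is the number of ranked
#' candidates: the top-ranked gene scores `(N-1)/N`, the bottom gene 0.
#' Strictly decreasing in rank.
#'
#' @param rank Integer rank(s), 1-based, in `[1, n_candidates]`.
#' @param n_candidates Total number of ranked candidates.
#' @return Numeric score(s) in `[0, 1)`.
#' @export
dada_score <- function(rank, n_candidates) {
  if (n_candidates < 1) stop("n_candidates must be positive")
  if (any(rank < 1 | rank > n_candidates))
    stop("rank must lie in [1, n_candidates]")
  (n_candidates - rank) / n_candidates
}

#' Build the 7-column rank-score feature block
#'
#' Converts seven ranked gene lists (one per seed class: the six labels
#' plus OG) into a genes x 7 matrix of [dada_score()] values, for the
#' `dada_*` feature variants.
#'
#' @param rankings Named list of 7 character vectors (full rankings of
#'   the same candidate set), names in [all_classes()].
#' @param genes Genes to extract (default: the first ranking).
#' @return Numeric matrix genes x 7 with columns `dada_<class>`.
#' @export
dada_feature_table <- function(rankings, genes = NULL) {
  if (!setequal(names(rankings), all_classes()))
    stop("rankings must be named by the seven classes: ",
         paste(all_classes(), collapse = ", "))
  if (is.null(genes)) genes <- sort(rankings[[1]])
  out <- matrix(NA_real_, length(genes), 7L,
                dimnames = list(genes, paste0("dada_", all_classes())))
  for (lab in all_classes()) {
    rk <- rankings[[lab]]
    if (!all(genes %in% rk))
      stop("ranking for ", lab, " does not cover every requested gene")
    out[, paste0("dada_", lab)] <- dada_score(match(genes, rk), length(rk))
  }
  out
}

#' Wilcoxon battery: class centralities against the background
#'
#' For each class and centrality measure, a two-sided Wilcoxon
#' rank-sum test of the class members' values against all nodes'
#' values (class included in the background), with the direction of
#' the median difference. Raw p-values are reported alongside a BH
#' column.
#'
#' @param centr Centrality data.frame from [centralities()] (column
#'   `gene` plus measures).
#' @param catalog A `gene_catalog` restricted to the same network.
#' @param classes Labels to test (default the six labels).
#' @return `data.frame`: class, measure, n_class, p_value, direction,
#'   testable, q_value.
#' @export
centrality_group_tests <- function(centr, catalog,
                                   classes = gene_classes()) {
  measures <- setdiff(names(centr), "gene")
  res <- list()
  for (m in measures) {
    bg <- centr[[m]]
    for (lab in classes) {
      idx <- centr$gene %in% catalog$members[[lab]]
      x <- centr[[m]][idx]
      if (length(x) < 2L) {
        res[[length(res) + 1L]] <- data.frame(
          class = lab, measure = m, n_class = length(x),
          p_value = NA_real_, direction = "none", testable = FALSE)
        next
      }
      p <- suppressWarnings(stats::wilcox.test(x, bg)$p.value)
      md <- stats::median(x) - stats::median(bg)
      res[[length(res) + 1L]] <- data.frame(
        class = lab, measure = m, n_class = length(x), p_value = p,
        direction = if (md > 0) "higher" else if (md < 0) "lower" else "none",
        testable = TRUE)
    }
  }
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  ok <- out$testable
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  rownames(out) <- NULL
  out
}
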