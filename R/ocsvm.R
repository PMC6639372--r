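#' @title One-class SVM drug-target predictor
#' @description Trains a one-class support vector machine (RBF kernel,
#'   libsvm via \pkg{e1071}) on the known drug-target genes only, and
#'   evaluates it with repeated k-fold cross-validation in which the
#'   unlabeled/negative genes never enter training but are folded for
#'   scoring, so that every gene receives exactly one out-of-fold
#'   decision score per round. Calls use the libsvm one-class
#'   convention: decision value > 0 is target-like.
#' @name ocsvm_predictor
NULL

#' Default hyperparameter grid
#'
#' `nu` in \{0.05, 0.1, 0.2, 0.3, 0.5\} crossed with `gamma` spanning
#' `1/d` scaled by powers of 4 from 4^-2 to 4^2, where `d` is the
#' feature count.
#'
#' @param d Number of features.
#' @return `data.frame` with columns `nu` and `gamma`.
#' @export
default_ocsvm_grid <- function(d) {
  expand.grid(nu = c(0.05, 0.1, 0.2, 0.3, 0.5),
              gamma = (1 / d) * 4^(-2:2))
}

#' Train a one-class SVM on positive genes only
#'
#' @param table A `feature_table` (scale it first, or let
#'   [ocsvm_cross_validate()] handle per-fold scaling).
#' @param positives Character vector of positive-class genes (rows of
#'   the table); at least 2 must be present.
#' @param nu One-class `nu` in (0, 1]: upper bound on the fraction of
#'   training outliers, lower bound on the fraction of support vectors.
#' @param gamma RBF kernel width (> 0).
#' @return An `ocsvm_model` wrapping the fitted libsvm model.
#' @export
ocsvm_train <- function(table, positives, nu = 0.1, gamma = NULL) {
  values <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  pos <- intersect(positives, rownames(values))
  if (length(pos) < 2L)
    stop("need at least 2 positive genes present in the feature table")
  if (!(nu > 0 && nu <= 1)) stop("nu must lie in (0, 1]")
  if (is.null(gamma)) gamma <- 1 / ncol(values)
  if (gamma <= 0) stop("gamma must be positive")
  fit <- e1071::svm(values[pos, , drop = FALSE], y = NULL,
                    type = "one-classification", kernel = "radial",
                    nu = nu, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, nu = nu, gamma = gamma,
                 feature_names = colnames(values), n_positives = length(pos)),
            class = "ocsvm_model")
}

#' Decision scores of a one-class model
#'
#' Higher = more target-like; > 0 is called positive.
#'
#' @param model An `ocsvm_model`.
#' @param table A `feature_table` or numeric matrix with the model's
#'   feature columns.
#' @return Named numeric vector of decision values.
#' @export
ocsvm_decision <- function(model, table) {
  values <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  miss <- setdiff(model$feature_names, colnames(values))
  extra <- setdiff(colnames(values), model$feature_names)
  if (length(miss) || length(extra))
    stop("feature schema mismatch; missing: ",
         paste(miss, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  values <- values[, model$feature_names, drop = FALSE]
  pr <- stats::predict(model$fit, values, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  stats::setNames(as.numeric(dv), rownames(values))
}

# deterministic fold assignment: shuffle then deal round-robin
make_folds <- function(x, k) {
  sh <- sample(x)
  stats::setNames(rep_len(seq_len(k), length(sh)), sh)[x]
}

#' Repeated k-fold cross-validation of the one-class predictor
#'
#' Per repeat, positives and negatives are independently partitioned
#' into `k` folds. For each fold a model is trained on the other
#' `k - 1` positive folds (negatives never train) and scores the
#' held-out positives and held-out negatives, so each gene is scored
#' exactly once per round. Per-round sensitivity/specificity/MCC pool
#' the confusion counts across folds at decision threshold 0; AUC uses
#' the pooled continuous scores. When `grid` has several rows the full
#' protocol runs for each (nu, gamma) with identical partitions, and
#' the pair maximizing mean AUC across repeats is selected once and
#' reported.
#'
#' Feature scaling (min-max by default) is fit per fold on the
#' training positives plus the unlabeled pool, never on held-out
#' positives.
#'
#' @param table An unscaled `feature_table`.
#' @param positives Positive-class genes.
#' @param k Folds (default 5).
#' @param repeats Rounds (default 10).
#' @param grid Hyperparameter `data.frame(nu, gamma)`; default
#'   [default_ocsvm_grid()]. A single row skips the search.
#' @param seed Master seed; per-repeat partition seeds are derived from
#'   it and recorded.
#' @param scale_method `"minmax"`, `"zscore"` or `"none"`.
#' @return An `ocsvm_cv` object: list with `rounds` (per round: scores,
#'   calls, folds, Sn, Sp, MCC, AUC, seed), `selected` (nu, gamma),
#'   `grid_results`, `positives`, `k`, `seed`.
#' @export
ocsvm_cross_validate <- function(table, positives, k = 5L, repeats = 10L,
                                 grid = NULL, seed = 1L,
                                 scale_method = c("minmax", "zscore", "none")) {
  stopifnot(inherits(table, "feature_table"))
  scale_method <- match.arg(scale_method)
  if (k < 2L) stop("k must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  values <- table$values
  genes <- rownames(values)
  pos <- intersect(positives, genes)
  neg <- setdiff(genes, pos)
  if (length(pos) < k)
    stop("only ", length(pos), " positives for k = ", k,
         " folds; every fold must hold out at least one positive --",
         " use a smaller k")
  if (is.null(grid)) grid <- default_ocsvm_grid(ncol(values))

  round_seeds <- seed + seq_len(repeats)
  partitions <- lapply(round_seeds, function(s) {
    set.seed(s)
    list(pos = make_folds(pos, k), neg = make_folds(neg, k))
  })

  run_round <- function(part, nu, gamma) {
    scores <- stats::setNames(numeric(length(genes)), genes)
    for (f in seq_len(k)) {
      train_pos <- names(part$pos)[part$pos != f]
      held <- c(names(part$pos)[part$pos == f], names(part$neg)[part$neg == f])
      if (scale_method == "none") {
        tr <- values[train_pos, , drop = FALSE]
        te <- values[held, , drop = FALSE]
      } else {
        fit_rows <- c(train_pos, neg)
        fit <- values[fit_rows, , drop = FALSE]
        if (scale_method == "minmax") {
          lo <- apply(fit, 2L, min); hi <- apply(fit, 2L, max)
          ctr <- lo; scl <- ifelse(hi > lo, hi - lo, 1)
        } else {
          ctr <- colMeans(fit); s <- apply(fit, 2L, stats::sd)
          scl <- ifelse(s > 0, s, 1)
        }
        sc <- list(center = ctr, scale = scl)
        tr <- apply_scaling(values[train_pos, , drop = FALSE], sc)
        te <- apply_scaling(values[held, , drop = FALSE], sc)
      }
      fit_m <- e1071::svm(tr, y = NULL, type = "one-classification",
                          kernel = "radial", nu = nu, gamma = gamma,
                          scale = FALSE)
      pr <- stats::predict(fit_m, te, decision.values = TRUE)
      scores[held] <- as.numeric(attr(pr, "decision.values"))
    }
    calls <- scores > 0
    lab <- genes %in% pos
    tp <- sum(calls & lab); fn <- sum(!calls & lab)
    tn <- sum(!calls & !lab); fp <- sum(calls & !lab)
    met <- confusion_metrics(tp, fn, tn, fp)
    auc <- roc_auc(scores, as.integer(lab))$auc
    list(scores = scores, calls = calls,
         fold_pos = part$pos, fold_neg = part$neg,
         Sn = met$Sn, Sp = met$Sp, MCC = met$MCC, AUC = auc)
  }

  grid_results <- grid
  grid_results$mean_auc <- NA_real_
  all_rounds <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    rounds <- lapply(seq_len(repeats), function(r) {
      rr <- run_round(partitions[[r]], grid$nu[gi], grid$gamma[gi])
      rr$round <- r
      rr$seed <- round_seeds[r]
      rr
    })
    all_rounds[[gi]] <- rounds
    grid_results$mean_auc[gi] <- mean(vapply(rounds, `[[`, numeric(1), "AUC"))
  }
  best <- which.max(grid_results$mean_auc)
  structure(list(rounds = all_rounds[[best]],
                 selected = list(nu = grid$nu[best], gamma = grid$gamma[best]),
                 grid_results = grid_results,
                 positives = pos, k = k, repeats = repeats, seed = seed,
                 scale_method = scale_method),
            class = "ocsvm_cv")
}

#' @export
print.ocsvm_cv <- function(x, ...) {
  cat("<ocsvm_cv> ", x$repeats, " repeats of ", x$k, "-fold CV, ",
      length(x$positives), " positives\n", sep = "")
  cat("  selected nu = ", x$selected$nu, ", gamma = ",
      signif(x$selected$gamma, 4), "\n", sep = "")
  print(cv_metrics(x))
  invisible(x)
}

#' Per-round metric table of a cross-validation run
#'
#' @param cv An `ocsvm_cv` object.
#' @return `data.frame`: round, Sn, Sp, MCC, AUC.
#' @export
cv_metrics <- function(cv) {
  stopifnot(inherits(cv, "ocsvm_cv"))
  do.call(rbind, lapply(cv$rounds, function(r)
    data.frame(round = r$round, Sn = r$Sn, Sp = r$Sp, MCC = r$MCC,
               AUC = r$AUC)))
}

#' Consensus prediction over cross-validation rounds
#'
#' Final score = mean of the per-round out-of-fold decision scores;
#' the predicted set contains only genes called positive in every
#' round.
#'
#' @param cv An `ocsvm_cv` object (or list of round results sharing one
#'   gene set).
#' @return List with `final_scores` (named numeric), `predicted`
#'   (character), `n_rounds`.
#' @export
ocsvm_consensus <- function(cv) {
  rounds <- if (inherits(cv, "ocsvm_cv")) cv$rounds else cv
  gene_sets <- lapply(rounds, function(r) names(r$scores))
  if (length(unique(vapply(gene_sets, paste, "", collapse = "\r"))) != 1L)
    stop("rounds do not cover the same gene set")
  genes <- gene_sets[[1]]
  score_mat <- vapply(rounds, `[[`, numeric(length(genes)), "scores")
  call_mat <- vapply(rounds, `[[`, logical(length(genes)), "calls")
  list(final_scores = stats::setNames(rowMeans(score_mat), genes),
       predicted = genes[rowSums(call_mat) == length(rounds)],
       n_rounds = length(rounds))
}

#' Freeze a deployable predictor from a cross-validation run
#'
#' Refits one model per round on all positives with the selected
#' hyperparameters (libsvm fits are deterministic, so the refits agree;
#' one is kept per round to honor the ensemble contract), stores the
#' scaling fit on positives plus the unlabeled pool, and records the
#' predictor's own scores on the training table.
#'
#' @param cv An `ocsvm_cv` object.
#' @param table The unscaled `feature_table` used for `cv`.
#' @return An `ocsvm_predictor`: list with `models`, `scaling`,
#'   `selected`, `feature_names`, `train_scores`, `train_calls`.
#' @export
ocsvm_finalize <- function(cv, table) {
  stopifnot(inherits(cv, "ocsvm_cv"), inherits(table, "feature_table"))
  values <- table$values
  if (cv$scale_method == "none") {
    scaling <- NULL
    sv <- values
  } else {
    scaled <- scale_features(table, cv$scale_method)
    scaling <- scaled$scaling
    sv <- scaled$values
  }
  models <- lapply(seq_len(cv$repeats), function(r)
    ocsvm_train(sv, cv$positives, nu = cv$selected$nu,
                gamma = cv$selected$gamma))
  score_mat <- vapply(models, function(m) ocsvm_decision(m, sv),
                      numeric(nrow(sv)))
  call_mat <- score_mat > 0
  structure(list(models = models, scaling = scaling,
                 selected = cv$selected,
                 feature_names = colnames(values),
                 train_scores = stats::setNames(rowMeans(score_mat),
                                                rownames(sv)),
                 train_calls = stats::setNames(rowSums(call_mat) ==
                                                 ncol(call_mat),
                                               rownames(sv))),
            class = "ocsvm_predictor")
}

#' Score new genes with a frozen predictor
#'
#' Applies the stored scaling, scores the rows with every per-round
#' model, and averages; a gene is called positive only when every
#' model calls it positive.
#'
#' @param object An `ocsvm_predictor`.
#' @param newdata A `feature_table` or matrix with the training feature
#'   schema (unscaled).
#' @param ... Unused.
#' @return `data.frame`: gene, score, call.
#' @export
predict.ocsvm_predictor <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "feature_table")) newdata$values
    else as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(values))
  extra <- setdiff(colnames(values), object$feature_names)
  if (length(miss) || length(extra))
    stop("feature schema mismatch; missing: ", paste(miss, collapse = ", "),
         "; extra: ", paste(extra, collapse = ", "))
  values <- values[, object$feature_names, drop = FALSE]
  if (!is.null(object$scaling)) values <- apply_scaling(values, object$scaling)
  score_mat <- vapply(object$models, function(m) ocsvm_decision(m, values),
                      numeric(nrow(values)))
  if (is.null(dim(score_mat)))
    score_mat <- matrix(score_mat, nrow = nrow(values))
  data.frame(gene = rownames(values),
             score = rowMeans(score_mat),
             call = rowSums(score_mat > 0) == ncol(score_mat),
             row.names = NULL)
}
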