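# two well-separated Gaussian clouds as a feature table
cloud_table <- function(n_pos = 60, n_neg = 200, sep = 6, d = 5, seed = 61) {
  set.seed(seed)
  pos <- matrix(rnorm(n_pos * d), n_pos)
  neg <- matrix(rnorm(n_neg * d, mean = sep), n_neg)
  vals <- rbind(pos, neg)
  rownames(vals) <- c(sprintf("P%03d", seq_len(n_pos)),
                      sprintf("N%03d", seq_len(n_neg)))
  colnames(vals) <- paste0("f", seq_len(d))
  structure(list(values = vals, variant = "primary",
                 cell_lines = character(), scaling = NULL),
            class = "feature_table")
}

test_that("training respects the nu bound and is deterministic", {
  tab <- cloud_table()
  pos <- sprintf("P%03d", 1:60)
  m <- ocsvm_train(tab, pos, nu = 0.2, gamma = 0.1)
  sc <- ocsvm_decision(m, tab)
  expect_lte(sum(sc[pos] < 0), ceiling(0.2 * 60) + 1)
  # duplicated row scores identically
  dup <- tab$values[c("P001", "P001"), ]
  rownames(dup) <- c("X1", "X2")
  sd_ <- ocsvm_decision(m, dup)
  expect_equal(unname(sd_[1]), unname(sd_[2]))
  expect_error(ocsvm_train(tab, "P001"), "at least 2")
  expect_error(ocsvm_train(tab, pos, nu = 1.5), "nu")
  expect_error(ocsvm_train(tab, pos, gamma = -1), "gamma")
})

test_that("separated clouds are ranked nearly perfectly", {
  tab <- cloud_table()
  pos <- sprintf("P%03d", 1:60)
  m <- ocsvm_train(tab, pos, nu = 0.1, gamma = 0.2)
  sc <- ocsvm_decision(m, tab)
  lab <- as.integer(startsWith(names(sc), "P"))
  expect_gt(roc_auc(sc, lab)$auc, 0.99)
})

test_that("cross-validation is seed-reproducible with full out-of-fold coverage", {
  tab <- cloud_table()
  pos <- sprintf("P%03d", 1:60)
  grid <- data.frame(nu = 0.1, gamma = 0.2)
  cv1 <- ocsvm_cross_validate(tab, pos, k = 5, repeats = 2, grid = grid,
                              seed = 9)
  cv2 <- ocsvm_cross_validate(tab, pos, k = 5, repeats = 2, grid = grid,
                              seed = 9)
  expect_identical(cv1$rounds[[1]]$fold_pos, cv2$rounds[[1]]$fold_pos)
  expect_identical(cv1$rounds[[2]]$scores, cv2$rounds[[2]]$scores)
  expect_identical(cv_metrics(cv1), cv_metrics(cv2))
  # every gene scored exactly once per round: fold labels partition genes
  for (r in cv1$rounds) {
    expect_setequal(c(names(r$fold_pos), names(r$fold_neg)),
                    rownames(tab$values))
    expect_true(all(table(r$fold_pos) >= 1))
  }
  cv3 <- ocsvm_cross_validate(tab, pos, k = 5, repeats = 2, grid = grid,
                              seed = 10)
  expect_false(identical(cv1$rounds[[1]]$fold_pos, cv3$rounds[[1]]$fold_pos))
  expect_error(ocsvm_cross_validate(tab, pos[1:3], k = 5, grid = grid),
               "smaller k")
})

test_that("grid search reports each candidate and selects by mean AUC", {
  tab <- cloud_table(n_pos = 40, n_neg = 120)
  pos <- sprintf("P%03d", 1:40)
  grid <- data.frame(nu = c(0.1, 0.1), gamma = c(0.2, 50))
  cv <- ocsvm_cross_validate(tab, pos, k = 4, repeats = 2, grid = grid,
                             seed = 3)
  expect_equal(nrow(cv$grid_results), 2)
  expect_true(all(is.finite(cv$grid_results$mean_auc)))
  best <- which.max(cv$grid_results$mean_auc)
  expect_equal(cv$selected$gamma, grid$gamma[best])
  expect_equal(mean(cv_metrics(cv)$AUC), cv$grid_results$mean_auc[best])
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(62)
  vals <- matrix(rnorm(1060 * 6), 1060)
  rownames(vals) <- sprintf("G%04d", seq_len(1060))
  colnames(vals) <- paste0("f", 1:6)
  tab <- structure(list(values = vals, variant = "primary",
                        cell_lines = character(), scaling = NULL),
                   class = "feature_table")
  pos <- sample(rownames(vals), 60)   # arbitrary labels, no signal
  cv <- ocsvm_cross_validate(tab, pos, k = 5, repeats = 3,
                             grid = data.frame(nu = 0.1, gamma = 1 / 6),
                             seed = 63)
  expect_lt(abs(mean(cv_metrics(cv)$AUC) - 0.5), 0.06)
})

test_that("consensus is the mean score and the intersection of round calls", {
  tab <- cloud_table()
  pos <- sprintf("P%03d", 1:60)
  cv <- ocsvm_cross_validate(tab, pos, k = 5, repeats = 4,
                             grid = data.frame(nu = 0.2, gamma = 0.2),
                             seed = 64)
  cons <- ocsvm_consensus(cv)
  calls <- lapply(cv$rounds, function(r) names(r$scores)[r$calls])
  expect_setequal(cons$predicted, Reduce(intersect, calls))
  g <- rownames(tab$values)[5]
  expect_equal(unname(cons$final_scores[g]),
               mean(vapply(cv$rounds, function(r) r$scores[[g]], numeric(1))))
  # a gene positive in some but not all rounds is excluded
  n_calls <- rowSums(vapply(cv$rounds, `[[`, logical(nrow(tab$values)), "calls"))
  partial <- names(n_calls)[n_calls > 0 & n_calls < length(cv$rounds)]
  expect_length(intersect(partial, cons$predicted), 0)
  # consensus never grows as rounds accumulate
  cons2 <- ocsvm_consensus(cv$rounds[1:2])
  expect_true(all(cons$predicted %in% cons2$predicted))
})

test_that("a frozen predictor reproduces its stored scores and permutes cleanly", {
  tab <- cloud_table()
  pos <- sprintf("P%03d", 1:60)
  cv <- ocsvm_cross_validate(tab, pos, k = 5, repeats = 3,
                             grid = data.frame(nu = 0.1, gamma = 0.2),
                             seed = 65)
  pred <- ocsvm_finalize(cv, tab)
  res <- predict(pred, tab)
  expect_equal(stats::setNames(res$score, res$gene), pred$train_scores,
               tolerance = 1e-9)
  perm <- sample(nrow(tab$values))
  tab_p <- tab
  tab_p$values <- tab$values[perm, ]
  res_p <- predict(pred, tab_p)
  expect_equal(res_p$score, res$score[perm], tolerance = 1e-12)
  # schema mismatch is named
  bad <- tab$values[, -1]
  expect_error(predict(pred, bad), "missing: f1")
  # a probe at the positive centroid outranks the negatives
  centroid <- t(colMeans(tab$values[pos, ]))
  rownames(centroid) <- "PROBE"
  probe <- predict(pred, centroid)
  neg_scores <- res$score[!startsWith(res$gene, "P")]
  expect_gt(probe$score, quantile(neg_scores, 0.9))
})

test_that("AUC is invariant under monotone transforms of the scores", {
  set.seed(66)
  sc <- rnorm(300)
  lab <- as.integer(runif(300) < 0.3)
  a1 <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(10 * sc + 3, lab)$auc, a1)
  expect_equal(roc_auc(exp(sc), lab)$auc, a1)
})
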