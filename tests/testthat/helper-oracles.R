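# Independent brute-force oracles. These deliberately share no code
# with the package internals: distances by Floyd-Warshall, betweenness
# by shortest-path counting over the distance matrix, AUC by O(n^2)
# pair comparison, Fisher by hypergeometric tail summation, rank-sum by
# exhaustive enumeration, Katz by truncated power series.

# adjacency matrix in igraph vertex order (undirected or directed)
adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n)) {
      new_d <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], new_d)
    }
  D
}

# number of shortest s->t paths for all pairs, by dynamic programming
# over increasing distance
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- diag(1, n)
  maxd <- max(D[is.finite(D)])
  for (d in seq_len(maxd)) {
    idx <- which(D == d, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 1]; t <- idx[r, 2]
      preds <- which(A[, t] > 0 & D[s, ] == d - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# normalized betweenness matching igraph's convention
oracle_betweenness <- function(g) {
  A <- adj_of(g)
  directed <- igraph::is_directed(g)
  D <- oracle_floyd_warshall(A)
  sigma <- oracle_path_counts(A, D)
  n <- nrow(A)
  b <- numeric(n)
  for (v in seq_len(n))
    for (s in seq_len(n))
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (is.finite(D[s, t]) && sigma[s, t] > 0 &&
            isTRUE(all.equal(D[s, v] + D[v, t], D[s, t])))
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
  if (!directed) b <- b / 2
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  b / denom
}

# Wasserman-Faust closeness from a distance matrix (outgoing rows)
oracle_closeness <- function(D) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    d <- D[i, ]
    fin <- is.finite(d)
    r <- sum(fin)
    s <- sum(d[fin])
    if (r > 1 && s > 0) ((r - 1) / (n - 1)) * ((r - 1) / s) else 0
  }, numeric(1))
}

# Katz centrality by truncated power series, unit-norm
oracle_katz <- function(A, alpha, beta = 1, K = 400) {
  n <- nrow(A)
  x <- rep(beta, n)          # k = 0 term
  term <- rep(beta, n)
  At <- t(A)
  for (k in seq_len(K)) {
    term <- alpha * (At %*% term)
    x <- x + as.numeric(term)
  }
  x / sqrt(sum(x^2))
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# one-sided (greater) Fisher p as a hypergeometric tail sum over
# tables at least as enriched
oracle_fisher_greater <- function(a, b, c_, d) {
  K <- a + c_      # reference positives
  n <- a + b       # predicted size
  N <- a + b + c_ + d
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# exact two-sided rank-sum p by exhaustive enumeration (no ties)
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up by the textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

oracle_paired_t_p <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  2 * stats::pt(-abs(t), df = n - 1)
}

# seeded Erdos-Renyi-ish random graph as a plain edge list (kept
# independent of the generator under test)
random_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
             stringsAsFactors = FALSE)
}
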