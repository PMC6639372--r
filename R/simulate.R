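#' @title Seeded synthetic study generator
#' @description Generates a complete synthetic study — scale-free-like
#'   interaction network, gene-class catalog, gene x cell-line
#'   dependency matrix, and paired tumor/normal expression matrix —
#'   with the statistical structure the method exploits: drug-target
#'   (DTG) and disease-associated (DAG) genes get extra edges and so
#'   elevated centrality; disease-class genes (DAG/PUG/URG) are wired
#'   preferentially toward DTGs, shortening DTG-class distances;
#'   prognostic-unfavorable and up-regulated genes are more essential
#'   (lower dependency scores) while favorable and down-regulated genes
#'   are less essential; and the expression matrix carries planted
#'   fold changes for URG/DRG. Everything is reproducible from a single
#'   master seed.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe the package's medium benchmark: a 2,000-gene
#' preferential-attachment network with 14 dependency cell lines and
#' 43 tumor/normal expression pairs.
#'
#' @param n_genes Number of genes/network nodes.
#' @param class_sizes Named integer vector over [gene_classes()];
#'   classes are disjoint blocks of randomly chosen genes. Their sum
#'   must not exceed `n_genes`.
#' @param pa_m Preferential-attachment edges per incoming node.
#' @param hub_boost Named vector of extra edges per gene for hub-like
#'   classes (wired degree-proportionally), default 10 for DTG and 4
#'   for DAG.
#' @param proximity_boost Probability that a DAG/PUG/URG gene gains a
#'   direct edge to a random DTG (clusters the disease classes around
#'   the targets).
#' @param n_cell_lines Dependency-screen cell lines (default 14).
#' @param dependency_effects Named per-class shift of mean dependency
#'   score (background mean 0; negative = more essential).
#' @param dependency_sd Dependency score standard deviation.
#' @param missing_rate Fraction of dependency cells set missing.
#' @param n_pairs Tumor/normal expression pairs (default 43).
#' @param expression_lfc Named planted log2 fold changes for URG and
#'   DRG genes.
#' @param expression_noise_sd Per-sample log2 noise standard deviation.
#' @param seed Master seed recorded in every output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              class_sizes = c(DTG = 100L, DAG = 120L,
                                              PFG = 90L, PUG = 300L,
                                              URG = 400L, DRG = 100L),
                              pa_m = 3L,
                              hub_boost = c(DTG = 10L, DAG = 4L),
                              proximity_boost = 0.5,
                              n_cell_lines = 14L,
                              dependency_effects = c(DTG = 0, DAG = 0,
                                                     PFG = 0.4, PUG = -0.4,
                                                     URG = -0.4, DRG = 0.4),
                              dependency_sd = 0.3,
                              missing_rate = 0.02,
                              n_pairs = 43L,
                              expression_lfc = c(URG = 2, DRG = -2),
                              expression_noise_sd = 0.5,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_sizes = class_sizes, pa_m = as.integer(pa_m),
              hub_boost = hub_boost, proximity_boost = proximity_boost,
              n_cell_lines = as.integer(n_cell_lines),
              dependency_effects = dependency_effects,
              dependency_sd = dependency_sd, missing_rate = missing_rate,
              n_pairs = as.integer(n_pairs),
              expression_lfc = expression_lfc,
              expression_noise_sd = expression_noise_sd,
              seed = as.integer(seed))
  if (!all(gene_classes() %in% names(cfg$class_sizes)))
    stop("class_sizes must name every class: ",
         paste(gene_classes(), collapse = ", "))
  if (sum(cfg$class_sizes) > cfg$n_genes)
    stop("class sizes sum (", sum(cfg$class_sizes),
         ") exceeds n_genes (", cfg$n_genes, ")")
  if (!all(is.finite(unlist(cfg$dependency_effects))))
    stop("dependency effects must be finite")
  structure(cfg, class = "simulation_config")
}

#' Null configuration: same shape, no planted structure
#'
#' All boosts, dependency effects and planted fold changes zeroed;
#' used for calibration runs.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_simulation_config <- function(...) {
  simulation_config(hub_boost = c(DTG = 0L, DAG = 0L),
                    proximity_boost = 0,
                    dependency_effects = c(DTG = 0, DAG = 0, PFG = 0,
                                           PUG = 0, URG = 0, DRG = 0),
                    expression_lfc = c(URG = 0, DRG = 0),
                    ...)
}

#' Run the generator
#'
#' @param config A [simulation_config()].
#' @return List with `net` (igraph), `catalog` (`gene_catalog`), `dep`
#'   (dependency matrix), `expr` (`paired_expression`), `truth`
#'   (planted class assignment, effects and seed), `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))

  ## network: preferential attachment + class-conditional wiring
  g <- igraph::sample_pa(n, m = config$pa_m, directed = FALSE)
  igraph::V(g)$name <- genes

  perm <- sample(genes)
  classes <- list(); offset <- 0L
  for (lab in gene_classes()) {
    sz <- config$class_sizes[[lab]]
    classes[[lab]] <- sort(perm[seq_len(sz) + offset])
    offset <- offset + sz
  }

  deg <- igraph::degree(g)
  extra <- list()
  for (lab in names(config$hub_boost)) {
    b <- config$hub_boost[[lab]]
    if (b <= 0) next
    for (v in classes[[lab]]) {
      pool <- setdiff(genes, v)
      tgt <- sample(pool, b, prob = deg[pool] + 1)
      extra[[length(extra) + 1L]] <- cbind(v, tgt)
    }
  }
  if (config$proximity_boost > 0 && length(classes$DTG)) {
    for (lab in c("DAG", "PUG", "URG")) {
      hit <- classes[[lab]][stats::runif(length(classes[[lab]])) <
                              config$proximity_boost]
      if (length(hit))
        extra[[length(extra) + 1L]] <-
          cbind(hit, sample(classes$DTG, length(hit), replace = TRUE))
    }
  }
  if (length(extra)) {
    el <- do.call(rbind, extra)
    g <- igraph::add_edges(g, as.vector(t(el)))
  }
  g <- igraph::simplify(g)

  catalog <- do.call(gene_catalog, classes)

  ## dependency matrix
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  mu <- stats::setNames(numeric(n), genes)
  for (lab in gene_classes())
    mu[classes[[lab]]] <- config$dependency_effects[[lab]]
  dep <- matrix(stats::rnorm(n * length(lines), mean = mu,
                             sd = config$dependency_sd),
                nrow = n, dimnames = list(genes, lines))
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dep)) < config$missing_rate
    dep[miss] <- NA_real_
  }

  ## paired expression (log-normal with planted shifts)
  base <- stats::rnorm(n, mean = 6, sd = 1.5)
  lfc <- stats::setNames(numeric(n), genes)
  lfc[classes$URG] <- config$expression_lfc[["URG"]]
  lfc[classes$DRG] <- config$expression_lfc[["DRG"]]
  noise <- function() matrix(stats::rnorm(n * config$n_pairs,
                                          sd = config$expression_noise_sd),
                             nrow = n)
  normal <- 2^(base + noise())
  tumor <- 2^(base + lfc + noise())
  dimnames(tumor) <- dimnames(normal) <-
    list(genes, sprintf("P%02d", seq_len(config$n_pairs)))
  expr <- paired_expression(tumor, normal)

  list(net = g, catalog = catalog, dep = dep, expr = expr,
       truth = list(classes = classes,
                    dependency_effects = config$dependency_effects,
                    expression_lfc = config$expression_lfc,
                    seed = config$seed),
       config = config)
}

#' Write a simulated study to disk in the loaders' file dialects
#'
#' Produces `network.tsv` (edge list), one `<CLASS>.txt` gene list per
#' class, `dependency.csv` (gene-row dialect), `expression.tsv` with
#' `pairs.tsv` manifest, and `truth.json`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- igraph::as_edgelist(sim$net)
  utils::write.table(el[order(el[, 1], el[, 2]), ],
                     file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (lab in gene_classes())
    writeLines(sim$catalog$members[[lab]], file.path(dir, paste0(lab, ".txt")))
  dep_df <- data.frame(gene = rownames(sim$dep), sim$dep,
                       check.names = FALSE)
  utils::write.csv(dep_df, file.path(dir, "dependency.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  tum <- sim$expr$tumor; nor <- sim$expr$normal
  colnames(tum) <- paste0(sim$expr$pairs, "_T")
  colnames(nor) <- paste0(sim$expr$pairs, "_N")
  expr_df <- data.frame(gene = sim$expr$genes, tum, nor, check.names = FALSE)
  utils::write.table(expr_df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(pair_id = sim$expr$pairs,
                                tumor_column = colnames(tum),
                                normal_column = colnames(nor)),
                     file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Frozen benchmark fixtures
#'
#' `small` — 200 genes, 14 cell lines, 10 expression pairs (seed 101):
#' fast smoke fixture. `medium` — the default 2,000-gene configuration
#' (seed 202): the benchmark on which cross-validation and
#' direction-recovery behavior is assessed.
#'
#' @param size `"small"` or `"medium"`.
#' @param dir Optional directory to also write the files to.
#' @return The simulated study (list as in [simulate_study()]), with
#'   the written directory in `$dir` when requested.
#' @export
make_golden_fixture <- function(size = c("small", "medium"), dir = NULL) {
  size <- match.arg(size)
  cfg <- switch(size,
    small = simulation_config(
      n_genes = 200L,
      class_sizes = c(DTG = 20L, DAG = 20L, PFG = 12L, PUG = 30L,
                      URG = 40L, DRG = 15L),
      n_pairs = 10L, seed = 101L),
    medium = simulation_config(seed = 202L))
  sim <- simulate_study(cfg)
  if (!is.null(dir)) {
    write_fixture(sim, dir)
    sim$dir <- dir
  }
  sim
}
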