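## Orchestration: data loading, chain serialization, and the end-to-end
## experiment driver that reproduces the tree-recovery simulation at a
## configurable scale. The driver composes only exported operations of the
## other modules, so its tests double as an integration test of everything.

#' Load an expression matrix from delimited text
#'
#' Reads a TSV/CSV of expression values with a header of variable (gene)
#' names. The canonical orientation is samples x genes; set
#' `genes_in_rows = TRUE` for the transposed layout. Missing or non-numeric
#' cells and duplicated gene names are errors, reported with their location.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param genes_in_rows Transpose after reading.
#' @param standardize Standardize columns to mean 0, variance 1.
#' @return A numeric matrix with gene names as column names.
#' @export
load_expression_matrix <- function(path, genes_in_rows = FALSE,
                                   standardize = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  first_is_id <- ncol(df) > 1L && !is.numeric(df[[1L]])
  rn <- if (first_is_id) as.character(df[[1L]]) else NULL
  if (first_is_id) df <- df[, -1L, drop = FALSE]
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(X), nrow(X)))) &
                   !is.na(X), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1L, 1L], colnames(X)[bad[1L, 2L]]))
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop(sprintf("missing value at row %d, column '%s'",
                 bad[1L, 1L], colnames(X)[bad[1L, 2L]]))
  }
  if (!is.null(rn)) rownames(X) <- rn
  if (genes_in_rows) X <- t(X)
  if (anyDuplicated(colnames(X)))
    stop(sprintf("duplicated gene name '%s'",
                 colnames(X)[anyDuplicated(colnames(X))]))
  if (standardize) {
    cn <- colnames(X)
    X <- standardize_columns(X)
    colnames(X) <- cn
  }
  X
}

#' Write an expression matrix
#'
#' @param X Numeric matrix with column names.
#' @param path Output path (`.csv` for comma-separated, else tab).
#' @export
write_expression_matrix <- function(X, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(X, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a chain
#'
#' The thinned records go to a gzipped TSV (`records.tsv.gz`: record index,
#' edge count, hyperparameters, labeling, flattened upper-triangle edge
#' indicators) and the run metadata (prior, dimensions, seed, acceptance
#' rates) to a JSON sidecar (`meta.json`).
#'
#' @param chain An `sfggm_chain`.
#' @param dir Output directory (created if needed).
#' @export
write_chain <- function(chain, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pair_names <- sprintf("e%d_%d", chain$pairs[, 1L], chain$pairs[, 2L])
  rec <- data.frame(record = seq_len(nrow(chain$edges)),
                    n_edges = rowSums(chain$edges))
  rec <- cbind(rec, as.data.frame(chain$theta))
  if (!is.null(chain$pi)) {
    pim <- chain$pi
    colnames(pim) <- sprintf("pi%d", seq_len(chain$p))
    rec <- cbind(rec, as.data.frame(pim))
  }
  ed <- as.data.frame(chain$edges * 1L)
  colnames(ed) <- pair_names
  rec <- cbind(rec, ed)
  con <- gzfile(file.path(dir, "records.tsv.gz"), "w")
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  meta <- list(prior = chain$prior, p = chain$p, seed = chain$seed,
               iterations = chain$config$iterations,
               burn_in = chain$config$burn_in, thin = chain$config$thin,
               acceptance = as.list(round(chain$acceptance, 6L)),
               counters = as.data.frame(chain$counters))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_chain
#' @export
read_chain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rec <- utils::read.table(gzfile(file.path(dir, "records.tsv.gz")),
                           header = TRUE, sep = "\t")
  p <- meta$p
  pairs <- which(upper.tri(matrix(0L, p, p)), arr.ind = TRUE)
  dimnames(pairs) <- NULL
  pair_names <- sprintf("e%d_%d", pairs[, 1L], pairs[, 2L])
  theta_cols <- intersect(c("beta", "alpha", "K"), colnames(rec))
  pi_cols <- grep("^pi\\d+$", colnames(rec), value = TRUE)
  theta <- as.matrix(rec[, theta_cols, drop = FALSE])
  rownames(theta) <- NULL
  structure(list(edges = unname(as.matrix(rec[, pair_names, drop = FALSE]) > 0L),
                 theta = theta,
                 pi = if (length(pi_cols))
                   unname(as.matrix(rec[, pi_cols, drop = FALSE])) else NULL,
                 pairs = pairs, p = p, prior = meta$prior, seed = meta$seed,
                 config = meta, counters = NULL,
                 acceptance = unlist(meta$acceptance)),
            class = "sfggm_chain")
}

#' Experiment configuration
#'
#' Describes a tree-recovery simulation: for each topology and replicate, a
#' tree is drawn, Gaussian data generated, both structure priors fitted, the
#' marginals thresholded and scored against the truth. Per-replicate seeds
#' are derived deterministically from the master seed.
#'
#' @param topologies Character vector from `binomial`, `ba`, `sf`,
#'   `crumple`, `star`.
#' @param replicates Trees per topology.
#' @param p,n Nodes per tree and samples per dataset.
#' @param r Parent-child edge correlation of the data generator.
#' @param gamma Tail exponent for the `sf` topology.
#' @param iterations,burn_in,thin Sampler schedule shared by both priors.
#' @param threshold Edge-marginal cut point for the network estimate.
#' @param seed Master seed.
#' @param priors Which structure priors to fit.
#' @export
experiment_config <- function(topologies = c("binomial", "star"),
                              replicates = 3L, p = 30L, n = 100L, r = 0.7,
                              gamma = 2.3, iterations = 20000L,
                              burn_in = 4000L, thin = 20L, threshold = 0.5,
                              seed = 1L, priors = c("er", "sf")) {
  structure(list(topologies = topologies, replicates = as.integer(replicates),
                 p = as.integer(p), n = as.integer(n), r = r, gamma = gamma,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 threshold = threshold, seed = as.integer(seed),
                 priors = match.arg(priors, several.ok = TRUE)),
            class = "sfggm_experiment_config")
}

replicate_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

#' Run a tree-recovery experiment
#'
#' The end-to-end driver: simulate tree, simulate data, standardize, run a
#' chain per requested prior, threshold the edge marginals, and score
#' PPV/sensitivity against the true tree (plus the exponent estimate for
#' the scale-free prior). A failed replicate is recorded and excluded from
#' the aggregates rather than aborting the experiment.
#'
#' @param config From [experiment_config()].
#' @param out_dir Optional directory for TSV/JSON reports.
#' @return A list with `replicates` (one row per topology x replicate x
#'   prior), `summary` (mean and sd of PPV, sensitivity and gamma-hat per
#'   topology x prior), `failures`, and the `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  rows <- list()
  failures <- list()
  for (topo in config$topologies) {
    for (rep in seq_len(config$replicates)) {
      seed_r <- replicate_seed(config$seed,
                               match(topo, config$topologies) * 1000L + rep)
      res <- tryCatch(
        run_replicate(topo, rep, seed_r, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(topology = topo, replicate = rep,
                     message = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  reps <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(ppv, sensitivity, gamma_hat) ~ topology + prior, data = reps,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x)),
    na.action = stats::na.pass)
  out <- list(replicates = reps, summary = summary,
              failures = if (length(failures)) do.call(rbind, failures)
                         else NULL,
              config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(reps, file.path(out_dir, "replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config),
           summary = experiment_summary_list(reps)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  out
}

run_replicate <- function(topo, rep, seed_r, config) {
  set.seed(seed_r)
  tree <- simulate_tree(topo, config$p, gamma = config$gamma)
  X <- gaussian_tree_data(tree, config$n, config$r)
  out <- list()
  for (prior in config$priors) {
    cfg <- sampler_config(prior = prior, iterations = config$iterations,
                          burn_in = config$burn_in, thin = config$thin,
                          seed = replicate_seed(seed_r,
                                                match(prior, c("er", "sf"))))
    ch <- run_chain(X, cfg)
    m <- edge_marginals(ch)
    est <- threshold_network(m, config$threshold)
    perf <- ppv_sensitivity(tree, est)
    out[[prior]] <- data.frame(
      topology = topo, replicate = rep, prior = prior, seed = seed_r,
      p = config$p, n = config$n,
      n_edges_est = n_edges(est), tp = perf$counts[["TP"]],
      ppv = perf$ppv, sensitivity = perf$sensitivity,
      gamma_hat = if (prior == "sf") estimate_gamma(ch) else NA_real_)
  }
  do.call(rbind, out)
}

experiment_summary_list <- function(reps) {
  split_df <- split(reps, interaction(reps$topology, reps$prior, drop = TRUE))
  lapply(split_df, function(d) {
    list(topology = d$topology[1L], prior = d$prior[1L],
         replicates = nrow(d),
         ppv = mean(d$ppv, na.rm = TRUE),
         sensitivity = mean(d$sensitivity, na.rm = TRUE),
         gamma_hat = if (all(is.na(d$gamma_hat))) NULL
                     else mean(d$gamma_hat, na.rm = TRUE))
  })
}
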