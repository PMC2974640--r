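## Posterior summaries: edge-inclusion marginals, the thresholded network
## estimate, the power-law exponent estimate, and the PPV/sensitivity
## performance measures of the simulation study.

#' Posterior edge-inclusion marginals of a chain
#'
#' Entry (u, v) is the fraction of thinned post-burn-in records in which the
#' edge \{u, v\} is present.
#'
#' @param chain An `sfggm_chain` from [run_chain()].
#' @return A symmetric p x p matrix with zero diagonal, entries in `[0, 1]`.
#' @export
edge_marginals <- function(chain) {
  if (!inherits(chain, "sfggm_chain")) stop("'chain' must be an sfggm_chain")
  if (nrow(chain$edges) == 0L) stop("chain holds no records")
  freq <- colMeans(chain$edges)
  m <- matrix(0, chain$p, chain$p)
  m[chain$pairs] <- freq
  m + t(m)
}

#' Threshold edge marginals into a network estimate
#'
#' Returns the network of all pairs whose marginal inclusion probability
#' strictly exceeds `threshold` (default 0.5, the median-probability
#' network). The estimate need not be decomposable.
#'
#' @param m Symmetric marginal matrix (e.g. from [edge_marginals()]).
#' @param threshold Cut point in `[0, 1]`.
#' @export
threshold_network <- function(m, threshold = 0.5) {
  m <- as.matrix(m)
  if (threshold < 0 || threshold > 1) stop("'threshold' must lie in [0, 1]")
  idx <- which(m > threshold & upper.tri(m), arr.ind = TRUE)
  network(nrow(m), idx)
}

#' Tune the threshold to a requested edge count
#'
#' For real-data comparisons the cut point is chosen so that the estimate
#' has exactly `n_edges` edges: pairs are ranked by marginal probability,
#' ties broken by pair order (smaller first node, then smaller second node,
#' first), and the top `n_edges` are kept.
#'
#' @param m Symmetric marginal matrix.
#' @param n_edges Requested edge count.
#' @return A list with the `network` and the implied `threshold` (the
#'   marginal of the last edge kept; every kept pair has marginal >= it).
#' @export
tune_threshold <- function(m, n_edges) {
  m <- as.matrix(m)
  p <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[ut]
  if (n_edges < 0L || n_edges > length(vals))
    stop("'n_edges' must lie in 0..p(p-1)/2")
  if (n_edges == 0L)
    return(list(network = network(p), threshold = 1))
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(n_edges)]
  list(network = network(p, ut[keep, , drop = FALSE]),
       threshold = vals[keep[n_edges]])
}

#' Estimate the power-law exponent from a scale-free-prior chain
#'
#' The static model implies a degree-distribution exponent
#' gamma = 1 + 1/alpha. The default estimator averages the per-record
#' gamma values over the chain; `from_mean_alpha = TRUE` instead transforms
#' the posterior mean of alpha. Any recorded alpha of exactly 0 maps to an
#' infinite gamma: the value `Inf` is returned with a warning.
#'
#' @param chain An `sfggm_chain` run with the scale-free prior.
#' @param from_mean_alpha Use 1 + 1/mean(alpha) instead of
#'   mean(1 + 1/alpha).
#' @export
estimate_gamma <- function(chain, from_mean_alpha = FALSE) {
  if (!inherits(chain, "sfggm_chain")) stop("'chain' must be an sfggm_chain")
  if (chain$prior != "sf")
    stop("gamma is defined only for scale-free-prior chains")
  a <- chain$theta[, "alpha"]
  if (any(a == 0)) {
    warning("alpha = 0 recorded: gamma is infinite (Erdos-Renyi limit)")
    return(Inf)
  }
  if (from_mean_alpha) 1 + 1 / mean(a) else mean(1 + 1 / a)
}

#' Confusion counts, positive predictive value and sensitivity
#'
#' Compares an estimated network to the truth over all M = p(p-1)/2 node
#' pairs: TP counts shared edges, FP edges only in the estimate, FN edges
#' only in the truth, TN the rest. PPV = TP / (TP + FP) (NaN when the
#' estimate is empty) and sensitivity = TP / (TP + FN). Specificity is
#' deliberately not headlined — sparse truths make TN dominate and the
#' measure uninformative — but is computable from the counts.
#'
#' @param truth,estimate Networks on the same node set.
#' @return A list with `counts` (TP, FP, FN, TN), `ppv`, `sensitivity`.
#' @export
ppv_sensitivity <- function(truth, estimate) {
  stopifnot_network(truth)
  stopifnot_network(estimate)
  if (truth$p != estimate$p) stop("networks must share the same node count")
  key <- function(g) g$edges[, 1L] + truth$p * g$edges[, 2L]
  M <- max_edges(truth)
  tp <- length(intersect(key(truth), key(estimate)))
  fp <- n_edges(estimate) - tp
  fn <- n_edges(truth) - tp
  tn <- M - tp - fp - fn
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       ppv = if (tp + fp == 0L) NaN else tp / (tp + fp),
       sensitivity = if (tp + fn == 0L) NaN else tp / (tp + fn))
}

#' Write edge marginals as a TSV matrix
#'
#' @param m Marginal matrix; column names become the header.
#' @param path Output file.
#' @export
write_marginals <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
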