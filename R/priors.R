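## Structure priors: the static-model scale-free prior P_SF(G | alpha, K, pi),
## the Erdos-Renyi prior P_ER(G | beta), their uniform hyperpriors, and exact
## labeling marginalization for small p.

#' Zipf node weights of the static model
#'
#' The static model assigns label i the weight w_i proportional to i^(-alpha),
#' normalized to sum to one. alpha = 0 gives uniform weights (the
#' Erdos-Renyi limit); as alpha grows toward 1 the weight mass concentrates on
#' the low labels, which become the prospective hubs.
#'
#' @param p Number of nodes (>= 2).
#' @param alpha Zipf exponent in `[0, 1)`.
#' @return Numeric vector of length p summing to 1, non-increasing in label.
#' @export
zipf_weights <- function(p, alpha) {
  check_static_params(alpha, 1, p)
  w <- seq_len(p)^(-alpha)
  w / sum(w)
}

check_static_params <- function(alpha, K, p) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1)")
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K > k_max(p))
    stop("'K' must lie in (0, k_max(p)]")
  invisible(NULL)
}

#' Upper bound of the K domain
#'
#' K is the expected number of edge-insertion attempts of the static model.
#' Its uniform hyperprior needs a bounded domain; the bound p(p-1)/2 is the
#' point at which the expected edge count saturates the graph.
#'
#' @param p Number of nodes.
#' @export
k_max <- function(p) p * (p - 1) / 2

#' Pair-connection probability under the static model
#'
#' The probability that the nodes carrying labels i and j end up connected
#' after K weighted insertion attempts, in the large-p exponential form
#' f_ij = 1 - exp(-2 K w_i w_j). Symmetric in (i, j) and strictly increasing
#' in K.
#'
#' @param i,j Distinct labels in 1..p.
#' @param p Number of nodes.
#' @param alpha Zipf exponent in `[0, 1)`.
#' @param K Attempt intensity in `(0, k_max(p)]`.
#' @return Probability in (0, 1).
#' @export
edge_probability <- function(i, j, p, alpha, K) {
  if (any(i == j)) stop("'i' and 'j' must be distinct labels")
  w <- zipf_weights(p, alpha)
  check_static_params(alpha, K, p)
  -expm1(-2 * K * w[i] * w[j])
}

## Pairwise log f and log(1 - f) indexed by LABEL (not node): entry (k, l)
## refers to the pair of nodes carrying labels k and l, so the matrices
## depend on theta only and survive any relabeling untouched; node pairs are
## looked up through pi. log(1 - f) = -2 K w_k w_l exactly, and
## log f = log(-expm1(.)) keeps precision for tiny probabilities. `base` is
## the empty-network total (the sum of log(1 - f) over all pairs), which is
## labeling-invariant.
sf_pair_logs <- function(p, alpha, K) {
  w <- zipf_weights(p, alpha)
  e <- -2 * K * tcrossprod(w)
  list(logf = log(-expm1(e)), log1mf = e, base = sum_upper(e))
}

sum_upper <- function(M) sum(M[upper.tri(M)])

log_prior_from_pair_logs <- function(pl, edges, pi) {
  tot <- pl$base
  if (nrow(edges)) {
    li <- cbind(pi[edges[, 1L]], pi[edges[, 2L]])
    tot <- tot + sum(pl$logf[li]) - sum(pl$log1mf[li])
  }
  tot
}

#' Log prior probability of a network under the scale-free (static) prior
#'
#' The static model connects pairs independently, so the log probability of a
#' network is the sum of log f over its edges plus the sum of log(1 - f) over
#' its non-edges, with f evaluated at the labels `pi` assigns to the
#' endpoints.
#'
#' @param g A network.
#' @param alpha,K Static-model hyperparameters.
#' @param pi Node labeling (permutation of 1..p); defaults to the identity.
#' @return Log probability (finite for all legal hyperparameters).
#' @export
log_prior_sf <- function(g, alpha, K, pi = identity_labeling(g$p)) {
  stopifnot_network(g)
  pi <- check_labeling(pi)
  if (length(pi) != g$p) stop("'pi' length must equal g$p")
  check_static_params(alpha, K, g$p)
  log_prior_from_pair_logs(sf_pair_logs(g$p, alpha, K), g$edges, pi)
}

#' Log prior probability under the Erdos-Renyi (random) prior
#'
#' Each of the M = p(p-1)/2 pairs is an edge independently with probability
#' beta, giving |E| log beta + (M - |E|) log(1 - beta). beta = 1/2 makes the
#' prior uniform over all networks.
#'
#' @param g A network.
#' @param beta Edge-inclusion probability in (0, 1).
#' @export
log_prior_er <- function(g, beta) {
  stopifnot_network(g)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta >= 1)
    stop("'beta' must lie in (0, 1)")
  e <- n_edges(g)
  e * log(beta) + (max_edges(g) - e) * log1p(-beta)
}

#' Log hyperprior density (uniform over each domain)
#'
#' All hyperpriors are flat: the log density is 0 (up to normalization)
#' inside the domain and -Inf outside. Domains: beta in (0, 1); alpha in
#' `[0, 1)`; K in `(0, k_max(p)]`.
#'
#' @param theta Hyperparameter value(s): `beta` for `kind = "er"`, a vector
#'   `c(alpha, K)` for `kind = "sf"`.
#' @param kind `"er"` or `"sf"`.
#' @param p Number of nodes (needed for the K domain).
#' @export
log_hyperprior <- function(theta, kind = c("er", "sf"), p) {
  kind <- match.arg(kind)
  if (kind == "er") {
    beta <- theta[[1L]]
    if (beta > 0 && beta < 1) 0 else -Inf
  } else {
    alpha <- theta[[1L]]; K <- theta[[2L]]
    if (alpha >= 0 && alpha < 1 && K > 0 && K <= k_max(p)) 0 else -Inf
  }
}

## All permutations of 1..n as an n! x n matrix, in lexicographic order.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Labeling-marginalized scale-free log prior (small p)
#'
#' Averages the static-model network probability over all p! labelings with
#' uniform weight, computed by exhaustive enumeration with log-sum-exp
#' stability. Guarded at p <= 9 where the enumeration is feasible.
#'
#' @inheritParams log_prior_sf
#' @export
log_prior_sf_marginal_pi <- function(g, alpha, K) {
  stopifnot_network(g)
  if (g$p > 9L) stop("exhaustive labeling marginalization requires p <= 9")
  perms <- permutations(g$p)
  lp <- apply(perms, 1L, function(pi) log_prior_sf(g, alpha, K, pi))
  log_mean_exp(lp)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))
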