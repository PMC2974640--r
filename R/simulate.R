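## Synthetic truth generation: labeled trees with prescribed
## degree-distribution ensembles and Gaussian data Markov with respect to a
## tree. These generators define the stated world of the simulation study:
## trees span a spectrum from binomial (uniform random labeled trees) through
## scale-free and crumple ensembles to the star.

tree_instance <- function(g, root = 1L) {
  stopifnot_network(g)
  if (nrow(g$edges) != g$p - 1L) stop("a tree on p nodes has p - 1 edges")
  par <- parent_map(g, root)
  if (anyNA(par[-root])) stop("network is not connected; not a tree")
  structure(list(p = g$p, edges = g$edges, root = as.integer(root),
                 parent = par),
            class = c("sfggm_tree", "sfggm_network"))
}

## Parents from orienting edges away from the root, plus the BFS visit order
## (parents always precede children).
parent_map <- function(g, root = 1L) {
  p <- g$p
  nbrs <- vector("list", p)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1L]; b <- g$edges[r, 2L]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  par <- rep(NA_integer_, p)
  seen <- logical(p)
  seen[root] <- TRUE
  queue <- as.integer(root)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    for (u in nbrs[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        par[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  attr(par, "bfs_order") <- order
  par
}

#' @export
print.sfggm_tree <- function(x, ...) {
  cat(sprintf("<sfggm_tree> p = %d, root = %d, max degree = %d\n",
              x$p, x$root, max(degree_sequence(x))))
  invisible(x)
}

## Linear-time Pruefer decode: consumed leaves get degree 0 so the two
## surviving degree-1 nodes form the last edge.
prufer_decode <- function(seq, p) {
  deg <- rep(1L, p)
  for (s in seq) deg[s] <- deg[s] + 1L
  edges <- matrix(0L, p - 1L, 2L)
  ptr <- 1L
  leaf <- -1L
  for (k in seq_along(seq)) {
    if (leaf < 0L) {
      while (deg[ptr] != 1L) ptr <- ptr + 1L
      leaf <- ptr
    }
    v <- seq[k]
    edges[k, ] <- c(leaf, v)
    deg[leaf] <- 0L
    deg[v] <- deg[v] - 1L
    if (deg[v] == 1L && v < ptr) {
      leaf <- v
    } else {
      ptr <- ptr + 1L
      leaf <- -1L
    }
  }
  edges[p - 1L, ] <- which(deg == 1L)
  edges
}

#' Random labeled trees
#'
#' `uniform_tree()` draws a tree uniformly from the p^(p-2) labeled trees on
#' p nodes by decoding a random Pruefer sequence; node degrees are then
#' 1 + Binomial(p - 2, 1/p), the "binomial" ensemble of the simulation
#' spectrum. `ba_tree()` grows a preferential-attachment tree: nodes arrive
#' one at a time and attach a single edge to an existing node with
#' probability proportional to its degree (the seed node counts as degree 1),
#' giving a power-law degree ensemble with exponent 3. `star_tree()` is the
#' deterministic extreme: node 1 joined to all others.
#'
#' @param p Number of nodes (>= 2).
#' @return A tree object (class `sfggm_tree`, also a valid network).
#' @export
uniform_tree <- function(p) {
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be at least 2")
  if (p == 2L) return(tree_instance(network(2L, matrix(c(1L, 2L), 1L))))
  seq <- sample.int(p, p - 2L, replace = TRUE)
  tree_instance(network(p, prufer_decode(seq, p)))
}

#' @rdname uniform_tree
#' @export
ba_tree <- function(p) {
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be at least 2")
  deg <- rep(0L, p)       # the seed node's notional degree 1 only steers the
  edges <- matrix(0L, p - 1L, 2L)   # first (deterministic) attachment
  for (t in 2:p) {
    tgt <- if (t == 2L) 1L
           else sample.int(t - 1L, 1L, prob = deg[seq_len(t - 1L)])
    edges[t - 1L, ] <- c(tgt, t)
    deg[tgt] <- deg[tgt] + 1L
    deg[t] <- deg[t] + 1L
  }
  tree_instance(network(p, edges))
}

#' @rdname uniform_tree
#' @export
star_tree <- function(p) {
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be at least 2")
  tree_instance(network(p, cbind(1L, 2:p)))
}

#' Degree-weight presets for the weighted tree ensemble
#'
#' Returns a vectorized function `lw(d)` with the tree ensemble defined by
#' P(T) proportional to the product over nodes of exp(lw(degree)).
#'
#' * `uniform`: lw = 0, the uniform labeled-tree law (identical to
#'   [uniform_tree()]'s ensemble).
#' * `scale_free`: lw(d) = log Gamma(d) - gamma log d. Because the number of
#'   labeled trees with a given degree sequence carries a factor
#'   1 / prod((d_v - 1)!), this weight makes the degree-sequence law
#'   proportional to prod(d_v^-gamma): a power-law ensemble with tail
#'   exponent gamma.
#' * `crumple`: the same family in its condensed phase (gamma = 3). Under
#'   the fixed total degree of a tree, the d^-gamma weight family condenses
#'   once gamma exceeds the point (about 2.48) where the unconstrained mean
#'   degree zeta(gamma - 1)/zeta(gamma) drops below 2: the surplus degree
#'   collects on a single macroscopic hub over a power-law bulk, a topology
#'   intermediate between scale-free and star. Operationally defined; see
#'   the methods vignette.
#'
#' @param kind Preset name.
#' @param gamma Target tail exponent (scale_free); ignored otherwise.
#' @export
tree_log_weight <- function(kind = c("scale_free", "uniform", "crumple"),
                            gamma = 2.5) {
  kind <- match.arg(kind)
  if (kind == "uniform") return(function(d) rep(0, length(d)))
  if (kind == "crumple") gamma <- 3
  force(gamma)
  function(d) lgamma(d) - gamma * log(d)
}

#' Metropolis sampler for trees with prescribed degree weights
#'
#' Runs a Metropolis chain on labeled trees with stationary law
#' P(T) proportional to prod_v w(deg(v)). The move detaches a uniformly
#' chosen leaf and reattaches it to a uniformly chosen other node; the
#' acceptance ratio combines the degree-weight change at the two affected
#' interior nodes with the Hastings correction for the changing leaf count.
#' The move set is ergodic on labeled trees (any tree can be crumpled to the
#' star and unfolded again one leaf at a time).
#'
#' @param p Number of nodes (>= 2).
#' @param log_weight Vectorized function of degree returning log w(d), e.g.
#'   from [tree_log_weight()]. Must be finite for degrees 1..p-1.
#' @param steps Number of Metropolis steps; the default 200 p comfortably
#'   exceeds the 10 p minimum burn-in.
#' @param init Optional starting tree; defaults to a uniform random tree.
#' @return The tree after `steps` moves (class `sfggm_tree`).
#' @export
weighted_tree_mcmc <- function(p, log_weight = tree_log_weight("scale_free", 2.5),
                               steps = 200L * p, init = NULL) {
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be at least 2")
  if (any(!is.finite(log_weight(seq_len(max(p - 1L, 1L))))))
    stop("'log_weight' must be finite for all attainable degrees")
  tr <- if (is.null(init)) uniform_tree(p) else tree_instance(init)
  if (p == 2L) return(tr)
  adj <- vector("list", p)
  for (r in seq_len(nrow(tr$edges))) {
    a <- tr$edges[r, 1L]; b <- tr$edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  n_leaf <- sum(deg == 1L)
  lw <- function(d) log_weight(d)
  for (s in seq_len(steps)) {
    repeat {
      v <- sample.int(p, 1L)
      if (deg[v] == 1L) break
    }
    u <- sample.int(p - 1L, 1L)
    if (u >= v) u <- u + 1L
    q <- adj[[v]][1L]
    if (u == q) next             # identical tree: accepted, nothing changes
    n_leaf2 <- n_leaf + (deg[q] == 2L) - (deg[u] == 1L)
    logr <- lw(deg[q] - 1L) - lw(deg[q]) + lw(deg[u] + 1L) - lw(deg[u]) +
      log(n_leaf) - log(n_leaf2)
    if (log(stats::runif(1L)) < logr) {
      adj[[q]] <- adj[[q]][adj[[q]] != v]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- u
      deg[q] <- deg[q] - 1L
      deg[u] <- deg[u] + 1L
      n_leaf <- n_leaf2
    }
  }
  edges <- do.call(rbind, lapply(seq_len(p), function(v) {
    w <- adj[[v]][adj[[v]] > v]
    if (length(w)) cbind(v, w) else NULL
  }))
  tree_instance(network(p, edges))
}

#' Gaussian data Markov with respect to a tree
#'
#' Simulates n samples of p variables whose conditional-independence
#' structure is exactly the tree: the root variable is standard normal and
#' each child is r times its parent plus sqrt(1 - r^2) fresh noise, so every
#' variable has unit population variance, the correlation along each edge is
#' r, and the correlation between nodes at tree distance d is r^d.
#'
#' @param tree A tree from one of the tree generators.
#' @param n Number of samples.
#' @param r Parent-child correlation, |r| < 1. Default 0.7.
#' @return An n x p numeric matrix with columns named `V1..Vp`.
#' @export
gaussian_tree_data <- function(tree, n, r = 0.7) {
  if (!inherits(tree, "sfggm_tree")) tree <- tree_instance(tree)
  if (abs(r) >= 1) stop("'r' must satisfy |r| < 1")
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  p <- tree$p
  ord <- attr(tree$parent, "bfs_order")
  X <- matrix(0, n, p)
  X[, tree$root] <- stats::rnorm(n)
  s <- sqrt(1 - r^2)
  for (v in ord[-1L]) {
    X[, v] <- r * X[, tree$parent[v]] + s * stats::rnorm(n)
  }
  colnames(X) <- paste0("V", seq_len(p))
  X
}

#' Simulate a tree of a named topology
#'
#' Convenience dispatcher used by the experiment driver and the CLI:
#' `"binomial"` is the uniform labeled tree, `"ba"` the
#' preferential-attachment tree, `"sf"` the weighted ensemble with tail
#' exponent `gamma`, `"crumple"` the condensed-phase preset, and `"star"`
#' the star.
#'
#' @param kind Topology name.
#' @param p Number of nodes.
#' @param gamma Tail exponent for `kind = "sf"`.
#' @param steps Metropolis steps for the weighted ensembles.
#' @export
simulate_tree <- function(kind = c("binomial", "ba", "sf", "crumple", "star"),
                          p, gamma = 2.5, steps = 200L * p) {
  kind <- match.arg(kind)
  switch(kind,
         binomial = uniform_tree(p),
         ba = ba_tree(p),
         sf = weighted_tree_mcmc(p, tree_log_weight("scale_free", gamma), steps),
         # condensed phase: start at the star (inside the phase) so the slow
         # hub nucleation is a relaxation, not a barrier crossing
         crumple = weighted_tree_mcmc(p, tree_log_weight("crumple"), steps,
                                      init = star_tree(p)),
         star = star_tree(p))
}

#' Tail-exponent fit for an empirical degree distribution
#'
#' Estimates the power-law exponent of pooled degree counts by Poisson
#' regression of the counts on log(d) with an additional linear term in d.
#' The linear term absorbs the exponential cutoff that the fixed mean degree
#' of a finite tree ensemble imposes on an otherwise d^-gamma law; without it
#' the plain log-log slope is biased steep. Degrees below `d_min` are
#' excluded (the head of the distribution is not power-law).
#'
#' @param degrees Integer vector of pooled node degrees.
#' @param d_min Smallest degree entering the fit (default 2).
#' @return The fitted exponent (positive for a decaying tail).
#' @export
fit_degree_exponent <- function(degrees, d_min = 2L) {
  tab <- table(degrees)
  d <- as.integer(names(tab))
  cnt <- as.integer(tab)
  keep <- d >= d_min
  if (sum(keep) < 3L) stop("too few distinct degrees to fit a tail exponent")
  d <- d[keep]; cnt <- cnt[keep]
  fit <- stats::glm(cnt ~ log(d) + d, family = stats::poisson())
  -unname(stats::coef(fit)[["log(d)"]])
}
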