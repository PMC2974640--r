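## Metropolis-Hastings sampler on the joint state (G, theta, pi):
## G a decomposable network, theta the structure-prior hyperparameters
## (beta for the random prior; alpha, K for the scale-free prior), pi the
## node labeling. The target is
##   p(G, theta, pi | X) propto p(X | G) P(G | theta, pi) q(theta) / p!
## with flat hyperpriors q and a uniform labeling weight. Three kernels are
## swept in turn every iteration: one single-edge move, one uniform-window
## update per hyperparameter component, and one adjacent-label swap
## (scale-free prior only; the random prior is labeling-free).

#' Sampler configuration
#'
#' Defaults follow the package's standard workflow shape: 110,000 iterations
#' with a 10,000-iteration burn-in, thinning every 100, uniform-window step
#' size 0.05 for alpha and beta and 0.05 k_max(p) for K, the empty network
#' and identity labeling as the initial state.
#'
#' @param prior `"er"` (random structure prior) or `"sf"` (scale-free).
#' @param iterations Total MH sweeps.
#' @param burn_in Sweeps discarded before recording; must be < iterations.
#' @param thin Record every `thin`-th sweep after burn-in.
#' @param xi Named step sizes: `c(beta = .)` or `c(alpha = ., K = .)`;
#'   `NULL` for the defaults (K's default depends on p, so it is resolved
#'   when the chain starts).
#' @param hiw Hyper-inverse Wishart parameters from [hiw_params()].
#' @param seed Integer RNG seed recorded in the chain; `NULL` leaves the RNG
#'   state alone.
#' @param init_graph Initial network (default: empty).
#' @param init_pi Initial labeling (default: identity).
#' @param theta0 Initial hyperparameters; `NULL` for `beta = 0.5` or
#'   `alpha = 0.5, K = p - 1` (a tree's edge count, the sparsity regime the
#'   simulations inhabit).
#' @param scan `"systematic"` sweeps the kernels in order; `"random"` picks
#'   one kernel per iteration uniformly.
#' @param label_moves Adjacent-swap proposals per sweep (scale-free prior);
#'   default `NULL` resolves to p - 1. A single adjacent swap per sweep
#'   leaves the labeling mixing by an O(p^2) random walk, which starves the
#'   alpha posterior on anything but toy problems.
#' @param standardize Standardize columns of the data before analysis
#'   (default `TRUE`; the unit-mode prior scale assumes it).
#' @param verbose Log acceptance rates every 1000 iterations.
#' @return A list of class `sfggm_config`.
#' @export
sampler_config <- function(prior = c("er", "sf"), iterations = 110000L,
                           burn_in = 10000L, thin = 100L, xi = NULL,
                           hiw = hiw_params(), seed = NULL,
                           init_graph = NULL, init_pi = NULL, theta0 = NULL,
                           scan = c("systematic", "random"),
                           standardize = TRUE, verbose = FALSE,
                           label_moves = NULL) {
  prior <- match.arg(prior)
  scan <- match.arg(scan)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0L || burn_in >= iterations)
    stop("'burn_in' must satisfy 0 <= burn_in < iterations")
  if (thin < 1L) stop("'thin' must be at least 1")
  if ((iterations - burn_in) %/% thin < 1L)
    stop("configuration yields a zero-length post-burn-in chain")
  if (!is.null(xi) && any(xi <= 0)) stop("step sizes 'xi' must be positive")
  structure(list(prior = prior, iterations = iterations, burn_in = burn_in,
                 thin = thin, xi = xi, hiw = hiw, seed = seed,
                 init_graph = init_graph, init_pi = init_pi, theta0 = theta0,
                 scan = scan, standardize = standardize, verbose = verbose,
                 label_moves = label_moves),
            class = "sfggm_config")
}

default_xi <- function(prior, p) {
  if (prior == "er") c(beta = 0.05) else c(alpha = 0.05, K = 0.05 * k_max(p))
}

default_theta0 <- function(prior, p) {
  if (prior == "er") c(beta = 0.5) else c(alpha = 0.5, K = p - 1)
}

## Structure-prior log probability of the current graph given theta, pi,
## together with whatever reusable pieces the kernels need.
prior_state <- function(st) {
  if (st$prior == "sf") {
    pl <- sf_pair_logs(st$p, st$theta[["alpha"]], st$theta[["K"]])
    st$pairG <- pl$logf - pl$log1mf
    list(pair = pl, total = prior_total_from_pairs(st, pl))
  } else {
    b <- st$theta[["beta"]]
    list(pair = NULL, total = st$e * log(b) + (st$M - st$e) * log1p(-b))
  }
}

## Structure-prior total for the current graph: the labeling-invariant
## empty-network base plus per-edge corrections looked up by label.
prior_total_from_pairs <- function(st, pl) {
  tot <- pl$base
  if (st$e > 0L) {
    idx <- which(st$A & upper.tri(st$A), arr.ind = TRUE)
    li <- cbind(st$pi[idx[, 1L]], st$pi[idx[, 2L]])
    tot <- tot + sum(pl$logf[li]) - sum(pl$log1mf[li])
  }
  tot
}

#' Initialize a sampler state
#'
#' Builds the mutable state the kernels operate on: the adjacency matrix,
#' clique decomposition and cached log marginal likelihood of the initial
#' network, the structure-prior bookkeeping, the labeling, and per-kernel
#' proposal/acceptance counters.
#'
#' @param X Data matrix (samples x variables).
#' @param config From [sampler_config()].
#' @return An environment of class `sfggm_state`.
#' @export
sampler_state <- function(X, config) {
  X <- as.matrix(X)
  if (config$standardize) X <- standardize_columns(X)
  p <- ncol(X)
  if (p < 2L) stop("need at least two variables")
  st <- new.env(parent = emptyenv())
  st$prior <- config$prior
  st$p <- p
  st$n <- nrow(X)
  st$M <- as.integer(p * (p - 1L) / 2L)
  st$S <- crossprod(X)
  st$hiw <- config$hiw
  st$kmax <- k_max(p)
  st$cache <- likelihood_cache()
  g0 <- if (is.null(config$init_graph)) network(p) else config$init_graph
  if (g0$p != p) stop("initial graph has the wrong number of nodes")
  st$A <- adjacency_matrix(g0)
  ord <- mcs_order(st$A)
  if (!chordal_given_order(st$A, ord))
    stop("initial graph must be decomposable")
  st$e <- n_edges(g0)
  st$decomp <- clique_decomposition_adj(st$A, ord)
  st$loglik <- log_marginal_decomposition(st$S, st$n, st$decomp, st$hiw,
                                          st$cache)
  st$pi <- if (is.null(config$init_pi)) identity_labeling(p)
           else check_labeling(config$init_pi)
  st$theta <- if (is.null(config$theta0)) default_theta0(config$prior, p)
              else config$theta0
  if (!is.finite(log_hyperprior(st$theta, config$prior, p)))
    stop("initial hyperparameters lie outside their domain")
  st$xi <- if (is.null(config$xi)) default_xi(config$prior, p) else config$xi
  st$label_moves <- if (is.null(config$label_moves)) p - 1L
                    else as.integer(config$label_moves)
  st$inv <- order(st$pi)              # inv[k] = node carrying label k
  st$nb <- apply(st$A, 1L, which, simplify = FALSE)   # adjacency lists
  pr <- prior_state(st)
  st$pair <- pr$pair
  st$logprior <- pr$total
  st$counters <- matrix(0L, 3L, 3L,
                        dimnames = list(c("edge", "theta", "label"),
                                        c("proposed", "accepted", "outright")))
  class(st) <- "sfggm_state"
  st
}

upper_index <- function(p, i, j) {
  a <- min(i, j); b <- max(i, j)
  (b - 1L) * (b - 2L) / 2L + a      # column-major upper-triangle rank
}

## ---- kernels --------------------------------------------------------------

#' Single-edge proposal
#'
#' A coin flip picks add versus delete; the edge is then drawn uniformly
#' from the non-edges (add) or the edges (delete). Boundary draws (delete on
#' the empty network, add on the complete one) and moves that leave the
#' decomposable class are immediate rejections, counted against the edge
#' kernel. The log Hastings ratio accounts for the changing candidate
#' counts: add has q-ratio (M - e) / (e + 1), delete e / (M - e + 1).
#'
#' @param state A `sfggm_state`.
#' @return A list with `ok` (logical: a decomposable candidate was drawn),
#'   and when `ok`: `move`, `edge`, `log_q_ratio`, the candidate adjacency
#'   matrix `A2` and its decomposition.
#' @export
propose_edge_move <- function(state) {
  st <- state
  add <- stats::runif(1L) < 0.5
  ut <- upper.tri(st$A)
  if (add) {
    cand <- which(!st$A & ut)
    if (!length(cand)) return(list(ok = FALSE))
    logq <- log(st$M - st$e) - log(st$e + 1)
  } else {
    cand <- which(st$A & ut)
    if (!length(cand)) return(list(ok = FALSE))
    logq <- log(st$e) - log(st$M - st$e + 1)
  }
  idx <- cand[sample.int(length(cand), 1L)]
  ij <- arrayInd(idx, dim(st$A))
  i <- ij[1L]; j <- ij[2L]
  A2 <- st$A
  A2[i, j] <- A2[j, i] <- add
  ord2 <- mcs_order(A2)
  if (!chordal_given_order(A2, ord2)) return(list(ok = FALSE))
  list(ok = TRUE, move = if (add) "add" else "delete", edge = c(i, j),
       log_q_ratio = logq, A2 = A2,
       decomp2 = clique_decomposition_adj(A2, ord2))
}

#' Uniform-window hyperparameter proposal
#'
#' Each component gets an independent uniform perturbation on
#' `[value - xi, value + xi]`; the proposal is symmetric so no Hastings
#' correction is needed. Domain violations are handled by the caller as
#' immediate rejections.
#'
#' @param theta Named numeric vector of hyperparameters.
#' @param xi Step size(s), recycled against `theta`.
#' @export
propose_theta <- function(theta, xi) {
  theta + stats::runif(length(theta), -xi, xi)
}

#' Adjacent-label swap proposal
#'
#' Draws k uniformly from 1..p-1 and exchanges the labels k and k+1 between
#' the two nodes carrying them; the proposal is symmetric and leaves the
#' graph and likelihood untouched, so only the structure-prior ratio enters
#' the acceptance probability.
#'
#' @param pi A node labeling.
#' @return A list with the candidate labeling `pi`, the swapped label `k`.
#' @export
propose_label_swap <- function(pi) {
  p <- length(pi)
  k <- sample.int(p - 1L, 1L)
  list(pi = swap_adjacent_labels(pi, k), k = k)
}

kernel_edge <- function(st) {
  st$counters["edge", "proposed"] <- st$counters["edge", "proposed"] + 1L
  prop <- propose_edge_move(st)
  if (!prop$ok) {
    st$counters["edge", "outright"] <- st$counters["edge", "outright"] + 1L
    return(invisible(st))
  }
  loglik2 <- log_marginal_decomposition(st$S, st$n, prop$decomp2, st$hiw,
                                        st$cache)
  sgn <- if (prop$move == "add") 1 else -1
  dprior <- if (st$prior == "sf") {
    li <- st$pi[prop$edge[1L]]; lj <- st$pi[prop$edge[2L]]
    sgn * (st$pair$logf[li, lj] - st$pair$log1mf[li, lj])
  } else {
    b <- st$theta[["beta"]]
    sgn * (log(b) - log1p(-b))
  }
  if (log(stats::runif(1L)) < loglik2 - st$loglik + dprior + prop$log_q_ratio) {
    st$counters["edge", "accepted"] <- st$counters["edge", "accepted"] + 1L
    st$A <- prop$A2
    st$e <- st$e + if (prop$move == "add") 1L else -1L
    st$decomp <- prop$decomp2
    st$loglik <- loglik2
    st$logprior <- st$logprior + dprior
    i <- prop$edge[1L]; j <- prop$edge[2L]
    if (prop$move == "add") {
      st$nb[[i]] <- c(st$nb[[i]], j)
      st$nb[[j]] <- c(st$nb[[j]], i)
    } else {
      st$nb[[i]] <- st$nb[[i]][st$nb[[i]] != j]
      st$nb[[j]] <- st$nb[[j]][st$nb[[j]] != i]
    }
  }
  invisible(st)
}

kernel_theta <- function(st) {
  for (comp in names(st$theta)) {
    st$counters["theta", "proposed"] <- st$counters["theta", "proposed"] + 1L
    theta2 <- st$theta
    theta2[comp] <- propose_theta(st$theta[[comp]], st$xi[[comp]])
    if (!is.finite(log_hyperprior(theta2, st$prior, st$p))) {
      st$counters["theta", "outright"] <- st$counters["theta", "outright"] + 1L
      next
    }
    if (st$prior == "sf") {
      pl2 <- sf_pair_logs(st$p, theta2[["alpha"]], theta2[["K"]])
      total2 <- prior_total_from_pairs(st, pl2)
    } else {
      b <- theta2[["beta"]]
      total2 <- st$e * log(b) + (st$M - st$e) * log1p(-b)
    }
    if (log(stats::runif(1L)) < total2 - st$logprior) {
      st$counters["theta", "accepted"] <- st$counters["theta", "accepted"] + 1L
      st$theta <- theta2
      st$logprior <- total2
      if (st$prior == "sf") {
        st$pair <- pl2
        st$pairG <- pl2$logf - pl2$log1mf
      }
    }
  }
  invisible(st)
}

## A label swap exchanges the Zipf weights of the two nodes carrying labels
## k and k + 1. With label-indexed pair logs nothing needs recomputation:
## pairs where both nodes relate identically to a and b cancel from the
## ratio, so only neighbours of exactly one of the two nodes contribute -
## O(deg a + deg b) work per proposal. Because adjacent swaps mix the
## labeling by a slow random walk, the sweep makes `label_moves` proposals
## (default p - 1).
kernel_label <- function(st) {
  if (st$prior != "sf") return(invisible(st))
  p <- st$p
  ks <- sample.int(p - 1L, st$label_moves, replace = TRUE)
  us <- stats::runif(st$label_moves)
  G <- st$pairG                 # logf - log1mf, label-indexed
  nbl <- st$nb
  pi <- st$pi
  inv <- st$inv
  acc <- 0L
  dtot <- 0
  for (rep in seq_along(ks)) {
    k <- ks[rep]
    a <- inv[k]
    b <- inv[k + 1L]
    d <- 0
    na <- nbl[[a]]
    if (length(na)) {
      lx <- pi[na]
      lx <- lx[lx != k + 1L]            # skip the (a, b) pair itself
      if (length(lx))
        d <- d + sum(G[k + 1L + (lx - 1L) * p] - G[k + (lx - 1L) * p])
    }
    nb2 <- nbl[[b]]
    if (length(nb2)) {
      lx <- pi[nb2]
      lx <- lx[lx != k]
      if (length(lx))
        d <- d - sum(G[k + 1L + (lx - 1L) * p] - G[k + (lx - 1L) * p])
    }
    if (d >= 0 || us[rep] < exp(d)) {
      acc <- acc + 1L
      pi[a] <- k + 1L
      pi[b] <- k
      inv[k] <- b
      inv[k + 1L] <- a
      dtot <- dtot + d
    }
  }
  st$pi <- pi
  st$inv <- inv
  st$logprior <- st$logprior + dtot
  st$counters["label", "proposed"] <- st$counters["label", "proposed"] +
    length(ks)
  st$counters["label", "accepted"] <- st$counters["label", "accepted"] + acc
  invisible(st)
}

#' Advance the sampler by one sweep
#'
#' A systematic sweep applies the edge kernel, one update per hyperparameter
#' component, and (scale-free prior) one label swap; a random scan applies a
#' single uniformly chosen kernel. Each kernel accepts with probability
#' min(1, posterior ratio x proposal ratio).
#'
#' @param state A `sfggm_state` from [sampler_state()].
#' @param scan `"systematic"` or `"random"`.
#' @return The state, invisibly (modified in place).
#' @export
mh_step <- function(state, scan = "systematic") {
  if (scan == "random") {
    k <- sample.int(3L, 1L)
    switch(k, kernel_edge(state), kernel_theta(state), kernel_label(state))
  } else {
    kernel_edge(state)
    kernel_theta(state)
    kernel_label(state)
  }
  invisible(state)
}

## ---- the chain ------------------------------------------------------------

#' Run the Metropolis-Hastings chain
#'
#' Runs `config$iterations` sweeps from the configured initial state,
#' recording the thinned post-burn-in states: the edge indicator vector
#' (upper-triangle order), the hyperparameters, and (scale-free prior) the
#' labeling. Fully reproducible given `config$seed`.
#'
#' @param X Data matrix, samples x variables.
#' @param config From [sampler_config()].
#' @return An object of class `sfggm_chain` with fields `edges` (records x M
#'   logical matrix), `theta`, `pi`, `pairs` (M x 2 node pairs matching the
#'   columns of `edges`), per-kernel `acceptance` counters, and the `config`.
#' @export
run_chain <- function(X, config) {
  if (!inherits(config, "sfggm_config")) stop("'config' must be a sampler_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- sampler_state(X, config)
  n_rec <- (config$iterations - config$burn_in) %/% config$thin
  ut_idx <- which(upper.tri(st$A))
  E <- matrix(FALSE, n_rec, st$M)
  TH <- matrix(NA_real_, n_rec, length(st$theta),
               dimnames = list(NULL, names(st$theta)))
  PI <- if (config$prior == "sf") matrix(NA_integer_, n_rec, st$p) else NULL
  rec <- 0L
  for (t in seq_len(config$iterations)) {
    mh_step(st, config$scan)
    if (t > config$burn_in && (t - config$burn_in) %% config$thin == 0L) {
      rec <- rec + 1L
      E[rec, ] <- st$A[ut_idx]
      TH[rec, ] <- st$theta
      if (!is.null(PI)) PI[rec, ] <- st$pi
    }
    if (config$verbose && t %% 1000L == 0L) {
      acc <- kernel_acceptance(st$counters)
      message(sprintf("iter %d |E| = %d acc(edge/theta/label) = %.2f/%.2f/%.2f",
                      t, st$e, acc[1L], acc[2L], acc[3L]))
    }
  }
  stopifnot(rec == n_rec)
  pairs <- which(upper.tri(matrix(0L, st$p, st$p)), arr.ind = TRUE)
  dimnames(pairs) <- NULL
  structure(list(edges = E, theta = TH, pi = PI, pairs = pairs, p = st$p,
                 prior = config$prior, config = config, seed = config$seed,
                 counters = st$counters,
                 acceptance = kernel_acceptance(st$counters),
                 final_state = list(g = adjacency_to_network(st$A), e = st$e,
                                    theta = st$theta, pi = st$pi,
                                    loglik = st$loglik,
                                    logprior = st$logprior)),
            class = "sfggm_chain")
}

kernel_acceptance <- function(counters) {
  prop <- counters[, "proposed"]
  acc <- counters[, "accepted"] / ifelse(prop > 0L, prop, NA_real_)
  stats::setNames(acc, rownames(counters))
}

#' @export
print.sfggm_chain <- function(x, ...) {
  cat(sprintf("<sfggm_chain> prior = %s, p = %d, records = %d\n",
              x$prior, x$p, nrow(x$edges)))
  cat("acceptance rates:\n")
  print(round(x$acceptance, 3L))
  invisible(x)
}

## ---- exhaustive enumeration oracle ---------------------------------------

gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1L)
  bd <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- bd
  J[cbind(i + 1L, i)] <- bd
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (b - a) / 2 * e$values + (a + b) / 2,
       weights = (b - a) / 2 * 2 * e$vectors[1L, ]^2)
}

#' Exact posterior edge marginals by exhaustive enumeration (small p)
#'
#' Enumerates every decomposable network on p nodes, integrates the flat
#' hyperpriors (exactly via the Beta function for the random prior;
#' Gauss-Legendre quadrature over (alpha, K) for the scale-free prior) and,
#' for the scale-free prior, sums over all p! labelings. Direct summation
#' then yields the normalized edge-inclusion marginals that the chain
#' approximates — the module's independent correctness oracle.
#'
#' @param X Data matrix, at most 5 columns.
#' @param prior `"er"` or `"sf"`.
#' @param hiw Hyper-inverse Wishart parameters.
#' @param n_quad Gauss-Legendre nodes per hyperparameter dimension (sf).
#' @param theta_grid Optional explicit grid: a vector of beta values (er) or
#'   a two-column matrix of (alpha, K) rows (sf), each point weighted
#'   equally; overrides the quadrature.
#' @param standardize Standardize the data first (match [run_chain()]).
#' @return A list: `marginals` (p x p), `log_post` over decomposable graphs,
#'   `graphs` (M x n_graphs edge indicators), `pairs`.
#' @export
exhaustive_posterior <- function(X, prior = c("er", "sf"), hiw = hiw_params(),
                                 n_quad = 16L, theta_grid = NULL,
                                 standardize = TRUE) {
  prior <- match.arg(prior)
  X <- as.matrix(X)
  if (standardize) X <- standardize_columns(X)
  p <- ncol(X)
  if (p > 5L) stop("exhaustive enumeration requires p <= 5")
  M <- as.integer(p * (p - 1L) / 2L)
  S <- crossprod(X)
  n <- nrow(X)
  cache <- likelihood_cache()
  ut <- which(upper.tri(matrix(0L, p, p)), arr.ind = TRUE)
  n_graphs <- 2L^M
  Gmat <- matrix(FALSE, M, n_graphs)
  loglik <- rep(NA_real_, n_graphs)
  keep <- logical(n_graphs)
  for (gidx in seq_len(n_graphs)) {
    bits <- as.logical(bitwAnd(gidx - 1L, 2L^(seq_len(M) - 1L)))
    A <- matrix(FALSE, p, p)
    A[ut[bits, , drop = FALSE]] <- TRUE
    A <- A | t(A)
    ord <- mcs_order(A)
    if (!chordal_given_order(A, ord)) next
    keep[gidx] <- TRUE
    Gmat[, gidx] <- bits
    loglik[gidx] <- log_marginal_decomposition(
      S, n, clique_decomposition_adj(A, ord), hiw, cache)
  }
  Gk <- Gmat[, keep, drop = FALSE]
  lik <- loglik[keep]
  e_cnt <- colSums(Gk)
  if (prior == "er") {
    logpri <- if (is.null(theta_grid)) {
      lbeta(e_cnt + 1, M - e_cnt + 1)      # exact integral over beta
    } else {
      vapply(seq_along(e_cnt), function(i) {
        log_mean_exp(e_cnt[i] * log(theta_grid) +
                       (M - e_cnt[i]) * log1p(-theta_grid))
      }, numeric(1))
    }
  } else {
    if (is.null(theta_grid)) {
      qa <- gauss_legendre(n_quad, 0, 1)
      qk <- gauss_legendre(n_quad, 0, k_max(p))
      grid <- as.matrix(expand.grid(alpha = qa$nodes, K = qk$nodes))
      lw_theta <- log(as.vector(outer(qa$weights, qk$weights))) - log(k_max(p))
    } else {
      grid <- as.matrix(theta_grid)
      lw_theta <- rep(-log(nrow(grid)), nrow(grid))
    }
    perms <- permutations(p)
    n_cfg <- nrow(grid) * nrow(perms)
    D <- matrix(0, n_cfg, M)
    base <- numeric(n_cfg)
    lw_cfg <- numeric(n_cfg)
    utri <- upper.tri(matrix(0, p, p))
    cfg <- 0L
    for (t in seq_len(nrow(grid))) {
      for (r in seq_len(nrow(perms))) {
        cfg <- cfg + 1L
        pl <- sf_pair_logs(p, grid[t, 1L], grid[t, 2L])
        pperm <- perms[r, ]
        lfn <- pl$logf[pperm, pperm]
        l1n <- pl$log1mf[pperm, pperm]
        D[cfg, ] <- (lfn - l1n)[utri]
        base[cfg] <- sum(l1n[utri])
        lw_cfg[cfg] <- lw_theta[t] - lfactorial(p)
      }
    }
    LP <- D %*% Gk + base            # n_cfg x n_graphs
    logpri <- apply(LP + lw_cfg, 2L, log_sum_exp)
  }
  log_post <- lik + logpri
  log_post <- log_post - log_sum_exp(log_post)
  post <- exp(log_post)
  m_pairs <- as.vector(Gk %*% post)
  marg <- matrix(0, p, p)
  marg[upper.tri(marg)] <- m_pairs
  marg <- marg + t(marg)
  list(marginals = marg, log_post = log_post, graphs = Gk,
       pairs = ut, edge_counts = e_cnt)
}
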