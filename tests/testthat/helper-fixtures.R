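## Shared fixtures and independent oracles, built in code at test time.

path_graph <- function(p) network(p, cbind(seq_len(p - 1L), 2:p))

cycle_graph <- function(p) network(p, rbind(cbind(seq_len(p - 1L), 2:p), c(1L, p)))

complete_graph <- function(p) network(p, t(utils::combn(p, 2L)))

random_graph <- function(p, prob = 0.4) {
  pairs <- t(utils::combn(p, 2L))
  keep <- stats::runif(nrow(pairs)) < prob
  network(p, pairs[keep, , drop = FALSE])
}

## Independent chordality oracle: a graph is chordal iff no vertex subset of
## size >= 4 induces a cycle (all induced degrees 2 and connected).
chordal_brute <- function(g) {
  A <- adjacency_matrix(g)
  p <- g$p
  if (p < 4L) return(TRUE)
  for (k in 4:p) {
    subs <- utils::combn(p, k)
    for (c in seq_len(ncol(subs))) {
      s <- subs[, c]
      B <- A[s, s]
      if (all(rowSums(B) == 2L)) {
        # connected 2-regular graph = a single induced cycle
        reach <- logical(k)
        reach[1L] <- TRUE
        for (step in seq_len(k)) reach <- reach | (B %*% reach) > 0
        if (all(reach)) return(FALSE)
      }
    }
  }
  TRUE
}

## Enumerate all graphs on p nodes (2^M of them) as networks.
all_graphs <- function(p) {
  pairs <- t(utils::combn(p, 2L))
  M <- nrow(pairs)
  lapply(seq_len(2L^M) - 1L, function(mask) {
    bits <- bitwAnd(mask, 2L^(seq_len(M) - 1L)) > 0L
    network(p, pairs[bits, , drop = FALSE])
  })
}

## Random decomposable graph: greedy random edge additions that keep the
## graph chordal.
random_decomposable <- function(p, target_edges) {
  g <- network(p)
  pairs <- t(utils::combn(p, 2L))
  for (idx in sample.int(nrow(pairs))) {
    if (n_edges(g) >= target_edges) break
    cand <- network(p, rbind(g$edges, pairs[idx, ]))
    if (is_decomposable(cand)) g <- cand
  }
  g
}

## Canonical string identity of an edge set (for tree frequency counting).
edge_key <- function(edges, p) paste(edges[, 1L] + p * edges[, 2L], collapse = ",")

## Sample a covariance matrix from the HIW prior of the 3-node path
## 1 - 2 - 3 by the hyper-Markov construction: the (1,2) block is inverse
## Wishart, and the clique {2,3} contributes its conditional (b, s3.2) drawn
## from an independent IW, glued through the shared sigma_22. Independent of
## the closed-form marginal (used as its oracle).
rhiw_path3 <- function(delta, tau) {
  riw2 <- function() {
    W <- stats::rWishart(1L, df = delta + 1, Sigma = diag(1 / tau, 2L))[, , 1L]
    solve(W)
  }
  S12 <- riw2()
  S23 <- riw2()
  b <- S23[1L, 2L] / S23[1L, 1L]
  s3.2 <- S23[2L, 2L] - S23[1L, 2L]^2 / S23[1L, 1L]
  s22 <- S12[2L, 2L]
  s23 <- b * s22
  s33 <- s3.2 + b^2 * s22
  rbind(c(S12[1L, 1L], S12[1L, 2L], b * S12[1L, 2L]),
        c(S12[1L, 2L], s22, s23),
        c(b * S12[1L, 2L], s23, s33))
}

mvn_loglik <- function(X, Sigma) {
  R <- chol(Sigma)
  n <- nrow(X)
  k <- ncol(X)
  -n * sum(log(diag(R))) - 0.5 * sum(backsolve(R, t(X), transpose = TRUE)^2) -
    n * k / 2 * log(2 * pi)
}

## Batch-means standard error of a marginal frequency along a chain.
batch_se <- function(x, n_batch = 20L) {
  n <- length(x)
  size <- n %/% n_batch
  means <- vapply(seq_len(n_batch), function(b) {
    mean(x[((b - 1L) * size + 1L):(b * size)])
  }, 0)
  stats::sd(means) / sqrt(n_batch)
}
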