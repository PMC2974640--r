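test_that("tau_for_unit_mode places the variance prior mode at 1", {
  for (delta in c(0.5, 1, 3, 6, 12)) {
    tau <- tau_for_unit_mode(delta)
    # 1-D optimization oracle on the implied inverse-gamma density
    dens <- function(s2) (delta / 2) * log(tau / 2) - lgamma(delta / 2) -
      (delta / 2 + 1) * log(s2) - tau / (2 * s2)
    opt <- stats::optimize(dens, c(1e-3, 50), maximum = TRUE)
    expect_equal(opt$maximum, 1, tolerance = 1e-4)
  }
  # monotone in delta per the closed-form relation
  expect_true(all(diff(vapply(1:6, tau_for_unit_mode, 0)) > 0))
})

test_that("complete-set marginal matches 1-D quadrature", {
  delta <- 3; tau <- 1
  for (x in list(0, 0.7, c(-0.4, 1.2))) {
    X <- matrix(x, ncol = 1)
    dens <- function(s2) {
      ig <- (tau / 2)^(delta / 2) / gamma(delta / 2) * s2^(-(delta / 2 + 1)) *
        exp(-tau / (2 * s2))
      lik <- vapply(s2, function(s) prod(stats::dnorm(x, 0, sqrt(s))), 0)
      lik * ig
    }
    o <- stats::integrate(dens, 0, Inf, rel.tol = 1e-10)
    expect_equal(log_marginal_complete_set(X, hiw_params(delta, tau)),
                 log(o$value), tolerance = 1e-6)
  }
})

test_that("complete-set marginal matches the Wishart Monte-Carlo oracle", {
  set.seed(601)
  delta <- 3; tau <- 1; k <- 3; n <- 5
  X <- matrix(stats::rnorm(n * k), n, k)
  lml <- log_marginal_complete_set(X, hiw_params(delta, tau))
  m <- 1e5
  W <- stats::rWishart(m, df = delta + k - 1, Sigma = diag(1 / tau, k))
  S <- crossprod(X)
  ll <- vapply(seq_len(m), function(i) {
    P <- W[, , i]
    sum(log(diag(chol(P)))) * n - 0.5 * sum(P * S) - n * k / 2 * log(2 * pi)
  }, 0)
  mx <- max(ll)
  w <- exp(ll - mx)
  est <- mx + log(mean(w))
  se_log <- stats::sd(w) / (mean(w) * sqrt(m))
  expect_lt(abs(lml - est), 3 * se_log)
})

test_that("complete-set marginal is invariant to column sign flips", {
  set.seed(602)
  X <- matrix(stats::rnorm(10), 5, 2)
  X2 <- X
  X2[, 2] <- -X2[, 2]
  expect_equal(log_marginal_complete_set(X), log_marginal_complete_set(X2))
})

test_that("graph marginal factorizes over cliques and separators", {
  set.seed(603)
  X <- matrix(stats::rnorm(12), 4, 3)
  h <- hiw_params()
  lml <- log_marginal_likelihood(X, path_graph(3), h)
  expect_equal(lml,
               log_marginal_complete_set(X[, 1:2], h) +
                 log_marginal_complete_set(X[, 2:3], h) -
                 log_marginal_complete_set(X[, 2, drop = FALSE], h),
               tolerance = 1e-12)
  # empty graph: full independence
  expect_equal(log_marginal_likelihood(X, network(3), h),
               sum(vapply(1:3, function(v)
                 log_marginal_complete_set(X[, v, drop = FALSE], h), 0)),
               tolerance = 1e-12)
  # complete graph: one unrestricted term
  expect_equal(log_marginal_likelihood(X, complete_graph(3), h),
               log_marginal_complete_set(X, h), tolerance = 1e-12)
  expect_error(log_marginal_likelihood(matrix(0, 2, 4), cycle_graph(4), h),
               "not decomposable")
})

test_that("path-graph marginal matches Monte-Carlo integration over the HIW prior", {
  set.seed(604)
  delta <- 3; tau <- tau_for_unit_mode(delta)
  n <- 4
  X <- matrix(stats::rnorm(n * 3), n, 3)
  lml <- log_marginal_likelihood(X, path_graph(3), hiw_params(delta, tau))
  m <- 2e5
  ll <- vapply(seq_len(m), function(i) mvn_loglik(X, rhiw_path3(delta, tau)), 0)
  mx <- max(ll)
  w <- exp(ll - mx)
  est <- mx + log(mean(w))
  se_log <- stats::sd(w) / (mean(w) * sqrt(m))
  expect_lt(abs(lml - est), 3 * se_log)
})

test_that("marginal is invariant to row permutation and joint relabeling", {
  set.seed(605)
  X <- matrix(stats::rnorm(24), 6, 4)
  g <- random_decomposable(4, 4)
  h <- hiw_params()
  base <- log_marginal_likelihood(X, g, h)
  expect_equal(log_marginal_likelihood(X[sample(6), ], g, h), base,
               tolerance = 1e-10)
  perm <- sample(4)
  g2 <- network(4, cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]))
  X2 <- X
  X2[, perm] <- X
  expect_equal(log_marginal_likelihood(X2, g2, h), base, tolerance = 1e-10)
})

test_that("edge-move ratios equal full recomputation and are reversible", {
  set.seed(606)
  h <- hiw_params()
  for (rep in 1:30) {
    p <- sample(3:6, 1)
    X <- matrix(stats::rnorm(8 * p), 8, p)
    cache <- sfggm:::likelihood_cache()   # caches are valid per (X, hiw)
    g <- random_decomposable(p, sample.int(max_edges(p), 1))
    pairs <- t(utils::combn(p, 2))
    idx <- sample(nrow(pairs))
    for (e in idx) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      mv <- if (has_edge(g, i, j)) "delete" else "add"
      r <- tryCatch(edge_move_log_ratio(X, g, c(i, j), mv, h, cache),
                    error = function(e) NULL)
      if (is.null(r)) next       # move leaves the decomposable class
      g2 <- if (mv == "add") network(p, rbind(g$edges, c(i, j)))
            else network(p, g$edges[!(g$edges[, 1] == i & g$edges[, 2] == j), ,
                                    drop = FALSE])
      full <- log_marginal_likelihood(X, g2, h) -
        log_marginal_likelihood(X, g, h)
      expect_equal(r, full, tolerance = 1e-9)
      # reversibility: the opposite move cancels
      back <- edge_move_log_ratio(X, g2, c(i, j),
                                  if (mv == "add") "delete" else "add",
                                  h, cache)
      expect_equal(r + back, 0, tolerance = 1e-9)
      break
    }
  }
  # smallest case: deleting the single edge of a 2-node graph
  X <- matrix(stats::rnorm(10), 5, 2)
  g <- network(2, rbind(c(1, 2)))
  expect_equal(edge_move_log_ratio(X, g, c(1, 2), "delete", h),
               sum(vapply(1:2, function(v)
                 log_marginal_complete_set(X[, v, drop = FALSE], h), 0)) -
                 log_marginal_complete_set(X, h),
               tolerance = 1e-12)
})

test_that("standardization yields unit-variance zero-mean columns", {
  set.seed(607)
  X <- matrix(stats::rnorm(60, mean = 3, sd = 5), 20, 3)
  Z <- standardize_columns(X)
  expect_equal(colMeans(Z), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(Z, 2, stats::var), rep(1, 3), tolerance = 1e-8)
})
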