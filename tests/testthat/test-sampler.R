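make_state <- function(X, prior = "er", ...) {
  sampler_state(X, sampler_config(prior = prior, iterations = 100,
                                  burn_in = 10, thin = 1, ...))
}

test_that("config validation catches degenerate schedules", {
  expect_error(sampler_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(sampler_config(iterations = 100, burn_in = 0, thin = 0), "thin")
  expect_error(sampler_config(iterations = 100, burn_in = 90, thin = 50),
               "zero-length")
  expect_error(sampler_config(xi = c(beta = -1)), "positive")
})

test_that("edge proposals respect boundaries and decomposability", {
  set.seed(701)
  X <- gaussian_tree_data(path_graph(4), 20)
  st <- make_state(X, init_graph = network(4))
  # empty graph: any delete draw is an immediate rejection
  outs <- replicate(50, propose_edge_move(st)$ok)
  expect_true(any(!outs))    # delete coin flips rejected
  # path 1-2-3-4: the only non-decomposable candidate is adding (1,4)
  stp <- make_state(X, init_graph = path_graph(4))
  saw_reject <- FALSE
  for (i in 1:200) {
    pr <- propose_edge_move(stp)
    if (!pr$ok) { saw_reject <- TRUE; next }
    A2 <- pr$A2
    expect_true(sfggm:::is_decomposable_adj(A2))
  }
  expect_true(saw_reject)
  # complete graph: add draws are immediate rejections
  stc <- make_state(X, init_graph = complete_graph(4))
  outs <- replicate(50, propose_edge_move(stc)$ok)
  expect_true(any(!outs))
})

test_that("edge-move Hastings ratios cancel over a move and its reverse", {
  set.seed(702)
  X <- gaussian_tree_data(uniform_tree(5), 20)
  st <- make_state(X, init_graph = random_decomposable(5, 4))
  for (i in 1:100) {
    pr <- propose_edge_move(st)
    if (!pr$ok) next
    e <- st$e
    M <- st$M
    if (pr$move == "add") {
      expect_equal(pr$log_q_ratio, log(M - e) - log(e + 1))
      # reverse: delete from a graph with e+1 edges
      expect_equal(pr$log_q_ratio + (log(e + 1) - log(M - e)), 0)
    } else {
      expect_equal(pr$log_q_ratio, log(e) - log(M - e + 1))
      expect_equal(pr$log_q_ratio + (log(M - e + 1) - log(e)), 0)
    }
  }
})

test_that("theta proposals are symmetric windows with domain rejection", {
  set.seed(703)
  th <- c(beta = 0.99)
  props <- replicate(2000, propose_theta(th, 0.05))
  expect_true(all(abs(props - 0.99) <= 0.05))
  expect_true(any(props > 1))      # boundary violations occur and must be
  # rejected by the hyperprior gate
  expect_identical(log_hyperprior(1.03, "er", 4), -Inf)
  # flat-target chain: likelihood constant, uniform prior => uniform marginal
  beta <- 0.5
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    cand <- propose_theta(beta, 0.05)
    if (is.finite(log_hyperprior(cand, "er", 4))) beta <- unname(cand)
    draws[i] <- beta
  }
  ks <- suppressWarnings(stats::ks.test(draws[seq(50, 20000, by = 50)], "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("label swaps favor moving a hub toward label 1 under the sf prior", {
  st <- star_tree(5)
  # hub carries label p; proposing it to p-1 must raise the prior
  pi <- c(5L, 1L, 2L, 3L, 4L)
  for (alpha in c(0.2, 0.5, 0.8)) {
    d <- log_prior_sf(st, alpha, 4, swap_adjacent_labels(pi, 4)) -
      log_prior_sf(st, alpha, 4, pi)
    expect_gt(d, 0)
  }
  # p = 2: the single swap is an involution
  pi2 <- propose_label_swap(identity_labeling(2))
  expect_equal(pi2$pi, c(2L, 1L))
  expect_equal(swap_adjacent_labels(pi2$pi, 1), identity_labeling(2))
})

test_that("chains are reproducible and bookkeeping is exact", {
  set.seed(704)
  X <- gaussian_tree_data(path_graph(3), 15)
  cfg <- sampler_config("sf", iterations = 600, burn_in = 100, thin = 7,
                        seed = 99)
  ch1 <- run_chain(X, cfg)
  ch2 <- run_chain(X, cfg)
  expect_identical(ch1$edges, ch2$edges)
  expect_identical(ch1$theta, ch2$theta)
  expect_identical(ch1$pi, ch2$pi)
  expect_equal(nrow(ch1$edges), (600L - 100L) %/% 7L)
  # burn-in boundary off-by-one checks
  for (it in c(107L, 113L, 114L)) {
    chb <- run_chain(X, sampler_config("er", iterations = it, burn_in = 100,
                                       thin = 7, seed = 1))
    expect_equal(nrow(chb$edges), (it - 100L) %/% 7L)
  }
  # below one record the configuration itself is rejected
  expect_error(sampler_config("er", iterations = 101L, burn_in = 100L,
                              thin = 7L), "zero-length")
  # counters account for every proposal
  cnt <- ch1$counters
  expect_equal(cnt["edge", "proposed"], 600L)
  expect_equal(cnt["theta", "proposed"], 1200L)   # two components
  expect_equal(cnt["label", "proposed"], 1200L)   # p - 1 = 2 swaps per sweep
  expect_true(all(cnt[, "accepted"] + cnt[, "outright"] <= cnt[, "proposed"]))
})

test_that("recorded graphs are decomposable and the cached total matches cold", {
  set.seed(705)
  X <- gaussian_tree_data(uniform_tree(5), 25)
  cfg <- sampler_config("sf", iterations = 2000, burn_in = 200, thin = 40,
                        seed = 17)
  ch <- run_chain(X, cfg)
  for (rec in seq_len(nrow(ch$edges))) {
    g <- network(5, ch$pairs[ch$edges[rec, ], , drop = FALSE])
    expect_true(is_decomposable(g))
  }
  Z <- standardize_columns(X)
  expect_equal(ch$final_state$loglik,
               log_marginal_likelihood(Z, ch$final_state$g),
               tolerance = 1e-8)
  expect_equal(ch$final_state$logprior,
               log_prior_sf(ch$final_state$g, ch$final_state$theta[["alpha"]],
                            ch$final_state$theta[["K"]], ch$final_state$pi),
               tolerance = 1e-8)
  # acceptance rates in (0, 1) on this non-degenerate problem
  expect_true(all(ch$acceptance > 0 & ch$acceptance < 1))
})

test_that("exhaustive posterior handles the two-graph case by hand", {
  set.seed(706)
  X <- matrix(stats::rnorm(40), 20, 2)
  h <- hiw_params()
  post <- exhaustive_posterior(X, "er", h)
  Z <- standardize_columns(X)
  l0 <- log_marginal_likelihood(Z, network(2), h)
  l1 <- log_marginal_likelihood(Z, complete_graph(2), h)
  # integral of beta^e (1-beta)^(1-e) over (0,1) is 1/2 for both graphs
  expect_equal(post$marginals[1, 2],
               exp(l1) / (exp(l0) + exp(l1)), tolerance = 1e-10)
  # uniform special case via an explicit one-point grid at beta = 1/2
  post2 <- exhaustive_posterior(X, "er", h, theta_grid = 0.5)
  expect_equal(post2$marginals[1, 2], post$marginals[1, 2], tolerance = 1e-10)
  expect_error(exhaustive_posterior(matrix(0, 2, 6), "er"), "p <= 5")
})

test_that("sf exhaustive marginals are invariant under joint relabeling", {
  set.seed(707)
  X <- gaussian_tree_data(path_graph(3), 20)
  post <- exhaustive_posterior(X, "sf", n_quad = 8)
  perm <- c(3L, 1L, 2L)
  X2 <- X
  X2[, perm] <- X
  post2 <- exhaustive_posterior(X2, "sf", n_quad = 8)
  expect_equal(post2$marginals[perm, perm], post$marginals, tolerance = 1e-9)
})

test_that("chain edge marginals agree with the exhaustive oracle (p = 3)", {
  set.seed(708)
  X <- gaussian_tree_data(path_graph(3), 30)
  for (prior in c("er", "sf")) {
    post <- exhaustive_posterior(X, prior, n_quad = 16)
    ch <- run_chain(X, sampler_config(prior, iterations = 24000,
                                      burn_in = 2000, thin = 5, seed = 31))
    m <- edge_marginals(ch)
    ut <- which(upper.tri(m))
    for (k in seq_along(ut)) {
      se <- max(batch_se(ch$edges[, k]), 1e-3)
      expect_lt(abs(m[ut[k]] - post$marginals[ut[k]]), 3 * se)
    }
  }
})
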