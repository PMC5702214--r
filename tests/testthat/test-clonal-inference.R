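test_that("K = 1 fit equals the closed-form smoothed column means", {
  set.seed(401)
  X <- matrix(rbinom(30 * 8, 1, 0.4), 30, 8)
  fit <- bmix(X, K = 1)
  expect_equal(as.numeric(fit$theta),
               (colSums(X) + 0.5) / (nrow(X) + 1), tolerance = 1e-12)
  expect_identical(fit$pi, 1)
  expect_true(all(fit$gamma == 1))
})

test_that("EM log-likelihood trace is non-decreasing on every seeded run", {
  set.seed(402)
  for (s in 1:15) {
    X <- block_matrix(8, 10, noise = runif(1, 0, 0.3))
    fit <- bmix(X, K = sample(2:4, 1), n_restarts = 3, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
})

test_that("EM optimum is at least the best brute-force hard 2-partition", {
  # soft EM ascends monotonically from any hard partition, so the optimum
  # over a restart pool containing every 2-coloring must score at least the
  # best coloring's own objective
  set.seed(403)
  for (rep in 1:8) {
    n <- sample(5:8, 1); J <- sample(3:4, 1)
    X <- matrix(rbinom(n * J, 1, runif(1, 0.2, 0.8)), n, J)
    all_colorings <- lapply(0:(2^(n - 1) - 1), function(code)
      as.integer(intToBits(code))[seq_len(n)] + 1L)
    fit <- bmix(X, K = 2, n_restarts = 20, tol = 1e-12, max_iter = 2000,
                seed = rep, init = all_colorings)
    expect_gte(fit$objective, brute_best_objective_k2(X) - 1e-6)
  }
})

test_that("identical seed gives identical fit; labels are data-determined", {
  X <- block_matrix(10, 12, noise = 0.05)
  f1 <- bmix(X, K = 2, n_restarts = 5, seed = 42)
  f2 <- bmix(X, K = 2, n_restarts = 5, seed = 42)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("mixture recovers planted clusters and parameters (ARI, theta error)", {
  set.seed(404)
  K <- 3; J <- 30; n <- 200
  theta_true <- matrix(0.05, K, J)
  for (k in 1:K) theta_true[k, ((k - 1) * 10 + 1):(k * 10)] <- 0.95
  z <- sample.int(K, n, replace = TRUE)
  X <- matrix(rbinom(n * J, 1, theta_true[z, ]), n)
  fit <- bmix(X, K = K, seed = 1)
  expect_gt(adjusted_rand_index(fit$cluster, z), 0.9)
  # match clusters to truth by best agreement, then check parameter error
  perm <- apply(fit$theta %*% t(theta_true), 1, which.max)
  expect_true(all(sort(perm) == 1:K))
  expect_lt(mean(abs(fit$theta - theta_true[perm, ])), 0.05)
})

test_that("theta estimation error shrinks as the number of cells grows", {
  theta_true <- rbind(c(rep(0.9, 6), rep(0.1, 6)),
                      c(rep(0.1, 6), rep(0.9, 6)))
  err <- vapply(c(50, 200, 800), function(n) {
    set.seed(405)
    z <- sample.int(2, n, replace = TRUE)
    X <- matrix(rbinom(n * 12, 1, theta_true[z, ]), n)
    fit <- bmix(X, K = 2, n_restarts = 5, seed = 1)
    perm <- apply(fit$theta %*% t(theta_true), 1, which.max)
    mean(abs(fit$theta - theta_true[perm, ]))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("ARI agrees with the mclust reference and is relabeling-invariant", {
  set.seed(406)
  x <- sample.int(3, 60, replace = TRUE)
  y <- sample.int(3, 60, replace = TRUE)
  expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))
  expect_equal(adjusted_rand_index(x, x), 1)
  relab <- c(2L, 3L, 1L)[x]
  expect_equal(adjusted_rand_index(x, relab), 1)
  expect_equal(adjusted_rand_index(x, y),
               adjusted_rand_index(relab, c(3L, 1L, 2L)[y]))
})

test_that("degenerate inputs: K > n errors, identical rows warn at K > 1", {
  X <- matrix(1L, 4, 3)
  expect_error(bmix(X, K = 5), "exceeds the number of cells")
  expect_warning(fit <- bmix(X, K = 2, n_restarts = 2, seed = 1),
                 "degenerate")
  expect_true(any(fit$pi < 0.05) || max(dist(fit$theta)) < 0.05)
})

test_that("cluster-number estimation: identical rows, two blocks, planted clones", {
  expect_identical(estimate_k(matrix(1L, 5, 4))$K, 1L)
  X <- block_matrix(10, 14, noise = 0)
  expect_identical(estimate_k(X)$K, 2L)
  # planted 3-clone regime with dropout/false positives at n = 200
  hits <- vapply(1:10, function(s) {
    tr <- simulate_truth(sim_config(seed = 500 + s, n_cells = 200,
                                    K_clones = 3, doublet_rate = 0,
                                    poor_assay_fraction = 0))
    sim <- simulate_observations(tr)
    sg <- sim_genotype_matrix(sim)
    estimate_k(sg$gm)$K == 3L
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("posterior prediction and simulation round-trip the fitted model", {
  set.seed(407)
  X <- block_matrix(15, 12, noise = 0.05)
  fit <- bmix(X, K = 2, n_restarts = 5, seed = 2)
  expect_identical(predict(fit), fit$cluster)
  gam <- predict(fit, newdata = X, type = "posterior")
  expect_equal(unname(rowSums(gam)), rep(1, nrow(X)))
  expect_equal(unname(gam), unname(fit$gamma), tolerance = 1e-8)
  draws <- simulate(fit, nsim = 400, seed = 3)
  refit <- bmix(draws$X, K = 2, n_restarts = 5, seed = 4)
  expect_gt(adjusted_rand_index(refit$cluster, draws$cluster), 0.9)
})
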