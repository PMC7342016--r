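test_that("sign permutation p-values match closed forms", {
  # unanimous positive effect: only the identity reaches the observed mean
  # (N = 20 so a random draw practically never replicates the all-plus row)
  set.seed(1)
  v <- matrix(rep(1, 20) + abs(rnorm(20, sd = 0.01)), ncol = 1)
  out <- sign_permutation_p(v, n_perm = 2000, seed = 3)
  expect_equal(out$p_obs, 1 / 2001)
  # perfectly symmetric sample: observed mean 0; exact enumeration gives
  # P(S >= 0) = 42/64 (the atom at 0 counts toward the right tail)
  v2 <- matrix(c(2, 2, 2, -2, -2, -2), ncol = 1)
  out2 <- sign_permutation_p(v2, n_perm = 4000, seed = 3)
  expect_gt(out2$p_obs, 0.61); expect_lt(out2$p_obs, 0.70)
  expect_error(sign_permutation_p(matrix(c(1, NA), 2, 1)), "nonfinite")
  expect_warning(sign_permutation_p(v, n_perm = 50, seed = 1), "coarse")
})

test_that("Monte-Carlo p matches exhaustive sign enumeration for N = 5", {
  set.seed(2)
  x <- rnorm(5, mean = 0.6)
  # oracle: enumerate all 2^5 sign assignments; the observed statistic is
  # the identity row of the same enumeration so both sides share one
  # floating-point summation order
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  null_stats <- drop(signs %*% x / 5)
  obs <- null_stats[rowSums(signs) == 5]
  p_exact <- mean(null_stats >= obs)
  n_perm <- 20000
  p_mc <- sign_permutation_p(matrix(x, ncol = 1), n_perm = n_perm,
                             seed = 7)$p_obs
  # binomial Monte-Carlo error around the exact enumeration value
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / n_perm) + 2 / n_perm
  expect_lt(abs(p_mc - p_exact), tol)
})

test_that("right-tail p on negated data is the left tail (symmetry)", {
  set.seed(3)
  x <- matrix(rnorm(20, 0.3), ncol = 1)
  pr <- sign_permutation_p(x, n_perm = 5000, seed = 5)$p_obs
  pl <- sign_permutation_p(-x, n_perm = 5000, seed = 5)$p_obs
  # same seeded schedule: the two tails cover the distribution exactly once,
  # with the observed statistic itself counted in both
  expect_equal(pr + pl, 1 + 1 / 5001)
})

test_that("p-values are valid under the global null", {
  set.seed(4)
  v <- matrix(rnorm(12 * 40), 12, 40)
  p <- sign_permutation_p(v, n_perm = 500, seed = 9)$p_obs
  expect_lt(mean(p <= 0.05), 0.13)    # no anticonservative blow-up
  expect_gt(mean(p), 0.35)
})

test_that("cluster correction finds planted contiguous effects only", {
  set.seed(5)
  n_sub <- 12; dims <- c(8, 10)
  effect <- matrix(0, dims[1], dims[2])
  effect[3:5, 4:8] <- 1.2                     # contiguous planted region
  maps <- t(replicate(n_sub, as.vector(effect) + rnorm(prod(dims))))
  perm <- sign_permutation_p(maps, n_perm = 1000, seed = 11)
  cr <- cluster_correct(perm, dims)
  expect_s3_class(cr, "cluster_result")
  expect_true(any(cr$significant))
  planted <- which(effect > 0)
  biggest <- cr$clusters[[which.max(cr$sizes)]]
  expect_gt(length(intersect(biggest, planted)) / length(planted), 0.8)
  # monotonicity: enlarging the effect never loses the cluster
  maps2 <- maps + rep(as.vector(effect), each = n_sub)
  perm2 <- sign_permutation_p(maps2, n_perm = 1000, seed = 11)
  cr2 <- cluster_correct(perm2, dims)
  expect_true(any(cr2$significant))
  expect_gte(max(cr2$sizes), max(cr$sizes))
  # a flat p-map yields no clusters and an empty mask
  flat <- perm
  flat$p_obs <- rep(1, prod(dims))
  cr3 <- cluster_correct(flat, dims)
  expect_length(cr3$clusters, 0)
  expect_false(any(cr3$significant_mask))
})

test_that("cluster contiguity respects 1-D adjacency and 2-D connectivity", {
  # hand-built permutation object: observed p-map plus a trivial null
  mk_perm <- function(p_obs, n_perm = 99) {
    list(p_obs = p_obs, stat_obs = 1 - p_obs,
         p_perm = rbind(p_obs, matrix(1, n_perm, length(p_obs))),
         n_samples = n_perm + 1)
  }
  # 1-D: two runs separated by a gap are two clusters
  p1 <- c(0.01, 0.01, 0.9, 0.01, 0.01, 0.01)
  cr1 <- cluster_correct(mk_perm(p1), c(6, 1))
  expect_equal(sort(cr1$sizes), c(2, 3))
  # 2-D: diagonal cells touch under 8-connectivity, not under 4
  p2 <- rep(1, 9); p2[c(1, 5)] <- 0.01        # cells (1,1) and (2,2)
  cr8 <- cluster_correct(mk_perm(p2), c(3, 3), connectivity = 8)
  expect_equal(cr8$sizes, 2)
  cr4 <- cluster_correct(mk_perm(p2), c(3, 3), connectivity = 4)
  expect_equal(cr4$sizes, c(1, 1))
  # Bonferroni factor tightens the size threshold monotonically
  set.seed(6)
  maps <- t(replicate(10, rnorm(50)))
  perm <- sign_permutation_p(maps, n_perm = 500, seed = 2)
  t1 <- cluster_correct(perm, c(5, 10), bonferroni_factor = 1)$size_threshold
  t3 <- cluster_correct(perm, c(5, 10), bonferroni_factor = 3)$size_threshold
  expect_gte(t3, t1)
})

test_that("BH-FDR matches a hand-computed step-up", {
  p <- c(0.001, 0.02, 0.04, 0.9)
  out <- fdr_correct(p)
  # manual step-up: adjusted_i = min_{j >= i} (m / j) p_(j)
  expect_equal(out$adjusted, c(0.004, 0.04, 4 / 3 * 0.04, 0.9))
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(0.01)$significant, TRUE)
  expect_false(any(fdr_correct(rep(1, 5))$significant))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.2, 1.4)), "0, 1")
})

test_that("peak latency and bootstrap CI behave on degenerate maps", {
  pt <- seq(0, 800, 100); it <- seq(0, 2400, 200)
  base <- outer(exp(-(pt - 400)^2 / 1e5), exp(-(it - 1400)^2 / 1e6)) * 10 + 50
  maps <- array(0, dim = c(4, length(pt), length(it)))
  for (k in 1:4) maps[k, , ] <- base
  out <- peak_latency_ci(maps, pt, it, n_boot = 200, seed = 1)
  expect_equal(out$perception$peak, 400)
  expect_equal(out$imagery$peak, 1400)
  expect_equal(unname(diff(out$perception$ci)), 0)   # identical participants
  expect_equal(unname(diff(out$imagery$ci)), 0)
  flat <- array(50, dim = c(3, 4, 5))
  expect_error(peak_latency_ci(flat, 1:4, 1:5), "flat")
})
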