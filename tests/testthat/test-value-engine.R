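test_that("deepest-level distribution matches small enumerations", {
  # nothing sampled: point mass at zero
  d0 <- initial_level_distribution(rich1, q1 = 0, b_eff = 3)
  expect_dist_equal(d0, 0, 1)
  # fully sampled pair of branches: P(+1) = 1 - 2^-b
  d1 <- initial_level_distribution(rich1, q1 = 1, b_eff = 2)
  expect_dist_equal(d1, c(-1, 1), c(1 / 4, 3 / 4))
  # half-sampled pair: brute-force over the 3^2 weighted joint leaf outcomes
  bf <- brute_force_max(c(-1, 0, 1), c(0.25, 0.5, 0.25), 2)
  dh <- initial_level_distribution(rich1, q1 = 0.5, b_eff = 2)
  expect_dist_equal(dh, bf$values, bf$probs)
  expect_equal(dist_mean(dh), 0.375)
})

test_that("diffusion step implements the stay/up/down stencil", {
  prior <- initial_level_distribution(rich1, 1, 2)
  # q = 0, gamma = 1: nothing sampled, nothing lost
  same <- diffusion_step(rich1, prior, q = 0, gamma = 1)
  expect_equal(dist_mean(same), dist_mean(prior))
  expect_dist_equal(same, c(-1, 1), c(1 / 4, 3 / 4))
  # point mass splits half-and-half at p = 1/2, q = 1
  pm <- bdtree:::new_value_dist(1, 3L, 1L, 1L, "J")
  split <- diffusion_step(rich1, pm, q = 1)
  expect_dist_equal(split, c(2, 4), c(0.5, 0.5))
  # gamma = 0: only the immediate reward survives, whatever the prior
  dead <- diffusion_step(rich1, prior, q = 1, gamma = 0)
  expect_dist_equal(dead, c(-1, 1), c(0.5, 0.5))
  # mass is conserved for any gamma
  for (g in c(0.3, 0.8)) {
    out <- diffusion_step(rich1, prior, q = 0.7, gamma = g)
    expect_equal(sum(out$probs), 1, tolerance = 1e-14)
  }
  # a poor-model prior cannot be diffused with a mismatched lattice
  poor2 <- reward_model("poor", 2)
  expect_error(diffusion_step(poor2, prior, q = 1), "scale")
})

test_that("maximization step is the CDF power and matches enumeration", {
  qd <- bdtree:::new_value_dist(c(1 / 8, 0, 1 / 2, 0, 3 / 8), -2L, 1L, 2L, "Q")
  # b = 1: choosing among one option changes nothing
  expect_equal(maximization_step(qd, 1)$probs, qd$probs)
  # b = 2 against brute force over the 3^2 ordered pairs
  bf <- brute_force_max(c(-2, 0, 2), c(1 / 8, 1 / 2, 3 / 8), 2)
  expect_dist_equal(maximization_step(qd, 2), bf$values, bf$probs)
  expect_equal(as.data.frame(maximization_step(qd, 2))$probability,
               c(1, 24, 39) / 64)
  # CDF of the output is the input CDF raised to b, key by key
  out <- maximization_step(qd, 3)
  expect_equal(cumsum(out$probs), cumsum(qd$probs)^3, tolerance = 1e-14)
})

test_that("exhaustive tree values match the closed form and brute force", {
  for (b in 1:6)
    expect_equal(tree_value(rich1, policy_exhaustive(b, 1))$value, 1 - 2^(1 - b))
  expect_equal(tree_value(rich1, policy_exhaustive(2, 2))$value, 19 / 16)
  expect_equal(brute_force_value(0.5, -1, b = 2, d = 2, q_fwd = c(1, 1)), 19 / 16)
  # a selective depth-2 case against full-configuration enumeration
  qf <- c(0.8, 0.4)
  expect_equal(tree_value(rich1, policy_heterogeneous(2, qf, order = "forward"))$value,
               brute_force_value(0.5, -1, b = 2, d = 2, q_fwd = qf),
               tolerance = 1e-12)
  # and for a rich n = 2 model on a single level
  m2 <- reward_model("rich", 2)
  expect_equal(tree_value(m2, policy_exhaustive(2, 1))$value,
               brute_force_value(2 / 3, -2, b = 2, d = 1, q_fwd = 1),
               tolerance = 1e-12)
})

test_that("value equals the mean of the terminal distribution and is normalized", {
  pols <- list(policy_exhaustive(3, 4),
               policy_homogeneous(2, 17),
               policy_heterogeneous(2, c(0.2, 0.7, 1, 0.9), gamma = 0.8),
               policy_two_b(2, 1, 1, 12))
  for (m in list(rich1, reward_model("poor", 3))) for (pol in pols) {
    res <- tree_value(m, pol)
    expect_equal(sum(res$terminal$probs), 1, tolerance = 1e-12)
    expect_equal(res$value, dist_mean(res$terminal))
  }
})

test_that("a b = 1 policy has value zero: no freedom to choose a path", {
  for (C in c(5, 25, 100))
    expect_equal(tree_value(rich1, policy_homogeneous(1, C))$value, 0,
                 tolerance = 1e-12)
})

test_that("exhaustive values grow with depth and breadth and stay under d", {
  vals <- outer(1:8, 1:4, Vectorize(function(d, b)
    tree_value(rich1, policy_exhaustive(b, d))$value))
  expect_true(all(diff(vals) >= 0))           # nondecreasing in d (flat at b = 1)
  expect_true(all(diff(vals[, 2:4]) > 0))     # strictly increasing once b > 1
  expect_true(all(t(diff(t(vals))) > 0))      # increasing in b at every d
  expect_true(all(vals <= matrix(1:8, 8, 4)))
})

test_that("value is monotone in each sampling probability", {
  base <- c(0.3, 0.6, 0.9)
  v0 <- tree_value(rich1, policy_heterogeneous(2, base))$value
  for (l in 1:3) {
    up <- base; up[l] <- up[l] + 0.05
    expect_gt(tree_value(rich1, policy_heterogeneous(2, up))$value, v0)
  }
})

test_that("family reductions collapse to the simpler policies", {
  m <- reward_model("poor", 2)
  # all-q = 1 selective equals exhaustive
  expect_equal(tree_value(m, policy_heterogeneous(2, rep(1, 3)))$value,
               tree_value(m, policy_exhaustive(2, 3))$value)
  # two-b with b1 = b2 equals the single-b homogeneous derivation
  expect_equal(tree_value(m, policy_two_b(2, 2, 2, 11))$value,
               tree_value(m, policy_homogeneous(2, 11))$value)
  # gamma = 1 equals the undiscounted policy
  q <- c(0.5, 1, 1)
  expect_identical(tree_value(rich1, policy_heterogeneous(2, q, gamma = 1))$value,
                   tree_value(rich1, policy_heterogeneous(2, q))$value)
  # gamma = 0 truncates to a depth-1 tree sampled with the first level's q
  deep <- policy_heterogeneous(2, c(0.3, 0.8, 0.6), gamma = 0)
  shallow <- policy_heterogeneous(2, 0.6)   # forward level 1 probability
  expect_equal(tree_value(rich1, deep)$value, tree_value(rich1, shallow)$value,
               tolerance = 1e-12)
  # all-q = 0 has value zero exactly
  expect_equal(tree_value(rich1, policy_heterogeneous(2, rep(0, 3)))$value, 0)
})

test_that("realized support size equals the distinct-state count", {
  for (n in 1:3) for (variant in c("rich", "poor")) {
    m <- reward_model(variant, n)
    pol <- policy_heterogeneous(2, rep(0.4, 5))
    expect_identical(length(dist_support(tree_value(m, pol)$terminal)),
                     as.integer(distinct_state_count(n, 5)))
  }
})
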