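test_that("enumeration reproduces hand-checkable expectations", {
  expect_equal(enumerate_tree_value(rich1, policy_exhaustive(2, 2)), 19 / 16)
  expect_equal(enumerate_tree_value(rich1, policy_heterogeneous(1, 1)), 0)
  expect_equal(enumerate_tree_value(rich1, policy_heterogeneous(2, 0.5)), 0.375)
  # and the genuinely naive 3^M configuration sweep agrees on a selective tree
  qf <- c(0.6, 0.3)
  expect_equal(enumerate_tree_value(rich1,
                                    policy_heterogeneous(2, qf, order = "forward")),
               brute_force_value(0.5, -1, b = 2, d = 2, q_fwd = qf),
               tolerance = 1e-12)
  expect_error(enumerate_tree_value(rich1, policy_exhaustive(3, 4),
                                    max_config = 100), "too large")
})

test_that("engine and enumeration agree across random fixtures", {
  kinds <- c("tiny_exhaustive", "tiny_selective", "tiny_two_b", "random_feasible_q")
  worst <- 0
  for (s in 1:24) {
    fx <- generate_fixture(kinds[(s %% 4) + 1], seed = s)
    v_engine <- tree_value(fx$model, fx$policy)$value
    v_enum <- enumerate_tree_value(fx$model, fx$policy)
    worst <- max(worst, abs(v_engine - v_enum))
  }
  expect_lt(worst, 1e-12)
})

test_that("fixtures are reproducible and respect their bounds", {
  a <- generate_fixture("tiny_selective", seed = 11)
  b <- generate_fixture("tiny_selective", seed = 11)
  expect_identical(a, b)
  ex <- generate_fixture("tiny_exhaustive", seed = 4)
  expect_lte(ex$policy$d, 3L)
  expect_lte(ex$policy$b, 3L)
  fq <- generate_fixture("random_feasible_q", seed = 5)
  expect_equal(capacity_of(fq$policy), fq$policy$C, tolerance = 1e-9)
})

test_that("Monte Carlo estimates are deterministic per seed and bracket the truth", {
  pol <- policy_exhaustive(2, 2)
  e1 <- mc_tree_value(rich1, pol, runs = 5000, seed = 9)
  e2 <- mc_tree_value(rich1, pol, runs = 5000, seed = 9)
  expect_identical(e1, e2)
  expect_lt(abs(e1$mean - 19 / 16), 4 * e1$standard_error)
  # a b = 1 chain has value zero
  chain <- mc_tree_value(rich1, policy_homogeneous(1, 10), runs = 5000, seed = 2)
  expect_lt(abs(chain$mean), 3 * chain$standard_error + 1e-12)
  # generic p is accepted here even though the exact engine refuses it
  g <- reward_model("generic", p = 0.37)
  eg <- mc_tree_value(g, policy_exhaustive(2, 2), runs = 2000, seed = 1)
  expect_true(is.finite(eg$mean))
})

test_that("MC agrees with the exact engine on selective and discounted trees", {
  cases <- list(policy_heterogeneous(2, c(0.4, 0.8, 1)),
                policy_heterogeneous(2, c(0.7, 1), gamma = 0.8),
                policy_two_b(2, 1, 1, 6))
  for (i in seq_along(cases)) {
    exact <- tree_value(rich1, cases[[i]])$value
    est <- mc_tree_value(rich1, cases[[i]], runs = 10000, seed = 100 + i)
    expect_lt(abs(est$mean - exact), 4 * est$standard_error)
  }
})

test_that("a randomly chosen path has zero expected cumulative reward", {
  for (m in list(rich1, reward_model("poor", 3), reward_model("generic", p = 0.23))) {
    est <- mc_tree_value(m, policy_exhaustive(3, 3), runs = 20000, seed = 12,
                         path = "random")
    expect_lt(abs(est$mean), 4 * est$standard_error)
  }
})
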