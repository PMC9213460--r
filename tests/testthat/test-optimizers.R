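test_that("projection onto the capacity plane is orthogonal and exact", {
  expect_equal(project_to_constraint(c(0, 0), 2, 3), c(0.3, 0.6))
  # a feasible point is returned unchanged (forward order: 2 + 4 + 4 = 10)
  q <- c(1, 1, 0.5)
  expect_equal(project_to_constraint(q, 2, 10), q)
  # correction is parallel to the weight vector
  set.seed(3)
  for (i in 1:10) {
    d <- sample(2:5, 1); b <- sample(2:3, 1)
    q0 <- runif(d)
    C <- runif(1, 1, 0.8 * sum(b^seq_len(d)))
    qp <- project_to_constraint(q0, b, C)
    w <- b^seq_len(d)
    expect_equal(sum(w * qp), C, tolerance = 1e-9)
    if (all(qp > 0 & qp < 1)) {
      diff <- qp - q0
      expect_equal(diff / w, rep(diff[1] / w[1], d), tolerance = 1e-9)
    }
  }
  # box and plane that cannot intersect
  expect_error(project_to_constraint(c(0.5, 0.5), 2, 10), "projection failed")
})

test_that("homogeneous optimum in a rich environment is two branches", {
  for (C in c(10, 100)) {
    rep <- optimize_homogeneous(rich1, C, b_range = 1:20)
    expect_identical(rep$best_params$b, 2L)
    expect_identical(rep$best_value, max(rep$candidates$value))
  }
  expect_error(optimize_homogeneous(rich1, 10, b_range = integer(0)), "empty")
})

test_that("poor environments at low capacity favor breadth", {
  rep <- optimize_homogeneous(reward_model("poor", 99), 10, b_range = 1:20)
  expect_gt(rep$best_params$b, 2L)
})

test_that("two-b grid restricted to the b1 regime reproduces the single-b optimum", {
  # with d1 = 10 and C = 6, capacity is exhausted inside the b1 regime for all
  # b1, so the family collapses to homogeneous single-b policies and b2 is a
  # pure tie: the lexicographic tie-break must pick b2 = 1
  two <- optimize_two_b(rich1, 6, b1_range = 1:4, b2_range = 1:3, d1_range = 10L)
  hom <- optimize_homogeneous(rich1, 6, b_range = 1:4)
  expect_equal(two$best_value, hom$best_value)
  expect_identical(two$best_params$b1, hom$best_params$b)
  expect_identical(two$best_params$b2, 1L)
  expect_identical(two$best_params$d2, 0L)
})

test_that("ascent leaves a fully determined depth-1 policy unchanged", {
  rep <- optimize_heterogeneous(rich1, C = 1.2, b = 2, d = 1,
                                settings = ascent_settings(max_iterations = 5))
  expect_equal(rep$best_params$q, 0.6)
  expect_equal(rep$best_value,
               tree_value(rich1, policy_heterogeneous(2, 0.6))$value)
})

test_that("ascent improves monotonically and stays feasible", {
  rep <- optimize_heterogeneous(rich1, C = 10, b = 2, d = 6,
                                settings = ascent_settings(max_iterations = 300))
  expect_true(all(diff(rep$trajectory) >= 0))
  q <- rep$best_params$q
  expect_true(all(q >= 0 & q <= 1))
  expect_equal(sum(q * 2^seq_len(6)), 10, tolerance = 1e-9)
  # beats the homogeneous policy it started from (or at worst matches it)
  expect_gte(rep$best_value, tree_value(rich1, policy_homogeneous(2, 10))$value)
})

test_that("ascent value is insensitive to the starting point", {
  vals <- sapply(1:3, function(s) optimize_heterogeneous(
    rich1, C = 3, b = 2, d = 3,
    settings = ascent_settings(max_iterations = 2e4, init = "random",
                               seed = s))$best_value)
  expect_lt(diff(range(vals)), 1e-4)
})

test_that("infeasible starting sets are rejected", {
  expect_error(optimize_heterogeneous(rich1, C = 100, b = 2, d = 2),
               "no feasible q")
})
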