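#' Expected number of samples allocated by a policy
#'
#' The average-capacity constraint ties a policy's parameters to the capacity
#' `C`: the expected number of sampled nodes is the sum over levels of the
#' level size times its sampling probability. For a single branching factor
#' `b`, level `l` holds `b^l` nodes, so `C = sum_l q[d - l + 1] * b^l` (note
#' the backward storage order of `q`). For two-`b` policies, levels `l <= d1`
#' hold `b1^l` nodes and deeper levels hold `b1^d1 * b2^(l - d1)`.
#'
#' @param policy a `bd_policy`.
#' @return the expected number of allocated samples.
#' @examples
#' capacity_of(policy_heterogeneous(b = 2, q = c(0.5, 1, 1)))  # 2 + 4 + 4 = 10
#' @export
capacity_of <- function(policy) {
  stopifnot(inherits(policy, "bd_policy"))
  q_fwd <- rev(policy$q)
  d <- policy$d
  if (policy$family == "two_b") {
    d1 <- policy$d1
    sizes <- c(policy$b1^seq_len(d1),
               if (d > d1) policy$b1^d1 * policy$b2^seq_len(d - d1))
  } else {
    sizes <- policy$b^seq_len(d)
  }
  sum(q_fwd * sizes)
}

#' Derive a homogeneous allocation from branching factor and capacity
#'
#' Full levels (`q = 1`) are stacked from the root until capacity would be
#' exceeded: the depth reached `d` is the largest for which the first `d - 1`
#' full levels cost strictly less than `C`, so that the residual
#' `C_r = C - sum_{l < d} b^l` is positive. Each of the `b^d` nodes of the
#' last level is then sampled independently with probability `q1 = C_r / b^d`.
#' When `C` exactly fills `m` levels the derivation returns depth `m` with
#' `q1 = 1` rather than a vacuous extra level with `q1 = 0`.
#'
#' @param b positive integer branching factor.
#' @param C capacity, at least 1.
#' @return list with `depth_reached`, `last_level_q`, `residual` (`C_r`) and
#'   `expected_cost` (equal to `C`).
#' @examples
#' derive_homogeneous(2, 10)   # depth 3, q1 = 0.5
#' derive_homogeneous(3, 2)    # depth 1, q1 = 2/3
#' @export
derive_homogeneous <- function(b, C) {
  b <- check_b(b)
  if (length(C) != 1L || !is.finite(C) || C < 1) stop("C must be a number >= 1")
  d <- 1L
  full_cost <- 0          # cost of levels 1 .. d-1 at q = 1
  while (full_cost + b^d < C) {
    full_cost <- full_cost + b^d
    d <- d + 1L
  }
  residual <- C - full_cost
  q1 <- residual / b^d
  list(depth_reached = d, last_level_q = q1, residual = residual,
       expected_cost = full_cost + q1 * b^d)
}

#' Derive a two-branching-factor allocation from (b1, b2, d1) and capacity
#'
#' The first `d1` levels branch with `b1` at `q = 1`; below them the tree
#' branches with `b2` for `d2` further levels, where `d2` is the largest depth
#' whose preceding levels cost strictly less than `C`. The residual
#' `C_r = C - sum_{l<=d1} b1^l - b1^d1 * sum_{l < d2} b2^l` is spread over the
#' `b1^d1 * b2^d2` deepest nodes with probability `q1 = C_r / (b1^d1 * b2^d2)`.
#' If capacity is exhausted within the first `d1` levels the derivation
#' truncates inside the `b1` regime (`d2 = 0`, effective `d1` possibly smaller
#' than requested) and `b2` plays no role, reproducing the single-`b`
#' homogeneous derivation with `b = b1`.
#'
#' @param b1,b2 positive integer branching factors.
#' @param d1 requested switching depth, at least 1.
#' @param C capacity, at least 1.
#' @return list with `d1` (effective), `d2`, `depth_reached` (`d1 + d2`),
#'   `last_level_q`, `residual` and `expected_cost`.
#' @examples
#' derive_two_b(2, 1, 1, 8)   # d2 = 3, q1 = 1
#' derive_two_b(3, 1, 1, 7)   # d2 = 2, q1 = 1/3
#' @export
derive_two_b <- function(b1, b2, d1, C) {
  b1 <- check_b(b1, "b1"); b2 <- check_b(b2, "b2")
  if (length(d1) != 1L || d1 < 1 || d1 != round(d1)) stop("d1 must be a positive integer")
  if (length(C) != 1L || !is.finite(C) || C <= 0) stop("C must be positive")
  d1 <- as.integer(d1)
  cost_b1 <- sum(b1^seq_len(d1))
  if (cost_b1 >= C) {
    der <- derive_homogeneous(b1, C)
    return(list(d1 = der$depth_reached, d2 = 0L,
                depth_reached = der$depth_reached,
                last_level_q = der$last_level_q, residual = der$residual,
                expected_cost = der$expected_cost))
  }
  base <- b1^d1
  d2 <- 1L
  full_cost <- cost_b1    # cost of all full levels above the last one
  while (full_cost + base * b2^d2 < C) {
    full_cost <- full_cost + base * b2^d2
    d2 <- d2 + 1L
  }
  residual <- C - full_cost
  q1 <- residual / (base * b2^d2)
  list(d1 = d1, d2 = d2, depth_reached = d1 + d2,
       last_level_q = q1, residual = residual,
       expected_cost = full_cost + q1 * base * b2^d2)
}

#' Random-allocation baseline policy
#'
#' Allocates samples with the same probability to every node of a tree of
#' depth `d = 2 * floor(log(C) / log(b)) + 3`, the depth cap also used for the
#' heterogeneous optimizer so that random and optimized policies can spread
#' samples over the same levels. The uniform probability
#' `q = C / sum_{l=1..d} b^l` satisfies the average-capacity constraint.
#'
#' @param b branching factor, at least 2 (the depth cap diverges at `b = 1`).
#' @param C capacity, at least 1.
#' @return a `bd_policy` of family `random_baseline`.
#' @examples
#' random_allocation(2, 10)   # depth 9, q = 10/1022
#' @export
random_allocation <- function(b, C) {
  b <- check_b(b)
  if (b < 2) stop("the random baseline requires b >= 2")
  if (length(C) != 1L || !is.finite(C) || C < 1) stop("C must be a number >= 1")
  d <- capped_depth(b, C)
  total <- sum(b^seq_len(d))
  qu <- C / total
  if (qu > 1)
    stop("capacity exceeds the size of the depth-capped tree; uniform q would exceed 1")
  pol <- new_policy("random_baseline", b = b, d = d, q = rep(qu, d), C = C)
  pol
}

#' Depth cap used for heterogeneous and random policies
#'
#' `d = 2 * floor(log(C) / log(b)) + 3`, roughly twice the depth a homogeneous
#' policy reaches, plus slack, so that optimized heterogeneous policies are
#' free to spread samples well beyond the homogeneous depth.
#'
#' @param b branching factor (>= 2).
#' @param C capacity.
#' @return integer depth.
#' @export
capped_depth <- function(b, C) {
  as.integer(2L * floor(log(C) / log(b)) + 3L)
}
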