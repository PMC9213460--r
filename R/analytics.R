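#' Probability that the optimal path is fully rewarded
#'
#' Iterates the recursion for the probability that a fully sampled tree of
#' depth `d` and branching factor `b` contains a path whose every node
#' carries the high reward, i.e. `P(J_d = d)`:
#' `P(J_1 = 1) = 1 - (1 - p)^b` and, for `d > 1`,
#' `P(J_d = d) = 1 - (1 - p * P(J_{d-1} = d-1))^b`.
#'
#' @param p probability of a high reward in (0, 1).
#' @param b positive integer branching factor.
#' @param d_max number of levels to iterate.
#' @return an object of class `success_curve` with `values` (`P(J_d = d)` for
#'   `d = 1..d_max`) and `limit`, the large-depth fixed point (see
#'   [success_fixed_point()]).
#' @examples
#' success_probability(0.5, 2, 5)$values[1]   # 3/4
#' @export
success_probability <- function(p, b, d_max) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  b <- check_b(b)
  if (d_max < 1 || d_max != round(d_max)) stop("d_max must be a positive integer")
  values <- numeric(d_max)
  values[1L] <- 1 - (1 - p)^b
  if (d_max > 1L) for (d in 2:d_max)
    values[d] <- 1 - (1 - p * values[d - 1L])^b
  structure(list(p = p, b = b, values = values,
                 limit = success_fixed_point(p, b)),
            class = "success_curve")
}

#' @export
print.success_curve <- function(x, ...) {
  cat(sprintf("Success probability P(J_d = d), p = %g, b = %d\n", x$p, x$b))
  d_show <- unique(pmin(c(1:5, 10, 20, 50, 100, length(x$values)), length(x$values)))
  print(data.frame(d = d_show, prob = x$values[d_show]))
  cat(sprintf("large-depth fixed point: %g (p*b %s 1)\n", x$limit,
              if (x$p * x$b > 1) ">" else "<="))
  invisible(x)
}

#' Large-depth fixed point of the success-probability recursion
#'
#' The recursion converges to a solution of `1 - P = (1 - p * P)^b`. The
#' right-hand side is convex and decreasing in `P` with slope `-p * b` at the
#' origin, so a nonzero solution exists only when `p * b > 1`; otherwise the
#' only fixed point in `[0, 1]` is `P = 0` and every path is eventually
#' blocked by negative-reward nodes with probability one. When `p * b > 1`
#' the unique positive root in `(0, 1]` is found by bracketed root-finding.
#'
#' @param p probability of a high reward in (0, 1).
#' @param b positive integer branching factor.
#' @return the fixed-point probability, resolved to `1e-12`.
#' @examples
#' success_fixed_point(0.5, 2)   # 0: p*b = 1
#' success_fixed_point(0.5, 3)   # positive root of 1 - P = (1 - P/2)^3
#' @export
success_fixed_point <- function(p, b) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  b <- check_b(b)
  if (p * b <= 1) return(0)
  f <- function(P) 1 - (1 - p * P)^b - P
  stats::uniroot(f, c(1e-15, 1), tol = 1e-14)$root
}

#' Number of distinct lattice states at a level
#'
#' For rational models indexed by `n`, the cumulative reward at level `s`
#' takes values `k = i - n*j` (rich; `i - j/n` for poor) with `i, j >= 0` and
#' `i + j <= s`. Distinct values number `(s + 1)(s + 2) / 2` while `s < n`
#' (no collisions yet) and `(n + 1)s - n(n - 1)/2 + 1` for `s >= n`, which
#' grows only linearly in `s` and is what makes the recursion polynomial.
#'
#' @param n positive integer rational index.
#' @param s level, at least 1.
#' @return integer count of distinct states.
#' @examples
#' distinct_state_count(1, 5)   # 2*5 + 1 = 11
#' distinct_state_count(3, 2)   # 6
#' @export
distinct_state_count <- function(n, s) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (s < 1 || s != round(s)) stop("s must be a positive integer")
  if (s < n) (s + 1) * (s + 2) / 2 else (n + 1) * s - n * (n - 1) / 2 + 1
}

#' Relative loss of a policy against the optimum, in percent
#'
#' `100 * (v_opt - v) / v_opt`: the percentage of the optimal value lost by
#' playing a suboptimal policy.
#'
#' @param v_opt value of the optimal policy; must be positive.
#' @param v value of the policy under comparison.
#' @return loss in percent (0 when `v = v_opt`, 100 when `v = 0`).
#' @export
relative_loss <- function(v_opt, v) {
  if (!is.numeric(v_opt) || any(v_opt <= 0))
    stop("relative loss is undefined for v_opt <= 0")
  100 * (v_opt - v) / v_opt
}

#' Number of nodes in the sampled sub-tree
#'
#' `sum_{l=1..d} b^l`, excluding the root. Illustrates the scale the exact
#' recursion handles: a depth-20, branching-5 sub-tree holds more than
#' `2e13` nodes yet its value is computed in a fraction of a second.
#'
#' @param b branching factor.
#' @param d depth.
#' @return node count (double, as counts overflow integers quickly).
#' @export
subtree_node_count <- function(b, d) {
  b <- check_b(b)
  if (d < 1 || d != round(d)) stop("d must be a positive integer")
  if (b == 1) return(as.numeric(d))
  b * (b^d - 1) / (b - 1)
}
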