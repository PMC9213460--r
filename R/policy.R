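#' Allocation policy constructors
#'
#' A policy describes how the agent spreads its samples over the first levels
#' of an infinitely large decision tree. All families share the same internal
#' representation: a total depth `d`, per-level sampling probabilities `q`
#' stored in *backward* order (`q[1]` is the deepest level, matching the
#' backward recursion of the value engine), a per-level branching factor, a
#' survival/discount probability `gamma`, and optionally the capacity `C` the
#' policy was derived from.
#'
#' * `policy_exhaustive(b, d)`: every node of the depth-`d`, branching-`b`
#'   sub-tree is sampled (`q = 1` everywhere).
#' * `policy_homogeneous(b, C)`: full levels with branching `b` as deep as
#'   capacity `C` allows; the last level absorbs the residual with probability
#'   `q1 = C_r / b^d` (see [derive_homogeneous()]).
#' * `policy_heterogeneous(b, q)`: free per-level sampling probabilities.
#'   `q` may be given in forward (root-first) order with `order = "forward"`.
#' * `policy_two_b(b1, b2, d1, C)`: branching `b1` over the first `d1` levels,
#'   then `b2` until capacity is exhausted (see [derive_two_b()]). With
#'   `d2 = 0` or `b1 = b2` this family reduces to the single-`b` ones.
#'   Discounting is restricted to the single-`b` families, so `gamma` is
#'   fixed at 1 here.
#' * [random_allocation()]: uniform sampling probability over a depth-capped
#'   tree, the baseline the optimized families are compared against.
#'
#' @param b,b1,b2 positive integer branching factors.
#' @param d,d1 positive integer depths (levels counted from the root).
#' @param C capacity: average number of allocated samples.
#' @param q numeric vector of per-level sampling probabilities in `[0, 1]`.
#' @param gamma survival probability in `[0, 1]`; with probability `1 - gamma`
#'   per level the continuation value is lost and only the immediate reward
#'   counts. `gamma = 1` recovers the undiscounted setting.
#' @param order `"backward"` (default, `q[1]` = deepest level) or `"forward"`
#'   (`q[1]` = first level below the root).
#' @return An object of class `bd_policy`.
#' @examples
#' policy_exhaustive(b = 2, d = 3)
#' policy_homogeneous(b = 2, C = 10)      # d = 3, q1 = 0.5
#' policy_two_b(b1 = 2, b2 = 1, d1 = 1, C = 8)
#' @name policies
NULL

new_policy <- function(family, b = NA_integer_, b1 = NA_integer_, b2 = NA_integer_,
                       d1 = NA_integer_, d2 = NA_integer_, d, q, gamma = 1,
                       C = NA_real_, derivation = NULL) {
  stopifnot(length(q) == d)
  if (any(q < -1e-12 | q > 1 + 1e-12))
    stop("all sampling probabilities q must lie in [0, 1]")
  q <- pmin(pmax(q, 0), 1)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  structure(list(family = family, b = b, b1 = b1, b2 = b2, d1 = d1, d2 = d2,
                 d = as.integer(d), q = as.numeric(q), gamma = as.numeric(gamma),
                 C = C, derivation = derivation),
            class = "bd_policy")
}

check_b <- function(b, name = "b") {
  if (length(b) != 1L || !is.finite(b) || b < 1 || b != round(b))
    stop(sprintf("%s must be a positive integer branching factor", name))
  as.integer(b)
}

#' @rdname policies
#' @export
policy_exhaustive <- function(b, d, gamma = 1) {
  b <- check_b(b)
  if (length(d) != 1L || d < 1 || d != round(d)) stop("d must be a positive integer")
  new_policy("exhaustive", b = b, d = d, q = rep(1, d), gamma = gamma)
}

#' @rdname policies
#' @export
policy_homogeneous <- function(b, C, gamma = 1) {
  b <- check_b(b)
  der <- derive_homogeneous(b, C)
  d <- der$depth_reached
  new_policy("homogeneous", b = b, d = d,
             q = c(der$last_level_q, rep(1, d - 1L)),
             gamma = gamma, C = C, derivation = der)
}

#' @rdname policies
#' @export
policy_heterogeneous <- function(b, q, gamma = 1, order = c("backward", "forward")) {
  b <- check_b(b)
  order <- match.arg(order)
  if (order == "forward") q <- rev(q)
  pol <- new_policy("heterogeneous", b = b, d = length(q), q = q, gamma = gamma)
  pol$C <- capacity_of(pol)
  pol
}

#' @rdname policies
#' @export
policy_two_b <- function(b1, b2, d1, C) {
  b1 <- check_b(b1, "b1"); b2 <- check_b(b2, "b2")
  if (length(d1) != 1L || d1 < 1 || d1 != round(d1)) stop("d1 must be a positive integer")
  der <- derive_two_b(b1, b2, d1, C)
  d2 <- der$d2
  d1_eff <- der$d1                      # truncated when C runs out inside the b1 regime
  d <- d1_eff + d2
  new_policy("two_b", b1 = b1, b2 = b2, d1 = as.integer(d1_eff), d2 = as.integer(d2),
             d = d, q = c(der$last_level_q, rep(1, d - 1L)),
             gamma = 1, C = C, derivation = der)
}

#' Per-level branching factors in backward order
#'
#' The value engine runs backward from the deepest level; for two-`b` policies
#' the first `d2` backward steps use `b2` and the remaining `d1` use `b1`.
#'
#' @param policy a `bd_policy`.
#' @return integer vector of length `policy$d`, `[1]` = deepest level.
#' @export
policy_branching <- function(policy) {
  stopifnot(inherits(policy, "bd_policy"))
  if (policy$family == "two_b") {
    c(rep(policy$b2, policy$d2), rep(policy$b1, policy$d1))
  } else {
    rep(policy$b, policy$d)
  }
}

#' @export
print.bd_policy <- function(x, ...) {
  hdr <- switch(x$family,
    exhaustive = sprintf("exhaustive, b = %d, d = %d", x$b, x$d),
    homogeneous = sprintf("homogeneous, b = %d, d = %d, q1 = %.6g", x$b, x$d, x$q[1]),
    heterogeneous = sprintf("heterogeneous, b = %d, d = %d", x$b, x$d),
    two_b = sprintf("two-b, b1 = %d (d1 = %d), b2 = %d (d2 = %d), q1 = %.6g",
                    x$b1, x$d1, x$b2, x$d2, x$q[1]),
    random_baseline = sprintf("random baseline, b = %d, d = %d, q = %.6g", x$b, x$d, x$q[1]))
  cat("Allocation policy:", hdr, "\n")
  if (x$gamma < 1) cat(sprintf("  survival probability gamma = %g\n", x$gamma))
  if (is.finite(x$C)) cat(sprintf("  capacity C = %g (expected samples %.10g)\n",
                                  x$C, capacity_of(x)))
  invisible(x)
}
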