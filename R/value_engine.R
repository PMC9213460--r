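# Core backward recursion, free of S3 overhead so optimizers can call it in a
# hot loop. Probabilities live on the integer lattice: key k <-> value k/scale,
# a positive reward shifts a key by sp (= scale), a negative one by sm
# (= scale * r_minus, a negative integer). q and bvec are in backward order
# (element 1 = deepest level). Every level renormalizes P(J) to sum one.
dm_core <- function(p, sp, sm, q, bvec, gamma) {
  d <- length(q)
  width <- sp - sm
  kmin <- sm
  probs <- numeric(width + 1L)
  probs[1L] <- q[1L] * (1 - p)                 # key sm
  probs[-kmin + 1L] <- 1 - q[1L]               # key 0
  probs[sp - kmin + 1L] <- probs[sp - kmin + 1L] + q[1L] * p
  cdf <- cumsum(probs)^bvec[1L]
  probs <- diff(c(0, cdf)) / cdf[length(cdf)]
  if (d > 1L) for (t in 2:d) {
    len <- length(probs)
    out <- numeric(len + width)
    qt <- q[t]
    stay <- (1 - qt) * gamma
    up <- qt * p * gamma
    down <- qt * (1 - p) * gamma
    idx <- seq_len(len)
    out[idx] <- down * probs
    out[idx - sm] <- out[idx - sm] + stay * probs
    out[idx + width] <- out[idx + width] + up * probs
    if (gamma < 1) {
      out_kmin <- kmin + sm
      out[sp - out_kmin + 1L] <- out[sp - out_kmin + 1L] + qt * p * (1 - gamma)
      out[-out_kmin + 1L] <- out[-out_kmin + 1L] + (1 - qt) * (1 - gamma)
      out[sm - out_kmin + 1L] <- out[sm - out_kmin + 1L] + qt * (1 - p) * (1 - gamma)
    }
    cdf <- cumsum(out)^bvec[t]
    probs <- diff(c(0, cdf)) / cdf[length(cdf)]
    kmin <- kmin + sm
  }
  list(probs = probs, kmin = kmin)
}

dm_value <- function(model, q, bvec, gamma = 1) {
  res <- dm_core(model$p, model$shift_plus, model$shift_minus, q, bvec, gamma)
  sum(seq.int(res$kmin, length.out = length(res$probs)) * res$probs) / model$scale
}

#' Distribution of the deepest level's state value
#'
#' Starts the backward recursion: each of the `b_eff` deepest branches carries
#' an action value in `{R-, 0, R+}` with probabilities `q1 * (1 - p)`,
#' `1 - q1` and `q1 * p` (sampled or not, then high or low reward), and the
#' maximization over the `b_eff` i.i.d. branches yields the state value `J_1`.
#' For two-`b` policies `b_eff` is `b2`, the branching factor of the deep
#' regime.
#'
#' @param model a rational [reward_model()].
#' @param q1 sampling probability of the deepest level, in `[0, 1]`.
#' @param b_eff branching factor at the deepest level.
#' @return a `value_dist` with role `"J"` at depth 1.
#' @examples
#' m <- reward_model("rich", 1)
#' initial_level_distribution(m, q1 = 1, b_eff = 2)    # P(+1) = 3/4
#' initial_level_distribution(m, q1 = 0.5, b_eff = 2)  # P(+1) = 0.4375
#' @export
initial_level_distribution <- function(model, q1, b_eff) {
  stop_if_generic(model)
  b_eff <- check_b(b_eff, "b_eff")
  if (q1 < 0 || q1 > 1) stop("q1 must lie in [0, 1]")
  res <- dm_core(model$p, model$shift_plus, model$shift_minus, q1, b_eff, 1)
  new_value_dist(res$probs, res$kmin, model$scale, depth = 1L, role = "J")
}

#' Diffusion step: from state values to action values one level up
#'
#' Maps `P(J_{d-1})` to `P(Q_d)` where `Q_d = R_d + J_{d-1}`: each mass at
#' lattice key `k` stays at `k` with probability `(1 - q) * gamma` (node not
#' sampled), moves to `k + R+` with `q * p * gamma` and to `k + R-` with
#' `q * (1 - p) * gamma`. With probability `1 - gamma` the agent does not
#' survive to collect the continuation, so only the immediate reward
#' contributes: mass `q * p * (1 - gamma)` at `R+`, `(1 - q) * (1 - gamma)`
#' at 0 and `q * (1 - p) * (1 - gamma)` at `R-`. `gamma = 1` recovers the
#' undiscounted step; keys outside the prior's lattice contribute zero.
#'
#' @param model a rational [reward_model()] sharing the prior's lattice scale.
#' @param prior a `value_dist` with role `"J"`.
#' @param q sampling probability of the level being added.
#' @param gamma survival probability.
#' @return a `value_dist` with role `"Q"` at depth `prior$depth + 1`.
#' @export
diffusion_step <- function(model, prior, q, gamma = 1) {
  stop_if_generic(model)
  stopifnot(inherits(prior, "value_dist"))
  if (prior$role != "J") stop("'prior' must be a state-value (role J) distribution")
  if (prior$scale != model$scale)
    stop("lattice scale of 'prior' does not match 'model'")
  if (q < 0 || q > 1 || gamma < 0 || gamma > 1) stop("q and gamma must lie in [0, 1]")
  sp <- model$shift_plus; sm <- model$shift_minus
  len <- length(prior$probs)
  width <- sp - sm
  out <- numeric(len + width)
  idx <- seq_len(len)
  out[idx] <- q * (1 - model$p) * gamma * prior$probs
  out[idx - sm] <- out[idx - sm] + (1 - q) * gamma * prior$probs
  out[idx + width] <- out[idx + width] + q * model$p * gamma * prior$probs
  out_kmin <- prior$kmin + sm
  if (gamma < 1) {
    out[sp - out_kmin + 1L] <- out[sp - out_kmin + 1L] + q * model$p * (1 - gamma)
    out[-out_kmin + 1L] <- out[-out_kmin + 1L] + (1 - q) * (1 - gamma)
    out[sm - out_kmin + 1L] <- out[sm - out_kmin + 1L] + q * (1 - model$p) * (1 - gamma)
  }
  new_value_dist(out, out_kmin, model$scale, depth = prior$depth + 1L, role = "Q")
}

#' Maximization step: best of b i.i.d. action values
#'
#' Maps `P(Q_d)` to `P(J_d)` through the order statistic of the maximum:
#' `P(J_d = k) = P(Q_d <= k)^b - P(Q_d <= k - 1)^b`, i.e. the CDF raised to
#' the `b`-th power at every lattice key. The emitted distribution is
#' renormalized to sum one.
#'
#' @param qdist a `value_dist` with role `"Q"`.
#' @param b_level positive integer number of available branches at this level.
#' @return a `value_dist` with role `"J"` at the same depth.
#' @examples
#' m <- reward_model("rich", 1)
#' q1 <- diffusion_step(m, initial_level_distribution(m, 1, 1), q = 1)
#' maximization_step(q1, 2)
#' @export
maximization_step <- function(qdist, b_level) {
  stopifnot(inherits(qdist, "value_dist"))
  if (qdist$role != "Q") stop("'qdist' must be an action-value (role Q) distribution")
  b_level <- check_b(b_level, "b_level")
  cdf <- cumsum(qdist$probs)^b_level
  probs <- diff(c(0, cdf)) / cdf[length(cdf)]
  new_value_dist(probs, qdist$kmin, qdist$scale, depth = qdist$depth, role = "J")
}

#' Value of playing a tree under an allocation policy
#'
#' Runs the diffusion-maximization recursion backward over the levels of the
#' sampled sub-tree: the deepest level's state-value distribution is built
#' first ([initial_level_distribution()]), then each shallower level adds a
#' diffusion step and a maximization step with its own sampling probability
#' and branching factor, until the root is reached. The tree value is the mean
#' of the terminal (root-level) distribution,
#' `V = E(J_d) = sum(value * probability)`. The cost is `O(n * b * d^2)`
#' operations, against `O(b^d)` for naive backward induction on the tree.
#'
#' @param model a rational [reward_model()].
#' @param policy a fully resolved `bd_policy` (see [policies]).
#' @return an object of class `tree_value_result` with fields `value`,
#'   `terminal` (the root `value_dist`), `policy` and `model`.
#' @examples
#' m <- reward_model("rich", 1)
#' tree_value(m, policy_exhaustive(b = 2, d = 2))$value   # 19/16
#' tree_value(m, policy_homogeneous(b = 2, C = 10))$value
#' @export
tree_value <- function(model, policy) {
  stop_if_generic(model)
  stopifnot(inherits(policy, "bd_policy"))
  if (length(policy$q) != policy$d)
    stop("policy q vector length does not match its depth")
  bvec <- policy_branching(policy)
  res <- dm_core(model$p, model$shift_plus, model$shift_minus,
                 policy$q, bvec, policy$gamma)
  terminal <- new_value_dist(res$probs, res$kmin, model$scale,
                             depth = policy$d, role = "J")
  structure(list(value = dist_mean(terminal), terminal = terminal,
                 policy = policy, model = model),
            class = "tree_value_result")
}

#' @export
print.tree_value_result <- function(x, ...) {
  cat(sprintf("Tree value V = %.10g\n", x$value))
  print(x$policy)
  print(x$model)
  invisible(x)
}
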