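# Aggregate duplicate integer keys, dropping zero mass.
aggregate_keys <- function(keys, probs) {
  keep <- probs != 0
  keys <- keys[keep]; probs <- probs[keep]
  tot <- rowsum(probs, keys)
  list(keys = as.integer(rownames(tot)), probs = as.numeric(tot))
}

# Distribution of the max of b i.i.d. draws by explicit enumeration of the
# m^b joint outcomes (deliberately not the CDF-power shortcut the engine uses).
max_enum <- function(keys, probs, b, max_config = 2e6) {
  m <- length(keys)
  if (b == 1L) return(list(keys = keys, probs = probs))
  if (m^b > max_config)
    stop("instance too large to enumerate (", m, "^", b, " joint outcomes)")
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(m)), b)))
  vals <- keys[idx[, 1L]]
  w <- probs[idx[, 1L]]
  for (j in 2:b) {
    vals <- pmax(vals, keys[idx[, j]])
    w <- w * probs[idx[, j]]
  }
  aggregate_keys(vals, w)
}

#' Exact tree value by explicit enumeration
#'
#' Independent cross-check of [tree_value()]: computes the same expectation
#' without the diffusion-maximization machinery. Level by level (backward),
#' the distribution of a branch's action value is built by enumerating the
#' sampling/reward/survival outcomes of the node explicitly, and the best of
#' the `b` i.i.d. branches is obtained by enumerating all `m^b` joint
#' configurations of their supports rather than raising the CDF to a power.
#' The cost grows as `support^b` per level, so only small instances (depth up
#' to roughly 5, `b` up to 3) are feasible; larger instances raise an error.
#'
#' @param model a rational [reward_model()].
#' @param policy a `bd_policy` of any family.
#' @param max_config cap on the number of joint configurations enumerated per
#'   maximization.
#' @return the exact expected cumulative reward of the optimal path.
#' @examples
#' m <- reward_model("rich", 1)
#' enumerate_tree_value(m, policy_exhaustive(2, 2))   # 19/16
#' @export
enumerate_tree_value <- function(model, policy, max_config = 2e6) {
  stop_if_generic(model)
  stopifnot(inherits(policy, "bd_policy"))
  q <- policy$q
  bvec <- policy_branching(policy)
  gamma <- policy$gamma
  sp <- model$shift_plus; sm <- model$shift_minus; p <- model$p
  rew <- c(sp, 0L, sm)
  # deepest level: branch action value in {R+, 0, R-}
  wr <- c(q[1L] * p, 1 - q[1L], q[1L] * (1 - p))
  dist <- aggregate_keys(rew, wr)
  dist <- max_enum(dist$keys, dist$probs, bvec[1L], max_config)
  for (t in seq_along(q)[-1L]) {
    wr <- c(q[t] * p, 1 - q[t], q[t] * (1 - p))
    nk <- integer(0); np <- numeric(0)
    for (j in 1:3) {
      if (wr[j] == 0) next
      nk <- c(nk, dist$keys + rew[j])        # survives: reward + continuation
      np <- c(np, dist$probs * wr[j] * gamma)
      if (gamma < 1) {                       # dies: immediate reward only
        nk <- c(nk, rew[j])
        np <- c(np, wr[j] * (1 - gamma))
      }
    }
    agg <- aggregate_keys(nk, np)
    dist <- max_enum(agg$keys, agg$probs, bvec[t], max_config)
  }
  sum(dist$keys * dist$probs) / model$scale
}

#' Bellman-Monte-Carlo estimate of the tree value
#'
#' Instantiates the sampled sub-tree explicitly: per run, every node draws a
#' sampling flag (Bernoulli with its level's `q`), sampled nodes draw `R+`
#' with probability `p` and `R-` otherwise, unsampled nodes keep reward 0,
#' and (when `gamma < 1`) every internal node draws a survival coin that
#' zeroes its continuation. Backward induction
#' `V(s) = R(s) + max over children of V(child)` then yields the root value of
#' the realization, and the estimate is the mean over runs. Works for any
#' `p` in (0, 1), including generic models the exact engine rejects.
#'
#' With `path = "random"` the maximization is replaced by a uniformly random
#' child choice, which estimates the value of a random path (zero under the
#' zero-average constraint, for any model).
#'
#' @param model a [reward_model()] (any variant).
#' @param policy a `bd_policy`.
#' @param runs number of Monte-Carlo realizations.
#' @param seed RNG seed; identical seeds give identical estimates.
#' @param path `"optimal"` (backward induction) or `"random"`.
#' @param max_nodes refuse trees with more nodes than this.
#' @return an object of class `mc_estimate` with `mean`, `standard_error`
#'   (sample sd / sqrt(runs)), `runs` and `seed`.
#' @examples
#' m <- reward_model("rich", 1)
#' mc_tree_value(m, policy_exhaustive(2, 2), runs = 2000, seed = 1)
#' @export
mc_tree_value <- function(model, policy, runs, seed = 0L,
                          path = c("optimal", "random"), max_nodes = 1e6) {
  stopifnot(inherits(model, "reward_model"), inherits(policy, "bd_policy"))
  path <- match.arg(path)
  if (runs < 1 || runs != round(runs)) stop("runs must be a positive integer")
  bvec_fwd <- rev(policy_branching(policy))
  q_fwd <- rev(policy$q)
  d <- policy$d
  sizes <- cumprod(bvec_fwd)
  if (sum(sizes) > max_nodes)
    stop("tree too large to instantiate (", sum(sizes), " nodes)")
  p <- model$p; rp <- model$r_plus; rm <- model$r_minus; gamma <- policy$gamma
  set.seed(seed)
  chunk <- max(1L, min(as.integer(runs), as.integer(floor(4e6 / sum(sizes)))))
  roots <- numeric(runs)
  done <- 0L
  while (done < runs) {
    nr <- min(chunk, runs - done)
    # draw rewards per level: sizes[l] x nr matrices
    vals <- vector("list", d)
    for (l in seq_len(d)) {
      nn <- sizes[l] * nr
      sampled <- stats::runif(nn) < q_fwd[l]
      r <- numeric(nn)
      r[sampled] <- ifelse(stats::runif(sum(sampled)) < p, rp, rm)
      vals[[l]] <- matrix(r, nrow = sizes[l], ncol = nr)
    }
    # backward induction
    v <- vals[[d]]
    if (d > 1L) for (l in (d - 1L):1L) {
      bl <- bvec_fwd[l + 1L]
      m <- matrix(v, nrow = bl)               # children of level-l nodes, stacked
      if (path == "optimal") {
        best <- m[1L, ]
        if (bl > 1L) for (i in 2:bl) best <- pmax(best, m[i, ])
      } else {
        pick <- sample.int(bl, ncol(m), replace = TRUE)
        best <- m[cbind(pick, seq_len(ncol(m)))]
      }
      cont <- matrix(best, nrow = sizes[l], ncol = nr)
      if (gamma < 1) {
        surv <- matrix(stats::runif(sizes[l] * nr) < gamma, nrow = sizes[l])
        cont <- cont * surv
      }
      v <- vals[[l]] + cont
    }
    b1 <- bvec_fwd[1L]
    m <- matrix(v, nrow = b1)
    if (path == "optimal") {
      best <- m[1L, ]
      if (b1 > 1L) for (i in 2:b1) best <- pmax(best, m[i, ])
    } else {
      pick <- sample.int(b1, ncol(m), replace = TRUE)
      best <- m[cbind(pick, seq_len(ncol(m)))]
    }
    roots[done + seq_len(nr)] <- best
    done <- done + nr
  }
  est <- list(mean = mean(roots),
              standard_error = stats::sd(roots) / sqrt(runs),
              runs = as.integer(runs), seed = as.integer(seed), path = path)
  structure(est, class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo tree value: %.6g +/- %.3g (SE, %d runs, seed %d%s)\n",
              x$mean, x$standard_error, x$runs, x$seed,
              if (x$path == "random") ", random path" else ""))
  invisible(x)
}

#' Reproducible small test instances
#'
#' Draws a tiny model/policy pair inside the enumeration limits of
#' [enumerate_tree_value()], reproducibly from a seed.
#'
#' @param kind `"tiny_exhaustive"` (d, b <= 3), `"tiny_selective"` (random
#'   per-level q, occasionally discounted), `"tiny_two_b"` (small two-`b`
#'   derivation) or `"random_feasible_q"` (heterogeneous policy whose q is a
#'   random point on the capacity plane).
#' @param seed RNG seed; equal seeds give identical fixtures.
#' @param C capacity for `"random_feasible_q"` and `"tiny_two_b"`.
#' @return list with `model`, `policy`, `kind` and `seed`.
#' @export
generate_fixture <- function(kind = c("tiny_exhaustive", "tiny_selective",
                                      "tiny_two_b", "random_feasible_q"),
                             seed = 0L, C = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  n <- sample(1:2, 1L)
  model <- reward_model(sample(c("rich", "poor"), 1L), n = n)
  policy <- switch(kind,
    tiny_exhaustive = policy_exhaustive(b = sample(1:3, 1L), d = sample(1:3, 1L)),
    tiny_selective = {
      d <- sample(1:3, 1L)
      gamma <- sample(c(1, 0.9, 0.6), 1L)
      policy_heterogeneous(b = sample(1:3, 1L),
                           q = round(stats::runif(d), 3), gamma = gamma)
    },
    tiny_two_b = {
      if (is.null(C)) C <- sample(3:8, 1L)
      policy_two_b(b1 = sample(1:3, 1L), b2 = sample(1:2, 1L),
                   d1 = sample(1:2, 1L), C = C)
    },
    random_feasible_q = {
      b <- sample(2:3, 1L)
      d <- sample(2:4, 1L)
      if (is.null(C)) C <- round(stats::runif(1, 1, 0.9 * sum(b^seq_len(d))), 2)
      q <- project_to_constraint(stats::runif(d), b, C)
      policy_heterogeneous(b = b, q = q, order = "forward")
    })
  list(model = model, policy = policy, kind = kind, seed = as.integer(seed))
}
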