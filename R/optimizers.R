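#' Settings for the projected gradient ascent
#'
#' Defaults follow the protocol used throughout: forward finite differences
#' with discretization step `delta_q = 1e-7`, learning rate `eta = 1e-3`, at
#' most `1e6` iterations, and a stopping tolerance of `1e-9` on the value
#' improvement per iteration.
#'
#' @param delta_q finite-difference step for the gradient of the value with
#'   respect to each sampling probability.
#' @param eta learning rate multiplying the projected gradient.
#' @param max_iterations iteration cap.
#' @param tolerance stop when the per-iteration value improvement falls below
#'   this.
#' @param init initial `q`: `"homogeneous"` embeds the homogeneous derivation
#'   (full first levels, residual on the next, zero below), `"uniform"`
#'   projects a constant vector onto the capacity plane, `"random"` projects a
#'   uniformly random vector.
#' @param seed RNG seed used for `init = "random"`.
#' @param central use central instead of forward finite differences.
#' @return a list of class `ascent_settings`.
#' @export
ascent_settings <- function(delta_q = 1e-7, eta = 1e-3, max_iterations = 1e6,
                            tolerance = 1e-9,
                            init = c("homogeneous", "uniform", "random"),
                            seed = 0L, central = FALSE) {
  stopifnot(delta_q > 0, eta > 0, max_iterations >= 1, tolerance > 0)
  structure(list(delta_q = delta_q, eta = eta,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, init = match.arg(init),
                 seed = as.integer(seed), central = isTRUE(central)),
            class = "ascent_settings")
}

new_report <- function(family, best_params, best_value, candidates = NULL,
                       trajectory = NULL, settings = NULL) {
  structure(list(family = family, best_params = best_params,
                 best_value = best_value, candidates = candidates,
                 trajectory = trajectory, settings = settings),
            class = "optimizer_report")
}

#' @export
print.optimizer_report <- function(x, ...) {
  cat(sprintf("Optimizer report (%s family)\n", x$family))
  cat("  best parameters:",
      paste(names(x$best_params), unlist(lapply(x$best_params, function(v)
        if (length(v) > 4) paste0("[", length(v), " values]") else paste(signif(v, 6), collapse = ","))),
        sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  best value: %.10g\n", x$best_value))
  if (!is.null(x$candidates)) cat(sprintf("  candidates evaluated: %d\n", nrow(x$candidates)))
  if (!is.null(x$trajectory)) cat(sprintf("  ascent iterations: %d\n", length(x$trajectory) - 1L))
  invisible(x)
}

#' Optimal branching factor for homogeneous allocation
#'
#' Evaluates the homogeneous policy derived from each `b` in `b_range` at
#' capacity `C` ([derive_homogeneous()] then [tree_value()]) and returns the
#' argmax. Ties are broken toward the smallest `b`, i.e. the deeper policy.
#'
#' @param model a rational [reward_model()].
#' @param C capacity.
#' @param b_range integer vector of candidate branching factors.
#' @param gamma survival probability (1 = undiscounted).
#' @return an `optimizer_report`; `best_params$b` is the optimal branching
#'   factor and `candidates` tabulates `(b, d, q1, value)`.
#' @examples
#' m <- reward_model("rich", 1)
#' optimize_homogeneous(m, C = 100)$best_params$b   # 2
#' @export
optimize_homogeneous <- function(model, C, b_range = 1:20, gamma = 1) {
  stop_if_generic(model)
  if (length(b_range) == 0L) stop("b_range must not be empty")
  b_range <- sort(unique(as.integer(b_range)))
  cand <- data.frame(b = b_range, d = NA_integer_, q1 = NA_real_, value = NA_real_)
  for (i in seq_along(b_range)) {
    pol <- policy_homogeneous(b_range[i], C, gamma = gamma)
    cand$d[i] <- pol$d
    cand$q1[i] <- pol$q[1]
    cand$value[i] <- dm_value(model, pol$q, policy_branching(pol), gamma)
  }
  best <- which.max(cand$value)   # first maximum = smallest b on ties
  new_report("homogeneous",
             best_params = list(b = cand$b[best], d = cand$d[best], q1 = cand$q1[best],
                                C = C, gamma = gamma),
             best_value = cand$value[best], candidates = cand)
}

#' Grid search over two-branching-factor policies
#'
#' Evaluates every `(b1, b2, d1)` tuple on the given grids through
#' [derive_two_b()] and [tree_value()] at capacity `C`, and returns the
#' argmax. Ties (within `1e-12`) are broken lexicographically: smallest `b1`,
#' then `b2`, then `d1`. Cells where capacity is exhausted inside the `b1`
#' regime collapse to the homogeneous policy with `b = b1` and are evaluated
#' as such.
#'
#' @param model a rational [reward_model()].
#' @param C capacity.
#' @param b1_range,b2_range,d1_range integer grids.
#' @return an `optimizer_report` with `best_params` `(b1, b2, d1, d2)` and a
#'   `candidates` table.
#' @export
optimize_two_b <- function(model, C, b1_range = 1:10, b2_range = 1:10,
                           d1_range = 1:10) {
  stop_if_generic(model)
  if (!length(b1_range) || !length(b2_range) || !length(d1_range))
    stop("parameter grids must not be empty")
  b1_range <- sort(unique(as.integer(b1_range)))
  b2_range <- sort(unique(as.integer(b2_range)))
  d1_range <- sort(unique(as.integer(d1_range)))
  grid <- expand.grid(d1 = d1_range, b2 = b2_range, b1 = b1_range)
  grid <- grid[order(grid$b1, grid$b2, grid$d1), c("b1", "b2", "d1")]
  n_cand <- nrow(grid)
  vals <- numeric(n_cand); d2s <- integer(n_cand)
  best <- 1L
  for (i in seq_len(n_cand)) {
    pol <- policy_two_b(grid$b1[i], grid$b2[i], grid$d1[i], C)
    d2s[i] <- pol$d2
    vals[i] <- dm_value(model, pol$q, policy_branching(pol), 1)
    if (vals[i] > vals[best] + 1e-12) best <- i
  }
  cand <- cbind(grid, d2 = d2s, value = vals)
  new_report("two_b",
             best_params = list(b1 = grid$b1[best], b2 = grid$b2[best],
                                d1 = grid$d1[best], d2 = d2s[best], C = C),
             best_value = vals[best], candidates = cand)
}

#' Orthogonal projection onto the capacity plane with box constraints
#'
#' Projects a forward-ordered vector of sampling probabilities onto the
#' hyperplane `sum_l q_l * b^l = C` (weights `w_l = b^l`), so that the
#' correction is parallel to the weight vector. Components pushed outside
#' `[0, 1]` are clipped to the nearer bound and frozen, and the remaining free
#' components are re-projected; the clip/re-project loop is capped at
#' `10 * length(q)` cycles and errors out if the box and the plane do not
#' intersect along the free directions.
#'
#' @param q numeric vector of sampling probabilities in forward (root-first)
#'   level order.
#' @param b branching factor defining the weights.
#' @param C capacity.
#' @return a feasible vector satisfying the capacity constraint to `1e-9`.
#' @examples
#' project_to_constraint(c(0, 0), b = 2, C = 3)   # c(0.3, 0.6)
#' @export
project_to_constraint <- function(q, b, C) {
  b <- check_b(b)
  d <- length(q)
  w <- b^seq_len(d)
  free <- rep(TRUE, d)
  for (cycle in seq_len(10L * d)) {
    if (!any(free)) break
    gap <- C - sum(w * q)
    q[free] <- q[free] + w[free] * gap / sum(w[free]^2)
    out_lo <- free & (q < 0); out_hi <- free & (q > 1)
    if (!any(out_lo) && !any(out_hi)) break
    q[out_lo] <- 0; q[out_hi] <- 1
    free <- free & !(out_lo | out_hi)
  }
  if (abs(sum(w * q) - C) > 1e-9)
    stop("projection failed: the box and the capacity plane do not intersect ",
         "along the free components")
  q
}

#' Projected gradient ascent over heterogeneous sampling probabilities
#'
#' Maximizes the tree value over the per-level sampling probabilities `q` at
#' fixed branching factor `b`, depth `d` and capacity `C`. Each iteration
#' computes a finite-difference gradient of the value with respect to `q`
#' (step `delta_q`; forward differences, flipped to backward at components
#' within a step of 1), projects it onto the capacity hyperplane, takes a step
#' of size `eta`, and restores feasibility with [project_to_constraint()].
#' The ascent stops at `max_iterations` or when the value improves by less
#' than `tolerance`.
#'
#' @param model a rational [reward_model()].
#' @param C capacity.
#' @param b branching factor.
#' @param d depth of the considered sub-tree; defaults to the
#'   [capped_depth()] `2 * floor(log(C)/log(b)) + 3`, deep enough that the
#'   optimum can spread samples beyond the homogeneous depth.
#' @param settings an [ascent_settings()] list.
#' @param gamma survival probability.
#' @return an `optimizer_report`: `best_params$q` is the final forward-ordered
#'   vector, `trajectory` the per-iteration value sequence (element 1 = value
#'   at the initial point).
#' @export
optimize_heterogeneous <- function(model, C, b, d = NULL,
                                   settings = ascent_settings(), gamma = 1) {
  stop_if_generic(model)
  b <- check_b(b)
  stopifnot(inherits(settings, "ascent_settings"))
  if (is.null(d)) {
    if (b < 2) stop("the default depth cap requires b >= 2; give d explicitly")
    d <- capped_depth(b, C)
  }
  d <- as.integer(d)
  w <- b^seq_len(d)
  if (C > sum(w))
    stop("no feasible q: capacity exceeds the size of the depth-", d, " sub-tree")
  bvec <- rep(b, d)
  value_of <- function(q_fwd) dm_value(model, rev(q_fwd), bvec, gamma)

  q <- switch(settings$init,
    homogeneous = {
      der <- derive_homogeneous(b, max(C, 1))
      dd <- min(der$depth_reached, d)
      qh <- numeric(d); if (dd > 1L) qh[seq_len(dd - 1L)] <- 1
      qh[dd] <- der$last_level_q
      project_to_constraint(qh, b, C)
    },
    uniform = project_to_constraint(rep(0.5, d), b, C),
    random = {
      set.seed(settings$seed)
      project_to_constraint(stats::runif(d), b, C)
    })

  v <- value_of(q)
  traj <- numeric(settings$max_iterations + 1L)
  traj[1L] <- v
  n_iter <- 0L
  dq <- settings$delta_q
  for (iter in seq_len(settings$max_iterations)) {
    g <- numeric(d)
    if (settings$central) {
      for (l in seq_len(d)) {
        hi <- min(q[l] + dq, 1); lo <- max(q[l] - dq, 0)
        qe <- q; qe[l] <- hi; vhi <- value_of(qe)
        qe[l] <- lo
        g[l] <- (vhi - value_of(qe)) / (hi - lo)
      }
    } else {
      for (l in seq_len(d)) {
        qe <- q
        if (q[l] + dq <= 1) { qe[l] <- q[l] + dq; g[l] <- (value_of(qe) - v) / dq }
        else               { qe[l] <- q[l] - dq; g[l] <- (v - value_of(qe)) / dq }
      }
    }
    g_proj <- g - w * sum(w * g) / sum(w * w)
    q_new <- project_to_constraint(q + settings$eta * g_proj, b, C)
    v_new <- value_of(q_new)
    n_iter <- iter
    improvement <- v_new - v
    if (v_new >= v) { q <- q_new; v <- v_new }
    traj[iter + 1L] <- v
    if (improvement < settings$tolerance) break
  }
  new_report("heterogeneous",
             best_params = list(b = b, d = d, C = C, gamma = gamma, q = q),
             best_value = v, trajectory = traj[seq_len(n_iter + 1L)],
             settings = settings)
}
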