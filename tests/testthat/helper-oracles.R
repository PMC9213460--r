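# Brute-force oracles, deliberately naive: they enumerate every joint
# configuration of node outcomes on an explicit tree and never touch the
# package's lattice recursion.

# Expected optimal-path value of an undiscounted tree: every non-root node is
# unsampled (reward 0, weight 1 - q), high (r_plus, weight q * p) or low
# (r_minus, weight q * (1 - p)); backward induction per configuration.
brute_force_value <- function(p, r_minus, b, d, q_fwd, r_plus = 1) {
  sizes <- b^seq_len(d)
  M <- sum(sizes)
  stopifnot(M <= 10)                       # 3^10 configurations at most
  level_of <- rep(seq_len(d), sizes)
  states <- as.matrix(do.call(expand.grid, rep(list(0:2), M)))
  rewards <- c(0, r_plus, r_minus)
  qn <- q_fwd[level_of]
  w_tab <- cbind(1 - qn, qn * p, qn * (1 - p))   # per-node outcome weights
  total <- 0
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    w <- prod(w_tab[cbind(seq_len(M), st + 1L)])
    if (w == 0) next
    r <- rewards[st + 1L]
    # backward induction over the regular tree
    v <- r[level_of == d]
    if (d > 1) for (l in (d - 1):1) {
      best <- apply(matrix(v, nrow = b), 2, max)
      v <- r[level_of == l] + best
    }
    total <- total + w * max(v)
  }
  total
}

# Distribution of the max of b i.i.d. draws from a finite distribution, by
# enumerating all tuples.
brute_force_max <- function(values, probs, b) {
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_along(values)), b)))
  vals <- apply(idx, 1, function(ii) max(values[ii]))
  w <- apply(idx, 1, function(ii) prod(probs[ii]))
  agg <- tapply(w, vals, sum)
  list(values = as.numeric(names(agg)), probs = as.numeric(agg))
}

rich1 <- reward_model("rich", 1)

expect_dist_equal <- function(dist, values, probs, tol = 1e-12) {
  df <- as.data.frame(dist)
  ord <- order(values)
  expect_equal(df$value, values[ord], tolerance = tol)
  expect_equal(df$probability, probs[ord], tolerance = tol)
}
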