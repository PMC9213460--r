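#' Distribution of cumulative rewards on the integer lattice
#'
#' The engine stores the distribution of the optimal path's cumulative reward
#' `J_d` (or of the action value `Q_d`) as a dense probability vector over an
#' integer lattice. A key `k` represents the true value `k / scale`: for rich
#' models (`p = n/(n+1)`) the admissible values `i - n*j` are integers and
#' `scale = 1`; for poor models (`p = 1/(n+1)`) the values `i - j/n` become
#' integers after multiplying by `scale = n`. Keeping keys integral avoids
#' floating-point collisions between degenerate states that coincide on the
#' lattice.
#'
#' @param probs numeric vector of probabilities, `probs[i]` belonging to
#'   integer key `kmin + i - 1`.
#' @param kmin integer key of the first element of `probs`.
#' @param scale positive integer lattice denominator.
#' @param depth level index this distribution describes.
#' @param role `"J"` (state value) or `"Q"` (action value).
#' @return An object of class `value_dist`.
#' @keywords internal
new_value_dist <- function(probs, kmin, scale, depth, role = c("J", "Q")) {
  role <- match.arg(role)
  structure(list(probs = probs, kmin = as.integer(kmin), scale = as.integer(scale),
                 depth = as.integer(depth), role = role),
            class = "value_dist")
}

#' @export
print.value_dist <- function(x, ...) {
  cat(sprintf("Value distribution (%s) at depth %d, lattice scale %d\n",
              if (x$role == "J") "state value J" else "action value Q",
              x$depth, x$scale))
  df <- as.data.frame(x)
  if (nrow(df) > 12L) {
    print(utils::head(df, 6L))
    cat(sprintf("  ... %d further support points ...\n", nrow(df) - 12L))
    print(utils::tail(df, 6L))
  } else {
    print(df)
  }
  cat(sprintf("mean = %.10g\n", dist_mean(x)))
  invisible(x)
}

#' @describeIn new_value_dist integer keys of the dense table.
#' @keywords internal
dist_keys <- function(x) seq.int(x$kmin, length.out = length(x$probs))

#' Mean of a lattice value distribution
#'
#' @param x a `value_dist`.
#' @return `sum(key * probability) / scale`, the expected cumulative reward.
#' @export
dist_mean <- function(x) {
  stopifnot(inherits(x, "value_dist"))
  sum(dist_keys(x) * x$probs) / x$scale
}

#' Support of a lattice value distribution
#'
#' @param x a `value_dist`.
#' @param drop_zero drop lattice points with (numerically) zero mass.
#' @param tol mass below which a point is considered unoccupied.
#' @return numeric vector of values `key / scale` carrying positive mass.
#' @export
dist_support <- function(x, drop_zero = TRUE, tol = 0) {
  stopifnot(inherits(x, "value_dist"))
  k <- dist_keys(x)
  if (drop_zero) k <- k[x$probs > tol]
  k / x$scale
}

#' @export
as.data.frame.value_dist <- function(x, row.names = NULL, optional = FALSE, ...) {
  keep <- x$probs > 0
  data.frame(value = dist_keys(x)[keep] / x$scale,
             probability = x$probs[keep])
}
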