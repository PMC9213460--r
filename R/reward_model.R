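#' Binary reward model with exact zero-average constraint
#'
#' Constructs the reward statistics of the environment. Sampling a node
#' reveals a high expected reward `R+ = +1` with probability `p`, otherwise a
#' low expected reward `R-`, chosen so that the zero-average constraint
#' `p * R+ + (1 - p) * R- = 0` holds exactly. Two rational families admit an
#' exact lattice representation and are accepted by the exact value engine:
#'
#' * `"rich"`: `p = n / (n + 1)`, `R- = -n`;
#' * `"poor"`: `p = 1 / (n + 1)`, `R- = -1 / n`.
#'
#' The `"generic"` variant carries an arbitrary `p` in (0, 1) with
#' `R- = -p / (1 - p)`; it is accepted only by the Monte-Carlo oracle
#' ([mc_tree_value()]), never by the exact engine.
#'
#' @param variant one of `"rich"`, `"poor"`, `"generic"`.
#' @param n positive integer index of the rational family (rich/poor only).
#' @param p probability of a high reward, required for `"generic"` only.
#'
#' @return An object of class `reward_model` with fields `variant`, `n`, `p`,
#'   `r_plus`, `r_minus`, the exact rational representation (`p_num`, `p_den`)
#'   and the integer lattice geometry used by the engine (`scale`,
#'   `shift_plus`, `shift_minus`): cumulative rewards live on the lattice
#'   `k / scale` with integer `k`, and the two reward outcomes move an integer
#'   key by `shift_plus` and `shift_minus`.
#'
#' @examples
#' reward_model("rich", n = 1)    # p = 1/2, rewards +1 / -1
#' reward_model("poor", n = 99)   # p = 0.01, rewards +1 / -1/99
#' @export
reward_model <- function(variant = c("rich", "poor", "generic"), n = NULL, p = NULL) {
  variant <- match.arg(variant)
  if (variant == "generic") {
    if (is.null(p) || !is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("generic variant requires a single probability p in (0, 1)")
    if (!is.null(n)) stop("n is not meaningful for the generic variant")
    m <- list(variant = variant, n = NA_integer_,
              p = as.numeric(p), p_num = NA_real_, p_den = NA_real_,
              r_plus = 1, r_minus = -p / (1 - p),
              scale = NA_integer_, shift_plus = NA_integer_, shift_minus = NA_integer_)
    return(structure(m, class = "reward_model"))
  }
  if (is.null(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("rational variants require a positive integer n")
  n <- as.integer(n)
  if (variant == "rich") {
    m <- list(variant = variant, n = n,
              p = n / (n + 1), p_num = n, p_den = n + 1L,
              r_plus = 1, r_minus = -as.numeric(n),
              scale = 1L, shift_plus = 1L, shift_minus = -n)
  } else {
    m <- list(variant = variant, n = n,
              p = 1 / (n + 1), p_num = 1L, p_den = n + 1L,
              r_plus = 1, r_minus = -1 / n,
              scale = n, shift_plus = n, shift_minus = -1L)
  }
  structure(m, class = "reward_model")
}

#' @export
print.reward_model <- function(x, ...) {
  if (x$variant == "generic") {
    cat(sprintf("Reward model: generic, p = %g, R+ = 1, R- = %g (Monte Carlo only)\n",
                x$p, x$r_minus))
  } else {
    cat(sprintf("Reward model: %s, n = %d, p = %s = %g, R+ = 1, R- = %s\n",
                x$variant, x$n,
                sprintf("%d/%d", x$p_num, x$p_den), x$p,
                if (x$variant == "rich") sprintf("-%d", x$n) else sprintf("-1/%d", x$n)))
  }
  invisible(x)
}

is_rational_model <- function(model) {
  inherits(model, "reward_model") && model$variant %in% c("rich", "poor")
}

stop_if_generic <- function(model) {
  if (!inherits(model, "reward_model")) stop("'model' must be a reward_model")
  if (!is_rational_model(model))
    stop("the exact engine requires a rational ('rich' or 'poor') reward model; ",
         "use mc_tree_value() for generic p")
  invisible(model)
}

#' Nearest rational reward model for a real-valued p
#'
#' Finds the rational family member (`rich` with `p = n/(n+1)` or `poor` with
#' `p = 1/(n+1)`, `n <= max_n`) whose high-reward probability is closest to a
#' requested real `p`, and reports the approximation error. The substitution is
#' never silent: the caller receives the chosen model together with the error
#' and decides whether to use it or fall back to the Monte-Carlo oracle with a
#' generic model.
#'
#' @param p requested probability in (0, 1).
#' @param max_n largest rational index to consider.
#' @return A list with `model` (the nearest rational [reward_model()]),
#'   `p_requested`, `p_used` and `error` (`p_used - p_requested`).
#' @examples
#' nearest_rational_model(0.34)  # poor n = 2, p = 1/3
#' @export
nearest_rational_model <- function(p, max_n = 1000L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must be a single probability in (0, 1)")
  ns <- seq_len(max_n)
  cand <- data.frame(variant = rep(c("rich", "poor"), each = max_n),
                     n = c(ns, ns),
                     p = c(ns / (ns + 1), 1 / (ns + 1)),
                     stringsAsFactors = FALSE)
  i <- which.min(abs(cand$p - p))
  model <- reward_model(cand$variant[i], n = cand$n[i])
  list(model = model, p_requested = p, p_used = model$p, error = model$p - p)
}
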