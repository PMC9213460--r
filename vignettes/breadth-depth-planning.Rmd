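---
title: "Methods: exact valuation of sample-allocation policies in large decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact valuation of sample-allocation policies in large decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdtree)
```

## The model and its assumptions

`bdtree` studies one-shot allocation of a finite sampling capacity `C` over
an infinitely deep, infinitely branching decision tree. The process has two
phases. In the *learning* phase the agent spends samples: sampling a node
reveals the expected reward of visiting it, `R+ = +1` with probability `p`
and a negative `R-` otherwise; unsampled nodes keep expected reward 0. In
the *exploitation* phase the agent walks the path with the highest expected
cumulative reward, found by backward induction over the finite sub-tree
that connects sampled nodes to the root. The value of a policy is the
expectation of that best-path reward, `V = E(J_d)`.

Three assumptions matter throughout:

* **Zero-average rewards.** `R-` is fixed by `p·R+ + (1-p)·R- = 0`. This is
  not cosmetic: if sampling had positive expected payoff, a policy could
  earn unboundedly by giving every node an infinitesimal sampling
  probability; with the constraint, a random (or unsampled) path is worth
  exactly 0 and every positive value is attributable to information bought
  with samples.
* **Independent rewards.** Node rewards are i.i.d.; correlations within a
  level are out of scope.
* **Average capacity.** Nodes in level `l` are sampled independently with a
  per-level probability, and `C` constrains the *expected* sample count,
  `Σ_l q_l·b^l = C`. A hard (exactly `C`) constraint is not implemented.

Two rational environment families admit an exact treatment: *rich*
(`p = n/(n+1)`, `R- = -n`) and *poor* (`p = 1/(n+1)`, `R- = -1/n`), with
`n` a positive integer. `reward_model()` stores `p` as an exact fraction and
the engine works on an integer lattice (below), so the zero-average identity
holds in integer arithmetic, not merely to rounding. Arbitrary real `p` is
supported only by the Monte-Carlo oracle; `nearest_rational_model()` finds
the closest rational family member and reports the approximation error
rather than substituting silently, so grids over `p` are always explicit
about which rational environment each point uses.

## The diffusion–maximization recursion

The engine never touches the `O(b^d)` tree. It propagates the distribution
of the optimal sub-tree value backward, one level at a time:

1. **Initial level.** A deepest-level branch has action value `R-`, `0` or
   `R+` with probabilities `q1(1-p)`, `1-q1`, `q1·p`; the best of `b`
   branches follows by raising the CDF to the `b`-th power.
2. **Diffusion.** `Q_d = R_d + J_{d-1}`: mass at state `k` stays (weight
   `(1-q)γ`), moves up by `R+` (`q·p·γ`) or down by `R-` (`q(1-p)γ`). With
   probability `1-γ` the continuation is lost and only the immediate reward
   remains, adding mass at `R+`, `0`, `R-`. `γ = 1` is the undiscounted
   case.
3. **Maximization.** `P(J_d ≤ k) = P(Q_d ≤ k)^b`, the max of `b` i.i.d.
   action values.

States are stored in a dense vector over integer keys: a value `v` is the
key `v·scale` with `scale = 1` for rich models (values `i - n·j` are
integers) and `scale = n` for poor models. Integer keys make degenerate
states (different `(i, j)` pairs with equal value) coincide exactly, which a
floating-point support could not guarantee; the number of distinct states
grows only linearly in depth (`distinct_state_count()`), so the whole
recursion costs `O(n·b·d²)`.

The discounted recursion is implemented literally as independent per-branch
survival: each branch's continuation is lost with probability `1-γ` inside
the expectation over the maximum. Whether this coin-flip semantics is
equivalent to deterministic exponential weighting of rewards is *not*
asserted anywhere; the Monte-Carlo oracle draws the same per-node coins so
that both routes compute the same quantity. Discounting is restricted to
single-`b` families; `policy_two_b()` fixes `γ = 1`.

### Numerical choices

* **Renormalization.** `P(J)` is renormalized to sum one after every
  maximization step. This matters only for very deep recursions (hundreds
  of levels), where the CDF powers slowly leak mass at rounding level; it
  is applied at every depth for uniformity.
* **Underflow.** Tail probabilities below ~1e-308 flush to zero and the
  realized support can then be smaller than the state-count formula; the
  support-size identity is therefore only tested on policies whose tails
  stay representable.
* **Degenerate inputs.** `q1 = 0` yields a point mass at 0; `b = 1` makes
  the maximization the identity, and a `b = 1` homogeneous policy has value
  0 (no freedom to choose a path) — reproduced to ~1e-14 after hundreds of
  renormalized levels, which is why tests assert it at 1e-12 rather than
  bitwise.
* **Backward indexing.** `q[1]` is the *deepest* level, matching the
  backward recursion; `policy_heterogeneous()` accepts `order = "forward"`
  and reverses internally.

## Capacity arithmetic

`derive_homogeneous(b, C)` stacks full levels while their cost stays
*strictly* below `C`, so the residual `C_r` spread over the last level is
always positive. When `C` exactly fills `m` levels the derivation returns
depth `m` with `q1 = 1`, not a vacuous `(m+1)`-th level with `q1 = 0` —
either convention satisfies the constraint, but this one keeps `C_r > 0`
and the policy's depth meaningful. `derive_two_b()` applies the same rule
to the deep regime; the deep levels hold `b1^d1 · b2^(l-d1)` nodes (the
first-regime leaf count times the second-regime growth). If capacity runs
out inside the first regime the derivation truncates there (`d2 = 0`,
effective `d1` possibly below the requested one) and `b2` becomes
irrelevant, so the family degrades gracefully to single-`b` homogeneous
allocation.

The random baseline spreads one uniform `q` over a tree of depth
`2·⌊ln C / ln b⌋ + 3` — roughly twice the homogeneous depth, plus slack.
The heterogeneous optimizer uses the same default depth so that "spread
deeper than homogeneous" is inside its feasible set and baseline and
optimum are comparable level for level.

## Optimizers

* **Homogeneous** (`optimize_homogeneous()`): exhaustive scan of `b` over a
  grid, default `1..20`. Ties break toward the smaller `b` (the deeper
  policy); in practice exact ties occur only between capacity-degenerate
  candidates.
* **Two-`b`** (`optimize_two_b()`): exhaustive grid over `(b1, b2, d1)`,
  ties broken lexicographically (smallest `b1`, then `b2`, then `d1`) with
  a 1e-12 tolerance, so the plateaus where `b2` is irrelevant report
  `b2 = 1`.
* **Heterogeneous** (`optimize_heterogeneous()`): projected gradient ascent
  on `q` at fixed `b` and depth. Defaults (`ascent_settings()`):
  finite-difference step `Δq = 1e-7`, learning rate `η = 1e-3`, up to 1e6
  iterations, stopping when the value improves by less than 1e-9. The
  gradient is a forward finite difference, flipped to a backward difference
  for components within `Δq` of 1 (a forward probe would leave the box and
  produce negative probabilities). The gradient is projected onto the
  capacity hyperplane (weights `w_l = b^l`); after the step, feasibility is
  restored by clipping out-of-box components to the nearer bound, freezing
  them, and re-projecting the free components — an active-set variant of
  the clip/re-project loop that terminates in at most `d` cycles, with a
  `10·d` cap and a diagnosable error if box and plane fail to intersect.
  The joint argmax over `(b, q)` is realized as a loop over `b` around the
  per-`b` ascent, not as a joint search. Concavity of `V` in `q` is
  suggested numerically but is not assumed or asserted.

The default starting point embeds the homogeneous derivation (feasible and
already close to optimal), which also guarantees that the reported optimum
is at least the homogeneous value since the trajectory is monotone.
Random feasible starts agree in value to ~1e-5 on small instances run to
convergence; with the iteration counts used in the test suite, larger
instances still carry an O(1e-3) initialization footprint, so the
insensitivity property is asserted on a small instance (`d = 3`, `C = 3`).

## Verification oracles and what they show

`enumerate_tree_value()` recomputes the same expectation with none of the
engine's machinery: per level it enumerates the sampling/reward/survival
outcomes of a node explicitly and obtains the best of `b` branches by
enumerating all `support^b` joint configurations instead of the CDF-power
identity. The test suite additionally carries a third, fully naive route —
all `3^M` outcome configurations of an explicit `M`-node tree, backward
induction per configuration — used to freeze expected values on hand-sized
instances. `mc_tree_value()` is the stochastic counterpart: it instantiates
reward realizations on the explicit tree (any `p`, including generic),
runs backward induction per realization, and reports mean ± standard
error from a single seeded RNG stream, so equal seeds give identical
estimates. Its `path = "random"` mode replaces the max with a uniformly
random child choice and checks the zero-average consequence `E = 0`.

Fixture generation (`generate_fixture()`) draws tiny instances — depths and
branching factors up to 3, rational indices up to 2, occasional discounting
— inside the enumeration limits. These fixtures exercise every code path of
the engine but are *small*; passing tests show exactness of the recursion
and correctness of the capacity arithmetic, not anything about real
behavioral data, which the model does not touch (it has no external data at
all: every input is a parameter setting).

Problem sizes used by the test and acceptance runs were chosen to keep the
full suite under a couple of minutes while leaving the scientific claims
intact: optimizer scans use `b ≤ 20`, two-`b` grids `10×10×10` at
`C = 1000`, ascent runs are capped at 1e4 iterations, Monte-Carlo checks
use 1e4 runs, and oracle sweeps cover 50+ random fixtures.

## Known limitations

* The exact engine requires rational `p`; generic `p` is Monte-Carlo only.
* Discounted two-`b` and heterogeneous-over-`(b1,b2)` optimization are not
  implemented (single-`b` homogeneous families cover the discounted
  analysis).
* The heterogeneous optimizer is a local ascent; no global optimality
  guarantee is claimed beyond the observed initialization insensitivity.
* Correlated rewards, sequential (feedback) allocation and hard capacity
  constraints are out of scope.
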