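# bdtree: breadth–depth tradeoffs for finite-capacity planning in decision trees

Planning agents facing a deep and wide decision tree — which country for the
holiday, then which city, then which restaurant — cannot evaluate every
course of action. With a finite budget of `C` "samples" (mental simulations
that reveal whether visiting a node promises high or low expected reward),
the agent must decide *in one shot* how to spread them: many branches per
level (breadth) or few branches over many levels (depth)? `bdtree`
implements an exact, polynomial-time machinery for answering this question
over infinitely large trees, for researchers in computational cognitive
science, decision theory and resource-rational analysis.

## The model

Every sampled node reveals an expected reward `R+ = +1` with probability `p`
or `R- = -p/(1-p)` otherwise, so that `p·R+ + (1-p)·R- = 0` (the
*zero-average constraint*: an unsampled node and a not-yet-sampled node both
promise 0). After sampling, the agent follows the path with the highest
expected cumulative reward, found by backward induction over the sampled
sub-tree. The value of an allocation policy is

```
V = E( J_d ),    J_d = cumulative reward of the best path over d levels.
```

Rather than enumerating the `O(b^d)` nodes, the engine propagates the full
probability distribution of `J` backward level by level, alternating

* a **diffusion step** `Q_d = R_d + J_{d-1}`: each lattice state splits into
  stay / up / down with weights `(1-q)`, `q·p`, `q·(1-p)` (times the
  survival probability `γ` in the discounted case), and
* a **maximization step** `P(J_d ≤ k) = P(Q_d ≤ k)^b`: the CDF-power of the
  best of `b` i.i.d. branches,

at cost `O(n·b·d²)` for the exact rational environments `p = n/(n+1)`
("rich") and `p = 1/(n+1)` ("poor"). Four allocation families are supported:
exhaustive, homogeneous (full levels, residual probability `q1` on the last),
heterogeneous (free per-level `q`, optimized by projected gradient ascent
under the average-capacity constraint `Σ q_l·b^l = C`), and two-branching
(`b1` for `d1` levels, then `b2`). Exact enumeration and Bellman–Monte-Carlo
oracles verify the engine on small instances.

## Worked example

```r
library(bdtree)
m <- reward_model("rich", 1)        # p = 1/2, rewards +1 / -1
optimize_homogeneous(m, C = 100, b_range = 1:20)
```

```
Optimizer report (homogeneous family)
  best parameters: b = 2, d = 6, q1 = 0.59375, C = 100, gamma = 1
  best value: 4.40371764
  candidates evaluated: 20
```

With 100 samples in a rich environment it is optimal to consider only two
branches per node (`b* = 2`): the agent reaches 6 levels deep (the last
sampled with probability 0.59375 so that the expected sample count is
exactly 100) and the best path promises 4.40 reward units on average.
Breadth is costly — `b = 3` already drops the value to 3.55 — and the
deepest policy `b = 1` is worthless (`V = 0`): with a single branch there is
no freedom left to choose a path. The same machinery values a single policy
directly:

```r
res <- tree_value(m, policy_homogeneous(2, 100))
res$value                       # 4.403718
head(as.data.frame(res$terminal))  # full distribution of the best path's reward
```

and analytics such as the probability that a fully sampled tree contains an
all-positive path, which decays to a fixed point that is nonzero only when
`p·b > 1`:

```r
success_probability(0.5, 3, 5)$values   # 0.875 0.822 0.796 0.782 0.774
success_fixed_point(0.5, 3)             # 0.763932
success_fixed_point(0.5, 2)             # 0: at p*b = 1 every path is blocked
```

A shell front end wrapping these functions lives in `inst/cli/bdtree.R`
(`value`, `optimize`, `success`, `oracle`, `surface` commands, with
reproducible CSV/JSON artifacts).

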