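---
title: "Focused true discovery guarantees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused true discovery guarantees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focusct)
```

## The inferential problem

In large-scale testing — gene sets in expression studies, anatomical regions
in imaging, study collections in replicability analysis — researchers rarely
stop at a list of individually significant features. They ask questions about
*sets* of features, often chosen after seeing the data: "how many genes in
this pathway are truly associated?" A *true discovery guarantee* answers this
with a lower confidence bound $d_\alpha(S)$ on the number of false null
hypotheses in $S$, simultaneously over **all** $S \subseteq W$:

$$
P\bigl(d_\alpha(S) \le |S \cap W_1| \text{ for all } S \in 2^W\bigr)
\ge 1 - \alpha,
$$

where $W$ is the feature universe and $W_1$ the unknown set of false nulls.
Simultaneity is what licenses post hoc set selection: because every set is
covered at once, looking first and asking later costs nothing extra.

The catch is power. Procedures of this type spread their budget over the
whole lattice $2^W$. When a practitioner knows in advance which sets matter —
a curated list of pathways, the rows of a study-by-feature p-value matrix —
it is wasteful to treat those sets like any other. `focusct` implements a
combination strategy: the user names $m$ *focus sets* $F_1, \dots, F_m$
(fixed before seeing the data; overlap allowed), each carrying a *partial*
true discovery guarantee procedure $d_i^\gamma$ valid on $2^{F_i}$, and the
package assembles a fully simultaneous procedure that concentrates power on
the focus sets while still answering arbitrary post hoc queries.

## From partial procedures to a simultaneous one

**Partial procedures.** The default partial procedure is closed testing
within $F_i$ with Fisher combination local tests: an intersection $K
\subseteq F_i$ is rejected when $-2\sum_{j \in K} \log p_j$ exceeds the
$\chi^2_{2|K|}$ quantile. Because the statistic is a sum and its threshold
depends only on $|K|$, the hardest-to-reject set of any given size consists
of the largest p-values, and the exact closed-testing bound for any $S
\subseteq F_i$ reduces to a two-index scan over sorted suffix sums
(`fisher_subset_bound()`), $O(|S|\cdot|F_i \setminus S|)$ after sorting.
The generic $2^{|F_i|}$ enumeration (`partial_bound_bruteforce()`) is kept
as the trust anchor and accepts any local test implementing the
`(p-values) -> combined p` contract, e.g. the Simes test. Any user-supplied
bound oracle can stand in for the default (`oracle_table()`), as long as it
is monotone in the level, respects `evaluate(level, S) <= evaluate(level, T)
+ |S \ T|` for `T ⊆ S`, and returns 0 on the empty set.

**Combination.** Each partial procedure is run on its own focus set at a
corrected level. The *Bonferroni* combination uses $\alpha/m$ throughout.
The *Holm* combination (the default) recycles the budget: starting from
$h = m$, every focus set whose bound reaches $|F_i|$ (all members declared
discoveries) is set aside, $h$ is reduced accordingly, and the remaining
sets are re-evaluated at $\alpha/h$, iterating until a sweep changes
nothing. Holm bounds dominate Bonferroni bounds on every instance, and the
procedure may be stopped early (`max_rounds`) without losing validity —
useful when each oracle call is expensive.

**Interpolation.** The per-focus bounds alone say nothing about other sets.
They are extended by interpolation:

$$
d^{(k+1)}(S) = \max_{U \subseteq W}
\bigl\{ d^{(k)}(U) - |U \setminus S| + d^{(k)}(S \setminus U) \bigr\},
$$

read as: if $U$ contains more discoveries than it has elements outside $S$,
the surplus must lie in $S$. Iterating to a fixpoint yields the *coherent*
procedure $d^{(r)}$, implemented exactly by lattice sweeps in
`coherent_bounds()` for universes up to `cap = 16` features (each sweep is
$O(4^w)$; in practice the exact mode is a verification device for small
problems). For real universes the package answers queries with
`greedy_bound()`: repeatedly credit the focus set with the largest
incremental contribution $\max(0, d_i - |F_i \setminus S'|)$ against the
not-yet-credited part $S'$ of the query, retire it, and stop when no
positive contribution remains. Each step is itself an interpolation, so the
greedy total never exceeds $d^{(r)}(S)$ and inherits its validity; it runs
in $O(m^2)$ set operations regardless of $w$. Ties are broken by the larger
overlap with $S'$, then the lower focus index, making the output
deterministic.

## The closed-testing view, and an honest gap

Admissible simultaneous procedures are closed testing procedures, so the
package also exposes the construction explicitly (`ct_bound()`), both to
verify the combination and to measure what the shortcuts give up. Three
local tests of decreasing power and cost are provided, where $m_S$ counts
the focus sets intersecting $S$ and $h$ is the converged Holm factor:

* $\phi(S) = 1$ iff some $d_i^{\alpha/m_S}(F_i \cap S) > 0$ — needs
  subset-capable oracles;
* $\tilde\phi(S) = 1$ iff some $d_i^{\alpha/m_S}(F_i) > |F_i \setminus S|$ —
  full-set bounds only, equal to $\phi$ when $S$ cuts no focus set
  partially;
* $\bar\phi(S)$ — the same with $\alpha/h$ in place of $\alpha/m_S$; being
  monotone, its effective (superset-minimised) test equals itself, so its
  closed-testing bound needs no search over supersets
  (`ct_bound_phibar()`).

The bounds are ordered $d \ge \tilde d \ge \bar d \ge d^{(r)} \ge$ greedy on
every instance, and the test suite checks this chain on thousands of random
instances.

One relationship deserves emphasis because it is *not* an equality, although
it is tempting to believe it is. For **disjoint** focus families the
coherent interpolated procedure coincides with $\bar\phi$ closed testing —
both reduce to $\sum_i \max(0, d_i - |F_i \setminus S|)$. For overlapping
families closed testing can be strictly sharper. The minimal example in the
test suite has $W = \{1,2,3,4\}$ with $F_1 = \{1,2,4\}$, $F_2 = \{1,2,3\}$,
$F_3 = \{1,3,4\}$ (each with bound 2) and $F_4 = \{2,3\}$ (bound 1): any
truth assignment satisfying all four partial statements must contain three
features, and $\bar\phi$ closed testing certifies $\bar d(W) = 3$, but
pairwise interpolation — which can only combine two sets at a time — tops
out at $d^{(r)}(W) = 2$. The package therefore treats interpolation (exact
or greedy) as a *conservative* shortcut to $\bar\phi$ closed testing, never
as its equal; users with small universes and overlapping families can call
`ct_bound_phibar()` directly for the sharper bound at $O(2^{|S|})$ cost.

```{r counterexample}
fam <- focus_family(list(F1 = c("1","2","4"), F2 = c("1","2","3"),
                         F3 = c("1","3","4"), F4 = c("2","3")),
                    universe = as.character(1:4))
d <- c(2, 2, 2, 1)
coherent_bounds(fam, d, queries = list(W = as.character(1:4)))$bound
hs <- bonferroni_partial_bounds(oracle_table(fam, d), fam, 0.05)
ct_bound_phibar(fam, hs, as.character(1:4))
```

## Replicability analysis

When the same $m$ features are tested in $v$ independent studies, the rows
of the $m \times v$ p-value matrix form a natural disjoint focus family. The
partial conjunction hypothesis $H^{r/v}_i$ ("fewer than $r$ studies carry a
true effect for feature $i$") is tested by Fisher combination of the $v-r+1$
*largest* p-values in the row; closed testing over the row reduces to
$d_i = \max\{r : p_i^{u/v} \le \alpha/m \ \text{for all}\ u \le r\}$
(`pc_feature_bound()`), giving each feature a lower confidence bound on its
number of replicating studies, simultaneous across features. The
quantification over all $u \le r$ matters: the partial conjunction p-value
is not monotone in $r$ (dropping the smallest remaining p-value lowers the
degrees of freedom faster than the statistic when the small p-values are
exhausted).

`adafilter()` implements the comparator, which fixes $r$, filters by
$R_i = (v-r+1)p_{i(r-1)}$, and rejects when $S_i = (v-r+1)p_{i(r)}$ falls
below the adaptive level
$\hat\alpha = \sup\{\gamma \in [0,\alpha] : \gamma \sum_i 1\{R_i < \gamma\}
\le \alpha\}$. The constraint is step-linear and right-continuous, so the
supremum is attained at one of $\{\alpha\} \cup \{\alpha/k\}_{k \le m} \cup
\{R_i\}$; the implementation scans exactly those candidates, with a
relative tolerance of $10^{-9}$ on the constraint to absorb the rounding of
products of the form $(\alpha/k)\cdot k$. Strict inequalities are used in
both the filter and the selection, matching the procedure's definition.
`run_table2()` drives the standard comparison design (below).

## Synthetic designs: what they emulate, and what they do not

All generators are pure functions of their arguments and a seed, and return
the ground truth alongside the data, so coverage can be checked by counting.

* `sim_two_group()` — $n = 100$ samples, $w = 1000$ independent
  $N(0, 1)$ features, Bernoulli(0.5) response; associated features are
  shifted by $\mu = 0.7$ in one group. These defaults are the focused-power
  study conditions; the shift is applied to the response-1 group, a choice
  the generator exposes because only the contrast magnitude matters for the
  equal-variance t-test.
* `sim_focus_structure()` — 11 focus and 11 nonfocus sets of size 20 whose
  realised TDP runs over $0, 0.1, \dots, 1$ exactly; half of each set's
  members are drawn from small shared pools so that sets overlap within and
  across kinds. Set size and overlap fraction are knobs, since any concrete
  overlap pattern is a modelling choice rather than something the design
  pins down.
* `sim_pc_matrix()` — $m = 10$ features by $v = 10$ studies; signal
  p-values Beta($a$, 1) with $a = 0.05$ by default, nulls Uniform(0,1);
  with scalar $v_1$, the first half of the features get $v_1$ signal
  studies and the rest none. The Beta shape is exposed because the cells of
  the replicability comparison that involve signal strength scale directly
  with it; the package's tests therefore only pin down the
  signal-independent cells (the all-null column, the saturated AdaFilter-2
  cell, the analytic truth row $v_1/2$) and check the signal-dependent ones
  qualitatively (monotone in $v_1$; partial conjunction closed testing
  dominating AdaFilter-$r$ away from $v_1 \approx r$).
* `sim_dyadic_tree()` — a complete dyadic tree (128 leaves, 8 layers by
  default, with optional truncation to a non-dyadic count such as 100),
  one-sided normal p-values at the leaves, signals grouped in one branch or
  scattered; each layer's nodes form a candidate focus family (layer-4
  nodes partition the leaves).

What the generators do *not* emulate: correlated features, heavy-tailed or
discrete p-values, data-driven focus sets, and unequal group variances.
Passing tests under these designs demonstrate correctness of the
combinatorial machinery and calibration under independence, not robustness
to dependence.

## Numerical choices

* Zero p-values are clamped to `1e-300` with a warning before taking logs.
* Oracle evaluations are memoised per (level rounded to 12 significant
  digits, subset); Holm revisits only a handful of distinct levels.
* Rejection is `p <= level` everywhere; the suffix scan uses the equivalent
  statistic-vs-quantile comparison, so the two routes agree exactly.
* Exact interpolation and the closed-testing oracle cap the universe at 16
  features (lattice enumeration); `ct_bound_phibar()` caps the query set at
  22. Beyond the caps the greedy path serves queries at any scale.
* Features are handled internally as integer indices into the universe;
  string ids are resolved once at the interface.
* Degenerate inputs: empty query sets give bound 0; zero-variance features
  give p = 1 with a warning; a response with one group is an error.

## Problem sizes in the test suite

The suite verifies the lemma-style properties on ~2100 random instances
(universes of 4–12 features, up to 4 focus sets, both Fisher-based and
tabulated oracles), runs the null-calibration checks at 2000 replications
(Monte Carlo tolerance $3\sqrt{p(1-p)/B}$), reproduces the stable
replicability cells at 1000 replications, and runs the focused-power
comparison at $w = 200$ with 100 replications — sizes chosen so the whole
suite completes in about a minute while keeping Monte Carlo error well below
the margins being tested.

## Known limitations

* Validity of the combination requires focus sets fixed independently of
  the data; nothing in the code can check this.
* The Fisher fast paths assume independent p-values within each focus set.
* Exact coherent bounds and the closed-testing oracle are exponential in
  $w$ and deliberately capped; they exist to verify the scalable paths, not
  to serve large problems.
* For heavily overlapping focus families the greedy and coherent bounds can
  be noticeably below the $\bar\phi$ closed-testing bound (see the gap
  discussion above); disjoint families avoid both this gap and the general
  conservativeness that overlap induces.
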