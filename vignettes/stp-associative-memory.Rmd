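---
title: "Methods: an STP-based associative memory and its Hopfield baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an STP-based associative memory and its Hopfield baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpam)
```

## The model

A pattern over $n$ binary neurons is a bipolar vector
$X = (l_1,\dots,l_n)^T \in \{-1,1\}^n$, equivalently a binary vector
$Y \in \{0,1\}^n$ with $k_i = 1$ iff $l_i = 1$. The semi-tensor product
(STP) generalizes the matrix product: for $A$ ($m \times n$) and $B$
($p \times q$), with $r = \mathrm{lcm}(n,p)$,
$$A \ltimes B = (A \otimes I_{r/n})(B \otimes I_{r/p}),$$
reducing to $AB$ when $n = p$. Identifying bit $k_i$ with the canonical
vector $\delta_2^{\,2-k_i}$ (a column of $I_2$), the STP chain
$\delta_2^{2-k_1} \ltimes \cdots \ltimes \delta_2^{2-k_n}$ collapses to a
single canonical vector $\delta_{2^n}^{\,r}$ with
$$r = (1-k_1)2^{n-1} + (1-k_2)2^{n-2} + \cdots + (1-k_{n-1})2 + (2-k_n).$$
This is the *algebraic form* of the pattern; component 1 is the most
significant bit, so the all-ones pattern has $r = 1$ and the all-zeros
pattern $r = 2^n$. The chain route and the closed form are implemented
independently (`encode_mode(x, via = "chain")` vs the default) and tested
against each other.

Because the $2^n$ canonical vectors are orthonormal, the memory matrix
$$L = \sum_{k=1}^{m} \delta_{2^n}^{\,r_k}\,(\delta_{2^n}^{\,r_k})^T$$
is a 0/1 diagonal matrix and every stored pattern is an exact fixed point:
$L\,\delta^{r} = \delta^{r}$ for stored $r$, and $L\,\delta^{r} = 0$
otherwise. Storage capacity is therefore $2^n$ by construction — the
contrast with the Hebbian Hopfield baseline, whose practical capacity for
non-orthogonal patterns is around $0.13n$–$0.15n$.

### Association under bit errors

Robustness comes from an on-demand column update governed by the **bit
error control** parameter $E_c$ (a non-negative integer, in bits). For a
probe index $r_i$ with no stored match, each stored pattern $k$ at Hamming
distance $s_{ki}$ with $0 < s_{ki} \le E_c$ receives
$$l_{r_k r_i} \;=\; \frac{1/s_{ki}}{\sum_{j\,:\,0 < s_{ji} \le E_c} 1/s_{ji}},$$
and all other entries are zero. The column is a probability vector
(or zero when no stored pattern is within reach); probability times
distance is constant across its support, so closer patterns are strictly
more likely and equal distances tie symmetrically with no tie-break
needed. Recognition (`recognize()`) follows the procedure: encode, look up
the column, and if it is zero run the update and re-check; a probe farther
than $E_c$ from every stored pattern is *rejected*. A hard label, when one
is needed, is a seeded draw from the distribution (`classify_sample()`).

## Tunable parameters

* `bec` ($E_c$, bits, default 0): the association radius. 0 disables
  association entirely (exact lookup only). Larger values trade precision
  for recall; when $E_c$ is large a probe may belong to several stored
  patterns at once, and the model deliberately returns the full
  distribution rather than forcing an assignment.
* `alpha` ($\alpha > 0$, default 1): the Hebbian gain
  $W = \alpha\sum_k (X^k (X^k)^T - I)$. Pure scaling — sign-based recall
  is invariant to it — kept because the storage rule is conventionally
  written with it.
* `zero` (sign-of-zero convention, default `"minus"`): a synchronous
  recall step is $\mathrm{sgn}(Wx)$, and a zero pre-activation must map
  somewhere. The default maps 0 to $-1$, which is the convention required
  to reproduce the worked 5-node recall arithmetic (the third pattern has
  a zero fifth pre-activation and recalls to $-1$ there); `"plus"` and
  `"keep"` (hold the previous state) are available as explicit options.
* `cap` in `learn_all()` (default 16) and the $n \le 8$ cap in
  `dense_memory_matrix()`: the full column map has $2^n$ entries and the
  dense matrix $4^n$; the caps keep both usable as exhaustive small-$n$
  oracles while the lazy per-query path handles larger $n$.

## Numerical choices

* **Indices are doubles, exact to $n = 53$.** Canonical-vector indices
  reach $2^n$, past R's 32-bit integers; doubles are exact integers to
  $2^{53}$ and `binary_to_index()` refuses longer patterns rather than
  silently losing precision.
* **Exact rationals in learned columns.** Distances are integers, so each
  learned column is computed over a common denominator (the lcm of the
  in-window distances): the worked example's column is carried as
  $2/5, 1/5, 2/5$ exactly, and the CLI emits both decimals and `"num/den"`
  strings. If the common denominator ever left exact integer range (very
  long patterns with a large $E_c$) the probabilities fall back to
  floating point and the rational fields are `NA`; numeric values are
  tested to $10^{-12}$.
* **Cache semantics.** Learned columns are cached inside the memory object
  (an environment, so learning-on-demand needs no reassignment). Rejected
  probes are *not* cached, so raising $E_c$ later reconsiders them.
  Changing $E_c$ via `set_bec()` clears the cache — every cached column is
  valid for exactly one $E_c$. Learned columns never count as stored
  patterns for later queries.
* **Degenerate inputs.** An empty pattern list yields the zero matrix;
  duplicate or mixed-length patterns are rejected at construction with the
  offending position; pattern components outside the accepted alphabets
  are rejected, never coerced. A probe that *is* a stored pattern is an
  error for `update_column()` (exact recognition short-circuits first),
  and the $0 < s$ guard is still enforced defensively.

## The synthetic generator and what the tests show

`generate_patterns(n, m, seed)` samples $m$ distinct patterns uniformly
from $\{-1,1\}^n$ (index sampling without replacement in the dense regime,
rejection sampling otherwise), and `corrupt_mode(x, flips, seed)` flips
exactly `flips` distinct uniformly chosen positions, so probe distance is
controlled exactly. `capacity_experiment()` uses both: for each load $m$
it stores the same random patterns in a Hebbian DHNN and an STP memory
($E_c$ = `flips`), probes every stored pattern after corruption, and
reports exact-recall fractions. DHNN success is one synchronous step
returning the original pattern (matching the worked example's
verification); STP success is recognition returning the original index —
automatic at `flips = 0` by the fixed-point property, and defined as the
unique most-probable candidate otherwise. Per-trial sub-seeds are derived
deterministically from the one experiment seed.

Uniform random patterns are the standard capacity-analysis regime and
roughly the hardest case for the Hebbian rule short of deliberately
correlated patterns. They do **not** emulate structured real data
(correlated bits, unequal on/off rates, burst rather than independent bit
errors), so a passing capacity contrast here shows the storage-capacity
mechanism, not field performance on, say, sensor patterns.

The problem sizes exercised by the test suite were chosen as the smallest
that make each claim meaningful: exhaustive small-$n$ oracles at
$n \le 6$–$8$ (dense matrices and full bijection checks), the
full-capacity property at $n = 10$ (all 1024 patterns stored and recalled,
far beyond the $0.15n \approx 1.5$ Hebbian regime at that size), and the
Monte-Carlo capacity contrast at $n = 32$ with loads 2–20 and 10 trials —
enough replication that near-perfect recall at $m = 2$ and clear
degradation by $m = 20$ are stable across seeds.

## Design choices

* The memory is an index set plus a sparse column cache; the dense
  $2^n \times 2^n$ matrix exists only as a capped test oracle. This
  mirrors how the model is meant to be used — only the probed column is
  ever needed.
* Synchronous whole-vector updates are the DHNN default because they match
  the worked single-step arithmetic; `dhnn_recall()` additionally iterates
  to a fixed point and reports 2-cycles (possible under synchronous
  symmetric dynamics) as `cycle_or_cap`. Asynchronous dynamics are out of
  scope.
* Canonical-vector indices are 1-based everywhere in the public interface,
  matching the $\delta_N^i$ notation.
* The bitstring file dialect (`11011`, leftmost character = component 1)
  is canonical because binary forms are what the encoding manipulates;
  signed tokens (`1 -1 1 ...`) are accepted for bipolar input. Dialects
  never mix within a file.

## Known limitations

* The canonical-vector state space is exponential; the implementation is
  lazy and sparse, but `learn_all()`/`dense_memory_matrix()` are
  inherently capped, and $n > 53$ is unsupported.
* A large $E_c$ dilutes the learned distributions (many stored patterns in
  reach); choosing $E_c$ is left to the user, as is any rule for resolving
  multi-membership — the model reports the distribution.
* One probe, one application of $L$: there are no iterated attractor
  dynamics on the STP side, and no energy-function analysis of the DHNN.
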