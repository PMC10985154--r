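# stpam — semi-tensor product associative memory

Associative memory for binary patterns built on the **semi-tensor product
(STP)** of matrices, with a classical discrete Hopfield network (DHNN) as a
capacity baseline.

A Hebbian Hopfield network with n neurons can reliably store only about
0.13n–0.15n non-orthogonal patterns; beyond that, recall degrades and the
network drifts to spurious attractors. The STP model sidesteps this limit
by a change of representation. A bipolar pattern X ∈ {−1, 1}ⁿ is converted
to its binary form Y ∈ {0, 1}ⁿ and then to a *canonical vector*
δ<sub>2ⁿ</sub><sup>r</sup> (the r-th column of the 2ⁿ × 2ⁿ identity), where

r = (1 − k₁)·2ⁿ⁻¹ + (1 − k₂)·2ⁿ⁻² + … + (1 − kₙ₋₁)·2 + (2 − kₙ).

Equivalently, each bit kᵢ becomes δ₂^(2−kᵢ) and the STP of the chain
collapses to a single canonical vector. All 2ⁿ canonical vectors are
mutually orthogonal, so the memory matrix

L = Σₖ δ<sub>2ⁿ</sub><sup>rₖ</sup> (δ<sub>2ⁿ</sub><sup>rₖ</sup>)ᵀ

stores every pattern as an exact fixed point: L δ<sup>r</sup> = δ<sup>r</sup>
for every stored r. Capacity is 2ⁿ by construction. Robustness to bit
errors comes from an on-demand update: a probe at index rᵢ that matches no
stored pattern gets a learned column whose entry for the k-th stored
pattern at Hamming distance s<sub>ki</sub> is

l<sub>rₖ rᵢ</sub> = (1/s<sub>ki</sub>) / Σ<sub>j: 0 < s<sub>ji</sub> ≤ E_c</sub> (1/s<sub>ji</sub>),

an inverse-distance probability distribution over the stored patterns
within the **bit error control** radius E_c. L is never materialized at
scale: the package keeps the stored index set plus a cache of learned
sparse columns.

The package is for anyone studying attractor-network storage capacity or
content-addressable memories over binary codes: it reproduces the model's
worked 5-node examples bit-exactly and demonstrates the capacity contrast
with the Hebbian DHNN by simulation.

## Worked example

Store the four 5-node patterns and probe the memory:

```r
library(stpam)
modes <- list(c(1,1,-1,1,1), c(1,-1,1,-1,-1), c(-1,1,1,-1,1), c(-1,-1,-1,1,1))
mem <- stp_memory(modes, bec = 2)
stored_indices(mem)
#> [1]  5 12 19 29

recognize(mem, c(1,-1,1,-1,-1))      # a stored pattern: exact fixed point
#> query delta index 12: recognized_exact
#>   -> 12  p = 1 (1/1)

recognize(mem, c(-1,1,-1,1,1))       # the first pattern with bit 1 flipped
#> query delta index 21: classified_by_association
#>   -> 5  p = 0.4 (2/5)
#>   -> 19  p = 0.2 (1/5)
#>   -> 29  p = 0.4 (2/5)
```

The probe (−1,1,−1,1,1) encodes to δ₃₂²¹, which is empty in L, so the
memory learns column 21 on demand: the stored patterns at distances 1, 2,
and 1 (the one at distance 5 is outside E_c = 2) receive inverse-distance
probabilities 2/5, 1/5, 2/5. `classify_sample()` draws a hard assignment
from that distribution.

The Hebbian baseline on the same patterns shows the capacity problem —
only the second pattern is a fixed point of one synchronous step:

```r
W <- hebbian_weights(modes)          # symmetric, zero diagonal
recall_step(W, c(1,1,-1,1,1))
#> [1] -1  1 -1  1  1                 # != the stored pattern
```

`capacity_experiment()` runs the Monte-Carlo contrast at any size, and the
`stpam` CLI (`inst/exec/stpam`) exposes `encode`, `memorize`, `recognize`,
`transitions` (DOT/TSV state-transition graph), `dhnn`, and `simulate`
from the shell.

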