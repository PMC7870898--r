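---
title: "Models and methods for autocatalytic RNA network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for autocatalytic RNA network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autocatnet)
```

This vignette documents the models implemented in `autocatnet`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The chemistry and its graph representation

A catalytic species is a covalent WXYZ ribozyme identified by two letters:
the variable base M of its internal guide sequence (IGS, `gMg`) and the
variable base N of its tag (`cNu`). Catalysis is directional: a catalyst
whose IGS base-pairs with a substrate's tag accelerates that substrate's
ligation into the covalent ribozyme. A species set therefore induces a
directed graph in which nodes are species and an edge j → i means "species
j catalyzes the formation of species i", drawn whenever
`alpha(igs_j, tag_i)` reaches the table's `edge_threshold`.

Two catalytic modes coexist and are quantified by the titration relation
`v0 = alpha * x + beta`:

* `alpha` (min⁻¹ per µM of catalyst): first-order catalysis by covalent
  ribozymes;
* `beta` (µM min⁻¹): zeroth-order catalysis by noncovalent WXY·Z fragment
  complexes, present from the start of the reaction.

`fit_titration()` estimates both by ordinary least squares and reports
standard errors, residual variance and R².

### The default rate table is a placeholder

Measured per-pair rates are experiment-specific, so every quantitative
function accepts a user-supplied table (`read_rate_table()`, CSV schema
`igs,tag,alpha,beta`). The shipped default encodes only the robust
qualitative structure of the chemistry: G·C and C·G are the strongest
pairs, A·U and U·A are weaker (ratio 0.3), and wobble (G·U, U·G) and
mismatched pairs are negligible (zero). Magnitudes — `alpha` = 0.02 min⁻¹
strong, `beta = alpha/10` µM min⁻¹ — were chosen once so that a 1-h
incubation of small networks accumulates covalent ribozyme on the
0.01–1 µM scale, the range where the landscape statistics (for example a
0.08 µM high-yield cut) are meaningful. Results that depend on rate
*ratios* and topology (fractions, perturbations, trajectory statistics)
are insensitive to the overall scale; absolute yields are not, and should
be computed with measured rates.

The default `edge_threshold` is half the smallest positive Watson-Crick
`alpha` (half the smallest positive rate for abstract alphabets): strong
and weak WC pairs become edges, wobble/mismatch pairs do not. Users
modelling weak non-WC catalysis explicitly can lower it.

## The linear kinetic model

Stacking species concentrations into `x` (µM), the production rates are

    dx/dt = A x + b,   x(0) = 0,

with `A[i,j] = alpha(igs_j, tag_i)` and `b[i] = sum_j beta(igs_j, tag_i)`.
The model makes two approximations: noncovalent complexes form fast
relative to the 1-h incubation (the forward rate 0.65 µM⁻¹min⁻¹ at 1.6 µM
of Z gives a ~1 min complex-formation time), and substrates are not
significantly depleted, so the system stays linear. Both covalent-driven
(`A x`) and noncovalent-driven (`b`) regimes are contained in the one
linear system; no hand-mixed interpolation between regimes is used.

`solve_kinetics()` evaluates the exact solution through the exponential of
the augmented matrix `[[A, b], [0, 0]]`. This avoids inverting `A`
(frequently singular: many species receive no catalysis) and is accurate
for any `t >= 0`; agreement with adaptive numeric integration
(`deSolve::ode`, rtol 1e-10) is verified to 1e-8 relative error in the
test suite. Tiny negative round-off (~1e-16) is clipped to zero.
`predict_fractions()` normalizes `x(t)` at the incubation time (default
`t = 60` min, the experimental 1 h, configurable) and `predict_yield()`
sums it.

Two network-theoretic approximations are provided. In the noncovalent-only
limit (`A = 0`) the composition equals the `beta`-weighted in-degree
fractions at every time — an identity used as a test oracle. In the
covalent-dominated long-time limit the composition direction converges to
the leading eigenvector of `A` whenever the dominant eigenvalue is simple
and positive. `eigenvector_fractions()` uses power iteration from the
uniform vector with an L1 convergence tolerance of 1e-12 and an iteration
cap (default 10,000); hitting the cap — possible under rotational
degeneracy, e.g. a pure cycle — flags the result and warns rather than
failing. `indegree_fractions()` takes `alpha` weights (the perturbation
theory's regime) or `beta` weights (the noncovalent regime) by argument.

## The perturbation statistic and its analytical prediction

For networks G and G′ = G + {a}, compositions are renormalized on the
common species V = species(G) and compared in L1:
`p = sum_{v in V} |y'_v − y_v|`, which is symmetric, zero iff the
renormalized compositions agree, and at most 2 (a full compositional
switch). Because the added species' own fraction is excluded by the
renormalization, p isolates how a reshuffles the *pre-existing* species.

Under the in-degree approximation the prediction is

    p_hat = 2 n (1 − n m / s) / (s + n),   s = sigma_G / e,

derived assuming each of a's n targets previously received catalysis only
from the m same-IGS catalysts at rate e. `predict_perturbation()` returns
the formula value as-is with `valid = FALSE` when it leaves [0, 2] (the
assumptions failed), rather than clamping; downstream analyses filter on
the flag. The test suite verifies the formula two ways: exactly (1e-10) on
constructed networks satisfying the assumptions, and via the generalized
identity `p = 2 e n (sigma_G − D_T) / (sigma_G (sigma_G + n e))` (with
`D_T` the targets' total prior in-degree) on random networks whenever all
target fraction changes are positive.

Conventions fixed here (the formula's inputs admit variants):

* `sigma_G` sums `alpha` rates of all interactions present in G at or
  above the edge threshold, self-loops included, each directed pair once.
  `beta` contributions are excluded — `e` is an `alpha` rate and the two
  must share units for `s` to be dimensionless.
* `n` counts targets among species of G only (p is evaluated on V).
* `e` is the maximal `alpha` over the added catalyst's IGS row — its
  strong-pair rate in the concrete chemistry.

## Landscape statistics

`aggregate_networks()` groups droplets by exact species set and reports
per-species mean ± s.d. fractions and mean yield ± SEM.
Ranking comparisons (`rank_conservation()`) use strict inequality; exact
ties count as conserved (ties are measure-zero on real data, but synthetic
landscapes need a fixed convention). A species pair is "non-conserved"
when the minority orientation occurs in at least `flip_threshold` (default
10%) of the networks containing both; pairs co-occurring in fewer than two
networks are excluded from the denominator.

The growth–variation trade-off test (`tradeoff_test()`) cross-classifies
records at `p > 0.8` and `yield > 0.08 µM` and applies a one-sided Fisher
exact test (alternative: fewer strongly-perturbable high-yield networks
than independence predicts), reporting the conditional-MLE odds ratio with
its exact 95% CI (`stats::fisher.test`). Degenerate margins warn and
return p = 1. Binned summaries (`sigma_yield_correlation()`,
`model_measurement_correlation()`) use decile bins and discard bins with
fewer than 10 points, following the figure convention.

## Growth trajectories, inflexions, innovations

`grow_trajectory()` starts from a uniform random species set and adds one
uniformly drawn species at a time, recording the perturbation of each
addition. Per-step compositions default to `alpha`-weighted in-degree
fractions — fast and matching the analytical theory — with the full
kinetic model available by flag (`composition = "kinetic"`). Steps where
both compositions have zero mass (no catalysis yet, common in sparse
chemistries) contribute p = 0 with a warning instead of aborting the
trajectory.

Inflexions of the cumulative series P are located where the discrete
second difference `d2[k] = P[k+1] − 2 P[k] + P[k−1]` changes sign; runs of
zeros between opposite signs count as a single change ("touches zero then
changes"). Second differences below `1e-8 * max(P)` are treated as zero so
that round-off on analytically straight segments cannot fabricate sign
changes. Sharpness is `|P[k+2] − 3 P[k+1] + 3 P[k] − P[k−1]|`, the third
difference spanning the change; the index convention places the inflexion
at the last index of the old curvature sign, so the addition that breaks
the curvature is step `k + 1`, and innovation labels are matched at that
step. Alternative stencils were considered (one-sided third differences)
but the spanning stencil is the only one whose magnitude equals the jump
in `d2` across the inflexion, which is the quantity being ranked.

"Strong" inflexions are the top quartile of sharpness: a
linear-interpolation 75th percentile (`stats::quantile`, type 7), computed
over the pooled ensemble by default, with per-trajectory classification
available by flag (the pooled variant is the default because a single
ensemble-wide scale makes counts comparable across trajectories).

A step is a catalytic innovation when the added species realizes at least
one edge whose (IGS, tag) letter pair is a designated strong pair — C·G or
G·C in the concrete chemistry, the table's maximal-rate pairs in general —
and that pair type was absent from every edge of the network before the
addition.

### Abstract chemistries and the density study

`make_chemistry(L, n_pairs, density, rate)` builds an L × L species grid
with a pool of specific IGS/tag letter pairs (letter i's IGS paired with
letter i+1's tag — a cyclic matching generalizing base-pair
complementarity — capped at 24 pairs). `density` is the fraction of the
pool retained by random removal; the resulting probability that one random
species catalyzes another (`retained pairs / L²`) is stored as
`catalytic_density`. All retained pairs carry the uniform rate e by
default; an optional two-tier variant (`n_strong`, `weak_ratio`) mirrors
the concrete strong/weak hierarchy.

`simulate_trajectory_study()` runs seeded trajectory ensembles per density
and summarizes: targeting breadth of strong-perturbation catalysts by
inflexion rank, waiting times between strong inflexions by rank, and the
distribution of strong-inflexion counts per trajectory. Every trajectory
draws its own deterministic sub-seed, so ensembles reproduce bit-for-bit
under a fixed seed.

One deliberate split in the analyses: innovation statistics (sharpness
contrast, innovation-count correlation) are evaluated on the *concrete*
chemistry, where innovations are rare, discrete events (at most the two
strong pair types per trajectory). In a uniform-rate abstract chemistry
every specific pair is maximal, so nearly every early addition is an
"innovation" (typically 13–21 per long trajectory) and the label loses its
discriminating meaning; the abstract chemistries are used for what they
are built for — varying catalytic density — where dense chemistries show
many weak inflexions and sparse chemistries few strong ones.

## Droplet count processing

The pipeline is a pure function of the UMI records and the configuration.
Records are deduplicated on (droplet barcode, molecule, UMI) with read
counts summed, then filtered by per-class minimum reads per UMI (default 2
for both ribozymes and hairpin reporters; the appropriate value depends on
the sequencing run's reads-per-UMI distribution and is configurable). Per
droplet:

1. hairpin reporters with < 7.5% of hairpin UMIs are discarded (they
   typically arise from barcode cross-contamination);
2. the droplet's species set is the union of fragment sets encoded by the
   retained reporters;
3. ribozyme UMIs of species outside that set are discarded;
4. droplets with fewer than 10 retained hairpin UMIs or 20 retained
   ribozyme UMIs are rejected (with a logged reason: `no_reporter`,
   `low_hairpin`, `low_ribozyme`); the thresholds are compared
   non-strictly (≥), a convention fixed here and configurable;
5. fractions are per-species ribozyme UMIs over total ribozyme UMIs, with
   explicit zeros for encoded species without UMIs.

Yield conversion uses the reporters of known concentration: conversion =
(number of retained reporters × effective per-reporter concentration) /
total retained hairpin UMIs, and yield = ribozyme UMIs × conversion. The
effective concentration is the nominal 0.03 µM diluted from one 5 pL
droplet into the fused volume (50 pL carrier + k × 5 pL, k approximated by
the retained-reporter count); both the volumes and a fixed effective
concentration override are configurable, since the true conversion
constant depends on the fusion geometry.

## Synthetic data: what it emulates, and what it does not

`design_combinations()` reproduces the two-stage combination design: the
total number of fragment slots (default 50 over 24 mixtures) can be
screened for network diversity (`choose_total_slots()`), and the
assignment is then selected among random candidates to maximize the summed
Shannon entropies of the distributions of the expected growth rate (first
eigenvalue of `A`) and transient time (gap between first and second
eigenvalues) over simulated random fusions. Histogram entropies use 20
fixed-width bins over the observed range (configurable); eigenvalues are
sorted by real part and imaginary parts are discarded with a warning if
encountered. Desk-scale defaults evaluate 1,000 candidates over 1,000
fusions each (the original screen used 100,000 over 10,000); network
eigenvalues are memoized by species-set key, which keeps this tractable.

`simulate_experiment()` draws, per droplet: a fusion count (default
uniform on 1–5; the empirical fusion distribution is not public, so this
is a stated model), mixtures with replacement, the union network, and the
true composition/yield from the kinetic model. It then emits hairpin UMIs
per encoded reporter (Poisson), ribozyme UMIs multinomially at the true
fractions (Poisson depth), reads per UMI as 1 + Poisson, and spurious
singleton error UMIs (Poisson per droplet) that the read filter should
remove. Species sets with no catalytic pairing at all accumulate nothing:
their truth fractions are zero, no ribozyme UMIs are emitted, and the
pipeline later rejects those droplets — mirroring what sequencing of such
a droplet would look like.

What passing tests on these synthetics do show: the pipeline's filters,
thresholds and conversions are internally consistent, and estimated
fractions converge to the generator's kinetic-model truth at realistic
depths (mean absolute error < 0.05 at 500 UMIs/droplet). What they do not
show: robustness to barcode error correction (upstream of this package),
reads-per-UMI distributions with heavy tails, droplet-fusion biases,
PCR-crossover contamination, or any mismatch between the linear kinetic
model and real reaction kinetics — on real data the model is an
approximation, and its residual structure cannot be learned from data
generated by the model itself.

## Problem sizes and determinism

The shipped test suite runs at desk scale, chosen as the smallest sizes at
which each statistical check is decisive: 100-instance oracle sweeps for
the kinetics and perturbation identities, 500 Monte-Carlo titrations,
1,000 synthetic droplets at depth 500 for pipeline recovery, and
trajectory ensembles of 200 (concrete chemistry 3 → 16; abstract 24-pair
chemistry 2 → 50, densities 0.1 and 1). The full-scale ensemble of the
density study (1,000 trajectories, 2 → 100) runs in well under 15 minutes
on one CPU via `simulate_trajectory_study()` defaults. All generators take
explicit integer seeds and derive per-trajectory/per-density sub-seeds, so
every ensemble statistic is reproducible bit-for-bit.

## Known limitations

* The default rate table is qualitative; absolute yields and any analysis
  sensitive to rate magnitudes require measured rates.
* Substrate depletion, saturation kinetics, temperature dependence and
  stochastic (small-copy-number) kinetics are out of scope; the linear
  model is an early-reaction approximation.
* Perturbation records compare *separately grown* networks; adding a
  species to a preformed network with multiple stable states could end
  elsewhere, and that scenario is not modelled.
* Multi-species additions are not enumerated; only single-addition pairs.
* The titration Monte-Carlo check evaluates recovery against design-based
  (true-noise) standard errors; estimated standard errors are validated
  against the analytic formula but carry the usual t-distribution
  inflation at small point counts.
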