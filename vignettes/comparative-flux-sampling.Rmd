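---
title: "Comparative flux sampling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative flux sampling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcontrast)
```

# The scientific question

Two cell types can express the same metabolic enzymes and still run their
central metabolism in qualitatively different regimes. A striking example is
the electron transport chain (ETC): when Complex I activity is high but
mitochondrial oxygen intake is low — a pattern seen when omics data show
up-regulated Complex I subunits while respirometry shows low oxygen
consumption — the quinone pool must be re-oxidized somewhere other than
Complexes III/IV. Succinate dehydrogenase (SDH, Complex II), which couples
succinate ⇌ fumarate to the quinone pool, can absorb those electrons by
running in reverse (fumarate → succinate), the hallmark of ischemic
metabolism. The reversal has a metabolomic fingerprint: an elevated
intra-cellular succinate-to-fumarate ratio, together with a low adenylate
energy state.

`fluxcontrast` implements the computational side of that argument as a
reusable, testable pipeline:

1. **Context-specific reconstruction** — reduce a generic metabolic network
   to the reactions supported by each cell type's transcripts and proteins.
2. **Comparative constraints** — encode the hypothesis "cell type A has high
   Complex I flux but low O~2~ intake relative to B" as fractional flux
   bounds.
3. **Uniform flux sampling** — characterize each constrained model by the
   distribution of feasible steady-state flux vectors rather than a single
   optimum.
4. **Distribution contrast** — flag reactions whose flux distributions
   separate between the models, and in particular reactions driven to
   negative (reverse) flux.
5. **Metabolomic indices** — intra-sample metabolite ratios and adenylate
   energy statistics that can corroborate or refute the flux prediction.

# The model

## Steady-state flux polytope

A metabolic network with $m$ metabolites and $r$ reactions is summarized by
its stoichiometric matrix $S \in \mathbb{R}^{m \times r}$. The feasible set
under the steady-state assumption is the polytope

$$P = \{ v \in \mathbb{R}^r : S v = 0,\; lb \le v \le ub \}.$$

All flux computations in the package operate on the null-space
parameterization $v = N t$, where the columns of $N$ form an orthonormal
basis of $\ker S$: flux balance analysis (FBA) maximizes one coordinate of
$v$ over $P$ by linear programming, flux variability analysis (FVA) computes
per-reaction extremes, and the sampler explores $P$ uniformly.

The LP solver is a dense two-phase primal simplex with Bland's rule. That
choice is deliberate: the polytopes here are small (tens of free
dimensions), Bland's rule makes the solver deterministic and immune to
cycling, and a dense tableau is simpler to audit than a sparse
factorization. Feasibility tolerance is $10^{-9}$; tests compare the solver
against brute-force vertex enumeration on random networks at $10^{-8}$.

## Gene–protein–reaction rules and presence calling

Each reaction may carry a boolean gene rule (`and` = complex subunits,
`or` = isozymes). Genes are called **absent** on a platform when their
signal falls below a cutoff in a majority of replicates — below 5 counts in
2 of 3 samples for transcripts, below 2000 abundance units in 2 of 3 for
proteins; for other replicate counts the rule generalizes to
$\lceil (n+1)/2 \rceil$-of-$n$, which reduces to 2-of-3 at $n = 3$. Calls
from the two platforms are merged conservatively: a gene is absent only if
it is absent on *every* platform where it was measured. This guards against
incomplete annotation on a single platform in cross-species comparisons,
where one platform may simply fail to detect a gene that is present.

Rule evaluation is three-valued (`active`/`inactive`/`unknown`), and
`unknown` — all genes unmeasured — is treated as *active* during pruning:
missing evidence never deletes a reaction.

## Pruning with protected functions

Reactions whose rule is inactive are candidates for removal. Candidates are
visited in lexicographic id order and removed one at a time, but only if the
reduced model retains flux-carrying capacity ($\ge \varepsilon = 10^{-6}$
flux units, well above LP tolerance and well below any physiological flux)
through a witness reaction for each protected function: ATP synthesis, the
TCA cycle (citrate synthase), and glycolysis. The paper-level concept names
pathways, not reactions, so the witnesses are configurable ids.

The fixed visit order makes pruning reproducible, at a price: when two
absent-gene reactions are alternative routes for the same protected
function, which one survives depends on the order. The package surfaces this
honestly — `prune_order_sensitivity()` reruns the pruning in reverse order
and reports every reaction whose fate differs.

## Comparative constraints

The hypothesis is encoded by fractional bounds relative to each model's own
*theoretical maximum* (the FBA optimum of that reaction):

* model A: Complex I **lower** bound at $f_{hi} = 0.7$ of its maximum, O~2~
  transport **upper** bound at $f_{lo} = 0.3$ of its maximum;
* model B: Complex I **upper** bound at $0.3$, O~2~ **lower** bound at
  $0.7$.

Both maxima are computed on the unconstrained context models *before* either
bound is applied — the two constraints express one joint hypothesis, not a
sequential curation. After construction the pipeline asserts that B's O~2~
lower bound strictly exceeds A's O~2~ upper bound, so the intended oxygen
ordering holds by construction, and that both models remain feasible. The
mirrored $f_{hi}/f_{lo}$ values for the O~2~ reaction are a package default
(exposed in the configuration), chosen for symmetry with the Complex I
fractions; `constraint_sensitivity_sweep()` shows how the reversal readout
behaves across $(f_{hi}, f_{lo}) \in \{0.5,\dots,0.9\} \times
\{0.1,\dots,0.5\}$ — on the toy network the reversal is forced in every
feasible combination.

## Uniform sampling

`sample_fluxes()` draws from the uniform distribution on $P$ by hit-and-run
Markov chain Monte Carlo in the null-space coordinates:

* **Pinned coordinates** (bounds equal, or FVA range below $10^{-9}$) are
  converted to equality constraints and removed from the walk. The null
  space of those equalities is taken from an SVD with an explicit rank
  tolerance, because a coordinate can be pinned by mass balance itself, in
  which case its constraint row is identically zero and contributes no
  direction.
* **Rounding**: a pilot run estimates the sample covariance; its Cholesky
  factor re-scales the walk so that elongated polytopes mix at the same
  rate in every direction.
* **Chains and thinning**: 4 chains by default (2 in reduced test settings),
  warmup 1000 steps, thinning $10 \times d$ steps where $d$ is the free
  dimension — the standard dimension-scaled spacing for hit-and-run. Each
  chain starts from a random pilot draw.
* **Randomness**: all draws come from R's seeded generator; one integer seed
  fully determines the output, byte for byte. (A counter-based generator
  would offer the same guarantee; R's Mersenne-Twister via `set.seed()` is
  the idiomatic choice in this language and keeps the package free of extra
  dependencies.)

Every emitted sample is asserted to satisfy
$\lVert S v \rVert_\infty \le 10^{-6} \max(1, \lVert v \rVert_\infty)$ and
the bounds to within $10^{-6}$. Convergence is reported per reaction as
split-chain $\hat R$ and effective sample size; pinned reactions are
reported as *not applicable* rather than propagating NaN.

## Distribution contrast

For each shared reaction the two sample sets are summarized by medians and
IQRs, plus a histogram overlap coefficient: 50 shared bins spanning the
pooled 1st–99th percentile range (robust to single outlier draws), overlap
$= \sum_b \min(f^A_b, f^B_b) \in [0, 1]$. A reaction is **shifted** when the
overlap falls below 0.2 *and* the median difference exceeds 1.0 pooled IQR —
the paper-level readout is visual, so these numeric defaults are declared
package choices, exposed in the configuration. A shifted reaction is
**reversed** when its model-A median is strictly negative while model-B's is
non-negative; this is the Complex II readout.

## Metabolomic indices

Ratios are computed *within* each sample before any group summarization,
which cancels per-sample scaling such as cell-number normalization; the
tests assert this invariance explicitly. Group comparisons use the unpaired
two-sided Student (equal-variance) t-test — the literal Student form, not
Welch — with Benjamini–Hochberg correction applied within an analysis panel
(all TCA ratios together; the three adenylate indices together). Tests are
computed on raw ratios by default with a `log_ratios` switch, since the
upstream convention leaves the scale unstated. The energy charge is
Atkinson's $(ATP + \tfrac12 ADP)/(ATP + ADP + AMP)$, in $[0, 1]$ with
equality at 1 exactly when ADP and AMP vanish. Degenerate inputs (a ratio
with zero variance in both groups, an infinite ATP/ADP ratio when ADP is 0)
yield `NA` statistics rather than aborting a whole panel, and `NA` p-values
are excluded from the BH family. The π-value ranking score for enrichment
pre-ranking is $\mathrm{lfc} \cdot (-\log_{10} p)$, with $p = 0$ rejected so
the caller must floor p-values explicitly.

# The synthetic-data layer

The generators are first-class, tested code: they define the conditions
under which every claim in the test suite is evaluated.

## Toy network

`build_toy_network()` returns a fixed 24-reaction, 24-metabolite model:
glucose uptake (capacity 5), a lumped glycolysis (`GLYC`: glucose + 2 ADP →
2 pyruvate + 2 ATP), a lactate branch, pyruvate dehydrogenase, a TCA loop
(CS → IDH → AKGDH → SDH → fumarase → MDH), the ETC (`CI_toy` with capacity
20 feeding a proton-motive pool, `CIII_toy`/`CIV_toy` consuming O~2~), ATP
synthase and an ATP demand, O~2~ transport (`O2tm_toy`, fed by an exchange
of capacity 10), and exchanges for lactate, succinate and malate (malate
uptake capacity 16). Only SDH (`CII_toy`) is reversible ($[-1000, 1000]$)
among the TCA steps, so any reverse-flux signal is attributable to it. Every
reaction carries a one-gene rule (`<reaction>_g`).

The malate uptake plus reversible fumarase provide the fumarate supply that
reverse SDH needs; the capacities were chosen so that the constrained
scenario at $f_{hi} = 0.7, f_{lo} = 0.3$ is feasible *and* forces
`CII_toy` to strictly negative flux (its FVA interval in constrained A is
$[-12.5, -11]$), which `build_toy_network(verify = TRUE)` re-derives by LP
at build time. The network is a test instrument, not a physiological model:
it omits proton/charge balancing, P/O ratios, and cofactor detail.

## Omics and metabolomics generators

`simulate_expression()` draws negative-binomial counts (3 replicates per
platform): absent genes at mean 1, present genes at mean 100, dispersion 10,
protein values scaled ×400 so the same separation holds at the protein
cutoff of 2000. At these parameters an absent gene falls below the
transcript cutoff in any one replicate with probability
`pnbinom(4, mu = 1, size = 10)` ≈ 0.997, so the 2-of-3 rule recovers planted
absences with high probability, while present genes are essentially never
miscalled — the separability the presence-calling acceptance check relies
on.

The planted absent-gene set defaults to the lactate branch and ATP synthase
(`toy_absent_pool()`). This pool is deliberately interaction-free: none of
these reactions are alternative routes for one another, so sequential
pruning and exhaustive single-deletion testing agree on it, and the
acceptance comparison between the two is exact. ATP synthase is itself a
protected witness, so planting it absent exercises the `retained_capacity`
branch of the log.

`simulate_metabolomics()` draws log-normal abundances (σ = 0.1 on the log
scale) for 3 + 3 samples with planted group-A fold changes: succinate ×5
(the ischemia-like ratio effect), ATP ×⅓ and AMP ×3 (the low-energy
adenylate profile). Base abundances put ATP:ADP:AMP at 100:25:5 in the
reference group, giving an energy charge of ≈ 0.87 there and ≈ 0.63 in
group A.

## What passing tests do and do not show

The synthetic layer emulates the *structure* of real inputs — presence
thresholds, replicate counts, log-normal abundance noise, a reversible SDH
with a fumarate supply — not their biological complexity. Passing tests
demonstrate that the pipeline's machinery is correct (the sampler is
uniform, the LP is optimal, pruning respects capacity, the statistics match
their definitions) and that the ischemia-like scenario is recovered *when
the data contain it by construction*. They do not show that real
transcript/protein thresholds are well calibrated for any particular
platform, that a genome-scale model prunes to a physiologically sensible
context, or that SDH reversal occurs in any real cell type.

# Numerical choices and problem sizes

* LP feasibility/optimality tolerance $10^{-9}$; oracle agreement asserted
  at $10^{-8}$; sample-level mass balance at $10^{-6}$.
* Pinned-coordinate threshold $10^{-9}$ on the FVA range; SVD rank tolerance
  $10^{-9}$ relative to the largest singular value.
* Histogram overlap on 50 bins over the pooled 1st–99th percentile range;
  shift thresholds overlap < 0.2, median shift > 1.0 pooled IQR.
* The analysis scripts sample $n = 5000$ draws per model and condition (4
  chains, warmup 1000), matching the scale of the study design; the test
  suite and multi-seed acceptance checks use $n$ between 400 and 2000 with
  2 chains, sizes at which the toy polytopes already mix to split-$\hat R$
  ≈ 1.00 and the checks complete in seconds per seed.
* The ratio-recovery experiment uses 20 replicates per group rather than the
  study's 3: with σ = 0.1 the per-sample ratio SD is ≈ 14%, so at $n = 3$
  the ±10% recovery band is only ≈ 1.2 standard errors wide and no correct
  implementation could sit inside it 95% of the time; at $n = 20$ the band
  is > 3 SE. The generator default stays at 3 + 3 to mirror the study
  design; only the power experiment enlarges it.

# Known limitations

* The simplex is dense: genome-scale models (thousands of reactions) would
  need a sparse LP backend. The design isolates this behind
  `maximize_flux()`/`flux_variability()`, so swapping the solver would not
  touch any other module.
* Sampling assumes a bounded polytope; unbounded models are flagged as
  missing bounds rather than sampled.
* No thermodynamic (loopless) constraints: sampled flux vectors may contain
  internal cycles, as in any plain constraint-based treatment.
* The merge rule for platforms and the O~2~ constraint fractions are
  declared package defaults for genuinely under-specified choices; both are
  configuration-exposed so a user can encode a different reading.
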