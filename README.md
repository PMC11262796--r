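# fluxcontrast

Comparative constraint-based flux sampling and metabolomic index statistics
for R.

`fluxcontrast` is for systems biologists who want to ask: *do two cell types
run the same metabolic network in qualitatively different regimes?* It was
built around a concrete instance of that question — whether a cell type with
highly expressed Complex I but low oxygen consumption must operate
succinate dehydrogenase (SDH, Complex II) at low or reversed flux, the
ischemia-like regime — but every stage is a general, reusable tool:

1. **Context-specific reconstruction.** Starting from a generic network
   (SBML Level 2/COBRA or Level 3+fbc, or a tabular native format), genes
   are called present/absent from transcript and protein tables (absent =
   below cutoff in a majority of replicates; defaults 5 counts and 2000
   abundance units at n = 3), platforms are merged conservatively, and
   reactions whose gene rule is inactive are pruned — unless removal would
   destroy flux-carrying capacity for ATP production, the TCA cycle, or
   glycolysis.
2. **Comparative constraints.** The hypothesis "A has high Complex I, low
   O2 intake; B the reverse" becomes fractional bounds: A gets a Complex I
   *lower* bound at 70% of its theoretical maximum (the FBA optimum) and an
   O2-transport *upper* bound at 30%; B gets the mirror image.
3. **Uniform flux sampling.** Each model's steady-state polytope
   {v : S v = 0, lb ≤ v ≤ ub} is sampled uniformly by hit-and-run MCMC in
   null-space coordinates, with covariance rounding, pinned-coordinate
   elimination, multiple chains, and split-R̂/ESS diagnostics. One integer
   seed makes the output byte-reproducible.
4. **Distribution contrast.** Per-reaction medians, IQRs, and a histogram
   overlap coefficient flag *shifted* reactions (overlap < 0.2 and median
   shift > 1 pooled IQR) and *reversed* ones (model-A median < 0 ≤ model-B
   median).
5. **Metabolomic indices.** Intra-sample metabolite ratios (computed within
   each replicate, so per-sample scaling cancels), adenylate energy charge
   (ATP + ½ADP)/(ATP + ADP + AMP), AMP fraction, ATP/ADP, fold changes,
   unpaired two-sided Student t-tests with Benjamini–Hochberg correction,
   and the π-value ranking score lfc·(−log10 p).

A synthetic-data layer (`build_toy_network()`, `simulate_expression()`,
`simulate_metabolomics()`) generates a 24-reaction central-metabolism
network — glycolysis, TCA loop with an explicitly reversible SDH, ETC,
ATP synthase, O2 transport — plus seeded negative-binomial expression and
log-normal metabolomics tables, so the full pipeline is testable without
any external data. The methods vignette
(`vignettes/comparative-flux-sampling.Rmd`) documents the model,
assumptions, parameter defaults and design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
scenario (`Rscript analysis/01_simulate.R` … `05_metabolite_stats.R`),
writing tables under `results/analysis/`. In condensed form:

```r
library(fluxcontrast)

toy <- build_toy_network()                      # verified fixed network
cfg <- toy_scenario_config(seed = 17)           # planted: LDH_g, ATPS_g absent
sim <- simulate_expression(toy, cfg)
calls <- merge_presence(call_presence(sim$transcript, "transcript"),
                        call_presence(sim$protein, "protein"))
ctx_a <- prune_model(toy, calls)$model          # context A; B = unpruned toy

pair <- build_constrained_pair(ctx_a, toy, ci_id = "CI_toy",
                               o2_id = "O2tm_toy", f_hi = 0.7, f_lo = 0.3)
sa <- sample_fluxes(pair$a, n = 5000, seed = 18, n_chains = 4)
sb <- sample_fluxes(pair$b, n = 5000, seed = 19, n_chains = 4)
rep <- compare_distributions(sa, sb)
rep[rep$reaction == "CII_toy", c("median_a", "median_b", "overlap", "shifted")]
flag_reversed_reactions(rep)
```

Running the scripts prints (seed 17):

```
context A: 23 reactions (removed: LDH; capacity-retained: ATPS)
theoretical maxima: CI_toy = 20, O2tm_toy = 10 (both contexts)
constrained simulation: 18/23 reactions shifted
  Complex II (SDH): median A = -11.95, median B = 1.32, overlap = 0.00
  reversed reactions: CII_toy, FUM
succinate/fumarate: A 5.14+/-0.84 vs B 0.98+/-0.07 (q = 0.00152)
energy_charge: A 0.613 vs B 0.866 (q = 9.8e-05)
atp_adp_ratio: A 1.293 vs B 4.145 (q = 0.00739)
```

Read: pruning removed only the lactate dehydrogenase branch (ATP synthase
was protected); under the 70%/30% constraints the SDH flux distribution in
model A sits entirely below zero — the reaction runs in reverse, fumarate →
succinate, and fumarase (`FUM`) reverses with it as the fumarate supplier —
while model B keeps forward flux. The metabolomic indices agree with the
regime the constraints encode: a five-fold succinate/fumarate ratio and a
depressed adenylate energy charge in group A. In the unconstrained control
simulation of identical models, no reaction is flagged.

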