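---
title: "Methods: route scanning, metabolome statistics and fermentation quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: route scanning, metabolome statistics and fermentation quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmaflux)
```

`pmaflux` bundles the three computational layers of a polymalic-acid (PMA)
fermentation study of *Aureobasidium pullulans*: constraint-based analysis
of the malate-supply routes feeding PMA synthesis, the differential
statistics applied to GC–MS metabolome tables, and the bookkeeping
arithmetic of fermentation outcomes. This vignette records the models,
their assumptions, the tunable parameters, and the design choices taken
where more than one defensible option existed.

## Flux balance analysis and the LP kernel

Flux balance analysis (FBA) treats metabolism at steady state: for the
stoichiometric matrix $S$ (metabolites × reactions) and flux vector $v$
(mmol/gDW/h), the feasible set is $\{v : S v = 0,\; l \le v \le u\}$ and
the analysis maximises one flux — here the PMA synthesis rate — over that
polytope. Because every reaction carries finite box bounds, the feasible
set is bounded and the linear program can never be unbounded; the two
reportable outcomes are an optimum or infeasibility.

The LP kernel (`lp_solve()`, internal) is a dense bounded-variable
two-phase primal simplex using Bland's smallest-index rule throughout.
Bland's rule guarantees termination under the heavy degeneracy typical of
metabolic networks, at the cost of extra pivots that are irrelevant at
this problem size (tens of reactions). Tolerances: pivoting at $10^{-9}$,
phase-1 feasibility at $10^{-7}$ relative to the right-hand side, and test
assertions at $10^{-6}$. Only the optimal *objective value* is
contractually reproducible; flux vectors at degenerate optima are returned
as solved and may differ between equivalent formulations.

Correctness is anchored by an independent oracle: for networks of at most
8 reactions, every candidate vertex of the flux polytope is enumerated
(pin $n - \operatorname{rank}(S)$ fluxes to a bound, solve $S v = 0$ for
the rest, keep feasible points) and the best vertex must match the simplex
optimum to $10^{-6}$ on 200 seeded random networks.

## The reduced central-carbon model

Genome-scale reconstructions of *A. pullulans* are not redistributable
here, so the package ships a deliberately small, fully auditable
central-carbon model (51 metabolites, 51 reactions, three compartments)
as both an R constructor (`build_reduced_model()`) and a JSON fixture
(`inst/extdata/apullulans_core_synthetic.json` — the filename marks it as
a synthetic stand-in). Absolute optima from this model are properties of
the fixture, not of any genome-scale network; only the qualitative
structure of the route comparison is asserted.

Key stoichiometric choices, all visible in the model notes:

* **Lumped glycolysis**: hexose → 2 pyruvate + 2 ATP + 2 NADH. Sucrose
  enters by invertase hydrolysis with no ATP cost and no carbon loss, so
  sucrose at 5 mmol/gDW/h is exactly hexose-equivalent to glucose at the
  default uptake bound of 10 mmol/gDW/h.
* **Oxidative TCA cycle** with each enzyme as its own reaction (pyruvate
  dehydrogenase, citrate synthase, aconitate hydratase, isocitrate
  dehydrogenase, oxoglutarate dehydrogenase, succinate-CoA ligase,
  succinate dehydrogenase, fumarase, mitochondrial malate dehydrogenase).
* **Reductive cytosolic branch**: pyruvate carboxylase (CO2-fixing) plus a
  cytosolic malate dehydrogenase distinct from the mitochondrial one.
* **Glyoxylate shunt** (isocitrate lyase + malate synthase) placed in the
  cytosol with its own support reactions: a cytosolic aconitase isoform,
  ATP-citrate lyase for cytosolic acetyl-CoA, and a lumped
  aspartate/purine-cycle bypass converting oxaloacetate to fumarate. The
  support reactions are what make the three-route scan simultaneously
  satisfiable: the scan fixes whole named-enzyme sets to zero, and without
  compartment-specific isoforms the glyoxylate route would be infeasible
  at any positive flux.
* **Energy**: oxidative phosphorylation at P/O 1.5 (NADH) and 1.0
  (FADH2); an ATP-maintenance reaction is present with default lower
  bound 0; respiratory O2 uptake is capped at 20 mmol/gDW/h, which is the
  constraint that separates the heavily NADH-producing oxidative route
  from the NADH-consuming reductive route.
* **PMA synthesis** polymerises cytosolic malate at 1 ATP per residue,
  releasing one water per ester bond (residue formula C4H4O4).
* **CO2 exchange is reversible** (as in the standard *E. coli* core
  model): when the scan forcibly zeroes all decarboxylating routes, the
  carboxylase can still draw CO2. This is an in-silico convenience, not a
  claim about net carbon fixation by the organism.
* **Biomass** is a lumped pseudo-reaction draining 6 pyruvate + 20 ATP
  per unit flux. The growth axis is labelled gDW/h, following the
  labelling convention of the study this package models, although a
  growth flux would dimensionally be 1/h; the package treats the label as
  a unit string and attaches no dimensional semantics to it.

Elemental bookkeeping is enforced strictly for carbon only: every internal
reaction must balance carbon exactly (`carbon_balance_report()`, sign
convention: carbon consumed minus produced). Hydrogen and oxygen are
checked only up to free water, protons and phosphate, which are flagged as
bookkeeping species — lumped reactions cannot be proton-exact without
inventing detail. Exchange and biomass pseudo-reactions are exempt by
construction.

## The route scan

Three malate-supply routes are compared by the named enzyme sets:
oxidative TCA {oxoglutarate dehydrogenase, aconitate hydratase, fumarase,
succinate dehydrogenase, succinate-CoA ligase}, reductive TCA {cytosolic
malate dehydrogenase}, and glyoxylate shunt {fumarase, isocitrate lyase,
malate synthase — the latter being the glyoxylate-consuming,
malate-producing step}. For each grid point the scan:

1. fixes every reaction of the scanned route to the same scalar flux
   (flux coupling: the routes are constrained as units);
2. fixes every reaction of the other two routes to zero, except reactions
   shared with the scanned route — fumarase appears in both the oxidative
   and glyoxylate sets, and the scanned constraint wins (otherwise the
   glyoxylate scan would be infeasible at any positive flux);
3. fixes the mitochondrial malate dehydrogenase to zero in all three
   scans (the reductive branch is modelled as purely cytosolic);
4. fixes the biomass flux to the imposed growth value; and
5. maximises PMA synthesis.

Fixing (rather than upper-bounding) the route flux and the growth is an
interpretation: the scan is read as an equality grid because the optimum
is plotted *as a function of* route flux, and the same verb constrains the
other routes to zero. Infeasible cells are recorded as `NA` with an
explicit status — deliberately distinct from a feasible optimum of zero,
since "the route cannot carry this flux" and "the route carries it but
makes no PMA" are different findings. The summary's *cutoff* is the
smallest scanned flux at or beyond the arg-max where the optimum is zero
or infeasible.

Default grids are 71 route-flux points on [0, 140] mmol/gDW/h × 21 growth
points on [0, 1] (steps 2 and 0.05). The packaged model's entire structure
— optima, ordering and all three cutoffs — lies below a route flux of 20,
so the test suite and the acceptance script scan an 11 × 5 grid on
[0, 20] × [0, 1]; the full default remains available from
`scan_surface()`.

On the packaged model the scan reproduces, qualitatively, the expected
biology: the reductive route achieves the highest optimal PMA rate and
tolerates the highest imposed flux before infeasibility (optimum
14 mmol/gDW/h, cutoff 16 on the test grid), the glyoxylate shunt is
intermediate in optimum (8) and the oxidative route lowest (6, limited by
the O2 cap on reoxidising its NADH); the optimum is non-increasing in
imposed growth everywhere (PMA and biomass compete for pyruvate and ATP);
the flux→optimum map is concave at fixed growth (a parametric-LP
property); and sucrose reproduces glucose optima to $10^{-6}$ at
hexose-equivalent uptake.

## Metabolome differential statistics

The pipeline mirrors standard GC–MS practice for a two-group comparison
with spiked internal standards:

* **Normalisation** divides each sample column by the geometric mean of
  its internal-standard intensities. The geometric mean is the natural
  location estimate for multiplicative (injection/recovery) error; with
  standards spiked at fixed amounts their measured intensity is, up to
  noise, exactly the per-sample factor.
* **Unit-variance scaling** (per metabolite: centre, divide by the n−1
  standard deviation) is applied only to the multivariate steps — PCA,
  PLS-DA, clustering. The univariate t tests run on *log* normalised
  intensities instead, because unit-variance scaling destroys the mean
  differences the tests measure, and log intensities match the
  multiplicative noise of peak areas. Zero-variance rows are dropped with
  a warning before scaling.
* **PCA** by SVD, with component signs fixed (largest-magnitude loading
  positive) for determinism.
* **Discrimination** is single-response PLS-DA fitted by NIPALS, with
  variable importance in projection
  $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{aj}^2 / \sum_a \mathrm{SSY}_a}$,
  which satisfies $\sum_j \mathrm{VIP}_j^2 = p$ identically. The
  orthogonal-signal-correction deflation of OPLS-DA is deliberately
  omitted: with a single binary response the predictive subspace is the
  same and single-response VIP is essentially unchanged, while PLS-DA is
  fully specifiable without proprietary software. Scores are
  cross-checked in the tests against an independent implementation
  (`mixOmics`) and a direct single-component projection oracle.
* **Inference**: two-sided pooled-variance Student's t per metabolite
  (df = nA + nB − 2); zero pooled variance maps to p = 1 (conservative)
  rather than NaN. Benjamini–Hochberg adjustment is applied within each
  contrast, not pooled across contrasts.
* **Selection** requires all of p < 0.05, VIP > 1 and q ≤ 0.05; each
  threshold is an explicit argument.
* **Clustering** is Ward (`ward.D2`) on Euclidean distances of the scaled
  profiles, validated against a naive Lance–Williams oracle; hierarchical
  clustering was named without a linkage in the source methodology, and
  Ward/Euclidean is the common choice for metabolite profiles.

## Synthetic data: what it emulates and what it does not

`gen_metabolome()` draws
$\exp\!\big(\mathcal{N}(\text{baseline} + \text{effect}\cdot\ln 2,\ \sigma)\big)
\times \text{injection factor}$, with defaults matching the emulated
design: 81 metabolites + 2 internal standards, glucose/sucrose × 48/72 h,
6 replicates, $\sigma = 0.5$ on the natural-log scale, injection factors
lognormal with sd 0.2. Effects are planted on the log2 scale so
fold-change truth is exact by construction, and $\sigma = 0$ is allowed
as the noise-free limit in which planted parameters are recovered
exactly. Each generator derives its own stream from the user seed
(seed × 8 + generator offset), so adding generators never perturbs
existing fixtures, and the caller's RNG state is restored afterwards.

Power simulations plant |log2 FC| = 2 on 10 of 81 metabolites; over 200
replicates the full selection rule recovers ≈ 86–88% of planted
metabolites (the BH step combined with the VIP cut is the binding
criterion), and on null tables the selected fraction is far below 5%.
What the generator does *not* emulate — retention-time drift, peak
co-elution, missingness, heteroscedastic low-intensity noise, correlated
metabolite blocks — means passing these simulations demonstrates the
statistics are implemented correctly, not that real GC–MS data would
behave this well.

`gen_timecourse()` integrates logistic growth with Luedeking–Piret
product formation in closed form. Defaults emulate a fed-batch run
(inoculum 0.5, capacity 25 g/L, μ 0.12 1/h, α 1.2, β 0.02, product yield
0.62 g/g, 200 g/L total sugar → ≈ 83 g/L product in 140 h); concentrations
are truncated at zero only when observation noise would take them
negative. Yields may be `Inf` to disable a drain — used to verify that
`quant_summary()` recovers a planted yield exactly when product is the
only substrate sink.

## Fermentation quantitation

The PMA↔malic-acid conversion uses the residue mass ratio
$(M_{\mathrm{C_4H_6O_5}} - M_{\mathrm{H_2O}})/M_{\mathrm{C_4H_6O_5}}
= 0.86565\ldots$, conventionally rounded to 0.87 — each ester bond of the
polymer releases one water on hydrolysis. Published PMA/MA pairs are not
all mutually consistent under a single factor, so the factor is always an
explicit argument and is never inferred from data. Comparisons against
conventionally printed values use round-half-away-from-zero
(`round_half_up()`; base R's `round()` rounds half to even, which would
turn 0.525 into 0.52). Percent change is reference-relative and therefore
asymmetric: the two directions never cancel additively, although their
ratio forms multiply to exactly 1 by construction.

## Numerical and degenerate-input conventions

* LP: pivot tolerance $10^{-9}$; assertions at $10^{-6}$; Bland's rule
  for anti-cycling; infeasible is a first-class status, never coerced
  to 0.
* Empty reaction lists are valid models whose every FBA is trivially
  optimal at 0.
* Scan summaries break arg-max ties toward the smallest flux; an all-zero
  grid has its cutoff at the first grid point.
* PCA/PLS sign and tie conventions are fixed for determinism; PLS
  components beyond the achievable rank are truncated with a warning.
* BH q-values are computed with `stats::p.adjust`, and clustering with
  `stats::hclust`; both sit behind package functions so the contract (and
  its oracle tests) stay in one place.

## Known limitations

The reduced model is a stand-in: its absolute optima and cutoffs are
fixture properties, and genome-scale values (which depend on a full
reconstruction) are out of reach by design. The LP kernel is dense and
suited to tens of reactions, not thousands. OPLS-DA's orthogonal
filtering, raw-spectra processing, spectral-library identification and
pathway enrichment are out of scope. The growth-unit question noted above
is recorded, not resolved.
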