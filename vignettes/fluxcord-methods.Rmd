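---
title: "Classifying metabolic flux regulation with fluxcord: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metabolic flux regulation with fluxcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcord)
```

## The question fluxcord answers

When the flux of a metabolic reaction differs between two cell
populations, the difference can be driven from above — the cell expresses
more or less of the catalysing enzyme — or from below, by the
availability of the reaction's substrates, or by both at once. fluxcord
classifies each reaction of a constraint-based metabolic model into
*transcriptionally regulated*, *metabolically regulated*, *concerted*
(both), or *other*, by measuring the agreement between three
reaction-centric datasets derived from heterogeneous omics:

* **RAS** (Reaction Activity Score): transcriptomics pushed through the
  gene-protein-reaction (GPR) rules,
* **RPS** (Reaction Propensity Score): metabolomics pushed through the
  reaction stoichiometry under mass action,
* **FFD** (Feasible Flux Distributions): flux vectors sampled
  near-uniformly from each group's constrained flux polytope.

The agreement between the *signs of variation* of these datasets across
group pairs, quantified per reaction by Cohen's kappa, is the final
output.

## Reaction scores

**RAS.** For each sample, a GPR rule is evaluated on the expression
values of its genes: `and` (enzyme subunits, all required) takes the
minimum, `or` (isoenzymes, additive) takes the sum, recursively with
standard precedence. The per-group score is the mean over that group's
samples, and the normalized score
$\overline{RAS}^c_r = RAS^c_r / \max_c RAS^c_r \in [0,1]$ compares groups
on each reaction. If a reaction's RAS is zero in every group the
normalized score stays 0; reactions without a usable rule carry the
sentinel score 1, so they are never penalized downstream. Missing genes
default to the `skip` policy: a missing isoform is dropped from an `or`
sum, while a missing subunit makes the rule undefined and the reaction
falls back to the sentinel path — the alternative (treating missing as
zero) would silently close fluxes.

**RPS.** Under mass action the rate of reaction $r$ is
$v_r = k_r \prod_q [X_q]^{s_{r,q}}$ over its substrates. The kinetic
constant $k_r$ cancels in every between-group ratio, so the propensity
score $RPS^c_r = \prod_q [X_q]^{|s_{r,q}|}$ is a valid proxy for the
direction of flux change attributable to substrate availability alone.
RPS is defined on the irreversible model (substrates are
direction-specific), and a reaction enters the dataset only if *every*
substrate is measured; a configurable exclusion list (a preset with
water, protons and phosphate is shipped, default off) can excuse
ubiquitous species. Measured metabolites that exist in several
compartments (e.g. citrate) are assigned identically to each
compartmental species, since bulk measurements cannot resolve
compartments. The biomass pseudo-reaction is excluded by default: its
"substrate pool" has no meaningful measurement.

## Cell-relative models

Absolute uptake rates are deliberately not fitted. The per-group models
encode only *relative* differences, in three incremental layers:

1. **Medium (type 1).** The uptake bound of each nutrient scales with its
   medium concentration relative to the maximum across groups, with
   `baseUptake` (default 10 flux units) granted to the richest group.
   Only ratios matter; the absolute scale is arbitrary. Nutrients absent
   from a group's medium cannot be taken up. Secretion bounds are left as
   modelled, so that fixture models with explicit secretion exchanges
   keep them.
2. **Exchange ratios (type 2).** From spent-medium concentrations at two
   time points, the produced/consumed ratios lactate/glucose,
   lactate/glutamine and glutamate/glutamine are computed per sample
   (technical replicates averaged within each biological replicate; mean
   $\bar{x}$ and sample standard deviation $\sigma$, $n-1$ convention,
   across biological replicates) and attached as two-sided rows
   $-\sigma \le v_{num} - \bar{x}\, v_{den} \le \sigma$ on consumption
   magnitudes. Dividing by cell numbers is unnecessary because only
   ratios are constrained.
3. **Transcriptomic bounds (type 3).** Flux variability analysis (FVA)
   under layers 1–2 gives each group's attainable interval
   $[v_L^c, v_U^c]$ per reaction — no biomass objective is imposed — and
   the normalized RAS shrinks it proportionally:
   $\overline{RAS}\,v_L^c \le v \le \overline{RAS}\,v_U^c$ for
   GPR-bearing reactions, with rule-free and explicitly exempt reactions
   keeping the plain interval. Exemptions exist for rules whose null
   score would make growth infeasible.

A growth-yield bracket keeps simulations realistic without an
optimality assumption: with glucose consumption converted to grams
($mw_{Glc} = 180.16$ g/mol) and protein taken as the fraction 0.131972 of
biomass, the yield is constrained to the observed range
$[3.90762\times10^{-5},\ 1.67998\times10^{-4}]$. This row is retained
through FVA and sampling.

**Ordering matters.** Ratio rows are attached on the *reversible* model
and rewritten onto the split variables when the model is made
irreversible (each reversible reaction becomes a forward and a
`_reverse` partner; uptake is the `_reverse` direction of an exchange).
Running FVA only after the ratio rows exist avoids inflating bounds with
futile-loop flux. Layer 2 may be switched off while keeping layer 3.

## Flux sampling

The FFD dataset is drawn with an artificial-centering hit-and-run chain
over $\{v : Sv = 0,\ v_L \le v \le v_U,\ \text{extra rows}\}$. The
steady-state equalities are eliminated by working in null-space
coordinates; directions along which the polytope has no extent (blocked
reactions, equality-collapsed ratio rows) are projected out, which also
makes point polytopes an explicit, warned-about special case. Warmup
points are the FVA optima; chain directions are drawn through the running
center, which adapts the step geometry to strong anisotropy such as the
thin growth-yield slab. Each batch discards `thinning * 100` burn-in
steps and records every `thinning`-th state (default 10); batch $b$ uses
seed `seed + b`, so runs are reproducible and batches are independent
enough for stability checks. The default test-scale protocol is 5,000
samples in 10 batches; a production run mirrors the full protocol of
1,000,000 samples in 10 batches of 100,000.

Validation is explicit: `verifySamples()` reports the worst steady-state
residual and bound/row violation (pass at $10^{-6}$), and
`growthYield()` recomputes the per-sample yield whose median is the
in-silico growth yield. Samples with vanishing glucose consumption are
excluded from the yield quotient — the ratio is numerically meaningless
below the consumption tolerance.

## Sign calling and concordance

For every ordered group pair (lexicographic, shared across datasets; 5
groups give 10 pairs) each reaction is called $+1$, $0$ or $-1$. FFD uses
the Mann–Whitney U test on the sampled distributions and compares
medians; RAS and RPS use a pooled-variance t-test on the per-sample
scores and compare means (the t-test runs on raw per-sample scores:
normalization is a per-reaction constant across groups only after
taking means). Pooled rather than Welch: at three samples per group
with multiplicative noise — variance scaling with the mean — Welch's
degrees of freedom collapse toward 2 and a clean two-fold change can
fail to reject; Welch remains available via \code{varEqual = FALSE}. A
sign is called only when the test rejects at $\alpha = 0.05$ *and* the
central values differ by at least 20% (ratio $\ge 1.2$ or $\le 0.8$; a
symmetric-log variant is a config option). Flux distributions larger
than 10,000 per group are thinned deterministically before testing:
rank-test p-values at very large $n$ reject for meaningless differences.

Cohen's kappa between two sign vectors,
$\kappa = (p_o - p_e)/(1 - p_e)$, corrects the observed agreement $p_o$
for the chance agreement $p_e$ implied by the marginal category
distributions. Degenerate inputs follow the documented convention: two
constant raters score 1 when equal and $-1$ when contradictory. One
consequence required care: a reaction with *no called variation at all*
(all-zero vectors on both sides) would score $\kappa = 1$ under that
convention and be mislabelled as strongly concordant. The concordance
stage therefore reports `NA` — no evidence — whenever both vectors of a
pair are all-zero; such reactions end up `inconclusive`. This choice is
what makes a zero-effect dataset come out all-inconclusive rather than
all-concerted.

**Empirical null.** The significance of a RPS-vs-FFD kappa is assessed
against an empirical null: the pooled distribution of RPS sign-test
outcomes is resampled with replacement into random pair-length vectors
(resampling test outcomes rather than raw scores avoids
over-representing zeros), each scored against the reaction's observed
FFD signs; 1000 resamples by default, add-one p-value
$p = (1 + \#\{\kappa_{null} \ge \kappa_{obs}\})/(1 + n)$ so $p$ is never
exactly zero, Benjamini–Hochberg adjustment across reactions. Pooling
across reactions is the default; a per-reaction null is available by
configuration. RAS-vs-FFD kappas are reported for context but never
drive significance — the FFD polytope is itself RAS-constrained, so the
two are not independent.

**Classification** at threshold 0.2: both RPS-vs-FFD and RPS-vs-RAS
above — *concerted*; RPS-vs-FFD above with RPS-vs-RAS below or missing —
*metabolic_only*; RPS-vs-FFD at or below with a high RAS-vs-FFD —
*transcriptional_only*; RPS-vs-RAS above with RPS-vs-FFD below —
*other* (expression and substrate agree, the flux follows neither);
anything else, including the quadrant with strongly negative scores and
low RAS-vs-FFD that the quadrant semantics leave unnamed, is
*inconclusive*.

## The synthetic fixture and what passing tests mean

`generateToyModel()` builds a ~20–30 reaction network: glucose/glutamine
uptake, a glycolysis-like backbone with `and`/`or` rules, lactate,
glutamate and alpha-ketoglutarate secretion, a rule-free transporter, a
reversible internal reaction, a biomass sink under the yield bracket, a
cytosol/mitochondrion citrate pair, and independent
uptake–conversion–secretion branches for planting. Each planted branch
gets group multipliers $1, e, e^2$ (effect size $e = 2$ by default over
3 groups, 3 samples each): *metabolic_only* co-varies substrate
abundance and medium bound with flat expression; *transcriptional_only*
varies expression only; *concerted* varies all three; *other* varies
expression and abundance concordantly while the medium bound varies
inversely, decoupling attainable flux from both omics layers. Per-sample
noise is multiplicative lognormal (mean-preserving,
$\mathrm{sd} = 0.1$ by default) — both expression and abundance are
positive, right-skewed quantities.

The fixture emulates the *structure* of real inputs, not their biology:
it has no kinetics, no allostery, no correlated noise between genes, and
its planted effects act through single dedicated branches. Passing the
recovery tests therefore shows the pipeline's machinery is sound — signs
propagate, constraints bind, the classifier lands in the right quadrant
— not that real regulation is recovered at these rates.

Problem sizes used by the test-suite checks: sampler validity and
recovery run at 20,000 samples per group (batch-stability at 50,000 in
10 batches of 5,000), 3 groups, 1,000 null resamples; these sizes give
stable kappas on the fixture while keeping a full suite run in minutes.

## Numerical choices

* LPs (feasibility, FVA) run on a two-phase simplex with variables
  shifted by their lower bounds; equality rows are sign-normalized.
  Reported FVA bounds are clipped to 0 below $10^{-9}$ and floored at 0
  for irreversible models.
* The null-space basis comes from the SVD of $S$ (rank tolerance
  relative to the largest singular value); warmup directions with
  singular value below $10^{-9}$ are dropped.
* Hit-and-run direction/segment tolerances are $10^{-11}$; active-face
  slacks are clamped at 0. Sample validity is asserted at $10^{-6}$.
* t-tests on two exactly constant groups fall back to p = 1 (equal) or
  p = 0 (different); ratios against a zero central value are $\infty$
  (or 1 when both are zero).
* Ties in the U test use the normal approximation (`exact = FALSE`).

## Known limitations

* The two-phase simplex is dense and pure R: comfortable for core-scale
  models (hundreds of reactions), not for genome-scale reconstructions.
* Plain SBML L3/fbc is supported (compartments, boundary species, fbc
  bounds, nested gene-product associations); exotic SBML features
  (groups, annotations, initial assignments) are ignored on read and not
  written.
* Sign calls at three samples per group have limited power; the 20% fold
  rule dominates at that size. This mirrors the method's intent —
  directions, not magnitudes.
* The empirical null pools sign calls across reactions by default; for
  strongly heterogeneous sign distributions the per-reaction option may
  be preferable, at the cost of a noisier null.
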