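---
title: "Methods: occupancy algebra, interactome calling and the synthetic assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy algebra, interactome calling and the synthetic assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsp90cl)
```

# Scope

`hsp90cl` implements the quantitative stages of a study of phosphorylation in
the charged linker (CL) of human Hsp90β.  Two serines in the CL, S226 and
S255, are constitutively phosphorylated; the package quantifies *how*
phosphorylated (occupancy), what changing that does to the interactome
(differential AP-MS), to global conformation (limited proteolysis), and to
secretion (capillary western, CWB).  Every assay has a forward simulator with
machine-readable ground truth, so the full pipeline is testable without any
external data.  The package consumes tabular exports (Skyline-style
transition reports, MaxQuant-style `proteinGroups` tables, CSV signal
tables); raw-spectrum processing is out of scope.

# Occupancy from SILAC ratio triplets

## Model

The measurement design mixes the native bait protein (light channel,
occupancy $p_L$ at a site) with a phosphatase-treated heavy-labeled reference
(residual occupancy $p_H$) *before* digestion, so both channels share
digestion efficiency and ionization behaviour.  Three heavy/light ratios are
measured per site and replicate:

* $x$ — the phosphopeptide,
* $y$ — its unmodified counterpart (identical backbone),
* $z$ — the whole protein, from normalization peptides far from the CL.

Under the two-state mixing model, with $\rho$ the heavy/light protein amount,

$$x = \rho \frac{p_H}{p_L}, \qquad
  y = \rho \frac{1 - p_H}{1 - p_L}, \qquad z = \rho,$$

and inversion is closed-form:

$$a = \frac{z - y}{x - z}, \quad b = a\,\frac{x}{y}, \quad
  \mathrm{occ}_{light} = \frac{a}{a+1} = p_L, \quad
  \mathrm{occ}_{heavy} = \frac{b}{b+1} = p_H.$$

The heavy-sample expression $b = a\,(x/y)$ is derived here from the mixing
model (substitute the three ratio identities and simplify); it reproduces
$p_H$ exactly for any $(p_L, p_H, \rho)$, and the test-suite verifies the
closed form against an independent grid-search inversion (grid $10^{-4}$,
then zoom refinement) to $10^{-9}$ on 1,000 random triplets.  A useful
algebraic identity, also asserted numerically, is
$\mathrm{occ}_{light} = (z-y)/(x-y)$.

## Numerical choices

* **Degeneracy.** $a$ diverges as $x \to z$ (the two channels have equal
  phospho fractions and the triplet carries no information).  Triplets with
  $|x - z|/z < 10^{-6}$ are flagged `x_equals_z` and marked invalid.
* **Out-of-range estimates.** Noise can push an estimate outside $[0, 1]$.
  Values are reported unclamped with an `out_of_range` flag — silent clamping
  would bias group means.  Summaries include flagged estimates only while the
  excess beyond $[0,1]$ is at most 0.05 and exclude larger excursions.
* **$z$ aggregation.** The statistic for combining normalization peptides is
  not prescribed by the assay; the median is used for robustness to a single
  aberrant peptide, and the count of contributing peptides is reported.
* **Peptide areas.** A peptide's area per channel is the plain (unweighted)
  sum of its fragment-ion areas; channels with no observed fragment become
  missing, flagged, never imputed.
* **Missed-cleavage variants.** The acidic CL inhibits trypsin/LysC, so each
  site is measured by two peptide species (with/without missed cleavage).
  Variants are reported separately — each yields its own triplet — with an
  optional mean-of-variants summary; collapsing them by default would hide
  digestion artefacts.
* **Group comparisons.** Two-sided two-sample t-tests, equal-variance
  (Student) by default with Welch behind a flag, unpaired (the replicate
  pairing across compartments is not a measurement pairing);
  Benjamini–Hochberg across the peptide variants tested together.

Co-occupancy of two sites is bounded by the Fréchet limits
$\max(0, p_1 + p_2 - 1) \le P(\text{both}) \le \min(p_1, p_2)$, with the
independence point $p_1 p_2$ reported alongside; phosphate stoichiometry is
the sum of per-site occupancies (each site contributes its occupancy in
expectation).

# Differential AP-MS interactome

The pipeline mirrors standard MaxQuant post-processing:

1. **Filters.** Remove decoy ("Reverse"), potential-contaminant and
   only-identified-by-site groups; require at least 2 unique peptides, 4
   peptides and 6 MS/MS counts in total; require identification by MS/MS in
   all replicates of at least one condition (label-free, 3 conditions × 6
   replicates) or in all replicates (SILAC, 4 replicates).  Counts filters
   are monotone by construction; removal reasons are logged per group.
2. **Ingest.** Intensities of 0 are missing (the MaxQuant convention for
   "not quantified"); everything is log2 downstream.
3. **Imputation.** Missing values are imputed *only* in negative-control
   samples — the minimum needed to run a t-test against the controls — from a
   down-shifted Gaussian $N(\mu_s - 1.8\sigma_s,\ (0.3\sigma_s)^2)$ per
   control sample $s$, the de-facto AP-MS convention for left-censored
   missingness.  Shift and width are configurable; imputed cells are masked
   so tests can prove nothing else moved.
4. **Bait normalization.** Per-replicate log2 ratios are aligned on the bait
   group, which then sits exactly at 0; this cancels unequal bait amounts
   between channels and is invariant to per-replicate constants.
5. **Calling.** Label-free specificity: two-sample Student t (bait condition
   vs control), BH across tested groups, specific ⇔ adjusted p < 0.05 *and*
   mean log2 difference ≥ 3.  The fold-change criterion is read as a mean
   difference of 3 log2 units (8-fold linear) — the phrase "fold-change of 3
   in log2 scale" is ambiguous and this reading is stated prominently.
   SILAC: each replicate carries both conditions in a single H/L ratio, so
   the WT-vs-AA test is a *one-sample* Student t of bait-normalized log2
   ratios against 0, BH-adjusted; a 0.4 log2 threshold only classifies
   display direction.
6. **Enrichment.** Annotation over-representation is a one-sided
   hypergeometric upper tail ($P(X \ge k)$ with population = background,
   successes = annotated background, draws = hits), BH across terms, with
   GeneRatio $k/K$.  Annotation maps are user-supplied inputs; no ontology
   structure is used.

# Limited proteolysis

Per peptide (identified by its residue span on the bait, 1-based inclusive):

* *fraction full length* = band-A intensity at dose $d$ over band-A intensity
  at dose 0 (peptides with a zero/missing baseline are excluded and logged);
* *band-vs-lane ratio* = band-A intensity over the summed intensity across
  all analyzed bands of the lane (in $[0,1]$ by construction; "rest of the
  lane" means every analyzed band except band A).

Peptides are grouped by side of the dominant cleavage site (default K607):
`before` (end < site+1), `after` (start > site); `spanning` peptides are
excluded from side statistics rather than fractionally weighted, since no
principled weights exist.  Comparisons (WT vs AA per dose, before vs after
per dose) use two-sided Welch t-tests on per-peptide ratios with BH across
doses.  Peptides are pseudo-replicates — they sample one protein population —
so these p-values rank evidence within the experiment rather than supporting
population inference; the direction of the before/after difference is
reported signed, not hard-coded.

# Capillary-western estimators

Signals are scaled to whole-sample totals (signal / analyzed fraction) before
any ratio; the analyzed fractions are required inputs.  The *absolute ratio*
is total-CM / (total-CM + total-lysate).  The *secreted fraction* subtracts
the β-actin absolute ratio — a non-secreted protein, so its CM presence
measures accidental release — pooled across constructs by default (a single
shared baseline; per-construct baselines behind a flag).  Negative corrected
values are reported and flagged, never clamped.  Probe binding is
desthiobiotin signal normalized by HA signal per replicate, summarized per
(construct, nucleotide) with Student t-tests between constructs (Student
rather than Welch to match the assay's usual reporting; configurable).

# The synthetic-data module

Each simulator draws from the generative model its estimator inverts, with
log-normal multiplicative noise on intensities (standard for MS and keeps
them positive), one RNG stream per simulator and deterministic sub-seeds per
table.  Defaults are the study conditions:

* **PRM**: S226/S255 at 95% light-channel occupancy; heavy residual
  occupancy 1% (phosphatase treatment near-complete but not assumed
  perfect — this exercises the non-zero $\mathrm{occ}_{heavy}$ path);
  mixing ratio $\rho = 1$; 3 replicates; 30% missed-cleavage fraction;
  3 fragments per peptide with fixed proportions shared between channels,
  so H/L ratios are independent of the per-species ionization factors —
  asserted exactly at $\sigma = 0$.
* **co-IP**: label-free 3 conditions × 6 replicates, 250 background groups,
  50 true interactors at +4 log2 over control, 80% control missingness,
  replicate sd 0.5 log2; 5% of groups drawn to fail the count filters, plus
  decoy and contaminant rows.  SILAC: 4 replicates, bait offset 0.5 log2
  (exercising bait normalization); the analysis scripts use replicate sd
  0.1 log2 for SILAC ratios, reflecting the higher precision of a duplex
  ratio measurement.
* **proteolysis**: full-length fractions 35%/10% (WT) and 22%/6% (AA) at
  7/14 ng/µL trypsin, cleavage at K607 on a 724-residue bait.  The cleaved
  portion of after-site peptides is reallocated to an in-lane small-fragment
  band; the cleaved portion of before-site peptides leaves the analyzed
  window.  Which side shows the lower band-A/lane ratio is a property of
  this generative choice, which is why the estimators report signed
  differences instead of assuming a direction.
* **CWB**: secreted fractions 1.6% (WT-like) and 4.5% (mutant-like) over a
  3% accidental-release baseline, 3 replicates, analyzed fractions 0.2 (CM)
  and 0.05 (lysate).

Noise magnitudes are calibration choices (the assays publish none): areas
use $\sigma = 0.05{-}0.1$ on the log scale by default, within the range a
well-behaved targeted-MS or CWB experiment achieves.

**What the simulators do not emulate:** retention time, m/z and spectral
interference; digestion chemistry beyond fixed species fractions; isotope
impurity; correlated fragment noise; batch effects between the two
label-free experiments; compositional distortions of iBAQ; gel densitometry.
Green tests therefore certify the *estimators and their algebra* under the
stated generative assumptions, not robustness of the upstream quantification
software on real spectra.

# Problem sizes and budgets

The test-suite and drivers use deliberately small problem sizes chosen to
make Monte-Carlo assertions stable: 1,000 triplets for the oracle-equivalence
check; 100 peptide pairs for the σ = 0.05 recovery check; 200 simulation
seeds for the null false-positive-rate and sensitivity/FDR properties of
interactor calling (250 background + 0 or 50 true groups each); 500 seeds
for the secretion-estimator bias bound.  These sizes keep each property's
Monte-Carlo error well below the asserted margin.

# Known limitations

* The occupancy algebra assumes a single phosphosite per measured peptide;
  isobaric multi-site peptides (the Hsp90α S252/S263 situation) are not
  disambiguated.
* Interference from the nearby S261 is ignored (negligible for this assay's
  purposes); no correction term is applied.
* The normalization-peptide panel is an input; the package does not re-derive
  the retention-time-based selection used when designing a targeted method.
* BH families are per experiment (all groups passing filters, or the peptide
  variants compared together); combining experiments would require a
  different family definition.
* The label-free caller supports iBAQ and ratio columns; when a table carries
  both, the mode flag decides, since either choice is defensible for
  pulldown data.
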