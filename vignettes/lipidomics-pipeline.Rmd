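---
title: "Methods: compositional lipidomics, acyl-chain pairing, and growth fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional lipidomics, acyl-chain pairing, and growth fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunlipidr)
```

This vignette documents the models and conventions behind the package: how
shorthand species names are interpreted, what each compositional statistic
means, how the acyl-chain pairing matrices are defined at the edge cases,
which statistical choices were open and how they were resolved, and what the
synthetic-data generator does and does not emulate.

## The data model

The pipeline's central object is a long table of (sample, species, amount in
pmol) joined to sample metadata (strain, medium, treatment, replicate).
Amounts are assumed to be already absolutely quantified; raw-spectra
processing, peak picking and internal-standard quantification are upstream
and out of scope. Two quality filters from the upstream identification stage
are available for inputs that still carry the columns: a strict
signal-to-noise cutoff (SNR > 5) and a strict five-fold-over-blank cutoff.
Rows lacking those columns pass unexamined, because most exported species
tables are already filtered.

Species names follow shotgun shorthand: `PC 17:0/14:1` is chain-resolved
(two fatty acyl chains of 17 and 14 carbons, 0 and 1 double bonds);
`IPC 44:0;2` is a sum composition (44 carbons, 0 double bonds, 2
hydroxylations across the ceramide backbone). Both `;` and `,` are accepted
before the hydroxylation count on input; `;` is emitted canonically.
Because the acquisition platform does not resolve sn-positions,
`PC 16:0/12:0` and `PC 12:0/16:0` are the same species; chains are stored
in a canonical order (descending carbons, then double bonds), which makes
parsing and rendering mutually inverse. Unknown class tokens and malformed
chains are rejected loudly rather than dropped, so unexpected nomenclature
(ether lipids, oxidized species) surfaces immediately.

Classes partition into four categories: sterols (Erg), sphingolipids (Cer,
IPC, MIPC, M(IP)2C), membrane glycerolipids (all glycerophospholipids plus
DAG), and storage lipids (TAG and ergosteryl esters). Chain-level analyses
use the two-chain MGL sub-category PA, PC, PE, PI, PS, DAG: lyso classes
(one chain), cardiolipin (four chains) and ceramides are excluded so that
per-chain bookkeeping is uniform.

## Compositional statistics

All abundances are reported in mol% with an explicit denominator: the whole
lipidome of the sample, a category, or a class. Every profile sums to 100
per sample by construction, which the test suite asserts at 1e-9 relative
tolerance. When tables are aligned across samples (for group statistics and
PCA), a species absent from a sample is an effective zero — in shotgun
lipidomics, non-detection below the noise floor is indistinguishable from
absence.

Total-length and total-double-bond histograms are keyed by the sum over both
chains of the two-chain MGL sub-category, so they are well-defined for
chain-resolved and sum-composition species alike, and collapsing resolved
species to their sum composition provably changes nothing. Complete profiles
are always computed; any "omit the least abundant species" trimming is a
display decision left to the caller.

## Acyl-chain pairing

For unordered chain pairs {x, y} with pooled amount A{x,y} and total
sub-category amount T:

* the **joint** matrix stores `100 * A{x,y} / T` symmetrically, with each
  pair's mass counted once in the normalization (upper triangle plus
  diagonal sums to 100);
* the **occurrence** total of chain x is `O(x) = 2 A{x,x} + sum over y != x
  of A{x,y}` — a homodimer molecule contributes two occurrences of its
  chain, each partnered with that same chain;
* the **conditional** matrix row for x is the partner distribution per
  occurrence: `100 * (2 A{x,x} if y = x else A{x,y}) / O(x)`.

The homodimer convention is the package's documented choice for an edge the
shorthand nomenclature leaves open; it is the one that makes the
conditional rows true partner distributions and keeps the marginal identity
`chain_usage(x) = 100 * O(x) / (2T)` exact, which the tests verify against
independent brute-force enumeration. Similarly, whether the conditional
panel should be occurrence-weighted or molecule-weighted is not fixed by
the mol% label alone; occurrence weighting is used throughout because it
composes with the marginal identity.

The asymmetric-lipid statistic, `pairing_selectivity()`, pools the medium
saturated chains (10:0, 12:0) and reports the percentage of their
occurrences partnered with a saturated long chain (16:0, 18:0) versus an
unsaturated long chain (16:1, 18:1) versus anything else. Under independent
pairing the selectivity equals the saturated-long usage share (about 33% in
the default rich-medium pool); values near 100 indicate the almost
exclusive saturated/saturated pairing characteristic of asymmetric lipids.
No enrichment test against the independence null is computed — the scalar
is descriptive.

## Statistical choices

* **Group summaries** are arithmetic mean and sample SD (n − 1) over
  replicates, matching the bar ± SD convention of n = 3 experiments. SD is
  reported missing at n = 1.
* **Differences** between stressed and control groups propagate error as
  `sqrt(sd_a^2 + sd_b^2)` — the SD of a difference of independent
  quantities. The delta is antisymmetric, the propagated SD symmetric.
* **t-tests** default to the pooled-variance unpaired Student t with
  two-tailed p (the default flavor of common graphing software when the
  Welch correction is not ticked); Welch is available by flag. Zero
  pooled-variance cases are handled explicitly (equal means give p = 1,
  unequal means p = 0 and are flagged degenerate) rather than producing
  NaN. Significance tiers use strict thresholds 0.05 / 0.01 / 0.001. No
  multiple-testing correction is applied by default, making the
  per-feature-stars convention explicit; a Benjamini-Hochberg option
  exists for users who want it.
* **PCA** operates on the mean-centered samples-by-species mol% matrix;
  unit-variance scaling is optional and off by default because compositional
  mol% values already share a scale, and scaling would inflate the influence
  of near-zero species. Component signs are fixed by making the
  largest-magnitude loading positive, so results are reproducible to the
  coordinate. The explained-variance fractions sum to one over all
  components.
* **Growth fitting** uses nonlinear least squares on the untransformed
  exponential OD(t) = OD0 * exp(k t), seeded by a log-linear regression
  (which is also exposed as a cross-check method; the two agree within 2%
  on low-noise data). Only points with 0.2 <= OD600 <= 2.5 enter the fit —
  below that window the instrument is near its detection floor, above it
  the culture leaves exponential phase. Non-positive fitted rates are
  flagged rather than silently reported as negative doubling times.

## The synthetic-data generator

The generator produces lipidome tables with the statistical structure the
analysis assumes, with every generating parameter recorded in a truth
object so that downstream estimators can be validated by parameter
recovery:

* a baseline class composition over ~20 classes in the four categories,
  with four default conditions (YPD/SCD medium crossed with untreated/DTT);
* condition effects as multiplicative class-level fold changes. Targeted
  classes get their fold exactly (the untargeted remainder is rescaled so
  the composition still sums to 100), so the default two-fold PA increase
  under DTT in rich medium is exact in mol%. Defaults also include higher
  storage lipids in synthetic medium and a moderate PA decrease under DTT
  there, mirroring the qualitative biology of slow-growing, stressed
  cultures;
* chain-resolved glycerophospholipids assembled molecule by molecule from a
  medium-specific chain pool spanning 10:0 to 18:1 (the rich-medium pool
  carries more medium chains). The first chain is a pool draw; the second
  follows the pairing rule: a medium saturated chain receives a saturated
  long partner with probability s (default 0.95) and otherwise an
  independent draw from the remaining non-medium chains, while non-medium
  chains receive a non-medium partner in pool proportion. The implied
  chain-occurrence frequencies are computed analytically and stored in the
  truth record; with s unset, pairing is fully independent and occurrence
  frequencies equal the pool;
* sphingolipids at sum-composition level with 2-4 hydroxylations, and fixed
  species templates for the remaining classes;
* multiplicative lognormal noise per species amount (default sigma 0.10,
  i.e. ~10% CV — the replicate variability typical of well-run shotgun
  experiments at n = 3), and n = 3 replicates per condition.

Growth curves are generated as OD(t) = OD0 * 2^(t / Td) with optional
piecewise slowdown at a stress-onset time and multiplicative lognormal
noise (default 2%). Default doubling times are 86 min (rich medium) and
107 min (synthetic medium), the textbook values for exponentially growing
budding yeast in these media.

What the generator does **not** emulate: correlated noise between species
of one class, compositional closure artifacts from the finite total,
censoring at the detection limit, isotope-correction residuals, or any
mechanistic lipid metabolism (fatty-acid synthase product spectra,
desaturase kinetics). Passing recovery tests therefore demonstrates that
the estimators are correct under the stated statistical model, not that
real instrument data satisfy that model.

## Problem sizes and numerical conventions

The validation suite runs at deliberately modest sizes chosen to exercise
the asymptotics without waste: 2,000 molecules per glycerolipid class per
sample for pairing recovery (about 4,700 medium-chain occurrences per
condition, giving a 95% binomial CI of roughly ±0.9 percentage points on
the selectivity), 100 simulated growth curves at 2% noise for
doubling-time recovery within 3 min, 10,000 null simulations at n = 3 + 3
for t-test calibration within ±0.01 of the nominal 0.05, and a depth of
1e5 molecules for the independence-null convergence check at 1% tolerance.
Compositional identities (profiles summing to 100, pairing marginal
consistency, joint symmetry) are asserted at 1e-9 relative tolerance;
oracle-equivalence checks against brute-force enumeration on small
fixtures are asserted at 1e-12.

Ties and degenerate inputs: zero-total normalization groups are errors that
name the sample and group; chains with fewer than two carbons, or as many
double bonds as carbons, are rejected at parse time; pairing rows for
chains with no occurrences are returned as all-zero and flagged rather
than dividing by zero.

## Known limitations

* The nomenclature grammar covers the class vocabulary of this pipeline,
  not the full shorthand universe (no ether/plasmalogen species, no
  oxidized lipids, sterol esters only as `EE <C>:<DB>`).
* Whether mol% denominators for "all lipids" should include ergosterol is
  a reporting decision; this package includes every quantified species in
  the whole-lipidome denominator.
* Pairing is computed on the pooled two-chain MGL sub-category; per-class
  pairing can be obtained by passing a single class, but cross-class
  heterogeneity of chain pools is then the caller's concern.
* The t-test operates feature by feature on compositional data; mol%
  values within a sample are not independent, and the tests inherit that
  caveat exactly as the underlying reporting convention does.
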