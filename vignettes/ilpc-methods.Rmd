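---
title: "Methods: the ilpc chemical-space map and QSPR workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ilpc chemical-space map and QSPR workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilpc)
```

## The problem

An ionic liquid (IL) is a salt defined by one cation and one anion, and its
bulk properties — viscosity, hydrophobicity (n-octanol–water partition
coefficient K~OW~), aqueous solubility, enthalpy of fusion ΔH~F~ — are tuned
by choosing the ions. `ilpc` implements a screening tool that needs nothing
but the molecular formulas: it computes composition-and-connectivity (0D/1D,
"constitutional") descriptors for each ion, places the salt on a fixed
two-component principal-component map fitted to a reference set, assigns it
to one of six structural clusters, and reads qualitative property levels off
documented trend rules on the map coordinates. A separate module provides a
quantitative QSPR workflow for ΔH~F~ (genetic-algorithm descriptor selection
plus multiple linear regression with full validation statistics).

## The constitutional descriptor block

Each ion is described by 41 descriptors computed from its molecular graph
alone (no geometry): molecular weight and weighted atomic sums, graph and
bond counts, element counts, percentage composition and carbon hybridization
counts. The registry (`constitutionalRegistry()`) is versioned because the
historical 41-member constitutional block is not enumerated anywhere
authoritative: version 1.0 keeps the cumulative carbon-scaled van der Waals
volume `Sv` and omits its mean, the least-anchored candidate member, so that
the block holds exactly 41 entries while containing every descriptor the map
interpretation uses (Se/Sp/Si, nAT, nBT, RBN/RBF, nH, nC, nCsp3, MW, H%,
nSK, nBO, SCBO, nDB, nO, nS, nF, nHet, …). An IL vector is the cation block
(names suffixed `^C`) followed by the anion block (`^A`): 82 slots.

Conventions that matter:

* **Weighted sums.** `Se`, `Sp`, `Si`, `Sv` are sums over *all* atoms —
  implicit hydrogens included — of the atomic Sanderson electronegativity,
  polarizability, first ionization potential and van der Waals volume, each
  divided by the carbon value. The element table ships with the package
  (`elementTable()`, sources in its help page) so these sums are
  reproducible across installs. Formal charge never changes a lookup:
  these are composition counts, so N⁺ uses the values of N.
* **SCBO** sums conventional bond orders over the hydrogen-depleted graph
  with aromatic bonds counted as 1.5.
* **RBN** counts non-ring single bonds whose two endpoints are heavy atoms
  of heavy-atom degree ≥ 2. The rule is purely topological — no amide or
  sulfonyl exclusions — because any chemical exclusion list is arbitrary
  and the simple rule is deterministic and easy to audit. `RBF = RBN/nBT`.
* **Aromaticity** is honored from the SMILES aromatic (lowercase) notation;
  kekulized input is processed as written, with localized double bonds.
  The parser is deliberately strict: impossible valences on organic-subset
  atoms and multi-fragment (dot) input are errors, never repaired, because
  a descriptor computed from a silently "fixed" structure is worse than no
  descriptor.

## The chemical-space map

Descriptor matrices are autoscaled (mean 0, sample sd 1 per column).
Columns whose sd is below `1e-12 * max(1, |mean|)` are constant — for ions
this happens systematically (e.g. `nTB` over a set with no triple bonds) —
and are dropped and reported rather than scaled by ~0. The map is then a
correlation-matrix PCA: eigendecomposition of the covariance of the
autoscaled data. Autoscaling (rather than covariance PCA on raw columns) is
forced by the units: MW in mass units would otherwise drown the counts.

Two conventions make the map reproducible and keep its orientation
chemically readable:

* Components are ordered by eigenvalue; the largest-|loading| entry of each
  component is made positive.
* Each component has an optional *orientation anchor*: a size descriptor
  that must load positively, by default `MW^C` for PC1 and `MW^A` for PC2.
  PC1 then grows with overall ion size and PC2 with anion size, which is
  the sense the trend rules assume. The anchors are configuration, not
  science: they flip signs only, never reorder components.

A descriptor significantly shapes a component when the absolute Pearson
correlation between the descriptor column and the score column *strictly
exceeds* 0.7 (a value of exactly 0.7 is not significant). On autoscaled
fits this correlation equals loading × √eigenvalue, an identity
`interpretLoadings()` verifies internally and the tests check to 1e-8.

With all components retained, scores reconstruct the autoscaled matrix to
1e-8 and score columns are uncorrelated; the eigenvalues sum to the number
of retained descriptors. These conservation properties are tested instead
of any particular variance percentage, because explained-variance figures
are dataset properties, not algorithm properties.

## Ward clustering and cluster letters

Training scores are clustered agglomeratively with the Ward minimum-variance
criterion on Euclidean distances, in the retained 2-D score space (the map
is the object of interest, and cluster identities are defined by positions
on it). The implementation uses the Lance–Williams recurrence with merge
heights equal to the increase in within-cluster sum of squares (ΔESS);
heights are non-decreasing, and numerically-zero inversions arising from
tied merges are flattened. Ties are broken deterministically: among
equal-cost pairs, the pair whose smallest original member index (then second
smallest) is lowest merges first — so row order never silently changes a
result, and an exhaustive naive agglomeration oracle can be matched merge
for merge.

The tree is cut at k = 6 by default. Letters follow the map geometry: when
the six centroids split 3/3 over the PC1 sign, the low-PC1 centroids get
A, B, C by ascending PC2 and the high-PC1 centroids F, D, E by ascending
PC2 — A is the small-cation/halide corner, C the small-cation/TFSI-type
corner, E the large-cation/large-anion corner. In any other configuration
letters simply run by (PC1, PC2) order. New ILs are assigned to the
Euclidean-nearest centroid; exact ties go to the alphabetically first
letter and are flagged.

## Property overlays and trend rules

Measured reference properties are standardized per property to z-scores
(sample sd). Viscosity, K~OW~ and solubility are log10-transformed first:
they are positive, span decades, and their documented trends are
multiplicative; ΔH~F~ stays linear. z-scores are binned into five levels
(very-low … very-high) at edges −1.5, −0.5, 0.5, 1.5; binning is half-open
with a boundary value belonging to the upper bin, and the outer bins absorb
everything beyond the outer edges.

Qualitative predictions come from four linear trend rules on the scores,
with unit weights as documented defaults (only the signs, and the dominance
of PC2 for ΔH~F~, are asserted by the underlying map reading):

| property | trend score |
|---|---|
| viscosity | +PC1 − PC2 |
| K~OW~ | +PC1 |
| solubility | −PC1 + PC2 |
| ΔH~F~ | +PC2 |

A query's trend score is converted to a percentile against the training
trend distribution (empirical CDF) and cut at 33⅓ % / 66⅔ % into
low/medium/high. Because the ECDF is monotone, raising PC1 at fixed PC2 can
never lower the K~OW~ level nor raise the solubility level. Two caveats are
attached: solubility predictions for high-PC1 ILs carry a flag (the cation
dominates there and the PC2 term of the trend is unreliable), and every
ΔH~F~ prediction carries a reduced-confidence note plus a cluster heuristic
(C-cluster ILs are high-prone, A/F low-prone, B/D/E uncertain) because the
ΔH~F~ trend is the least consistent across data sources.

## The QSPR workflow for ΔH~F~

* **Split.** Records are sorted by the response; every rank ≡ 2 (mod 3)
  goes to validation. 30 records give 20/10, and both extremes always stay
  in training, so the validation set lies inside the calibrated range.
* **Selection.** A genetic algorithm over fixed-size descriptor subsets
  maximizes leave-one-out Q² of the MLR on the subset (population 50,
  generations 100, crossover 0.8, mutation 0.05 by default; fully seeded).
  Elitism guarantees the final fitness is never below the best random
  initial individual. Model sizes above n/5 are capped with a warning — a
  standard parsimony guard against chance correlation. On pools small
  enough to enumerate, the GA's winner is checked against exhaustive
  search in the tests.
* **Fit and validation.** Ordinary least squares; R² and RMSE on training;
  Q²~LOO~ = 1 − PRESS/TSS with PRESS through the hat-matrix shortcut
  e/(1−h) (the explicit n-refit route is also implemented and must agree to
  1e-10); external Q²~ext~ = 1 − Σ(ŷ−y)²/Σ(y−ȳ~train~)². Q² values are
  reported as computed, never clamped.
* **Applicability domain.** Leverage-only: h = xᵀ(XᵀX)⁻¹x with
  intercept-augmented rows, threshold h* = 3(p+1)/n. Training leverages
  satisfy 1/n ≤ h ≤ 1 and sum to p+1. When observations are supplied,
  standardized residuals are exported so a Williams plot
  (leverage × residual, by set) can be drawn; ±3 sd is the residual cut.

The ΔH~F~ model published with the original tool is not re-derived here —
its equation is not in the public record — so the workflow is validated by
planted-model recovery: on noiseless synthetic data it must achieve
R² = Q²~LOO~ = Q²~ext~ = 1 exactly, and on noisy data recover planted
coefficients within standard errors.

## The synthetic reference generator

The original reference measurements are not redistributable, so every stage
is exercised against a synthetic set (`generateReferenceSet()`), and the
generator is first-class, tested code. It emulates the *structure* of a
realistic IL reference panel:

* six cation families (imidazolium, ammonium, phosphonium, pyridinium,
  pyrrolidinium, sulfonium) built from template SMILES in which all alkyl
  substituents grow together, as real homologous series are synthesized;
* a small-cation tier and a large-cation tier (default chains 1–5 and
  9–16 carbons per substituent);
* anion classes paired with the tiers the way the six reference clusters
  describe: small cations with halide, fluoroborate/sulfonate and
  TFSI-type anions; large cations with amino-acid-type plus halide and
  fluoroborate/sulfonate anions; several concrete anions per class
  (Cl⁻/Br⁻/I⁻; BF₄⁻/PF₆⁻/mesylate/hydrogensulfate; TFSI/triflate/FSI;
  amino-acid carboxylates with growing side chains) so the anion block is
  structurally diverse rather than a single binary contrast.

Property values are generated from two structural latents plus Gaussian
noise (default sd 0.3 on the log scales, 1.5 kJ/mol for ΔH~F~): the organic
size *u* (total carbon count of both ions) and the anion heavy-atom size.
Viscosity rises with *u* and falls with anion size (so TFSI-type salts are
the least viscous at matched cation), K~OW~ rises with *u*, solubility
falls with *u* and rises with anion size, and ΔH~F~ rises with the anion's
size *relative to the cation* (0.8·anion heavy atoms − 0.3·cation carbons):
as the two ions approach each other in size the crystal packs more
regularly and melts at a higher enthalpy. That relative-size latent is also
what the second map axis measures, which is why the ΔH~F~ trend rule reads
+PC2.

What the generator does **not** emulate: real measured values or their
units' absolute scales, the exact descriptor numerics of any legacy
descriptor engine, a 38-anion census, heteroscedastic experimental error,
or the reference set's exact variance split — the synthetic map explains
about 58 % of the variance in two components, not the ~90 % a curated
literature panel shows, because the synthetic panel is deliberately small
and balanced. Passing tests therefore demonstrate that the machinery is
correct and that the documented trends are recovered when they are truly
present; they do not certify predictive accuracy on experimental data.

## Numerical choices

* Constant-column tolerance: relative sd below 1e-12.
* Ward tie-break: smallest-member-index pair first; merge-height
  inversions ≤ 1e-9 (relative) are flattened as tie noise.
* Bin boundaries belong to the upper bin; outer bins are clamped.
* Percentile levels use the empirical CDF, so a query at the training
  maximum is at percentile 1 ("high") by construction.
* Bundle JSON is written with 17 significant digits; save/load round-trips
  are bit-exact and verified by reprojection.
* GA randomness is isolated: the caller's RNG state is saved and restored.

## Problem sizes used by the tests

The suite runs a 60-IL reference fixture (10 per family), Ward oracle
equivalence on all instances up to n = 8, exhaustive GA cross-checks on
pools of 10–12 descriptors, a 200-seed coefficient-recovery study at n = 30,
and planted-rank PCA fixtures at 40 × 8 — sizes chosen so each property is
demonstrated on the smallest instance where failure would be visible.

## Known limitations

* The SMILES subset covers the ion chemistry the tool targets (organic
  subset, brackets, aromatic notation, rings/branches); it does not parse
  stereo bonds beyond treating them as single, isotopes beyond ignoring
  them, or multi-fragment records.
* Aromaticity is not re-perceived from kekulized input.
* Cluster letters carry the documented geometric semantics only when the
  fitted map resembles the reference geometry (3/3 split over the PC1
  sign); otherwise they are positional labels.
* Trend rules are qualitative by design; only ΔH~F~ has a quantitative
  model, and only within its leverage-based applicability domain.
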