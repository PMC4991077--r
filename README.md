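# ilpc — qualitative physicochemical screening of ionic liquids

`ilpc` is an R package for pre-synthesis screening of ionic liquids (ILs):
given nothing but the SMILES of a cation and an anion, it predicts
qualitative levels (low / medium / high) for four bulk properties —
viscosity, n-octanol–water partition coefficient (K<sub>OW</sub>), aqueous
solubility and enthalpy of fusion (ΔH<sub>F</sub>) — and, for
ΔH<sub>F</sub>, offers a full quantitative QSPR workflow. It is aimed at
people designing ILs who want to rank candidate ion combinations before any
synthesis or measurement.

## What it computes

1. **Constitutional descriptors.** For each ion, 41 composition-and-
   connectivity descriptors (MW, weighted atomic sums Se/Sp/Si/Sv, atom and
   bond counts, rotatable bonds, hybridization counts, percentage
   composition, …); an IL is the 82-slot concatenation of its cation and
   anion blocks.
2. **A chemical-space map.** The 82-column descriptor matrix of a reference
   set is autoscaled (x → (x−μ)/σ per column, constant columns dropped) and
   decomposed by correlation-matrix PCA. An IL's position is its score pair
   **t** = L<sup>T</sup> z on the first two components: PC1 grows with
   overall ion size, PC2 with anion size. A descriptor shapes a component
   when |cor(descriptor, score)| > 0.7.
3. **Six structural clusters.** Ward/Euclidean hierarchical clustering of
   the training scores, cut at k = 6 and lettered A–F by map geometry; new
   ILs go to the nearest centroid.
4. **Trend rules.** T<sub>visc</sub> = +PC1 − PC2, T<sub>Kow</sub> = +PC1,
   T<sub>sol</sub> = −PC1 + PC2, T<sub>ΔHF</sub> = +PC2; each query score is
   converted to a percentile against the training distribution and cut into
   low/medium/high.
5. **QSPR for ΔH<sub>F</sub>.** Rank-based 2:1 training/validation split,
   genetic-algorithm selection of a fixed-size descriptor subset maximizing
   Q²<sub>LOO</sub>, multiple linear regression with R², Q²<sub>LOO</sub>,
   Q²<sub>ext</sub>, RMSE, and a leverage applicability domain with
   h\* = 3(p+1)/n (Williams-plot export).

A deterministic synthetic reference-set generator
(`generateReferenceSet()`) stands in for proprietary reference data, so the
whole pipeline is testable offline; see the methods vignette
(`vignettes/ilpc-methods.Rmd`) for the model, every tunable default, and
what the synthetic set does and does not emulate.

## Worked example

```r
library(ilpc)

ref    <- generateReferenceSet(seed = 1)            # 60 synthetic ILs
bundle <- buildReferenceModel(ref$ils, ref$properties)
bundle
#> ModelBundle (reference chemical-space map)
#> ChemSpaceModel: 65 retained descriptors (17 dropped as constant), 2 components
#>   explained variance: PC1 33.06%, PC2 25.07% (total 58.14%)
#>   training set: 60 ionic liquids
#> ClusterModel: 60 training ILs in 6 clusters (Ward/Euclidean)
#>   A:17  B:8  C:21  D:4  E:6  F:4

query <- data.frame(
  il_id         = c("emim_Cl", "P4444_TFSI"),
  cation_smiles = c("CC[n+]1ccn(C)c1", "CCCC[P+](CCCC)(CCCC)CCCC"),
  anion_smiles  = c("[Cl-]", "C(F)(F)(F)S(=O)(=O)[N-]S(=O)(=O)C(F)(F)F"))
predictNew(bundle, query)[, c("il_id", "PC1", "PC2", "cluster",
                              "viscosity_level", "Kow_level",
                              "solubility_level", "enthalpy_of_fusion_level")]
#>        il_id   PC1  PC2 cluster viscosity_level Kow_level solubility_level
#> 1    emim_Cl -6.43 2.17       B             low       low             high
#> 2 P4444_TFSI  5.01 6.11       E          medium      high           medium
#>   enthalpy_of_fusion_level
#> 1                     high
#> 2                     high
```

Reading: the small 1-ethyl-3-methylimidazolium chloride sits far left on the
map (small organic size), so it is predicted fluid, hydrophilic and highly
water-soluble; the large tetrabutylphosphonium TFSI salt sits far right and
is predicted markedly more hydrophobic and less soluble. `saveBundle()` /
`loadBundle()` persist the fitted map as a single JSON document, and
`plotChemSpace()` draws the score map with up to ten highlighted queries.

A thin command-line front end covering the same verbs
(`fixtures`, `descriptors`, `fit`, `project`, `predict`, `qspr`) installs
as `exec/ilpc` inside the package.

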