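# synthenum

Reaction-based combinatorial library enumeration and diversity analytics
in R.

Virtual screening campaigns are limited by the chemistry space they can
reach: make-on-demand libraries are built by encoding a handful of robust
reactions as SMARTS transforms and combinatorially combining them with
purchasable building blocks. synthenum is a toolkit for building and
analysing such libraries, aimed at computational chemists who want to turn
a bench reaction — including chemistry that commercial libraries do not
cover — into a screening-ready virtual collection.

The core objects and steps:

* **Reaction definitions** — for each reaction, synthon inclusion SMARTS
  (`reagent A + reagent B → product`), synthon-specific and global
  exclusion SMARTS, symmetric-reagent detectors, and atom-mapped transform
  variants `T: (m_A, m_B) ↦ {p}` written as reaction SMARTS. Six
  definitions are packaged: β-keto-imides (with one-component precursor
  transforms turning β-keto acids/esters into the reactive dioxinone),
  5-amino-thiatriazoles, 5-amino-tetrazoles, the Truce-Smiles
  rearrangement (12 variants), and the [2+2] (4 variants) and [4+2]
  (6 variants) cycloadditions.
* **Building-block filtering** — catalogs of SMILES annotated with vendor
  id and availability tier (BB-50 … BB-10) are salt-stripped, capped at 40
  heavy atoms, and screened against the synthon filters.
* **Enumeration** — the chunked cross-product of the reagent pools through
  the transform engine, deduplicated on InChIKey, with provenance
  (reaction, variant, reagent ids) and purchasability coding
  (1 = all BB-50 reagents; 2 = all cheap with ≥1 BB-40).
* **Profiling** — MW, clogP, HBA/HBD, ROTB, TPSA, Fsp3, QED; the
  Lipinski + Veber druglikeness gate (MW ≤ 500, logP ≤ 5, HBA ≤ 10,
  HBD ≤ 5, ROTB ≤ 10, TPSA ≤ 140, HAC ≤ 38); PAINS A/B/C and
  Brenk-/NIH-style structural alerts.
* **Diversity** — Bemis-Murcko scaffold census and between-library
  overlap, principal-moments-of-inertia shape triangles
  (NPR1 = I₁/I₃, NPR2 = I₂/I₃, binned 200 × 200), and InChIKey identity
  partitions for fast exact-identity search between libraries.

Chemistry perception (SMILES/SMARTS/InChIKey, descriptors, 3D building) is
provided by Open Babel, linked through Rcpp; the mapped-reaction transform
engine is implemented in the package and validated against an independent
reaction engine (see the methods vignette,
`vignettes/enumeration-workflow.Rmd`).

## Worked example

Enumerate 5-amino-tetrazoles from a small synthetic catalog of primary
amines and isothiocyanates:

```r
library(synthenum)

defn <- builtin_reaction("aminotetrazoles")
defn
#> <reaction_definition> aminotetrazoles (5-amino-tetrazoles)
#>   synthons: TET_A, TET_B
#>   variants: 1;  global exclusions: 23

catalog <- rbind(generate_fixtures("primary_amine", 4, seed = 7),
                 generate_fixtures("isothiocyanate", 3, seed = 7))
pools    <- build_pools(defn, catalog)
products <- enumerate_products(defn, pools)
nrow(products)
#> [1] 12

head(products[, c("smiles", "product_id", "purchasability")], 2)
#>           smiles                                                         product_id purchasability
#> 1 CCCNc1nnnn1CCC aminotetrazoles_TET_1_FIX-primary_amine-003_FIX-isothiocyanate-003              1
#> 2 CCCNc1nnnn1CCCC aminotetrazoles_TET_1_FIX-primary_amine-003_FIX-isothiocyanate-004     expensive
```

Each of the 4 × 3 reagent pairs reacted exactly once (12 products, no
InChIKey duplicates). The purchasability code follows the reagent tiers:
code 1 products are made from BB-50 reagents only. Profiling and
diversity:

```r
desc <- compute_descriptors(products$smiles)
round(100 * mean(desc$druglike), 1)
#> [1] 100

scaffold_summary(products$smiles)
#> <scaffold_summary> 12 compounds, 2 scaffolds, 6 compounds/scaffold
```

All twelve aminotetrazoles pass the druglikeness gate; they share the
1,5-disubstituted tetrazole scaffold (plus one benzyl-bearing scaffold),
giving 6 compounds per Bemis-Murcko scaffold.

A thin CLI wraps the same functions
(`exec/synthenum fixtures|filter-bb|enumerate|descriptors|diversity`).

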