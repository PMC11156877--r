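---
title: "Reaction-based library enumeration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-based library enumeration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthenum)
```

## The procedure

synthenum builds virtual chemical libraries the way modern make-on-demand
collections are built: a chemical reaction is encoded once as a set of
SMARTS definitions, commercial building-block catalogs are screened for
compatible reagents, and the library is the combinatorial cross-product of
the reagent pools pushed through the encoded transform.

A reaction definition has three layers:

* **Synthons** — reagent classes. Each synthon carries *inclusion* SMARTS
  (a block qualifies if it matches any of them), synthon-specific
  *exclusion* SMARTS, an optional *symmetric-reagent* detector (so that the
  two equivalent acyl halves of an anhydride do not double-count products),
  and *reaction tags* that bind the synthon to transform component slots.
  A synthon may instead be a *precursor* class: a purchasable surrogate
  (e.g. a β-keto acid or its O-protected ester) that is converted by a
  one-component transform into the reactive class (a dioxinone) before the
  main reaction.
* **Variants** — atom-mapped reaction SMARTS (`reagents >> product`), one
  per substitution/chain-length/chirality case of the same chemistry, each
  with an ordered tag list naming which synthon feeds which template.
* **Global exclusions** — reaction-level SMARTS vetoing reactive or
  unstable groups in any reagent. The default list shipped in
  `inst/extdata/global_exclusions.txt` is an editable, explicitly
  non-canonical approximation of ZINC-style reactivity filters; each
  packaged reaction carries its own pruned copy (rules describing the
  reaction's own reactive groups — acyl halides for a reaction consuming
  acyl halides — are dropped, mirroring case-by-case curation).

The package ships six built-in definitions: β-keto-imides (with five
precursor transforms), 5-amino-thiatriazoles, 5-amino-tetrazoles, the
Truce-Smiles rearrangement (12 variants: {aryl-ZH, aryl-sulfonamide} ×
{achiral, chiral} × chain length 0–2), and the [2+2] (4 variants) and
[4+2] (6 variants) cycloadditions via 1,2-acyloxycyclohexadienes.

## The transform engine

R has no equivalent of a mapped-reaction engine, so synthenum implements
one. Open Babel (linked through Rcpp) provides perception: SMILES/MOL
parsing, SMARTS matching with atom indices, canonical SMILES and InChIKey.
The engine itself works on hydrogen-explicit molecular graphs:

1. each reagent template is matched against its reagent (explicit
   hydrogens make templates such as `[CX4H2!R:5][H]` and `[*,H:22]`
   behave as written);
2. the product template is parsed into a graph whose mapped atoms are
   placeholders; each placeholder inherits the matched reagent atom plus
   every substituent reachable through unmatched atoms, while
   matched-but-unmapped atoms (leaving groups) are consumed;
3. bonds between mapped atoms are defined solely by the product template;
4. hydrogen counts rebalance against the valence change at each mapped
   atom (`ΔH = new template bond order − removed bond order`), with an
   explicit `Hn` in the product template taking precedence;
5. the assembled graph round-trips through a V2000 MOL block and Open
   Babel for sanitization, aromaticity perception and canonicalization;
   multi-fragment products keep the largest fragment by heavy atoms
   (ties: lexicographically smallest canonical SMILES), which silently
   discards by-products such as the acetonide fragment of the
   β-keto-imide transform.

One dialect note: Open Babel rejects mapped bare hydrogens (`[H:99]`), so
those are rewritten to the equivalent `[#1:99]` on the way into the
matcher; the registry keeps the verbatim strings. The engine was validated
case by case against an independent reference reaction engine; the
expected products are frozen in the test suite as InChIKeys, which are
toolkit-independent identities.

## Enumeration semantics

`enumerate_products()` streams the cross-product of the reagent pools in
chunks of `chunk_size` (default 2000, the batch size used for distributing
large enumerations over worker processes). The product set is a pure
function of definition, pools and options: chunking changes only the order
of work, never the result, and the test suite asserts equality between
`chunk_size = 1` and `chunk_size = 2000` and against a brute-force
double-loop oracle.

Products are deduplicated on InChIKey within the enumeration
(`dedup_scope = "per_reaction"`, the default, matching a per-reaction
library layout); cross-reaction deduplication is a caller decision via
`dedup_products()`, because whether a compound reachable by two reactions
should be counted once is a library-design question, not an enumeration
one. Multi-embedding reagents (a diamine offers two amine sites) generate
one raw product per embedding before deduplication — losing sites would
lose products. Purchasability is coded from reagent tiers: `1` when every
reagent is BB50, `2` when all reagents are cheap (BB50/BB40) with at least
one BB40, `expensive` otherwise; `classify_cheap()` implements the
BB50/BB40 vs rest split.

Stereochemistry is deliberately absent: the printed transforms assign no
configurations and the enumeration is 2D; the chiral/achiral distinction
of the Truce-Smiles variants is kept as a provenance annotation only.

`curation_sample()` reproduces the curation step in which up to 100
representative products are drawn for visual inspection: greedy MaxMin
under Tanimoto distance on hashed radius-2, 2048-bit circular
fingerprints. The fingerprint is a faithful Morgan-style algorithm
implemented in R (no circular fingerprint exists in the available
toolkits) and is *not* bit-compatible with other ECFP4 implementations;
within-package distances are all MaxMin needs, and the greedy pick is
tested against an exhaustive-subset oracle.

## Descriptors, gate, alerts

`compute_descriptors()` reports MW, Wildman–Crippen atom-contribution logP
(Open Babel's estimator; the gate needs a reproducible estimate more than
any particular flavour), Lipinski-convention HBA (N+O count) and HBD (N/O
bearing ≥1 H), rotatable bonds, TPSA, heavy atoms, Fsp3 and QED. The
druglike verdict is the conjunction MW ≤ 500, logP ≤ 5, HBA ≤ 10,
HBD ≤ 5, ROTB ≤ 10, TPSA ≤ 140, and — configurable, default on — heavy
atoms ≤ 38. The heavy-atom rule is shipped as a gate rather than a
descriptive statistic because a hard cap composes cleanly with the others
and can be switched off (`hac_gate = FALSE`) when only the classical
Lipinski/Veber reading is wanted.

QED uses the published asymmetric-double-sigmoid desirability functions
and weights. Two terms necessarily deviate from the reference
implementation: the acceptor term uses the Lipinski N+O count rather than
a pharmacophore-based acceptor definition, and the ALERTS term counts hits
of the packaged Brenk-style catalog. QED values are therefore internally
consistent but not numerically interchangeable with other codes.

Structural alerts: the PAINS A/B/C files are the published WEHI patterns
(480 in total, 16/55/409 per family) and every pattern compiles in Open
Babel; matching is done against hydrogen-explicit molecules because the
published patterns use explicit `[#1]` atoms. The Brenk-style and
NIH-style catalogs could not be obtained as redistributable text, so the
package ships curated approximations (`*_synthetic.txt`) covering the
canonical motif families of the original publications; their hit rates
are indicative, not reference values, and the file headers say so.

## Diversity analytics

*Scaffolds.* Bemis–Murcko scaffolds are computed by graph pruning:
iteratively delete non-ring atoms of degree ≤ 1, then re-attach atoms
multiply bonded to the remaining ring-and-linker frame (exocyclic
carbonyls). Acyclic molecules map to an explicit empty-scaffold sentinel
(`""`), counted separately in the census — Bemis–Murcko is undefined
without rings and silently dropping acyclics would bias
compounds-per-scaffold ratios.

*Shape.* `npr_shape()` builds a single conformer per molecule (Open
Babel's rule-based 3D builder plus a short steepest-descent relaxation,
200 steps by default — deterministic, which is why a single fast conformer
is preferred over stochastic multi-conformer searches) and returns the
normalized principal-moment ratios NPR1 = I1/I3, NPR2 = I2/I3.
`bin_shapes()` histograms the (NPR1, NPR2) pairs on a 200 × 200 grid over
[0, 1] × [0.5, 1]; out-of-triangle points beyond 1e-6 are clamped with a
warning rather than dropped, so counts are conserved.

*Identity.* `build_partition()` buckets standard InChIKeys by heavy-atom
count and the first two key letters, mirroring a directories-and-files
store that can be searched with `grep`; `partition_lookup()` is tested to
be exactly equivalent to a linear scan. Identity means the full
27-character standard InChIKey — the conservative reading; the
14-character skeleton would conflate stereoisomers and isotopologues.

## The synthetic building-block generator

`generate_fixtures()` emits deterministic catalogs for seventeen reagent
classes (amines, amides, isothiocyanates, EWG-bearing acyl halides,
β-keto acids and esters, dioxinones, anhydrides, acyl chlorides, mono- and
1,1-disubstituted olefins, furans, N-substituted pyrroles,
cyclopentadienes, aryl-ZH and aryl sulfonamides). Blocks are assembled
from curated fragment grammars — small alkyl/aryl decorations on each
class's core motif — so class membership is guaranteed by construction and
re-verified at generation time against the packaged synthon SMARTS and the
consuming reaction's pruned global exclusions; a grammar that emitted a
non-conforming block would error rather than under-deliver. Tier labels
are drawn reproducibly from a *balanced* default mix
(BB50 .35 / BB40 .25 / BB30 .20 / BB20 .10 / BB10 .10): a test catalog
needs all purchasability codes exercised, which the heavily skewed tier
frequencies of real catalogs (where cheap blocks are roughly a percent of
stock) would not provide at fixture scale.

What the generator does *not* emulate: vendor salt forms beyond simple
counterions, charged species, stereochemistry, the size distribution of
real catalogs (fixtures are small, 1–12 heavy-atom decorations), or
pattern-breaking pathological SMILES. Passing tests therefore demonstrate
the correctness of the machinery — matching, grafting, bookkeeping,
analytics — on guaranteed-valid chemistry, not robustness against the full
messiness of commercial catalog data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: five to six
blocks per reagent class, pools of at most a few dozen reagents, a few
hundred enumerated products per run, 300–500 embedded conformers, and
10^4-key partition checks. These sizes were chosen so that every check has
an exhaustive or brute-force oracle; the machinery itself is
size-independent (chunked streaming, compiled pattern screens).

Other fixed choices: SMARTS matching always salt-strips to the largest
organic fragment first and applies the 40-heavy-atom cap after stripping
(a counterion should not disqualify a small block); the MaxMin seed
controls only the first pick, with ties broken on the lowest index; float
columns in the exchange CSV are serialized at 6 significant digits.

## Known limitations

* Product sanitization relies on Open Babel's valence model; a raw product
  it cannot kekulize is dropped (with a warning) rather than repaired.
* The Brenk-style and NIH-style alert rates are approximations (see
  above); PAINS rates are computed from the published patterns.
* logP, QED and the pharmacophore-free HBA count differ numerically from
  other toolkits; gates and rates are internally consistent.
* No retro-feasibility or synthesis success-rate modelling: an enumerated
  product is a combinatorial possibility, not a synthesis guarantee.
* One conformer per molecule for shape analysis; flexible molecules'
  NPR positions are single samples of their conformational ensembles.
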