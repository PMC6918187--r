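---
title: "Analytic correlation filtration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic correlation filtration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acorf)
```

## The problem: analytical redundancy in MS metabolomics

During electrospray (or electron-impact) ionisation a single metabolite
produces several detected features: the monoisotopic parent ion, its
isotopologues (one ^13^C shifts *m/z* by ≈ 1.003355 Da), adducts (e.g. a
sodium-for-proton exchange, +21.981944 Da) and in-source fragments (e.g. a
water loss, −18.010565 Da). After XCMS-style peak picking, a peak table of a
few thousand features therefore contains far fewer distinct analytes than
rows, and the redundant features carry near-proportional intensity profiles
across samples. This analytical correlation inflates multiple-testing
burdens and clutters interpretation; it should be removed without touching
*biological* correlation between genuinely distinct metabolites.

`acorf` groups features that plausibly originate from the same analyte and
nominates one representative (quantifier) feature per group, so the dataset
can be reduced to one variable per analyte.

## The algorithm

Three independent criteria are applied to every feature pair, in a cascade
where each stage only removes candidate pairs:

1. **Similarity threshold.** From a pairwise similarity matrix *s(i, j)*
   (any measure; Pearson or Spearman correlation of intensity profiles can
   be computed internally), keep the pairs with *s(i, j)* strictly greater
   than the threshold.
2. **Retention-time gate** (optional, recommended). Keep a pair only if the
   two features co-elute: |rt~a~ − rt~b~| ≤ Δ~RT~.
3. **Mass-difference gate** (optional, recommended; requires the RT gate,
   because a chemical link between non-co-eluting ions is not meaningful).
   Keep a pair only if its *m/z* difference matches some entry of a
   reference list of isotope/adduct/fragment mass deltas:
   ||mz~a~ − mz~b~| − δ~k~| ≤ tol for some *k*. The matching label is
   recorded and drives the annotation columns.

Groups are the **connected components** of the graph whose edges are the
surviving pairs: if A–B and B–C were validated, {A, B, C} form one group
even when A–C itself failed a gate. This transitive reading reflects how
redundancy propagates through a shared parent ion (the parent correlates
with, co-elutes with and is mass-linked to each derived ion, while two
derived ions may differ by an uncatalogued combined delta). Features with
no surviving edge become singleton groups; singletons receive ordinary
group ids because group counting — and the identity "kept features =
number of groups" — depends on it.

Finally one representative is chosen per group, by one of four methods:
highest mean intensity, highest mass, highest mass² × mean intensity, or
highest mass among the `topN` most intense members. The last method suits
GC-MS, where a heavy, moderately abundant fragment is often the most
specific quantifier.

## Parameters

| parameter | units | preset values | notes |
|---|---|---|---|
| `corThreshold` | dimensionless | 0.90 (`lc-hrms`, `gc-ms`), 0.75 (`sacurine-camera-compat`) | strict `>`; signed comparison |
| `rtDelta` | units of the rt column | 0.1 min | inclusive `≤`; `acorfPreset(..., rtUnits = "s")` converts to seconds |
| `massTol` | Da | 0.005 (`lc-hrms`), 0.2 (`gc-ms`, low-resolution quadrupole), 0.002 (`sacurine-camera-compat`) | inclusive `≤` |
| `repMethod` | — | highest intensity (LC), highest mass in top n (GC) | four methods |
| `topN` | count | 5 (`gc-ms`) | only for `highest_mass_in_top_n` |

Design choices where the behaviour was genuinely open, and the conventions
adopted:

* **Boundary conventions.** The similarity cutoff is a strict `>` ("higher
  than the threshold"); the RT and mass tolerances are inclusive `≤` ("more
  or less a delta"). Both are exercised at the boundary in the tests.
* **Signed similarity.** Anti-correlated features never group by default:
  derived ions of one analyte are positively proportional to their parent.
  `absolute = TRUE` is available for similarity measures where sign carries
  no chemical meaning.
* **"Highest intensity"** is the arithmetic mean across samples (missing
  values excluded), consistently for methods 1, 3 and 4.
* **Tie-breaks.** Any argmax tie is broken by higher *m/z*, then by
  lexicographic feature id, so results are deterministic. A mass delta
  matching several list entries within tolerance takes the closest entry;
  residual ties take the earlier list entry.
* **`topN = 5`** is the `gc-ms` preset default, a middle value of the
  commonly used top-3/top-5/top-10 range.
* **Output rendering.** Singleton rows carry `"-"` in the annotation and
  representative cells but keep a unique group id and a keep flag of 1.
  The in-group annotation grammar is `label@partner` (partners ascending);
  the representative-relative column uses `+label`/`-label` sign prefixes
  (heavier/lighter than the representative), `"unmatched"` when no list
  entry fits, and `"M (representative)"` for the representative itself.
  These strings are this package's convention.
* **SIF scope.** The exported SIF network contains the pairs passing the
  similarity threshold *before* the RT/mass gates, one line per unordered
  pair with the similarity rendered to 4 decimals as the interaction label,
  so the network shows every correlation above the cutoff.
* **Missing data.** Similarities are computed on pairwise-complete
  observations; a pair sharing fewer than 3 samples, or any pair involving
  a zero-variance feature, gets a missing similarity, which no threshold
  selects. Pairwise deletion is the least destructive option for sparse
  peak tables.

## The default delta list

The shipped reference list (`defaultDeltaList()`,
`inst/extdata/default_delta_list.tsv`) holds twelve standard monoisotopic
mass differences: ^13^C and 2×^13^C isotopologue spacings, NH~3~, Na−H,
K−H exchanges, H~2~O and CO~2~ losses, formic and acetic acid, sodium
formate, SO~3~ and HPO~3~ moieties. It is this package's own versioned
list, chosen to cover the most common electrospray species in either
ionisation mode; instrument- or chemistry-specific work should supply its
own two-column list via `readDeltaList()`.

## The synthetic-data generator

`simulateDataset()` emulates exactly the structure the algorithm exploits:
each analyte gets a parent feature (uniform *m/z* in 100–800 Da, uniform RT
in 60–900 s, per-sample base intensities log-uniform over three decades,
10^3^–10^6^) and 0–`maxDerived` derived features whose *m/z* is the parent
*m/z* ± a delta drawn from the reference list (minus for `_loss` entries),
whose RT is the parent RT plus a bounded uniform jitter, and whose
intensities are `ratio × parent × (1 + ε)` with `ratio` uniform in
[0.05, 0.8] and ε Gaussian with relative standard deviation `cvNoise`
(multiplicative noise mimics electrospray response variability).
Uncorrelated background features have independent log-uniform profiles.
Ground truth (analyte membership, role, applied delta) is returned
alongside, and `scoreRecovery()` reports the adjusted Rand index plus the
fraction of analyte groups recovered exactly.

What the generator does **not** emulate: chromatographic peak shapes and
co-elution structure, correlated (biological) analytes, m/z measurement
error, detector saturation, missing values, and batch effects. Passing the
recovery tests therefore demonstrates the correctness of the gate cascade
and grouping logic under the stated noise model — not performance on real
data, where the similarity measure and tolerances must absorb those extra
effects (hence the more conservative real-data presets).

## Validation problem sizes

The shipped checks use: 200 random graphs of ≤ 50 features against a
brute-force BFS oracle; 100 simulated datasets (6 analytes, ≤ 3 derived,
10 noise features, 10 samples) for the monotone-refinement property; the
printed 5-feature toy dataset end to end; 500 random groups for the
representative-method identities; and a recovery study at 50 analytes with
≤ 4 derived features each, 100 noise features, 50 samples, 5% intensity
noise and ±3 s RT jitter under the `lc-hrms` preset (thresholds 0.90 /
6 s / 0.005 Da), where the pipeline attains ARI ≥ 0.95 and ≥ 90% exactly
recovered analyte groups. These sizes make the whole suite run in well
under a minute while keeping every property at a scale where failures
would be visible.

## Known limitations

* The cascade validates pairs, not spectra: it cannot split two analytes
  that are mutually correlated above the threshold, co-eluting *and*
  separated by a listed delta — such pairs are chemically indistinguishable
  from genuine redundancy at the peak-table level.
* Connected components can chain groups through hub features; the RT and
  mass gates exist precisely to prune such bridges, and the per-stage group
  counts (`stageGroupCounts()`) let users audit how much each criterion
  refines the grouping.
* The tool flags redundant features (`ACorF_filter = 0`) but deliberately
  leaves row deletion to downstream filters; `applyFilter()` is provided as
  a convenience.
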