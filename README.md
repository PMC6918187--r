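# acorf — analytic correlation filtration of MS metabolomics feature tables

LC- and GC-MS metabolomics peak tables are analytically redundant: one
metabolite spawns many detected features (the monoisotopic parent ion, its
isotopologues, adducts and in-source fragments), all with near-proportional
intensity profiles across samples. This inflates multiple-testing
corrections and clutters interpretation. `acorf` detects this redundancy —
without confusing it with biological correlation — and reduces the dataset
to one representative feature per analyte.

It is aimed at metabolomics data analysts working at the peak-table level
(after XCMS-style pre-processing), using the Workflow4Metabolomics (W4M)
two-file convention: a *data matrix* (features × samples intensities) and a
*variable metadata* table (feature id, m/z, retention time, free columns).

## The algorithm

Feature pairs are validated through a cascade of three independent
criteria, each only removing pairs:

1. **similarity** — keep pairs with s(i, j) > threshold, where s is any
   pairwise similarity (Pearson/Spearman correlation can be computed
   internally, or any external matrix can be supplied);
2. **retention time** — keep co-eluting pairs, |rt_a − rt_b| ≤ Δ_RT;
3. **mass difference** — keep pairs whose m/z difference matches a
   reference list of isotope/adduct/fragment deltas:
   ||mz_a − mz_b| − δ_k| ≤ tol for some list entry k (the matched label is
   recorded and reported).

Groups are the connected components of the surviving-pair graph; features
with no validated partner form singleton groups. One representative per
group is then chosen by one of four methods (highest mean intensity,
highest mass, highest mass² × mean intensity, highest mass among the top-n
most intense), and every non-representative member is flagged for deletion
(`ACorF_filter = 0`).

Outputs: the variable metadata with five appended result columns
(`ACorF_groups`, `isotopes_adducts_fragments`, `ACorF_filter`,
`representative_<method>`, `annotation_relative_to_representative`) and a
Cytoscape SIF file of all above-threshold correlations.

## Worked example

The package ships a 5-feature / 3-sample toy dataset: F1–F3 are one
analyte (parent, ¹³C isotopologue at +1.0033 Da, sodium adduct at
+21.9819 Da, proportional profiles, co-eluting near 120 s), F4 is
anti-correlated, F5 is highly correlated with F1–F3 and co-eluting but at
a chemically unexplainable mass offset.

```r
library(acorf)
dm <- system.file("extdata", "toy", "dataMatrix.tsv", package = "acorf")
vm <- system.file("extdata", "toy", "variableMetadata.tsv", package = "acorf")
m  <- readDataMatrix(dm)
ft <- readVariableMetadata(vm)
res <- acorFilter(m, ft, simMethod = "pearson", corThreshold = 0.9,
                  rtDelta = 6, deltas = defaultDeltaList(), massTol = 0.005,
                  repMethod = "highest_intensity")
res
```

```
pairs above similarity threshold 0.9: 6
pairs within RT window 6: 6
pairs with a matched mass difference (tol 0.005 Da): 2
analytical correlation groups: 3
AcorfResult
  features: 5   groups: 3 (2 single-ion)
  flagged redundant (ACorF_filter = 0): 2 (40.0%)
  pairs after similarity gate: 6
  pairs after rt gate: 6
  pairs after mass gate: 2
  representative method: highest_intensity
```

Six pairs pass the correlation threshold (F5 correlates at 0.9934 with
F1–F3); all six co-elute within 6 s except none is removed; the mass gate
keeps only F1–F2 (¹³C) and F1–F3 (Na−H), so F5 falls out into its own
group while F2–F3 stay together through their shared parent F1. The
annotated table:

```r
annotatedTable(res)[c(1, 5:9)]
```

```
  variableMetadata ACorF_groups isotopes_adducts_fragments ACorF_filter
1               F1            1     isotope_13C@F2;Na-H@F3            1
2               F2            1             isotope_13C@F1            0
3               F3            1                    Na-H@F1            0
4               F4            2                          -            1
5               F5            3                          -            1
  representative_highest_intensity annotation_relative_to_representative
1                               F1                    M (representative)
2                               F1                          +isotope_13C
3                               F1                                 +Na-H
4                                -                                     -
5                                -                                     -
```

F1 (highest mean intensity) represents its group; F2 and F3 are flagged
for deletion; the singletons F4 and F5 keep their rows. Write the outputs
with `writeAnnotatedMetadata(annotatedTable(res), "out.tsv")` and
`writeSif(candidatePairs(res, "similarity"), "out.sif")`, or filter the
data matrix directly with `applyFilter(res, m)`.

Presets for common platforms are available via `acorfPreset()`:
`"lc-hrms"` (0.90 / 0.1 min / 0.005 Da, highest intensity), `"gc-ms"`
(0.90 / 0.1 min / 0.2 Da, highest mass in top 5) and
`"sacurine-camera-compat"` (0.75 / 0.1 min / 0.002 Da).

## Command line

A thin CLI wraps the same functions:

```sh
acorf=$(Rscript -e 'cat(system.file("scripts", "acorf", package = "acorf"))')
Rscript $acorf similarity --data-matrix dataMatrix.tsv --method pearson --out sim.tsv
Rscript $acorf run --data-matrix dataMatrix.tsv --variable-metadata variableMetadata.tsv \
    --similarity-matrix sim.tsv --delta-list default --preset lc-hrms --rt-units s \
    --out-metadata out.tsv --out-sif out.sif
Rscript $acorf simulate --n-analytes 50 --seed 1 --out-prefix sim
Rscript $acorf score --annotated-metadata out.tsv --ground-truth sim_groundTruth.tsv
```

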