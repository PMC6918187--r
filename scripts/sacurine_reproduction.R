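#!/usr/bin/env Rscript

## Best-effort reproduction on the public Sacurine LC-HRMS urine dataset
## (W4M00002_Sacurine-comprehensive; 184 samples x 3120 ions after noise
## filtration), which must be downloaded separately from
## Workflow4Metabolomics. Usage:
##
##   Rscript scripts/sacurine_reproduction.R <dataMatrix.tsv> <variableMetadata.tsv>
##
## Runs the CAMERA-comparable preset (Pearson, threshold 0.75, RT window
## 0.1 min, mass tolerance 0.002 Da, highest-intensity representative) and
## prints the group accounting. Expected ballpark on the published subset:
## ~2697 groups, ~2397 of them single-ion, ~14% of ions flagged redundant.
## The published subset definition is not fully specified, so exact
## equality is not guaranteed.

suppressPackageStartupMessages(library(acorf))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2L)
    stop("usage: Rscript scripts/sacurine_reproduction.R <dataMatrix.tsv> <variableMetadata.tsv>")

m <- readDataMatrix(args[[1L]])
ft <- readVariableMetadata(args[[2L]])
p <- acorfPreset("sacurine-camera-compat", rtUnits = "s")
res <- acorFilter(m, ft, simMethod = "pearson",
                  corThreshold = p$corThreshold, rtDelta = p$rtDelta,
                  deltas = defaultDeltaList(), massTol = p$massTol,
                  repMethod = p$repMethod)
sizes <- table(groups(res))
cat(sprintf("ions: %d\ngroups: %d\nsingle-ion groups: %d\nflagged redundant: %d (%.1f%%)\n",
            length(groups(res)), nGroups(res), sum(sizes == 1L),
            sum(filterFlags(res) == 0L), 100 * mean(filterFlags(res) == 0L)))
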