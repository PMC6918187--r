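## The 5-feature / 3-sample toy dataset shipped under extdata: three
## proportional profiles F1-F3 (one analyte: monoisotopic peak, 13C
## isotopologue, sodium adduct), an anti-correlated feature F4 and a highly
## but imperfectly correlated feature F5 at a chemically unexplainable mass
## offset.

toyPath <- function(file) {
    system.file("extdata", "toy", file, package = "acorf", mustWork = TRUE)
}

toyObjects <- function() {
    suppressMessages(list(
        m = readDataMatrix(toyPath("dataMatrix.tsv")),
        ft = readVariableMetadata(toyPath("variableMetadata.tsv")),
        s = readSimilarityMatrix(toyPath("similarityMatrix.tsv"))
    ))
}

toyResult <- function(repMethod = "highest_intensity", topN = NULL) {
    toy <- toyObjects()
    suppressMessages(acorFilter(toy$m, toy$ft, similarity = toy$s,
        corThreshold = 0.9, rtDelta = 6, deltas = defaultDeltaList(),
        massTol = 0.005, repMethod = repMethod, topN = topN))
}
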