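#' @include AllClasses.R AllGenerics.R grouping.R representative.R
NULL

#' @describeIn acorFilter workhorse method: `object` is the features x
#'   samples intensity matrix.
#'
#' @param featureTable a [FeatureTable-class] describing the features
#'   (m/z, retention time, passthrough columns).
#' @param similarity symmetric similarity matrix; when `NULL` it is computed
#'   from the intensities with [computeSimilarity()] and `simMethod`.
#' @param simMethod `"pearson"` or `"spearman"`; required (explicitly) when
#'   `similarity` is `NULL`.
#' @param corThreshold similarity cutoff; pairs must exceed it strictly.
#' @param rtDelta retention-time tolerance in the units of the rt column;
#'   `NULL` disables the RT gate.
#' @param deltas a [DeltaList-class] of reference mass differences; `NULL`
#'   disables the mass gate. The mass gate requires the RT gate.
#' @param massTol mass tolerance (Da) for delta matching; required with
#'   `deltas`.
#' @param repMethod representative-selection method, one of
#'   `"highest_intensity"`, `"highest_mass"`, `"mass2_x_intensity"`,
#'   `"highest_mass_in_top_n"`.
#' @param topN positive integer, required for `highest_mass_in_top_n`.
#' @param absolute compare absolute similarities (default: signed, so
#'   anti-correlated features never group).
#'
#' @examples
#' dm <- system.file("extdata", "toy", "dataMatrix.tsv", package = "acorf")
#' vm <- system.file("extdata", "toy", "variableMetadata.tsv", package = "acorf")
#' m <- readDataMatrix(dm)
#' ft <- readVariableMetadata(vm)
#' res <- acorFilter(m, ft, simMethod = "pearson", corThreshold = 0.9,
#'                   rtDelta = 6, deltas = defaultDeltaList(), massTol = 0.005,
#'                   repMethod = "highest_intensity")
#' res
#' annotatedTable(res)
#' @export
setMethod("acorFilter", "matrix", function(object, featureTable,
        similarity = NULL, simMethod = NULL, corThreshold,
        rtDelta = NULL, deltas = NULL, massTol = NULL,
        repMethod = c("highest_intensity", "highest_mass",
                      "mass2_x_intensity", "highest_mass_in_top_n"),
        topN = NULL, absolute = FALSE) {
    repMethod <- match.arg(repMethod)
    stopifnot(is(featureTable, "FeatureTable"))
    if (repMethod == "highest_mass_in_top_n" && is.null(topN))
        stop("'topN' is required for repMethod = 'highest_mass_in_top_n'",
             call. = FALSE)
    if (!is.null(topN) && repMethod != "highest_mass_in_top_n")
        stop("'topN' is only meaningful for repMethod = 'highest_mass_in_top_n'",
             call. = FALSE)
    ids <- featureIds(featureTable)
    .checkIdCoverage(rownames(object), ids, "data matrix")
    if (is.null(similarity)) {
        if (is.null(simMethod))
            stop("no similarity matrix supplied: name 'simMethod' explicitly ",
                 "(\"pearson\" or \"spearman\") to compute one internally",
                 call. = FALSE)
        similarity <- computeSimilarity(object[ids, , drop = FALSE], simMethod)
    }
    run <- runFiltration(featureTable, similarity, corThreshold,
                         rtDelta = rtDelta, deltas = deltas, massTol = massTol,
                         intensities = object, absolute = absolute)
    assignment <- run$assignment
    meanInt <- rowMeans(object[ids, , drop = FALSE], na.rm = TRUE)
    mzv <- mz(featureTable)
    members <- split(ids, assignment[ids])
    reps <- vapply(members, function(mIds) {
        if (length(mIds) == 1L) return(mIds)
        chooseRepresentative(mIds, meanInt[mIds],
                             if (is.null(mzv)) NULL else mzv[mIds],
                             repMethod, topN = topN)
    }, character(1L))
    flags <- assignFilterFlags(assignment, reps)
    withinAnn <- annotateWithinGroup(ids, run$pairs$mass)
    vsRepAnn <- annotateVsRepresentative(assignment, reps, mzv, deltas,
                                         massTol = massTol)
    annotated <- assembleOutput(featureTable, assignment, reps, flags,
                                withinAnn, vsRepAnn, repMethod)
    new("AcorfResult", featureTable = featureTable, assignment = assignment,
        representatives = reps, flags = flags, annotated = annotated,
        pairs = run$pairs,
        parameters = list(corThreshold = corThreshold, rtDelta = rtDelta,
                          massTol = massTol, repMethod = repMethod,
                          topN = topN, absolute = absolute,
                          simMethod = simMethod,
                          deltas = if (is.null(deltas)) NULL else
                              as.data.frame(deltas)))
})

#' @describeIn acorFilter convenience method for a `SummarizedExperiment`:
#'   the first assay supplies the intensities and `rowData` (plus rownames
#'   as feature ids) the feature metadata.
#' @param mzColumn,rtColumn names of the m/z and retention-time columns in
#'   `rowData` (case-insensitive).
#' @export
setMethod("acorFilter", "SummarizedExperiment", function(object,
        mzColumn = "mz", rtColumn = "rt", ...) {
    if (is.null(rownames(object)))
        stop("the SummarizedExperiment must have feature ids as rownames",
             call. = FALSE)
    rd <- as.data.frame(SummarizedExperiment::rowData(object))
    df <- cbind(data.frame(feature_id = rownames(object),
                           stringsAsFactors = FALSE), rd)
    ft <- FeatureTable(df, mzColumn = mzColumn, rtColumn = rtColumn)
    acorFilter(SummarizedExperiment::assay(object, 1L), ft, ...)
})

#' Parameter presets for common platforms
#'
#' Returns ready-made parameter sets for [acorFilter()]:
#' \describe{
#'   \item{`lc-hrms`}{UPLC high-resolution MS defaults: Pearson threshold
#'     0.90, RT window 0.1 min, mass tolerance 0.005 Da, representative =
#'     highest intensity.}
#'   \item{`gc-ms`}{GC-MS settings: threshold 0.90, RT window 0.1 min, mass
#'     tolerance 0.2 Da (low-resolution quadrupole), representative =
#'     highest mass among the top 5 most intense members.}
#'   \item{`sacurine-camera-compat`}{CAMERA-comparable LC settings:
#'     threshold 0.75, RT window 0.1 min, mass tolerance 0.002 Da,
#'     representative = highest intensity.}
#' }
#' The RT window is quoted in minutes; set `rtUnits = "s"` to convert it
#' when the table's rt column is in seconds.
#'
#' @param name preset name.
#' @param rtUnits units of the feature table's rt column (`"min"` or `"s"`).
#' @return named list of [acorFilter()] arguments (`corThreshold`,
#'   `rtDelta`, `massTol`, `repMethod`, `topN`).
#' @examples
#' acorfPreset("lc-hrms", rtUnits = "s")
#' @export
acorfPreset <- function(name = c("lc-hrms", "gc-ms", "sacurine-camera-compat"),
                        rtUnits = c("min", "s")) {
    name <- match.arg(name)
    rtUnits <- match.arg(rtUnits)
    p <- switch(name,
        "lc-hrms" = list(corThreshold = 0.90, rtDelta = 0.1,
                         massTol = 0.005, repMethod = "highest_intensity",
                         topN = NULL),
        "gc-ms" = list(corThreshold = 0.90, rtDelta = 0.1, massTol = 0.2,
                       repMethod = "highest_mass_in_top_n", topN = 5L),
        "sacurine-camera-compat" = list(corThreshold = 0.75, rtDelta = 0.1,
                                        massTol = 0.002,
                                        repMethod = "highest_intensity",
                                        topN = NULL))
    if (rtUnits == "s") p$rtDelta <- p$rtDelta * 60
    p
}

#' Apply the keep/delete flags to an intensity matrix
#'
#' Convenience filtration step: returns the data matrix restricted to the
#' kept features (representatives and singletons), one row per group.
#'
#' @param result an [AcorfResult-class].
#' @param m features x samples intensity matrix.
#' @return the filtered matrix.
#' @export
applyFilter <- function(result, m) {
    stopifnot(is(result, "AcorfResult"))
    kept <- names(filterFlags(result))[filterFlags(result) == 1L]
    .checkIdCoverage(rownames(m), kept, "data matrix")
    m[kept, , drop = FALSE]
}

#' Per-gate group counts of a filtration result
#'
#' Audits how each criterion refines the grouping: the number of groups
#' obtained from the pairs surviving each enabled stage. Gates only remove
#' edges, so the counts are non-decreasing along the cascade.
#'
#' @param result an [AcorfResult-class].
#' @return named integer vector with elements among `similarity`, `rt`,
#'   `mass`.
#' @export
stageGroupCounts <- function(result) {
    stopifnot(is(result, "AcorfResult"))
    ids <- featureIds(result)
    counts <- integer(0)
    for (s in c("similarity", "rt", "mass")) {
        p <- result@pairs[[s]]
        if (!is.null(p))
            counts[[s]] <- length(unique(buildGroups(p, ids)))
    }
    counts
}
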