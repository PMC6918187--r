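## Core of the filtration algorithm: pair selection through the similarity
## threshold, the retention-time and mass-difference gates, and group
## formation as connected components of the validated-pair graph.

#' Select feature pairs above the similarity threshold
#'
#' Returns all unordered feature pairs whose similarity is strictly greater
#' than the threshold. Missing similarities are never selected. Similarity
#' is compared signed by default, so strongly anti-correlated pairs do not
#' group; set `absolute = TRUE` to compare `|s|`.
#'
#' @param similarity symmetric numeric matrix with feature ids as dimnames.
#' @param threshold finite similarity cutoff (strict `>`).
#' @param absolute compare the absolute similarity instead of the signed one.
#' @return data.frame with columns `idA`, `idB`, `similarity`; `idA` precedes
#'   `idB` in the matrix row order.
#' @export
selectPairs <- function(similarity, threshold, absolute = FALSE) {
    stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
    if (!is.finite(threshold)) stop("'threshold' must be finite", call. = FALSE)
    s <- if (absolute) abs(similarity) else similarity
    sel <- upper.tri(s) & !is.na(s) & s > threshold
    idx <- which(sel, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(idA = rownames(similarity)[idx[, 1L]],
               idB = colnames(similarity)[idx[, 2L]],
               similarity = similarity[idx],
               stringsAsFactors = FALSE)
}

.lookupNumeric <- function(values, ids, what) {
    if (is.null(values))
        stop(sprintf("no %s column bound in the feature table", what),
             call. = FALSE)
    v <- values[ids]
    bad <- ids[is.na(v)]
    if (length(bad))
        stop(sprintf("missing %s for feature(s): %s", what,
                     paste(unique(bad), collapse = ", ")), call. = FALSE)
    v
}

#' Retention-time gate
#'
#' Keeps the candidate pairs whose members co-elute: `|rt_a - rt_b| <=
#' rtDelta` (inclusive at the boundary). `rtDelta` is in the same units as
#' the table's retention-time column.
#'
#' @param pairs data.frame of candidate pairs (`idA`, `idB`, ...).
#' @param table a [FeatureTable-class] with a bound retention-time column.
#' @param rtDelta non-negative tolerance, same units as the rt column.
#' @return the surviving subset of `pairs`.
#' @export
rtGate <- function(pairs, table, rtDelta) {
    stopifnot(is.numeric(rtDelta), rtDelta >= 0)
    if (nrow(pairs) == 0L) return(pairs)
    rts <- rt(table)
    rtA <- .lookupNumeric(rts, pairs$idA, "retention time")
    rtB <- .lookupNumeric(rts, pairs$idB, "retention time")
    pairs[abs(rtA - rtB) <= rtDelta, , drop = FALSE]
}

#' Mass-difference gate
#'
#' Confirms the chemical link between co-eluting correlated features: a pair
#' is kept iff its absolute m/z difference matches some reference delta
#' within `massTol` (inclusive), i.e. `||mz_a - mz_b| - delta| <= massTol`
#' for at least one [DeltaList-class] entry. The matched label is recorded;
#' when several entries fit, the closest wins, ties going to the earlier
#' list entry.
#'
#' @param pairs data.frame of candidate pairs that already passed the RT
#'   gate.
#' @param table a [FeatureTable-class] with a bound m/z column.
#' @param deltas a [DeltaList-class].
#' @param massTol non-negative tolerance in Da.
#' @return the surviving subset of `pairs` with an added `label` column.
#' @export
massGate <- function(pairs, table, deltas, massTol) {
    stopifnot(is(deltas, "DeltaList"), is.numeric(massTol), massTol >= 0)
    if (length(deltas) == 0L)
        stop("the mass gate requires a non-empty delta list", call. = FALSE)
    if (nrow(pairs) == 0L) {
        pairs$label <- character(0)
        return(pairs)
    }
    mzs <- mz(table)
    mzA <- .lookupNumeric(mzs, pairs$idA, "m/z")
    mzB <- .lookupNumeric(mzs, pairs$idB, "m/z")
    dobs <- abs(mzA - mzB)
    dev <- abs(outer(dobs, deltaValues(deltas), "-"))
    best <- apply(dev, 1L, which.min)            # first min = first in list on ties
    bestDev <- dev[cbind(seq_along(best), best)]
    keep <- bestDev <= massTol
    out <- pairs[keep, , drop = FALSE]
    out$label <- deltaLabels(deltas)[best[keep]]
    out
}

#' Form analytical-correlation groups from validated pairs
#'
#' Groups are the connected components of the graph whose vertices are all
#' features and whose edges are the validated pairs: if A--B and B--C were
#' both validated, A, B and C are considered to come from the same analyte
#' even if A--C itself failed a gate. Features with no validated edge form
#' singleton groups. Group ids are consecutive integers assigned in order of
#' first member appearance in `allIds`.
#'
#' @param pairs data.frame of validated pairs (`idA`, `idB`, ...).
#' @param allIds character vector of every feature id, in table order.
#' @return named integer vector: group id per feature.
#' @examples
#' buildGroups(data.frame(idA = c("A", "B"), idB = c("B", "C")),
#'             c("A", "B", "C", "D"))
#' @export
buildGroups <- function(pairs, allIds) {
    stopifnot(!anyDuplicated(allIds))
    bad <- setdiff(unique(c(pairs$idA, pairs$idB)), allIds)
    if (length(bad))
        stop(sprintf("pair feature(s) absent from the feature universe: %s",
                     paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
    g <- igraph::graph_from_data_frame(
        pairs[, c("idA", "idB"), drop = FALSE], directed = FALSE,
        vertices = data.frame(name = allIds, stringsAsFactors = FALSE))
    memb <- igraph::components(g)$membership[allIds]
    ids <- match(memb, unique(memb))             # renumber by first appearance
    names(ids) <- allIds
    ids
}

.checkIdCoverage <- function(have, need, what) {
    missing <- setdiff(need, have)
    if (length(missing))
        stop(sprintf("%s is missing %d feature id(s): %s%s", what,
                     length(missing),
                     paste(utils::head(missing, 10L), collapse = ", "),
                     if (length(missing) > 10L) ", ..." else ""),
             call. = FALSE)
    invisible(TRUE)
}

#' Run the pair-validation and grouping stages
#'
#' Executes the gate cascade -- similarity threshold, then (optionally) the
#' retention-time window, then (optionally) the mass-difference match -- and
#' forms the analytical-correlation groups from the surviving pairs. The
#' mass gate presupposes co-elution and therefore cannot be enabled without
#' the RT gate. Intermediate pair lists are returned for the SIF writer and
#' for diagnostics (e.g. auditing how each criterion refines the grouping).
#'
#' @param table a [FeatureTable-class]; defines the feature universe and
#'   order.
#' @param similarity symmetric similarity matrix covering all table features.
#' @param corThreshold similarity cutoff (strict `>`).
#' @param rtDelta RT tolerance; `NULL` disables the RT gate.
#' @param deltas a [DeltaList-class]; `NULL` disables the mass gate.
#' @param massTol mass tolerance in Da; required when `deltas` is given.
#' @param intensities optional intensity matrix, only checked for id
#'   coverage here.
#' @param absolute compare absolute similarities (see [selectPairs()]).
#' @return a list with `assignment` (named integer group ids) and `pairs`
#'   (list of per-stage pair data.frames: `similarity`, `rt`, `mass`).
#' @export
runFiltration <- function(table, similarity, corThreshold, rtDelta = NULL,
                          deltas = NULL, massTol = NULL, intensities = NULL,
                          absolute = FALSE) {
    stopifnot(is(table, "FeatureTable"))
    if (!is.null(deltas) && is.null(rtDelta))
        stop("the mass gate requires the RT gate: supply 'rtDelta' together with 'deltas'",
             call. = FALSE)
    if (!is.null(deltas) && is.null(massTol))
        stop("'massTol' is required when a delta list is supplied", call. = FALSE)
    ids <- featureIds(table)
    .checkIdCoverage(rownames(similarity), ids, "similarity matrix")
    if (!is.null(intensities))
        .checkIdCoverage(rownames(intensities), ids, "data matrix")
    similarity <- similarity[ids, ids, drop = FALSE]
    if (!is.null(deltas)) {
        mzv <- mz(table)
        if (is.null(mzv))
            stop("the mass gate requires a bound m/z column", call. = FALSE)
        if (any(!is.na(mzv) & mzv <= 0))
            stop(sprintf("non-positive m/z for feature(s): %s",
                         paste(names(mzv)[!is.na(mzv) & mzv <= 0], collapse = ", ")),
                 call. = FALSE)
    }
    pSim <- selectPairs(similarity, corThreshold, absolute = absolute)
    message(sprintf("pairs above similarity threshold %g: %d", corThreshold,
                    nrow(pSim)))
    pRt <- NULL
    pMass <- NULL
    final <- pSim
    if (!is.null(rtDelta)) {
        pRt <- rtGate(pSim, table, rtDelta)
        message(sprintf("pairs within RT window %g: %d", rtDelta, nrow(pRt)))
        final <- pRt
    }
    if (!is.null(deltas)) {
        pMass <- massGate(pRt, table, deltas, massTol)
        message(sprintf("pairs with a matched mass difference (tol %g Da): %d",
                        massTol, nrow(pMass)))
        final <- pMass
    }
    assignment <- buildGroups(final, ids)
    message(sprintf("analytical correlation groups: %d",
                    length(unique(assignment))))
    list(assignment = assignment,
         pairs = list(similarity = pSim, rt = pRt, mass = pMass))
}
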