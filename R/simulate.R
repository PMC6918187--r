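#' Simulate an LC-/GC-MS-like peak table with known analyte groups
#'
#' Generates a features x samples intensity matrix, the matching variable
#' metadata and a ground-truth ledger, emulating the analytical redundancy
#' the filtration algorithm targets: each analyte spawns a parent feature
#' and 0 to `maxDerived` derived features (isotopologues, adducts,
#' in-source fragments) whose m/z is offset from the parent by a reference
#' delta, whose retention time matches the parent within `rtJitter`, and
#' whose intensity profile is proportional to the parent's up to
#' multiplicative noise. Uncorrelated background features are added on top.
#'
#' Parent base intensities are log-uniform over three decades (1e3 to 1e6),
#' derived-feature response ratios uniform in \[0.05, 0.8\] and intensity
#' noise multiplicative Gaussian with relative standard deviation
#' `cvNoise`, mimicking typical electrospray response. Delta entries whose
#' label ends in `"_loss"` shift the derived feature below the parent mass
#' (fragment); the others shift it above (isotope/adduct). Retention times
#' are in seconds.
#'
#' @param nAnalytes number of analytes.
#' @param maxDerived per-analyte cap on derived features (count drawn
#'   uniformly from 0..`maxDerived`).
#' @param nSamples number of samples (columns).
#' @param nNoiseFeatures number of uncorrelated background features.
#' @param deltas a [DeltaList-class] used for the m/z offsets.
#' @param cvNoise relative intensity noise of derived features (>= 0).
#' @param rtJitter within-analyte RT spread in seconds; derived features
#'   elute within `rtJitter` of their parent (uniform).
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   exactly.
#' @param nDerived optional fixed number of derived features per analyte,
#'   overriding the random 0..`maxDerived` draw.
#' @param mzRange,rtRange ranges for parent m/z (Da) and RT (s).
#' @return a list with `intensities` (matrix), `features`
#'   ([FeatureTable-class]) and `truth` (data.frame with columns
#'   `feature_id`, `analyte`, `role`, `delta_label`, `parent_id`; the
#'   `analyte` of background features is `"noise"`). The seed is stored in
#'   `attr(truth, "seed")`.
#' @examples
#' sim <- simulateDataset(nAnalytes = 5, maxDerived = 2, nSamples = 10,
#'                        nNoiseFeatures = 3, seed = 7)
#' nrow(sim$truth)
#' @export
simulateDataset <- function(nAnalytes = 50, maxDerived = 4, nSamples = 50,
                            nNoiseFeatures = 100, deltas = defaultDeltaList(),
                            cvNoise = 0.05, rtJitter = 3, seed = 1,
                            nDerived = NULL, mzRange = c(100, 800),
                            rtRange = c(60, 900)) {
    stopifnot(nAnalytes >= 0, maxDerived >= 0, nSamples >= 0,
              nNoiseFeatures >= 0, cvNoise >= 0, rtJitter >= 0)
    set.seed(seed)
    rows <- list()
    truth <- list()
    addFeature <- function(id, mzv, rtv, profile, analyte, role,
                           deltaLabel, parentId) {
        rows[[length(rows) + 1L]] <<- stats::setNames(
            list(id, mzv, rtv, profile), c("id", "mz", "rt", "profile"))
        truth[[length(truth) + 1L]] <<- data.frame(
            feature_id = id, analyte = analyte, role = role,
            delta_label = deltaLabel, parent_id = parentId,
            stringsAsFactors = FALSE)
    }
    for (a in seq_len(nAnalytes)) {
        aid <- sprintf("A%03d", a)
        pmz <- stats::runif(1L, mzRange[1L], mzRange[2L])
        prt <- stats::runif(1L, rtRange[1L], rtRange[2L])
        base <- 10^stats::runif(nSamples, 3, 6)
        pid <- sprintf("%s.P", aid)
        addFeature(pid, pmz, prt, base, aid, "parent", "-", "-")
        nd <- if (is.null(nDerived)) sample.int(maxDerived + 1L, 1L) - 1L
              else nDerived
        for (d in seq_len(nd)) {
            j <- sample.int(length(deltas), 1L)
            lab <- deltaLabels(deltas)[j]
            isLoss <- grepl("_loss$", lab)
            sign <- if (isLoss) -1 else 1
            dmz <- pmz + sign * deltaValues(deltas)[j]
            if (dmz <= 50) { sign <- 1; dmz <- pmz + deltaValues(deltas)[j] }
            role <- if (startsWith(lab, "isotope")) "isotope"
                    else if (sign < 0) "fragment" else "adduct"
            ratio <- stats::runif(1L, 0.05, 0.8)
            noise <- 1 + stats::rnorm(nSamples, 0, cvNoise)
            profile <- pmax(ratio * base * noise, 0)
            drt <- prt + stats::runif(1L, -rtJitter, rtJitter)
            addFeature(sprintf("%s.D%d", aid, d), dmz, drt, profile,
                       aid, role, lab, pid)
        }
    }
    for (k in seq_len(nNoiseFeatures)) {
        addFeature(sprintf("N%04d", k),
                   stats::runif(1L, mzRange[1L], mzRange[2L]),
                   stats::runif(1L, rtRange[1L], rtRange[2L]),
                   10^stats::runif(nSamples, 3, 6),
                   "noise", "noise", "-", "-")
    }
    ids <- vapply(rows, `[[`, character(1L), "id")
    m <- do.call(rbind, lapply(rows, `[[`, "profile"))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(rows))
    rownames(m) <- ids
    colnames(m) <- sprintf("S%03d", seq_len(nSamples))
    meta <- data.frame(
        feature_id = ids,
        mz = sprintf("%.5f", vapply(rows, `[[`, numeric(1L), "mz")),
        rt = sprintf("%.3f", vapply(rows, `[[`, numeric(1L), "rt")),
        stringsAsFactors = FALSE)
    truth <- do.call(rbind, truth)
    attr(truth, "seed") <- seed
    list(intensities = m,
         features = FeatureTable(meta, mzColumn = "mz", rtColumn = "rt"),
         truth = truth)
}

#' Score a predicted grouping against the simulated ground truth
#'
#' Compares a predicted partition with the true analyte partition (each
#' analyte's features form one true group; every background feature is its
#' own singleton). Reports the fraction of true analyte groups recovered
#' exactly (same member set as some predicted group) and the adjusted Rand
#' index of the two partitions.
#'
#' @param assignment named integer (or character) group id per feature, e.g.
#'   `groups(result)`.
#' @param truth ground-truth data.frame from [simulateDataset()].
#' @return list with `exactFraction` and `ari`.
#' @export
scoreRecovery <- function(assignment, truth) {
    if (!setequal(names(assignment), truth$feature_id))
        stop("predicted grouping and ground truth cover different features",
             call. = FALSE)
    ids <- truth$feature_id
    pred <- assignment[ids]
    trueLabels <- ifelse(truth$analyte == "noise",
                         paste0("noise.", ids), truth$analyte)
    ari <- mclust::adjustedRandIndex(as.character(pred), trueLabels)
    analytes <- unique(truth$analyte[truth$analyte != "noise"])
    predSizes <- table(pred)
    recovered <- vapply(analytes, function(a) {
        members <- ids[truth$analyte == a]
        g <- unique(pred[members])
        length(g) == 1L && predSizes[[as.character(g)]] == length(members)
    }, logical(1L))
    list(exactFraction = if (length(recovered)) mean(recovered) else NA_real_,
         ari = ari)
}

#' Write the simulated dataset as W4M-style input files
#'
#' Writes the data matrix, variable metadata, a Pearson similarity matrix
#' and the ground-truth ledger as tab-separated files sharing a path
#' prefix.
#'
#' @param sim the list returned by [simulateDataset()].
#' @param prefix output path prefix; files get suffixes
#'   `_dataMatrix.tsv`, `_variableMetadata.tsv`, `_similarityMatrix.tsv`,
#'   `_groundTruth.tsv`.
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulatedDataset <- function(sim, prefix) {
    paths <- c(dataMatrix = paste0(prefix, "_dataMatrix.tsv"),
               variableMetadata = paste0(prefix, "_variableMetadata.tsv"),
               similarityMatrix = paste0(prefix, "_similarityMatrix.tsv"),
               groundTruth = paste0(prefix, "_groundTruth.tsv"))
    writeDataMatrix(sim$intensities, paths[["dataMatrix"]])
    utils::write.table(as.data.frame(sim$features),
                       paths[["variableMetadata"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeSimilarityMatrix(computeSimilarity(sim$intensities, "pearson"),
                          paths[["similarityMatrix"]])
    utils::write.table(sim$truth, paths[["groundTruth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
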