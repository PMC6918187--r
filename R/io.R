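## Tabular I/O for the W4M-style three-file convention (data matrix,
## variable metadata, similarity matrix), the delta list, and the outputs
## (annotated variable metadata, Cytoscape SIF network).

.sniffDelimiter <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    if (file.size(path) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
    first <- readLines(path, n = 1L, warn = FALSE)
    nTab <- nchar(gsub("[^\t]", "", first))
    nCom <- nchar(gsub("[^,]", "", first))
    delim <- if (nTab >= nCom) "\t" else ","
    message(sprintf("detected %s delimiter in %s",
                    if (delim == "\t") "tab" else "comma", basename(path)))
    delim
}

## All cells read as character; callers parse numerics where needed so that
## passthrough columns round-trip byte-identically.
.readTabular <- function(path) {
    delim <- .sniffDelimiter(path)
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)
    df
}

.asNumericMatrix <- function(df) {
    ids <- df[[1L]]
    vals <- vapply(df[-1L], function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(df)))
    m <- matrix(vals, nrow = nrow(df),
                dimnames = list(ids, names(df)[-1L]))
    m
}

#' Read a W4M-style data matrix (feature intensities per sample)
#'
#' Reads a tab- or comma-delimited table with one header row and the feature
#' (or sample) ids in the first column. The delimiter is auto-detected.
#' Non-numeric cells become `NA`.
#'
#' @param path path to the file.
#' @param featuresInRows logical; if `FALSE` the file stores samples in rows
#'   and the matrix is transposed so that features are rows on return.
#' @return a numeric matrix, features in rows, samples in columns.
#' @examples
#' f <- system.file("extdata", "toy", "dataMatrix.tsv", package = "acorf")
#' m <- readDataMatrix(f)
#' dim(m)
#' @export
readDataMatrix <- function(path, featuresInRows = TRUE) {
    df <- .readTabular(path)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate feature ids in %s: %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             call. = FALSE)
    m <- .asNumericMatrix(df)
    if (!featuresInRows) m <- t(m)
    message(sprintf("data matrix: %d features x %d samples", nrow(m), ncol(m)))
    m
}

#' Read a W4M-style variable metadata table
#'
#' Reads the per-feature metadata table (feature id in the first column,
#' m/z, retention time and arbitrary extra columns) and binds the m/z and
#' retention-time columns by name, case-insensitively. Columns requested
#' explicitly must exist; the defaults (`"mz"`, `"rt"`) are bound only when
#' present.
#'
#' @param path path to the file.
#' @param mzColumn,rtColumn names of the m/z and retention-time columns.
#' @return a [FeatureTable-class].
#' @examples
#' f <- system.file("extdata", "toy", "variableMetadata.tsv", package = "acorf")
#' readVariableMetadata(f)
#' @export
readVariableMetadata <- function(path, mzColumn = "mz", rtColumn = "rt") {
    df <- .readTabular(path)
    if (missing(mzColumn) && missing(rtColumn))
        ft <- FeatureTable(df)
    else if (missing(rtColumn))
        ft <- FeatureTable(df, mzColumn = mzColumn)
    else if (missing(mzColumn))
        ft <- FeatureTable(df, rtColumn = rtColumn)
    else
        ft <- FeatureTable(df, mzColumn = mzColumn, rtColumn = rtColumn)
    message(sprintf("variable metadata: %d features, %d columns",
                    nrow(df), ncol(df)))
    ft
}

#' Read a pairwise similarity matrix
#'
#' Reads a square similarity table (CSV or TSV, auto-detected) whose first
#' row and first column carry the feature ids. The matrix must be symmetric
#' within `1e-6`; columns are reordered to match the row order.
#'
#' @param path path to the file.
#' @return a symmetric numeric matrix with feature ids as dimnames.
#' @examples
#' f <- system.file("extdata", "toy", "similarityMatrix.tsv", package = "acorf")
#' s <- readSimilarityMatrix(f)
#' s["F1", "F2"]
#' @export
readSimilarityMatrix <- function(path) {
    df <- .readTabular(path)
    ids <- df[[1L]]
    if (ncol(df) - 1L != nrow(df))
        stop(sprintf("non-square similarity matrix in %s: %d rows, %d columns",
                     path, nrow(df), ncol(df) - 1L), call. = FALSE)
    m <- .asNumericMatrix(df)
    if (!setequal(colnames(m), ids))
        stop(sprintf("similarity matrix row and column ids differ in %s", path),
             call. = FALSE)
    m <- m[, ids, drop = FALSE]
    naMismatch <- xor(is.na(m), is.na(t(m)))
    d <- abs(m - t(m))
    if (any(naMismatch) || any(d > 1e-6, na.rm = TRUE)) {
        d[is.na(d)] <- 0
        d[naMismatch] <- Inf
        w <- arrayInd(which.max(d), dim(d))
        stop(sprintf(
            "similarity matrix is asymmetric: worst cell (%s, %s), |s(i,j) - s(j,i)| = %g",
            ids[w[1L]], ids[w[2L]], d[w[1L], w[2L]]), call. = FALSE)
    }
    message(sprintf("similarity matrix: %d x %d", nrow(m), ncol(m)))
    m
}

#' Read a list of isotope/adduct/fragment mass differences
#'
#' Reads a two-column tabular file (label, delta in Da) with no header, or
#' returns the packaged default list when `path` is the token `"default"`.
#'
#' @param path path to a two-column file, or `"default"` for the shipped
#'   reference list (see [defaultDeltaList()]).
#' @return a [DeltaList-class].
#' @export
readDeltaList <- function(path) {
    if (identical(path, "default")) return(defaultDeltaList())
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop(sprintf("empty delta list: %s", path), call. = FALSE)
    delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
    labels <- character(length(lines))
    deltas <- numeric(length(lines))
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], delim, fixed = TRUE)[[1L]]
        if (length(fields) < 2L)
            stop(sprintf("line %d of %s: expected two fields (label, delta)",
                         i, path), call. = FALSE)
        d <- suppressWarnings(as.numeric(fields[[2L]]))
        if (is.na(d) || d <= 0)
            stop(sprintf("line %d of %s: delta must be a positive number, got '%s'",
                         i, path, fields[[2L]]), call. = FALSE)
        labels[i] <- trimws(fields[[1L]])
        deltas[i] <- d
    }
    DeltaList(labels, deltas)
}

#' The packaged default mass-difference list
#'
#' Twelve standard monoisotopic mass differences commonly observed between
#' features of the same analyte in electrospray MS: 13C isotopologue
#' spacings, alkali-for-proton exchanges, ammonia, water / carbon dioxide /
#' acid neutral losses and sulfate / phosphate moieties. The list is this
#' package's own versioned reference, shipped at
#' `inst/extdata/default_delta_list.tsv`; users with instrument-specific
#' chemistry should supply their own list via [readDeltaList()].
#'
#' @return a [DeltaList-class] with 12 entries.
#' @examples
#' defaultDeltaList()
#' @export
defaultDeltaList <- function() {
    path <- system.file("extdata", "default_delta_list.tsv", package = "acorf",
                        mustWork = TRUE)
    readDeltaList(path)
}

#' Write a Cytoscape SIF network of the similarity-selected pairs
#'
#' One line per unordered feature pair: `idA<TAB>similarity<TAB>idB`, with
#' the similarity rendered to 4 decimal places as the interaction label.
#' The pairs written are those passing the similarity threshold (before the
#' RT and mass gates), so the network shows all correlations above the
#' cutoff.
#'
#' @param pairs data.frame with columns `idA`, `idB`, `similarity` (as
#'   returned by [selectPairs()] or [candidatePairs()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSif <- function(pairs, path) {
    if (is.null(pairs) || nrow(pairs) == 0L) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    key <- paste(pmin(pairs$idA, pairs$idB), pmax(pairs$idA, pairs$idB))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    writeLines(sprintf("%s\t%.4f\t%s", pairs$idA, pairs$similarity, pairs$idB),
               path)
    invisible(path)
}

.RESULT_COLUMNS <- c("ACorF_groups", "isotopes_adducts_fragments",
                     "ACorF_filter", "annotation_relative_to_representative")

#' Write the annotated variable metadata table
#'
#' Writes the input variable metadata with the five appended result columns
#' (`ACorF_groups`, `isotopes_adducts_fragments`, `ACorF_filter`,
#' `representative_<method>`, `annotation_relative_to_representative`) as a
#' tab-separated file. Original columns are written first and unchanged.
#'
#' @param annotated data.frame as returned by [annotatedTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotatedMetadata <- function(annotated, path) {
    hasRep <- any(startsWith(names(annotated), "representative_"))
    missingCols <- setdiff(.RESULT_COLUMNS, names(annotated))
    if (length(missingCols) || !hasRep)
        stop(sprintf("annotated table is missing result columns: %s",
                     paste(c(missingCols, if (!hasRep) "representative_<method>"),
                           collapse = ", ")), call. = FALSE)
    utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

#' Write a features x samples matrix in the W4M data-matrix layout
#'
#' @param m numeric matrix with feature ids as rownames.
#' @param path output file path.
#' @param idHeader header of the feature-id column.
#' @return `path`, invisibly.
#' @export
writeDataMatrix <- function(m, path, idHeader = "dataMatrix") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- idHeader
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Write a similarity matrix in the square tabular layout
#'
#' @param s symmetric numeric matrix with feature ids as dimnames.
#' @param path output file path.
#' @param idHeader header of the feature-id column.
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(s, path, idHeader = "similarity") {
    df <- data.frame(id = rownames(s), s, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- idHeader
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
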