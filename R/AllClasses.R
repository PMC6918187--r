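#' @include AllGenerics.R
NULL

#' DeltaList: reference isotope/adduct/fragment mass differences
#'
#' A labelled list of positive mass differences (Da) used by the mass gate to
#' decide whether the m/z difference between two correlated, co-eluting
#' features is chemically explainable (e.g. one 13C isotopologue spacing,
#' a sodium-for-proton exchange, a water loss).
#'
#' @slot label character, unique non-empty labels (e.g. `"isotope_13C"`,
#'   `"Na-H"`, `"H2O_loss"`).
#' @slot delta numeric, strictly positive mass differences in Da, parallel to
#'   `label`.
#'
#' @seealso [defaultDeltaList()], [readDeltaList()], [massGate()]
#' @examples
#' DeltaList(c("isotope_13C", "Na-H"), c(1.003355, 21.981944))
#' @name DeltaList-class
#' @aliases DeltaList
#' @export DeltaList
#' @exportClass DeltaList
setClass("DeltaList", representation(label = "character", delta = "numeric"))

setValidity("DeltaList", function(object) {
    msg <- character(0)
    if (length(object@label) != length(object@delta))
        msg <- c(msg, "'label' and 'delta' must have equal length")
    if (anyDuplicated(object@label))
        msg <- c(msg, sprintf("duplicated labels: %s",
                 paste(unique(object@label[duplicated(object@label)]), collapse = ", ")))
    if (any(!nzchar(object@label)))
        msg <- c(msg, "labels must be non-empty")
    if (any(!is.finite(object@delta)) || any(object@delta <= 0))
        msg <- c(msg, "all deltas must be finite and strictly positive")
    if (length(msg)) msg else TRUE
})

#' @param label character vector of unique labels.
#' @param delta numeric vector of positive mass differences (Da).
#' @rdname DeltaList-class
DeltaList <- function(label, delta) {
    new("DeltaList", label = as.character(label), delta = as.numeric(delta))
}

#' @rdname DeltaList-class
#' @param x a `DeltaList`
#' @export
setMethod("length", "DeltaList", function(x) length(x@label))

#' @rdname DeltaList-class
#' @export
setMethod("deltaLabels", "DeltaList", function(x) x@label)

#' @rdname DeltaList-class
#' @export
setMethod("deltaValues", "DeltaList", function(x) x@delta)

#' @rdname DeltaList-class
#' @param row.names,optional,... passed for S3 compatibility, ignored.
#' @export
as.data.frame.DeltaList <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(label = x@label, delta = x@delta, stringsAsFactors = FALSE)
}

setMethod("show", "DeltaList", function(object) {
    cat(sprintf("DeltaList with %d mass differences (Da)\n", length(object)))
    n <- min(length(object), 8L)
    for (i in seq_len(n))
        cat(sprintf("  %-14s %10.6f\n", object@label[i], object@delta[i]))
    if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
})


#' FeatureTable: per-feature metadata (variable metadata)
#'
#' Wraps the W4M-style "variable metadata" table: one row per detected
#' feature (ion), keyed by a unique feature id in the first column, with
#' optional m/z and retention-time bindings and arbitrary extra columns that
#' are passed through verbatim to the annotated output. All cells are stored
#' as character so that a read -> write round trip reproduces the input
#' exactly; `mz()` and `rt()` parse the bound columns on access.
#'
#' @slot data data.frame of character columns; the first column is the
#'   feature id.
#' @slot mzColumn name of the bound m/z column, or `NA` if unbound.
#' @slot rtColumn name of the bound retention-time column, or `NA` if unbound.
#'
#' @seealso [readVariableMetadata()]
#' @name FeatureTable-class
#' @aliases FeatureTable
#' @export FeatureTable
#' @exportClass FeatureTable
setClass("FeatureTable", representation(data = "data.frame",
                                        mzColumn = "character",
                                        rtColumn = "character"))

setValidity("FeatureTable", function(object) {
    msg <- character(0)
    df <- object@data
    if (ncol(df) < 1L) return("feature table needs at least an id column")
    ids <- df[[1L]]
    if (any(is.na(ids)) || any(!nzchar(ids)))
        msg <- c(msg, "feature ids must be non-empty")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate feature ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    for (col in c(object@mzColumn, object@rtColumn))
        if (!is.na(col) && !col %in% names(df))
            msg <- c(msg, sprintf("bound column '%s' not present", col))
    if (length(msg)) msg else TRUE
})

.resolveColumn <- function(columns, requested, required, what) {
    if (is.null(requested) || length(requested) == 0L || is.na(requested))
        return(NA_character_)
    hit <- which(tolower(columns) == tolower(requested))
    if (length(hit) == 0L) {
        if (required)
            stop(sprintf("no column matching '%s' for %s; available columns: %s",
                         requested, what, paste(columns, collapse = ", ")),
                 call. = FALSE)
        return(NA_character_)
    }
    columns[hit[1L]]
}

#' @param data a data.frame; first column is the feature id. Non-character
#'   columns are converted with `as.character()`.
#' @param mzColumn,rtColumn column names to bind as m/z and retention time.
#'   Matching is case-insensitive. When left at their defaults (`"mz"`,
#'   `"rt"`) an absent column is silently left unbound; an explicitly
#'   requested column that is absent is an error. Use `NA` to leave a
#'   binding off.
#' @rdname FeatureTable-class
FeatureTable <- function(data, mzColumn = "mz", rtColumn = "rt") {
    mzRequired <- !missing(mzColumn)
    rtRequired <- !missing(rtColumn)
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    data[] <- lapply(data, as.character)
    mzc <- .resolveColumn(names(data), mzColumn, mzRequired, "m/z")
    rtc <- .resolveColumn(names(data), rtColumn, rtRequired, "retention time")
    new("FeatureTable", data = data, mzColumn = mzc, rtColumn = rtc)
}

#' @rdname FeatureTable-class
#' @param x a `FeatureTable`
#' @export
setMethod("featureIds", "FeatureTable", function(x) x@data[[1L]])

#' @rdname FeatureTable-class
#' @export
setMethod("mz", "FeatureTable", function(x) {
    if (is.na(x@mzColumn)) return(NULL)
    v <- suppressWarnings(as.numeric(x@data[[x@mzColumn]]))
    names(v) <- featureIds(x)
    v
})

#' @rdname FeatureTable-class
#' @export
setMethod("rt", "FeatureTable", function(x) {
    if (is.na(x@rtColumn)) return(NULL)
    v <- suppressWarnings(as.numeric(x@data[[x@rtColumn]]))
    names(v) <- featureIds(x)
    v
})

#' @rdname FeatureTable-class
#' @export
setMethod("nrow", "FeatureTable", function(x) nrow(x@data))

#' @rdname FeatureTable-class
#' @export
as.data.frame.FeatureTable <- function(x, row.names = NULL, optional = FALSE, ...) {
    x@data
}

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable with %d features, %d columns\n",
                nrow(object@data), ncol(object@data)))
    cat(sprintf("  id column: '%s'; mz: %s; rt: %s\n", names(object@data)[1L],
                if (is.na(object@mzColumn)) "<unbound>" else sQuote(object@mzColumn),
                if (is.na(object@rtColumn)) "<unbound>" else sQuote(object@rtColumn)))
})


#' AcorfResult: an analytical-correlation filtration result
#'
#' Holds the full outcome of a filtration run: the partition of features into
#' analytical-correlation groups, the candidate pair lists surviving each
#' gate (similarity threshold, retention-time window, mass-difference match),
#' the representative feature of each group, the keep/delete flags and the
#' annotated feature table ready for [writeAnnotatedMetadata()].
#'
#' @slot featureTable the input [FeatureTable-class].
#' @slot assignment integer group id per feature, named by feature id; group
#'   ids are consecutive from 1 in order of first member appearance.
#' @slot representatives representative feature id per group, named by group
#'   id (for singleton groups the sole member).
#' @slot flags integer 1 (keep) / 0 (delete) per feature, named by feature id.
#' @slot annotated data.frame: the input table plus the five result columns.
#' @slot pairs list of candidate-pair data.frames per stage:
#'   `similarity`, `rt`, `mass` (`NULL` when a gate was disabled).
#' @slot parameters list echoing the run parameters.
#'
#' @seealso [acorFilter()], [runFiltration()]
#' @name AcorfResult-class
#' @exportClass AcorfResult
setClass("AcorfResult", representation(featureTable = "FeatureTable",
                                       assignment = "integer",
                                       representatives = "character",
                                       flags = "integer",
                                       annotated = "data.frame",
                                       pairs = "list",
                                       parameters = "list"))

setValidity("AcorfResult", function(object) {
    msg <- character(0)
    ids <- featureIds(object@featureTable)
    if (!identical(sort(names(object@assignment)), sort(ids)))
        msg <- c(msg, "assignment must cover exactly the features of the table")
    k <- length(unique(object@assignment))
    if (!identical(sort(unique(unname(object@assignment))), seq_len(k)))
        msg <- c(msg, "group ids must be consecutive integers starting at 1")
    if (length(object@representatives) != k)
        msg <- c(msg, "one representative per group required")
    if (sum(object@flags) != k)
        msg <- c(msg, "number of kept features must equal the number of groups")
    for (g in names(object@representatives)) {
        members <- names(object@assignment)[object@assignment == as.integer(g)]
        if (!object@representatives[[g]] %in% members)
            msg <- c(msg, sprintf("representative of group %s is not a member", g))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname AcorfResult-class
#' @param x an `AcorfResult`
#' @export
setMethod("groups", "AcorfResult", function(x) x@assignment)

#' @rdname AcorfResult-class
#' @export
setMethod("nGroups", "AcorfResult", function(x) length(unique(x@assignment)))

#' @rdname AcorfResult-class
#' @export
setMethod("representatives", "AcorfResult", function(x) x@representatives)

#' @rdname AcorfResult-class
#' @export
setMethod("filterFlags", "AcorfResult", function(x) x@flags)

#' @rdname AcorfResult-class
#' @export
setMethod("annotatedTable", "AcorfResult", function(x) x@annotated)

#' @rdname AcorfResult-class
#' @export
setMethod("featureIds", "AcorfResult", function(x) featureIds(x@featureTable))

#' @rdname AcorfResult-class
#' @param stage which candidate-pair list to return: pairs surviving the
#'   similarity threshold (`"similarity"`), the RT gate (`"rt"`), the mass
#'   gate (`"mass"`), or the last enabled stage (`"final"`).
#' @export
setMethod("candidatePairs", "AcorfResult",
    function(x, stage = c("final", "similarity", "rt", "mass")) {
    stage <- match.arg(stage)
    if (stage == "final") {
        for (s in c("mass", "rt", "similarity"))
            if (!is.null(x@pairs[[s]])) return(x@pairs[[s]])
        return(NULL)
    }
    x@pairs[[stage]]
})

#' @rdname AcorfResult-class
#' @export
setMethod("runParameters", "AcorfResult", function(x) x@parameters)

setMethod("show", "AcorfResult", function(object) {
    k <- nGroups(object)
    sizes <- table(object@assignment)
    nSingle <- sum(sizes == 1L)
    cat("AcorfResult\n")
    cat(sprintf("  features: %d   groups: %d (%d single-ion)\n",
                length(object@assignment), k, nSingle))
    cat(sprintf("  flagged redundant (ACorF_filter = 0): %d (%.1f%%)\n",
                sum(object@flags == 0L),
                100 * mean(object@flags == 0L)))
    for (s in c("similarity", "rt", "mass")) {
        p <- object@pairs[[s]]
        if (!is.null(p))
            cat(sprintf("  pairs after %s gate: %d\n", s, nrow(p)))
    }
    cat(sprintf("  representative method: %s\n",
                object@parameters$repMethod %||% "<none>"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
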