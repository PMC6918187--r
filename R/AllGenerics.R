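#' @title Generics for acorf classes
#' @description Accessor generics for [FeatureTable-class], [DeltaList-class]
#'   and [AcorfResult-class] objects.
#' @param x an acorf object
#' @param ... additional arguments passed to methods
#' @name acorf-generics
#' @keywords internal
NULL

#' @rdname acorf-generics
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @rdname acorf-generics
#' @export
setGeneric("mz", function(x, ...) standardGeneric("mz"))

#' @rdname acorf-generics
#' @export
setGeneric("rt", function(x, ...) standardGeneric("rt"))

#' @rdname acorf-generics
#' @export
setGeneric("deltaLabels", function(x, ...) standardGeneric("deltaLabels"))

#' @rdname acorf-generics
#' @export
setGeneric("deltaValues", function(x, ...) standardGeneric("deltaValues"))

#' @rdname acorf-generics
#' @export
setGeneric("groups", function(x, ...) standardGeneric("groups"))

#' @rdname acorf-generics
#' @export
setGeneric("nGroups", function(x, ...) standardGeneric("nGroups"))

#' @rdname acorf-generics
#' @export
setGeneric("representatives", function(x, ...) standardGeneric("representatives"))

#' @rdname acorf-generics
#' @export
setGeneric("filterFlags", function(x, ...) standardGeneric("filterFlags"))

#' @rdname acorf-generics
#' @export
setGeneric("annotatedTable", function(x, ...) standardGeneric("annotatedTable"))

#' @rdname acorf-generics
#' @export
setGeneric("candidatePairs", function(x, ...) standardGeneric("candidatePairs"))

#' @rdname acorf-generics
#' @export
setGeneric("runParameters", function(x, ...) standardGeneric("runParameters"))

#' Run the analytic correlation filtration pipeline
#'
#' `acorFilter()` is the main entry point: it chains pair selection by
#' similarity, the optional retention-time and mass-difference gates, group
#' formation by connected components, representative selection, and
#' annotation. See the method documentation in [acorFilter,matrix-method].
#'
#' @param object a features x samples intensity `matrix`, or a
#'   `SummarizedExperiment` whose first assay holds the intensities and whose
#'   `rowData` carries the feature metadata (m/z, retention time).
#' @param ... arguments passed to the workhorse method; see
#'   [acorFilter,matrix-method].
#' @return an [AcorfResult-class] object.
#' @export
setGeneric("acorFilter", function(object, ...) standardGeneric("acorFilter"))
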