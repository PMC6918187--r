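## Representative-ion selection and annotation of the grouped features.

.REP_METHODS <- c("highest_intensity", "highest_mass", "mass2_x_intensity",
                  "highest_mass_in_top_n")

## deterministic argmax: ties broken by higher m/z, then lexicographic id
.argmaxId <- function(ids, metric, mzTie) {
    ord <- order(-metric, -mzTie, ids)
    ids[ord[1L]]
}

#' Choose the representative feature of a group
#'
#' Four selection methods, matching common quantifier-ion practice:
#' `highest_intensity` (argmax mean intensity), `highest_mass` (argmax m/z),
#' `mass2_x_intensity` (argmax m/z squared times mean intensity), and
#' `highest_mass_in_top_n` (the highest m/z among the `topN` members with
#' the highest mean intensity -- the GC-MS recommendation, where heavy but
#' less abundant fragments are the more specific quantifiers). Ties are
#' broken by higher m/z, then lexicographic feature id.
#'
#' @param memberIds character vector of the group's feature ids.
#' @param meanIntensity numeric, mean intensity per member (same order).
#' @param mzValues numeric, m/z per member (same order); may be `NULL` for
#'   `highest_intensity` only.
#' @param method one of the four method names.
#' @param topN positive integer, required for `highest_mass_in_top_n`.
#' @return the representative feature id.
#' @examples
#' chooseRepresentative(c("F1", "F2", "F3"), c(2000, 220, 1000),
#'                      c(180.0634, 181.0667, 202.0453),
#'                      "highest_mass_in_top_n", topN = 2)
#' @export
chooseRepresentative <- function(memberIds, meanIntensity, mzValues,
                                 method = .REP_METHODS, topN = NULL) {
    method <- match.arg(method)
    n <- length(memberIds)
    stopifnot(n >= 1L, length(meanIntensity) == n)
    needMz <- method != "highest_intensity"
    if (needMz && (is.null(mzValues) || any(is.na(mzValues))))
        stop(sprintf("method '%s' requires m/z for every group member", method),
             call. = FALSE)
    mzTie <- if (is.null(mzValues)) rep(-Inf, n) else
        ifelse(is.na(mzValues), -Inf, mzValues)
    switch(method,
        highest_intensity = .argmaxId(memberIds, meanIntensity, mzTie),
        highest_mass = .argmaxId(memberIds, mzValues, mzValues),
        mass2_x_intensity = .argmaxId(memberIds, mzValues^2 * meanIntensity, mzTie),
        highest_mass_in_top_n = {
            if (is.null(topN))
                stop("'topN' is required for method 'highest_mass_in_top_n'",
                     call. = FALSE)
            stopifnot(topN >= 1L)
            top <- order(-meanIntensity, -mzTie, memberIds)[seq_len(min(topN, n))]
            .argmaxId(memberIds[top], mzValues[top], mzValues[top])
        })
}

#' Keep/delete flags from a grouping and its representatives
#'
#' Flag 1 (keep) for every representative and every singleton, 0 (delete)
#' otherwise, so that the number of kept features equals the number of
#' groups.
#'
#' @param assignment named integer group id per feature (see
#'   [buildGroups()]).
#' @param reps representative feature id per group, named by group id.
#' @return named integer vector of 1/0 flags.
#' @export
assignFilterFlags <- function(assignment, reps) {
    flags <- as.integer(names(assignment) == reps[as.character(assignment)])
    names(flags) <- names(assignment)
    flags
}

#' In-group isotope/adduct/fragment annotation
#'
#' For each feature, lists the mass-gate labels of its validated in-group
#' edges as semicolon-joined `"<label>@<partner_id>"` entries, partners in
#' ascending id order. Features without labelled edges (singletons, or any
#' feature when the mass gate was off) get `"-"`.
#'
#' @param allIds character vector of every feature id.
#' @param massPairs data.frame of mass-gate-validated pairs with a `label`
#'   column, or `NULL` when the mass gate was off.
#' @return named character vector of annotation strings.
#' @export
annotateWithinGroup <- function(allIds, massPairs) {
    out <- stats::setNames(rep("-", length(allIds)), allIds)
    if (is.null(massPairs) || nrow(massPairs) == 0L) return(out)
    long <- data.frame(
        id = c(massPairs$idA, massPairs$idB),
        partner = c(massPairs$idB, massPairs$idA),
        label = c(massPairs$label, massPairs$label),
        stringsAsFactors = FALSE)
    long <- long[order(long$id, long$partner), , drop = FALSE]
    ann <- vapply(split(long, long$id),
                  function(d) paste0(d$label, "@", d$partner, collapse = ";"),
                  character(1L))
    out[names(ann)] <- ann
    out
}

#' Annotation of each member relative to its group representative
#'
#' For every non-representative member of a multi-feature group, matches
#' `|mz_member - mz_rep|` against the delta list within `massTol` and
#' renders the matched label with a `"+"` prefix when the member is heavier
#' than the representative and `"-"` when lighter; `"unmatched"` when no
#' entry fits. Representatives of multi-feature groups get
#' `"M (representative)"`; singletons get `"-"`. When no delta list is in
#' use, non-representative cells are `"-"`.
#'
#' @param assignment named integer group id per feature.
#' @param reps representative id per group, named by group id.
#' @param mzValues named numeric m/z per feature (may be `NULL` when no
#'   delta list is in use).
#' @param deltas a [DeltaList-class] or `NULL`.
#' @param massTol mass tolerance in Da (ignored when `deltas` is `NULL`).
#' @return named character vector of annotation strings.
#' @export
annotateVsRepresentative <- function(assignment, reps, mzValues, deltas,
                                     massTol = NULL) {
    sizes <- table(assignment)
    out <- stats::setNames(rep("-", length(assignment)), names(assignment))
    for (id in names(assignment)) {
        grp <- as.character(assignment[[id]])
        if (sizes[[grp]] == 1L) next
        repId <- reps[[grp]]
        if (id == repId) {
            out[[id]] <- "M (representative)"
        } else if (!is.null(deltas)) {
            d <- mzValues[[id]] - mzValues[[repId]]
            dev <- abs(abs(d) - deltaValues(deltas))
            j <- which.min(dev)
            out[[id]] <- if (dev[[j]] <= massTol)
                paste0(if (d >= 0) "+" else "-", deltaLabels(deltas)[[j]])
            else "unmatched"
        }
    }
    out
}

#' Assemble the annotated variable metadata table
#'
#' Appends the five result columns to the input table, in order:
#' `ACorF_groups` (group id; singletons get their own id so that groups can
#' be counted), `isotopes_adducts_fragments`, `ACorF_filter` (1 keep /
#' 0 delete), `representative_<method>` (the representative's id, `"-"` for
#' singletons) and `annotation_relative_to_representative`.
#'
#' @param table the input [FeatureTable-class].
#' @param assignment named integer group id per feature.
#' @param reps representative id per group, named by group id.
#' @param flags named integer keep flags per feature.
#' @param withinAnn,vsRepAnn named character annotation vectors (see
#'   [annotateWithinGroup()], [annotateVsRepresentative()]).
#' @param repMethod the representative-selection method name (embedded in
#'   the representative column header).
#' @return data.frame: original columns first and unchanged, then the five
#'   result columns.
#' @export
assembleOutput <- function(table, assignment, reps, flags, withinAnn,
                           vsRepAnn, repMethod) {
    df <- as.data.frame(table)
    ids <- featureIds(table)
    sizes <- table(assignment)
    grp <- assignment[ids]
    repCol <- ifelse(sizes[as.character(grp)] == 1L, "-",
                     reps[as.character(grp)])
    df[["ACorF_groups"]] <- as.character(grp)
    df[["isotopes_adducts_fragments"]] <- unname(withinAnn[ids])
    df[["ACorF_filter"]] <- as.character(flags[ids])
    df[[paste0("representative_", repMethod)]] <- unname(repCol)
    df[["annotation_relative_to_representative"]] <- unname(vsRepAnn[ids])
    df
}
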