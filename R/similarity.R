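#' Compute a pairwise feature similarity matrix
#'
#' Convenience computation of the similarity matrix from the intensity
#' matrix, using Pearson or Spearman correlation of the intensity profiles
#' across samples. The grouping algorithm itself accepts any externally
#' computed similarity matrix; this helper covers the common case. The
#' method must be named explicitly -- there is no silent default, because
#' the appropriate measure depends on the data.
#'
#' Missing intensities are handled by pairwise-complete observations. A pair
#' of features sharing fewer than 3 non-missing samples gets a missing
#' similarity (treated as below any threshold downstream). A feature whose
#' non-missing intensities have zero variance gets missing similarities to
#' every other feature, with a warning.
#'
#' @param m numeric matrix, features in rows, samples in columns; at least
#'   3 samples.
#' @param method `"pearson"` or `"spearman"` (no default).
#' @return a symmetric numeric matrix with unit diagonal and values in
#'   \[-1, 1\] (or `NA`).
#' @examples
#' m <- rbind(F1 = c(1000, 2000, 3000), F2 = c(110, 220, 330))
#' computeSimilarity(m, "pearson")["F1", "F2"]
#' @export
computeSimilarity <- function(m, method) {
    if (missing(method))
        stop("'method' is missing: name the similarity measure explicitly ",
             "(\"pearson\" or \"spearman\")", call. = FALSE)
    method <- match.arg(method, c("pearson", "spearman"))
    if (!is.matrix(m) || !is.numeric(m))
        stop("'m' must be a numeric matrix (features x samples)", call. = FALSE)
    if (ncol(m) < 3L)
        stop(sprintf("at least 3 samples required to compute similarities, got %d",
                     ncol(m)), call. = FALSE)
    if (is.null(rownames(m)))
        stop("'m' must have feature ids as rownames", call. = FALSE)
    s <- suppressWarnings(
        stats::cor(t(m), use = "pairwise.complete.obs", method = method))
    ## pairs with < 3 shared non-missing samples are not trustworthy
    obs <- crossprod(!is.na(t(m)))
    s[obs < 3L] <- NA_real_
    ## zero-variance features cannot be correlated
    zeroVar <- apply(m, 1L, function(x) {
        x <- x[!is.na(x)]
        length(x) == 0L || stats::var(x) == 0
    })
    if (any(zeroVar)) {
        warning(sprintf("zero-variance feature(s), similarities set to missing: %s",
                        paste(rownames(m)[zeroVar], collapse = ", ")),
                call. = FALSE)
        s[zeroVar, ] <- NA_real_
        s[, zeroVar] <- NA_real_
    }
    diag(s)[!zeroVar] <- 1
    s
}
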