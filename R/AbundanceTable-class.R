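#' AbundanceTable: a two-group metabolite abundance table
#'
#' Container for a samples x metabolites abundance matrix with a two-level
#' phenotype label per sample. Internally the data are stored as a
#' \linkS4class{SummarizedExperiment} (metabolites as rows, samples as
#' columns) with the group label in \code{colData} and a scale flag
#' recording whether values are raw positive intensities or already on the
#' log scale.
#'
#' Validity requires unique sample and metabolite identifiers, exactly two
#' group levels, and fully finite values. Freshly read input tables must
#' additionally have at least three samples per group (enforced by
#' [readAbundanceTable()]); subsets produced by splitting may be smaller.
#'
#' @slot scaleState either \code{"raw"} or \code{"log"}.
#'
#' @seealso [readAbundanceTable()], [logTransform()], [stratifiedSplit()]
#' @export
setClass("AbundanceTable",
    contains = "SummarizedExperiment",
    slots = c(scaleState = "character"))

.validAbundanceTable <- function(object) {
    msg <- character()
    vals <- SummarizedExperiment::assay(object, "abundance")
    if (is.null(rownames(vals)) || is.null(colnames(vals)))
        msg <- c(msg, "sample and metabolite identifiers are required")
    else {
        if (anyDuplicated(rownames(vals)))
            msg <- c(msg, "duplicated metabolite identifiers")
        if (anyDuplicated(colnames(vals)))
            msg <- c(msg, "duplicated sample identifiers")
    }
    if (!all(is.finite(vals)))
        msg <- c(msg, "values contain non-finite entries")
    g <- object$group
    if (is.null(g))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- factor(g)
        if (nlevels(g) != 2L)
            msg <- c(msg, sprintf("group must have exactly 2 levels, found %d",
                                  nlevels(g)))
    }
    if (length(object@scaleState) != 1L ||
        !object@scaleState %in% c("raw", "log"))
        msg <- c(msg, "scaleState must be 'raw' or 'log'")
    if (length(msg)) msg else TRUE
}

setValidity("AbundanceTable", .validAbundanceTable)

#' Construct an AbundanceTable
#'
#' @param values numeric samples x metabolites matrix with sample identifiers
#'   as row names and metabolite names as column names.
#' @param group two-level label per sample (character or factor, recycled
#'   against the rows of \code{values}).
#' @param scaleState \code{"raw"} for positive intensities, \code{"log"} for
#'   values already on the log scale.
#'
#' @return an [AbundanceTable-class] object.
#' @examples
#' m <- matrix(rexp(60), 12, 5,
#'             dimnames = list(paste0("s", 1:12), paste0("m", 1:5)))
#' at <- AbundanceTable(m, rep(c("case", "ctrl"), each = 6))
#' at
#' @export
AbundanceTable <- function(values, group, scaleState = c("raw", "log")) {
    scaleState <- match.arg(scaleState)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = t(values)),
        colData = S4Vectors::DataFrame(group = factor(group),
                                       row.names = rownames(values)))
    new("AbundanceTable", se, scaleState = scaleState)
}

#' Extract the samples x metabolites value matrix
#'
#' @param x an [AbundanceTable-class].
#' @return numeric matrix, samples as rows.
#' @rdname abundanceValues
#' @export
setMethod("abundanceValues", "AbundanceTable", function(x)
    t(SummarizedExperiment::assay(x, "abundance")))

#' Per-sample group labels
#'
#' @param x an [AbundanceTable-class].
#' @return factor with two levels, one entry per sample.
#' @rdname groupLabels
#' @export
setMethod("groupLabels", "AbundanceTable", function(x) factor(x$group))

#' Scale state of an abundance table
#'
#' @param x an [AbundanceTable-class].
#' @return \code{"raw"} or \code{"log"}.
#' @rdname scaleState
#' @export
setMethod("scaleState", "AbundanceTable", function(x) x@scaleState)

#' Metabolite names of an AbundanceTable
#'
#' @param object an [AbundanceTable-class].
#' @return character vector of metabolite identifiers.
#' @export
metaboliteNames <- function(object) rownames(object)

setMethod("show", "AbundanceTable", function(object) {
    tab <- table(groupLabels(object))
    cat(sprintf("AbundanceTable: %d samples x %d metabolites (%s scale)\n",
                ncol(object), nrow(object), object@scaleState))
    cat(sprintf("groups: %s\n",
                paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
})

# subset samples by index/id, preserving class and scale state
.subsetSamples <- function(x, idx) {
    se <- as(x, "SummarizedExperiment")[, idx]
    new("AbundanceTable", se, scaleState = x@scaleState)
}
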