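#' NetworkFeatureMatrix: backbone-derived classifier features
#'
#' Samples x features matrix translating a backbone into classifier input:
#' one autoscaled column per connected backbone metabolite, plus one
#' interaction column per backbone edge, named \code{"i – j"} (en-dash
#' separator). An interaction column is the elementwise product of the two
#' autoscaled node columns, itself autoscaled afterwards, so every feature
#' arrives at the classifier with zero mean and unit variance on the
#' training set. All scaling statistics are learned in fit mode and frozen;
#' transform mode reuses them so test data never leak into the scaling.
#'
#' @slot features numeric samples x features matrix.
#' @slot labels two-level factor of sample phenotypes.
#' @slot nodeNames metabolites contributing node columns.
#' @slot edgeTable backbone edges behind the interaction columns (columns
#'   \code{i}, \code{j}, \code{name}).
#' @slot nodeCenter,nodeScale training mean and sd per node column.
#' @slot intCenter,intScale training mean and sd per interaction column.
#' @slot caseLevel the positive-class label.
#' @seealso [buildFeatureMatrix()], [applyFeatureMatrix()]
#' @export
setClass("NetworkFeatureMatrix",
    slots = c(features = "matrix", labels = "factor",
              nodeNames = "character", edgeTable = "data.frame",
              nodeCenter = "numeric", nodeScale = "numeric",
              intCenter = "numeric", intScale = "numeric",
              caseLevel = "character"))

setMethod("show", "NetworkFeatureMatrix", function(object) {
    cat(sprintf(
        "NetworkFeatureMatrix: %d samples x %d features (%d node + %d interaction)\n",
        nrow(object@features), ncol(object@features),
        length(object@nodeNames), nrow(object@edgeTable)))
    cat(sprintf("  positive class: '%s'\n", object@caseLevel))
})

.interactionName <- function(i, j) paste0(i, " – ", j)

.assembleFeatures <- function(vals, nodeNames, edgeTable,
                              nodeCenter, nodeScale, intCenter, intScale) {
    Z <- sweep(sweep(vals[, nodeNames, drop = FALSE], 2L, nodeCenter),
               2L, nodeScale, "/")
    if (nrow(edgeTable)) {
        P <- Z[, edgeTable$i, drop = FALSE] * Z[, edgeTable$j, drop = FALSE]
        P <- sweep(sweep(P, 2L, intCenter), 2L, intScale, "/")
        colnames(P) <- edgeTable$name
        cbind(Z, P)
    } else Z
}

#' Build the network feature matrix (fit mode)
#'
#' Learns per-column scaling on \code{table} (normally the training set)
#' and assembles node plus interaction features for the connected backbone
#' metabolites.
#'
#' @param table a log-scale [AbundanceTable-class] containing every
#'   backbone metabolite.
#' @param backbone a non-empty [Backbone-class].
#' @return a [NetworkFeatureMatrix-class] carrying the learned scaling.
#' @export
buildFeatureMatrix <- function(table, backbone) {
    if (scaleState(table) != "log")
        stop("feature construction expects a log-scale table")
    nn <- nodes(backbone)
    if (!length(nn))
        stop("backbone has no connected nodes; relax the disparity alpha ",
             "or the edge p-value cutoff and rebuild")
    missing <- setdiff(nn, metaboliteNames(table))
    if (length(missing))
        stop("backbone metabolite(s) absent from the table: ",
             paste(missing, collapse = ", "))
    vals <- abundanceValues(table)
    ctr <- colMeans(vals[, nn, drop = FALSE])
    scl <- apply(vals[, nn, drop = FALSE], 2L, stats::sd)
    if (any(scl == 0))
        stop("zero-variance metabolite(s) in the training data: ",
             paste(nn[scl == 0], collapse = ", "))
    bet <- edges(backbone)
    et <- data.frame(i = bet$i, j = bet$j,
                     name = .interactionName(bet$i, bet$j),
                     stringsAsFactors = FALSE)
    Z <- sweep(sweep(vals[, nn, drop = FALSE], 2L, ctr), 2L, scl, "/")
    if (nrow(et)) {
        P <- Z[, et$i, drop = FALSE] * Z[, et$j, drop = FALSE]
        ictr <- colMeans(P)
        iscl <- apply(P, 2L, stats::sd)
        if (any(iscl == 0)) iscl[iscl == 0] <- 1  # constant product, keep centred
        names(ictr) <- names(iscl) <- et$name
    } else {
        ictr <- iscl <- numeric()
    }
    feats <- .assembleFeatures(vals, nn, et, ctr, scl, ictr, iscl)
    new("NetworkFeatureMatrix", features = feats,
        labels = groupLabels(table), nodeNames = nn, edgeTable = et,
        nodeCenter = ctr, nodeScale = scl,
        intCenter = ictr, intScale = iscl,
        caseLevel = backbone@groupLabels[1L])
}

#' Apply a fitted feature construction to new samples (transform mode)
#'
#' Rebuilds the identical feature columns for another table (normally the
#' test set) using the scaling statistics frozen at fit time; nothing is
#' re-estimated. Columns are matched by metabolite name, so column order
#' in the new table is irrelevant.
#'
#' @param table a log-scale [AbundanceTable-class] containing every
#'   fitted metabolite.
#' @param fitted a [NetworkFeatureMatrix-class] from [buildFeatureMatrix()].
#' @return a [NetworkFeatureMatrix-class] for the new samples, carrying the
#'   same scaling parameters.
#' @export
applyFeatureMatrix <- function(table, fitted) {
    if (scaleState(table) != "log")
        stop("feature construction expects a log-scale table")
    missing <- setdiff(fitted@nodeNames, metaboliteNames(table))
    if (length(missing))
        stop("fitted metabolite(s) absent from the table: ",
             paste(missing, collapse = ", "))
    feats <- .assembleFeatures(abundanceValues(table), fitted@nodeNames,
                               fitted@edgeTable, fitted@nodeCenter,
                               fitted@nodeScale, fitted@intCenter,
                               fitted@intScale)
    methods::initialize(fitted, features = feats,
                        labels = groupLabels(table))
}

#' Feature matrix and labels as plain objects
#'
#' @param x a [NetworkFeatureMatrix-class].
#' @return for \code{featureValues}, the numeric matrix; for
#'   \code{featureLabels}, the factor of sample labels.
#' @export
featureValues <- function(x) x@features

#' @rdname featureValues
#' @export
featureLabels <- function(x) x@labels

#' Write a feature matrix as TSV
#'
#' Header carries the node and en-dash interaction names; the label column
#' is preserved.
#'
#' @param x a [NetworkFeatureMatrix-class].
#' @param path output file path.
#' @export
writeFeatureMatrix <- function(x, path) {
    df <- data.frame(sample_id = rownames(x@features),
                     label = as.character(x@labels),
                     x@features, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
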