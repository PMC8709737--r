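#' Read a two-group metabolite abundance table
#'
#' Reads a delimited text file with samples as rows: the first column holds
#' sample identifiers, one designated column the two-level phenotype label,
#' and every remaining column a numeric metabolite intensity. Metabolites
#' with zero variance in either group are dropped with a warning, because a
#' Pearson correlation is undefined for them.
#'
#' @param path path to a CSV/TSV file.
#' @param groupColumn name of the column holding the phenotype label.
#' @param delimiter field separator, default comma.
#' @param keepLevels optional character vector of exactly two group levels;
#'   samples with other labels are discarded before validation. Required
#'   when the file contains more than two phenotypes.
#' @param impute if \code{TRUE}, missing entries are replaced by the
#'   per-metabolite median computed within the sample's group; the default
#'   is to reject tables with missing values, since silent imputation would
#'   change correlations invisibly.
#' @param scaleState whether the stored intensities are \code{"raw"} or
#'   already \code{"log"} transformed.
#'
#' @return an [AbundanceTable-class].
#' @seealso [writeAbundanceTable()], [logTransform()]
#' @export
readAbundanceTable <- function(path, groupColumn, delimiter = ",",
                               keepLevels = NULL, impute = FALSE,
                               scaleState = "raw") {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            row.names = 1L)
    if (!groupColumn %in% colnames(df))
        stop("group column '", groupColumn, "' not present in ", path)
    group <- as.character(df[[groupColumn]])
    df[[groupColumn]] <- NULL
    if (!is.null(keepLevels)) {
        keep <- group %in% keepLevels
        df <- df[keep, , drop = FALSE]
        group <- group[keep]
    }
    if (length(unique(group)) != 2L)
        stop("expected exactly 2 group levels, found ",
             length(unique(group)),
             "; use keepLevels to select a phenotype pair")
    nonNum <- !vapply(df, is.numeric, logical(1))
    if (any(nonNum))
        stop("non-numeric metabolite column(s): ",
             paste(colnames(df)[nonNum], collapse = ", "))
    values <- as.matrix(df)
    if (anyNA(values)) {
        if (!impute)
            stop("table contains missing values; set impute=TRUE for ",
                 "within-group median imputation")
        values <- .imputeWithinGroup(values, group)
    }
    if (any(table(group) < 3L))
        stop("each group needs at least 3 samples")
    values <- .dropZeroVariance(values, group)
    AbundanceTable(values, group, scaleState = scaleState)
}

.imputeWithinGroup <- function(values, group) {
    for (lev in unique(group)) {
        rows <- group == lev
        for (j in seq_len(ncol(values))) {
            miss <- rows & is.na(values[, j])
            if (any(miss))
                values[miss, j] <- stats::median(values[rows, j], na.rm = TRUE)
        }
    }
    if (anyNA(values))
        stop("imputation failed: a metabolite is entirely missing in a group")
    values
}

.dropZeroVariance <- function(values, group) {
    bad <- logical(ncol(values))
    for (lev in unique(group)) {
        v <- apply(values[group == lev, , drop = FALSE], 2L, stats::var)
        bad <- bad | v == 0 | !is.finite(v)
    }
    if (any(bad)) {
        warning("dropping ", sum(bad),
                " metabolite(s) with zero variance within a group: ",
                paste(colnames(values)[bad], collapse = ", "))
        values <- values[, !bad, drop = FALSE]
    }
    values
}

#' Write an AbundanceTable to a delimited file
#'
#' Inverse of [readAbundanceTable()]: samples as rows, first column
#' \code{sample_id}, then \code{group}, then one numeric column per
#' metabolite. Round-trips values at full double precision.
#'
#' @param x an [AbundanceTable-class].
#' @param path output file path.
#' @param delimiter field separator.
#' @export
writeAbundanceTable <- function(x, path, delimiter = ",") {
    vals <- abundanceValues(x)
    df <- data.frame(sample_id = rownames(vals),
                     group = as.character(groupLabels(x)),
                     vals, check.names = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Natural-log transform an abundance table
#'
#' Applies \code{log()} elementwise to a raw-scale table. Calling it on an
#' already log-scale table is an error (the transform must not be applied
#' twice), as is any non-positive intensity.
#'
#' @param x an [AbundanceTable-class] with \code{scaleState == "raw"}.
#' @param ... unused.
#' @return the transformed [AbundanceTable-class] with
#'   \code{scaleState == "log"}.
#' @rdname logTransform
#' @export
setMethod("logTransform", "AbundanceTable", function(x, ...) {
    if (scaleState(x) == "log")
        stop("table is already log-scale; refusing a second log transform")
    vals <- abundanceValues(x)
    if (any(vals <= 0)) {
        idx <- which(vals <= 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "non-positive value for sample '%s', metabolite '%s'; %s",
            rownames(vals)[idx[1L]], colnames(vals)[idx[2L]],
            "log transform requires strictly positive intensities"))
    }
    AbundanceTable(log(vals), groupLabels(x), scaleState = "log")
})

#' SplitResult: a stratified train/test partition
#'
#' @slot train,test disjoint [AbundanceTable-class] partitions whose union
#'   is the input sample set.
#' @slot fraction the requested training fraction.
#' @slot seed the RNG seed used for the per-group sampling.
#' @export
setClass("SplitResult",
    slots = c(train = "AbundanceTable", test = "AbundanceTable",
              fraction = "numeric", seed = "integer"))

setMethod("show", "SplitResult", function(object) {
    cat(sprintf("SplitResult (fraction %.2f, seed %d):\n",
                object@fraction, object@seed))
    cat("  train: "); show(object@train)
    cat("  test:  "); show(object@test)
})

#' Stratified train/test split
#'
#' Samples are drawn without replacement within each phenotype group so the
#' class balance of the training set matches the input within one sample.
#' The per-group training size is \code{floor(fraction * n + 0.5)}, clamped
#' to \code{[1, n - 1]} so both partitions keep every group non-empty.
#'
#' @param x an [AbundanceTable-class].
#' @param trainFraction training fraction in (0, 1).
#' @param seed integer seed; identical seeds give identical partitions.
#' @param ... unused.
#' @return a [SplitResult-class].
#' @rdname stratifiedSplit
#' @export
setMethod("stratifiedSplit", "AbundanceTable",
          function(x, trainFraction = 0.7, seed = 1L, ...) {
    if (!is.numeric(trainFraction) || trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must lie strictly between 0 and 1")
    g <- groupLabels(x)
    ids <- colnames(x)
    trainIds <- withSeed(seed, unlist(lapply(levels(g), function(lev) {
        grp <- ids[g == lev]
        k <- min(max(floor(trainFraction * length(grp) + 0.5), 1L),
                 length(grp) - 1L)
        sample(grp, k)
    }), use.names = FALSE))
    new("SplitResult",
        train = .subsetSamples(x, ids %in% trainIds),
        test = .subsetSamples(x, !ids %in% trainIds),
        fraction = trainFraction, seed = as.integer(seed))
})
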