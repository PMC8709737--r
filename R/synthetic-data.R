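#' Specification of a synthetic two-group metabolite dataset
#'
#' Defines a block-structured correlation model on the log (Gaussian) scale:
#' metabolites inside a block share a common pairwise correlation that may
#' differ between the two groups, so those within-block pairs are planted
#' differential correlations; all remaining pairs sit at
#' \code{backgroundRho}. The per-group correlation matrices implied by the
#' blocks are validated for positive semi-definiteness before any sampling;
#' a non-PSD matrix is an error rather than being silently repaired, since
#' repair would distort the planted effect sizes.
#'
#' @param nPerGroup integer vector of length two, samples per group.
#' @param nMetabolites number of metabolites.
#' @param blocks list of blocks, each a list with elements \code{members}
#'   (metabolite indices), \code{rhoA} and \code{rhoB} (the common
#'   within-block correlation in each group). Blocks must be disjoint.
#' @param backgroundRho correlation for all off-block pairs (default 0).
#' @param noiseSd marginal standard deviation of every metabolite.
#' @param lognormal if \code{TRUE} the Gaussian draws are exponentiated so
#'   the table holds strictly positive raw intensities; planted
#'   correlations then refer to the log scale, matching the pipeline's
#'   log-transform-then-correlate order.
#' @param seed RNG seed used by [generateTwoGroup()].
#'
#' @return a validated \code{SyntheticSpec} list.
#' @seealso [generateTwoGroup()], [nullPairTable()]
#' @export
syntheticSpec <- function(nPerGroup = c(60L, 60L), nMetabolites = 100L,
                          blocks = list(), backgroundRho = 0,
                          noiseSd = 1, lognormal = FALSE, seed = 1L) {
    stopifnot(length(nPerGroup) == 2L, all(nPerGroup >= 3),
              nMetabolites >= 2L, noiseSd > 0,
              abs(backgroundRho) <= 1)
    used <- integer()
    for (b in blocks) {
        stopifnot(is.list(b), all(c("members", "rhoA", "rhoB") %in% names(b)))
        if (abs(b$rhoA) > 1 || abs(b$rhoB) > 1)
            stop("block correlations must lie in [-1, 1]")
        if (any(b$members < 1L | b$members > nMetabolites))
            stop("block member index out of range")
        if (any(b$members %in% used))
            stop("blocks must be disjoint")
        used <- c(used, b$members)
    }
    spec <- structure(list(nPerGroup = as.integer(nPerGroup),
                           nMetabolites = as.integer(nMetabolites),
                           blocks = blocks, backgroundRho = backgroundRho,
                           noiseSd = noiseSd, lognormal = lognormal,
                           seed = as.integer(seed)),
                      class = "SyntheticSpec")
    .groupCorrelation(spec, "A")   # PSD validation for both groups
    .groupCorrelation(spec, "B")
    spec
}

# implied correlation matrix of one group; errors if not PSD
.groupCorrelation <- function(spec, which = c("A", "B")) {
    which <- match.arg(which)
    m <- spec$nMetabolites
    R <- matrix(spec$backgroundRho, m, m)
    diag(R) <- 1
    for (k in seq_along(spec$blocks)) {
        b <- spec$blocks[[k]]
        rho <- if (which == "A") b$rhoA else b$rhoB
        R[b$members, b$members] <- rho
    }
    diag(R) <- 1
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) {
        blk <- if (length(spec$blocks)) sprintf(" (check block(s) %s)",
            paste(seq_along(spec$blocks), collapse = ", ")) else ""
        stop(sprintf(
            "implied correlation matrix for group %s is not positive semi-definite (min eigenvalue %.3g)%s",
            which, ev, blk))
    }
    R
}

#' Generate a synthetic two-group abundance table with planted truth
#'
#' Draws each group's samples independently from a multivariate normal with
#' the group's block-structured correlation matrix, then (optionally)
#' exponentiates to produce lognormal raw intensities. The returned truth
#' table records, for every metabolite pair, the specified per-group
#' correlations and whether the pair is a planted differential correlation.
#'
#' @param spec a [syntheticSpec()] object.
#' @return a list with elements \code{table} (an [AbundanceTable-class];
#'   scale state \code{"log"} for Gaussian output, \code{"raw"} for
#'   lognormal) and \code{truth} (a data.frame with columns \code{i},
#'   \code{j}, \code{rhoA}, \code{rhoB}, \code{differential}).
#' @examples
#' spec <- syntheticSpec(nPerGroup = c(30, 30), nMetabolites = 8,
#'                       blocks = list(list(members = 1:2,
#'                                          rhoA = 0.8, rhoB = 0)),
#'                       seed = 7)
#' sim <- generateTwoGroup(spec)
#' sim$table
#' head(sim$truth)
#' @export
generateTwoGroup <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    m <- spec$nMetabolites
    metNames <- sprintf("m%03d", seq_len(m))
    Rs <- list(A = .groupCorrelation(spec, "A"),
               B = .groupCorrelation(spec, "B"))
    vals <- withSeed(spec$seed, {
        rbind(
            MASS::mvrnorm(spec$nPerGroup[1L], mu = rep(0, m),
                          Sigma = spec$noiseSd^2 * Rs$A),
            MASS::mvrnorm(spec$nPerGroup[2L], mu = rep(0, m),
                          Sigma = spec$noiseSd^2 * Rs$B))
    })
    if (spec$lognormal) vals <- exp(vals)
    group <- rep(c("A", "B"), spec$nPerGroup)
    dimnames(vals) <- list(sprintf("%s_%03d", group,
                                   c(seq_len(spec$nPerGroup[1L]),
                                     seq_len(spec$nPerGroup[2L]))),
                           metNames)
    tab <- AbundanceTable(vals, group,
                          scaleState = if (spec$lognormal) "raw" else "log")
    pairs <- utils::combn(m, 2L)
    truth <- data.frame(i = metNames[pairs[1L, ]], j = metNames[pairs[2L, ]],
                        rhoA = Rs$A[t(pairs)], rhoB = Rs$B[t(pairs)],
                        stringsAsFactors = FALSE)
    truth$differential <- truth$rhoA != truth$rhoB
    list(table = tab, truth = truth)
}

#' Two-group table with no group/correlation association
#'
#' Convenience wrapper around [generateTwoGroup()] drawing both groups from
#' the identical uncorrelated multivariate normal: the null model of the
#' edge-significance permutation test, used for calibration checks.
#'
#' @param nPerGroup integer vector of length two.
#' @param nMetabolites number of metabolites.
#' @param seed RNG seed.
#' @return an [AbundanceTable-class] on the log scale.
#' @export
nullPairTable <- function(nPerGroup = c(60L, 60L), nMetabolites = 20L,
                          seed = 1L) {
    generateTwoGroup(syntheticSpec(nPerGroup = nPerGroup,
                                   nMetabolites = nMetabolites,
                                   seed = seed))$table
}

#' Write a planted-truth pair table
#'
#' @param truth the \code{truth} data.frame from [generateTwoGroup()].
#' @param path output TSV path.
#' @export
writePlantedTruth <- function(truth, path) {
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
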