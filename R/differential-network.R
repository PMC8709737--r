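#' Per-group Pearson correlation matrix
#'
#' Pearson correlations over the samples of one phenotype group of a
#' log-scale abundance table.
#'
#' @param table an [AbundanceTable-class] with \code{scaleState == "log"}.
#' @param groupLevel which group's samples to use.
#' @return symmetric correlation matrix with unit diagonal, metabolites as
#'   dimnames.
#' @export
pairwiseCorrelations <- function(table, groupLevel) {
    if (scaleState(table) != "log")
        stop("correlations are computed on the log scale; call logTransform() first")
    g <- groupLabels(table)
    if (!groupLevel %in% levels(g))
        stop("group level '", groupLevel, "' not present")
    vals <- abundanceValues(table)[g == groupLevel, , drop = FALSE]
    if (nrow(vals) < 3L)
        stop("need at least 3 samples in group '", groupLevel, "'")
    stats::cor(vals)
}

#' Differential association weight
#'
#' The power-transformed absolute correlation difference
#' \eqn{w = |\rho_A - \rho_B|^\gamma}. The exponent \eqn{\gamma > 1} pushes
#' small correlation differences towards zero while conserving large ones.
#' Vectorised over the correlation arguments.
#'
#' @param rhoA,rhoB Pearson correlations in \eqn{[-1, 1]}.
#' @param gamma exponent, must exceed 1.
#' @return non-negative weight(s) in \eqn{[0, 2^\gamma]}.
#' @examples
#' differentialWeight(0.8, 0.3, 4)   # 0.5^4 = 0.0625
#' @export
differentialWeight <- function(rhoA, rhoB, gamma) {
    if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1)
        stop("gamma must be a single number greater than 1")
    if (any(abs(rhoA) > 1 + 1e-12, na.rm = TRUE) ||
        any(abs(rhoB) > 1 + 1e-12, na.rm = TRUE))
        stop("correlations must lie in [-1, 1]")
    abs(rhoA - rhoB)^gamma
}

# weight matrix from one split of the rows of X into case/control index sets;
# non-finite correlations (constant column within a split) become weight 0.
.weightMatrix <- function(X, caseIdx, ctrlIdx, gamma, warnNonFinite = TRUE) {
    rA <- suppressWarnings(stats::cor(X[caseIdx, , drop = FALSE]))
    rB <- suppressWarnings(stats::cor(X[ctrlIdx, , drop = FALSE]))
    bad <- !is.finite(rA) | !is.finite(rB)
    if (any(bad)) {
        if (warnNonFinite)
            warning("non-finite correlation(s) encountered; treated as weight 0")
        rA[bad] <- 0
        rB[bad] <- 0
    }
    list(w = abs(rA - rB)^gamma, rhoCase = rA, rhoControl = rB)
}

#' Permutation p-values for all differential associations
#'
#' For each label permutation the samples are reallocated to the two
#' phenotypes once (group sizes preserved) and both Pearson correlation
#' matrices, hence all pairwise differential weights, are recomputed from
#' that single shared shuffle; pairs are never permuted independently. The
#' p-value of each pair is the add-one exceedance proportion
#' \eqn{p_{ij} = (1 + \#\{b : w_{ij}^{(b)} \ge w_{ij}^{obs}\}) / (B + 1)},
#' which can never be exactly zero; ties count as exceedances
#' (conservative). \code{estimator = "raw"} instead returns the plain
#' proportion with strict \code{>} counting, and \code{exhaustive = TRUE}
#' replaces random shuffles by the complete enumeration of label
#' assignments (feasible only for tiny samples), with
#' \eqn{p = \#\{w^{(b)} \ge w^{obs}\}/B} over all \eqn{B} assignments.
#'
#' @param table a log-scale [AbundanceTable-class].
#' @param gamma differential-weight exponent (> 1).
#' @param nPermutations number of random shuffles (ignored when
#'   \code{exhaustive}); at least 100.
#' @param seed RNG seed for the shuffles.
#' @param caseLevel group level treated as cases; default the first level.
#' @param estimator \code{"addone"} (default) or \code{"raw"}.
#' @param exhaustive enumerate all \code{choose(n, nCase)} assignments.
#' @return list with symmetric matrices \code{pValues} and \code{weights}
#'   (observed), matrices \code{rhoCase}, \code{rhoControl}, and the
#'   effective \code{nPermutations}.
#' @export
permutationPvalues <- function(table, gamma = 4, nPermutations = 1000L,
                               seed = 1L, caseLevel = NULL,
                               estimator = c("addone", "raw"),
                               exhaustive = FALSE) {
    estimator <- match.arg(estimator)
    g <- groupLabels(table)
    caseLevel <- caseLevel %||% levels(g)[1L]
    if (!caseLevel %in% levels(g))
        stop("case level '", caseLevel, "' not present")
    if (!exhaustive && nPermutations < 100L)
        stop("at least 100 permutations are required")
    X <- abundanceValues(table)
    n <- nrow(X)
    isCase <- g == caseLevel
    nCase <- sum(isCase)
    obs <- .weightMatrix(X, which(isCase), which(!isCase), gamma)
    exceed <- matrix(0, ncol(X), ncol(X))
    if (exhaustive) {
        assignments <- utils::combn(n, nCase)
        B <- ncol(assignments)
        for (b in seq_len(B)) {
            caseIdx <- assignments[, b]
            wb <- .weightMatrix(X, caseIdx, setdiff(seq_len(n), caseIdx),
                                gamma, warnNonFinite = FALSE)$w
            exceed <- exceed + (wb >= obs$w)
        }
        p <- exceed / B
    } else {
        B <- as.integer(nPermutations)
        perms <- withSeed(seed, replicate(B, sample.int(n), simplify = FALSE))
        for (perm in perms) {
            caseIdx <- perm[seq_len(nCase)]
            wb <- .weightMatrix(X, caseIdx, perm[(nCase + 1L):n],
                                gamma, warnNonFinite = FALSE)$w
            exceed <- exceed +
                (if (estimator == "raw") wb > obs$w else wb >= obs$w)
        }
        p <- if (estimator == "raw") exceed / B else (1 + exceed) / (B + 1)
    }
    diag(p) <- 1
    dimnames(p) <- dimnames(obs$w)
    list(pValues = p, weights = obs$w,
         rhoCase = obs$rhoCase, rhoControl = obs$rhoControl,
         nPermutations = B)
}

#' Build the significant-edge differential network
#'
#' Runs the shared-shuffle permutation test on every metabolite pair and
#' links two metabolites if and only if the p-value of their differential
#' association is below \code{pCutoff}. Nodes comprise all metabolites,
#' including those left isolated.
#'
#' @inheritParams permutationPvalues
#' @param pCutoff edge-significance cut-off (default 0.05).
#' @param adjust multiple-testing adjustment applied to the pair p-values
#'   before thresholding; default \code{"none"} (a fixed per-edge cut-off),
#'   \code{"BH"} enables Benjamini-Hochberg.
#' @return a [DifferentialNetwork-class].
#' @examples
#' tab <- generateTwoGroup(syntheticSpec(
#'     nPerGroup = c(40, 40), nMetabolites = 6,
#'     blocks = list(list(members = 1:2, rhoA = 0.9, rhoB = 0)),
#'     seed = 3))$table
#' net <- buildDifferentialNetwork(tab, nPermutations = 199, seed = 9)
#' net
#' @export
buildDifferentialNetwork <- function(table, gamma = 4, pCutoff = 0.05,
                                     nPermutations = 1000L, seed = 1L,
                                     caseLevel = NULL,
                                     estimator = c("addone", "raw"),
                                     adjust = c("none", "BH")) {
    estimator <- match.arg(estimator)
    adjust <- match.arg(adjust)
    if (pCutoff <= 0 || pCutoff > 1)
        stop("pCutoff must lie in (0, 1]")
    g <- groupLabels(table)
    caseLevel <- caseLevel %||% levels(g)[1L]
    controlLevel <- setdiff(levels(g), caseLevel)
    res <- permutationPvalues(table, gamma = gamma,
                              nPermutations = nPermutations, seed = seed,
                              caseLevel = caseLevel, estimator = estimator)
    mets <- colnames(res$pValues)
    pairs <- which(upper.tri(res$pValues), arr.ind = TRUE)
    p <- res$pValues[pairs]
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    keep <- p < pCutoff
    et <- data.frame(i = mets[pairs[keep, 1L]], j = mets[pairs[keep, 2L]],
                     rhoCase = res$rhoCase[pairs][keep],
                     rhoControl = res$rhoControl[pairs][keep],
                     weight = res$weights[pairs][keep],
                     pValue = p[keep], stringsAsFactors = FALSE)
    new("DifferentialNetwork", nodes = mets, edgeTable = et,
        gamma = gamma, pCutoff = pCutoff,
        nPermutations = res$nPermutations,
        groupLabels = c(caseLevel, controlLevel))
}
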