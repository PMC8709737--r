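#' PLSDAModel: single-response PLS discriminant model
#'
#' Partial least squares regression of a 0/1 class indicator on the network
#' feature matrix (PLS1-DA): the two phenotype labels are encoded case = 1,
#' control = 0, the continuous predicted response is thresholded at 0.5 for
#' class prediction, and variable importance in projection (VIP) summarises
#' each feature's contribution across components, weighted by the response
#' variance each component explains. The fit is the classical NIPALS
#' sequence (deterministic for fixed input).
#'
#' @slot nComponents number of latent components.
#' @slot xWeights,xLoadings features x components weight and loading
#'   matrices.
#' @slot yLoadings per-component response loadings.
#' @slot scores training samples x components score matrix.
#' @slot xCenter training feature means removed before fitting.
#' @slot yMean training mean of the 0/1 response.
#' @slot ssY per-component explained response sum of squares (VIP weights).
#' @slot classEncoding named 0/1 vector mapping the two labels.
#' @slot decisionThreshold response threshold for calling a case,
#'   default 0.5.
#' @slot featureNames column names the model was fitted on.
#' @seealso [fitPlsda()], [vipScores()], [evaluateClassifier()]
#' @export
setClass("PLSDAModel",
    slots = c(nComponents = "integer", xWeights = "matrix",
              xLoadings = "matrix", yLoadings = "numeric",
              scores = "matrix", xCenter = "numeric", yMean = "numeric",
              ssY = "numeric", classEncoding = "numeric",
              decisionThreshold = "numeric", featureNames = "character"))

setMethod("show", "PLSDAModel", function(object) {
    enc <- object@classEncoding
    cat(sprintf("PLSDAModel: %d component(s) on %d feature(s); %s=1 vs %s=0\n",
                object@nComponents, length(object@featureNames),
                names(enc)[enc == 1], names(enc)[enc == 0]))
})

#' CVResult: component selection by repeated cross-validation
#'
#' @slot grid data.frame with one row per candidate component count and
#'   the mean and sd of accuracy and AUROC over repeats x folds.
#' @slot chosen selected component count: highest mean accuracy, ties
#'   broken by mean AUROC then by the smaller count.
#' @slot repeats,folds,seed the CV configuration.
#' @export
setClass("CVResult",
    slots = c(grid = "data.frame", chosen = "integer",
              repeats = "integer", folds = "integer", seed = "integer"))

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %dx repeated %d-fold CV, chosen ncomp = %d\n",
                object@repeats, object@folds, object@chosen))
    print(object@grid, row.names = FALSE, digits = 4)
})

#' ClassificationReport: two-class performance panel
#'
#' Confusion counts at the decision threshold plus the derived metric
#' panel: accuracy, AUROC, F1 (harmonic mean of PPV and sensitivity),
#' sensitivity, specificity, PPV, NPV and FNR. Metrics with a zero
#' denominator are reported as \code{NA}, never silently as 0.
#'
#' @slot tp,fp,tn,fn confusion counts (positive class = case group).
#' @slot metrics named numeric vector of the eight panel metrics.
#' @slot cohort \code{"cv"} or \code{"test"}.
#' @export
setClass("ClassificationReport",
    slots = c(tp = "integer", fp = "integer", tn = "integer",
              fn = "integer", metrics = "numeric", cohort = "character"))

setMethod("show", "ClassificationReport", function(object) {
    cat(sprintf("ClassificationReport [%s] TP=%d FP=%d TN=%d FN=%d\n",
                object@cohort, object@tp, object@fp, object@tn, object@fn))
    print(round(object@metrics, 4))
})

#' F1 score from PPV and sensitivity
#'
#' Harmonic mean \eqn{2 \cdot PPV \cdot sens / (PPV + sens)}.
#'
#' @param ppv positive predictive value.
#' @param sensitivity true positive rate.
#' @return the F1 score (\code{NA} if both arguments are zero).
#' @examples
#' f1Score(0.84, 0.73)  # 0.78 at two decimals
#' @export
f1Score <- function(ppv, sensitivity) {
    ifelse(ppv + sensitivity > 0,
           2 * ppv * sensitivity / (ppv + sensitivity), NA_real_)
}

#' Build a classification report from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts.
#' @param auroc optional AUROC from the continuous response, \code{NA} if
#'   unavailable.
#' @param cohort report tag, e.g. \code{"cv"} or \code{"test"}.
#' @return a [ClassificationReport-class].
#' @export
classificationReport <- function(tp, fp, tn, fn, auroc = NA_real_,
                                 cohort = "test") {
    stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
    div <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- div(tp, tp + fn)
    spec <- div(tn, tn + fp)
    ppv <- div(tp, tp + fp)
    npv <- div(tn, tn + fn)
    metrics <- c(accuracy = (tp + tn) / (tp + fp + tn + fn),
                 auroc = auroc,
                 f1 = if (!is.na(ppv) && !is.na(sens)) f1Score(ppv, sens)
                      else NA_real_,
                 sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv,
                 fnr = if (!is.na(sens)) 1 - sens else NA_real_)
    new("ClassificationReport", tp = as.integer(tp), fp = as.integer(fp),
        tn = as.integer(tn), fn = as.integer(fn), metrics = metrics,
        cohort = cohort)
}

#' Area under the ROC curve by rank statistic
#'
#' Probability that a random case outscores a random control, computed
#' from midranks (ties contribute 1/2), i.e. the normalized Mann-Whitney
#' U statistic.
#'
#' @param scores continuous classifier responses.
#' @param isCase logical, \code{TRUE} for case samples.
#' @return AUROC in \eqn{[0, 1]}; \code{NA} if either class is absent.
#' @export
aurocScore <- function(scores, isCase) {
    nCase <- sum(isCase)
    nCtrl <- sum(!isCase)
    if (nCase == 0L || nCtrl == 0L) return(NA_real_)
    r <- rank(scores)
    (sum(r[isCase]) - nCase * (nCase + 1) / 2) / (nCase * nCtrl)
}

# ---- PLS1 core ----

.encodeLabels <- function(labels, caseLevel) {
    labels <- factor(labels)
    if (nlevels(labels) != 2L)
        stop("exactly two classes are required, found ", nlevels(labels))
    if (!caseLevel %in% levels(labels))
        stop("case level '", caseLevel, "' not present in the labels")
    as.numeric(labels == caseLevel)
}

#' Fit a PLS1-DA model
#'
#' @param features a [NetworkFeatureMatrix-class] (training samples, both
#'   classes present).
#' @param nComponents number of latent components, at most
#'   \code{min(#features, #samples - 1)}.
#' @return a [PLSDAModel-class].
#' @export
fitPlsda <- function(features, nComponents) {
    X <- featureValues(features)
    y <- .encodeLabels(featureLabels(features), features@caseLevel)
    nComponents <- as.integer(nComponents)
    maxA <- min(ncol(X), nrow(X) - 1L)
    if (nComponents < 1L || nComponents > maxA)
        stop("nComponents must lie in [1, ", maxA, "]")
    xCenter <- colMeans(X)
    Xc <- sweep(X, 2L, xCenter)
    yMean <- mean(y)
    yc <- y - yMean
    p <- ncol(X)
    W <- P <- matrix(0, p, nComponents)
    Tm <- matrix(0, nrow(X), nComponents)
    cvec <- ssY <- numeric(nComponents)
    for (a in seq_len(nComponents)) {
        w <- drop(crossprod(Xc, yc))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) {
            nComponents <- a - 1L
            if (nComponents < 1L)
                stop("response is orthogonal to all features; nothing to fit")
            warning("residual response exhausted; using ", nComponents,
                    " component(s)")
            W <- W[, seq_len(nComponents), drop = FALSE]
            P <- P[, seq_len(nComponents), drop = FALSE]
            Tm <- Tm[, seq_len(nComponents), drop = FALSE]
            cvec <- cvec[seq_len(nComponents)]
            ssY <- ssY[seq_len(nComponents)]
            break
        }
        w <- w / nw
        t <- drop(Xc %*% w)
        tt <- sum(t^2)
        pl <- drop(crossprod(Xc, t)) / tt
        cc <- sum(yc * t) / tt
        Xc <- Xc - tcrossprod(t, pl)
        yc <- yc - cc * t
        W[, a] <- w; P[, a] <- pl; Tm[, a] <- t
        cvec[a] <- cc; ssY[a] <- cc^2 * tt
    }
    enc <- c(1, 0)
    labs <- levels(featureLabels(features))
    names(enc) <- c(features@caseLevel, setdiff(labs, features@caseLevel))
    rownames(W) <- rownames(P) <- colnames(X)
    rownames(Tm) <- rownames(X)
    new("PLSDAModel", nComponents = nComponents, xWeights = W,
        xLoadings = P, yLoadings = cvec, scores = Tm, xCenter = xCenter,
        yMean = yMean, ssY = ssY, classEncoding = enc,
        decisionThreshold = 0.5, featureNames = colnames(X))
}

# regression coefficients for the first `a` components
.plsCoef <- function(model, a = model@nComponents) {
    W <- model@xWeights[, seq_len(a), drop = FALSE]
    P <- model@xLoadings[, seq_len(a), drop = FALSE]
    cvec <- model@yLoadings[seq_len(a)]
    drop(W %*% solve(crossprod(P, W), cvec))
}

#' Predict the continuous PLS-DA response
#'
#' @param model a [PLSDAModel-class].
#' @param features a [NetworkFeatureMatrix-class] scaled with the training
#'   parameters.
#' @param nComponents optionally use only the leading components.
#' @return numeric vector of predicted responses (case class ~ 1).
#' @export
predictResponse <- function(model, features, nComponents = model@nComponents) {
    X <- featureValues(features)
    if (!identical(colnames(X), model@featureNames))
        X <- X[, model@featureNames, drop = FALSE]
    drop(sweep(X, 2L, model@xCenter) %*% .plsCoef(model, nComponents)) +
        model@yMean
}

#' Predict class labels
#'
#' @inheritParams predictResponse
#' @return factor of predicted labels (case when the response exceeds the
#'   decision threshold).
#' @export
predictClass <- function(model, features, nComponents = model@nComponents) {
    resp <- predictResponse(model, features, nComponents)
    enc <- model@classEncoding
    factor(ifelse(resp > model@decisionThreshold,
                  names(enc)[enc == 1], names(enc)[enc == 0]),
           levels = names(enc)[order(-enc)])
}

#' Variable importance in projection
#'
#' \eqn{VIP_f = \sqrt{p \sum_a SS_a (w_{af}/\lVert w_a \rVert)^2 / \sum_a
#' SS_a}} with \eqn{SS_a} the response variance explained by component
#' \eqn{a}; by construction the mean squared VIP over features is exactly 1.
#'
#' @param model a [PLSDAModel-class].
#' @return named per-feature VIP scores.
#' @export
vipScores <- function(model) {
    W <- model@xWeights
    w2 <- sweep(W^2, 2L, colSums(W^2), "/")
    vip <- sqrt(nrow(W) * drop(w2 %*% model@ssY) / sum(model@ssY))
    names(vip) <- model@featureNames
    vip
}

#' Evaluate a fitted model on a feature matrix
#'
#' Confusion counts at the decision threshold plus rank-statistic AUROC
#' from the continuous response; the positive class is the case group.
#'
#' @param model a [PLSDAModel-class].
#' @param features a [NetworkFeatureMatrix-class] scaled with training
#'   parameters (e.g. from [applyFeatureMatrix()]).
#' @param cohort report tag.
#' @return a [ClassificationReport-class].
#' @export
evaluateClassifier <- function(model, features, cohort = "test") {
    resp <- predictResponse(model, features)
    isCase <- featureLabels(features) == features@caseLevel
    pred <- resp > model@decisionThreshold
    classificationReport(tp = sum(pred & isCase), fp = sum(pred & !isCase),
                         tn = sum(!pred & !isCase), fn = sum(!pred & isCase),
                         auroc = aurocScore(resp, isCase), cohort = cohort)
}

# stratified fold ids for one repeat (sizes differ by at most one per class)
.stratifiedFolds <- function(labels, folds) {
    ids <- integer(length(labels))
    for (lev in levels(labels)) {
        idx <- sample(which(labels == lev))
        ids[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ids
}

#' Select the number of PLS components by repeated cross-validation
#'
#' Stratified k-fold cross-validation repeated with fresh fold draws; for
#' each candidate component count the mean held-out accuracy (and AUROC)
#' is accumulated over all repeats and folds. Features arrive pre-scaled
#' with training-set statistics and are not re-scaled per fold by default,
#' matching a protocol that builds the network and scaling once on the
#' full training set and cross-validates only the classifier;
#' \code{rescale = TRUE} enables the stricter per-fold re-autoscaling.
#'
#' @param features a [NetworkFeatureMatrix-class].
#' @param repeats number of CV repetitions, default 20.
#' @param folds folds per repetition, default 10; reduced with a warning
#'   if it exceeds the smallest class size.
#' @param maxComponents largest candidate, default 10, capped by the data
#'   dimensions.
#' @param seed RNG seed for the fold draws.
#' @param rescale re-autoscale each fold's training part and apply to its
#'   held-out part.
#' @return a [CVResult-class].
#' @export
selectComponents <- function(features, repeats = 20L, folds = 10L,
                             maxComponents = 10L, seed = 1L,
                             rescale = FALSE) {
    if (maxComponents < 1L) stop("maxComponents must be at least 1")
    X <- featureValues(features)
    labels <- featureLabels(features)
    minClass <- min(table(labels))
    if (folds > minClass) {
        warning("folds reduced from ", folds, " to ", minClass,
                " (smallest class size)")
        folds <- minClass
    }
    if (folds < 2L) stop("need at least 2 folds")
    nTrainMin <- nrow(X) - ceiling(nrow(X) / folds)
    maxA <- min(as.integer(maxComponents), ncol(X), nTrainMin - 1L)
    acc <- auc <- matrix(NA_real_, repeats * folds, maxA)
    row <- 0L
    withSeed(seed, for (r in seq_len(repeats)) {
        foldId <- .stratifiedFolds(labels, folds)
        for (k in seq_len(folds)) {
            row <- row + 1L
            hold <- foldId == k
            Xtr <- X[!hold, , drop = FALSE]
            Xte <- X[hold, , drop = FALSE]
            if (rescale) {
                ctr <- colMeans(Xtr)
                scl <- apply(Xtr, 2L, stats::sd)
                scl[scl == 0] <- 1
                Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, "/")
                Xte <- sweep(sweep(Xte, 2L, ctr), 2L, scl, "/")
            }
            fTr <- methods::initialize(features, features = Xtr,
                                       labels = droplevels(labels[!hold]))
            fTe <- methods::initialize(features, features = Xte,
                                       labels = labels[hold])
            if (nlevels(fTr@labels) < 2L) next  # degenerate fold, skip
            aCap <- min(maxA, nrow(Xtr) - 1L)
            fit <- suppressWarnings(fitPlsda(fTr, aCap))
            isCase <- labels[hold] == features@caseLevel
            for (a in seq_len(fit@nComponents)) {
                resp <- predictResponse(fit, fTe, a)
                pred <- resp > fit@decisionThreshold
                acc[row, a] <- mean(pred == isCase)
                auc[row, a] <- aurocScore(resp, isCase)
            }
        }
    })
    grid <- data.frame(ncomp = seq_len(maxA),
                       accuracy = colMeans(acc, na.rm = TRUE),
                       accuracy_sd = apply(acc, 2L, stats::sd, na.rm = TRUE),
                       auroc = colMeans(auc, na.rm = TRUE),
                       auroc_sd = apply(auc, 2L, stats::sd, na.rm = TRUE))
    best <- order(-round(grid$accuracy, 12), -round(grid$auroc, 12),
                  grid$ncomp)[1L]
    new("CVResult", grid = grid, chosen = as.integer(grid$ncomp[best]),
        repeats = as.integer(repeats), folds = as.integer(folds),
        seed = as.integer(seed))
}

#' VIP table with per-group summaries
#'
#' Tables the features by VIP score (descending) together with each
#' group's mean and standard deviation of the feature and a Mann-Whitney
#' test of the between-group difference, Benjamini-Hochberg adjusted.
#'
#' @param model a [PLSDAModel-class].
#' @param features the training [NetworkFeatureMatrix-class].
#' @return data.frame with columns \code{feature}, \code{vip},
#'   per-group \code{mean_*}/\code{sd_*}, \code{p_value}, \code{p_adj}.
#' @export
vipTable <- function(model, features) {
    vip <- vipScores(model)
    X <- featureValues(features)
    labs <- featureLabels(features)
    lev <- levels(labs)
    pv <- apply(X, 2L, function(col)
        stats::wilcox.test(col[labs == lev[1L]],
                           col[labs == lev[2L]], exact = FALSE)$p.value)
    out <- data.frame(feature = names(vip), vip = unname(vip),
                      stringsAsFactors = FALSE)
    for (lv in lev) {
        out[[paste0("mean_", lv)]] <- colMeans(X[labs == lv, , drop = FALSE])
        out[[paste0("sd_", lv)]] <- apply(X[labs == lv, , drop = FALSE],
                                          2L, stats::sd)
    }
    out$p_value <- unname(pv)
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    out[order(-out$vip), , drop = FALSE]
}
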