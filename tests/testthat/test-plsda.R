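makeFeatures <- function(X, labels, case = levels(factor(labels))[1]) {
    colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
    rownames(X) <- rownames(X) %||% paste0("s", seq_len(nrow(X)))
    new("NetworkFeatureMatrix", features = X, labels = factor(labels),
        nodeNames = colnames(X),
        edgeTable = data.frame(i = character(), j = character(),
                               name = character()),
        nodeCenter = colMeans(X), nodeScale = apply(X, 2, sd),
        intCenter = numeric(), intScale = numeric(), caseLevel = case)
}

test_that("linearly separable data is fit perfectly with one component", {
    set.seed(3)
    X <- cbind(c(rnorm(20, 3), rnorm(20, -3)), rnorm(40))
    fm <- makeFeatures(X, rep(c("case", "ctrl"), each = 20))
    fit <- fitPlsda(fm, 1)
    rep <- evaluateClassifier(fit, fm, cohort = "train")
    expect_equal(unname(rep@metrics["accuracy"]), 1)
    expect_equal(unname(rep@metrics["auroc"]), 1)
    expect_equal(unname(rep@metrics["fnr"]), 0)
    expect_error(fitPlsda(fm, 50), "nComponents")
    oneClass <- makeFeatures(X[1:20, ], rep("case", 20))
    expect_error(fitPlsda(oneClass, 1), "two classes")
})

test_that("duplicated feature columns leave predictions unchanged", {
    set.seed(11)
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- ifelse(X[, 1] + rnorm(40, sd = 0.5) > 0, "case", "ctrl")
    fm1 <- makeFeatures(X, y)
    fm2 <- makeFeatures(cbind(X, X), y)
    p1 <- predictResponse(fitPlsda(fm1, 2), fm1)
    p2 <- predictResponse(fitPlsda(fm2, 2), fm2)
    expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("predictions agree with an independent PLS regression implementation", {
    set.seed(19)
    X <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(paste0("s", 1:30), paste0("f", 1:6)))
    y <- rep(c("case", "ctrl"), each = 15)
    fm <- makeFeatures(X, y)
    fit <- fitPlsda(fm, 3)
    ref <- mixOmics::pls(X, as.numeric(y == "case"), ncomp = 3,
                         mode = "regression", scale = FALSE)
    refPred <- predict(ref, X)$predict[, 1, 3]
    expect_equal(unname(predictResponse(fit, fm)), unname(refPred),
                 tolerance = 1e-8)
})

test_that("VIP scores satisfy their identities and rank informative features first", {
    set.seed(23)
    X <- matrix(rnorm(60), 60, 1)
    y <- ifelse(X[, 1] > 0, "case", "ctrl")
    oneFeat <- fitPlsda(makeFeatures(X, y), 1)
    expect_equal(unname(vipScores(oneFeat)), 1.0)
    X2 <- cbind(signal = c(rnorm(30, 2), rnorm(30, -2)), noise = rnorm(60))
    fit2 <- fitPlsda(makeFeatures(X2, rep(c("case", "ctrl"), each = 30)), 2)
    vip <- vipScores(fit2)
    expect_equal(mean(vip^2), 1, tolerance = 1e-8)
    expect_gt(vip["signal"], 1)
    expect_lt(vip["noise"], 1)
    # identity holds for an arbitrary fitted model too
    set.seed(29)
    Xr <- matrix(rnorm(50 * 7), 50, 7)
    fitR <- fitPlsda(makeFeatures(Xr, rep(c("a", "b"), 25)), 4)
    expect_equal(mean(vipScores(fitR)^2), 1, tolerance = 1e-8)
})

test_that("classification report identities hold on random confusion tables", {
    rep0 <- classificationReport(tp = 3, fp = 1, tn = 5, fn = 1)
    m <- rep0@metrics
    expect_equal(unname(m["sensitivity"]), 0.75)
    expect_equal(unname(m["ppv"]), 0.75)
    expect_equal(unname(m["f1"]), 0.75)
    expect_equal(unname(m["accuracy"]), 0.8)
    expect_equal(unname(m["fnr"]), 0.25)
    set.seed(41)
    for (r in 1:50) {
        cts <- rmultinom(1, sample(10:200, 1), rep(0.25, 4))
        rp <- classificationReport(cts[1], cts[2], cts[3], cts[4])@metrics
        if (!is.na(rp["sensitivity"]))
            expect_equal(unname(rp["fnr"]), 1 - unname(rp["sensitivity"]))
        if (!is.na(rp["f1"]))
            expect_equal(unname(rp["f1"]),
                         f1Score(rp[["ppv"]], rp[["sensitivity"]]))
        expect_equal(unname(rp["accuracy"]), sum(cts[c(1, 3)]) / sum(cts))
    }
    # zero denominators surface as NA, never as 0
    noCases <- classificationReport(tp = 0, fp = 0, tn = 5, fn = 0)
    expect_true(is.na(noCases@metrics["sensitivity"]))
    expect_true(is.na(noCases@metrics["ppv"]))
})

test_that("rank-based AUROC equals the all-pairs probability oracle", {
    set.seed(47)
    for (r in 1:30) {
        n <- sample(6:14, 1)
        isCase <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(isCase) || all(isCase)) next
        scores <- round(rnorm(n), 1)   # rounding forces occasional ties
        expect_equal(aurocScore(scores, isCase),
                     allPairsAuroc(scores, isCase))
    }
    expect_true(is.na(aurocScore(rnorm(4), rep(TRUE, 4))))
})

test_that("labels independent of the features give chance-level CV accuracy", {
    set.seed(53)
    X <- matrix(rnorm(200 * 5), 200, 5)
    fm <- makeFeatures(X, sample(rep(c("case", "ctrl"), each = 100)))
    cv <- selectComponents(fm, repeats = 3, folds = 5, maxComponents = 3,
                           seed = 7)
    expect_gt(max(cv@grid$accuracy), 0.4)
    expect_lt(max(cv@grid$accuracy), 0.6)
})

test_that("component selection is reproducible and prefers the latent dimension", {
    set.seed(59)
    # two latent directions drive the class, embedded in 10 features
    n <- 120
    t1 <- c(rnorm(n / 2, 1.2), rnorm(n / 2, -1.2))
    t2 <- c(rnorm(n / 2, -0.8), rnorm(n / 2, 0.8))
    load1 <- rnorm(10); load2 <- rnorm(10)
    X <- outer(t1, load1) + outer(t2, load2) + matrix(rnorm(n * 10), n)
    fm <- makeFeatures(X, rep(c("case", "ctrl"), each = n / 2))
    cv <- selectComponents(fm, repeats = 4, folds = 5, maxComponents = 8,
                           seed = 2)
    expect_lte(cv@chosen, 4)
    cv2 <- selectComponents(fm, repeats = 4, folds = 5, maxComponents = 8,
                            seed = 2)
    expect_identical(cv2@grid, cv@grid)
    expect_identical(cv2@chosen, cv@chosen)
})

test_that("fold counts exceeding the smallest class are reduced with a warning", {
    set.seed(61)
    X <- matrix(rnorm(16 * 3), 16, 3)
    fm <- makeFeatures(X, rep(c("case", "ctrl"), c(4, 12)))
    expect_warning(cv <- selectComponents(fm, repeats = 1, folds = 10,
                                          maxComponents = 2, seed = 1),
                   "reduced")
    expect_equal(cv@folds, 4L)
    expect_true(all(is.finite(cv@grid$accuracy)))
})

test_that("the printed-table F1 arithmetic reproduces the harmonic mean", {
    expect_equal(round(f1Score(0.84, 0.73), 2), 0.78)
    expect_equal(round(f1Score(0.74, 0.82), 2), 0.78)
    expect_true(is.na(f1Score(0, 0)))
})

test_that("planted correlation differences plus mean shifts are classified accurately", {
    # regression guard for the whole feature->classifier chain: strong
    # group-dependent correlations and concentration shifts at n = 100
    # per group should yield high held-out accuracy
    spec <- syntheticSpec(nPerGroup = c(100, 100), nMetabolites = 15,
                          blocks = list(list(members = 1:4,
                                             rhoA = 0.85, rhoB = 0.0),
                                        list(members = 5:7,
                                             rhoA = -0.3, rhoB = 0.6)),
                          seed = 88)
    sim <- generateTwoGroup(spec)
    vals <- abundanceValues(sim$table)
    g <- groupLabels(sim$table)
    vals[g == "A", 1:6] <- vals[g == "A", 1:6] + 1.2  # shift on log scale
    tab <- AbundanceTable(vals, g, scaleState = "log")
    sp <- stratifiedSplit(tab, 0.7, seed = 89)
    net <- buildDifferentialNetwork(sp@train, nPermutations = 500,
                                    seed = 90)
    bb <- extractBackbone(net, 0.3)
    fm <- buildFeatureMatrix(sp@train, bb)
    cv <- selectComponents(fm, repeats = 5, folds = 5, maxComponents = 5,
                           seed = 91)
    model <- fitPlsda(fm, cv@chosen)
    rep <- evaluateClassifier(model, applyFeatureMatrix(sp@test, fm))
    expect_gt(unname(rep@metrics["accuracy"]), 0.8)
    expect_gt(unname(rep@metrics["auroc"]), 0.8)
})
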