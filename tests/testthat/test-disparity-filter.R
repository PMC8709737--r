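test_that("weight normalization and its degenerate cases", {
    expect_equal(normalizeNodeWeights(c(2, 2)), c(0.5, 0.5))
    expect_equal(normalizeNodeWeights(c(3, 1)), c(0.75, 0.25))
    expect_equal(normalizeNodeWeights(5), 1)
    expect_error(normalizeNodeWeights(c(0, 0)), "degenerate")
    expect_error(normalizeNodeWeights(numeric()), "non-empty")
})

test_that("disparity measure hits its homogeneous and heterogeneous limits", {
    for (k in c(2, 5, 20))
        expect_equal(disparityMeasure(rep(1 / k, k)), 1)
    expect_equal(disparityMeasure(c(1, 0, 0, 0, 0)), 5)
    expect_equal(disparityMeasure(c(0.75, 0.25)), 1.25)
    expect_error(disparityMeasure(c(0.5, 0.4)), "sum to 1")
    # 1 <= Y <= n on random weight profiles
    set.seed(31)
    for (r in 1:50) {
        k <- sample(2:15, 1)
        p <- normalizeNodeWeights(rexp(k))
        y <- disparityMeasure(p)
        expect_gte(y, 1); expect_lte(y, k)
    }
})

test_that("edge significance closed form matches the uniform-partition Monte Carlo null", {
    draws <- 1e5
    set.seed(77)
    for (case in list(c(p = 0.3, k = 4), c(p = 0.6, k = 3),
                      c(p = 0.15, k = 8))) {
        p <- case["p"]; k <- case["k"]
        # k-1 uniform breakpoints partition [0,1]; take the first segment
        seg <- replicate(draws, {
            b <- sort(runif(k - 1))
            b[1L]
        })
        mc <- mean(seg >= p)
        se <- sqrt(mc * (1 - mc) / draws)
        expect_lt(abs(edgeAlpha(p, k) - mc), 3 * se + 1e-12)
    }
    expect_equal(edgeAlpha(0.5, 2), 0.5)
    expect_equal(edgeAlpha(1.0, 5), 0.0)
    expect_equal(edgeAlpha(0.9, 1), 1.0)   # degree-1 endpoints never qualify
})

test_that("star with one dominant edge keeps it through the hub side only", {
    et <- data.frame(i = rep("hub", 5), j = paste0("leaf", 1:5),
                     weight = c(10, 1, 1, 1, 1))
    bb <- extractBackbone(networkFromEdges(et), 0.3)
    ke <- edges(bb)
    expect_equal(ke$alphaJ, rep(1, nrow(ke)))           # all leaves degree 1
    heavy <- ke[ke$j == "leaf1", ]
    expect_equal(heavy$alphaI, (1 - 10 / 14)^4, tolerance = 1e-12)
    expect_true(nrow(heavy) == 1L)
    # light edges: alpha = (1 - 1/14)^4 ~ 0.744 > 0.3 -> dropped
    expect_equal(ke$j, "leaf1")
    expect_equal(bb@edgeFraction, 0.2)
    expect_equal(bb@weightFraction, 10 / 14)
    expect_gt(bb@weightFraction, bb@edgeFraction)
})

test_that("perfectly homogeneous graphs yield an empty backbone", {
    # 4-clique, equal weights: alpha_ij = (1 - 1/3)^2 = 4/9 > 0.3 everywhere
    pairs <- t(combn(paste0("n", 1:4), 2))
    et <- data.frame(i = pairs[, 1], j = pairs[, 2], weight = 1)
    expect_warning(bb <- extractBackbone(networkFromEdges(et), 0.3), NA)
    expect_equal(nrow(edges(bb)), 0L)
    expect_length(nodes(bb), 0L)
    expect_setequal(bb@isolatedNodes, paste0("n", 1:4))
})

test_that("backbones are monotone nested over an alpha grid", {
    set.seed(13)
    for (r in 1:20) {
        et <- randomEdgeList(8)
        et$weight <- rexp(nrow(et))^2
        net <- networkFromEdges(et)
        grid <- c(0.05, 0.15, 0.3, 0.5, 0.8)
        kept <- lapply(grid, function(a) {
            ke <- edges(extractBackbone(net, a))
            paste(ke$i, ke$j)
        })
        for (k in seq_along(grid)[-1])
            expect_true(all(kept[[k - 1]] %in% kept[[k]]))
    }
})

test_that("under locally uniform random weights each eligible edge-end passes at rate alpha", {
    # star nodes: normalized weights of a degree-k hub drawn as a uniform
    # partition; the hub-side criterion should fire with probability alpha
    set.seed(55)
    alpha <- 0.25; k <- 6; reps <- 4000
    pass <- replicate(reps, {
        w <- diff(sort(c(0, runif(k - 1), 1)))
        any(edgeAlpha(w[1], k) < alpha)
    })
    se <- sqrt(alpha * (1 - alpha) / reps)
    expect_lt(abs(mean(pass) - alpha), 4 * se)
})

test_that("heterogeneous weights concentrate kept weight above kept edges", {
    set.seed(91)
    for (r in 1:10) {
        et <- randomEdgeList(10, 0.5)
        # planted dominance: a few edges carry most of the weight
        et$weight <- ifelse(runif(nrow(et)) < 0.2, 50, 1) * rexp(nrow(et))
        bb <- extractBackbone(networkFromEdges(et), 0.3)
        if (nrow(edges(bb)) > 0)
            expect_gt(bb@weightFraction, bb@edgeFraction)
    }
})

test_that("disparity records and the scaling exponent fit recover planted slopes", {
    rec <- data.frame(node = paste0("n", 1:6), degree = c(2, 3, 5, 8, 13, 21),
                      disparity = c(2, 3, 5, 8, 13, 21)^0.5)
    expect_equal(disparityExponentFit(rec), 0.5, tolerance = 1e-12)
    rec$disparity <- 1
    expect_equal(disparityExponentFit(rec), 0, tolerance = 1e-12)
    rec$disparity <- rec$degree
    expect_equal(disparityExponentFit(rec), 1, tolerance = 1e-12)
    expect_error(disparityExponentFit(rec[1:2, ]), "at least 3")
    # records computed from a network agree with direct normalization
    et <- data.frame(i = c("a", "a", "b"), j = c("b", "c", "c"),
                     weight = c(3, 1, 1))
    r <- disparityRecords(networkFromEdges(et))
    expect_equal(r$degree[r$node == "a"], 2L)
    expect_equal(r$disparity[r$node == "a"],
                 disparityMeasure(c(0.75, 0.25)))
})

test_that("an empty differential network yields an empty backbone with a warning", {
    et <- data.frame(i = character(), j = character(), weight = numeric())
    net <- networkFromEdges(et, nodes = c("x", "y", "z"))
    expect_warning(bb <- extractBackbone(net, 0.3), "empty")
    expect_equal(bb@edgeFraction, 0)
    expect_equal(bb@weightFraction, 0)
})
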