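# Independent brute-force oracles used to validate the fast implementations.
# They deliberately avoid the code paths (igraph, vectorised cor, rank
# statistics) they are checking.

# Pearson correlation from the definition, one pair at a time.
naiveCor <- function(x, y) {
    dx <- x - mean(x); dy <- y - mean(y)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exhaustive permutation p-values over all choose(n, nCase) label
# assignments, counting ties as exceedances; p = #{w_perm >= w_obs} / B
# (the identity assignment is included, so p >= 1/B).
exhaustivePermOracle <- function(values, isCase, gamma) {
    n <- nrow(values); m <- ncol(values)
    nCase <- sum(isCase)
    wOf <- function(rows) {
        w <- matrix(0, m, m)
        for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
            rA <- naiveCor(values[rows, a], values[rows, b])
            rB <- naiveCor(values[-rows, a], values[-rows, b])
            w[a, b] <- w[b, a] <- abs(rA - rB)^gamma
        }
        w
    }
    wObs <- wOf(which(isCase))
    sets <- utils::combn(n, nCase)
    counts <- matrix(0, m, m)
    for (k in seq_len(ncol(sets)))
        counts <- counts + (wOf(sets[, k]) >= wObs)
    p <- counts / ncol(sets)
    diag(p) <- 1
    p
}

# All-shortest-path betweenness by explicit path enumeration (raw counts,
# each unordered pair once, fractional credit for tied paths).
bruteBetweenness <- function(nodeNames, edgeFrom, edgeTo) {
    n <- length(nodeNames)
    adj <- matrix(FALSE, n, n, dimnames = list(nodeNames, nodeNames))
    adj[cbind(edgeFrom, edgeTo)] <- TRUE
    adj[cbind(edgeTo, edgeFrom)] <- TRUE
    allPaths <- function(s, t, len) {
        # all simple paths s -> t of exactly `len` edges
        if (len == 0L) return(if (s == t) list(s) else list())
        out <- list()
        for (v in which(adj[s, ])) {
            for (pth in allPaths(v, t, len - 1L))
                if (!s %in% pth) out[[length(out) + 1L]] <- c(s, pth)
        }
        out
    }
    dist <- function(s, t) {   # BFS hop distance
        seen <- rep(NA_integer_, n); seen[s] <- 0L; q <- s
        while (length(q)) {
            v <- q[1L]; q <- q[-1L]
            for (u in which(adj[v, ])) if (is.na(seen[u])) {
                seen[u] <- seen[v] + 1L; q <- c(q, u)
            }
        }
        seen[t]
    }
    btw <- setNames(numeric(n), nodeNames)
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
        d <- dist(s, t)
        if (is.na(d) || d < 2L) next
        paths <- allPaths(s, t, d)
        for (pth in paths) {
            inner <- pth[-c(1L, length(pth))]
            btw[inner] <- btw[inner] + 1 / length(paths)
        }
    }
    btw
}

# AUROC as the explicit all-pairs probability that a case outscores a
# control, ties counting one half.
allPairsAuroc <- function(scores, isCase) {
    cs <- scores[isCase]; ct <- scores[!isCase]
    tot <- 0
    for (a in cs) for (b in ct)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
}

# small deterministic log-scale table for plumbing tests
toyTable <- function(n = 6L, m = 3L, seed = 1L) {
    set.seed(seed)
    vals <- matrix(rnorm(n * m), n, m,
                   dimnames = list(paste0("s", seq_len(n)),
                                   paste0("m", seq_len(m))))
    AbundanceTable(vals, rep(c("case", "ctrl"), each = n / 2),
                   scaleState = "log")
}

# random connected-ish edge list on k nodes (no self loops, unique pairs)
randomEdgeList <- function(k, pEdge = 0.45) {
    pairs <- t(utils::combn(k, 2L))
    keep <- runif(nrow(pairs)) < pEdge
    if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
    data.frame(i = paste0("n", pairs[keep, 1L]),
               j = paste0("n", pairs[keep, 2L]),
               stringsAsFactors = FALSE)
}

# wrap an edge table (i, j, weight) as a DifferentialNetwork for filter
# tests; weights are rescaled into the admissible [0, 2^gamma] range (the
# disparity filter is invariant under global weight scaling)
networkFromEdges <- function(et, gamma = 4, nodes = NULL) {
    if (nrow(et) && max(et$weight) > 2^gamma)
        et$weight <- et$weight * (0.9 * 2^gamma / max(et$weight))
    et$rhoCase <- rep(0, nrow(et)); et$rhoControl <- rep(0, nrow(et))
    et$pValue <- rep(0.01, nrow(et))
    new("DifferentialNetwork",
        nodes = nodes %||% sort(unique(c(et$i, et$j))),
        edgeTable = et[, c("i", "j", "rhoCase", "rhoControl",
                           "weight", "pValue")],
        gamma = gamma, pCutoff = 0.05, nPermutations = 100L,
        groupLabels = c("case", "ctrl"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
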