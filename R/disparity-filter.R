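#' Backbone: the multiscale backbone of a differential network
#'
#' Subgraph of a [DifferentialNetwork-class] retained by the disparity
#' filter. Each surviving edge is annotated with the filter statistic
#' \eqn{\alpha_{ij} = (1 - p_{ij})^{n_i - 1}} as seen from both endpoints;
#' an edge survives when at least one endpoint gives
#' \eqn{\alpha_{ij} < \alpha}.
#'
#' @slot nodes metabolites incident to at least one kept edge.
#' @slot isolatedNodes parent-network nodes not incident to a kept edge.
#' @slot edgeTable kept edges with their parent annotations plus columns
#'   \code{alphaI}, \code{alphaJ}.
#' @slot alphaCutoff the disparity-filter threshold.
#' @slot weightFraction kept weight / total parent weight.
#' @slot edgeFraction kept edges / total parent edges.
#' @slot groupLabels inherited \code{c(case, control)} orientation.
#'
#' @seealso [extractBackbone()]
#' @export
setClass("Backbone",
    slots = c(nodes = "character", isolatedNodes = "character",
              edgeTable = "data.frame", alphaCutoff = "numeric",
              weightFraction = "numeric", edgeFraction = "numeric",
              groupLabels = "character"))

.validBackbone <- function(object) {
    msg <- character()
    et <- object@edgeTable
    if (nrow(et)) {
        if (!all(pmin(et$alphaI, et$alphaJ) < object@alphaCutoff))
            msg <- c(msg, "kept edge fails the disparity criterion at both endpoints")
    }
    for (f in c("weightFraction", "edgeFraction")) {
        v <- slot(object, f)
        if (length(v) != 1L || v < 0 || v > 1)
            msg <- c(msg, paste(f, "must lie in [0, 1]"))
    }
    if (length(msg)) msg else TRUE
}

setValidity("Backbone", .validBackbone)

setMethod("show", "Backbone", function(object) {
    cat(sprintf("Backbone (alpha < %g): %d connected nodes, %d edges (%d isolated)\n",
                object@alphaCutoff, length(object@nodes),
                nrow(object@edgeTable), length(object@isolatedNodes)))
    cat(sprintf("  keeps %.1f%% of edges, %.1f%% of total weight\n",
                100 * object@edgeFraction, 100 * object@weightFraction))
})

#' @rdname edges
#' @export
setMethod("edges", "Backbone", function(x, ...) x@edgeTable)

#' @rdname nodes
#' @export
setMethod("nodes", "Backbone", function(x, ...) x@nodes)

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "Backbone", function(x, ...) {
    igraph::graph_from_data_frame(
        x@edgeTable, directed = FALSE,
        vertices = data.frame(name = x@nodes))
})

#' @rdname exportGraphML
#' @export
setMethod("exportGraphML", "Backbone", function(x, path, ...) {
    igraph::write_graph(asIgraph(x), path, format = "graphml")
    invisible(path)
})

#' Normalize the incident edge weights of a node
#'
#' \eqn{p_{ij} = w_{ij} / \sum_j w_{ij}} over the \eqn{n_i} edges of node
#' \eqn{i}.
#'
#' @param incidentWeights non-negative weights of one node's edges.
#' @return weights rescaled to sum to one.
#' @export
normalizeNodeWeights <- function(incidentWeights) {
    if (length(incidentWeights) == 0L || any(incidentWeights < 0))
        stop("incident weights must be a non-empty non-negative vector")
    s <- sum(incidentWeights)
    if (s <= 0)
        stop("degenerate node: all incident weights are zero")
    incidentWeights / s
}

#' Local disparity measure
#'
#' \eqn{Y(n_i) = n_i \sum_j p_{ij}^2}, a heterogeneity index over a node's
#' normalized incident weights: 1 under perfect homogeneity (all edges
#' equal), \eqn{n_i} under perfect heterogeneity (one edge carries all the
#' weight).
#'
#' @param normalizedWeights per-edge \eqn{p_{ij}} values summing to one.
#' @return the disparity measure, in \eqn{[1, n_i]}.
#' @examples
#' disparityMeasure(rep(0.2, 5))       # 1: perfect homogeneity
#' disparityMeasure(c(1, 0, 0, 0, 0))  # 5: one edge carries all weight
#' @export
disparityMeasure <- function(normalizedWeights) {
    if (abs(sum(normalizedWeights) - 1) > 1e-8)
        stop("normalized weights must sum to 1")
    length(normalizedWeights) * sum(normalizedWeights^2)
}

#' Disparity-filter significance of one edge end
#'
#' Probability, under the null model that a node's \eqn{n_i} normalized
#' weights arise from a uniform-random partition of the unit interval, that
#' one weight is at least \eqn{p_{ij}}:
#' \eqn{\alpha_{ij} = (1 - p_{ij})^{n_i - 1}}. A degree-1 endpoint returns
#' 1 exactly: its single edge carries all weight by necessity, not
#' organization, so it can never justify its own edge.
#'
#' @param pij normalized weight(s) in \eqn{[0, 1]}.
#' @param degree the node's degree \eqn{n_i \ge 1} (recycled).
#' @return \eqn{\alpha_{ij}} value(s) in \eqn{[0, 1]}.
#' @export
edgeAlpha <- function(pij, degree) {
    if (any(pij < 0 | pij > 1)) stop("normalized weights must lie in [0, 1]")
    if (any(degree < 1)) stop("degree must be at least 1")
    ifelse(degree == 1L, 1, (1 - pij)^(degree - 1))
}

#' Per-node disparity records of a network
#'
#' Degree and disparity measure of every non-isolated node, computed from
#' the node's locally normalized incident weights.
#'
#' @param network a [DifferentialNetwork-class] or [Backbone-class].
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{disparity}.
#' @seealso [disparityExponentFit()]
#' @export
disparityRecords <- function(network) {
    et <- edges(network)
    if (!nrow(et))
        return(data.frame(node = character(), degree = integer(),
                          disparity = numeric()))
    ends <- c(et$i, et$j)
    w <- rep(et$weight, 2L)
    byNode <- split(w, ends)
    data.frame(node = names(byNode),
               degree = lengths(byNode),
               disparity = vapply(byNode, function(wi)
                   disparityMeasure(normalizeNodeWeights(wi)), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the disparity-degree scaling exponent
#'
#' Ordinary least-squares slope of \eqn{\log Y} against \eqn{\log n_i} over
#' nodes of degree at least 2 (degree-1 nodes have \eqn{Y = 1} by
#' construction and carry no information), estimating the exponent \eqn{b}
#' in \eqn{Y(n_i) \propto n_i^{\,b}}. Real correlation networks typically
#' sit near \eqn{b = 1/2}, the regime where the disparity filter is most
#' useful.
#'
#' @param records the data.frame from [disparityRecords()].
#' @return the fitted exponent.
#' @export
disparityExponentFit <- function(records) {
    records <- records[records$degree >= 2L, , drop = FALSE]
    if (nrow(records) < 3L)
        stop("need at least 3 nodes of degree >= 2 to fit the exponent")
    unname(stats::coef(stats::lm(log(disparity) ~ log(degree),
                                 data = records))[2L])
}

#' Extract the multiscale backbone of a differential network
#'
#' For every edge, the filter statistic
#' \eqn{\alpha_{ij} = (1 - p_{ij})^{n_i - 1}} is evaluated from both
#' endpoints' local weight normalizations; the edge is kept when the
#' criterion \eqn{\alpha_{ij} < \alpha} holds for at least one of the two
#' nodes it joins. The retained fractions of parent edges and of total
#' parent weight are recorded.
#'
#' @param network a [DifferentialNetwork-class] with at least one edge (an
#'   empty network yields an empty backbone with zero fractions and a
#'   warning).
#' @param alphaCutoff disparity threshold in (0, 1), default 0.3.
#' @param ... unused.
#' @return a [Backbone-class].
#' @rdname extractBackbone
#' @export
setMethod("extractBackbone", "DifferentialNetwork",
          function(network, alphaCutoff = 0.3, ...) {
    if (alphaCutoff <= 0 || alphaCutoff >= 1)
        stop("alphaCutoff must lie strictly between 0 and 1")
    et <- network@edgeTable
    if (!nrow(et)) {
        warning("empty differential network: backbone is empty")
        return(new("Backbone", nodes = character(),
                   isolatedNodes = network@nodes,
                   edgeTable = cbind(et, alphaI = numeric(),
                                     alphaJ = numeric()),
                   alphaCutoff = alphaCutoff,
                   weightFraction = 0, edgeFraction = 0,
                   groupLabels = network@groupLabels))
    }
    strength <- tapply(c(et$weight, et$weight), c(et$i, et$j), sum)
    degree <- table(c(et$i, et$j))
    aFrom <- function(end) {
        pij <- et$weight / as.numeric(strength[end])
        edgeAlpha(pij, as.integer(degree[end]))
    }
    et$alphaI <- aFrom(et$i)
    et$alphaJ <- aFrom(et$j)
    keep <- pmin(et$alphaI, et$alphaJ) < alphaCutoff
    kept <- et[keep, , drop = FALSE]
    rownames(kept) <- NULL
    connected <- sort(unique(c(kept$i, kept$j)))
    new("Backbone", nodes = connected,
        isolatedNodes = setdiff(network@nodes, connected),
        edgeTable = kept, alphaCutoff = alphaCutoff,
        weightFraction = if (sum(et$weight) > 0)
            sum(kept$weight) / sum(et$weight) else 0,
        edgeFraction = nrow(kept) / nrow(et),
        groupLabels = network@groupLabels)
})
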