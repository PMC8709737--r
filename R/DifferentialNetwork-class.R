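#' DifferentialNetwork: significant differential correlations as a graph
#'
#' Weighted undirected graph over metabolites in which an edge joins two
#' metabolites whose differential association weight
#' \eqn{w_{ij} = |\rho_{case}(i,j) - \rho_{control}(i,j)|^{\gamma}} is
#' significant under the group-label permutation test. Every edge carries
#' the two per-group Pearson correlations, the weight, and the permutation
#' p-value. Isolated metabolites remain listed in \code{nodes}.
#'
#' @slot nodes all metabolite names, including isolated ones.
#' @slot edgeTable data.frame with columns \code{i}, \code{j},
#'   \code{rhoCase}, \code{rhoControl}, \code{weight}, \code{pValue}; one
#'   row per unordered significant pair.
#' @slot gamma the exponent of the differential weight (> 1).
#' @slot pCutoff edge-significance cut-off; every stored edge has
#'   \code{pValue < pCutoff}.
#' @slot nPermutations number of label permutations used.
#' @slot groupLabels length-2 character vector \code{c(case, control)}.
#'
#' @seealso [buildDifferentialNetwork()], [extractBackbone()]
#' @export
setClass("DifferentialNetwork",
    slots = c(nodes = "character", edgeTable = "data.frame",
              gamma = "numeric", pCutoff = "numeric",
              nPermutations = "integer", groupLabels = "character"))

.validDifferentialNetwork <- function(object) {
    msg <- character()
    et <- object@edgeTable
    need <- c("i", "j", "rhoCase", "rhoControl", "weight", "pValue")
    if (!all(need %in% colnames(et)))
        msg <- c(msg, "edgeTable must have columns i, j, rhoCase, rhoControl, weight, pValue")
    else if (nrow(et)) {
        if (any(et$i == et$j)) msg <- c(msg, "self-loop edge found")
        key <- paste(pmin(et$i, et$j), pmax(et$i, et$j))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate unordered edge")
        if (!all(c(et$i, et$j) %in% object@nodes))
            msg <- c(msg, "edge endpoint missing from nodes")
        if (any(et$pValue >= object@pCutoff))
            msg <- c(msg, "edge with pValue >= pCutoff")
        if (any(et$weight < 0) || any(et$weight > 2^object@gamma + 1e-12))
            msg <- c(msg, "edge weight outside [0, 2^gamma]")
    }
    if (object@gamma <= 1) msg <- c(msg, "gamma must exceed 1")
    if (length(object@groupLabels) != 2L)
        msg <- c(msg, "groupLabels must name the case and control levels")
    if (length(msg)) msg else TRUE
}

setValidity("DifferentialNetwork", .validDifferentialNetwork)

setMethod("show", "DifferentialNetwork", function(object) {
    cat(sprintf(
        "DifferentialNetwork: %d nodes, %d significant edges\n",
        length(object@nodes), nrow(object@edgeTable)))
    cat(sprintf("  gamma = %g, p < %g (%d permutations), case = '%s' vs control = '%s'\n",
                object@gamma, object@pCutoff, object@nPermutations,
                object@groupLabels[1L], object@groupLabels[2L]))
})

#' Edge table of a network or backbone
#' @param x a [DifferentialNetwork-class] or [Backbone-class].
#' @param ... unused.
#' @return data.frame, one row per edge.
#' @rdname edges
#' @export
setMethod("edges", "DifferentialNetwork", function(x, ...) x@edgeTable)

#' Node names of a network or backbone
#' @param x a [DifferentialNetwork-class] or [Backbone-class].
#' @param ... unused.
#' @return character vector.
#' @rdname nodes
#' @export
setMethod("nodes", "DifferentialNetwork", function(x, ...) x@nodes)

#' Convert to an igraph graph
#'
#' @param x a [DifferentialNetwork-class] or [Backbone-class].
#' @param ... unused.
#' @return an undirected \pkg{igraph} graph with edge attributes
#'   \code{weight} and \code{pValue} (plus \code{alphaI}/\code{alphaJ} for
#'   backbones).
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "DifferentialNetwork", function(x, ...) {
    igraph::graph_from_data_frame(
        x@edgeTable, directed = FALSE,
        vertices = data.frame(name = x@nodes))
})

#' Export a network as GraphML
#'
#' @param x a [DifferentialNetwork-class] or [Backbone-class].
#' @param path output file path.
#' @param ... unused.
#' @rdname exportGraphML
#' @export
setMethod("exportGraphML", "DifferentialNetwork", function(x, path, ...) {
    igraph::write_graph(asIgraph(x), path, format = "graphml")
    invisible(path)
})

#' Write an edge list as TSV
#'
#' Columns \code{node_i}, \code{node_j}, \code{rho_cases},
#' \code{rho_controls}, \code{weight}, \code{p_value}; backbones add
#' \code{alpha_i}, \code{alpha_j}.
#'
#' @param x a [DifferentialNetwork-class] or [Backbone-class].
#' @param path output file path.
#' @export
writeEdgeList <- function(x, path) {
    et <- edges(x)
    out <- data.frame(node_i = et$i, node_j = et$j,
                      rho_cases = et$rhoCase, rho_controls = et$rhoControl,
                      weight = et$weight, p_value = et$pValue)
    if (!is.null(et$alphaI)) {
        out$alpha_i <- et$alphaI
        out$alpha_j <- et$alphaJ
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
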