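#' Degree and betweenness centrality of a backbone
#'
#' Computes, for each connected backbone node, its degree (number of
#' backbone edges at the node) and shortest-path betweenness (how often the
#' node lies on shortest paths between other node pairs, with
#' Brandes-style fractional credit when a pair has several shortest
#' paths). The backbone is treated as an unweighted undirected graph by
#' default, matching the plain verbal definitions of hub (high degree) and
#' bottleneck (high betweenness); \code{weighted = TRUE} instead uses
#' shortest paths under edge distance \code{1/weight}. Betweenness is
#' first normalized by the \eqn{(N-1)(N-2)/2} pair-count convention and
#' both centralities are then min-max rescaled so their maxima are 1,
#' which makes the key-node product threshold comparable across networks.
#'
#' @param backbone a [Backbone-class].
#' @param weighted use \code{1/weight} edge distances for shortest paths.
#' @param keyThreshold threshold on \code{degree_norm * betweenness_norm}
#'   used to flag key nodes (strict \code{>}), default 0.5.
#' @param ... unused.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{degree_norm}, \code{betweenness}, \code{betweenness_norm},
#'   \code{key_score}, \code{is_key}; empty backbone gives an empty table.
#' @seealso [identifyKeyNodes()]
#' @rdname centralities
#' @export
setMethod("centralities", "Backbone",
          function(backbone, weighted = FALSE, keyThreshold = 0.5, ...) {
    empty <- data.frame(node = character(), degree = integer(),
                        degree_norm = numeric(), betweenness = numeric(),
                        betweenness_norm = numeric(), key_score = numeric(),
                        is_key = logical())
    if (!length(nodes(backbone))) return(empty)
    g <- asIgraph(backbone)
    deg <- igraph::degree(g)
    btwRaw <- igraph::betweenness(
        g, directed = FALSE,
        weights = if (weighted) 1 / igraph::E(g)$weight else NA)
    n <- igraph::vcount(g)
    btw <- if (n >= 3L) btwRaw / ((n - 1) * (n - 2) / 2) else btwRaw * 0
    degNorm <- if (max(deg) > 0) deg / max(deg) else deg * 0
    btwNorm <- if (max(btw) > 0) btw / max(btw) else btw * 0
    score <- degNorm * btwNorm
    data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
               degree_norm = unname(degNorm), betweenness = unname(btw),
               betweenness_norm = unname(btwNorm),
               key_score = unname(score),
               is_key = unname(score > keyThreshold),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' Key (hub-and-bottleneck) metabolites
#'
#' Nodes whose product of min-max-normalized degree and betweenness
#' strictly exceeds the threshold, sorted by that score descending: the
#' metabolites that are simultaneously hubs and bottlenecks of the
#' differential backbone.
#'
#' @param table a centrality table from [centralities()].
#' @param threshold non-negative product threshold, default 0.5.
#' @return character vector of node names.
#' @export
identifyKeyNodes <- function(table, threshold = 0.5) {
    if (threshold < 0) stop("threshold must be non-negative")
    hits <- table[table$key_score > threshold, , drop = FALSE]
    hits$node[order(hits$key_score, decreasing = TRUE)]
}

#' Write a centrality table as TSV
#'
#' @param table a centrality table from [centralities()].
#' @param path output file path.
#' @export
writeCentralityTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
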