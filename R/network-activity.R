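#' Select the seed set for network analysis
#'
#' The seed K is the set of over-expressed identifiers driving the
#' topology analysis: either every identifier with z >= 2
#' (\code{mode = "threshold"}) or the 200 highest-z identifiers
#' (\code{mode = "top"}; ties at the boundary broken by z then
#' lexicographic id so the selection is deterministic).  The seed is then
#' intersected with the network's nodes.
#'
#' @param zp a \code{\linkS4class{ZProfile}} keyed like the network nodes.
#' @param net an \code{\linkS4class{InteractionNetwork}}.
#' @param mode \code{"threshold"} or \code{"top"}.
#' @param threshold z cut for threshold mode (default 2).
#' @param topN seed size for top mode (default 200).
#' @return Character vector of seed node ids (possibly shorter than
#'   \code{topN} after intersection with the network).
#' @export
selectSeed <- function(zp, net, mode = c("threshold", "top"),
                       threshold = 2, topN = 200L) {
    mode <- match.arg(mode)
    z <- zScores(zp)
    if (!length(z)) stop("empty profile")
    ids <- if (mode == "threshold") {
        names(z)[z >= threshold]
    } else {
        ord <- order(-z, names(z))
        names(z)[ord][seq_len(min(topN, length(z)))]
    }
    intersect(ids, igraph::V(net@graph)$name)
}

#' Directed shortest-path network over a seed set
#'
#' Builds the subnetwork S: the union of every node and edge lying on any
#' shortest directed path from each seed to each other seed, traversing
#' non-seed nodes of the global network as necessary.  Ordered seed pairs
#' with no connecting path contribute nothing.
#'
#' @param net an \code{\linkS4class{InteractionNetwork}} (or igraph).
#' @param K character vector of seed node ids, length >= 2.
#' @return An igraph directed graph (possibly empty) whose vertices and
#'   edges all belong to the global network.
#' @examples
#' net <- interactionNetwork(data.frame(source = c("a", "b"),
#'                                      target = c("b", "c")))
#' igraph::E(shortestPathNetwork(net, c("a", "c")))
#' @export
shortestPathNetwork <- function(net, K) {
    g <- if (is(net, "InteractionNetwork")) net@graph else net
    K <- intersect(K, igraph::V(g)$name)
    if (length(K) < 2L) stop("need at least 2 seed nodes in the network")
    from <- character(); to <- character()
    for (k in K) {
        res <- suppressWarnings(igraph::all_shortest_paths(
            g, from = k, to = setdiff(K, k), mode = "out"))$res
        for (p in res) {
            v <- names(p)
            if (length(v) >= 2L) {
                from <- c(from, v[-length(v)])
                to <- c(to, v[-1L])
            }
        }
    }
    if (!length(from))
        return(igraph::make_empty_graph(directed = TRUE))
    eids <- unique(igraph::get_edge_ids(g, rbind(from, to)))
    igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
}

# ordered connected pairs (s, t), s != t, finite directed distance
.connectedPairs <- function(D) {
    idx <- which(is.finite(D) & row(D) != col(D), arr.ind = TRUE)
    cbind(s = rownames(D)[idx[, 1L]], t = colnames(D)[idx[, 2L]])
}

# is some shortest s->t path through both i and j?  True iff
# d(s,i)+d(i,j)+d(j,t) = d(s,t) or the same with i and j swapped.
# (endpoints count as on the path)

#' Count source-target pairs routed through node pairs
#'
#' For each unordered node pair (i, j), counts how many ordered pairs
#' (s, t) of the supplied universe have at least one shortest directed
#' s -> t path passing through both i and j (in either order along the
#' path; endpoints count).  This is the K_ij statistic when the graph is
#' the seed shortest-path network and the universe its ordered seed pairs,
#' and the N_ij statistic when both are taken from the global network.
#'
#' @param graph igraph directed graph.
#' @param universe two-column matrix or data.frame of ordered (s, t) node
#'   pairs; defaults to all connected ordered pairs of the graph.
#' @param candidates optional two-column matrix of (i, j) node pairs to
#'   count for; defaults to all unordered pairs of graph nodes (use the
#'   default only on small graphs).
#' @return data.frame with columns \code{i}, \code{j} (i < j
#'   lexicographically), \code{count}.
#' @export
pairCounts <- function(graph, universe = NULL, candidates = NULL) {
    g <- if (is(graph, "InteractionNetwork")) graph@graph else graph
    D <- igraph::distances(g, mode = "out")
    if (is.null(universe)) universe <- .connectedPairs(D)
    universe <- as.matrix(universe)
    if (nrow(universe)) {
        keep <- is.finite(D[universe]) & universe[, 1L] != universe[, 2L]
        universe <- universe[keep, , drop = FALSE]
    }
    nodes <- sort(igraph::V(g)$name)
    if (is.null(candidates)) {
        if (length(nodes) < 2L)
            return(data.frame(i = character(), j = character(),
                              count = integer()))
        candidates <- t(utils::combn(nodes, 2L))
    }
    candidates <- as.matrix(candidates)
    # canonical unordered orientation
    swap <- candidates[, 1L] > candidates[, 2L]
    candidates[swap, ] <- candidates[swap, c(2L, 1L), drop = FALSE]
    candidates <- unique(candidates)
    counts <- integer(nrow(candidates))
    if (nrow(universe)) {
        # integer indexing: the universe can hold ~|V|^2 pairs
        nm <- rownames(D)
        nV <- length(nm)
        si <- match(universe[, 1L], nm)
        ti <- match(universe[, 2L], nm)
        dst <- D[si + (ti - 1L) * nV]
        for (r in seq_len(nrow(candidates))) {
            ii <- match(candidates[r, 1L], nm)
            jj <- match(candidates[r, 2L], nm)
            dSi <- D[si + (ii - 1L) * nV]; dJt <- D[jj + (ti - 1L) * nV]
            dSj <- D[si + (jj - 1L) * nV]; dIt <- D[ii + (ti - 1L) * nV]
            via <- dSi + D[ii, jj] + dJt
            rev <- dSj + D[jj, ii] + dIt
            # i and j must be interior: a pair is connected *through*
            # (i, j), so its own endpoints do not count
            interior <- si != ii & si != jj & ti != ii & ti != jj
            counts[r] <- sum((via == dst | rev == dst) & interior)
        }
    }
    data.frame(i = candidates[, 1L], j = candidates[, 2L], count = counts,
               row.names = NULL)
}

#' Tail probability for a node pair's seed-path count
#'
#' Models the seed's ordered connected pairs as a draw of
#' \code{seedTotal} pairs from the global population of
#' \code{globalTotal} connected ordered pairs, of which \code{Nij} are
#' routed through the node pair (i, j), and returns the hypergeometric
#' upper-tail probability of observing \code{Kij} or more routed pairs in
#' the draw.  Small p marks a node pair carrying far more of the seed's
#' shortest-path traffic than the global topology predicts.
#'
#' @param Kij routed seed-pair count (in S).
#' @param Nij routed pair count in the global network.
#' @param globalTotal number of connected ordered pairs in the global
#'   network.
#' @param seedTotal number of connected ordered seed pairs.
#' @return p in (0, 1]; degenerate totals give 1.
#' @examples
#' nodePairProbability(3, 4, 10, 5)
#' @export
nodePairProbability <- function(Kij, Nij, globalTotal, seedTotal) {
    stopifnot(Kij >= 0, Nij >= Kij, globalTotal >= Nij,
              seedTotal >= Kij, globalTotal >= seedTotal)
    if (Kij == 0 || globalTotal == 0 || seedTotal == 0) return(1)
    phyper(Kij - 1, Nij, globalTotal - Nij, seedTotal, lower.tail = FALSE)
}

#' Network target activity method
#'
#' Infers active drug targets from topology: selects the over-expressed
#' seed, builds the directed shortest-path network S over it, counts for
#' every node pair how many seed pairs route through it (K_ij), compares
#' with the same count in the global network (N_ij) through the
#' hypergeometric tail, and maps significant node pairs to the drug
#' targets they contain.
#'
#' @param zp a \code{\linkS4class{ZProfile}} keyed like the network.
#' @param net an \code{\linkS4class{InteractionNetwork}} carrying the
#'   node -> drug target map.
#' @param mode,threshold,topN seed selection, see \code{\link{selectSeed}}.
#' @param alpha reporting threshold on p (default 0.05).
#' @return Calls data.frame (drug, method \code{"network-activity"},
#'   verdict indicated, genes = target node, p = best p over node pairs
#'   containing the target, score) plus attribute \code{"pairs"}: the
#'   per-node-pair K_ij/N_ij/p table.  Empty when the seed has fewer than
#'   2 connected members.
#' @export
runNetworkMethod <- function(zp, net, mode = "threshold", threshold = 2,
                             topN = 200L, alpha = 0.05) {
    stopifnot(is(net, "InteractionNetwork"))
    empty <- function() {
        out <- .emptyCalls()
        attr(out, "pairs") <- data.frame(i = character(), j = character(),
            Kij = integer(), Nij = integer(), p = numeric())
        out
    }
    K <- selectSeed(zp, net, mode = mode, threshold = threshold,
                    topN = topN)
    if (length(K) < 2L) {
        message("network method skipped: seed has fewer than 2 nodes")
        return(empty())
    }
    S <- shortestPathNetwork(net, K)
    if (igraph::vcount(S) == 0L) return(empty())
    Ds <- igraph::distances(S, mode = "out")
    seedIn <- intersect(K, rownames(Ds))
    seedPairs <- if (length(seedIn) >= 2L)
        .connectedPairs(Ds[seedIn, seedIn, drop = FALSE])
    else matrix(character(), 0L, 2L)
    if (!nrow(seedPairs)) return(empty())
    Ktab <- pairCounts(S, universe = seedPairs)
    cand <- Ktab[Ktab$count > 0L, , drop = FALSE]
    if (!nrow(cand)) return(empty())
    Dg <- igraph::distances(net@graph, mode = "out")
    globalTotal <- sum(is.finite(Dg) & row(Dg) != col(Dg))
    Ntab <- pairCounts(net@graph, candidates = as.matrix(cand[c("i", "j")]))
    pairs <- merge(cand, Ntab, by = c("i", "j"),
                   suffixes = c("K", "N"))
    names(pairs)[names(pairs) == "countK"] <- "Kij"
    names(pairs)[names(pairs) == "countN"] <- "Nij"
    pairs$p <- mapply(nodePairProbability, pairs$Kij, pairs$Nij,
                      MoreArgs = list(globalTotal = globalTotal,
                                      seedTotal = nrow(seedPairs)))
    sig <- pairs[pairs$p < alpha, , drop = FALSE]
    tmap <- net@targets
    rows <- lapply(unique(tmap$node), function(node) {
        inPair <- sig$i == node | sig$j == node
        if (!any(inPair)) return(NULL)
        bestP <- min(sig$p[inPair])
        data.frame(drug = sort(unique(tmap$drug[tmap$node == node])),
                   method = "network-activity", verdict = "indicated",
                   genes = node, z = NA_real_, p = bestP,
                   score = -log10(bestP))
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- .emptyCalls()
    else {
        # a drug may act on several implicated targets: keep its best p
        out <- .collapsePerDrug(out)
    }
    rownames(out) <- NULL
    attr(out, "pairs") <- pairs
    out
}
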