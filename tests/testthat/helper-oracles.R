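# Independent oracles for the rank, path and tail statistics.  These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the implementations they check.

# KS enrichment by definitional double loop over candidate suprema
oracleKsEnrichment <- function(ids, ranking) {
    V <- sort(match(ids, ranking))
    V <- V[!is.na(V)]
    t <- length(V); n <- length(ranking)
    if (!t) return(NA_real_)
    a <- -Inf; b <- -Inf
    for (j in seq_len(t)) {
        a <- max(a, j / t - V[j] / n)
        b <- max(b, V[j] / n - (j - 1) / t)
    }
    if (a > b) a else -b
}

# hypergeometric upper tail by direct combinatorial summation
oracleHyperTail <- function(K, N, total, draws) {
    if (K == 0) return(1)
    ks <- K:min(N, draws)
    sum(choose(N, ks) * choose(total - N, draws - ks)) /
        choose(total, draws)
}

# all simple directed paths between two nodes of an edge-list graph,
# by depth-first enumeration
.allSimplePaths <- function(edges, from, to) {
    out <- list()
    recurse <- function(path) {
        last <- path[length(path)]
        if (last == to) {
            out[[length(out) + 1L]] <<- path
            return(invisible())
        }
        nxt <- edges$target[edges$source == last]
        for (v in nxt) if (!v %in% path) recurse(c(path, v))
    }
    recurse(from)
    out
}

# exhaustive shortest-path machinery on small graphs: for each ordered
# pair of `universe`, enumerate every shortest path; S = union of their
# edges; count, for each unordered node pair, the universe pairs with at
# least one shortest path carrying both nodes as interior waypoints
oraclePathAnalysis <- function(edges, universe) {
    shortest <- list()
    for (r in seq_len(nrow(universe))) {
        s <- universe[r, 1L]; t <- universe[r, 2L]
        if (s == t) next
        paths <- .allSimplePaths(edges, s, t)
        if (!length(paths)) next
        len <- vapply(paths, length, integer(1L))
        shortest[[paste(s, t)]] <- paths[len == min(len)]
    }
    sEdges <- unique(do.call(rbind, lapply(unlist(shortest,
        recursive = FALSE), function(p)
            data.frame(source = p[-length(p)], target = p[-1L]))))
    nodes <- sort(unique(c(edges$source, edges$target)))
    counts <- list()
    if (length(nodes) >= 2L) {
        cmb <- t(combn(nodes, 2L))
        counts <- data.frame(i = cmb[, 1L], j = cmb[, 2L], count = 0L)
        for (r in seq_len(nrow(counts))) {
            i <- counts$i[r]; j <- counts$j[r]
            counts$count[r] <- sum(vapply(shortest, function(paths)
                any(vapply(paths, function(p) {
                    mid <- p[-c(1L, length(p))]
                    i %in% mid && j %in% mid
                }, logical(1L))), logical(1L)))
        }
    }
    list(sEdges = sEdges, counts = counts)
}

# small random directed graph as an edge list (no self loops)
randomEdgeList <- function(nNodes, nEdges, seed) {
    set.seed(seed)
    nodes <- letters[seq_len(nNodes)]
    e <- data.frame(source = sample(nodes, nEdges, replace = TRUE),
                    target = sample(nodes, nEdges, replace = TRUE))
    unique(e[e$source != e$target, , drop = FALSE])
}

# tiny profile constructor used across suites
zprof <- function(..., sampleId = "s1", space = "human-gene") {
    ZProfile(sampleId, c(...), space = space)
}
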