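chainNet <- interactionNetwork(data.frame(
    source = c("a", "b", "c"), target = c("b", "c", "d")))

test_that("seed selection thresholds, truncates and breaks ties", {
    z <- setNames(c(3, 2.5, 2, 1.9, -4), c("a", "b", "c", "d", "e"))
    zp <- ZProfile("s", z, "human-gene")
    expect_setequal(selectSeed(zp, chainNet), c("a", "b", "c"))
    expect_length(selectSeed(
        ZProfile("s", setNames(rep(0, 4), letters[1:4]), "human-gene"),
        chainNet), 0)
    # top mode takes exactly topN, ties resolved lexicographically
    zt <- setNames(c(5, 3, 3, 3, 1), c("e", "d", "b", "c", "a"))
    names(zt) <- c("e", "d", "b", "c", "a")
    big <- interactionNetwork(data.frame(
        source = c("a", "b", "c", "d"), target = c("b", "c", "d", "e")))
    top3 <- selectSeed(ZProfile("s", zt, "human-gene"), big,
                       mode = "top", topN = 3)
    expect_setequal(top3, c("e", "b", "c"))  # b, c beat d at z = 3
})

test_that("the shortest-path network is the union of all shortest paths", {
    S <- shortestPathNetwork(chainNet, c("a", "c"))
    ed <- igraph::as_data_frame(S)
    expect_equal(nrow(ed), 2)
    expect_setequal(paste(ed$from, ed$to), c("a b", "b c"))
    # two equal-length routes are both retained
    diamond <- interactionNetwork(data.frame(
        source = c("a", "a", "b", "d"), target = c("b", "d", "c", "c")))
    Sd <- shortestPathNetwork(diamond, c("a", "c"))
    edd <- igraph::as_data_frame(Sd)
    expect_setequal(paste(edd$from, edd$to),
                    c("a b", "a d", "b c", "d c"))
    # disconnected seeds give an empty subnetwork
    iso <- interactionNetwork(data.frame(source = c("a", "c"),
                                         target = c("b", "d")))
    expect_equal(igraph::vcount(shortestPathNetwork(iso, c("b", "c"))),
                 0)
})

test_that("pair counts match the chain example and bounds", {
    counts <- pairCounts(chainNet@graph,
                         universe = cbind("a", "d"))
    expect_equal(counts$count[counts$i == "b" & counts$j == "c"], 1)
    # every pair containing an off-path node counts zero
    loose <- interactionNetwork(data.frame(
        source = c("a", "b", "a"), target = c("b", "c", "x")))
    c2 <- pairCounts(loose@graph, universe = cbind("a", "c"))
    expect_true(all(c2$count[c2$i == "x" | c2$j == "x"] == 0))
})

test_that("S, K_ij and N_ij agree with exhaustive path enumeration", {
    for (seed in 1:8) {
        edges <- randomEdgeList(nNodes = sample(6:12, 1), nEdges = 24,
                                seed = seed)
        g <- igraph::graph_from_data_frame(edges, directed = TRUE)
        D <- igraph::distances(g, mode = "out")
        conn <- which(is.finite(D) & row(D) != col(D), arr.ind = TRUE)
        universe <- cbind(rownames(D)[conn[, 1]],
                          colnames(D)[conn[, 2]])
        oracle <- oraclePathAnalysis(edges, universe)
        got <- pairCounts(g, universe = universe)
        merged <- merge(got, oracle$counts, by = c("i", "j"),
                        all = TRUE, suffixes = c("Got", "Oracle"))
        merged[is.na(merged)] <- 0L
        expect_equal(merged$countGot, merged$countOracle,
                     label = paste("seed", seed))
        # S on a random seed set agrees with enumerated shortest paths
        nodes <- igraph::V(g)$name
        K <- sample(nodes, min(4L, length(nodes)))
        S <- shortestPathNetwork(g, K)
        seedUni <- as.matrix(expand.grid(K, K,
                                         stringsAsFactors = FALSE))
        oS <- oraclePathAnalysis(edges, seedUni)$sEdges
        gotEdges <- igraph::as_data_frame(S)
        if (is.null(oS)) {
            expect_equal(nrow(gotEdges), 0)
        } else {
            expect_setequal(paste(gotEdges$from, gotEdges$to),
                            paste(oS$source, oS$target))
        }
    }
})

test_that("node-pair probability equals the combinatorial tail sum", {
    expect_equal(nodePairProbability(3, 4, 10, 5),
                 oracleHyperTail(3, 4, 10, 5), tolerance = 1e-12)
    expect_equal(nodePairProbability(0, 4, 10, 5), 1)
    # exhaustive draw: outcome certain
    expect_equal(nodePairProbability(4, 4, 10, 10), 1)
    set.seed(2)
    for (i in 1:25) {
        total <- sample(5:40, 1)
        N <- sample.int(total, 1)
        draws <- sample.int(total, 1)
        K <- sample.int(min(N, draws), 1)
        expect_equal(nodePairProbability(K, N, total, draws),
                     oracleHyperTail(K, N, total, draws),
                     tolerance = 1e-10)
    }
    # monotone: p decreases as K_ij grows, other counts fixed
    ps <- vapply(1:5, nodePairProbability, numeric(1L),
                 Nij = 8, globalTotal = 60, seedTotal = 12)
    expect_true(all(diff(ps) < 0))
})

test_that("a planted hub funnel is recovered and nulls stay quiet", {
    cfg <- simConfig(seed = 19, kbSizes = list(targetRules = 40L,
        targetDrugs = 30L, networkExtraNodes = 20L,
        networkEdges = 240L))
    kb <- simulateKnowledgeBases(cfg)
    fl <- kb$funnel
    z <- setNames(rep(0, length(igraph::V(kb$network@graph))),
                  igraph::V(kb$network@graph)$name)
    z[c(fl$sources, fl$sinks)] <- 5
    zp <- ZProfile("s", z, "human-gene")
    calls <- runNetworkMethod(zp, kb$network)
    hubDrugs <- kb$targetRules$drug[kb$targetRules$gene == fl$hub]
    expect_true(all(hubDrugs %in% calls$drug))
    pairs <- attr(calls, "pairs")
    funnelPair <- pairs[pairs$i %in% c(fl$hub, fl$relay) &
                        pairs$j %in% c(fl$hub, fl$relay), ]
    expect_equal(nrow(funnelPair), 1)
    # every ordered source -> sink seed pair routes through (hub, relay)
    expect_gte(funnelPair$Kij, length(fl$sources) * length(fl$sinks))
    expect_lt(funnelPair$p, 0.05)
    expect_true(all(pairs$Kij <= pairs$Nij))
    # null profile: seed too small, method skips
    z0 <- setNames(rep(0, 5), igraph::V(kb$network@graph)$name[1:5])
    expect_message(
        out <- runNetworkMethod(ZProfile("s", z0, "human-gene"),
                                kb$network),
        "skipped")
    expect_equal(nrow(out), 0)
})
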