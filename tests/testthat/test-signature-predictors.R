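test_that("query construction thresholds at +/-2 inclusively", {
    q <- buildQuery(zprof(a = 2.5, b = -2.5, c = 0, d = 2.0, e = -1.99))
    expect_setequal(q$up, c("a", "d"))
    expect_equal(q$down, "b")
    expect_length(intersect(q$up, q$down), 0)
    qe <- buildQuery(zprof(a = 1.5, b = -1.5))
    expect_length(qe$up, 0)
    expect_length(qe$down, 0)
})

test_that("KS enrichment matches hand-worked values and the oracle", {
    universe <- paste0("g", 1:10)
    expect_equal(ksEnrichment(c("g1", "g2"), universe), 0.8)
    # bottom-of-list set: near-mirror magnitude (the running statistic is
    # offset by one rank step between its two suprema, so |ES| differs
    # from the top-set case by 1/n)
    expect_equal(ksEnrichment(c("g9", "g10"), universe), -0.9)
    expect_equal(ksEnrichment(c("g9", "g10"), universe),
                 oracleKsEnrichment(c("g9", "g10"), universe))
    expect_true(is.na(ksEnrichment("absent", universe)))
    set.seed(11)
    for (i in 1:50) {
        n <- sample(5:60, 1)
        uni <- paste0("u", seq_len(n))
        t <- sample.int(n - 1, 1)
        ids <- sample(uni, t)
        es <- ksEnrichment(ids, uni)
        expect_equal(es, oracleKsEnrichment(ids, uni), tolerance = 1e-12)
        expect_lte(abs(es), 1)
    }
})

test_that("connectivity combines sides the CMAP way", {
    uni <- paste0("g", 1:20)
    # up-set at the signature bottom, down-set at the top: reversal
    rev <- connectivityScore(list(up = c("g19", "g20"),
                                  down = c("g1", "g2")), uni)
    expect_lt(rev$s, -0.8)
    fwd <- connectivityScore(list(up = c("g1", "g2"),
                                  down = c("g19", "g20")), uni)
    expect_gt(fwd$s, 0.8)
    expect_equal(fwd$s, -rev$s)  # antisymmetric under set swap
    # same-sign enrichment is incoherent: s = 0
    same <- connectivityScore(list(up = c("g1", "g2"),
                                   down = c("g3", "g4")), uni)
    expect_true(same$esUp > 0 && same$esDown > 0)
    expect_equal(same$s, 0)
    expect_null(connectivityScore(list(up = "x", down = "y"), uni))
})

test_that("permutation p is seeded, bounded and minimal at s = -1", {
    p1 <- permutationPvalue(-1, 3, 3, 50, nPerm = 999, seed = 7)
    p2 <- permutationPvalue(-1, 3, 3, 50, nPerm = 999, seed = 7)
    expect_identical(p1, p2)
    expect_equal(p1, 1 / 1000)
    expect_gte(permutationPvalue(-0.2, 3, 3, 50, nPerm = 99, seed = 1),
               1 / 100)
    expect_lte(permutationPvalue(1, 3, 3, 50, nPerm = 99, seed = 1), 1)
})

test_that("null permutation p values are valid and tail-calibrated", {
    # the connectivity score has an atom at s = 0 (same-sign rule), so
    # null p values are super-uniform rather than exactly uniform; what
    # reporting relies on is the lower tail, which must be calibrated
    set.seed(23)
    n <- 40L; tUp <- 3L; tDown <- 3L; nPerm <- 199L
    uni <- paste0("g", seq_len(n))
    ps <- vapply(seq_len(500L), function(i) {
        picks <- sample(uni, tUp + tDown)
        q <- list(up = picks[seq_len(tUp)],
                  down = picks[tUp + seq_len(tDown)])
        s <- connectivityScore(q, uni)$s
        permutationPvalue(s, tUp, tDown, n, nPerm = nPerm)
    }, numeric(1L))
    # super-uniform: P(p <= x) never exceeds x by more than noise
    for (x in c(0.01, 0.05, 0.1, 0.25))
        expect_lt(mean(ps <= x), x + 3 * sqrt(x * (1 - x) / 500))
    # and the reporting tail is calibrated, not merely bounded
    expect_gt(binom.test(sum(ps < 0.05), 500, 0.05)$p.value, 0.01)
})

test_that("the response method reports planted reversals and not nulls", {
    set.seed(5)
    uni <- paste0("g", 1:80)
    sigs <- lapply(1:6, function(i) sample(uni))
    names(sigs) <- paste0("drug", 1:6)
    # tumor whose up-genes sit at the bottom of drug3's ranking and
    # down-genes at its top: the planted reversal
    target <- sigs[["drug3"]]
    z <- setNames(rep(0, 80), uni)
    z[target[1:6]] <- -3
    z[target[75:80]] <- 3
    calls <- runResponseMethod(ZProfile("s", z, "human-gene"), sigs,
                               nPerm = 2000, seed = 9)
    expect_true("drug3" %in% calls$drug)
    scanned <- attr(calls, "scanned")
    expect_equal(nrow(scanned), 6)
    expect_lt(scanned$s[scanned$drug == "drug3"], 0)
    # null profile: nothing reported
    null <- runResponseMethod(zprof(a = 0.1, b = -0.2), sigs,
                              nPerm = 500, seed = 9)
    expect_equal(nrow(null), 0)
})

test_that("PGSEA equals the closed-form one-sample t-test", {
    zp <- zprof(a = 1, b = 2, c = 3)
    r <- pgseaScore(zp, data.frame(gene = c("a", "b", "c"), sign = 1))
    expect_equal(r$t, 3.464, tolerance = 1e-3)
    expect_equal(r$df, 2)
    expect_equal(r$p, 0.0371, tolerance = 1e-3)
    # oracle: stats::t.test on the same numbers
    tt <- t.test(c(1, 2, 3), alternative = "greater")
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    # antisymmetry under sign flip
    rNeg <- pgseaScore(zp, data.frame(gene = c("a", "b", "c"),
                                      sign = -1))
    expect_equal(rNeg$t, -r$t)
    # degenerate all-zero vector
    r0 <- pgseaScore(zprof(a = 0, b = 0, c = 0),
                     data.frame(gene = c("a", "b", "c"), sign = 1))
    expect_equal(r0$t, 0)
    expect_equal(r0$p, 0.5)
    # fewer than 2 genes in the profile: no result
    expect_null(pgseaScore(zprof(a = 1),
                data.frame(gene = c("a", "zz"), sign = 1)))
    # randomized equality with the t.test oracle
    set.seed(3)
    for (i in 1:20) {
        m <- sample(3:12, 1)
        z <- setNames(rnorm(m), paste0("g", seq_len(m)))
        sg <- sample(c(-1, 1), m, replace = TRUE)
        r <- pgseaScore(ZProfile("s", z, "human-gene"),
                        data.frame(gene = names(z), sign = sg))
        tt <- t.test(sg * z, alternative = "greater")
        expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
        expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    }
})

test_that("the sensitivity method filters at p < 0.05 and recovers plants", {
    set.seed(6)
    genes <- paste0("g", 1:40)
    sigs <- lapply(1:5, function(i)
        data.frame(gene = sample(genes, 8),
                   sign = sample(c(1, -1), 8, replace = TRUE)))
    names(sigs) <- paste0("drug", 1:5)
    # align the tumor with drug2's signature: z = 3 * sign
    z <- setNames(rep(0, 40), genes)
    z[sigs[["drug2"]]$gene] <- 3 * sigs[["drug2"]]$sign
    calls <- runSensitivityMethod(ZProfile("s", z, "human-gene"), sigs)
    expect_true("drug2" %in% calls$drug)
    expect_true(all(calls$p < 0.05))
    expect_equal(nrow(attr(calls, "scanned")), 5)
})
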