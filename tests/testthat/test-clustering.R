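test_that("correlation distance hits its landmark values", {
    f <- c(1, 2, 3, 4)
    m <- cbind(s1 = f, s2 = f * 2 + 1, s3 = rev(f),
               s4 = c(1, -1, 1, -1) + f * 0)
    d <- pearsonDistance(m)
    expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)   # identical shape
    expect_equal(d["s1", "s3"], 2, tolerance = 1e-12)   # anticorrelated
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 2 + 1e-12))
    # orthogonal profiles sit at distance 1
    m2 <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
    expect_equal(pearsonDistance(m2)["a", "b"], 1, tolerance = 1e-12)
    expect_error(pearsonDistance(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "zero-variance.*a")
})

test_that("classical MDS reconstructs planted Euclidean configurations", {
    set.seed(12)
    xy <- matrix(rnorm(2 * 15), 15, 2)
    rownames(xy) <- paste0("s", 1:15)
    D <- as.matrix(dist(xy))
    emb <- classicalMDS(D, k = 2)
    expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(unname(colMeans(emb$points)), c(0, 0),
                 tolerance = 1e-10)
    expect_true(all(diff(emb$eig) <= 1e-8))
    # n = 2 closed form: points at +/- d/2
    d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
    e2 <- classicalMDS(d2, k = 1)
    expect_equal(sort(e2$points[, 1]), c(-1.5, 1.5),
                 ignore_attr = TRUE)
    # duplicated samples land on the same point
    xy3 <- rbind(xy, s16 = xy[1, ])
    D3 <- as.matrix(dist(xy3))
    e3 <- classicalMDS(D3, k = 2)
    expect_equal(e3$points["s16", ], e3$points["s1", ],
                 tolerance = 1e-8)
    # deterministic under sample reordering (up to the same embedding)
    ord <- sample(nrow(D))
    e4 <- classicalMDS(D[ord, ord], k = 2)
    expect_equal(as.matrix(dist(e4$points))[rownames(D), rownames(D)],
                 as.matrix(dist(emb$points)), tolerance = 1e-8)
    expect_error(classicalMDS(D, k = 0), "k must be")
})

test_that("silhouette separates planted clusters and not random labels", {
    set.seed(9)
    pts <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
                 matrix(rnorm(40, 5, 0.3), ncol = 2))
    labels <- rep(c("A", "B"), each = 20)
    expect_gt(clusterSeparation(pts, labels), 0.5)
    expect_lt(abs(clusterSeparation(pts, sample(labels))), 0.25)
    same <- matrix(1, 6, 2)
    expect_lte(clusterSeparation(same, rep(c("A", "B"), 3)), 0)
    expect_error(clusterSeparation(pts, rep("A", 40)), "2 distinct")
})

test_that("synthetic cohorts cluster by planted cancer type", {
    cfg <- simConfig(seed = 41, nProbes = 800, typeEffect = 2,
                     nTumorsPerType = c(TCC = 5L, lymphoma = 5L,
                                        melanoma = 5L))
    ex <- simulateExpression(cfg)
    st <- computeReferenceStats(ex$reference)
    zmat <- vapply(colnames(ex$tumors), function(s)
        zScores(zscoreSample(ex$tumors[, s], st, sampleId = s)),
        numeric(nrow(ex$tumors)))
    emb <- classicalMDS(pearsonDistance(zmat), k = 2)
    types <- ex$truth$cancerType[rownames(emb$points)]
    expect_gt(clusterSeparation(emb$points, types), 0)
})

test_that("patient-specific drug perturbations blur type structure", {
    # same planted cohort, but drug scores are driven by per-patient
    # perturbations: expression clustering should respect type labels
    # more than drug-score clustering does
    cfg0 <- simConfig(seed = 43, nProbes = 800, typeEffect = 2,
                      nTumorsPerType = c(TCC = 4L, lymphoma = 4L))
    ann <- simulateAnnotation(cfg0)
    kb <- simulateKnowledgeBases(simConfig(seed = 43, nProbes = 800,
        nTumorsPerType = c(TCC = 4L, lymphoma = 4L),
        kbSizes = list(targetRules = 30L, targetDrugs = 30L,
                       networkEdges = 200L)))
    cfgKb <- simConfig(seed = 43, nProbes = 800,
        nTumorsPerType = c(TCC = 4L, lymphoma = 4L),
        kbSizes = list(targetRules = 30L, targetDrugs = 30L,
                       networkEdges = 200L))
    samples <- sprintf("%s_%02d", rep(c("TCC", "lymphoma"), each = 4),
                       rep(1:4, 2))
    set.seed(101)
    planted <- do.call(rbind, lapply(samples, function(s)
        data.frame(sample = s,
                   gene = humanToCanine(sample(kb$targetRules$gene, 3),
                                        cfgKb),
                   shift = 6)))
    cfg <- simConfig(seed = 43, nProbes = 800, typeEffect = 2,
        nTumorsPerType = c(TCC = 4L, lymphoma = 4L),
        plantedTargets = planted,
        kbSizes = list(targetRules = 30L, targetDrugs = 30L,
                       networkEdges = 200L))
    ex <- simulateExpression(cfg)
    st <- computeReferenceStats(ex$reference)
    zps <- profileCohort(ex$tumors, st, ann$canineAnnot, ann$homologs)
    zmat <- vapply(zps, zScores, numeric(length(zScores(zps[[1]]))))
    reports <- lapply(zps, function(zp) compileReport(list(
        applyTargetRules(zp, kb$targetRules),
        applyBiomarkerRules(zp, kb$biomarkerRules)), sampleId(zp)))
    dsm <- drugScoreMatrix(reports)
    types <- ex$truth$cancerType[colnames(zmat)]
    silExpr <- clusterSeparation(
        classicalMDS(pearsonDistance(zmat), k = 2)$points, types)
    silDrug <- clusterSeparation(
        classicalMDS(pearsonDistance(dsm + matrix(rnorm(length(dsm),
            0, 1e-6), nrow(dsm))), k = 2)$points,
        ex$truth$cancerType[colnames(dsm)])
    expect_gt(silExpr, silDrug)
})
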