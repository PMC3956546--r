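test_that("fixed seed regenerates every artifact identically", {
    cfg <- simConfig(seed = 42, nProbes = 400, nTypeGenes = 10L,
                     kbSizes = list(targetRules = 30L, targetDrugs = 20L,
                                    networkEdges = 150L))
    expect_identical(simulateExpression(cfg), simulateExpression(cfg))
    kb1 <- simulateKnowledgeBases(cfg)
    kb2 <- simulateKnowledgeBases(cfg)
    flat <- function(kb) {
        kb$network <- list(igraph::as_data_frame(kb$network@graph,
                                                 what = "both"),
                           kb$network@targets)
        kb
    }
    expect_identical(flat(kb1), flat(kb2))
    expect_identical(simulateAnnotation(cfg), simulateAnnotation(cfg))
    # and the generator does not disturb the caller's RNG stream
    set.seed(99); before <- .Random.seed
    invisible(simulateExpression(cfg))
    expect_identical(before, .Random.seed)
})

test_that("generated dimensions and knowledge-base sizes follow the config", {
    cfg <- simConfig(seed = 3, nProbes = 400, nRefSamples = 40, nTypeGenes = 10L)
    ex <- simulateExpression(cfg)
    expect_equal(ncol(ex$reference), 40)
    expect_equal(ncol(ex$tumors), sum(c(4, 5, 5, 10)))
    kb <- simulateKnowledgeBases(simConfig(seed = 3))
    expect_equal(nrow(kb$targetRules), 260)
    expect_equal(length(unique(kb$targetRules$gene)), 260)
    expect_equal(length(unique(kb$targetRules$drug)), 123)
    expect_equal(nrow(kb$biomarkerRules), 34)
    expect_equal(length(kb$responseSignatures), 107)
    expect_equal(length(kb$sensitivitySignatures), 11)
    expect_equal(length(kb$drugPool), 184)
    small <- simulateKnowledgeBases(simConfig(seed = 3,
        kbSizes = list(targetRules = 5L, targetDrugs = 5L)))
    expect_equal(nrow(small$targetRules), 5)
    expect_error(simConfig(seed = 1, nProbes = 0), "positive")
    expect_error(simConfig(seed = 1, fracAmbiguous = 1), "fracAmbiguous")
})

test_that("unperturbed tumors are standard normal against the reference", {
    cfg <- simConfig(seed = 7, nProbes = 1000, typeEffect = 0,
                     nTumorsPerType = c(open = 6L))
    ex <- simulateExpression(cfg)
    st <- computeReferenceStats(ex$reference)
    zbar <- vapply(colnames(ex$tumors), function(s)
        mean(zScores(zscoreSample(ex$tumors[, s], st, sampleId = s))),
        numeric(1L))
    expect_lt(mean(abs(zbar)), 0.2)
    zsd <- sd(zScores(zscoreSample(ex$tumors[, 1L], st, sampleId = "a")))
    expect_lt(abs(zsd - 1), 0.15)
})

test_that("homolog table plants the requested ambiguity", {
    bij <- simulateHomologTable(simConfig(seed = 5, nProbes = 400, nTypeGenes = 10L,
                                          fracAmbiguous = 0))
    expect_false(any(bij$ambiguous))
    expect_false(anyDuplicated(bij$canine) > 0)
    expect_false(anyDuplicated(bij$human) > 0)

    tab <- simulateHomologTable(simConfig(seed = 5, nProbes = 400, nTypeGenes = 10L,
                                          fracAmbiguous = 0.2))
    nGenes <- length(unique(tab$canine))
    expect_equal(length(unique(tab$canine[tab$ambiguous])),
                 round(0.2 * nGenes))
})

test_that("knowledge bases only reference genes surviving the full chain", {
    cfg <- simConfig(seed = 13, nProbes = 800,
                     kbSizes = list(targetRules = 40L, targetDrugs = 20L,
                                    networkEdges = 200L))
    ann <- simulateAnnotation(cfg)
    kb <- simulateKnowledgeBases(cfg)
    reachable <- ann$strict$human
    expect_true(all(kb$targetRules$gene %in% reachable))
    expect_true(all(kb$biomarkerRules$gene %in% reachable))
    expect_true(all(unlist(kb$responseSignatures) %in% reachable))
    expect_true(all(vapply(kb$sensitivitySignatures,
        function(d) all(d$gene %in% reachable), logical(1L))))
    # every rule target is a network node
    expect_true(all(kb$targetRules$gene %in%
                    igraph::V(kb$network@graph)$name))
    # the exemplar rules are present and consistently labeled
    expect_true(any(kb$targetRules$gene == "EGFR" &
                    kb$targetRules$drug == "cetuximab"))
    expect_true(any(kb$biomarkerRules$gene == "ERCC1" &
                    kb$biomarkerRules$drug == "oxaliplatin" &
                    kb$biomarkerRules$effect == "resistant"))
    expect_equal(humanToCanine("EGFR", cfg),
                 ann$strict$canine[ann$strict$human == "EGFR"])
})

test_that("the QC fixture carries the printed failure metrics", {
    fx <- qcFixtureTable()
    expect_equal(nrow(fx), 31)
    expect_equal(fx$rin[fx$sample_id == "0507"], 2.60)
    expect_equal(fx$tumor_nuclei_category[fx$sample_id == "0506"],
                 "0-24%")
    expect_equal(fx$necrosis_category[fx$sample_id == "0503"], ">20%")
    expect_equal(fx$rna_conc[fx$sample_id == "1301"], 16.67)
    expect_equal(as.vector(table(fx$cohort)[c("TCC", "lymphoma",
        "melanoma", "open")]), c(5, 5, 6, 15))
})

test_that("event logs round-trip their requested business-hours spans", {
    cal <- businessCalendar(holidays = usHolidays2011())
    targets <- data.frame(
        sample_id = c("a", "b", "c"), cohort = "x",
        business_hours = c(116.46, 5, 0))
    logs <- simulateEventLogs(targets, cal, seed = 21)
    got <- caseTurnaround(logs, cal)
    expect_equal(got[match(targets$sample_id, got$sample_id),
                     "business_hours"],
                 targets$business_hours, tolerance = 0.01,
                 ignore_attr = TRUE)
    # zero-duration case: all events coincide
    tc <- logs$time[logs$sample_id == "c"]
    expect_equal(length(unique(parseEventTime(tc))), 1L)
    # a span inside one business day has business hours = wall hours
    gb <- got[got$sample_id == "b", ]
    expect_equal(gb$business_hours, gb$total_hours)
    expect_identical(simulateEventLogs(targets, cal, seed = 21), logs)
})
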