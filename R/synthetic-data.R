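#' SimConfig: synthetic study configuration
#'
#' Describes the synthetic study the generator emulates: a normal-tissue
#' reference compendium, tumor cohorts carrying shared cancer-type
#' signatures and patient-specific planted perturbations of drug-relevant
#' genes, knowledge bases sized like the study's, and a cross-species
#' homolog table with a controlled fraction of ambiguous mappings.  A
#' fixed seed makes every generated artifact bit-identical across calls.
#'
#' @slot seed integer RNG seed.
#' @slot nRefSamples reference compendium size (default 40).
#' @slot nProbes canine array probes simulated.
#' @slot probesPerGene inclusive integer range of probes per gene.
#' @slot nTumorsPerType named integer vector: tumors per cancer-type
#'   cohort.
#' @slot typeEffect planted cancer-type signature size, in z units.
#' @slot nTypeGenes genes carrying each type signature.
#' @slot plantedTargets data.frame (sample, gene, shift): patient-specific
#'   z-unit perturbations, gene in canine-gene ids.
#' @slot kbSizes named list of knowledge-base sizes (see
#'   \code{\link{simConfig}}).
#' @slot fracAmbiguous fraction of canine genes given ambiguous homolog
#'   mappings, in [0, 1).
#' @exportClass SimConfig
setClass("SimConfig",
    representation(seed = "integer", nRefSamples = "integer",
        nProbes = "integer", probesPerGene = "integer",
        nTumorsPerType = "integer", typeEffect = "numeric",
        nTypeGenes = "integer", plantedTargets = "data.frame",
        kbSizes = "list", fracAmbiguous = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nRefSamples < 2L || object@nProbes < 1L ||
        any(object@nTumorsPerType < 1L) || object@nTypeGenes < 1L)
        msg <- c(msg, "all counts must be positive")
    if (length(object@probesPerGene) != 2L ||
        any(object@probesPerGene < 1L))
        msg <- c(msg, "probesPerGene must be a positive integer range")
    if (object@fracAmbiguous < 0 || object@fracAmbiguous >= 1)
        msg <- c(msg, "fracAmbiguous must lie in [0, 1)")
    if (is.null(names(object@nTumorsPerType)))
        msg <- c(msg, "nTumorsPerType must be named by cancer type")
    if (any(vapply(object@kbSizes, function(x) x < 1, logical(1L))))
        msg <- c(msg, "kbSizes must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a synthetic study configuration
#'
#' Defaults mirror the study conditions: a 40-sample normal reference
#' (the deposited reference series is described with both 39 and 40
#' samples; the count is a parameter), four tumor cohorts of 4/5/5/10
#' passing samples, a 2 z-unit type signature on 50 genes per type, and
#' knowledge bases of 260 drug-target rules covering 123 drugs, 34
#' biomarker rules, 107 response-signature drugs, 11 sensitivity-signature
#' drugs and a 184-drug pool.
#'
#' @param seed integer seed; fixed seed means byte-identical artifacts.
#' @param nRefSamples,nProbes,probesPerGene,nTumorsPerType see slots.
#' @param typeEffect,nTypeGenes planted type-signature size and breadth.
#' @param plantedTargets data.frame (sample, gene, shift) of
#'   patient-specific perturbations in canine-gene ids and z units.
#' @param kbSizes named list overriding any of: targetRules, targetDrugs,
#'   biomarkerRules, responseDrugs, signatureUniverse, sensitivityDrugs,
#'   sensitivityGenes, drugPool, networkExtraNodes, networkEdges.
#' @param fracAmbiguous fraction of canine genes with ambiguous homology.
#' @return A validated \code{\linkS4class{SimConfig}}.
#' @examples
#' cfg <- simConfig(seed = 7, nProbes = 300)
#' @export
simConfig <- function(seed = 1L, nRefSamples = 40L, nProbes = 2000L,
                      probesPerGene = c(1L, 3L),
                      nTumorsPerType = c(TCC = 4L, lymphoma = 5L,
                                         melanoma = 5L, open = 10L),
                      typeEffect = 2, nTypeGenes = 50L,
                      plantedTargets = data.frame(sample = character(),
                          gene = character(), shift = numeric()),
                      kbSizes = list(), fracAmbiguous = 0.1) {
    defaults <- list(targetRules = 260L, targetDrugs = 123L,
        biomarkerRules = 34L, responseDrugs = 107L,
        signatureUniverse = 200L, sensitivityDrugs = 11L,
        sensitivityGenes = 10L, drugPool = 184L,
        networkExtraNodes = 40L, networkEdges = 900L)
    defaults[names(kbSizes)] <- kbSizes
    new("SimConfig", seed = as.integer(seed),
        nRefSamples = as.integer(nRefSamples),
        nProbes = as.integer(nProbes),
        probesPerGene = as.integer(probesPerGene),
        nTumorsPerType = setNames(as.integer(nTumorsPerType),
                                  names(nTumorsPerType)),
        typeEffect = typeEffect, nTypeGenes = as.integer(nTypeGenes),
        plantedTargets = as.data.frame(plantedTargets),
        kbSizes = defaults, fracAmbiguous = fracAmbiguous)
}

# run expr under a derived seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# deterministic identifier catalog shared by all generators:
# canine probes -> canine genes -> human genes -> human probesets,
# with planted homolog ambiguity and a strict "clean" gene subset
.catalog <- function(config) {
    .withSeed(config@seed + 104729L, {
        nP <- config@nProbes
        probes <- sprintf("CfaAffy.%05d_at", seq_len(nP))
        nUnannot <- round(0.05 * nP)
        annotated <- sort(sample.int(nP, nP - nUnannot))
        sizes <- integer()
        left <- length(annotated)
        while (left > 0L) {
            s <- sample(seq(config@probesPerGene[1L],
                            config@probesPerGene[2L]), 1L)
            s <- min(s, left)
            sizes <- c(sizes, s)
            left <- left - s
        }
        nG <- length(sizes)
        genes <- sprintf("CFA%05d", seq_len(nG))
        canineAnnot <- data.frame(
            probe = probes[annotated],
            gene = rep(genes, times = sizes))
        # homologs: nAmb genes ambiguous, half as one-to-many, half as
        # shared-human pairs (count exact by construction)
        nAmb <- round(config@fracAmbiguous * nG)
        ambIdx <- sort(sample.int(nG, nAmb))
        nShared <- (nAmb %/% 4L) * 2L      # even count used for pairs
        sharedIdx <- ambIdx[seq_len(nShared)]
        multiIdx <- setdiff(ambIdx, sharedIdx)
        cleanIdx <- setdiff(seq_len(nG), ambIdx)
        human <- sprintf("HSA%05d", seq_len(nG + length(multiIdx)))
        rows <- data.frame(canine = genes[cleanIdx],
                           human = human[cleanIdx], ambiguous = FALSE)
        if (length(sharedIdx)) {
            pairMate <- rep(human[sharedIdx[c(TRUE, FALSE)]], each = 2L)
            rows <- rbind(rows, data.frame(canine = genes[sharedIdx],
                human = pairMate, ambiguous = TRUE))
        }
        if (length(multiIdx)) {
            extra <- human[nG + seq_along(multiIdx)]
            rows <- rbind(rows,
                data.frame(canine = rep(genes[multiIdx], each = 2L),
                    human = as.vector(rbind(human[multiIdx], extra)),
                    ambiguous = TRUE))
        }
        homologs <- rows[order(rows$canine, rows$human), , drop = FALSE]
        rownames(homologs) <- NULL
        # human probesets: 5% of clean genes fan out to 2 probesets and
        # are therefore lost to the strict one-to-one projection
        cleanHuman <- human[cleanIdx]
        nMulti <- round(0.05 * length(cleanHuman))
        multiHuman <- sample(cleanHuman, nMulti)
        singleHuman <- setdiff(cleanHuman, multiHuman)
        humanAnnot <- rbind(
            data.frame(gene = singleHuman,
                probe = sprintf("2%05d_at", seq_along(singleHuman))),
            data.frame(gene = rep(multiHuman, each = 2L),
                probe = sprintf("9%05d_at",
                    seq_len(2L * length(multiHuman)))))
        humanAnnot <- humanAnnot[order(humanAnnot$probe), c("probe", "gene")]
        rownames(humanAnnot) <- NULL
        # strict chain: unambiguous homolog + single human probeset
        strict <- data.frame(canine = genes[cleanIdx], human = cleanHuman)
        strict <- strict[strict$human %in% singleHuman, , drop = FALSE]
        # two strict genes carry real exemplar symbols (EGFR, ERCC1) so
        # the classic rules read like the curated ones; relabel them
        # consistently across every identifier artifact
        exemplars <- setNames(strict$human[1:2], c("EGFR", "ERCC1"))
        relabel <- function(x) {
            for (nm in names(exemplars)) x[x == exemplars[[nm]]] <- nm
            x
        }
        homologs$human <- relabel(homologs$human)
        humanAnnot$gene <- relabel(humanAnnot$gene)
        strict$human <- relabel(strict$human)
        # disjoint type-signature genes drawn from the strict set
        types <- names(config@nTumorsPerType)
        need <- length(types) * config@nTypeGenes
        if (need + 50L > nrow(strict))
            stop("not enough cleanly-mapped genes for the type ",
                 "signatures; increase nProbes")
        exemplarCanine <- strict$canine[strict$human %in%
                                        names(exemplars)]
        picked <- sample(setdiff(strict$canine, exemplarCanine), need)
        typeGenes <- split(picked,
            rep(types, each = config@nTypeGenes))
        kbPool <- setdiff(strict$human, strict$human[
            strict$canine %in% picked])
        list(probes = probes, canineAnnot = canineAnnot,
             homologs = homologs, humanAnnot = humanAnnot,
             strict = strict, typeGenes = typeGenes, kbPool = kbPool)
    })
}

#' Simulated platform annotations and homolog table
#'
#' Returns the identifier scaffolding of the synthetic study: the canine
#' probe-to-gene annotation, the human probeset annotation, and the
#' canine-to-human homolog table whose \code{ambiguous} column flags rows
#' the one-to-one mapping filter must drop (planted one-to-many mappings
#' and canine pairs sharing a human gene).
#'
#' @param config a \code{\link{simConfig}}.
#' @return List: \code{canineAnnot} (probe, gene), \code{humanAnnot}
#'   (probe, gene), \code{homologs} (canine, human, ambiguous),
#'   \code{strict} (the canine/human gene pairs surviving the whole
#'   chain), \code{typeGenes} (canine gene ids per cancer type).
#' @examples
#' ann <- simulateAnnotation(simConfig(seed = 3, nProbes = 300))
#' head(ann$homologs)
#' @export
simulateAnnotation <- function(config) {
    stopifnot(is(config, "SimConfig"))
    cat <- .catalog(config)
    cat[c("canineAnnot", "humanAnnot", "homologs", "strict", "typeGenes")]
}

#' Simulated homolog table
#'
#' @param config a \code{\link{simConfig}}.
#' @return data.frame (canine, human, ambiguous); with
#'   \code{fracAmbiguous = 0} the table is a bijection.
#' @export
simulateHomologTable <- function(config) {
    simulateAnnotation(config)$homologs
}

#' Simulated expression matrices with planted truth
#'
#' Generates the probe-level reference compendium and tumor cohort the
#' pipeline consumes.  Per-probe intensities are Gaussian on the log
#' scale: probe p has baseline mean \eqn{\mu_p \sim N(8, 1)} and noise sd
#' \eqn{\sigma_p \sim U(0.2, 0.6)}; reference samples draw
#' \eqn{N(\mu_p, \sigma_p^2)}.  Tumor samples add the cancer-type
#' signature (\code{typeEffect} z units, i.e. \code{typeEffect} times
#' \eqn{\sigma_p}, on that type's signature genes) and any
#' patient-specific planted shifts from \code{plantedTargets}, so a
#' planted shift of +5 surfaces as z close to +5 after standardization.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List: \code{reference} (probes x nRefSamples matrix),
#'   \code{tumors} (probes x tumors matrix), \code{truth} (list:
#'   \code{cancerType} named by sample, \code{typeGenes} canine gene ids
#'   per type, \code{planted} the realized planted data.frame).
#' @examples
#' sim <- simulateExpression(simConfig(seed = 5, nProbes = 300))
#' dim(sim$reference)
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "SimConfig"))
    cat <- .catalog(config)
    .withSeed(config@seed + 15485863L, {
        nP <- config@nProbes
        mu <- rnorm(nP, 8, 1)
        sg <- runif(nP, 0.2, 0.6)
        ref <- matrix(rnorm(nP * config@nRefSamples, mu, sg), nrow = nP,
            dimnames = list(cat$probes,
                sprintf("normal_%02d", seq_len(config@nRefSamples))))
        types <- names(config@nTumorsPerType)
        samples <- unlist(lapply(types, function(ty)
            sprintf("%s_%02d", ty, seq_len(config@nTumorsPerType[[ty]]))))
        cancerType <- setNames(rep(types, config@nTumorsPerType), samples)
        geneProbes <- split(cat$canineAnnot$probe, cat$canineAnnot$gene)
        shift <- matrix(0, nP, length(samples),
                        dimnames = list(cat$probes, samples))
        for (ty in types) {
            pr <- unlist(geneProbes[cat$typeGenes[[ty]]])
            shift[pr, cancerType == ty] <- config@typeEffect
        }
        pl <- config@plantedTargets
        if (nrow(pl)) {
            bad <- setdiff(pl$sample, samples)
            if (length(bad)) stop("unknown planted sample(s): ",
                                  paste(bad, collapse = ", "))
            for (r in seq_len(nrow(pl))) {
                pr <- geneProbes[[pl$gene[r]]]
                if (is.null(pr)) stop("planted gene has no probes: ",
                                      pl$gene[r])
                shift[pr, pl$sample[r]] <-
                    shift[pr, pl$sample[r]] + pl$shift[r]
            }
        }
        tumors <- matrix(rnorm(nP * length(samples), mu, sg), nrow = nP,
                         dimnames = list(cat$probes, samples))
        tumors <- tumors + shift * sg
        list(reference = ref, tumors = tumors,
             truth = list(cancerType = cancerType,
                          typeGenes = cat$typeGenes, planted = pl))
    })
}

.tokenNames <- function(prefix, n)
    sprintf("%s%03d", prefix, seq_len(n))

#' Simulated knowledge bases
#'
#' Generates the five knowledge bases the prediction methods consume,
#' sized like the study's (260 drug-target rules covering 123 drugs, 34
#' biomarker rules, 107 response-signature drugs over a common ranked
#' universe, 11 signed sensitivity signatures, a 184-drug pool) plus the
#' directed interaction network carrying every rule target as a node.
#' Gene and drug names are synthetic tokens except two exemplar rules
#' (EGFR/cetuximab target rule and ERCC1/oxaliplatin resistance rule).
#' All knowledge bases are keyed in human-gene space and only reference
#' genes that survive the one-to-one mapping chain, so any planted
#' perturbation of a rule gene is guaranteed to reach the methods.
#' The network additionally contains a "funnel" motif around the first
#' target rule's gene: a hub whose in- and out-neighbours make it the
#' waypoint of their shortest paths, recorded in the \code{funnel}
#' element for planted-truth tests.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List: \code{targetRules} (gene, drug, threshold, evidence),
#'   \code{biomarkerRules} (gene, drug, direction, effect, threshold,
#'   evidence), \code{responseSignatures} (named list of rankings),
#'   \code{sensitivitySignatures} (named list of signed gene sets),
#'   \code{network} (\code{\linkS4class{InteractionNetwork}}),
#'   \code{drugPool} (character), \code{funnel} (list: hub gene, source
#'   and sink genes).
#' @examples
#' kb <- simulateKnowledgeBases(simConfig(seed = 2, nProbes = 600,
#'     kbSizes = list(targetRules = 20L, targetDrugs = 10L,
#'                    networkEdges = 150L)))
#' nrow(kb$biomarkerRules)
#' @export
simulateKnowledgeBases <- function(config) {
    stopifnot(is(config, "SimConfig"))
    cat <- .catalog(config)
    ks <- config@kbSizes
    .withSeed(config@seed + 32452843L, {
        pool <- cat$kbPool
        if (length(pool) < ks$targetRules + 22L)
            stop("not enough cleanly-mapped genes for the knowledge ",
                 "bases; increase nProbes")
        drugPool <- .tokenNames("drug", ks$drugPool)
        drugPool[1:2] <- c("cetuximab", "oxaliplatin")
        # drug-target rules: unique targets, drugs reused across rules;
        # the first rule is the classic EGFR/cetuximab exemplar
        targets <- c("EGFR", sample(setdiff(pool, c("EGFR", "ERCC1")),
                                    ks$targetRules - 1L))
        ruleDrugs <- c("cetuximab",
            sample(setdiff(drugPool, "cetuximab"),
                   min(ks$targetDrugs, ks$drugPool) - 1L))
        targetRules <- data.frame(gene = targets,
            drug = c(ruleDrugs, sample(ruleDrugs,
                max(0L, ks$targetRules - length(ruleDrugs)),
                replace = TRUE))[seq_len(ks$targetRules)],
            threshold = 3, evidence = "curated")
        # biomarker rules over 22 marker genes and 20 drugs, led by the
        # ERCC1/oxaliplatin resistance exemplar
        bmGenes <- c("ERCC1",
                     sample(setdiff(pool, c(targets, "ERCC1")), 21L))
        # the exemplar drugs keep distinct roles (cetuximab is never a
        # biomarker drug) so planted rules trigger unambiguously
        bmDrugs <- c("oxaliplatin",
                     sample(setdiff(drugPool,
                         c("oxaliplatin", "cetuximab")), 19L))
        nbm <- ks$biomarkerRules
        biomarkerRules <- data.frame(
            gene = bmGenes[1L + (seq_len(nbm) - 1L) %% 22L],
            drug = bmDrugs[1L + (seq_len(nbm) - 1L) %% 20L],
            direction = sample(c("over", "under"), nbm, replace = TRUE,
                               prob = c(0.7, 0.3)),
            effect = sample(c("sensitive", "resistant"), nbm,
                            replace = TRUE, prob = c(0.7, 0.3)),
            threshold = 3, evidence = "curated")
        biomarkerRules$direction[1L] <- "over"
        biomarkerRules$effect[1L] <- "resistant"
        if (nbm >= 2L && ks$targetRules >= 2L) {
            # closure: at least one drug is reachable by two methods
            # (a target rule plus a sensitivity biomarker rule)
            biomarkerRules$drug[2L] <- targetRules$drug[2L]
            biomarkerRules$direction[2L] <- "over"
            biomarkerRules$effect[2L] <- "sensitive"
        }
        # response signatures: rankings over a common universe that
        # includes rule genes, so planted reversals reach the methods
        uniExtra <- setdiff(pool, c(targets, bmGenes))
        universeFull <- c(targets[seq_len(min(50L, length(targets)))],
                          uniExtra)
        universe <- universeFull[seq_len(min(ks$signatureUniverse,
                                             length(universeFull)))]
        responseSignatures <- lapply(
            seq_len(ks$responseDrugs), function(i) sample(universe))
        names(responseSignatures) <- sample(drugPool, ks$responseDrugs)
        # signed sensitivity signatures
        sensitivitySignatures <- lapply(
            seq_len(ks$sensitivityDrugs), function(i)
                data.frame(gene = sample(pool, ks$sensitivityGenes),
                           sign = sample(c(1, -1), ks$sensitivityGenes,
                                         replace = TRUE)))
        names(sensitivitySignatures) <-
            sample(setdiff(drugPool, names(responseSignatures)),
                   ks$sensitivityDrugs)
        # interaction network: every rule target is a node; random
        # background edges plus a funnel motif through the first two
        # targets: the only way out of the funnel sources is into the
        # hub, the only way into the funnel sinks is from the relay, so
        # every source-to-sink shortest path runs source -> hub ->
        # relay -> sink and the (hub, relay) pair carries all of them
        hub <- targets[1L]
        relay <- targets[2L]
        nodes <- unique(c(targets, bmGenes,
            sample(universe, min(ks$networkExtraNodes,
                                 length(universe)))))
        sources <- sample(setdiff(nodes, c(hub, relay)), 6L)
        sinks <- sample(setdiff(nodes, c(hub, relay, sources)), 6L)
        edges <- data.frame(
            source = sample(nodes, ks$networkEdges, replace = TRUE),
            target = sample(nodes, ks$networkEdges, replace = TRUE))
        edges <- edges[edges$source != edges$target, , drop = FALSE]
        edges <- edges[!(edges$source %in% sources) &
                       !(edges$target %in% sinks), , drop = FALSE]
        edges <- rbind(edges,
            data.frame(source = sources, target = hub),
            data.frame(source = hub, target = relay),
            data.frame(source = relay, target = sinks))
        edges <- unique(edges)
        edges$type <- "regulates"
        # keep isolated rule targets as nodes: every target is part of
        # the network even when no background edge touched it
        g <- igraph::graph_from_data_frame(edges, directed = TRUE,
            vertices = data.frame(name = nodes))
        net <- interactionNetwork(g,
            targets = data.frame(node = targetRules$gene,
                                 drug = targetRules$drug))
        list(targetRules = targetRules, biomarkerRules = biomarkerRules,
             responseSignatures = responseSignatures,
             sensitivitySignatures = sensitivitySignatures,
             network = net, drugPool = drugPool,
             funnel = list(hub = hub, relay = relay, sources = sources,
                           sinks = sinks))
    })
}

#' Human gene ids back to canine gene ids
#'
#' Helper for planting perturbations: translates knowledge-base (human)
#' gene ids to the canine gene ids \code{plantedTargets} uses, via the
#' strict one-to-one chain.
#'
#' @param humanIds character vector of human gene ids (including the
#'   EGFR/ERCC1 exemplars).
#' @param config the \code{\link{simConfig}} used throughout.
#' @return Character vector of canine gene ids.
#' @export
humanToCanine <- function(humanIds, config) {
    cat <- .catalog(config)
    out <- cat$strict$canine[match(humanIds, cat$strict$human)]
    if (anyNA(out)) stop("id(s) not on the strict mapping chain: ",
        paste(humanIds[is.na(out)], collapse = ", "))
    out
}

#' The 31-sample QA/QC fixture
#'
#' A cohort of QC records emulating the study's enrollment: seven records
#' carry the printed failure metrics (failing samples such as 0507 with
#' RIN 2.60 or 0503 with >20\% necrosis; metrics printed as N/A are
#' substituted with passing values) and the remaining 24 records pass
#' every gate.  Stages a sample never reached are recorded as NA (not
#' measured): cDNA was assessed for the 30 samples passing RNA QC and the
#' array stage only for the 24 samples passing everything upstream.
#'
#' @return data.frame of 31 QC records suitable for
#'   \code{\link{gateCohort}}.
#' @examples
#' gateCohort(qcFixtureTable())$summary
#' @export
qcFixtureTable <- function() {
    fail <- data.frame(
        sample_id = c("0204", "0503", "0506", "0507", "0502", "1301",
                      "1302"),
        cohort = c("TCC", "open", "open", "open", "melanoma", "open",
                   "open"),
        disease = c("bladder TCC", "lymphoma", "osteosarcoma",
                    "mast cell tumor", "melanoma", "lymphoma",
                    "histiocytic sarcoma"),
        tumor_surface_category = c("25-49%", "75-100%", "0-24%",
                                   "75-100%", "0-24%", "0-24%", "0-24%"),
        tumor_nuclei_category = c("25-49%", "75-100%", "0-24%",
                                  "75-100%", "0-24%", "0-24%", "0-24%"),
        necrosis_category = c("10-20%", ">20%", "<10%", "<10%", "<10%",
                              "10-20%", "10-20%"),
        rna_conc = c(3.91, 3092.04, 69.99, 614.62, 536.99, 16.67,
                     657.76),
        rna_volume = 14,
        rna_ratio = c(3.76, 2.03, 2.08, 2.10, 2.08, 1.93, 2.12),
        rin = c(9.0, 9.40, 9.60, 2.60, 8.2, 9.60, 9.80),
        cdna_ratio = c(1.9, 1.9, 1.9, NA, 1.9, 1.9, 1.9),
        cdna_yield = c(6, 6, 6, NA, 6, 6, 6),
        array_background = NA_real_, array_present_call = NA_real_,
        array_scale_factor = NA_real_)
    passCohorts <- rep(c("TCC", "lymphoma", "melanoma", "open"),
                       c(4L, 5L, 5L, 10L))
    pass <- data.frame(
        sample_id = sprintf("P%02d", seq_len(24L)),
        cohort = passCohorts, disease = passCohorts,
        tumor_surface_category = "75-100%",
        tumor_nuclei_category = "75-100%",
        necrosis_category = "<10%",
        rna_conc = 150, rna_volume = 14, rna_ratio = 2.0, rin = 9.0,
        cdna_ratio = 1.9, cdna_yield = 6,
        array_background = 55, array_present_call = 42,
        array_scale_factor = 110)
    out <- rbind(fail, pass)
    rownames(out) <- NULL
    out
}

#' Default per-case turnaround targets
#'
#' Per-case business-hours durations whose cohort means reproduce the
#' study's turnaround table: cohorts of 10/5/4/5 cases with mean business
#' hours 114.50, 117.00, 116.75 and 119.60 (case-weighted all-cases mean
#' 116.46) and mean total hours 174.50, 165.00, 158.75, 167.60
#' (all-cases 168.46).  Within-cohort spread is a fixed symmetric jitter
#' around the mean.
#'
#' @return data.frame: sample_id, cohort, business_hours, total_hours.
#' @export
defaultTurnaroundTargets <- function() {
    cohorts <- list(
        list(name = "Open histology", n = 10L, bh = 114.50, th = 174.50),
        list(name = "Lymphoma", n = 5L, bh = 117.00, th = 165.00),
        list(name = "TCC", n = 4L, bh = 116.75, th = 158.75),
        list(name = "Melanoma", n = 5L, bh = 119.60, th = 167.60))
    do.call(rbind, lapply(cohorts, function(co) {
        jit <- seq(-2, 2, length.out = co$n)
        jit <- jit - mean(jit)        # exact cohort mean preserved
        data.frame(
            sample_id = sprintf("%s_%02d", gsub(" ", "", co$name),
                                seq_len(co$n)),
            cohort = co$name,
            business_hours = co$bh + jit,
            total_hours = co$th + jit)
    }))
}

#' Simulated timestamped event logs
#'
#' Generates per-case event logs (biopsy, shipped, arrived, QA complete,
#' report issued) whose business-hours span from first to last event
#' reproduces each case's requested duration under the package clock.
#' Cases start on randomized business-day mornings inside the 2011 study
#' window and their timestamps are rendered in a mix of US source time
#' zones with explicit offsets, as recorded logs would be.
#'
#' @param targets data.frame with \code{sample_id}, \code{cohort},
#'   \code{business_hours} (see \code{\link{defaultTurnaroundTargets}}).
#' @param cal a \code{\link{businessCalendar}}; default uses the 2011 US
#'   federal holidays.
#' @param seed integer seed.
#' @return data.frame: sample_id, cohort, event, time (ISO-8601 with zone
#'   offset).  \code{caseTurnaround} on the result recovers
#'   \code{business_hours} to within 0.01 h.
#' @examples
#' logs <- simulateEventLogs(defaultTurnaroundTargets()[1:2, ])
#' caseTurnaround(logs)
#' @export
simulateEventLogs <- function(targets,
                              cal = businessCalendar(
                                  holidays = usHolidays2011()),
                              seed = 1L) {
    targets <- as.data.frame(targets)
    stopifnot(all(c("sample_id", "cohort", "business_hours") %in%
                  names(targets)), all(targets$business_hours >= 0))
    zones <- c("America/New_York", "America/Chicago", "America/Denver",
               "America/Los_Angeles")
    .withSeed(seed + 49979687L, {
        mondays <- seq(as.Date("2011-05-16"), as.Date("2011-09-26"),
                       by = "7 days")
        do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
            day <- sample(mondays, 1L) + sample(0:3, 1L)
            startHour <- sample(7:11, 1L)
            start <- as.POSIXct(sprintf("%s %02d:00:00", day, startHour),
                                tz = cal@tz)
            bh <- targets$business_hours[i]
            marks <- c(biopsy = 0, shipped = 0.05 * bh,
                       arrived = 0.2 * bh, qa_complete = 0.6 * bh,
                       report_issued = bh)
            zone <- sample(zones, 1L)
            data.frame(sample_id = targets$sample_id[i],
                cohort = targets$cohort[i], event = names(marks),
                time = vapply(marks, function(h) formatEventTime(
                    advanceBusinessHours(start, h, cal), tz = zone),
                    character(1L)))
        }))
    })
}

#' Simulate a complete study
#'
#' One-call orchestrator: annotations, knowledge bases, expression
#' matrices and planted truth from a single configuration.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List: \code{annotation} (see \code{\link{simulateAnnotation}}),
#'   \code{kb} (see \code{\link{simulateKnowledgeBases}}),
#'   \code{expression} (see \code{\link{simulateExpression}}).
#' @export
simulateStudy <- function(config) {
    list(annotation = simulateAnnotation(config),
         kb = simulateKnowledgeBases(config),
         expression = simulateExpression(config))
}
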