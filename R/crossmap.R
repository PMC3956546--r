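#' Per-identifier reference statistics
#'
#' Computes the per-row mean and standard deviation of a normal-tissue
#' reference expression matrix.  Tumor samples are later standardized
#' against these moments, so the matrix must be in the same identifier
#' space (rows) as the samples to be z-scored.  Rows with zero variance are
#' retained but flagged; z-scores are undefined for them and they are
#' dropped at standardization time.
#'
#' @param ref numeric matrix, identifiers x reference samples, with row and
#'   column names.
#' @return A \code{\linkS4class{ReferenceStats}} object.
#' @examples
#' ref <- matrix(rnorm(40), 4, 10,
#'     dimnames = list(paste0("p", 1:4), paste0("n", 1:10)))
#' computeReferenceStats(ref)
#' @export
computeReferenceStats <- function(ref) {
    ref <- as.matrix(ref)
    if (ncol(ref) < 2L)
        stop("need at least 2 reference samples")
    if (is.null(rownames(ref)))
        stop("reference matrix must have row identifiers")
    mu <- rowMeans(ref)
    sg <- apply(ref, 1L, sd)   # n - 1 denominator
    new("ReferenceStats", mean = mu, sd = sg, nRef = ncol(ref),
        flagged = rownames(ref)[sg == 0])
}

#' Standardize one sample against the reference
#'
#' Converts one sample's expression values to z-scores,
#' \eqn{z_g = (x_g - \mu_g)/\sigma_g}, the number of reference standard
#' deviations from the reference mean.  Identifiers flagged with zero
#' reference variance are dropped with a warning.
#'
#' @param x named numeric vector of expression values (one sample), or a
#'   one-column matrix.
#' @param stats a \code{\linkS4class{ReferenceStats}}.
#' @param sampleId sample identifier; defaults to the column name of
#'   \code{x} if present.
#' @param space identifier space of \code{x} (default canine-probe).
#' @return A \code{\linkS4class{ZProfile}} in the same identifier space.
#' @examples
#' ref <- matrix(rnorm(400), 4, 100,
#'     dimnames = list(paste0("p", 1:4), paste0("n", 1:100)))
#' st <- computeReferenceStats(ref)
#' zscoreSample(setNames(refMean(st) + 2 * refSd(st), names(refMean(st))),
#'     st, sampleId = "t1")
#' @export
zscoreSample <- function(x, stats, sampleId = NULL, space = "canine-probe") {
    if (is.matrix(x)) {
        if (is.null(sampleId)) sampleId <- colnames(x)[1L]
        x <- setNames(x[, 1L], rownames(x))
    }
    if (is.null(sampleId)) stop("sampleId required for unnamed input")
    ids <- names(refMean(stats))
    missing <- setdiff(ids, names(x))
    if (length(missing))
        stop("sample is missing identifiers present in the reference: ",
             paste(head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ...")
    keep <- setdiff(ids, stats@flagged)
    if (length(keep) < length(ids))
        warning(length(ids) - length(keep),
                " zero-variance identifiers dropped at z-scoring")
    z <- (x[keep] - stats@mean[keep]) / stats@sd[keep]
    ZProfile(sampleId, z, space = space)
}

#' Aggregate a probe-level profile to genes
#'
#' Replaces each gene's probes by the mean of their z-scores, moving the
#' profile from canine-probe to canine-gene space.  Probes without a gene
#' annotation are dropped.
#'
#' @param zp a \code{\linkS4class{ZProfile}} in canine-probe space.
#' @param annot platform annotation: data.frame with columns \code{probe}
#'   and \code{gene} (each probe maps to at most one gene).
#' @return A \code{ZProfile} in canine-gene space.
#' @examples
#' zp <- ZProfile("s", c(p1 = 1, p2 = 3, p3 = 5))
#' aggregateToGenes(zp, data.frame(probe = c("p1", "p2"), gene = "g1"))
#' @export
aggregateToGenes <- function(zp, annot) {
    stopifnot(is(zp, "ZProfile"))
    if (idSpace(zp) != "canine-probe")
        stop("profile must be in canine-probe space, got ", idSpace(zp))
    annot <- .cleanTwoCol(annot, c("probe", "gene"))
    if (anyDuplicated(annot$probe))
        stop("annotation maps a probe to more than one gene")
    z <- zScores(zp)
    hit <- annot[annot$probe %in% names(z), , drop = FALSE]
    if (!nrow(hit)) stop("no annotated probes in profile")
    agg <- tapply(z[hit$probe], hit$gene, mean)
    ZProfile(sampleId(zp), setNames(as.numeric(agg), names(agg)),
             space = "canine-gene")
}

#' Map a gene profile across species through a homolog table
#'
#' Relabels canine gene ids as their human homologs, keeping only genes
#' with a clear and concise one-to-one mapping: a canine gene is retained
#' only if it occurs in exactly one homolog row and the human gene of that
#' row likewise occurs in exactly one row.  Any ambiguity on either side
#' (one canine gene with two human homologs, or two canine genes sharing a
#' human gene) removes all genes involved.  z values are copied unchanged.
#'
#' @param zp a \code{\linkS4class{ZProfile}} in canine-gene space.
#' @param table homolog table: data.frame with columns \code{canine},
#'   \code{human}.
#' @return A \code{ZProfile} in human-gene space.
#' @examples
#' zp <- ZProfile("s", c(cg1 = 2, cg2 = -1), space = "canine-gene")
#' mapHomologs(zp, data.frame(canine = c("cg1", "cg2"),
#'                            human = c("hg1", "hg2")))
#' @export
mapHomologs <- function(zp, table) {
    stopifnot(is(zp, "ZProfile"))
    if (idSpace(zp) != "canine-gene")
        stop("profile must be in canine-gene space, got ", idSpace(zp))
    table <- .cleanTwoCol(table, c("canine", "human"))
    if (!nrow(table)) stop("empty homolog table")
    ok <- .conciseRows(table$canine, table$human)
    table <- table[ok, , drop = FALSE]
    z <- zScores(zp)
    table <- table[table$canine %in% names(z), , drop = FALSE]
    ZProfile(sampleId(zp), setNames(z[table$canine], table$human),
             space = "human-gene")
}

#' Project a human-gene profile onto array probesets
#'
#' Final step of the identifier chain: keys the profile by human array
#' probeset ids.  Under the default strict mode only genes with a concise
#' one-to-one probeset mapping are retained (mirroring the homolog
#' filter); \code{mode = "fan-out"} instead replicates a gene's z across
#' all of its probesets, for downstream consumers that need probe-level
#' coverage.  z values are copied unchanged.
#'
#' @param zp a \code{\linkS4class{ZProfile}} in human-gene space.
#' @param annot human platform annotation: data.frame with columns
#'   \code{probe}, \code{gene}.
#' @param mode \code{"one-to-one"} (default) or \code{"fan-out"}.
#' @return A \code{ZProfile} in human-probe space.
#' @examples
#' zp <- ZProfile("s", c(hg1 = 2.5), space = "human-gene")
#' projectToProbesets(zp, data.frame(probe = "200001_at", gene = "hg1"))
#' @export
projectToProbesets <- function(zp, annot, mode = c("one-to-one", "fan-out")) {
    stopifnot(is(zp, "ZProfile"))
    mode <- match.arg(mode)
    if (idSpace(zp) != "human-gene")
        stop("profile must be in human-gene space, got ", idSpace(zp))
    annot <- .cleanTwoCol(annot, c("probe", "gene"))
    if (anyDuplicated(annot$probe))
        stop("annotation maps a probeset to more than one gene")
    if (mode == "one-to-one") {
        keep <- names(table(annot$gene))[table(annot$gene) == 1L]
        annot <- annot[annot$gene %in% keep, , drop = FALSE]
    }
    z <- zScores(zp)
    annot <- annot[annot$gene %in% names(z), , drop = FALSE]
    ZProfile(sampleId(zp), setNames(z[annot$gene], annot$probe),
             space = "human-probe")
}

#' Standardize and map a whole tumor cohort to human-gene space
#'
#' Convenience wrapper running the full identifier chain for every tumor
#' column: probe z-scores against the reference, mean aggregation to canine
#' genes, one-to-one homolog mapping.  Set \code{humanAnnot} to also project
#' onto human probesets.
#'
#' @param tumors numeric matrix, canine probes x tumor samples.
#' @param stats \code{\linkS4class{ReferenceStats}} over the same probes.
#' @param canineAnnot canine probe -> gene annotation (columns \code{probe},
#'   \code{gene}).
#' @param homologs homolog table (columns \code{canine}, \code{human}).
#' @param humanAnnot optional human probeset annotation; when supplied the
#'   returned profiles are in human-probe space.
#' @param mode probeset projection mode, see \code{\link{projectToProbesets}}.
#' @return Named list of \code{\linkS4class{ZProfile}} objects, one per
#'   tumor column.
#' @export
profileCohort <- function(tumors, stats, canineAnnot, homologs,
                          humanAnnot = NULL, mode = "one-to-one") {
    tumors <- as.matrix(tumors)
    out <- lapply(colnames(tumors), function(s) {
        zp <- zscoreSample(tumors[, s], stats, sampleId = s)
        zp <- aggregateToGenes(zp, canineAnnot)
        zp <- mapHomologs(zp, homologs)
        if (!is.null(humanAnnot))
            zp <- projectToProbesets(zp, humanAnnot, mode = mode)
        zp
    })
    setNames(out, colnames(tumors))
}

# -- helpers ----------------------------------------------------------------

# trim whitespace, drop NA rows, exact-string id comparison (no case folding)
.cleanTwoCol <- function(df, cols) {
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
        stop("expected columns: ", paste(cols, collapse = ", "))
    df <- df[cols]
    for (cl in cols) df[[cl]] <- trimws(as.character(df[[cl]]))
    df[stats::complete.cases(df) & df[[1L]] != "" & df[[2L]] != "", ,
       drop = FALSE]
}

# rows whose left id occurs once and whose right id occurs once
.conciseRows <- function(left, right) {
    tabL <- table(left); tabR <- table(right)
    tabL[left] == 1L & tabR[right] == 1L
}
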