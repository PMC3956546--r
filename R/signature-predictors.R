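#' Build the over/under-expression query from a profile
#'
#' The connectivity query: identifiers over-expressed at z >= +2.0 form the
#' up set, identifiers with z <= -2.0 form the down set (both thresholds
#' inclusive).
#'
#' @param zp a \code{\linkS4class{ZProfile}}.
#' @param threshold z magnitude cut (default 2.0).
#' @return List with character vectors \code{up} and \code{down} (disjoint
#'   by construction).
#' @examples
#' buildQuery(ZProfile("s", c(a = 2.5, b = -2.5, c = 0),
#'                     space = "human-gene"))
#' @export
buildQuery <- function(zp, threshold = 2.0) {
    z <- zScores(zp)
    list(up = names(z)[z >= threshold], down = names(z)[z <= -threshold])
}

# ES from the sorted ascending ranks V (length t) of a set within a ranking
# of length n; CMAP-style running statistic
.esFromRanks <- function(V, t, n) {
    j <- seq_len(t)
    a <- max(j / t - V / n)
    b <- max(V / n - (j - 1) / t)
    if (a > b) a else -b
}

#' Kolmogorov-Smirnov enrichment score
#'
#' Rank-based enrichment of a gene set within a drug's ranked response
#' signature.  With \eqn{V(j)} the ascending ranks of the set's members in
#' the signature (1 = most up-regulated by the drug) and \eqn{t}, \eqn{n}
#' the set and universe sizes: \eqn{a = \max_j (j/t - V(j)/n)},
#' \eqn{b = \max_j (V(j)/n - (j-1)/t)}, and ES = \eqn{a} if \eqn{a > b}
#' else \eqn{-b}.  ES near +1 means the set concentrates at the top of the
#' ranking, near -1 at the bottom.
#'
#' @param ids character vector, the gene set.
#' @param ranking character vector, the drug signature: a permutation of
#'   the signature universe ordered most-up-regulated first.
#' @return ES in [-1, 1], or NA if the set does not intersect the
#'   universe.
#' @examples
#' ksEnrichment(c("g1", "g2"), paste0("g", 1:10))  # top of the list: 0.8
#' @export
ksEnrichment <- function(ids, ranking) {
    V <- sort(match(ids, ranking))
    V <- V[!is.na(V)]
    if (!length(V)) return(NA_real_)
    .esFromRanks(V, length(V), length(ranking))
}

#' Connectivity score of a query against one drug signature
#'
#' Combines the up- and down-set enrichment scores the Connectivity Map
#' way: when ES_up and ES_down have opposite signs,
#' \eqn{s = (ES_{up} - ES_{down})/2}; when they share a sign the evidence
#' is incoherent and \eqn{s = 0}.  A side whose set does not intersect the
#' universe contributes ES = 0.  Negative s is inverse connectivity: the
#' drug's signature runs against the tumor profile, i.e. the drug is
#' predicted to push the expression state back toward normal.
#'
#' @param query list with \code{up} and \code{down} id vectors (see
#'   \code{\link{buildQuery}}).
#' @param ranking drug signature ranking (permutation of the universe).
#' @return List: \code{esUp}, \code{esDown}, \code{s} (all in [-1, 1]), or
#'   NULL when neither set intersects the universe.
#' @export
connectivityScore <- function(query, ranking) {
    esUp <- ksEnrichment(query$up, ranking)
    esDown <- ksEnrichment(query$down, ranking)
    if (is.na(esUp) && is.na(esDown)) return(NULL)
    if (is.na(esUp)) esUp <- 0
    if (is.na(esDown)) esDown <- 0
    s <- if (esUp * esDown > 0) 0 else (esUp - esDown) / 2
    list(esUp = esUp, esDown = esDown, s = s)
}

# permutation null of s for query sizes (tUp, tDown) against a ranking of
# length n; by symmetry the null depends on the ranking only through n,
# so random rank sets are drawn directly
.permutationNull <- function(tUp, tDown, n, nPerm) {
    vapply(seq_len(nPerm), function(i) {
        picks <- sample.int(n, tUp + tDown)
        esUp <- if (tUp) .esFromRanks(sort(picks[seq_len(tUp)]), tUp, n)
                else 0
        esDown <- if (tDown)
            .esFromRanks(sort(picks[tUp + seq_len(tDown)]), tDown, n)
        else 0
        if (esUp * esDown > 0) 0 else (esUp - esDown) / 2
    }, numeric(1L))
}

#' Permutation p value for inverse connectivity
#'
#' Estimates how often random queries of the observed sizes score at least
#' as inversely connected as the observed query:
#' \eqn{p = (1 + \#\{s_{perm} \le s_{obs}\}) / (n_{perm} + 1)} (add-one
#' estimator, so the minimum attainable p is \eqn{1/(n_{perm}+1)}).
#' Random queries are drawn as disjoint up/down rank sets from the
#' signature universe.
#'
#' @param sObs observed connectivity score.
#' @param tUp,tDown observed up/down set sizes after intersection with the
#'   universe.
#' @param n signature universe size.
#' @param nPerm number of permutations (the study default is 50000).
#' @param seed integer seed making the draw reproducible; if NULL the
#'   current RNG stream is used.
#' @param null optional precomputed permutation null (vector of s values)
#'   to reuse across drugs sharing query sizes.
#' @return p in (0, 1].
#' @export
permutationPvalue <- function(sObs, tUp, tDown, n, nPerm = 50000,
                              seed = NULL, null = NULL) {
    stopifnot(nPerm >= 1)
    if (is.null(null)) {
        if (!is.null(seed)) set.seed(seed)
        null <- .permutationNull(tUp, tDown, n, nPerm)
    }
    (1 + sum(null <= sObs)) / (length(null) + 1)
}

#' Drug response signature method
#'
#' Scans every drug's ranked response signature for significant inverse
#' connectivity with the tumor's over/under-expression query.  Only drugs
#' with \eqn{s < 0} and permutation \eqn{p < maxP} are reported; each
#' carries a score of \eqn{-\log_{10} p}.  Permutation nulls are shared
#' across drugs with identical query sizes within one call (valid because
#' the null law depends only on the sizes and the universe length).
#'
#' @param zp a \code{\linkS4class{ZProfile}} keyed like the signatures.
#' @param signatures named list (by drug) of rankings over a common
#'   signature universe.
#' @param nPerm permutations per null (study default 50000).
#' @param seed integer seed for the permutation draws.
#' @param maxP reporting threshold (default 0.05).
#' @param queryThreshold z cut for \code{\link{buildQuery}}.
#' @return Calls data.frame (drug, method \code{"response-signature"},
#'   verdict indicated, genes summary, p, score) plus attribute
#'   \code{"scanned"}: the full per-drug table of s and p.
#' @export
runResponseMethod <- function(zp, signatures, nPerm = 50000, seed = 1L,
                              maxP = 0.05, queryThreshold = 2.0) {
    stopifnot(length(signatures) > 0)
    q <- buildQuery(zp, queryThreshold)
    if (!length(q$up) && !length(q$down)) {
        out <- .emptyCalls()
        attr(out, "scanned") <- data.frame(drug = character(),
            s = numeric(), p = numeric())
        return(out)
    }
    set.seed(seed)
    nullCache <- new.env(parent = emptyenv())
    rows <- lapply(names(signatures), function(drug) {
        ranking <- signatures[[drug]]
        cs <- connectivityScore(q, ranking)
        if (is.null(cs)) return(NULL)
        tUp <- sum(q$up %in% ranking)
        tDown <- sum(q$down %in% ranking)
        key <- paste(tUp, tDown, length(ranking))
        if (is.null(nullCache[[key]]))
            nullCache[[key]] <- .permutationNull(tUp, tDown,
                                                 length(ranking), nPerm)
        p <- permutationPvalue(cs$s, tUp, tDown, length(ranking),
                               null = nullCache[[key]])
        data.frame(drug = drug, s = cs$s, p = p)
    })
    scanned <- do.call(rbind, rows)
    if (is.null(scanned))
        scanned <- data.frame(drug = character(), s = numeric(),
                              p = numeric())
    hit <- scanned[scanned$s < 0 & scanned$p < maxP, , drop = FALSE]
    out <- if (nrow(hit)) {
        calls <- data.frame(drug = hit$drug, method = "response-signature",
            verdict = "indicated",
            genes = sprintf("up:%d,down:%d", length(q$up), length(q$down)),
            z = NA_real_, p = hit$p, score = -log10(hit$p))
        calls[order(calls$p, calls$drug), , drop = FALSE]
    } else .emptyCalls()
    rownames(out) <- NULL
    attr(out, "scanned") <- scanned
    out
}

#' Parametric gene-set enrichment for one sensitivity signature
#'
#' The drug sensitivity method scores a signed signature (genes higher in
#' sensitive cell lines carry +1, genes higher in resistant lines -1)
#' against one sample by a one-sample t-test on the signed z values
#' \eqn{v_i = sign_i z_i}: \eqn{t = \bar v / (s_v / \sqrt m)} with
#' \eqn{m - 1} degrees of freedom, one-sided toward sensitivity.
#'
#' @param zp a \code{\linkS4class{ZProfile}}.
#' @param signature data.frame with columns \code{gene} and \code{sign}
#'   (+1/-1).
#' @return List: \code{t}, \code{df}, \code{p} (upper tail), \code{m},
#'   \code{meanSigned}; or NULL when fewer than 2 signature genes are in
#'   the profile.  A degenerate zero-variance signed vector gets the
#'   smallest representable p (positive mean) or p = 1, with
#'   \code{degenerate = TRUE}.
#' @examples
#' zp <- ZProfile("s", c(a = 1, b = 2, c = 3), space = "human-gene")
#' pgseaScore(zp, data.frame(gene = c("a", "b", "c"), sign = 1))
#' @export
pgseaScore <- function(zp, signature) {
    signature <- as.data.frame(signature)
    stopifnot(all(signature$sign %in% c(-1, 1)))
    z <- zScores(zp)
    sig <- signature[signature$gene %in% names(z), , drop = FALSE]
    m <- nrow(sig)
    if (m < 2L) return(NULL)
    v <- sig$sign * z[sig$gene]
    sv <- sd(v)
    if (sv == 0) {
        # degenerate: direction decided by the (constant) mean alone
        tdeg <- if (mean(v) > 0) Inf else if (mean(v) < 0) -Inf else 0
        pdeg <- if (mean(v) > 0) .Machine$double.xmin
                else if (mean(v) < 0) 1 else 0.5
        return(list(t = tdeg, df = m - 1L, p = pdeg, m = m,
                    meanSigned = mean(v), degenerate = TRUE))
    }
    tstat <- mean(v) / (sv / sqrt(m))
    list(t = tstat, df = m - 1L,
         p = pt(tstat, df = m - 1L, lower.tail = FALSE),
         m = m, meanSigned = mean(v), degenerate = FALSE)
}

#' Drug sensitivity signature method
#'
#' Runs \code{\link{pgseaScore}} for every drug's signed signature and
#' reports drugs with \eqn{p < maxP}, scored as \eqn{-\log_{10} p}.
#'
#' @param zp a \code{\linkS4class{ZProfile}}.
#' @param signatures named list (by drug) of signed signatures
#'   (data.frames with \code{gene}, \code{sign}).
#' @param maxP reporting threshold (default 0.05).
#' @return Calls data.frame (method \code{"sensitivity-signature"}) plus
#'   attribute \code{"scanned"} with the full per-drug t/p table.
#' @export
runSensitivityMethod <- function(zp, signatures, maxP = 0.05) {
    stopifnot(length(signatures) > 0)
    rows <- lapply(names(signatures), function(drug) {
        r <- pgseaScore(zp, signatures[[drug]])
        if (is.null(r)) return(NULL)
        data.frame(drug = drug, t = r$t, df = r$df, p = r$p, m = r$m)
    })
    scanned <- do.call(rbind, rows)
    if (is.null(scanned))
        scanned <- data.frame(drug = character(), t = numeric(),
                              df = integer(), p = numeric(), m = integer())
    hit <- scanned[scanned$p < maxP, , drop = FALSE]
    out <- if (nrow(hit)) {
        calls <- data.frame(drug = hit$drug,
            method = "sensitivity-signature", verdict = "indicated",
            genes = sprintf("m:%d", hit$m), z = NA_real_, p = hit$p,
            score = -log10(hit$p))
        calls[order(calls$p, calls$drug), , drop = FALSE]
    } else .emptyCalls()
    rownames(out) <- NULL
    attr(out, "scanned") <- scanned
    out
}
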