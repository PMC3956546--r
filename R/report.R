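#' Score a call from its p value
#'
#' @param p p value(s) in (0, 1].
#' @param base logarithm base (default 10).
#' @return \eqn{-\log_{base} p}, non-negative.
#' @examples
#' scoreCall(0.01)  # 2
#' @export
scoreCall <- function(p, base = 10) {
    if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
    -log(p, base = base)
}

#' Compile per-method calls into a personalized drug report
#'
#' Aggregates the call tables of all prediction methods for one sample.
#' Each drug's summary score is the sum of \eqn{-\log_{10} p} over the
#' methods that indicated it, so drugs suggested by several methods carry
#' more weight than equally significant single-method drugs.  Any drug hit
#' by a resistance biomarker (contraindicated) call is excluded from the
#' ranked summary and listed in the contraindications section instead.
#' Ranking ties are broken alphabetically by drug.
#'
#' @param calls a single calls data.frame or a list of them (one per
#'   method), as produced by the \code{apply*}/\code{run*} methods.
#' @param sampleId sample identifier for the report.
#' @return A \code{\linkS4class{PMedReport}}.
#' @examples
#' zp <- ZProfile("case01", c(EGFR = 3.5), space = "human-gene")
#' calls <- applyTargetRules(zp, data.frame(gene = "EGFR",
#'                                          drug = "cetuximab"))
#' compileReport(calls, "case01")
#' @export
compileReport <- function(calls, sampleId) {
    if (is.data.frame(calls)) calls <- list(calls)
    calls <- if (length(calls)) {
        do.call(rbind, c(lapply(calls, function(d) {
            d <- as.data.frame(d)
            attr(d, "scanned") <- NULL; attr(d, "pairs") <- NULL
            d
        }), list(make.row.names = FALSE)))
    } else .emptyCalls()
    # deterministic across method processing order
    calls <- calls[order(calls$method, calls$drug, calls$verdict), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    contra <- calls[calls$verdict == "contraindicated", , drop = FALSE]
    ind <- calls[calls$verdict == "indicated", , drop = FALSE]
    summary <- if (nrow(ind)) {
        s <- do.call(rbind, lapply(split(ind, ind$drug), function(d) {
            data.frame(drug = d$drug[1L], score = sum(d$score),
                       nMethods = length(unique(d$method)),
                       methods = paste(sort(unique(d$method)),
                                       collapse = "+"))
        }))
        s <- s[!s$drug %in% contra$drug, , drop = FALSE]
        s <- s[order(-s$score, s$drug), , drop = FALSE]
        rownames(s) <- NULL
        s
    } else data.frame(drug = character(), score = numeric(),
                      nMethods = integer(), methods = character())
    contraTab <- if (nrow(contra)) {
        ct <- do.call(rbind, lapply(split(contra, contra$drug), function(d) {
            data.frame(drug = d$drug[1L], genes = paste(unique(d$genes),
                       collapse = ","), p = min(d$p))
        }))
        ct <- ct[order(ct$drug), , drop = FALSE]
        rownames(ct) <- NULL
        ct
    } else data.frame(drug = character(), genes = character(),
                      p = numeric())
    new("PMedReport", sampleId = as.character(sampleId), calls = calls,
        summary = summary, contraindications = contraTab)
}

#' Render a report to JSON and readable text
#'
#' @param report a \code{\linkS4class{PMedReport}}.
#' @param jsonPath,textPath optional file paths; when NULL the strings are
#'   only returned.
#' @return Invisibly, list with \code{json} (character scalar) and
#'   \code{text} (markdown summary).  The JSON round-trips through
#'   \code{\link{readReport}} losslessly.
#' @export
renderReport <- function(report, jsonPath = NULL, textPath = NULL) {
    stopifnot(is(report, "PMedReport"))
    obj <- list(schema = "pmed-report/1", sampleId = sampleId(report),
                calls = methodCalls(report),
                summary = reportSummary(report),
                contraindications = contraindications(report))
    json <- jsonlite::toJSON(obj, dataframe = "rows", digits = NA,
                             na = "null", auto_unbox = TRUE, pretty = TRUE)
    lines <- c(sprintf("# PMed report: sample %s", sampleId(report)), "")
    sm <- reportSummary(report)
    if (nrow(sm)) {
        lines <- c(lines, "## Ranked drug summary", "",
            "| rank | drug | score | methods |",
            "| ---- | ---- | ----- | ------- |",
            sprintf("| %d | %s | %.3f | %s |", seq_len(nrow(sm)), sm$drug,
                    sm$score, sm$methods), "")
    } else lines <- c(lines, "No indications.", "")
    ct <- contraindications(report)
    if (nrow(ct))
        lines <- c(lines, "## Contraindicated", "",
            sprintf("- %s (marker %s, p = %.3g)", ct$drug, ct$genes,
                    ct$p), "")
    cl <- methodCalls(report)
    for (m in unique(cl$method)) {
        d <- cl[cl$method == m, , drop = FALSE]
        lines <- c(lines, sprintf("## Method: %s", m), "",
            sprintf("- %s %s (p = %.3g, score %.3f; genes %s)", d$drug,
                    d$verdict, d$p, d$score, d$genes), "")
    }
    text <- paste(lines, collapse = "\n")
    if (!is.null(jsonPath)) writeLines(json, jsonPath)
    if (!is.null(textPath)) writeLines(text, textPath)
    invisible(list(json = as.character(json), text = text))
}

#' Read a report back from JSON
#'
#' @param json JSON string or file path produced by
#'   \code{\link{renderReport}}.
#' @return A \code{\linkS4class{PMedReport}}.
#' @export
readReport <- function(json) {
    obj <- jsonlite::fromJSON(json)
    fix <- function(d, template) {
        if (is.null(d) || !length(d)) return(template)
        d <- as.data.frame(d)
        for (cl in names(template)) {
            if (is.null(d[[cl]])) d[[cl]] <- template[[cl]][0L]
            # all-NA columns lose their type in JSON; restore it
            mode(d[[cl]]) <- mode(template[[cl]])
        }
        d[names(template)]
    }
    new("PMedReport", sampleId = obj$sampleId,
        calls = fix(obj$calls, .emptyCalls()),
        summary = fix(obj$summary, data.frame(drug = character(),
            score = numeric(), nMethods = integer(),
            methods = character())),
        contraindications = fix(obj$contraindications,
            data.frame(drug = character(), genes = character(),
                       p = numeric())))
}

#' Run all six prediction methods and compile the report
#'
#' Convenience pipeline for one profiled sample against a full knowledge
#' base bundle.
#'
#' @param zp a \code{\linkS4class{ZProfile}} in the space the knowledge
#'   bases are keyed in.
#' @param kb list with elements \code{targetRules}, \code{biomarkerRules},
#'   \code{responseSignatures}, \code{sensitivitySignatures},
#'   \code{network} (see \code{\link{simulateKnowledgeBases}} for the
#'   shapes).
#' @param nPerm permutations for the response-signature method.
#' @param seed seed for the permutation draws.
#' @param networkMode seed-selection mode for the network method.
#' @return A \code{\linkS4class{PMedReport}}.
#' @export
predictDrugs <- function(zp, kb, nPerm = 50000, seed = 1L,
                         networkMode = "threshold") {
    calls <- list(
        applyTargetRules(zp, kb$targetRules),
        applyBiomarkerRules(zp, kb$biomarkerRules),
        runResponseMethod(zp, kb$responseSignatures, nPerm = nPerm,
                          seed = seed),
        runSensitivityMethod(zp, kb$sensitivitySignatures),
        runNetworkMethod(zp, kb$network, mode = networkMode))
    compileReport(calls, sampleId(zp))
}
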