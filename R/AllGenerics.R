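#' @rdname ZProfile-class
#' @param object,x a \code{ZProfile}.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname ZProfile-class
#' @export
setGeneric("idSpace", function(x) standardGeneric("idSpace"))

#' @rdname ZProfile-class
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname ZProfile-class
#' @export
setMethod("sampleId", "ZProfile", function(x) x@sampleId)

#' @rdname ZProfile-class
#' @export
setMethod("idSpace", "ZProfile", function(x) x@space)

#' @rdname ZProfile-class
#' @export
setMethod("zScores", "ZProfile", function(x) x@z)

#' @rdname ZProfile-class
#' @export
setMethod("length", "ZProfile", function(x) length(x@z))

setMethod("show", "ZProfile", function(object) {
    cat("ZProfile for sample", object@sampleId,
        "in", object@space, "space\n")
    cat(length(object@z), "identifiers;",
        sum(object@z >= 2), "with z >= 2,",
        sum(object@z <= -2), "with z <= -2\n")
    if (length(object@z)) {
        top <- head(sort(object@z, decreasing = TRUE), 3L)
        cat("top:", paste(sprintf("%s=%.2f", names(top), top),
                          collapse = ", "), "\n")
    }
})

#' @rdname PMedReport-class
#' @param x a \code{PMedReport}.
#' @export
setMethod("sampleId", "PMedReport", function(x) x@sampleId)

#' Accessors for PMedReport
#'
#' @param x a \code{PMedReport}.
#' @return \code{methodCalls} returns the per-method call table;
#'   \code{reportSummary} the ranked summary; \code{contraindications} the
#'   excluded drugs.
#' @name PMedReport-accessors
NULL

#' @rdname PMedReport-accessors
#' @export
setGeneric("methodCalls", function(x) standardGeneric("methodCalls"))

#' @rdname PMedReport-accessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))

#' @rdname PMedReport-accessors
#' @export
setGeneric("contraindications", function(x) standardGeneric("contraindications"))

#' @rdname PMedReport-accessors
#' @export
setMethod("methodCalls", "PMedReport", function(x) x@calls)

#' @rdname PMedReport-accessors
#' @export
setMethod("reportSummary", "PMedReport", function(x) x@summary)

#' @rdname PMedReport-accessors
#' @export
setMethod("contraindications", "PMedReport", function(x) x@contraindications)

setMethod("show", "PMedReport", function(object) {
    cat("PMedReport for sample", object@sampleId, "\n")
    cat(nrow(object@calls), "method calls;",
        nrow(object@summary), "ranked drugs;",
        nrow(object@contraindications), "contraindicated\n")
    if (nrow(object@summary))
        print(head(object@summary, 5L), row.names = FALSE)
})

#' @rdname ReferenceStats-class
#' @param object a \code{ReferenceStats}.
#' @export
setGeneric("refMean", function(x) standardGeneric("refMean"))

#' @rdname ReferenceStats-class
#' @export
setGeneric("refSd", function(x) standardGeneric("refSd"))

#' @rdname ReferenceStats-class
#' @param x a \code{ReferenceStats}.
#' @export
setMethod("refMean", "ReferenceStats", function(x) x@mean)

#' @rdname ReferenceStats-class
#' @export
setMethod("refSd", "ReferenceStats", function(x) x@sd)

setMethod("show", "ReferenceStats", function(object) {
    cat("ReferenceStats over", object@nRef, "reference samples,",
        length(object@mean), "identifiers")
    if (length(object@flagged))
        cat(" (", length(object@flagged), " zero-variance)", sep = "")
    cat("\n")
})

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork:", igraph::vcount(object@graph), "nodes,",
        igraph::ecount(object@graph), "directed edges;",
        length(unique(object@targets$node)), "drug-target nodes\n")
})

setMethod("show", "BusinessCalendar", function(object) {
    cat("BusinessCalendar (", object@tz, "): weekend ",
        paste(object@weekend, collapse = "/"), ", ",
        length(object@holidays), " holidays\n", sep = "")
})
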