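#' @import methods
#' @importFrom stats sd pnorm pt phyper cmdscale cor setNames rnorm runif
#'   dist as.dist
#' @importFrom utils head
NULL

.ID_SPACES <- c("canine-probe", "canine-gene", "human-gene", "human-probe")

#' ZProfile: a single sample's z-score profile
#'
#' Holds one tumor sample's expression profile expressed as z-scores —
#' standard deviations from the mean expression of each identifier in a
#' normal-tissue reference set — together with a tag recording which
#' identifier space the profile currently lives in.  Profiles move along the
#' chain canine-probe -> canine-gene -> human-gene -> human-probe; mapping
#' steps relabel or drop identifiers but never alter z values (only the
#' probe-to-gene aggregation changes magnitudes).
#'
#' @slot sampleId single character sample identifier.
#' @slot space identifier space, one of \code{"canine-probe"},
#'   \code{"canine-gene"}, \code{"human-gene"}, \code{"human-probe"}.
#' @slot z named numeric vector of z-scores (unitless, standard deviations).
#' @exportClass ZProfile
setClass("ZProfile",
    representation(sampleId = "character", space = "character", z = "numeric"))

setValidity("ZProfile", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-NA string")
    if (length(object@space) != 1L || !object@space %in% .ID_SPACES)
        msg <- c(msg, sprintf("space must be one of: %s",
                              paste(.ID_SPACES, collapse = ", ")))
    if (length(object@z) && is.null(names(object@z)))
        msg <- c(msg, "z must be named")
    if (anyDuplicated(names(object@z)))
        msg <- c(msg, "duplicate identifiers in z")
    if (length(object@z) && any(!is.finite(object@z)))
        msg <- c(msg, "z values must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a ZProfile
#'
#' @param sampleId sample identifier.
#' @param z named numeric vector of z-scores.
#' @param space identifier space tag (see \code{\linkS4class{ZProfile}}).
#' @return A \code{ZProfile} object.
#' @examples
#' zp <- ZProfile("case01", c(EGFR = 3.5, ERCC1 = -0.2), space = "human-gene")
#' zScores(zp)[["EGFR"]]
#' @export
ZProfile <- function(sampleId, z, space = "canine-probe") {
    new("ZProfile", sampleId = as.character(sampleId),
        space = space, z = z)
}

#' ReferenceStats: per-identifier reference moments
#'
#' Per-identifier mean and standard deviation of expression over the normal
#' reference compendium, used to standardize tumor samples.  Identifiers
#' whose reference standard deviation is zero are retained here but flagged;
#' they are dropped (with a warning) at z-scoring time since the z-score is
#' undefined for them.
#'
#' @slot mean named numeric, per-identifier reference mean.
#' @slot sd named numeric, per-identifier reference standard deviation
#'   (sample variance, n - 1 denominator).
#' @slot nRef number of reference samples.
#' @slot flagged identifiers with zero reference variance.
#' @exportClass ReferenceStats
setClass("ReferenceStats",
    representation(mean = "numeric", sd = "numeric", nRef = "integer",
                   flagged = "character"))

setValidity("ReferenceStats", function(object) {
    msg <- character()
    if (!identical(names(object@mean), names(object@sd)))
        msg <- c(msg, "mean and sd must share identifiers")
    if (any(object@sd < 0)) msg <- c(msg, "sd must be non-negative")
    if (object@nRef < 2L) msg <- c(msg, "nRef must be >= 2")
    if (length(msg)) msg else TRUE
})

#' BusinessCalendar: weekend and holiday exclusions for the turnaround clock
#'
#' Defines which calendar days are excluded when converting wall-clock spans
#' to business hours.  All 24 hours of an excluded day are subtracted; hours
#' on business days count in full, so 116.46 business hours correspond to
#' 116.46/24 = 4.85 business days.
#'
#' @slot weekend weekday names excluded every week.
#' @slot holidays \code{Date} vector of whole-day holiday exclusions.
#' @slot tz Olson time zone all event times are converted to before
#'   arithmetic (the study clock runs on US Eastern time).
#' @exportClass BusinessCalendar
setClass("BusinessCalendar",
    representation(weekend = "character", holidays = "Date", tz = "character"))

setValidity("BusinessCalendar", function(object) {
    days <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")
    if (!all(object@weekend %in% days))
        return("weekend must contain English weekday names")
    if (length(object@tz) != 1L) return("tz must be a single zone name")
    TRUE
})

#' Construct a BusinessCalendar
#'
#' @param weekend weekday names to exclude (default Saturday and Sunday).
#' @param holidays \code{Date} vector (or coercible) of holiday dates.
#' @param tz Olson time zone for the clock (default \code{"America/New_York"}).
#' @return A \code{BusinessCalendar}.
#' @examples
#' cal <- businessCalendar(holidays = as.Date("2011-07-04"))
#' @export
businessCalendar <- function(weekend = c("Saturday", "Sunday"),
                             holidays = as.Date(character()),
                             tz = "America/New_York") {
    new("BusinessCalendar", weekend = weekend,
        holidays = as.Date(holidays), tz = tz)
}

#' InteractionNetwork: directed interaction graph with drug-target map
#'
#' A directed gene/protein interaction network (no self loops) plus a map
#' from drug-target nodes to the drugs that act on them, as consumed by the
#' network target-activity method.
#'
#' @slot graph an \code{igraph} directed graph; vertex names are gene ids.
#' @slot targets data.frame with columns \code{node} (gene id) and
#'   \code{drug}.
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
    representation(graph = "ANY", targets = "data.frame"))

setValidity("InteractionNetwork", function(object) {
    msg <- character()
    if (!igraph::is_igraph(object@graph) ||
        !igraph::is_directed(object@graph))
        msg <- c(msg, "graph must be a directed igraph")
    else {
        if (any(igraph::which_loop(object@graph)))
            msg <- c(msg, "self-loops are not allowed")
        if (anyDuplicated(igraph::V(object@graph)$name))
            msg <- c(msg, "node ids must be unique")
    }
    if (!all(c("node", "drug") %in% names(object@targets)))
        msg <- c(msg, "targets needs columns node, drug")
    if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param edges data.frame with columns \code{source}, \code{target} and
#'   optionally \code{type} (interaction kind), or an \code{igraph} object.
#' @param targets data.frame with columns \code{node}, \code{drug}.
#' @return An \code{InteractionNetwork}.
#' @examples
#' net <- interactionNetwork(
#'     data.frame(source = c("A", "B"), target = c("B", "C")),
#'     targets = data.frame(node = "B", drug = "drugX"))
#' @export
interactionNetwork <- function(edges, targets = data.frame(
        node = character(), drug = character())) {
    g <- if (igraph::is_igraph(edges)) edges else {
        stopifnot(all(c("source", "target") %in% names(edges)))
        igraph::graph_from_data_frame(edges, directed = TRUE)
    }
    new("InteractionNetwork", graph = g,
        targets = as.data.frame(targets))
}

#' PMedReport: per-sample personalized drug report
#'
#' Aggregates the calls of all prediction methods for one sample.  The
#' summary table ranks drugs by the sum of \eqn{-\log_{10} p} scores over the
#' methods that indicated them; drugs hit by a resistance biomarker rule are
#' excluded from the ranking and listed in a separate contraindications
#' section.
#'
#' @slot sampleId sample identifier.
#' @slot calls data.frame of per-method calls (drug, method, verdict, genes,
#'   p, score).
#' @slot summary ranked data.frame (drug, score, nMethods, methods).
#' @slot contraindications data.frame of contraindicated drugs.
#' @exportClass PMedReport
setClass("PMedReport",
    representation(sampleId = "character", calls = "data.frame",
                   summary = "data.frame", contraindications = "data.frame"))

setValidity("PMedReport", function(object) {
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    if (nrow(object@summary) &&
        is.unsorted(rev(object@summary$score), strictly = FALSE))
        return("summary must be ranked by non-increasing score")
    TRUE
})
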