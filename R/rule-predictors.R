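.emptyCalls <- function() {
    data.frame(drug = character(), method = character(),
               verdict = character(), genes = character(),
               z = numeric(), p = numeric(), score = numeric())
}

# one-sided standard-normal tail; monotone in |z| as required of the
# rule-triggered p values
.pFromZ <- function(z) pnorm(abs(z), lower.tail = FALSE)

.collapseDuplicateRules <- function(rules, keys) {
    dup <- duplicated(rules[keys])
    if (any(dup)) {
        warning(sum(dup), " duplicate rules collapsed")
        rules <- rules[!dup, , drop = FALSE]
    }
    rules
}

# within one method, a drug triggered by several rules keeps the minimum p
# and lists every triggering gene
.collapsePerDrug <- function(calls) {
    if (!nrow(calls)) return(.emptyCalls())
    out <- do.call(rbind, lapply(
        split(calls, paste(calls$drug, calls$verdict)), function(d) {
            best <- which.min(d$p)
            data.frame(drug = d$drug[1L], method = d$method[1L],
                verdict = d$verdict[1L],
                genes = paste(unique(d$genes), collapse = ","),
                z = d$z[best], p = d$p[best],
                score = -log10(d$p[best]))
        }))
    rownames(out) <- NULL
    out[order(out$p, out$drug), , drop = FALSE]
}

#' Drug target expression rules
#'
#' The most direct prediction method: an over-expressed gene (z at or above
#' the rule threshold, default +3) that is the known molecular target of an
#' antagonist indicates that drug — e.g. IF EGFR z >= +3 THEN INDICATE
#' cetuximab.  The call's p value is the upper-tail standard-normal
#' probability of the triggering z, so larger z gives smaller p.  Genes
#' absent from the profile trigger nothing; under-expression never fires
#' this method.
#'
#' @param zp a \code{\linkS4class{ZProfile}} in the identifier space the
#'   rules are keyed in.
#' @param rules data.frame with columns \code{gene}, \code{drug} and
#'   optionally \code{threshold} (z units, default 3; per-rule overrides
#'   allowed) and \code{evidence}.
#' @return Calls data.frame: drug, method (\code{"target-expression"}),
#'   verdict \code{"indicated"}, triggering genes, z of the best trigger,
#'   p, score \eqn{-\log_{10} p}.  Multiple triggered rules for one drug
#'   are collapsed to the minimum p with all genes listed.
#' @examples
#' zp <- ZProfile("s", c(EGFR = 3.5), space = "human-gene")
#' applyTargetRules(zp, data.frame(gene = "EGFR", drug = "cetuximab"))
#' @export
applyTargetRules <- function(zp, rules) {
    stopifnot(is(zp, "ZProfile"))
    rules <- as.data.frame(rules)
    if (is.null(rules$threshold)) rules$threshold <- 3
    stopifnot(all(rules$threshold > 0))
    rules <- .collapseDuplicateRules(rules, c("gene", "drug"))
    z <- zScores(zp)
    rules <- rules[rules$gene %in% names(z), , drop = FALSE]
    hit <- rules[z[rules$gene] >= rules$threshold, , drop = FALSE]
    if (!nrow(hit)) return(.emptyCalls())
    calls <- data.frame(drug = hit$drug, method = "target-expression",
        verdict = "indicated", genes = hit$gene, z = z[hit$gene],
        p = .pFromZ(z[hit$gene]))
    calls$score <- -log10(calls$p)
    .collapsePerDrug(calls)
}

#' Biomarker sensitivity and resistance rules
#'
#' Curated drug-biomarker rules in both directions: a marker state can
#' indicate a drug (sensitivity) or contraindicate it (resistance, e.g. IF
#' ERCC1 z >= +3 THEN CONTRAINDICATE oxaliplatin), and rules may trigger on
#' over-expression (z >= threshold) or under-expression (z <= -threshold).
#' p values are the one-sided normal tail of |z| as for target rules.
#'
#' @param zp a \code{\linkS4class{ZProfile}}.
#' @param rules data.frame with columns \code{gene}, \code{drug},
#'   \code{direction} (\code{"over"}/\code{"under"}), \code{effect}
#'   (\code{"sensitive"}/\code{"resistant"}) and optionally
#'   \code{threshold} (magnitude, default 3) and \code{evidence}.
#' @return Calls data.frame as in \code{\link{applyTargetRules}}; method is
#'   \code{"biomarker-sensitive"} or \code{"biomarker-resistant"}, verdict
#'   \code{"indicated"} for sensitive rules and \code{"contraindicated"}
#'   for resistant ones.
#' @examples
#' zp <- ZProfile("s", c(ERCC1 = 3.2), space = "human-gene")
#' applyBiomarkerRules(zp, data.frame(gene = "ERCC1", drug = "oxaliplatin",
#'     direction = "over", effect = "resistant"))
#' @export
applyBiomarkerRules <- function(zp, rules) {
    stopifnot(is(zp, "ZProfile"))
    rules <- as.data.frame(rules)
    stopifnot(all(rules$direction %in% c("over", "under")),
              all(rules$effect %in% c("sensitive", "resistant")))
    if (is.null(rules$threshold)) rules$threshold <- 3
    stopifnot(all(rules$threshold > 0))
    rules <- .collapseDuplicateRules(rules,
        c("gene", "drug", "direction", "effect"))
    z <- zScores(zp)
    rules <- rules[rules$gene %in% names(z), , drop = FALSE]
    if (!nrow(rules)) return(.emptyCalls())
    zr <- z[rules$gene]
    fired <- ifelse(rules$direction == "over",
                    zr >= rules$threshold, zr <= -rules$threshold)
    hit <- rules[fired, , drop = FALSE]
    if (!nrow(hit)) return(.emptyCalls())
    calls <- data.frame(drug = hit$drug,
        method = ifelse(hit$effect == "sensitive",
                        "biomarker-sensitive", "biomarker-resistant"),
        verdict = ifelse(hit$effect == "sensitive",
                         "indicated", "contraindicated"),
        genes = hit$gene, z = z[hit$gene], p = .pFromZ(z[hit$gene]))
    calls$score <- -log10(calls$p)
    .collapsePerDrug(calls)
}
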