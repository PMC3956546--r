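#' Default QA/QC thresholds
#'
#' The quality gates applied before a sample proceeds to expression
#' profiling: histopathology (at least 75\% tumor surface and nuclei, at
#' most 20\% necrosis), RNA (total yield >= 20 ng in the extraction volume,
#' A260/A280 >= 1.8, RIN >= 8.0), cDNA (ratio >= 1.8, yield >= 5 ug) and
#' array (mean background < 100, percent present call >= 30, scale factor
#' within a fold-tolerance of its target 100).
#'
#' @param necrosisFailCategory necrosis category that fails (default
#'   \code{">20%"}: categories up to 20\% pass).
#' @param rnaYieldNg minimum total RNA yield in ng (conc x volume).
#' @param rnaVolumeUl default extraction volume when a record lacks one.
#' @param rnaRatio,rin,cdnaRatio,cdnaYieldUg,arrayBackground,arrayPresentCall
#'   scalar thresholds as described above.
#' @param scaleFactorTarget,scaleFactorFold scale factor target and the
#'   maximum fold deviation from it considered acceptable.
#' @return Named list of thresholds consumed by the \code{evaluate*} gates.
#' @export
qcThresholds <- function(necrosisFailCategory = ">20%",
                         rnaYieldNg = 20, rnaVolumeUl = 14,
                         rnaRatio = 1.8, rin = 8.0,
                         cdnaRatio = 1.8, cdnaYieldUg = 5,
                         arrayBackground = 100, arrayPresentCall = 30,
                         scaleFactorTarget = 100, scaleFactorFold = 3) {
    list(necrosisFailCategory = necrosisFailCategory,
         rnaYieldNg = rnaYieldNg, rnaVolumeUl = rnaVolumeUl,
         rnaRatio = rnaRatio, rin = rin,
         cdnaRatio = cdnaRatio, cdnaYieldUg = cdnaYieldUg,
         arrayBackground = arrayBackground,
         arrayPresentCall = arrayPresentCall,
         scaleFactorTarget = scaleFactorTarget,
         scaleFactorFold = scaleFactorFold)
}

.SURFACE_LEVELS <- c("0-24%", "25-49%", "50-74%", "75-100%")
.NECROSIS_LEVELS <- c("<10%", "10-20%", ">20%")

.normCategory <- function(x) {
    # unify unicode dashes and the 0%-24% spelling variants
    x <- gsub("–|—", "-", as.character(x))
    gsub("%-", "-", x, fixed = TRUE)
}

.verdict <- function(stage, verdict, reasons = NULL) {
    list(stage = stage, verdict = verdict,
         reasons = if (is.null(reasons))
             data.frame(metric = character(), value = character(),
                        threshold = character())
         else reasons)
}

.reason <- function(metric, value, threshold) {
    data.frame(metric = metric, value = as.character(value),
               threshold = as.character(threshold))
}

.fieldNA <- function(rec, field) {
    is.null(rec[[field]]) || is.na(rec[[field]])
}

#' Histopathology QA/QC gate
#'
#' Passes a sample when both tumor surface area and tumor nuclei fall in
#' the top ordinal category (75-100\%) and the necrosis category is not the
#' failing one (by default >20\%).  A missing category yields a
#' not-evaluated verdict rather than a failure.
#'
#' @param rec one QC record: a list or one-row data.frame with fields
#'   \code{tumor_surface_category}, \code{tumor_nuclei_category},
#'   \code{necrosis_category} from the ordinal sets
#'   0-24\%/25-49\%/50-74\%/75-100\% and <10\%/10-20\%/>20\%.
#' @param thresholds see \code{\link{qcThresholds}}.
#' @return Stage verdict: list with \code{stage}, \code{verdict}
#'   (pass/fail/not-evaluated) and a \code{reasons} data.frame.
#' @examples
#' evaluateHistopathology(list(tumor_surface_category = "75-100%",
#'     tumor_nuclei_category = "75-100%", necrosis_category = "<10%"))
#' @export
evaluateHistopathology <- function(rec, thresholds = qcThresholds()) {
    fields <- c("tumor_surface_category", "tumor_nuclei_category",
                "necrosis_category")
    if (any(vapply(fields, function(f) .fieldNA(rec, f), logical(1L))))
        return(.verdict("histopathology", "not-evaluated",
                        .reason("histopathology", "NA", "categories present")))
    surface <- .normCategory(rec$tumor_surface_category)
    nuclei <- .normCategory(rec$tumor_nuclei_category)
    necrosis <- .normCategory(rec$necrosis_category)
    if (!surface %in% .SURFACE_LEVELS || !nuclei %in% .SURFACE_LEVELS)
        stop("unknown tumor category: ", surface, " / ", nuclei)
    if (!necrosis %in% .NECROSIS_LEVELS)
        stop("unknown necrosis category: ", necrosis)
    reasons <- NULL
    if (surface != "75-100%")
        reasons <- rbind(reasons, .reason("tumor_surface", surface, "75-100%"))
    if (nuclei != "75-100%")
        reasons <- rbind(reasons, .reason("tumor_nuclei", nuclei, "75-100%"))
    if (necrosis == .normCategory(thresholds$necrosisFailCategory))
        reasons <- rbind(reasons, .reason("necrosis", necrosis,
            paste("not", thresholds$necrosisFailCategory)))
    .verdict("histopathology", if (is.null(reasons)) "pass" else "fail",
             reasons)
}

#' RNA QA/QC gate
#'
#' Passes when total yield (concentration x volume) reaches 20 ng, the
#' A260/A280 purity ratio reaches 1.8, and the RNA integrity number (RIN)
#' reaches 8.0.  Metrics recorded as NA are skipped (not failed); if all
#' are missing the stage is not evaluated.
#'
#' @param rec record with fields \code{rna_conc} (ng/ul),
#'   \code{rna_volume} (ul; defaulted when absent), \code{rna_ratio},
#'   \code{rin}.
#' @inheritParams evaluateHistopathology
#' @return Stage verdict list.
#' @examples
#' evaluateRNA(list(rna_conc = 614.62, rna_ratio = 2.10, rin = 2.60))
#' @export
evaluateRNA <- function(rec, thresholds = qcThresholds()) {
    haveYield <- !.fieldNA(rec, "rna_conc")
    haveRatio <- !.fieldNA(rec, "rna_ratio")
    haveRin <- !.fieldNA(rec, "rin")
    if (!haveYield && !haveRatio && !haveRin)
        return(.verdict("rna", "not-evaluated"))
    reasons <- NULL
    if (haveYield) {
        if (rec$rna_conc < 0) stop("negative rna_conc")
        vol <- if (.fieldNA(rec, "rna_volume")) thresholds$rnaVolumeUl
               else rec$rna_volume
        yield <- rec$rna_conc * vol
        if (yield < thresholds$rnaYieldNg)
            reasons <- rbind(reasons, .reason("rna_yield_ng",
                round(yield, 2), paste(">=", thresholds$rnaYieldNg)))
    }
    if (haveRatio && rec$rna_ratio < thresholds$rnaRatio)
        reasons <- rbind(reasons, .reason("rna_ratio", rec$rna_ratio,
            paste(">=", thresholds$rnaRatio)))
    if (haveRin && rec$rin < thresholds$rin)
        reasons <- rbind(reasons, .reason("rin", rec$rin,
            paste(">=", thresholds$rin)))
    .verdict("rna", if (is.null(reasons)) "pass" else "fail", reasons)
}

#' cDNA QA/QC gate
#'
#' Passes when the amplified cDNA A260/A280 ratio reaches 1.8 and the yield
#' reaches 5 ug.
#'
#' @param rec record with fields \code{cdna_ratio}, \code{cdna_yield} (ug).
#' @inheritParams evaluateHistopathology
#' @return Stage verdict list.
#' @export
evaluateCDNA <- function(rec, thresholds = qcThresholds()) {
    haveRatio <- !.fieldNA(rec, "cdna_ratio")
    haveYield <- !.fieldNA(rec, "cdna_yield")
    if (!haveRatio && !haveYield)
        return(.verdict("cdna", "not-evaluated"))
    reasons <- NULL
    if (haveRatio && rec$cdna_ratio < thresholds$cdnaRatio)
        reasons <- rbind(reasons, .reason("cdna_ratio", rec$cdna_ratio,
            paste(">=", thresholds$cdnaRatio)))
    if (haveYield && rec$cdna_yield < thresholds$cdnaYieldUg)
        reasons <- rbind(reasons, .reason("cdna_yield_ug", rec$cdna_yield,
            paste(">=", thresholds$cdnaYieldUg)))
    .verdict("cdna", if (is.null(reasons)) "pass" else "fail", reasons)
}

#' Array QA/QC gate
#'
#' Passes when mean array background is below 100 intensity units, percent
#' present call is at least 30, and the scale factor lies within a
#' configurable fold tolerance (default 3-fold) of its target of 100.
#'
#' @param rec record with fields \code{array_background},
#'   \code{array_present_call} (percent), \code{array_scale_factor}.
#' @inheritParams evaluateHistopathology
#' @return Stage verdict list.
#' @export
evaluateArray <- function(rec, thresholds = qcThresholds()) {
    haveBg <- !.fieldNA(rec, "array_background")
    havePc <- !.fieldNA(rec, "array_present_call")
    haveSf <- !.fieldNA(rec, "array_scale_factor")
    if (!haveBg && !havePc && !haveSf)
        return(.verdict("array", "not-evaluated"))
    reasons <- NULL
    if (haveBg && rec$array_background >= thresholds$arrayBackground)
        reasons <- rbind(reasons, .reason("array_background",
            rec$array_background, paste("<", thresholds$arrayBackground)))
    if (havePc && rec$array_present_call < thresholds$arrayPresentCall)
        reasons <- rbind(reasons, .reason("array_present_call",
            rec$array_present_call,
            paste(">=", thresholds$arrayPresentCall)))
    if (haveSf) {
        lo <- thresholds$scaleFactorTarget / thresholds$scaleFactorFold
        hi <- thresholds$scaleFactorTarget * thresholds$scaleFactorFold
        if (rec$array_scale_factor < lo || rec$array_scale_factor > hi)
            reasons <- rbind(reasons, .reason("array_scale_factor",
                rec$array_scale_factor, sprintf("[%g, %g]", lo, hi)))
    }
    .verdict("array", if (is.null(reasons)) "pass" else "fail", reasons)
}

#' Gate a cohort of QC records
#'
#' Applies all four stage gates to every record and summarizes pass counts.
#' A sample passes overall when every evaluated stage passes; stages whose
#' metrics were never measured (for instance because the sample already
#' failed an earlier stage and was not processed further) are
#' not-evaluated and do not veto.
#'
#' @param records data.frame of QC records, one row per sample, with a
#'   \code{sample_id} column and the metric fields consumed by the
#'   \code{evaluate*} gates (NA = not measured).
#' @param thresholds see \code{\link{qcThresholds}}.
#' @return List with \code{verdicts} (data.frame: sample_id, one column per
#'   stage, \code{overall}, \code{reasons} string) and \code{summary}
#'   (data.frame per stage plus overall: n evaluated, n passed, percent of
#'   the whole cohort passing; overall percent rounded to the nearest
#'   integer as reported).
#' @examples
#' gateCohort(qcFixtureTable())$summary
#' @export
gateCohort <- function(records, thresholds = qcThresholds()) {
    records <- as.data.frame(records)
    if (!nrow(records)) stop("no QC records supplied")
    if (is.null(records$sample_id)) stop("records need a sample_id column")
    stages <- c("histopathology", "rna", "cdna", "array")
    evalFuns <- list(histopathology = evaluateHistopathology,
                     rna = evaluateRNA, cdna = evaluateCDNA,
                     array = evaluateArray)
    rows <- lapply(seq_len(nrow(records)), function(i) {
        rec <- as.list(records[i, ])
        vs <- lapply(evalFuns, function(f) f(rec, thresholds))
        verdicts <- vapply(vs, `[[`, character(1L), "verdict")
        reasons <- do.call(rbind, lapply(vs, `[[`, "reasons"))
        overall <- if (any(verdicts == "fail")) "fail" else "pass"
        data.frame(sample_id = rec$sample_id,
                   as.list(setNames(verdicts, stages)),
                   overall = overall,
                   reasons = paste(sprintf("%s=%s (need %s)",
                       reasons$metric, reasons$value, reasons$threshold),
                       collapse = "; "))
    })
    verdicts <- do.call(rbind, rows)
    n <- nrow(verdicts)
    summary <- do.call(rbind, lapply(c(stages, "overall"), function(st) {
        v <- verdicts[[st]]
        data.frame(stage = st,
                   evaluated = sum(v != "not-evaluated"),
                   passed = sum(v == "pass"),
                   pctPassed = if (st == "overall")
                       round(100 * sum(v == "pass") / n)
                   else round(100 * sum(v == "pass") / n, 2))
    }))
    list(verdicts = verdicts, summary = summary)
}
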