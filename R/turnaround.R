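#' Parse ISO-8601 timestamps with zone offsets
#'
#' Reads timestamps of the form \code{2011-06-03T16:00:00-0400} (or with a
#' colon in the offset) and returns POSIXct.  Timestamps without an
#' explicit zone offset are rejected: the turnaround clock converts all
#' event times to a single civil zone before any arithmetic, so the source
#' offset must be known.
#'
#' @param x character vector of timestamps.
#' @param tz zone to represent the result in (display only; the instant is
#'   defined by the embedded offset).
#' @return POSIXct vector.
#' @examples
#' parseEventTime("2011-06-03T16:00:00-0600")
#' @export
parseEventTime <- function(x, tz = "America/New_York") {
    x <- as.character(x)
    if (any(!grepl("[+-][0-9]{2}:?[0-9]{2}$", x)))
        stop("timestamp lacks a zone offset: ",
             paste(head(x[!grepl("[+-][0-9]{2}:?[0-9]{2}$", x)], 3L),
                   collapse = ", "))
    x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
    out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S%z", tz = tz))
    if (anyNA(out)) stop("unparseable timestamp")
    out
}

#' Format a POSIXct as ISO-8601 with offset
#'
#' @param x POSIXct vector.
#' @param tz zone whose offset to embed.
#' @return character vector like \code{"2011-06-03T16:00:00-0400"}.
#' @export
formatEventTime <- function(x, tz = "America/New_York") {
    format(x, "%Y-%m-%dT%H:%M:%S%z", tz = tz)
}

.isBusinessDay <- function(dates, cal) {
    !(weekdays(dates) %in% cal@weekend) & !(dates %in% cal@holidays)
}

#' Elapsed business hours between two events
#'
#' Wall-clock hours between \code{start} and \code{end} minus every hour
#' falling on a weekend day or holiday of the calendar, evaluated in the
#' calendar's civil time zone (US Eastern by default, so daylight saving is
#' honoured).  All 24 hours of a business day count: the clock measures
#' around-the-clock laboratory turnaround, not a 9-to-5 window.
#' Fractional hours are preserved.
#'
#' @param start,end POSIXct instants (or ISO-8601 strings with zone
#'   offsets, see \code{\link{parseEventTime}}); \code{end} must not
#'   precede \code{start}.
#' @param cal a \code{\link{businessCalendar}}.
#' @return Elapsed business hours (numeric scalar).
#' @examples
#' cal <- businessCalendar()
#' elapsedBusinessHours("2011-06-03T16:00:00-0400",
#'                      "2011-06-06T10:00:00-0400", cal)  # Fri 16h -> Mon 10h
#' @export
elapsedBusinessHours <- function(start, end, cal = businessCalendar()) {
    if (is.character(start)) start <- parseEventTime(start, cal@tz)
    if (is.character(end)) end <- parseEventTime(end, cal@tz)
    stopifnot(length(start) == 1L, length(end) == 1L)
    if (end < start) stop("end precedes start")
    total <- as.numeric(difftime(end, start, units = "hours"))
    days <- seq(as.Date(start, tz = cal@tz), as.Date(end, tz = cal@tz),
                by = "day")
    excluded <- days[!.isBusinessDay(days, cal)]
    if (!length(excluded)) return(total)
    cut <- 0
    for (d in as.list(excluded)) {
        dayStart <- as.POSIXct(paste(d, "00:00:00"), tz = cal@tz)
        dayEnd <- as.POSIXct(paste(d + 1L, "00:00:00"), tz = cal@tz)
        lo <- max(as.numeric(start), as.numeric(dayStart))
        hi <- min(as.numeric(end), as.numeric(dayEnd))
        if (hi > lo) cut <- cut + (hi - lo) / 3600
    }
    total - cut
}

#' Advance a timestamp by a number of business hours
#'
#' Inverse of \code{\link{elapsedBusinessHours}}: walks forward from
#' \code{start}, skipping weekend and holiday days entirely, until the
#' requested number of business hours has elapsed.
#'
#' @param start POSIXct start instant.
#' @param hours business hours to add (non-negative).
#' @param cal a \code{\link{businessCalendar}}.
#' @return POSIXct end instant with
#'   \code{elapsedBusinessHours(start, end, cal) == hours}.
#' @export
advanceBusinessHours <- function(start, hours, cal = businessCalendar()) {
    stopifnot(hours >= 0)
    if (is.character(start)) start <- parseEventTime(start, cal@tz)
    cur <- start
    remaining <- hours
    repeat {
        d <- as.Date(cur, tz = cal@tz)
        dayEnd <- as.POSIXct(paste(d + 1L, "00:00:00"), tz = cal@tz)
        if (.isBusinessDay(d, cal)) {
            left <- as.numeric(difftime(dayEnd, cur, units = "hours"))
            if (remaining <= left + 1e-9)
                return(cur + remaining * 3600)
            remaining <- remaining - left
        }
        cur <- dayEnd
    }
}

#' Convert business hours to days
#'
#' @param hours non-negative business hours.
#' @param digits decimals to round to for reporting (default 2).
#' @return \code{hours / 24}, rounded.
#' @examples
#' hoursToDays(116.46)  # 4.85
#' hoursToDays(91)      # 3.79
#' @export
hoursToDays <- function(hours, digits = 2) {
    if (any(hours < 0)) stop("negative hours")
    round(hours / 24, digits)
}

#' Deadline check
#'
#' Flags whether a case's turnaround met the prospectively defined clinical
#' deadline of 168 business hours (7 business days).
#'
#' @param businessHours non-negative hours (vectorized).
#' @param threshold deadline in business hours (default 168).
#' @return character vector, \code{"within"} or \code{"over"} (boundary is
#'   within: the deadline is inclusive).
#' @export
checkDeadline <- function(businessHours, threshold = 168) {
    stopifnot(all(businessHours >= 0))
    ifelse(businessHours <= threshold, "within", "over")
}

#' Summarize cohort turnaround times
#'
#' Computes per-cohort mean business and total (wall) hours plus a
#' case-weighted all-cases row, with day conversions (hours / 24) and a
#' deadline flag per cohort mean.  Accepts either per-case rows or
#' pre-aggregated cohort means with an \code{n} column.
#'
#' @param cases data.frame with columns \code{cohort},
#'   \code{business_hours}, \code{total_hours} and optionally \code{n}
#'   (defaults to 1 per row, i.e. per-case data).
#' @param deadline business-hours deadline passed to
#'   \code{\link{checkDeadline}}.
#' @param digits reporting decimals.
#' @return data.frame with one row per cohort plus an \code{"All Cases"}
#'   row: n, mean business hours, business days, mean total hours, total
#'   days, deadline flag.  The all-cases means are case-weighted:
#'   \eqn{\sum_c n_c \bar x_c / \sum_c n_c}.
#' @examples
#' summarizeCohorts(data.frame(
#'     cohort = c("Open histology", "Lymphoma", "TCC", "Melanoma"),
#'     n = c(10, 5, 4, 5),
#'     business_hours = c(114.50, 117.00, 116.75, 119.60),
#'     total_hours = c(174.50, 165.00, 158.75, 167.60)))
#' @export
summarizeCohorts <- function(cases, deadline = 168, digits = 2) {
    cases <- as.data.frame(cases)
    need <- c("cohort", "business_hours", "total_hours")
    if (!nrow(cases)) stop("no cases supplied")
    if (!all(need %in% names(cases)))
        stop("cases needs columns: ", paste(need, collapse = ", "))
    if (is.null(cases$n)) cases$n <- 1L
    agg <- do.call(rbind, lapply(split(cases, cases$cohort), function(d) {
        data.frame(cohort = d$cohort[1L], n = sum(d$n),
                   business_hours = sum(d$business_hours * d$n) / sum(d$n),
                   total_hours = sum(d$total_hours * d$n) / sum(d$n))
    }))
    agg <- agg[order(match(agg$cohort, unique(cases$cohort))), ,
               drop = FALSE]
    all <- data.frame(cohort = "All Cases", n = sum(agg$n),
        business_hours = sum(agg$business_hours * agg$n) / sum(agg$n),
        total_hours = sum(agg$total_hours * agg$n) / sum(agg$n))
    out <- rbind(agg, all)
    data.frame(cohort = out$cohort, n = out$n,
        business_hours = round(out$business_hours, digits),
        business_days = hoursToDays(out$business_hours, digits),
        total_hours = round(out$total_hours, digits),
        total_days = hoursToDays(out$total_hours, digits),
        deadline = checkDeadline(out$business_hours, deadline),
        row.names = NULL)
}

#' Per-case turnaround from event logs
#'
#' Computes business and wall hours from the first to the last event of
#' each sample's log.
#'
#' @param events data.frame with columns \code{sample_id}, \code{cohort},
#'   \code{event}, \code{time} (ISO-8601 with zone offset, or POSIXct).
#' @param cal a \code{\link{businessCalendar}}.
#' @return data.frame: sample_id, cohort, business_hours, total_hours.
#' @export
caseTurnaround <- function(events, cal = businessCalendar()) {
    events <- as.data.frame(events)
    if (is.character(events$time))
        events$time <- parseEventTime(events$time, cal@tz)
    do.call(rbind, lapply(split(events, events$sample_id), function(d) {
        d <- d[order(d$time), , drop = FALSE]
        span <- range(d$time)
        data.frame(sample_id = d$sample_id[1L], cohort = d$cohort[1L],
            business_hours = elapsedBusinessHours(span[1L], span[2L], cal),
            total_hours = as.numeric(difftime(span[2L], span[1L],
                                              units = "hours")))
    }))
}

#' US federal holidays for the 2011 study window
#'
#' Holiday dates bundled as the default exclusion list for the study-year
#' calendar.
#'
#' @return \code{Date} vector of 2011 US federal holidays.
#' @export
usHolidays2011 <- function() {
    f <- system.file("extdata", "holidays-us-2011.txt",
                     package = "PMedProfiler")
    x <- readLines(f)
    as.Date(x[nzchar(x) & !startsWith(x, "#")])
}
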