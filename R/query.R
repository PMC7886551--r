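## Cohort identification, index-time anchoring and feature construction over
## long-format event tables (patient_id, event_type, timestamp, attr_name,
## attr_value).

.OPS <- c("==", "!=", "<", "<=", ">", ">=")

#' Build a cohort query
#'
#' A query is a list of filters plus an optional index-event rule. Each
#' filter names an event type and attribute, a comparison operator and a
#' value; a patient is selected when, for every filter, at least one of
#' their events satisfies it (set semantics, order-insensitive). Attribute
#' values are compared numerically when both sides parse as numbers, as
#' dates when the filter value parses as an ISO date, and as strings
#' (equality only) otherwise.
#'
#' @param filters list of filters, each a list with elements
#'   \code{event_type}, \code{attribute}, \code{op} (one of ==, !=, <, <=,
#'   >, >=) and \code{value}.
#' @param indexEventRule optional list with \code{event_type} and
#'   \code{which} ("first" or "last") selecting the anchor event per patient.
#' @return A list of class \code{CohortQuery}.
#' @examples
#' cohortQuery(filters = list(
#'   list(event_type = "demographic", attribute = "sex", op = "==",
#'        value = "male")))
#' @export
cohortQuery <- function(filters = list(), indexEventRule = NULL) {
    if (!length(filters) && is.null(indexEventRule))
        stop("at least one of filters/index rule must be present")
    for (f in filters) {
        if (is.null(f$event_type) || is.null(f$attribute) ||
            is.null(f$op) || is.null(f$value))
            stop("each filter needs event_type, attribute, op, value")
        if (!f$op %in% .OPS)
            stop("unsupported operator: ", f$op)
    }
    structure(list(filters = filters, indexEventRule = indexEventRule),
              class = "CohortQuery")
}

.applyFilter <- function(events, f) {
    hit <- events$event_type == f$event_type & events$attr_name == f$attribute
    if (!any(hit))
        stop(sprintf("schema error: no attribute '%s' on event type '%s'",
                     f$attribute, f$event_type))
    vals <- events$attr_value[hit]
    fv <- f$value
    numTarget <- suppressWarnings(as.numeric(fv))
    if (!is.na(numTarget)) {
        v <- suppressWarnings(as.numeric(vals))
        ok <- !is.na(v) & do.call(f$op, list(v, numTarget))
    } else {
        dateTarget <- parseInstant(as.character(fv))
        if (!is.na(dateTarget)) {
            v <- parseInstant(vals)
            ok <- !is.na(v) & do.call(f$op, list(v, dateTarget))
        } else {
            if (!f$op %in% c("==", "!="))
                stop("ordering comparison on non-numeric, non-date value: ", fv)
            ok <- do.call(f$op, list(vals, as.character(fv)))
        }
    }
    unique(events$patient_id[hit][ok])
}

#' Select a cohort from longitudinal event data
#'
#' Applies every filter of a [cohortQuery()] with AND semantics: the result
#' is exactly the set of patient ids having, for each filter, at least one
#' satisfying event. Deterministic and insensitive to event order; an empty
#' filter list selects every patient.
#'
#' @param events long-format event data.frame (see [readEventTable()]).
#' @param query a \code{CohortQuery}.
#' @return Sorted character vector of patient ids.
#' @export
selectCohort <- function(events, query) {
    ids <- sort(unique(events$patient_id))
    for (f in query$filters)
        ids <- intersect(ids, .applyFilter(events, f))
    sort(ids)
}

#' Per-patient index-event times
#'
#' @param events long-format event data.frame.
#' @param rule list with \code{event_type} and \code{which} ("first"/"last").
#' @return Named POSIXct vector (one anchor per patient having the event).
#' @export
indexEventTimes <- function(events, rule) {
    hit <- events[events$event_type == rule$event_type, , drop = FALSE]
    ts <- parseInstant(hit$timestamp)
    pick <- if (identical(rule$which, "last")) max else min
    out <- tapply(ts, hit$patient_id, function(t) pick(t))
    .POSIXct(as.numeric(out), tz = "UTC", names = names(out))
}

#' Index time for non-event-anchored stays
#'
#' For stays longer than 24 hours the anchor is the midpoint between
#' admission and discharge; stays of 24 hours or less (boundary included)
#' are anchored 12 hours into the admission.
#'
#' @param admit,discharge POSIXct instants (or ISO-8601 strings).
#' @return POSIXct index time.
#' @examples
#' nonsepsisIndexTime("2015-01-01 00:00:00", "2015-01-03 00:00:00")
#' @export
nonsepsisIndexTime <- function(admit, discharge) {
    admit <- parseInstant(admit); discharge <- parseInstant(discharge)
    if (any(is.na(admit)) || any(is.na(discharge)))
        stop("unparseable admission/discharge instants")
    if (any(discharge < admit))
        stop("ordering error: discharge precedes admission")
    stay <- as.numeric(difftime(discharge, admit, units = "hours"))
    ifelse(stay > 24, admit + stay / 2 * 3600, admit + 12 * 3600) |>
        .POSIXct(tz = "UTC")
}

#' Slice events into a look-back window relative to an index time
#'
#' Retains exactly the events whose look-back lag \code{index - t} lies in
#' \code{[window[1], window[2]]} hours, closed at both ends.
#'
#' @param events event data.frame with a \code{timestamp} column.
#' @param indexTime POSIXct (or ISO-8601 string) anchor.
#' @param window numeric length-2 look-back interval in hours (upper may be
#'   \code{Inf}).
#' @return The retained subset of \code{events}.
#' @export
windowSlice <- function(events, indexTime, window = c(6, 24)) {
    if (length(window) != 2L || window[1] > window[2])
        stop("window must be an ordered length-2 interval")
    indexTime <- parseInstant(indexTime)
    lag <- as.numeric(difftime(indexTime, parseInstant(events$timestamp),
                               units = "hours"))
    events[!is.na(lag) & lag >= window[1] & lag <= window[2], , drop = FALSE]
}

#' Aggregate a value sequence into a scalar feature
#'
#' Supported aggregators: max, median, variance (n-1 denominator), count,
#' sum, mean, sd, first, last. \code{count} of an empty sequence is 0; every
#' other aggregator yields \code{NA} on empty input.
#'
#' @param values numeric vector.
#' @param aggregator aggregator name.
#' @return A scalar.
#' @examples
#' aggregateFeature(c(1, 2, 3, 4), "variance") # 1.6667
#' @export
aggregateFeature <- function(values, aggregator = c("max", "median",
        "variance", "count", "sum", "mean", "sd", "first", "last")) {
    aggregator <- match.arg(aggregator)
    if (aggregator == "count") return(length(values))
    if (!is.numeric(values)) stop("type error: numeric input required for '",
                                  aggregator, "'")
    if (!length(values)) return(NA_real_)
    switch(aggregator,
           max = max(values), median = stats::median(values),
           variance = stats::var(values), sum = sum(values),
           mean = mean(values), sd = stats::sd(values),
           first = values[1L], last = values[length(values)])
}

#' Derive a composite feature from named scalars
#'
#' Evaluates an arithmetic formula (e.g. \code{"weight / height^2"} for BMI,
#' \code{"heart_rate / sbp"} for the shock index) over named operands. A
#' missing or absent operand propagates a missing result and logs the reason
#' as a message.
#'
#' @param features named list or vector of scalars.
#' @param formula character arithmetic expression over the feature names.
#' @return Scalar value, or \code{NA} (with attribute \code{reason}) when an
#'   operand is missing.
#' @examples
#' deriveComposite(list(weight = 80, height = 1.6), "weight / height^2")
#' @export
deriveComposite <- function(features, formula) {
    expr <- str2lang(formula)
    vars <- all.vars(expr)
    feats <- as.list(features)
    absent <- setdiff(vars, names(feats))
    na <- vars[vars %in% names(feats) &
               vapply(feats[intersect(vars, names(feats))],
                      function(v) is.na(v[1L]), logical(1))]
    if (length(absent) || length(na)) {
        reason <- sprintf("missing operand(s): %s",
                          paste(c(absent, na), collapse = ", "))
        message("deriveComposite: ", reason)
        return(structure(NA_real_, reason = reason))
    }
    eval(expr, envir = feats)
}

#' One-hot encode a categorical column
#'
#' Cardinality-2 columns stay a single 0/1 indicator of the second level;
#' higher cardinalities expand to one binary column per level (each row's
#' level columns then sum to 1).
#'
#' @param x character/factor vector.
#' @param name column name prefix.
#' @param levels declared level set; defaults to the sorted observed levels.
#'   A value outside the declared set is a schema error.
#' @return data.frame of binary columns.
#' @export
oneHotEncode <- function(x, name = "x", levels = NULL) {
    x <- as.character(x)
    if (is.null(levels)) levels <- sort(unique(x))
    if (length(levels) < 2L) stop("cardinality must be >= 2")
    bad <- setdiff(unique(x), levels)
    if (length(bad))
        stop("schema error: unseen level(s): ", paste(bad, collapse = ", "))
    if (length(levels) == 2L) {
        out <- data.frame(as.integer(x == levels[2L]))
        names(out) <- paste(name, levels[2L], sep = "_")
        return(out)
    }
    out <- as.data.frame(lapply(levels, function(l) as.integer(x == l)))
    names(out) <- paste(name, levels, sep = "_")
    out
}

#' Convert a numeric result into binary abnormal flags
#'
#' Threshold comparisons are inclusive: a low flag fires at values \eqn{\le}
#' the low threshold, high and critical flags at values \eqn{\ge} their
#' thresholds. Thresholds must be ordered low < high \eqn{\le} critical, so
#' a critical value always also carries the high flag.
#'
#' @param value numeric vector of results.
#' @param low,high,critical optional thresholds.
#' @return data.frame with one 0/1 column per supplied threshold.
#' @examples
#' abnormalFlags(4.5, high = 2, critical = 4) # high 1, critical 1
#' @export
abnormalFlags <- function(value, low = NULL, high = NULL, critical = NULL) {
    thr <- c(low = low[1L], high = high[1L], critical = critical[1L])
    if (!length(thr)) stop("configuration error: no thresholds supplied")
    if (!is.null(low) && !is.null(high) && low >= high)
        stop("configuration error: thresholds must satisfy low < high")
    if (!is.null(high) && !is.null(critical) && high > critical)
        stop("configuration error: thresholds must satisfy high <= critical")
    out <- list()
    if (!is.null(low)) out$low <- as.integer(value <= low)
    if (!is.null(high)) out$high <- as.integer(value >= high)
    if (!is.null(critical)) out$critical <- as.integer(value >= critical)
    as.data.frame(out)
}

#' Sample controls at a fixed ratio per case
#'
#' Draws exactly \code{ratio x length(caseIds)} distinct ids uniformly at
#' random from the pool (cases are excluded from the pool first, so the
#' result is disjoint from the cases).
#'
#' @param caseIds character/integer ids of cases.
#' @param poolIds candidate control ids.
#' @param ratio controls per case (default 2).
#' @param seed integer seed.
#' @return Vector of sampled control ids.
#' @export
sampleControls <- function(caseIds, poolIds, ratio = 2, seed = 1L) {
    pool <- setdiff(unique(poolIds), caseIds)
    need <- ratio * length(unique(caseIds))
    if (length(pool) < need)
        stop(sprintf("sampling error: pool of %d cannot supply %d controls",
                     length(pool), need))
    set.seed(as.integer(seed))
    sample(pool, need)
}
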