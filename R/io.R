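#' Read and write feature specifications as JSON
#'
#' The on-disk form is a JSON array with one object per feature:
#' \code{\{"name", "kind", "lower", "upper", "grouping", "levels"\}}.
#'
#' @param path file path.
#' @return \code{readFeatureSpec} returns a [FeatureSpec-class];
#'   \code{writeFeatureSpec} returns \code{path} invisibly.
#' @export
readFeatureSpec <- function(path) {
    if (!file.exists(path)) stop("feature spec file not found: ", path)
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    lv <- list()
    rows <- lapply(raw, function(f) {
        if (is.null(f$name) || is.null(f$kind))
            stop("each feature entry needs 'name' and 'kind'")
        if (!is.null(f$levels)) lv[[f$name]] <<- as.character(unlist(f$levels))
        data.frame(name = f$name, kind = f$kind,
                   lower = if (is.null(f$lower)) NA_real_ else as.numeric(f$lower),
                   upper = if (is.null(f$upper)) NA_real_ else as.numeric(f$upper),
                   grouping = isTRUE(f$grouping), stringsAsFactors = FALSE)
    })
    new("FeatureSpec", info = do.call(rbind, rows), levels = lv)
}

#' @rdname readFeatureSpec
#' @param spec a [FeatureSpec-class].
#' @export
writeFeatureSpec <- function(spec, path) {
    info <- spec@info
    out <- lapply(seq_len(nrow(info)), function(i) {
        f <- list(name = info$name[i], kind = info$kind[i],
                  grouping = info$grouping[i])
        if (!is.na(info$lower[i])) f$lower <- info$lower[i]
        if (!is.na(info$upper[i])) f$upper <- info$upper[i]
        lv <- spec@levels[[info$name[i]]]
        if (!is.null(lv)) f$levels <- as.list(lv)
        f
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read and write feature matrices as CSV
#'
#' CSV with header; column types are imposed by the accompanying
#' [FeatureSpec-class] (numeric kinds parsed as numeric, categoricals kept
#' as character).
#'
#' @param path CSV path.
#' @param spec a [FeatureSpec-class] or path to its JSON form.
#' @return \code{readFeatureMatrix} returns a [FeatureMatrix-class];
#'   \code{writeFeatureMatrix} returns \code{path} invisibly.
#' @export
readFeatureMatrix <- function(path, spec) {
    if (is.character(spec)) spec <- readFeatureSpec(spec)
    if (!file.exists(path)) stop("feature matrix file not found: ", path)
    dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    miss <- setdiff(spec@info$name, names(dat))
    if (length(miss))
        stop("matrix is missing spec columns: ", paste(miss, collapse = ", "))
    for (i in seq_len(nrow(spec@info))) {
        nm <- spec@info$name[i]
        if (spec@info$kind[i] != "categorical")
            dat[[nm]] <- as.numeric(dat[[nm]])
    }
    FeatureMatrix(dat, spec, provenance = list(source = path))
}

#' @rdname readFeatureMatrix
#' @param x a [FeatureMatrix-class] (or [SyntheticCohort-class], whose table
#'   is written together with a JSON sidecar of synthesis bookkeeping).
#' @export
writeFeatureMatrix <- function(x, path) {
    if (is(x, "SyntheticCohort")) {
        sidecar <- paste0(sub("\\.csv$", "", path), "_meta.json")
        jsonlite::write_json(list(
            censored_count = x@censoredCount, clip_count = x@clipCount,
            seed = x@seed,
            config = list(min_group_size = x@config@minGroupSize,
                          n_quantile_bins = x@config@nQuantileBins,
                          bandwidth_rule = x@config@bandwidthRule,
                          envelope_policy = x@config@envelopePolicy,
                          max_rejects = x@config@maxRejects)),
            sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        x <- x@matrix
    }
    utils::write.csv(x@data, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a longitudinal event table
#'
#' Long-format CSV with columns \code{patient_id}, \code{event_type},
#' \code{timestamp}, \code{attr_name}, \code{attr_value}: one row per
#' attribute of each time-stamped patient event.
#'
#' @param path CSV path.
#' @return data.frame with the five columns above (all character) and
#'   timestamps validated as parseable ISO-8601.
#' @export
readEventTable <- function(path) {
    if (!file.exists(path)) stop("event table not found: ", path)
    ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("patient_id", "event_type", "timestamp", "attr_name",
              "attr_value")
    miss <- setdiff(need, names(ev))
    if (length(miss))
        stop("event table is missing columns: ", paste(miss, collapse = ", "))
    if (any(!nzchar(ev$patient_id))) stop("patient_id must be non-empty")
    ts <- parseInstant(ev$timestamp)
    if (anyNA(ts)) stop("unparseable timestamps in event table")
    ev
}

#' Parse ISO-8601 instants (date or date-time) as UTC POSIXct
#' @param x character vector.
#' @return POSIXct vector (NA where unparseable).
#' @export
parseInstant <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    x <- as.character(x)
    fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
    out <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
    for (f in fmts) {
        idx <- which(is.na(out) & !is.na(x))
        if (!length(idx)) break
        out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
    }
    out
}
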