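## Population rates per 100,000 with census denominators, real-vs-synthetic
## rate differences with 95% confidence intervals, and choropleth-ready CSV
## export.

#' Event rate per 100,000 persons
#'
#' @param count nonnegative event count.
#' @param population positive denominator.
#' @return count / population x 100,000 (unrounded; table builders round to
#'   1 decimal for reporting).
#' @examples
#' eventRate(456, 580892) # 78.5 per 100,000 (to 1 decimal)
#' @export
eventRate <- function(count, population) {
    if (any(population <= 0)) stop("population must be > 0")
    if (any(count < 0)) stop("count must be >= 0")
    count / population * 1e5
}

#' Tally events and compute rates by year and/or zip code
#'
#' Counts events exhaustively per key combination and attaches census
#' denominators: the per-zip population when \code{"zip"} is a key, the
#' total population otherwise. Every event zip must have a denominator.
#' Mean age and percent female are carried along when the event table has
#' \code{age}/\code{sex} columns.
#'
#' @param events data.frame of patient-level events with columns among
#'   \code{year}, \code{zip}, \code{age}, \code{sex}.
#' @param denominators data.frame with columns \code{zip},
#'   \code{population}.
#' @param keys grouping keys, subset of c("year", "zip").
#' @return A [RateTable-class] (rates per 100,000, 1 decimal).
#' @export
aggregateRates <- function(events, denominators, keys = c("year", "zip")) {
    keys <- match.arg(keys, c("year", "zip"), several.ok = TRUE)
    missing <- setdiff(unique(as.character(events$zip)),
                       as.character(denominators$zip))
    if (length(missing))
        stop("zip(s) without census denominator: ",
             paste(missing, collapse = ", "))
    keyDf <- unique(events[, keys, drop = FALSE])
    keyDf <- keyDf[do.call(order, keyDf), , drop = FALSE]
    rows <- lapply(seq_len(nrow(keyDf)), function(i) {
        sel <- rep(TRUE, nrow(events))
        for (k in keys) sel <- sel & events[[k]] == keyDf[[k]][i]
        sub <- events[sel, , drop = FALSE]
        pop <- if ("zip" %in% keys)
            denominators$population[
                match(as.character(keyDf$zip[i]),
                      as.character(denominators$zip))]
        else sum(denominators$population)
        out <- keyDf[i, , drop = FALSE]
        out$count <- nrow(sub)
        out$population <- pop
        out$rate <- round(eventRate(nrow(sub), pop), 1)
        out$mean_age <- if ("age" %in% names(sub) && nrow(sub))
            mean(sub$age) else NA_real_
        out$pct_female <- if ("sex" %in% names(sub) && nrow(sub))
            100 * mean(sub$sex == "F") else NA_real_
        out
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    new("RateTable", table = tab)
}

#' Difference between synthetic and real rates with a 95% CI
#'
#' The difference is synthetic minus real (per 100,000). The confidence
#' interval is a Wald interval with Poisson variance for each rate
#' (var = rate^2 / count): difference +/- 1.96 sqrt(rate_r^2/n_r +
#' rate_s^2/n_s). Values are reported to 1 decimal.
#'
#' @param rateReal,rateSynth rates per 100,000.
#' @param countReal,countSynth the positive event counts behind each rate.
#' @param label optional label (e.g. the year).
#' @return One-row data.frame (label, difference, lower, upper).
#' @examples
#' rateDifference(83.6, 475, 80.2, 475, label = 2011) # difference -3.4
#' @export
rateDifference <- function(rateReal, countReal, rateSynth, countSynth,
                           label = NA) {
    if (any(c(countReal, countSynth) <= 0))
        stop("zero count: confidence interval undefined")
    diff <- rateSynth - rateReal
    se <- sqrt(rateReal^2 / countReal + rateSynth^2 / countSynth)
    data.frame(label = label,
               difference = round(diff, 1),
               lower = round(diff - 1.96 * se, 1),
               upper = round(diff + 1.96 * se, 1))
}

#' Export a rate table as a choropleth-ready CSV
#'
#' Writes exactly the columns \code{zip,year,count,population,rate,mean_age,
#' pct_female}, with zips as 5-character zero-padded strings.
#'
#' @param rateTable a [RateTable-class] keyed by year and zip.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
exportGeoCSV <- function(rateTable, path) {
    tab <- rateTable@table
    if (!nrow(tab)) stop("rate table is empty")
    out <- data.frame(
        zip = gsub(" ", "0", formatC(as.character(tab$zip), width = 5)),
        year = tab$year, count = tab$count, population = tab$population,
        rate = tab$rate, mean_age = tab$mean_age,
        pct_female = tab$pct_female)
    con <- tryCatch(file(path, "w"), error = function(e)
        stop("I/O error: cannot write ", path))
    on.exit(close(con))
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}
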