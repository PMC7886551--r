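## Summary-analysis stage: per-feature distributional comparisons and
## pairwise correlation deltas between a real table and its synthetic
## derivative.

#' Six-point quantile panel of a numeric feature
#'
#' Returns the minimum, 25th, 50th, 75th and 90th percentiles and the
#' maximum, with linear-interpolation (type 7) quantiles.
#'
#' @param values non-empty numeric vector.
#' @return Named numeric vector (min, q25, q50, q75, q90, max).
#' @export
summaryQuantiles <- function(values) {
    if (!length(values)) stop("empty input")
    q <- stats::quantile(values, probs = c(0, .25, .5, .75, .9, 1),
                         type = 7, names = FALSE)
    stats::setNames(q, c("min", "q25", "q50", "q75", "q90", "max"))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is below 20 and there are
#' no ties; otherwise the normal approximation with tie correction and no
#' continuity correction. If every value is tied across both samples the
#' rank-sum statistic is degenerate and p = 1 is returned with a flag.
#'
#' @param a,b numeric samples.
#' @return list(statistic, p.value, method, degenerate).
#' @export
wilcoxonRankSum <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    if (length(unique(c(a, b))) == 1L)
        return(list(statistic = length(a) * length(b) / 2, p.value = 1,
                    method = "degenerate", degenerate = TRUE))
    ties <- any(duplicated(c(a, b)))
    exact <- (length(a) + length(b)) < 20L && !ties
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = FALSE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         method = if (exact) "exact" else "normal approximation",
         degenerate = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic distribution.
#'
#' @param a,b numeric samples.
#' @return list(statistic, p.value).
#' @export
ksTwoSample <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Pearson chi-squared test of independence on a count table
#'
#' @param table r x c matrix of nonnegative counts with no all-zero row or
#'   column.
#' @return list(statistic, df, p.value).
#' @export
chiSquaredIndependence <- function(table) {
    table <- as.matrix(table)
    if (any(table < 0)) stop("counts must be nonnegative")
    zr <- which(rowSums(table) == 0); zc <- which(colSums(table) == 0)
    if (length(zr))
        stop("zero-margin error: all-zero row ", paste(zr, collapse = ", "))
    if (length(zc))
        stop("zero-margin error: all-zero column ", paste(zc, collapse = ", "))
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-safe). A constant input vector has
#' no defined rank correlation: \code{NA} is returned with a warning flag.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Scalar rho (possibly NA).
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("x and y must have equal length >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant input: Spearman rho undefined")
        return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
}

.numericFeatures <- function(spec)
    spec@info$name[spec@info$kind %in% c("continuous", "count", "binary")]

#' All pairwise correlation deltas between a real and a synthetic table
#'
#' @param real,synth [FeatureMatrix-class] objects (or data.frames) sharing
#'   at least two numeric features.
#' @param method "pearson" or "spearman".
#' @return data.frame with one row per unordered feature pair:
#'   \code{feature_a}, \code{feature_b}, \code{method}, \code{real},
#'   \code{synthetic}, \code{delta} (absolute difference).
#' @export
correlationDelta <- function(real, synth, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    rd <- if (is(real, "FeatureMatrix")) real@data else real
    sd_ <- if (is(synth, "FeatureMatrix")) synth@data else synth
    if (is(real, "FeatureMatrix")) {
        keep <- .numericFeatures(real@spec)
    } else {
        keep <- names(rd)[vapply(rd, is.numeric, logical(1))]
    }
    keep <- intersect(keep, names(sd_))
    if (length(keep) < 2L)
        stop("need at least 2 shared numeric features")
    cr <- stats::cor(rd[keep], method = method)
    cs <- stats::cor(sd_[keep], method = method)
    pairs <- utils::combn(keep, 2)
    data.frame(
        feature_a = pairs[1, ], feature_b = pairs[2, ], method = method,
        real = cr[t(pairs)], synthetic = cs[t(pairs)],
        delta = abs(cr[t(pairs)] - cs[t(pairs)]),
        stringsAsFactors = FALSE)
}

.levelCounts <- function(x, levels) {
    as.numeric(table(factor(as.character(x), levels = levels)))
}

#' Build the fidelity report comparing real and synthetic tables
#'
#' Numeric (continuous/count) features are compared with the Wilcoxon
#' rank-sum and Kolmogorov-Smirnov tests and a six-point quantile panel;
#' binary and categorical features with a chi-squared test on level counts.
#' All pairwise correlations are compared across the shared numeric
#' features. No multiple-testing adjustment is applied; the report instead
#' flags the number of tests with p below \code{alpha}.
#'
#' @param real a [FeatureMatrix-class].
#' @param synth a [FeatureMatrix-class] or [SyntheticCohort-class] with the
#'   same feature set (a mismatch is an error listing the difference).
#' @param alpha significance threshold for the summary flags (default 0.05).
#' @param corMethod correlation method for the pairwise panel.
#' @return A [FidelityReport-class].
#' @export
buildReport <- function(real, synth, alpha = 0.05,
                        corMethod = c("pearson", "spearman")) {
    corMethod <- match.arg(corMethod)
    if (is(synth, "SyntheticCohort")) synth <- synth@matrix
    rn <- featureNames(real); sn <- featureNames(synth)
    if (!setequal(rn, sn))
        stop("feature-set mismatch; only in real: [",
             paste(setdiff(rn, sn), collapse = ", "), "]; only in synthetic: [",
             paste(setdiff(sn, rn), collapse = ", "), "]")
    info <- real@spec@info
    rows <- list()
    for (i in seq_len(nrow(info))) {
        nm <- info$name[i]
        x <- real@data[[nm]]; y <- synth@data[[nm]]
        if (info$kind[i] %in% c("continuous", "count")) {
            qx <- summaryQuantiles(x); qy <- summaryQuantiles(y)
            w <- wilcoxonRankSum(x, y)
            k <- ksTwoSample(x, y)
            qcols <- c(stats::setNames(as.list(qx), paste0("real_", names(qx))),
                       stats::setNames(as.list(qy), paste0("synth_", names(qy))))
            rows[[length(rows) + 1L]] <- data.frame(
                feature = nm, kind = info$kind[i], test = "wilcoxon",
                statistic = w$statistic, p_value = w$p.value, qcols,
                stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                feature = nm, kind = info$kind[i], test = "ks",
                statistic = k$statistic, p_value = k$p.value, qcols,
                stringsAsFactors = FALSE)
        } else {
            lv <- if (info$kind[i] == "binary") c("0", "1")
                  else real@spec@levels[[nm]]
            tab <- rbind(real = .levelCounts(x, lv),
                         synth = .levelCounts(y, lv))
            tab <- tab[, colSums(tab) > 0, drop = FALSE]
            res <- tryCatch(chiSquaredIndependence(tab),
                            error = function(e) list(statistic = NA_real_,
                                                     df = NA_real_,
                                                     p.value = NA_real_))
            qna <- stats::setNames(
                as.list(rep(NA_real_, 12)),
                c(paste0("real_", c("min","q25","q50","q75","q90","max")),
                  paste0("synth_", c("min","q25","q50","q75","q90","max"))))
            rows[[length(rows) + 1L]] <- data.frame(
                feature = nm, kind = info$kind[i], test = "chi-squared",
                statistic = res$statistic, p_value = res$p.value, qna,
                stringsAsFactors = FALSE)
        }
    }
    fc <- do.call(rbind, rows)
    cc <- if (length(.numericFeatures(real@spec)) >= 2L)
        correlationDelta(real, synth, corMethod)
    else data.frame(feature_a = character(), feature_b = character(),
                    method = character(), real = numeric(),
                    synthetic = numeric(), delta = numeric())
    flags <- list(nSignificant = sum(fc$p_value < alpha, na.rm = TRUE),
                  maxCorrelationDelta = if (nrow(cc)) max(cc$delta) else NA_real_)
    new("FidelityReport", featureComparisons = fc,
        correlationComparisons = cc, alpha = alpha, flags = flags)
}

#' Write a fidelity report as JSON plus a flat TSV
#'
#' @param report a [FidelityReport-class].
#' @param jsonPath output JSON path.
#' @param tsvPath output TSV path (one row per feature comparison).
#' @return Invisibly, the JSON path.
#' @export
writeFidelityReport <- function(report, jsonPath, tsvPath = NULL) {
    jsonlite::write_json(list(
        alpha = report@alpha, flags = report@flags,
        feature_comparisons = report@featureComparisons,
        correlation_comparisons = report@correlationComparisons),
        jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows",
        na = "null", pretty = TRUE)
    if (!is.null(tsvPath))
        utils::write.table(report@featureComparisons, tsvPath, sep = "\t",
                           row.names = FALSE, quote = FALSE)
    invisible(jsonPath)
}
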