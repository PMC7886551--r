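#' Accessors for package containers
#'
#' \code{featureData} returns the underlying data.frame of a
#' [FeatureMatrix-class] or [SyntheticCohort-class]; \code{featureSpec}
#' returns the [FeatureSpec-class]; \code{censoredCount} and \code{clipCount}
#' return synthesis bookkeeping; \code{tstrMetrics} and \code{rateData}
#' return the result tables of the evaluation stages.
#'
#' @param x an object.
#' @return See details per class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname accessors
#' @export
setGeneric("featureSpec", function(x) standardGeneric("featureSpec"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("censoredCount", function(x) standardGeneric("censoredCount"))

#' @rdname accessors
#' @export
setGeneric("clipCount", function(x) standardGeneric("clipCount"))

#' @rdname accessors
#' @export
setGeneric("tstrMetrics", function(x) standardGeneric("tstrMetrics"))

#' @rdname accessors
#' @export
setGeneric("rateData", function(x) standardGeneric("rateData"))

#' @rdname accessors
#' @export
setMethod("featureData", "FeatureMatrix", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("featureData", "SyntheticCohort", function(x) x@matrix@data)

#' @rdname accessors
#' @export
setMethod("featureSpec", "FeatureMatrix", function(x) x@spec)

#' @rdname accessors
#' @export
setMethod("featureSpec", "SyntheticCohort", function(x) x@matrix@spec)

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureSpec", function(x) x@info$name)

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) x@spec@info$name)

#' @rdname accessors
#' @export
setMethod("censoredCount", "SyntheticCohort", function(x) x@censoredCount)

#' @rdname accessors
#' @export
setMethod("clipCount", "SyntheticCohort", function(x) x@clipCount)

#' @rdname accessors
#' @export
setMethod("tstrMetrics", "TSTRResult", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("rateData", "RateTable", function(x) x@table)

#' @describeIn accessors dimensions of the underlying table.
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@data))

#' Coerce a FeatureMatrix to a data.frame
#' @param x a [FeatureMatrix-class].
#' @param ... ignored.
#' @return The underlying data.frame.
#' @export
setMethod("as.data.frame", "FeatureMatrix", function(x, ...) x@data)

setMethod("show", "FeatureSpec", function(object) {
    cat(sprintf("FeatureSpec with %d features\n", nrow(object@info)))
    k <- table(object@info$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(k), k), collapse = ", "), "\n")
    g <- object@info$name[object@info$grouping]
    cat("  grouping:", if (length(g)) paste(g, collapse = ", ") else "<none>",
        "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix: %d rows x %d features\n",
                nrow(object@data), ncol(object@data)))
    show(object@spec)
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf(
        "SyntheticCohort: %d synthetic rows (censored %d, clipped %d, seed %d)\n",
        nrow(object@matrix@data), object@censoredCount, object@clipCount,
        object@seed))
})

setMethod("show", "FidelityReport", function(object) {
    fc <- object@featureComparisons
    cat(sprintf("FidelityReport: %d feature tests, %d correlation pairs\n",
                nrow(fc), nrow(object@correlationComparisons)))
    cat(sprintf("  tests with p < %.3g: %d; max |correlation delta|: %.4f\n",
                object@alpha, object@flags$nSignificant,
                object@flags$maxCorrelationDelta))
})

setMethod("show", "TSTRResult", function(object) {
    cat("TSTRResult (train -> test, holdout AUROC):\n")
    m <- object@metrics[object@metrics$split == "test", ]
    for (i in seq_len(nrow(m)))
        cat(sprintf("  %s -> %s: %.3f\n", m$train[i], m$test[i], m$auroc[i]))
})

setMethod("show", "RateTable", function(object) {
    cat(sprintf("RateTable: %d rows\n", nrow(object@table)))
    print(utils::head(object@table, 8))
})
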