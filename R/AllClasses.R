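#' @import methods
NULL

.FEATURE_KINDS <- c("continuous", "count", "binary", "categorical")

#' Typed description of the columns of a clinical feature matrix
#'
#' A \code{FeatureSpec} declares, for every column of a cohort feature matrix,
#' its kind (\code{continuous}, \code{count}, \code{binary} or
#' \code{categorical}), optional bounds, the level set for categorical
#' columns, and whether the column defines the "similar patient" strata used
#' by the synthesis engine.
#'
#' @slot info data.frame with columns \code{name}, \code{kind}, \code{lower},
#'   \code{upper}, \code{grouping} (one row per feature).
#' @slot levels named list of character level vectors, one entry per
#'   categorical feature.
#'
#' @seealso [FeatureSpec()], [FeatureMatrix-class]
#' @export
setClass("FeatureSpec",
    representation(info = "data.frame", levels = "list"))

setValidity("FeatureSpec", function(object) {
    info <- object@info
    msgs <- character()
    need <- c("name", "kind", "lower", "upper", "grouping")
    if (!all(need %in% names(info)))
        return(sprintf("info must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(info$name))
        msgs <- c(msgs, "feature names must be unique")
    if (!all(info$kind %in% .FEATURE_KINDS))
        msgs <- c(msgs, sprintf("kind must be one of %s",
                                paste(.FEATURE_KINDS, collapse = "/")))
    bad <- !is.na(info$lower) & !is.na(info$upper) & info$lower > info$upper
    if (any(bad))
        msgs <- c(msgs, sprintf("bounds out of order for: %s",
                                paste(info$name[bad], collapse = ", ")))
    for (nm in info$name[info$kind == "categorical"]) {
        lv <- object@levels[[nm]]
        if (is.null(lv) || length(lv) < 2L)
            msgs <- c(msgs, sprintf(
                "categorical feature '%s' needs >= 2 declared levels", nm))
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureSpec
#'
#' @param name character vector of feature names.
#' @param kind character vector (recycled) of kinds; one of
#'   \code{"continuous"}, \code{"count"}, \code{"binary"},
#'   \code{"categorical"}.
#' @param lower,upper optional numeric bounds (\code{NA} = unbounded).
#' @param grouping logical; does the feature define synthesis strata?
#' @param levels named list of level vectors for categorical features.
#'
#' @return A [FeatureSpec-class] object.
#' @examples
#' FeatureSpec(c("age", "sex"), kind = c("continuous", "categorical"),
#'             lower = c(0, NA), levels = list(sex = c("F", "M")))
#' @export
FeatureSpec <- function(name, kind, lower = NA_real_, upper = NA_real_,
                        grouping = FALSE, levels = list()) {
    info <- data.frame(
        name = as.character(name),
        kind = rep_len(as.character(kind), length(name)),
        lower = rep_len(as.numeric(lower), length(name)),
        upper = rep_len(as.numeric(upper), length(name)),
        grouping = rep_len(as.logical(grouping), length(name)),
        stringsAsFactors = FALSE)
    new("FeatureSpec", info = info, levels = levels)
}

#' Rectangular cohort feature matrix with typed columns
#'
#' Couples a patient-by-feature data.frame with the [FeatureSpec-class]
#' describing its columns, plus free-form provenance metadata (query, seed).
#' Validity enforces rectangularity, column/spec agreement, and per-kind value
#' conformity (counts integral, binaries in \{0,1\}, categoricals within the
#' declared level sets, bounds respected); values may be \code{NA}.
#'
#' @slot data data.frame of feature values, one row per cohort member.
#' @slot spec a [FeatureSpec-class].
#' @slot provenance list of metadata (e.g. generator name, seed).
#' @export
setClass("FeatureMatrix",
    representation(data = "data.frame", spec = "FeatureSpec",
                   provenance = "list"))

setValidity("FeatureMatrix", function(object) {
    info <- object@spec@info
    dat <- object@data
    if (!identical(sort(names(dat)), sort(info$name)))
        return(sprintf("columns (%s) do not match spec (%s)",
                       paste(names(dat), collapse = ","),
                       paste(info$name, collapse = ",")))
    msgs <- character()
    for (i in seq_len(nrow(info))) {
        nm <- info$name[i]; x <- dat[[nm]]; ok <- !is.na(x)
        switch(info$kind[i],
            continuous = , count = {
                if (!is.numeric(x)) {
                    msgs <- c(msgs, sprintf("'%s' must be numeric", nm)); next
                }
                if (info$kind[i] == "count" &&
                    any(abs(x[ok] - round(x[ok])) > 1e-8))
                    msgs <- c(msgs, sprintf("'%s' (count) must be integral", nm))
                if (!is.na(info$lower[i]) && any(x[ok] < info$lower[i]))
                    msgs <- c(msgs, sprintf("'%s' below lower bound", nm))
                if (!is.na(info$upper[i]) && any(x[ok] > info$upper[i]))
                    msgs <- c(msgs, sprintf("'%s' above upper bound", nm))
            },
            binary = {
                if (!is.numeric(x) || any(!x[ok] %in% c(0, 1)))
                    msgs <- c(msgs, sprintf("'%s' (binary) must be 0/1", nm))
            },
            categorical = {
                lv <- object@spec@levels[[nm]]
                if (any(!as.character(x[ok]) %in% lv))
                    msgs <- c(msgs, sprintf(
                        "'%s' has values outside declared levels", nm))
            })
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param data data.frame of feature values (columns must match \code{spec}).
#' @param spec a [FeatureSpec-class].
#' @param provenance optional list of metadata.
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(data, spec, provenance = list()) {
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    data <- data[, spec@info$name, drop = FALSE]
    new("FeatureMatrix", data = data, spec = spec, provenance = provenance)
}

#' Tuning knobs of the synthesis engine
#'
#' @slot minGroupSize privacy threshold k: strata with fewer members are
#'   censored in full (default 10).
#' @slot nQuantileBins number of quantile bins used to discretise continuous
#'   grouping features when forming strata (default 2: the stratum count
#'   grows exponentially with the number of grouping features, and strata
#'   must stay comfortably above the privacy threshold).
#' @slot bandwidthRule kernel bandwidth rule; only \code{"silverman"}.
#' @slot envelopePolicy treatment of out-of-envelope draws; only
#'   \code{"reject-then-clip"}.
#' @slot maxRejects kernel-noise redraws allowed before clipping (default 10).
#' @slot seed integer seed controlling all synthesis randomness.
#' @export
setClass("SynthesisConfig",
    representation(minGroupSize = "integer", nQuantileBins = "integer",
                   bandwidthRule = "character", envelopePolicy = "character",
                   maxRejects = "integer", seed = "integer"))

setValidity("SynthesisConfig", function(object) {
    msgs <- character()
    if (object@minGroupSize < 2L) msgs <- c(msgs, "minGroupSize must be >= 2")
    if (object@nQuantileBins < 1L) msgs <- c(msgs, "nQuantileBins must be >= 1")
    if (object@maxRejects < 1L) msgs <- c(msgs, "maxRejects must be >= 1")
    if (!identical(object@bandwidthRule, "silverman"))
        msgs <- c(msgs, "bandwidthRule must be 'silverman'")
    if (!identical(object@envelopePolicy, "reject-then-clip"))
        msgs <- c(msgs, "envelopePolicy must be 'reject-then-clip'")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SynthesisConfig
#'
#' @param minGroupSize,nQuantileBins,maxRejects,seed integers; see
#'   [SynthesisConfig-class].
#' @param bandwidthRule,envelopePolicy character; currently fixed choices.
#' @return A [SynthesisConfig-class] object.
#' @export
synthesisConfig <- function(minGroupSize = 10L, nQuantileBins = 2L,
                            bandwidthRule = "silverman",
                            envelopePolicy = "reject-then-clip",
                            maxRejects = 10L, seed = 1L) {
    new("SynthesisConfig", minGroupSize = as.integer(minGroupSize),
        nQuantileBins = as.integer(nQuantileBins),
        bandwidthRule = bandwidthRule, envelopePolicy = envelopePolicy,
        maxRejects = as.integer(maxRejects), seed = as.integer(seed))
}

#' Per-group kernel-density synthesis model
#'
#' Fitted on one stratum of "similar patients": per-dimension Gaussian kernel
#' bandwidths for numeric features, empirical level frequencies for
#' categorical features, the observed per-dimension envelope, and the member
#' rows themselves (the donors resampled during synthesis).
#'
#' @slot groupKey character label of the stratum.
#' @slot memberCount number of member rows.
#' @slot bandwidths named numeric; Gaussian kernel bandwidth per numeric
#'   feature (0 only for zero-dispersion columns).
#' @slot freqTables named list of per-level probabilities for categorical
#'   features.
#' @slot envelope named list of c(min, max) observed per numeric feature.
#' @slot kernelCor within-group correlation matrix of the numeric features
#'   with positive bandwidth; the Gaussian kernel draws its per-dimension
#'   noise jointly under this correlation so multivariate structure is not
#'   diluted by the smoothing.
#' @slot members data.frame of donor rows.
#' @slot spec the [FeatureSpec-class] of the parent matrix.
#' @export
setClass("GroupModel",
    representation(groupKey = "character", memberCount = "integer",
                   bandwidths = "numeric", freqTables = "list",
                   envelope = "list", kernelCor = "matrix",
                   members = "data.frame", spec = "FeatureSpec"))

setValidity("GroupModel", function(object) {
    msgs <- character()
    if (object@memberCount != nrow(object@members))
        msgs <- c(msgs, "memberCount must equal nrow(members)")
    for (nm in names(object@freqTables)) {
        p <- object@freqTables[[nm]]
        if (abs(sum(p) - 1) > 1e-8)
            msgs <- c(msgs, sprintf("frequencies for '%s' must sum to 1", nm))
    }
    if (any(object@bandwidths < 0))
        msgs <- c(msgs, "bandwidths must be nonnegative")
    if (length(msgs)) msgs else TRUE
})

#' A synthetic cohort and its synthesis bookkeeping
#'
#' @slot matrix the synthetic [FeatureMatrix-class]; rows carry no link to any
#'   source row (irreversibility by construction).
#' @slot censoredCount source rows withheld because their stratum fell below
#'   the privacy threshold.
#' @slot clipCount synthetic values clipped to the group envelope after
#'   exhausting kernel-noise redraws.
#' @slot config the [SynthesisConfig-class] used.
#' @slot seed the seed actually used.
#' @export
setClass("SyntheticCohort",
    representation(matrix = "FeatureMatrix", censoredCount = "integer",
                   clipCount = "integer", config = "SynthesisConfig",
                   seed = "integer"))

#' Fidelity report comparing a real table with its synthetic derivative
#'
#' @slot featureComparisons data.frame, one row per feature x test
#'   (rank-sum and Kolmogorov-Smirnov for numeric features, chi-squared on
#'   level counts otherwise) with quantile panels for numeric features.
#' @slot correlationComparisons data.frame of all pairwise correlations in
#'   both tables and their absolute deltas.
#' @slot alpha significance threshold used for the summary flags.
#' @slot flags list: \code{nSignificant} (tests with p < alpha) and
#'   \code{maxCorrelationDelta}.
#' @export
setClass("FidelityReport",
    representation(featureComparisons = "data.frame",
                   correlationComparisons = "data.frame",
                   alpha = "numeric", flags = "list"))

#' Numeric/binary feature matrix with a binary outcome label
#'
#' @slot features data.frame of numeric columns only.
#' @slot labels integer vector of 0/1 outcomes, one per row.
#' @slot meta list of metadata (e.g. the generative coefficients of a
#'   simulated cohort).
#' @export
setClass("LabeledMatrix",
    representation(features = "data.frame", labels = "integer",
                   meta = "list"))

setValidity("LabeledMatrix", function(object) {
    msgs <- character()
    if (nrow(object@features) != length(object@labels))
        msgs <- c(msgs, "labels must have one entry per feature row")
    if (!all(vapply(object@features, is.numeric, logical(1))))
        msgs <- c(msgs, "all feature columns must be numeric")
    if (!all(object@labels %in% c(0L, 1L)))
        msgs <- c(msgs, "labels must be 0/1")
    if (length(unique(object@labels)) < 2L && length(object@labels) > 0L)
        msgs <- c(msgs, "both outcome classes must be present")
    if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledMatrix
#' @param features data.frame of numeric columns.
#' @param labels 0/1 outcome vector.
#' @param meta optional metadata list.
#' @return A [LabeledMatrix-class].
#' @export
LabeledMatrix <- function(features, labels, meta = list()) {
    new("LabeledMatrix", features = as.data.frame(features),
        labels = as.integer(labels), meta = meta)
}

#' Train/test metric grid of the train-on-synthetic/test-on-real evaluation
#'
#' @slot metrics data.frame with columns \code{train}, \code{test},
#'   \code{split} (train/cv/test), and the five metrics accuracy, precision,
#'   recall, f1, auroc. The three (train, test) cells are
#'   (real, real), (synthetic, synthetic) and (synthetic, real).
#' @slot holdoutIndex integer row indices of the real held-out test set,
#'   shared by the (real, real) and (synthetic, real) cells.
#' @export
setClass("TSTRResult",
    representation(metrics = "data.frame", holdoutIndex = "integer"))

setValidity("TSTRResult", function(object) {
    cells <- unique(object@metrics[, c("train", "test")])
    want <- c("real|real", "synthetic|synthetic", "synthetic|real")
    have <- paste(cells$train, cells$test, sep = "|")
    if (!setequal(have, want))
        return("grid must contain exactly the three train/test cells")
    TRUE
})

#' Event rates per 100,000 by year and/or zip code
#'
#' @slot table data.frame with columns among \code{year}, \code{zip},
#'   \code{count}, \code{population}, \code{rate} (per 100,000, 1 decimal),
#'   \code{mean_age}, \code{pct_female}.
#' @export
setClass("RateTable", representation(table = "data.frame"))

setValidity("RateTable", function(object) {
    tab <- object@table
    msgs <- character()
    if (any(tab$population <= 0)) msgs <- c(msgs, "population must be > 0")
    if (any(tab$count < 0)) msgs <- c(msgs, "count must be >= 0")
    if (any(abs(tab$rate - round(tab$count / tab$population * 1e5, 1)) > 1e-8))
        msgs <- c(msgs, "rate must equal count/population x 100,000 (1 dp)")
    if (length(msgs)) msgs else TRUE
})
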