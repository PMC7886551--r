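## Synthesis core: stratify the cohort into groups of similar patients,
## fit a per-group kernel-density model, sample a synthetic cohort and
## censor unsupported extremes.

.isNumericKind <- function(kind) kind %in% c("continuous", "count")

## round half away from zero (used for count kinds after kernel jitter)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Silverman's rule-of-thumb kernel bandwidth
#'
#' \eqn{0.9 \min(s, IQR/1.34) n^{-1/5}}, computed within-group. A zero
#' interquartile range with positive standard deviation falls back to the
#' standard deviation, so the bandwidth is 0 only for zero-dispersion
#' columns (which the sampler then reproduces exactly).
#'
#' @param x numeric vector.
#' @return Nonnegative bandwidth.
#' @export
silvermanBandwidth <- function(x) {
    n <- length(x)
    if (n < 2L) return(0)
    s <- stats::sd(x)
    iqr <- stats::IQR(x, type = 7)
    scale <- min(s, iqr / 1.34)
    if (scale == 0) scale <- s
    0.9 * scale * n^(-1 / 5)
}

#' Partition a cohort into strata of similar patients
#'
#' Strata are the joint levels of the grouping categorical features crossed
#' with quantile bins (\code{nQuantileBins}) of the grouping numeric
#' features. Any stratum with fewer than \code{minGroupSize} members is
#' censored in full: its rows join the censored set and contribute no
#' synthetic rows. With no grouping features declared, all rows form a
#' single stratum.
#'
#' @param fm a [FeatureMatrix-class].
#' @param config a [SynthesisConfig-class].
#' @return list with \code{groups} (named list of row-index vectors) and
#'   \code{censored} (integer vector of censored row indices).
#' @export
partitionSimilar <- function(fm, config = synthesisConfig()) {
    dat <- fm@data
    if (!nrow(dat)) stop("input error: empty feature matrix")
    info <- fm@spec@info
    gfeat <- info[info$grouping, , drop = FALSE]
    if (!nrow(gfeat)) {
        keys <- rep("all", nrow(dat))
    } else {
        parts <- lapply(seq_len(nrow(gfeat)), function(i) {
            x <- dat[[gfeat$name[i]]]
            if (.isNumericKind(gfeat$kind[i])) {
                br <- unique(stats::quantile(
                    x, probs = seq(0, 1, length.out = config@nQuantileBins + 1L),
                    type = 7, na.rm = FALSE))
                if (length(br) < 2L) br <- c(br, br + 1)
                as.character(cut(x, breaks = br, include.lowest = TRUE))
            } else as.character(x)
        })
        keys <- do.call(paste, c(parts, sep = "|"))
    }
    idx <- split(seq_len(nrow(dat)), keys)
    small <- vapply(idx, length, integer(1)) < config@minGroupSize
    censored <- sort(unlist(idx[small], use.names = FALSE))
    groups <- idx[!small]
    if (!length(groups)) {
        sizes <- vapply(idx, length, integer(1))
        stop("empty-model error: all strata below the privacy threshold (",
             paste(sprintf("%s: %d", names(sizes), sizes), collapse = "; "),
             ")")
    }
    list(groups = groups[order(names(groups))],
         censored = if (is.null(censored)) integer(0) else censored)
}

#' Fit the kernel-density synthesis model of one stratum
#'
#' Numeric features get a within-group Gaussian-kernel bandwidth by
#' Silverman's rule and their observed min/max envelope; categorical
#' features get empirical level frequencies. The member rows are retained as
#' the donors resampled at synthesis time.
#'
#' @param rows data.frame of member rows (at least \code{minGroupSize}).
#' @param spec the [FeatureSpec-class].
#' @param config a [SynthesisConfig-class].
#' @param groupKey stratum label.
#' @return A [GroupModel-class].
#' @export
fitGroupModel <- function(rows, spec, config = synthesisConfig(),
                          groupKey = "all") {
    if (nrow(rows) < config@minGroupSize)
        stop(sprintf("precondition violation: %d rows < minGroupSize %d",
                     nrow(rows), config@minGroupSize))
    info <- spec@info
    bw <- numeric(0); env <- list(); freq <- list()
    for (i in seq_len(nrow(info))) {
        nm <- info$name[i]; x <- rows[[nm]]
        if (.isNumericKind(info$kind[i])) {
            bw[nm] <- silvermanBandwidth(x)
            env[[nm]] <- c(min(x), max(x))
        } else if (info$kind[i] == "binary") {
            tab <- c(`0` = mean(x == 0), `1` = mean(x == 1))
            freq[[nm]] <- tab
        } else {
            lv <- spec@levels[[nm]]
            tab <- table(factor(as.character(x), levels = lv))
            freq[[nm]] <- as.numeric(tab) / nrow(rows)
            names(freq[[nm]]) <- lv
        }
    }
    ## kernel correlation over the jittered (positive-bandwidth) dims
    active <- names(bw)[bw > 0]
    kc <- if (length(active) >= 2L) {
        r <- suppressWarnings(stats::cor(rows[active]))
        r[!is.finite(r)] <- 0; diag(r) <- 1
        r
    } else diag(length(active))
    if (length(active)) dimnames(kc) <- list(active, active)
    new("GroupModel", groupKey = groupKey, memberCount = nrow(rows),
        bandwidths = bw, freqTables = freq, envelope = env, kernelCor = kc,
        members = rows, spec = spec)
}

## mixing matrix M with M M' = R (eigenvalue clip keeps it usable when the
## empirical correlation is rank-deficient)
.corMixing <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    lam <- pmax(e$values, 1e-8)
    e$vectors %*% diag(sqrt(lam), nrow = length(lam))
}

#' Envelope censoring of kernel-jittered draws
#'
#' Re-draws the kernel noise of out-of-envelope values up to
#' \code{maxRejects} times, then clips survivors to the envelope and counts
#' the clip events. Values already inside the envelope pass unchanged.
#'
#' @param candidate numeric vector of first-draw values.
#' @param base donor values the kernel noise was added to.
#' @param bandwidth Gaussian kernel bandwidth used for the draws.
#' @param envelope c(min, max) observed in the group.
#' @param maxRejects redraw budget per value.
#' @param integerValued round half away from zero after each draw (count
#'   kinds).
#' @return list with \code{values} and \code{clipCount}.
#' @export
censorEnvelope <- function(candidate, base, bandwidth, envelope,
                           maxRejects = 10L, integerValued = FALSE) {
    lo <- envelope[1]; hi <- envelope[2]
    if (!all(is.finite(c(lo, hi)))) stop("envelope must be finite")
    x <- candidate
    out <- !is.na(x) & (x < lo | x > hi)
    tries <- 0L
    while (any(out) && tries < maxRejects) {
        redraw <- base[out] + stats::rnorm(sum(out), sd = bandwidth)
        if (integerValued) redraw <- .roundHalfAway(redraw)
        x[out] <- redraw
        out <- !is.na(x) & (x < lo | x > hi)
        tries <- tries + 1L
    }
    clip <- sum(out)
    x[x < lo] <- lo
    x[x > hi] <- hi
    list(values = x, clipCount = clip)
}

#' Sample synthetic rows from a group model
#'
#' Each synthetic row reuses a single donor row drawn uniformly from the
#' group, so cross-feature dependence is inherited; numeric features are
#' then independently jittered with Gaussian kernel noise at the fitted
#' bandwidth and envelope-censored ([censorEnvelope()]), count kinds rounded
#' half away from zero, and categorical/binary features keep the donor's
#' level (equivalently: a draw from the group's empirical joint frequency,
#' whose margins are the model's frequency tables). The jitter uses the
#' variance-corrected smoothed bootstrap: donor deviations from the group
#' mean and the kernel noise are both shrunk by
#' \eqn{1/\sqrt{1 + h^2/s^2}} so the within-group mean and variance (and
#' with them cross-feature correlations) are preserved instead of being
#' inflated by the kernel variance. Draw order: all donor indices first,
#' then kernel noise feature by feature in spec order.
#'
#' @param model a [GroupModel-class].
#' @param n number of rows to draw (uses the current RNG stream; seed
#'   handling is done once in [synthesize()]).
#' @param maxRejects kernel-noise redraw budget per value before clipping.
#' @return list with \code{data} (data.frame of n synthetic rows) and
#'   \code{clipCount}.
#' @export
sampleGroup <- function(model, n, maxRejects = 10L) {
    info <- model@spec@info
    if (n == 0L) {
        empty <- model@members[0, , drop = FALSE]
        return(list(data = empty, clipCount = 0L))
    }
    donors <- sample.int(model@memberCount, n, replace = TRUE)
    out <- model@members[donors, , drop = FALSE]
    rownames(out) <- NULL
    clip <- 0L
    ## joint kernel noise over the jittered dims, correlated per kernelCor
    active <- names(model@bandwidths)[model@bandwidths > 0]
    eps <- if (length(active)) {
        e <- matrix(stats::rnorm(n * length(active)), n) %*%
            t(.corMixing(model@kernelCor))
        colnames(e) <- active
        e
    } else NULL
    for (i in seq_len(nrow(info))) {
        nm <- info$name[i]
        if (!.isNumericKind(info$kind[i])) next   # donor level kept as-is
        bw <- model@bandwidths[[nm]]
        if (bw == 0) next                         # zero dispersion: constant
        ## smoothed bootstrap with Silverman shrinkage: mean and variance of
        ## the group are preserved under donor + kernel noise
        s2 <- stats::var(model@members[[nm]])
        shrink <- 1 / sqrt(1 + bw^2 / s2)
        mu <- mean(model@members[[nm]])
        base <- mu + (out[[nm]] - mu) * shrink
        bwEff <- bw * shrink
        cand <- base + bwEff * eps[, nm]
        intv <- info$kind[i] == "count"
        if (intv) cand <- .roundHalfAway(cand)
        cen <- censorEnvelope(cand, base, bwEff, model@envelope[[nm]],
                              maxRejects = maxRejects, integerValued = intv)
        x <- cen$values
        ## declared bounds are at least as wide as the envelope, but floor
        ## count kinds at any declared lower bound for safety
        if (!is.na(info$lower[i])) x[x < info$lower[i]] <- info$lower[i]
        out[[nm]] <- x
        clip <- clip + cen$clipCount
    }
    list(data = out, clipCount = clip)
}

#' Synthesize a privacy-preserving derivative of a feature matrix
#'
#' Runs the full pipeline: stratify into groups of similar patients
#' ([partitionSimilar()]), censor strata below the privacy threshold, fit a
#' per-group kernel-density model ([fitGroupModel()]) and draw per-group
#' synthetic rows in proportion to group size ([sampleGroup()]), so the
#' requested draw total equals the original row count and the emitted count
#' equals it minus the censored rows. Univariate and multivariate structure
#' of the source matrix is preserved; no synthetic row corresponds to any
#' source row.
#'
#' @param fm a [FeatureMatrix-class] with no missing values (or
#'   \code{naAction = "drop"} to drop incomplete rows first).
#' @param config a [SynthesisConfig-class]; its seed drives all randomness.
#' @param naAction \code{"error"} (default) or \code{"drop"}.
#' @return A [SyntheticCohort-class].
#' @examples
#' spec <- FeatureSpec(c("a", "b"), "continuous")
#' fm <- FeatureMatrix(data.frame(a = rnorm(50), b = rnorm(50)), spec)
#' synthesize(fm, synthesisConfig(seed = 7))
#' @export
synthesize <- function(fm, config = synthesisConfig(),
                       naAction = c("error", "drop")) {
    naAction <- match.arg(naAction)
    dat <- fm@data
    if (!nrow(dat)) stop("input error: empty feature matrix")
    if (anyNA(dat)) {
        if (naAction == "error")
            stop("input error: missing values present (set naAction='drop')")
        keep <- stats::complete.cases(dat)
        fm <- FeatureMatrix(dat[keep, , drop = FALSE], fm@spec,
                            fm@provenance)
    }
    set.seed(config@seed)
    part <- partitionSimilar(fm, config)
    clip <- 0L
    pieces <- vector("list", length(part$groups))
    for (g in seq_along(part$groups)) {
        rows <- fm@data[part$groups[[g]], , drop = FALSE]
        model <- fitGroupModel(rows, fm@spec, config,
                               groupKey = names(part$groups)[g])
        smp <- sampleGroup(model, nrow(rows), maxRejects = config@maxRejects)
        clip <- clip + smp$clipCount
        pieces[[g]] <- smp$data
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    synth <- FeatureMatrix(out, fm@spec,
                           provenance = list(synthetic = TRUE,
                                             seed = config@seed))
    new("SyntheticCohort", matrix = synth,
        censoredCount = length(part$censored), clipCount = clip,
        config = config, seed = config@seed)
}
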