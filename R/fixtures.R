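## Simulated "real-world" cohorts emulating the three study settings:
## a PICU trauma cohort with heavy-tailed alarm counts, a sepsis
## case-control matrix generated from a known logistic model, and six years
## of zip-coded chlamydia events with census denominators. Only published
## summaries of the real data exist, so the generators target those
## summaries (medians, prevalences, rank correlation, rate band); every
## target is a named parameter.

## correlated standard normals via Cholesky (latent Gaussian copula)
.mvnorm <- function(n, sigma) {
    z <- matrix(stats::rnorm(n * ncol(sigma)), n)
    z %*% chol(sigma)
}

#' Simulated PICU trauma cohort
#'
#' Generates n patients with the four-feature panel (severity score, alarm
#' count, ICU length of stay, alarms per day of stay) plus a critical-alarm
#' count and an injury-mechanism categorical. Marginals: the severity score is a heavy-tailed zero-inflated
#' discrete (negative binomial) with median 2; alarm counts and length of
#' stay are log-normal with medians near 229 and 1.3; the alarm rate is the
#' count/stay ratio. Dependence between severity and the alarm stream is
#' imposed through a Gaussian copula calibrated so the realized Spearman
#' correlation between severity and alarm rate is near \code{rhoS}.
#' Severity, alarm count and length of stay are declared as grouping
#' anchors, so default synthesis stratifies the cohort on their joint
#' quantile bins: within-stratum dispersion (hence kernel bandwidth) stays
#' local, which is what lets the heavy-tailed, zero-inflated marginals
#' survive synthesis.
#'
#' Draw order under the seed: latent copula normals, then mechanism, then
#' the critical-alarm thinning.
#'
#' @param n cohort size (default 410).
#' @param rhoS target Spearman correlation between severity score and alarm
#'   rate (default 0.34).
#' @param seed integer seed.
#' @return A [FeatureMatrix-class] with features \code{prism},
#'   \code{alarms}, \code{los}, \code{alarm_rate}, \code{critical_alarms},
#'   \code{mechanism}.
#' @export
genTrauma <- function(n = 410L, rhoS = 0.34, seed = 1L) {
    spec <- FeatureSpec(
        c("prism", "alarms", "los", "alarm_rate", "critical_alarms",
          "mechanism"),
        kind = c("count", "count", "continuous", "continuous", "count",
                 "categorical"),
        lower = c(0, 1, 0.1, 0, 0, NA),
        grouping = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
        levels = list(mechanism = c("blunt", "penetrating", "burn", "other")))
    if (n == 0L) {
        dat <- data.frame(prism = numeric(0), alarms = numeric(0),
                          los = numeric(0), alarm_rate = numeric(0),
                          critical_alarms = numeric(0),
                          mechanism = character(0))
        return(FeatureMatrix(dat, spec, list(generator = "trauma", seed = seed)))
    }
    set.seed(as.integer(seed))
    ## latent correlations: severity ties attenuate the rank correlation by
    ## about as much as the latent-vs-rank inflation, so the latent
    ## severity~alarm correlation equals the rhoS target (calibrated once)
    r12 <- min(0.99, rhoS)             # severity ~ alarm volume
    r13 <- 0.05                        # severity ~ stay
    r23 <- 0.55                        # alarm volume ~ stay
    sigma <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
    z <- .mvnorm(n, sigma)
    u <- stats::pnorm(z)
    prism <- stats::qnbinom(u[, 1], size = 0.6, mu = 3.8)
    alarms <- pmax(1, round(stats::qlnorm(u[, 2], log(229), 1.75)))
    los <- pmax(0.1, round(stats::qlnorm(u[, 3], log(1.3), 1.15), 1))
    mech <- sample(c("blunt", "penetrating", "burn", "other"), n,
                   replace = TRUE, prob = c(0.55, 0.30, 0.13, 0.02))
    crit <- stats::rbinom(n, size = alarms, prob = 0.02)
    dat <- data.frame(prism = prism, alarms = alarms, los = los,
                      alarm_rate = round(alarms / los, 1),
                      critical_alarms = crit, mechanism = mech,
                      stringsAsFactors = FALSE)
    FeatureMatrix(dat, spec, provenance = list(generator = "trauma",
                                               seed = seed, rhoS = rhoS))
}

.sepsisBeta <- function(p) {
    cont <- c(age = 0.15, temp_mean = 0.55, rr_mean = 0.60, hr_mean = 0.50,
              sbp_mean = -0.20, spo2_mean = -0.35, shock_index = 0.70)
    nFlag <- p - length(cont)
    flagBeta <- rep(0, nFlag)
    lead <- c(0.9, -0.6, 0.7, 0.5, -0.45, 0.6, 0.35, -0.3)
    flagBeta[seq_len(min(8L, nFlag))] <- lead[seq_len(min(8L, nFlag))]
    names(flagBeta) <- sprintf("flag_%03d", seq_len(nFlag))
    c(cont, flagBeta)
}

.sepsisBatch <- function(n, p) {
    s <- stats::rnorm(n)                      # latent acuity
    e <- function() stats::rnorm(n)
    age <- pmin(100, pmax(18, round(60 + 16 * (0.25 * s + 0.97 * e()))))
    temp <- round(36.3 + 0.15 * s + 0.35 * e(), 2)
    rr <- round(18 + 1.2 * s + 1.5 * e(), 1)
    hr <- round(82 + 6 * s + 14 * e(), 1)
    sbp <- round(127 - 2 * s + 18 * e(), 1)
    spo2 <- round(pmin(100, 96.8 - 0.6 * s + 2 * e()), 1)
    shock <- round(hr / sbp, 3)
    nFlag <- p - 7L
    base <- rep_len(c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.45), nFlag)
    gam <- rep_len(c(1.0, 0.6, 0.3, 0), nFlag)
    flags <- vapply(seq_len(nFlag), function(j)
        stats::rbinom(n, 1L, stats::plogis(stats::qlogis(base[j]) + gam[j] * s)),
        integer(n))
    x <- data.frame(age = age, temp_mean = temp, rr_mean = rr, hr_mean = hr,
                    sbp_mean = sbp, spo2_mean = spo2, shock_index = shock)
    flags <- as.data.frame(flags)
    names(flags) <- sprintf("flag_%03d", seq_len(nFlag))
    cbind(x, flags)
}

## reference location/scale used to standardize the linear predictor
.sepsisRef <- function(p) {
    nFlag <- p - 7L
    base <- rep_len(c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.45), nFlag)
    m <- c(age = 60, temp_mean = 36.3, rr_mean = 18, hr_mean = 82,
           sbp_mean = 127, spo2_mean = 96.8, shock_index = 0.65,
           stats::setNames(base, sprintf("flag_%03d", seq_len(nFlag))))
    s <- c(age = 16, temp_mean = 0.38, rr_mean = 1.9, hr_mean = 15.2,
           sbp_mean = 18.1, spo2_mean = 2.1, shock_index = 0.12,
           stats::setNames(sqrt(base * (1 - base)),
                           sprintf("flag_%03d", seq_len(nFlag))))
    list(m = m, s = s)
}

#' Simulated sepsis case-control matrix from a known logistic model
#'
#' Features (continuous vitals/demographics plus binary abnormal flags,
#' cross-correlated through a latent acuity variable) are drawn from a
#' population model; the outcome is assigned by a fixed logistic model on
#' the standardized features, and the case/control counts are then enforced
#' exactly by stratified rejection (keep drawing batches until the quotas
#' of \code{nCases} cases and \code{controlsPerCase x nCases} controls are
#' filled). Prevalence is therefore exactly
#' \code{1/(1 + controlsPerCase)} by construction. The true coefficient
#' vector is returned in \code{meta} for recoverability checks.
#'
#' @param nCases number of cases (default 643).
#' @param controlsPerCase controls sampled per case (default 2).
#' @param p total feature count (default 169; 7 continuous, the rest binary
#'   flags).
#' @param seed integer seed.
#' @param maxBatches rejection-sampling budget (error if exhausted).
#' @return A [LabeledMatrix-class]; \code{meta} holds the generative
#'   \code{coefficients} (standardized scale), \code{intercept} and the
#'   reference location/scale.
#' @export
genSepsis <- function(nCases = 643L, controlsPerCase = 2L, p = 169L,
                      seed = 1L, maxBatches = 200L) {
    if (p < 9L) stop("p must be at least 9")
    set.seed(as.integer(seed))
    beta <- .sepsisBeta(p)
    ref <- .sepsisRef(p)
    alpha <- stats::qlogis(0.30)
    nCtrl <- controlsPerCase * nCases
    cases <- list(); ctrls <- list()
    nCase <- 0L; nCtrlGot <- 0L
    for (b in seq_len(maxBatches)) {
        x <- .sepsisBatch(3000L, p)
        xs <- sweep(sweep(as.matrix(x), 2, ref$m), 2, ref$s, "/")
        eta <- alpha + as.numeric(xs %*% beta)
        y <- stats::rbinom(nrow(x), 1L, stats::plogis(eta))
        if (nCase < nCases) {
            take <- which(y == 1L)[seq_len(min(sum(y == 1L), nCases - nCase))]
            if (length(take)) {
                cases[[length(cases) + 1L]] <- x[take, , drop = FALSE]
                nCase <- nCase + length(take)
            }
        }
        if (nCtrlGot < nCtrl) {
            take <- which(y == 0L)[seq_len(min(sum(y == 0L), nCtrl - nCtrlGot))]
            if (length(take)) {
                ctrls[[length(ctrls) + 1L]] <- x[take, , drop = FALSE]
                nCtrlGot <- nCtrlGot + length(take)
            }
        }
        if (nCase >= nCases && nCtrlGot >= nCtrl) break
    }
    if (nCase < nCases || nCtrlGot < nCtrl)
        stop("count enforcement infeasible within the batch budget")
    feats <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
    rownames(feats) <- NULL
    labels <- c(rep(1L, nCases), rep(0L, nCtrl))
    LabeledMatrix(feats, labels,
                  meta = list(coefficients = beta, intercept = alpha,
                              ref = ref, seed = seed))
}

#' Feature spec and matrix view of a labeled sepsis table
#'
#' Packs features plus the outcome label (as a binary column named
#' \code{label}) into a [FeatureMatrix-class] so the synthesis engine can
#' model outcome and features jointly; \code{labeledFromMatrix} is the
#' inverse.
#'
#' @param lm a [LabeledMatrix-class].
#' @return A [FeatureMatrix-class].
#' @export
labeledToMatrix <- function(lm) {
    feats <- lm@features
    isBin <- vapply(feats, function(v) all(v %in% c(0, 1)), logical(1))
    spec <- FeatureSpec(c(names(feats), "label"),
                        kind = c(ifelse(isBin, "binary", "continuous"),
                                 "binary"))
    FeatureMatrix(cbind(feats, label = lm@labels), spec,
                  provenance = list(label = "label"))
}

#' @rdname labeledToMatrix
#' @param fm a [FeatureMatrix-class] (or [SyntheticCohort-class]) containing
#'   a binary \code{label} column.
#' @export
labeledFromMatrix <- function(fm) {
    if (is(fm, "SyntheticCohort")) fm <- fm@matrix
    dat <- fm@data
    if (!"label" %in% names(dat)) stop("no 'label' column present")
    LabeledMatrix(dat[setdiff(names(dat), "label")], dat$label)
}

.defaultZips <- function() {
    data.frame(
        zip = sprintf("631%02d", 1:12),
        population = c(78000, 64500, 55200, 61200, 47800, 39500, 52400,
                       44100, 36800, 33900, 31700, 35792),
        stringsAsFactors = FALSE)
}

#' Simulated zip-coded chlamydia events with census denominators
#'
#' Per zip and year, the event count is Poisson with mean
#' population x target rate / 100,000; patient ages are normal(23, 5.7)
#' truncated at 13+, sex is majority female with a per-year share, and race
#' is a fixed categorical mix. Default yearly target rates and female
#' shares follow the published yearly pattern (rates between roughly 78 and
#' 106 per 100,000, female share drifting from 69% down to 57%). The
#' denominator table is a synthetic 12-zip catchment whose populations sum
#' to 580,892.
#'
#' @param years integer years (default 2010:2015).
#' @param zips data.frame(zip, population); default synthetic catchment.
#' @param targetRates per-year rates per 100,000 (recycled to the years).
#' @param pctFemale per-year female share in [0,1] (recycled).
#' @param seed integer seed.
#' @return list(events, denominators): \code{events} has one row per case
#'   (year, zip, age, sex, race, diagnosis); \code{denominators} has zip,
#'   population, pct_below_poverty.
#' @export
genChlamydia <- function(years = 2010:2015, zips = .defaultZips(),
                         targetRates = c(78.5, 83.6, 105.5, 92.2, 96.3, 86.6),
                         pctFemale = c(0.693, 0.676, 0.680, 0.623, 0.580,
                                       0.572),
                         seed = 1L) {
    stopifnot(all(zips$population > 0), all(targetRates > 0))
    targetRates <- rep_len(targetRates, length(years))
    pctFemale <- rep_len(pctFemale, length(years))
    set.seed(as.integer(seed))
    rows <- list()
    for (i in seq_along(years)) {
        for (j in seq_len(nrow(zips))) {
            lam <- zips$population[j] * targetRates[i] / 1e5
            m <- stats::rpois(1L, lam)
            if (!m) next
            age <- numeric(0)   # truncated normal by rejection
            while (length(age) < m) {
                draw <- stats::rnorm(m, 23, 5.7)
                age <- c(age, draw[draw >= 13])
            }
            rows[[length(rows) + 1L]] <- data.frame(
                year = years[i], zip = zips$zip[j],
                age = round(age[seq_len(m)], 1),
                sex = ifelse(stats::rbinom(m, 1L, pctFemale[i]) == 1L,
                             "F", "M"),
                race = sample(c("white", "black", "other"), m, replace = TRUE,
                              prob = c(0.45, 0.45, 0.10)),
                diagnosis = 1L, stringsAsFactors = FALSE)
        }
    }
    events <- do.call(rbind, rows)
    rownames(events) <- NULL
    denom <- zips
    denom$pct_below_poverty <- round(stats::runif(nrow(zips), 0.05, 0.35), 3)
    list(events = events, denominators = denom)
}
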