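## Train-on-synthetic/test-on-real (TSTR) harness: L2-regularized logistic
## regression evaluated across real and synthetic train/test combinations
## with stratified 5-fold cross-validation and a 20% holdout.

.subsetLabeled <- function(lm, idx)
    LabeledMatrix(lm@features[idx, , drop = FALSE], lm@labels[idx], lm@meta)

#' Stratified holdout split
#'
#' Splits a labeled matrix into train and test parts, stratified by label:
#' within each class, round(fraction x class size) rows go to the test
#' part. The parts are disjoint and exhaustive.
#'
#' @param data a [LabeledMatrix-class].
#' @param fraction test fraction in (0, 1) (default 0.2).
#' @param seed integer seed.
#' @return list(train, test, testIndex) where testIndex are the row indices
#'   of the test part in \code{data}.
#' @export
splitHoldout <- function(data, fraction = 0.2, seed = 1L) {
    if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
    set.seed(as.integer(seed))
    testIdx <- integer(0)
    for (cl in sort(unique(data@labels))) {
        idx <- which(data@labels == cl)
        nTest <- round(fraction * length(idx))
        testIdx <- c(testIdx, sample(idx, nTest))
    }
    testIdx <- sort(testIdx)
    trainIdx <- setdiff(seq_along(data@labels), testIdx)
    train <- .subsetLabeled(data, trainIdx)
    test <- .subsetLabeled(data, testIdx)
    if (length(unique(train@labels)) < 2L || length(unique(test@labels)) < 2L)
        stop("stratification error: a class is absent from one part")
    list(train = train, test = test, testIndex = testIdx)
}

#' Fit an L2-regularized logistic regression
#'
#' Features are standardized internally on the training data (mean 0, sd 1;
#' zero-variance columns kept at scale 1) and the penalized model is fitted
#' with glmnet (ridge path, single penalty, convergence threshold 1e-12).
#' The default penalty is unit-strength L2 on standardized features,
#' i.e. lambda = 1/n so the total objective is
#' sum of negative log-likelihood terms + ||w||^2 / 2.
#'
#' @param train a [LabeledMatrix-class].
#' @param lambda penalty (default \code{1/nrow}).
#' @return list of class \code{l2logit}: weights (on the standardized
#'   scale), intercept, center, scale, lambda.
#' @export
trainL2Logistic <- function(train, lambda = NULL) {
    x <- as.matrix(train@features)
    if (any(!is.finite(x))) stop("input error: non-finite feature values")
    if (is.null(lambda)) lambda <- 1 / nrow(x)
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = center, scale = scl)
    fit <- glmnet::glmnet(xs, factor(train@labels, levels = c(0, 1)),
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE, thresh = 1e-12, maxit = 1e6)
    beta <- as.numeric(fit$beta)
    names(beta) <- colnames(x)
    structure(list(weights = beta, intercept = as.numeric(fit$a0),
                   center = center, scale = scl, lambda = lambda),
              class = "l2logit")
}

#' Predicted event probabilities from an l2logit model
#'
#' @param model an \code{l2logit} fit.
#' @param features data.frame/matrix of features on the original scale.
#' @return Numeric vector of probabilities.
#' @export
predictScores <- function(model, features) {
    x <- as.matrix(features)[, names(model$weights), drop = FALSE]
    xs <- scale(x, center = model$center, scale = model$scale)
    as.numeric(stats::plogis(model$intercept + xs %*% model$weights))
}

#' Confusion-matrix metrics and AUROC of a scored binary outcome
#'
#' Accuracy, precision, recall and F1 at the classification threshold;
#' AUROC by the rank-sum statistic with mid-ranks for ties (equal to the
#' concordant-pair fraction). Precision/F1 are \code{NA} when no positive
#' calls are made; AUROC is \code{NA} when only one class is present.
#'
#' @param scores numeric scores in [0, 1].
#' @param labels 0/1 labels.
#' @param threshold classification threshold (default 0.5).
#' @return One-row data.frame (accuracy, precision, recall, f1, auroc).
#' @export
evaluateMetrics <- function(scores, labels, threshold = 0.5) {
    labels <- as.integer(labels)
    pred <- as.integer(scores >= threshold)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    accuracy <- (tp + tn) / length(labels)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
        2 * precision * recall / (precision + recall) else NA_real_
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    auroc <- if (n1 > 0 && n0 > 0) {
        r <- rank(scores)  # mid-ranks for ties
        (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    } else NA_real_
    data.frame(accuracy = accuracy, precision = precision, recall = recall,
               f1 = f1, auroc = auroc)
}

.stratifiedFolds <- function(labels, k) {
    fold <- integer(length(labels))
    for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
}

#' Stratified k-fold cross-validation of the L2 logistic model
#'
#' Every row lands in exactly one validation fold; reported metrics are the
#' unweighted mean of the per-fold metrics.
#'
#' @param data a [LabeledMatrix-class].
#' @param k number of folds (default 5).
#' @param lambda penalty passed to [trainL2Logistic()].
#' @param seed integer seed for fold assignment.
#' @return One-row data.frame of mean metrics, with attribute
#'   \code{perFold} (k-row data.frame).
#' @export
crossValidate <- function(data, k = 5L, lambda = NULL, seed = 1L) {
    n <- length(data@labels)
    if (k > n) stop("k must not exceed the number of rows")
    set.seed(as.integer(seed))
    fold <- .stratifiedFolds(data@labels, k)
    per <- lapply(seq_len(k), function(i) {
        tr <- .subsetLabeled(data, which(fold != i))
        va <- .subsetLabeled(data, which(fold == i))
        m <- trainL2Logistic(tr, lambda)
        evaluateMetrics(predictScores(m, va@features), va@labels)
    })
    per <- do.call(rbind, per)
    out <- as.data.frame(as.list(colMeans(per)))
    attr(out, "perFold") <- per
    out
}

.cellMetrics <- function(trainName, testName, trainMet, cvMet, testMet) {
    out <- rbind(trainMet, cvMet, testMet)
    data.frame(train = trainName, test = testName,
               split = c("train", "cv", "test"), out,
               stringsAsFactors = FALSE)
}

#' Train/test evaluation grid across real and synthetic data
#'
#' Builds the three-cell grid (real->real, synthetic->synthetic,
#' synthetic->real). Each data set gets a stratified 20% holdout; the real
#' holdout is computed once and shared by the real->real and
#' synthetic->real cells. Per cell, metrics are reported on the training
#' split, under stratified 5-fold cross-validation, and on the holdout.
#' For the synthetic->real cell the fold models are trained on synthetic
#' folds and validated on the corresponding real training folds, and both
#' the training-split and holdout rows are scored with the synthetic-trained
#' model on real data.
#'
#' @param real,synth [LabeledMatrix-class] objects with identical feature
#'   schemas.
#' @param lambda penalty passed to [trainL2Logistic()].
#' @param seed integer seed (all sub-seeds derive from it).
#' @return A [TSTRResult-class].
#' @export
runTSTRGrid <- function(real, synth, lambda = NULL, seed = 1L) {
    if (!identical(names(real@features), names(synth@features)))
        stop("schema mismatch between real and synthetic feature tables")
    seed <- as.integer(seed)
    spR <- splitHoldout(real, 0.2, seed)
    spS <- splitHoldout(synth, 0.2, seed + 1L)

    mR <- trainL2Logistic(spR$train, lambda)
    mS <- trainL2Logistic(spS$train, lambda)

    rr <- .cellMetrics("real", "real",
        evaluateMetrics(predictScores(mR, spR$train@features), spR$train@labels),
        crossValidate(spR$train, 5L, lambda, seed + 2L),
        evaluateMetrics(predictScores(mR, spR$test@features), spR$test@labels))
    ss <- .cellMetrics("synthetic", "synthetic",
        evaluateMetrics(predictScores(mS, spS$train@features), spS$train@labels),
        crossValidate(spS$train, 5L, lambda, seed + 3L),
        evaluateMetrics(predictScores(mS, spS$test@features), spS$test@labels))

    ## synthetic-trained, real-validated cross-validation
    set.seed(seed + 4L)
    k <- 5L
    foldR <- .stratifiedFolds(spR$train@labels, k)
    foldS <- .stratifiedFolds(spS$train@labels, k)
    perSR <- do.call(rbind, lapply(seq_len(k), function(i) {
        m <- trainL2Logistic(.subsetLabeled(spS$train, which(foldS != i)),
                             lambda)
        va <- .subsetLabeled(spR$train, which(foldR == i))
        evaluateMetrics(predictScores(m, va@features), va@labels)
    }))
    sr <- .cellMetrics("synthetic", "real",
        evaluateMetrics(predictScores(mS, spR$train@features), spR$train@labels),
        as.data.frame(as.list(colMeans(perSR))),
        evaluateMetrics(predictScores(mS, spR$test@features), spR$test@labels))

    new("TSTRResult", metrics = rbind(rr, ss, sr),
        holdoutIndex = as.integer(spR$testIndex))
}

#' Write a TSTR metric grid as JSON and TSV
#'
#' @param result a [TSTRResult-class].
#' @param jsonPath output JSON path.
#' @param tsvPath optional output TSV path.
#' @return Invisibly, the JSON path.
#' @export
writeTSTRResult <- function(result, jsonPath, tsvPath = NULL) {
    jsonlite::write_json(result@metrics, jsonPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    if (!is.null(tsvPath))
        utils::write.table(result@metrics, tsvPath, sep = "\t",
                           row.names = FALSE, quote = FALSE)
    invisible(jsonPath)
}
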