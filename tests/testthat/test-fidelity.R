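test_that("summaryQuantiles returns the six-point linear-interpolation panel", {
    q <- summaryQuantiles(c(0, 1, 2, 3, 4))
    expect_equal(unname(q[c("min", "q25", "q50", "q75", "max")]),
                 c(0, 1, 2, 3, 4))
    expect_equal(unname(summaryQuantiles(1:10)["q90"]), 9.1)
    expect_equal(unname(summaryQuantiles(7)), rep(7, 6))
    expect_true(all(diff(summaryQuantiles(rnorm(50))) >= 0))
    expect_error(summaryQuantiles(numeric(0)), "empty")
})

test_that("wilcoxonRankSum agrees with exact enumeration and the z approximation", {
    ## exact two-sided p for a=[1,2], b=[3,4] from all 6 rank assignments
    w <- wilcoxonRankSum(c(1, 2), c(3, 4))
    expect_equal(w$p.value, 1 / 3, tolerance = 1e-12)
    expect_equal(w$p.value, enumWilcoxonP(c(1, 2), c(3, 4)),
                 tolerance = 1e-12)

    ## enumeration agreement over several small untied cases
    set.seed(31)
    for (i in 1:10) {
        a <- sample(1:100, sample(2:5, 1))
        b <- sample(101:200, sample(2:5, 1)) / 3
        expect_equal(wilcoxonRankSum(a, b)$p.value, enumWilcoxonP(a, b),
                     tolerance = 1e-9)
    }

    ## identical samples: p near 1; all-tied: degenerate flag
    set.seed(32)
    x <- rnorm(30)
    expect_gt(wilcoxonRankSum(x, x)$p.value, 0.9)
    deg <- wilcoxonRankSum(rep(2, 5), rep(2, 8))
    expect_true(deg$degenerate)
    expect_equal(deg$p.value, 1)

    ## two n=400 normals shifted by 1 sd: overwhelming evidence
    set.seed(33)
    expect_lt(wilcoxonRankSum(rnorm(400), rnorm(400, 1))$p.value, 0.001)
})

test_that("ksTwoSample matches ECDF enumeration", {
    expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
    expect_equal(ksTwoSample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
    expect_equal(ksTwoSample(c(1, 3), c(2, 4))$statistic, 0.5)
    set.seed(41)
    for (i in 1:8) {
        a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), 0.3)
        expect_equal(ksTwoSample(a, b)$statistic, enumKsD(a, b),
                     tolerance = 1e-9)
    }
    ## D is invariant under a strictly monotone transform of both samples
    a <- rexp(25); b <- rexp(30, 0.5)
    expect_equal(ksTwoSample(a, b)$statistic,
                 ksTwoSample(log(a), log(b))$statistic, tolerance = 1e-12)
})

test_that("chiSquaredIndependence matches the 2x2 closed form", {
    tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
    res <- chiSquaredIndependence(tab)
    expect_equal(res$statistic, chi2x2Closed(tab), tolerance = 1e-9)
    expect_equal(res$statistic, 20 / 3, tolerance = 1e-4)
    expect_equal(res$df, 1)
    ## proportional rows are independent
    expect_equal(chiSquaredIndependence(rbind(c(10, 30), c(20, 60)))$statistic,
                 0, tolerance = 1e-12)
    expect_error(chiSquaredIndependence(rbind(c(5, 0), c(0, 0))),
                 "zero-margin")
})

test_that("spearmanRho matches the d-squared formula and flags constants", {
    expect_equal(spearmanRho(1:5, 2:6), 1)
    expect_equal(spearmanRho(1:5, 5:1), -1)
    expect_equal(spearmanRho(c(1, 2, 3, 4, 5), c(2, 1, 3, 5, 4)), 0.8)
    set.seed(51)
    x <- sample(1:1000, 20); y <- sample(1:1000, 20)
    expect_equal(spearmanRho(x, y), spearmanD2(x, y), tolerance = 1e-9)
    expect_warning(res <- spearmanRho(rep(1, 5), 1:5), "constant")
    expect_true(is.na(res))
    expect_error(spearmanRho(1:2, 1:2), "length")
})

test_that("correlationDelta covers all pairs and matches brute force", {
    set.seed(61)
    d1 <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
    d1$b <- d1$b + d1$a
    d2 <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
    cd <- correlationDelta(d1, d2, "pearson")
    expect_equal(nrow(cd), 3L)   # p(p-1)/2
    for (i in seq_len(nrow(cd))) {
        r1 <- cor(d1[[cd$feature_a[i]]], d1[[cd$feature_b[i]]])
        r2 <- cor(d2[[cd$feature_a[i]]], d2[[cd$feature_b[i]]])
        expect_equal(cd$delta[i], abs(r1 - r2), tolerance = 1e-12)
    }
    expect_equal(max(correlationDelta(d1, d1)$delta), 0)
    expect_error(correlationDelta(d1["a"], d2["a"]), "at least 2")
})

test_that("buildReport covers every feature once per test and flags mismatches", {
    fm <- genTrauma(n = 200, seed = 71)
    sc <- synthesize(fm, synthesisConfig(seed = 72))
    rep <- buildReport(fm, sc)
    fc <- rep@featureComparisons
    numeric_feats <- c("prism", "alarms", "los", "alarm_rate",
                       "critical_alarms")
    for (f in numeric_feats)
        expect_setequal(fc$test[fc$feature == f], c("wilcoxon", "ks"))
    expect_equal(fc$test[fc$feature == "mechanism"], "chi-squared")
    expect_true(all(fc$p_value >= 0 & fc$p_value <= 1, na.rm = TRUE))
    expect_equal(nrow(rep@correlationComparisons), choose(5, 2))
    ## quantile panels are nondecreasing
    qr <- as.matrix(fc[fc$test == "wilcoxon",
                       paste0("real_", c("min", "q25", "q50", "q75", "q90",
                                         "max"))])
    expect_true(all(apply(qr, 1, function(r) all(diff(r) >= 0))))

    ## missing column in the synthetic table is a mismatch error
    y <- featureData(sc)
    specLess <- FeatureSpec(setdiff(featureNames(fm), "los"),
        kind = fm@spec@info$kind[fm@spec@info$name != "los"],
        levels = fm@spec@levels)
    fmLess <- FeatureMatrix(y[setdiff(names(y), "los")], specLess)
    expect_error(buildReport(fm, fmLess), "mismatch.*los")
})

test_that("fidelity report writes JSON and TSV", {
    fm <- genTrauma(n = 200, seed = 81)
    rep <- buildReport(fm, synthesize(fm, synthesisConfig(seed = 82)))
    jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
    writeFidelityReport(rep, jp, tp)
    parsed <- jsonlite::fromJSON(jp)
    expect_equal(parsed$alpha, 0.05)
    expect_equal(nrow(parsed$feature_comparisons),
                 nrow(rep@featureComparisons))
    tsv <- read.delim(tp)
    expect_equal(nrow(tsv), nrow(rep@featureComparisons))
})
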