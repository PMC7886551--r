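test_that("partitionSimilar enumerates strata and censors small ones", {
    ## no grouping features: one group with every row
    fm <- makeGaussianMatrix(30, seed = 1)
    part <- partitionSimilar(fm, synthesisConfig(minGroupSize = 5))
    expect_length(part$groups, 1L)
    expect_setequal(part$groups[[1]], 1:30)
    expect_length(part$censored, 0L)

    ## sex x 2 age bins matches exhaustive enumeration
    set.seed(2)
    n <- 60
    d <- data.frame(sex = rep(c("F", "M"), each = n / 2),
                    age = c(rnorm(n / 2, 40, 10), rnorm(n / 2, 60, 10)))
    spec <- FeatureSpec(c("sex", "age"), c("categorical", "continuous"),
                        grouping = TRUE, levels = list(sex = c("F", "M")))
    fm <- FeatureMatrix(d, spec)
    cfg <- synthesisConfig(minGroupSize = 2, nQuantileBins = 2)
    part <- partitionSimilar(fm, cfg)
    expect_lte(length(part$groups), 4L)
    ## brute-force assignment: same split by (sex, above/below its median bin)
    med <- unname(quantile(d$age, 0.5, type = 7))
    key <- paste(d$sex, d$age <= med)
    expect_equal(sort(vapply(part$groups, length, integer(1)),
                      decreasing = TRUE) |> unname(),
                 sort(as.integer(table(key)), decreasing = TRUE))

    ## a stratum of size k-1 is censored in full
    d2 <- data.frame(g = c(rep("big", 20), rep("tiny", 9)), v = rnorm(29))
    spec2 <- FeatureSpec(c("g", "v"), c("categorical", "continuous"),
                         grouping = c(TRUE, FALSE),
                         levels = list(g = c("big", "tiny")))
    part2 <- partitionSimilar(FeatureMatrix(d2, spec2),
                              synthesisConfig(minGroupSize = 10))
    expect_setequal(part2$censored, 21:29)
    expect_length(part2$groups, 1L)

    ## every stratum below k is an error with diagnostics
    d3 <- d2[c(1:5, 21:29), ]
    expect_error(partitionSimilar(FeatureMatrix(d3, spec2),
                                  synthesisConfig(minGroupSize = 10)),
                 "empty-model error")
})

test_that("fitGroupModel computes Silverman bandwidths and frequencies", {
    ## direct arithmetic oracle for the Silverman rule on a stated vector
    x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
    bwExpected <- 0.9 * min(sd(x), IQR(x) / 1.34) * length(x)^(-1 / 5)
    expect_equal(silvermanBandwidth(x), bwExpected, tolerance = 1e-12)

    set.seed(3)
    d <- data.frame(v = rnorm(25), konst = rep(7, 25),
                    g = sample(c("a", "b"), 25, TRUE))
    spec <- FeatureSpec(c("v", "konst", "g"),
                        c("continuous", "continuous", "categorical"),
                        levels = list(g = c("a", "b")))
    gm <- fitGroupModel(d, spec, synthesisConfig(minGroupSize = 10))
    expect_equal(unname(gm@bandwidths["konst"]), 0)   # zero dispersion
    expect_equal(unname(gm@bandwidths["v"]), silvermanBandwidth(d$v))
    expect_equal(sum(gm@freqTables$g), 1)
    expect_equal(gm@envelope$v, c(min(d$v), max(d$v)))
    expect_error(fitGroupModel(d[1:5, ], spec, synthesisConfig()),
                 "precondition")

    ## constant column is reproduced exactly by sampling
    smp <- sampleGroup(gm, 40)
    expect_true(all(smp$data$konst == 7))
})

test_that("sampleGroup preserves the group mean and respects the envelope", {
    set.seed(5)
    d <- data.frame(v = rnorm(200, 10, 2))
    spec <- FeatureSpec("v", "continuous")
    gm <- fitGroupModel(d, spec, synthesisConfig())
    expect_identical(nrow(sampleGroup(gm, 0)$data), 0L)
    set.seed(6)
    smp <- sampleGroup(gm, 10000)$data$v
    se <- sd(d$v) / sqrt(200)      # dominated by donor resampling
    expect_lt(abs(mean(smp) - mean(d$v)), 3 * se * sqrt(10000 / 200 + 1))
    expect_gte(min(smp), min(d$v))
    expect_lte(max(smp), max(d$v))
})

test_that("censorEnvelope redraws then clips, counting clip events", {
    set.seed(7)
    base <- rep(5, 100)
    cand <- base + rnorm(100, sd = 1)
    keep <- censorEnvelope(cand, base, 1, c(0, 10), maxRejects = 10)
    expect_identical(keep$values, cand)     # inside: unchanged
    expect_identical(keep$clipCount, 0L)

    ## forced one-point envelope: everything clips to the point
    res <- censorEnvelope(cand + 100, base, 1, c(5, 5), maxRejects = 3)
    expect_true(all(res$values == 5))
    expect_gt(res$clipCount, 0)

    ## above-envelope values are not emitted as-is
    res2 <- censorEnvelope(rep(20, 50), base[1:50], 1, c(0, 10),
                           maxRejects = 10)
    expect_true(all(res2$values <= 10))
})

test_that("synthesize preserves counts, envelope and determinism", {
    fm <- genTrauma(seed = 11)
    cfg <- synthesisConfig(seed = 99)
    sc <- synthesize(fm, cfg)
    d <- featureData(fm); y <- featureData(sc)
    expect_equal(nrow(y), nrow(d) - censoredCount(sc))
    numeric_cols <- c("prism", "alarms", "los", "alarm_rate",
                      "critical_alarms")
    for (f in numeric_cols) {
        expect_gte(min(y[[f]]), min(d[[f]]))
        expect_lte(max(y[[f]]), max(d[[f]]))
    }
    ## determinism: identical inputs and seed give identical output
    sc2 <- synthesize(fm, cfg)
    expect_identical(featureData(sc2), y)
    expect_identical(clipCount(sc2), clipCount(sc))

    ## privacy: no synthetic row equals any real row on continuous features
    key_real <- paste(d$los, d$alarm_rate)
    key_syn <- paste(y$los, y$alarm_rate)
    ## jittered continuous pair collisions are possible only via clipping at
    ## rounded support; full-row matches must not occur
    full_real <- do.call(paste, d[numeric_cols])
    full_syn <- do.call(paste, y[numeric_cols])
    expect_length(intersect(full_syn, full_real), 0L)

    expect_error(synthesize(FeatureMatrix(d[0, ], fm@spec)), "input error")
    dna <- d; dna$los[1] <- NA
    expect_error(synthesize(FeatureMatrix(dna, fm@spec)), "missing")
    scDrop <- synthesize(FeatureMatrix(dna, fm@spec), cfg, naAction = "drop")
    expect_lte(nrow(featureData(scDrop)), nrow(d) - 1L)
})

test_that("synthesize keeps bivariate dependence near the source", {
    fm <- makeGaussianMatrix(2000, rho = 0.8, seed = 21)
    sc <- synthesize(fm, synthesisConfig(seed = 22))
    y <- featureData(sc)
    expect_gt(cor(y$x, y$y), 0.75)
    expect_lt(cor(y$x, y$y), 0.85)
    expect_lte(ksTwoSample(featureData(fm)$x, y$x)$statistic, 0.06)
})
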