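test_that("selectCohort applies compound filters with set semantics", {
    ## 8 patients: demographics + diagnosis events with date and age
    ev <- makeEvents(
        list("p1", "demographic", "2000-01-01", "sex", "male"),
        list("p1", "demographic", "2000-01-01", "deceased", "1"),
        list("p1", "diagnosis", "2012-06-01", "code", "C61"),
        list("p1", "diagnosis", "2012-06-01", "age_at_dx", "45"),
        list("p2", "demographic", "2000-01-01", "sex", "male"),
        list("p2", "demographic", "2000-01-01", "deceased", "1"),
        list("p2", "diagnosis", "2009-03-01", "code", "C61"),
        list("p2", "diagnosis", "2009-03-01", "age_at_dx", "44"),
        list("p3", "demographic", "2000-01-01", "sex", "female"),
        list("p3", "demographic", "2000-01-01", "deceased", "1"),
        list("p3", "diagnosis", "2013-02-01", "code", "C61"),
        list("p3", "diagnosis", "2013-02-01", "age_at_dx", "43"),
        list("p4", "demographic", "2000-01-01", "sex", "male"),
        list("p4", "demographic", "2000-01-01", "deceased", "0"),
        list("p4", "diagnosis", "2014-02-01", "code", "C61"),
        list("p4", "diagnosis", "2014-02-01", "age_at_dx", "41"),
        list("p5", "demographic", "2000-01-01", "sex", "male"),
        list("p5", "demographic", "2000-01-01", "deceased", "1"),
        list("p5", "diagnosis", "2015-02-01", "code", "C61"),
        list("p5", "diagnosis", "2015-02-01", "age_at_dx", "55"),
        list("p6", "demographic", "2000-01-01", "sex", "male"),
        list("p6", "demographic", "2000-01-01", "deceased", "1"),
        list("p6", "diagnosis", "2016-02-01", "code", "C50"),
        list("p6", "diagnosis", "2016-02-01", "age_at_dx", "40"),
        list("p7", "demographic", "2000-01-01", "sex", "male"),
        list("p7", "demographic", "2000-01-01", "deceased", "1"),
        list("p7", "diagnosis", "2011-02-01", "code", "C61"),
        list("p7", "diagnosis", "2011-02-01", "age_at_dx", "49"),
        list("p8", "demographic", "2000-01-01", "sex", "male"),
        list("p8", "demographic", "2000-01-01", "deceased", "1"),
        list("p8", "diagnosis", "2009-12-31", "code", "C61"),
        list("p8", "diagnosis", "2009-12-31", "age_at_dx", "30"))
    q <- cohortQuery(filters = list(
        list(event_type = "demographic", attribute = "sex", op = "==",
             value = "male"),
        list(event_type = "demographic", attribute = "deceased", op = "==",
             value = 1),
        list(event_type = "diagnosis", attribute = "code", op = "==",
             value = "C61"),
        list(event_type = "diagnosis", attribute = "timestampless",
             op = ">", value = "ignored")))
    expect_error(selectCohort(ev, q), "schema error")

    q <- cohortQuery(filters = list(
        list(event_type = "demographic", attribute = "sex", op = "==",
             value = "male"),
        list(event_type = "demographic", attribute = "deceased", op = "==",
             value = 1),
        list(event_type = "diagnosis", attribute = "dx_date", op = ">",
             value = "2010-01-01"),
        list(event_type = "diagnosis", attribute = "age_at_dx", op = "<",
             value = 50)))
    ## encode the diagnosis date as an attribute for the date filter
    dates <- ev[ev$event_type == "diagnosis" & ev$attr_name == "code", ]
    dates$attr_name <- "dx_date"; dates$attr_value <- dates$timestamp
    ev2 <- rbind(ev, dates)

    ## independent per-patient predicate evaluation: p1 (45y, 2012), p6
    ## (40y, 2016) and p7 (49y, 2011) satisfy every predicate; p2/p8 are too
    ## early, p3 female, p4 alive, p5 too old
    expected <- c("p1", "p6", "p7")
    got <- selectCohort(ev2, q)
    expect_identical(got, expected)

    ## order-insensitive and idempotent
    shuffled <- ev2[rev(seq_len(nrow(ev2))), ]
    expect_identical(selectCohort(shuffled, q), got)
    expect_identical(selectCohort(ev2[ev2$patient_id %in% got |
                                      ev2$patient_id %in% ev2$patient_id, ], q),
                     got)

    ## vacuous and single-filter queries
    q0 <- cohortQuery(indexEventRule = list(event_type = "diagnosis",
                                            which = "first"))
    expect_identical(selectCohort(ev2, q0), sort(unique(ev2$patient_id)))
    q1 <- cohortQuery(filters = list(
        list(event_type = "diagnosis", attribute = "code", op = "==",
             value = "C50")))
    expect_identical(selectCohort(ev2, q1), "p6")
})

test_that("nonsepsisIndexTime uses the midpoint for long stays and 12 h otherwise", {
    admit <- parseInstant("2015-01-01 00:00:00")
    expect_equal(nonsepsisIndexTime(admit, admit + 48 * 3600),
                 admit + 24 * 3600)
    expect_equal(nonsepsisIndexTime(admit, admit + 20 * 3600),
                 admit + 12 * 3600)
    ## boundary: exactly 24 h stays use the short-stay rule
    expect_equal(nonsepsisIndexTime(admit, admit + 24 * 3600),
                 admit + 12 * 3600)
    expect_error(nonsepsisIndexTime(admit, admit - 1), "ordering")
})

test_that("windowSlice keeps closed-interval look-back lags", {
    idx <- parseInstant("2015-01-10 12:00:00")
    ev <- data.frame(
        patient_id = "p", event_type = "lab",
        timestamp = format(idx - c(10, 2, 6, 24, 25) * 3600,
                           "%Y-%m-%dT%H:%M:%S"),
        attr_name = "lactate", attr_value = "1", stringsAsFactors = FALSE)
    kept <- windowSlice(ev, idx, c(6, 24))
    lag <- as.numeric(difftime(idx, parseInstant(kept$timestamp), units = "hours"))
    expect_setequal(lag, c(10, 6, 24))   # both closed endpoints retained
    ## [0, Inf) returns everything at or before the index time
    all_before <- windowSlice(ev, idx, c(0, Inf))
    expect_equal(nrow(all_before), 5L)
})

test_that("aggregateFeature matches direct formulas and empty conventions", {
    expect_identical(aggregateFeature(numeric(0), "count"), 0L)
    expect_true(is.na(aggregateFeature(numeric(0), "mean")))
    expect_equal(aggregateFeature(c(1, 2, 3), "median"), 2)
    x <- c(1, 2, 3, 4)
    expect_equal(aggregateFeature(x, "variance"),
                 sum((x - mean(x))^2) / (length(x) - 1))
    expect_equal(aggregateFeature(x, "variance"), 1.6667, tolerance = 1e-4)
    expect_equal(aggregateFeature(c(5, 1, 9), "first"), 5)
    expect_equal(aggregateFeature(c(5, 1, 9), "last"), 9)
    expect_error(aggregateFeature(letters[1:3], "sum"), "type error")
    ## additivity of sum over concatenation
    set.seed(4)
    a <- rnorm(10); b <- rnorm(7)
    expect_equal(aggregateFeature(c(a, b), "sum"),
                 aggregateFeature(a, "sum") + aggregateFeature(b, "sum"))
})

test_that("deriveComposite evaluates formulas and propagates missingness", {
    expect_equal(deriveComposite(list(weight = 80, height = 1.6),
                                 "weight / height^2"), 31.25)
    expect_equal(deriveComposite(list(heart_rate = 100, sbp = 125),
                                 "heart_rate / sbp"), 0.8)
    expect_message(
        res <- deriveComposite(list(weight = 80, height = NA),
                               "weight / height^2"),
        "missing operand")
    expect_true(is.na(res))
    expect_match(attr(res, "reason"), "height")
})

test_that("oneHotEncode expands levels and keeps binary columns single", {
    race <- c("white", "black", "unknown", "other", "white")
    enc <- oneHotEncode(race, "race",
                        levels = c("white", "black", "unknown", "other"))
    expect_equal(ncol(enc), 4L)
    expect_true(all(rowSums(enc) == 1))      # partition of unity
    sex <- oneHotEncode(c("F", "M", "F"), "sex")
    expect_equal(ncol(sex), 1L)
    expect_equal(sex[[1]], c(0L, 1L, 0L))
    expect_error(oneHotEncode(c("x", "y", "z"), levels = c("x", "y")),
                 "schema error")
})

test_that("abnormalFlags uses inclusive nested thresholds", {
    expect_equal(abnormalFlags(1.0, high = 2.0)$high, 0L)
    f <- abnormalFlags(4.5, high = 2.0, critical = 4.0)
    expect_equal(f$high, 1L)
    expect_equal(f$critical, 1L)            # critical implies high
    expect_equal(abnormalFlags(2.0, high = 2.0)$high, 1L)  # inclusive
    expect_equal(abnormalFlags(3.5, low = 3.5)$low, 1L)
    expect_error(abnormalFlags(1, low = 5, high = 2), "configuration error")
    ## critical below high is a configuration error
    expect_error(abnormalFlags(1, high = 4, critical = 2), "configuration")
})

test_that("sampleControls draws the exact ratio, disjoint and reproducibly", {
    cases <- sprintf("c%03d", 1:50)
    pool <- c(cases, sprintf("k%04d", 1:150))
    ctr <- sampleControls(cases, pool, ratio = 2, seed = 9)
    expect_length(ctr, 100L)
    expect_length(unique(ctr), 100L)
    expect_length(intersect(ctr, cases), 0L)
    expect_identical(ctr, sampleControls(cases, pool, ratio = 2, seed = 9))
    expect_error(sampleControls(letters[1:6], letters[1:10], ratio = 2),
                 "sampling error")
})
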