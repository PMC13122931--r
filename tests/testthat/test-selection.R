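.toy_matrix <- function(v, d = NULL) {
    if (is.null(d)) d <- matrix(100L, nrow(v), ncol(v))
    dimnames(d) <- dimnames(v)
    RegionMatrix(v, d)
}

test_that("preprocessing masks shallow cells and drops mostly-missing regions", {
    v <- matrix(runif(40), 4, 10,
                dimnames = list(paste0("r", 1:4), paste0("s", 1:10)))
    d <- matrix(100L, 4, 10)
    d[2, 1] <- 49L                      # shallow cell
    v[3, 1:10] <- NA                    # 100% missing region
    x <- .toy_matrix(v, d)
    y <- preprocessRegions(x)
    expect_false("r3" %in% regionIds(y))
    expect_true(is.na(featureValues(y)["r2", "s1"]))
    expect_equal(featureValues(y)["r1", ], v[1, ])
    ## clean matrix passes through unchanged
    z <- .toy_matrix(matrix(runif(20), 2, 10,
                            dimnames = list(c("a", "b"), paste0("s", 1:10))))
    expect_identical(featureValues(preprocessRegions(z)), featureValues(z))
    ## everything dropped -> error
    allna <- .toy_matrix(matrix(NA_real_, 1, 10,
                                dimnames = list("r", paste0("s", 1:10))))
    expect_error(preprocessRegions(allna), "all regions dropped")
})

test_that("region statistics follow the order-statistic cutoff convention", {
    controls <- seq(0.1, 1.0, by = 0.1)
    cases <- c(0.85, 0.9, 0.5, 0.95)
    st <- regionStats(cases, controls, specificity = 0.80)
    expect_equal(st$delta, mean(cases) - mean(controls))
    expect_equal(st$delta, 0.25)
    expect_equal(st$cutoff, 0.8)              # 8th order statistic of 10
    expect_equal(st$sensitivity_at_spec, 0.75)
    expect_equal(st$direction, "up")
    ## all cases above every control
    st2 <- regionStats(c(2, 2.1, 2.2), controls)
    expect_equal(st2$sensitivity_at_spec, 1.0)
    ## down-regulated region mirrors the convention
    st3 <- regionStats(-cases, -controls)
    expect_equal(st3$direction, "down")
    expect_equal(st3$sensitivity_at_spec, 0.75)
    ## too few values -> skipped
    expect_null(regionStats(1, controls))
})

test_that("threshold selection is conjunctive and monotone in its thresholds", {
    stats <- data.frame(
        region_id = c("a", "b", "c", "d"),
        delta = c(0.03, 0.019, 0.5, -0.04),
        sensitivity_at_spec = c(0.45, 0.9, 0.39, 0.6),
        p_value = c(0.005, 0.001, 0.001, 0.02),
        stringsAsFactors = FALSE)
    cfg <- selectionConfig("entropy")
    expect_equal(selectBinaryFeatures(stats, cfg), "a")
    ## b fails |delta|, c fails sensitivity, d fails p
    expect_warning(
        selectBinaryFeatures(stats[stats$region_id == "b", ], cfg),
        "no regions")
    ## tightening any threshold never enlarges the set
    set.seed(8)
    rs <- data.frame(region_id = paste0("r", 1:50),
                     delta = rnorm(50, 0, 0.05),
                     sensitivity_at_spec = runif(50),
                     p_value = runif(50, 0, 0.05))
    base <- suppressWarnings(selectBinaryFeatures(rs, cfg))
    for (fld in c("min_abs_delta", "min_sensitivity")) {
        cfg2 <- cfg; cfg2[[fld]] <- cfg[[fld]] + 0.1
        expect_true(all(suppressWarnings(
            selectBinaryFeatures(rs, cfg2)) %in% base))
    }
    cfg3 <- cfg; cfg3$max_p <- cfg$max_p / 10
    expect_true(all(suppressWarnings(
        selectBinaryFeatures(rs, cfg3)) %in% base))
})

test_that("the importance filter keeps informative features, drops noise, and is seeded", {
    set.seed(21)
    n <- 80
    y <- rep(c("cancer", "non_cancer"), each = n / 2)
    X <- cbind(strong1 = rnorm(n, ifelse(y == "cancer", 0.2, 0), 0.05),
               strong2 = rnorm(n, ifelse(y == "cancer", 0.2, 0), 0.05),
               noise = rnorm(n))
    r1 <- importanceFilter(X, y, threshold = 0.006, seed = 5)
    expect_setequal(r1$selected, c("strong1", "strong2"))
    r2 <- importanceFilter(X, y, threshold = 0.006, seed = 5)
    expect_identical(r1$selected, r2$selected)
    expect_identical(r1$importance, r2$importance)
    ## single candidate above threshold is trivially retained
    r3 <- importanceFilter(X[, "strong1", drop = FALSE], y, 0.006, seed = 5)
    expect_equal(r3$selected, "strong1")
})

test_that("shadow-feature selection confirms planted effects and controls the null", {
    set.seed(31)
    n <- 60
    y <- rep(c("A", "B"), each = n / 2)
    X <- cbind(planted = rnorm(n, ifelse(y == "A", 1, 0), 0.3),
               n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    bs <- borutaSelect(X, y, max_iter = 20, seed = 3)
    expect_true("planted" %in% bs$confirmed)
    expect_false(any(c("n1", "n2", "n3") %in% bs$confirmed))
    ## permuted labels: no confirmations expected
    set.seed(32)
    bs_null <- borutaSelect(X, sample(y), max_iter = 20, seed = 4)
    expect_length(bs_null$confirmed, 0)
    ## determinism
    bs2 <- borutaSelect(X, y, max_iter = 20, seed = 3)
    expect_identical(bs$confirmed, bs2$confirmed)
    expect_identical(bs$hits, bs2$hits)
})

test_that("KW/Dunn cascade attributes type-specific regions and respects top_k", {
    set.seed(41)
    types <- rep(c("colorectal", "lung", "liver"), each = 20)
    X <- matrix(rnorm(60 * 6), 60, 6,
                dimnames = list(NULL, paste0("r", 1:6)))
    X[types == "lung", "r2"] <- X[types == "lung", "r2"] + 2  # planted
    sel <- kwDunnSelect(X, types, seed = 2)
    expect_true("r2" %in% sel$lung)
    expect_false("r2" %in% sel$colorectal)
    ## global null: no attribution expected after FDR
    X0 <- matrix(rnorm(60 * 8), 60, 8,
                 dimnames = list(NULL, paste0("q", 1:8)))
    sel0 <- kwDunnSelect(X0, types, seed = 2)
    expect_equal(sum(lengths(sel0)), 0L)
    ## top_k = 1 caps every type at one region
    X2 <- X
    X2[types == "lung", "r3"] <- X2[types == "lung", "r3"] + 2
    sel1 <- kwDunnSelect(X2, types, top_k = 1, seed = 2)
    expect_lte(length(sel1$lung), 1L)
    expect_error(kwDunnSelect(X, rep(c("a", "b"), c(59, 1))), "at least 2")
})
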