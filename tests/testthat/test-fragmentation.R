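test_that("autosome tiling keeps a short final bin and excludes sex chromosomes", {
    gb <- makeBins(c(chrA = 250000L), width = 100000L)
    expect_equal(gb$bins$start, c(0L, 100000L, 200000L))
    expect_equal(gb$bins$end, c(100000L, 200000L, 250000L))
    gb2 <- makeBins(c(chr1 = 300000L, chrX = 300000L))
    expect_false("chrX" %in% gb2$bins$chrom)
    expect_error(makeBins(c(weird_contig = 1e6)), "unknown chromosome")
})

test_that("bin filtering drops blacklisted bins then the lowest-coverage fraction", {
    gb <- makeBins(c(chr1 = 1000000L), width = 100000L)
    cov <- 1:10
    f <- filterBins(gb, cov)
    expect_equal(which(!f$bins$retained), 1L)   # coverage 1 dropped
    bl <- data.frame(chrom = "chr1", start = 450000L, end = 460000L)
    f2 <- filterBins(gb, cov, blacklist = bl)
    expect_false(f2$bins$retained[5])           # overlaps blacklist
    f3 <- filterBins(gb, cov, drop_fraction = 0)
    expect_true(all(f3$bins$retained))
})

test_that("length classes partition [100, 320] with half-open internal bounds", {
    expect_equal(lengthClass(c(120, 150, 149, 259, 260, 320, 321, 90, 99)),
                 c("short", "middle", "short", "middle", "long", "long",
                   "none", "none", "none"))
    expect_error(lengthClass(0), "positive")
    ## partition: every integer length in [100,320] gets exactly one class
    cl <- lengthClass(100:320)
    expect_true(all(cl != "none"))
})

test_that("coverage profiles count each classed fragment once and conserve totals", {
    gb <- makeBins(c(chr1 = 2000000L), width = 100000L)
    frags <- data.frame(
        sample_id = "S1", chrom = "chr1",
        start = c(10000L, 15000L, 20000L, 1500000L),
        end = c(10120L, 15290L, 20050L, 1500200L),
        stringsAsFactors = FALSE)
    frags$length <- frags$end - frags$start
    p <- coverageProfile(frags, gb, samples = "S1")
    pr <- p$profile
    b1 <- pr[pr$bin == "chr1:0", ]
    expect_equal(unlist(b1[, c("short_cov", "middle_cov", "long_cov",
                               "nfrags")], use.names = FALSE),
                 c(1L, 0L, 1L, 2L))    # 120 bp short + 290 bp long; 50 bp none
    expect_equal(sum(pr$nfrags), sum(lengthClass(frags$length) != "none"))
    ## conservation on a random fleet
    set.seed(9)
    n <- 500
    len <- sample(80:340, n, TRUE)
    st <- sample(0:1900000, n, TRUE)
    rf <- data.frame(sample_id = sample(c("A", "B"), n, TRUE), chrom = "chr1",
                     start = st, end = st + len, length = len,
                     stringsAsFactors = FALSE)
    p2 <- coverageProfile(rf, gb, samples = c("A", "B"))
    expect_equal(sum(p2$profile$nfrags), sum(lengthClass(len) != "none"))
})

test_that("PCA keeps the minimal component count at 98% variance and projects consistently", {
    set.seed(5)
    X <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(5, 3, 1, 0.3, 0.1, 0.05))
    colnames(X) <- paste0("f", 1:6)
    rownames(X) <- paste0("s", 1:40)
    pc <- pcaFeatures(X, var_frac = 0.98)
    ve <- cumsum(pc$var_explained)
    expect_gte(ve[pc$k], 0.98)
    if (pc$k > 1) expect_lt(ve[pc$k - 1], 0.98)
    ## projecting the training data reproduces stored scores
    expect_equal(projectPca(pc, X), pc$scores, tolerance = 1e-10)
    ## zero-variance feature dropped with a warning
    X2 <- cbind(X, const = 1)
    expect_warning(pc2 <- pcaFeatures(X2), "zero-variance")
    expect_false("const" %in% pc2$kept_features)
    ## identical samples -> degenerate error
    expect_error(suppressWarnings(pcaFeatures(matrix(1, 5, 3))), "degenerate")
    expect_error(projectPca(pc, X[, 1:3]), "missing feature")
})
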