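test_that("binary derivative is the XOR of adjacent bits", {
    expect_equal(binaryDerivative(c(1, 1, 1, 1, 0, 0)), c(0L, 0L, 0L, 1L, 0L))
    expect_equal(binaryDerivative(c(1, 0, 1, 0)), c(1L, 1L, 1L))
    expect_equal(binaryDerivative(rep(1L, 6)), rep(0L, 5))
    expect_error(binaryDerivative(1L), "at least 2")
})

test_that("bien reproduces hand-computed and published pattern values", {
    ## frozen from the independent naive implementation in helper-oracles.R
    expect_equal(bien("111100"), 0.4422103, tolerance = 1e-6)
    expect_equal(round(bien("111100"), 2), 0.44)
    expect_equal(bien("0110"), 0.4052274, tolerance = 1e-6)
    expect_equal(bien("1010"), 1 / 7)
    expect_equal(bien("111111"), 0)
    expect_equal(bien("000000"), 0)
    expect_error(bien("1"), "at least 2")
    expect_error(bien(c(0, 2)), "0/1")
})

test_that("bien agrees with the naive direct evaluation on all short strings", {
    for (n in 2:8) {
        ss <- all_bitstrings(n)
        expect_equal(bienVector(ss), vapply(ss, naive_bien, numeric(1)),
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
})

test_that("bien is in [0,1], complement-invariant and zero on constants", {
    set.seed(7)
    for (i in 1:50) {
        n <- sample(2:16, 1)
        bits <- sample(0:1, n, replace = TRUE)
        s <- paste(bits, collapse = "")
        comp <- paste(1 - bits, collapse = "")
        e <- bien(s)
        expect_gte(e, 0); expect_lte(e, 1)
        expect_equal(e, bien(comp), tolerance = 1e-12)
    }
    expect_equal(bien(strrep("1", 12)), 0)
})

test_that("fragment filter trims edge-missing calls and rejects internal gaps and size violations", {
    res <- fragmentFilter(c("MMU", "M.UM", paste(rep("M", 33), collapse = ""),
                            "..MUM..", "MU", "...MMUM"))
    expect_equal(res$keep, c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
    expect_equal(res$reason,
                 c("ok", "internal_missing", "too_many_cpgs", "ok",
                   "too_few_cpgs", "ok"))
    expect_equal(res$pattern[1], "110")
    expect_equal(res$pattern[4], "101")   # trimmed to MUM
    expect_equal(res$pattern[6], "1101")
    ## exactly 32 CpGs passes, 3 passes
    res2 <- fragmentFilter(c(strrep("M", 32), "UUU"))
    expect_true(all(res2$keep))
})

test_that("region entropy is the arithmetic mean of fragment entropies", {
    expect_equal(regionEntropy(c("111111", "000000"))$value, 0)
    expect_equal(regionEntropy("111100")$value, bien("111100"))
    r <- regionEntropy(c("0110", "1010"))
    expect_equal(r$value, (0.4052274 + 1 / 7) / 2, tolerance = 1e-6)
    expect_equal(r$N, 2L)
    expect_true(is.na(regionEntropy(character(0))$value))
})

test_that("entropy matrix marks unobserved pairs NA and is read-order invariant", {
    regions <- toy_regions()
    ids <- regionIds(regions)
    reads <- data.frame(
        sample_id = c("S1", "S1", "S2"),
        chrom = "chr1",
        frag_start = c(95L, 1995L, 95L),
        frag_end = c(210L, 2160L, 210L),
        cpg_positions = c("100,150,200", "2000,2050,2100,2150",
                          "100,150,200"),
        calls = c("MMU", "MUMU", "UUU"),
        stringsAsFactors = FALSE)
    m <- entropyMatrix(reads, regions, samples = c("S1", "S2"))
    v <- featureValues(m)
    expect_true(is.na(v[ids[2], "S2"]))
    expect_equal(v[ids[1], "S1"], bien("110"))
    expect_equal(v[ids[1], "S2"], 0)    # constant UUU
    expect_equal(featureDepths(m)[ids[2], "S2"], 0L)
    set.seed(1)
    m2 <- entropyMatrix(reads[sample(nrow(reads)), ], regions,
                        samples = c("S1", "S2"))
    expect_identical(featureValues(m2), v)

    empty <- entropyMatrix(reads[0, ], regions, samples = c("S1", "S2"))
    expect_true(all(is.na(featureValues(empty))))
    expect_true(all(featureDepths(empty) == 0L))

    expect_warning(entropyMatrix(reads, regions, samples = "S1"),
                   "not in the sample sheet")
})
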