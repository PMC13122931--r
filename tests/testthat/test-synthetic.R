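test_that("the generator is reproducible: same seed, byte-identical artifacts", {
    cfg <- simulationConfig(n_cancer_train = 6, n_control_train = 6,
                            n_cancer_test = 3, n_control_test = 3,
                            n_regions = 6, n_informative_binary = 1,
                            depth_mean = 30, n_frags_per_sample = 100,
                            seed = 99)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    simulateCohort(cfg, outdir = d1)
    simulateCohort(cfg, outdir = d2)
    for (f in c("epireads.tsv", "fragments.bed", "labels.tsv", "regions.bed"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))))
    ## a different seed changes the data
    cfg2 <- simulationConfig(n_cancer_train = 6, n_control_train = 6,
                             n_cancer_test = 3, n_control_test = 3,
                             n_regions = 6, n_informative_binary = 1,
                             depth_mean = 30, n_frags_per_sample = 100,
                             seed = 100)
    d3 <- withr::local_tempdir()
    simulateCohort(cfg2, outdir = d3)
    expect_false(identical(
        unname(tools::md5sum(file.path(d1, "epireads.tsv"))),
        unname(tools::md5sum(file.path(d3, "epireads.tsv")))))
})

test_that("generated artifacts satisfy their format contracts", {
    cfg <- simulationConfig(n_cancer_train = 8, n_control_train = 8,
                            n_cancer_test = 4, n_control_test = 4,
                            n_regions = 8, n_informative_binary = 2,
                            depth_mean = 40, n_frags_per_sample = 200,
                            seed = 5)
    d <- withr::local_tempdir()
    co <- simulateCohort(cfg, outdir = d)
    expect_silent(validateEpireads(readEpireads(file.path(d, "epireads.tsv"))))
    expect_silent(validateLabels(readLabels(file.path(d, "labels.tsv"))))
    frags <- readFragments(file.path(d, "fragments.bed"))
    expect_true(all(frags$length >= 100 & frags$length <= 320))
    ## CpG counts per read within the configured range
    nc <- nchar(epireads(co)$calls)
    expect_true(all(nc >= cfg$cpg_range[1] & nc <= cfg$cpg_range[2]))
    ## truth ids refer to real regions
    tr <- truthSet(co)
    expect_true(all(unlist(tr[c("binary_entropy", "binary_ura")]) %in%
                    regionIds(cohortRegions(co))))
    ## ovarian samples are always female
    lab <- labelSheet(co)
    expect_true(all(lab$sex[lab$cancer_type == "ovarian"] == "female"))
})

test_that("null effects produce no group difference; planted disorder raises case entropy", {
    nullcfg <- simulationConfig(n_cancer_train = 12, n_control_train = 12,
                                n_cancer_test = 0, n_control_test = 0,
                                n_regions = 10, n_informative_binary = 0,
                                entropy_effect = 0, ura_effect = 0,
                                frag_short_shift = 0, depth_mean = 60,
                                n_frags_per_sample = 100, seed = 13)
    co <- simulateCohort(nullcfg)
    em <- entropyMatrix(epireads(co), cohortRegions(co),
                        labelSheet(co)$sample_id)
    grp <- labelSheet(co)$group
    v <- featureValues(em)
    expect_lt(abs(mean(v[, grp == "cancer"]) - mean(v[, grp == "non_cancer"])),
              0.02)
    ## strong disorder: planted case entropy exceeds control in every seed tried
    for (sd in 1:5) {
        cfg <- simulationConfig(n_cancer_train = 10, n_control_train = 10,
                                n_cancer_test = 0, n_control_test = 0,
                                n_regions = 6, n_informative_binary = 2,
                                entropy_effect = 0.45, depth_mean = 60,
                                n_frags_per_sample = 50, seed = sd)
        coi <- simulateCohort(cfg)
        ei <- featureValues(entropyMatrix(epireads(coi), cohortRegions(coi),
                                          labelSheet(coi)$sample_id))
        tri <- truthSet(coi)
        gi <- labelSheet(coi)$group
        expect_gt(mean(ei[tri$binary_entropy, gi == "cancer"]),
                  mean(ei[tri$binary_entropy, gi == "non_cancer"]))
    }
})

test_that("presets mirror the study cohort split and validate", {
    ps <- scenarioPresets(3)
    expect_named(ps, c("null", "strong-signal", "seven-type"))
    ss <- ps[["strong-signal"]]
    expect_equal(ss$n_cancer_train, 197L)
    expect_equal(ss$n_control_train, 157L)
    expect_equal(ss$n_cancer_test, 91L)
    expect_equal(ss$n_control_test, 76L)
    st <- ps[["seven-type"]]
    expect_equal(sum(st$type_counts_test), 91L)
    expect_equal(sum(st$type_counts_train), 197L)
    expect_equal(st$type_counts_test[["colorectal"]], 21L)
    expect_equal(ps[["null"]]$entropy_effect, 0)
})

test_that("infeasible effect sizes are rejected at config time", {
    expect_error(simulationConfig(seed = 1, entropy_effect = 0.99),
                 "infeasible entropy_effect")
    expect_error(simulationConfig(seed = 1, ura_effect = 1.2),
                 "infeasible ura_effect")
    expect_error(simulationConfig(seed = 1, n_regions = 5,
                                  n_informative_binary = 10),
                 "more informative regions")
    expect_error(simulationConfig(n_cancer_train = 10), "seed")
})
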