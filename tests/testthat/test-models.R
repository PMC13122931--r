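.sep_data <- function(n = 40, seed = 1) {
    set.seed(seed)
    y <- rep(c("cancer", "non_cancer"), each = n / 2)
    X <- cbind(f1 = ifelse(y == "cancer", 1, 0) + rnorm(n, 0, 0.01),
               f2 = rnorm(n))
    rownames(X) <- paste0("s", seq_len(n))
    list(X = X, y = y)
}

test_that("binary training separates separable data, is seeded, and rejects one-class labels", {
    d <- .sep_data()
    b <- trainBinary(d$X, d$y, "logistic", seed = 3)
    sc <- predictScore(b, d$X)
    expect_equal(evaluateModel(sc, d$y, b@threshold)@auc, 1)
    b2 <- trainBinary(d$X, d$y, "logistic", seed = 3)
    expect_identical(b@fit$coef, b2@fit$coef)
    expect_error(trainBinary(d$X, rep("cancer", 40), "logistic"),
                 "single class")
    ## elastic net path with PCA embedding
    pca <- suppressWarnings(pcaFeatures(d$X))
    be <- trainBinary(d$X, d$y, "elastic_net", "fragmentation",
                      seed = 3, pca = pca)
    expect_gte(evaluateModel(predictScore(be, d$X), d$y, 0.5)@auc, 0.99)
})

test_that("prediction is self-consistent, row-order invariant, NA-safe, and strict on columns", {
    d <- .sep_data(seed = 2)
    b <- trainBinary(d$X, d$y, "logistic", seed = 1)
    sc <- predictScore(b, d$X)
    expect_equal(sc, b@meta$train_scores, tolerance = 1e-12)
    perm <- sample(nrow(d$X))
    expect_equal(predictScore(b, d$X[perm, ]), sc[perm])
    Xna <- d$X[1:2, ]; Xna[1, ] <- NA
    expect_true(all(is.finite(predictScore(b, Xna))))
    expect_error(predictScore(b, d$X[, "f1", drop = FALSE]),
                 "missing feature column.*f2")
})

test_that("score fusion aligns ids, tracks a dominant modality, and ignores constant ones", {
    d <- .sep_data(60, seed = 4)
    e <- stats::setNames(plogis(d$X[, "f1"] * 6 - 3), rownames(d$X))
    m <- stats::setNames(rep(0.5, 60), rownames(d$X))      # constant
    f <- e
    fus2 <- fuseEmced(e, f, NULL, d$y, seed = 1)
    expect_equal(names(sort(predictScore(fus2, cbind(entropy = e, ura = f)))),
                 names(sort(e)))
    ## constant third modality leaves the fused ranking unchanged
    fus3 <- fuseEmced(e, f, m, d$y, seed = 1)
    s3 <- predictScore(fus3,
                       cbind(entropy = e, ura = f, fragmentation = m))
    expect_equal(order(s3), order(predictScore(
        fus2, cbind(entropy = e, ura = f))))
    bad <- e; names(bad)[1] <- "zzz"
    expect_error(fuseEmced(e, bad, NULL, d$y), "misaligned")
})

test_that("evaluation matches the pair-counting oracle and the confusion identities", {
    expect_equal(evaluateModel(c(a = 0.9, b = 0.8, c = 0.2, d = 0.1),
                               c("cancer", "cancer", "non_cancer",
                                 "non_cancer"), 0.5)@auc, 1)
    sc <- c(rep(0.9, 10), rep(0.1, 10))
    names(sc) <- paste0("s", 1:20)
    y <- rep(c("cancer", "non_cancer"), each = 10)
    r <- evaluateModel(sc, y, 0.5)
    expect_equal(r@sensitivity, 1); expect_equal(r@specificity, 1)
    expect_equal(r@confusion["predicted_positive", "positive"], 10)
    set.seed(12)
    for (i in 1:5) {
        n <- sample(6:20, 1)
        yy <- rbinom(n, 1, 0.5)
        if (length(unique(yy)) < 2) yy[1:2] <- c(0, 1)
        ss <- round(runif(n), 2)   # force some ties
        expect_equal(evaluateModel(ss, yy, 0.5)@auc, pairwise_auc(ss, yy))
    }
    expect_error(evaluateModel(sc, rep("cancer", 20), 0.5), "single class")
})

test_that("cross-validation folds are stratified, reproducible, and guarded", {
    d <- .sep_data(40, seed = 6)
    cv <- crossValidate(d$X, d$y, k = 5, seed = 9)
    expect_true(max(table(cv$fold)) - min(table(cv$fold)) <= 1)
    cv2 <- crossValidate(d$X, d$y, k = 5, seed = 9)
    expect_identical(cv$fold, cv2$fold)
    expect_equal(cv$pooled_auc, 1)
    expect_error(crossValidate(d$X, rep(c("cancer", "non_cancer"),
                                        c(36, 4)), k = 5), "at least k")
})

test_that("TOO models recover separated type signatures and use the sex covariate for ovarian", {
    set.seed(15)
    n_per <- 12
    types <- rep(CANCER_TYPES <- c("colorectal", "esophageal", "gastric",
                                   "liver", "lung", "ovarian", "thyroid"),
                 each = n_per)
    n <- length(types)
    X <- matrix(rnorm(n * 14, 0, 0.3), n, 14,
                dimnames = list(paste0("s", 1:n), paste0("m", 1:14)))
    for (j in seq_along(CANCER_TYPES))
        X[types == CANCER_TYPES[j], 2 * j - 1] <-
            X[types == CANCER_TYPES[j], 2 * j - 1] +
            if (CANCER_TYPES[j] == "ovarian") 0.25 else 2
    sex <- ifelse(types == "ovarian", "female",
                  sample(c("male", "female"), n, TRUE))
    model <- trainToo(list(entropy = X, ura = X, fragmentation = NULL),
                      types, sex, seed = 5)
    pred <- predictToo(model, list(entropy = X, ura = X), sex, "e_m")
    expect_equal(unname(rowSums(pred$prob)), rep(1, n), tolerance = 1e-9)
    expect_gte(mean(pred$top1 == types), 0.85)
    ## male sample: ovarian probability suppressed via the sex feature
    Xm <- X[types == "ovarian", , drop = FALSE]
    pm <- predictToo(model, list(entropy = Xm, ura = Xm),
                     rep("male", nrow(Xm)), "entropy_only")
    pf <- predictToo(model, list(entropy = Xm, ura = Xm),
                     rep("female", nrow(Xm)), "entropy_only")
    expect_lt(mean(pm$prob[, "ovarian"]), mean(pf$prob[, "ovarian"]))
    expect_error(trainToo(list(entropy = X), types[types != "liver"],
                          sex[types != "liver"], seed = 1),
                 "absent from training")
})

test_that("TOO fusion is the renormalised arithmetic mean with fixed-order ties", {
    p1 <- matrix(c(0.6, 0.4), 1, 2,
                 dimnames = list("s1", c("colorectal", "lung")))
    p2 <- matrix(c(0.2, 0.8), 1, 2,
                 dimnames = list("s1", c("colorectal", "lung")))
    fused <- (p1 + p2) / 2
    expect_equal(unname(fused[1, ]), c(0.4, 0.6))
    r <- evaluateToo(fused, "lung")
    expect_equal(r@extras$top1_accuracy, 1)
    expect_gte(r@extras$top2_accuracy, r@extras$top1_accuracy)
    ## exact tie -> alphabetical order wins the first slot
    tie <- matrix(c(0.5, 0.5), 1, 2,
                  dimnames = list("s1", c("lung", "colorectal")))
    rt <- evaluateToo(tie[, sort(colnames(tie)), drop = FALSE], "colorectal")
    expect_equal(rt@extras$top1_accuracy, 1)
})

test_that("no test-split sample influences selection, preprocessing, or fitting", {
    cfg <- simulationConfig(n_cancer_train = 16, n_control_train = 16,
                            n_cancer_test = 8, n_control_test = 8,
                            n_regions = 10, n_informative_binary = 2,
                            depth_mean = 70, n_frags_per_sample = 400,
                            seed = 77)
    co <- simulateCohort(cfg)
    res1 <- runStudy(co, seed = 5)
    ## corrupt every test sample's reads and fragments; refit
    lab <- labelSheet(co)
    test_ids <- lab$sample_id[lab$split == "test"]
    ep <- epireads(co)
    is_test <- ep$sample_id %in% test_ids
    ep$calls[is_test] <- chartr("MU", "UM", ep$calls[is_test])
    fr <- fragmentRecords(co)
    co2 <- list(epireads = ep, fragments = fr, labels = lab,
                regions = cohortRegions(co), config = co@config)
    res2 <- runStudy(co2, seed = 5)
    expect_identical(res1$selected, res2$selected)
    expect_identical(res1$bundles$entropy@fit$coef,
                     res2$bundles$entropy@fit$coef)
    expect_identical(res1$bundles$entropy@imputation,
                     res2$bundles$entropy@imputation)
    expect_identical(res1$bundles$e_m_f@fit$coef,
                     res2$bundles$e_m_f@fit$coef)
    ## training scores cover exactly the training split
    expect_setequal(names(res1$bundles$entropy@meta$train_scores),
                    lab$sample_id[lab$split == "train"])
})
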