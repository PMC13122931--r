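## region dropping decided on TRAINING samples only; per-cell depth masking
## is sample-local so it cannot leak across the split
.preprocess_split <- function(x, train_ids, min_depth = 50L,
                              max_na_fraction = 0.90) {
    v <- featureValues(x); d <- featureDepths(x)
    v[d < min_depth] <- NA_real_
    na_frac <- rowMeans(is.na(v[, train_ids, drop = FALSE]))
    keep <- na_frac <= max_na_fraction
    if (!any(keep)) stop("all regions dropped by preprocessing")
    RegionMatrix(v[keep, , drop = FALSE], d[keep, , drop = FALSE])
}

.select_modality <- function(x, labels, cfg) {
    train_ids <- labels$sample_id[labels$split == "train"]
    xt <- x[, colnames(x) %in% train_ids]
    stats <- regionStatsAll(xt, labels, cfg$specificity)
    cand <- suppressWarnings(selectBinaryFeatures(stats, cfg))
    if (!length(cand))
        return(list(selected = character(0), stats = stats))
    X <- t(featureValues(xt)[cand, , drop = FALSE])
    grp <- labels$group[match(rownames(X), labels$sample_id)]
    imp <- importanceFilter(X, grp, cfg$importance_threshold,
                            seed = cfg$rng_seed)
    sel <- imp$selected
    if (!length(sel)) sel <- cand   # degenerate: keep threshold-stage set
    list(selected = sel, stats = stats, importance = imp$importance)
}

## TOO marker discovery: entropy one-vs-rest thresholds + Boruta refinement;
## URA Kruskal-Wallis / Dunn / top-k Boruta
.too_markers <- function(ent, ura, labels, seed) {
    train <- labels[labels$split == "train" & labels$group == "cancer", ]
    cfg_e <- selectionConfig("entropy", seed)
    ve <- featureValues(ent)[, train$sample_id, drop = FALSE]
    cand <- character(0)
    for (tp in unique(train$cancer_type)) {
        in_type <- train$cancer_type == tp
        for (i in seq_len(nrow(ve))) {
            st <- regionStats(ve[i, in_type], ve[i, !in_type],
                              cfg_e$specificity)
            if (!is.null(st) &&
                abs(st$delta) >= cfg_e$min_abs_delta &&
                st$sensitivity_at_spec >= cfg_e$min_sensitivity &&
                st$p_value < cfg_e$max_p)
                cand <- c(cand, rownames(ve)[i])
        }
    }
    cand <- unique(cand)
    ent_markers <- cand
    if (length(cand) > 1L) {
        bs <- borutaSelect(t(ve[cand, , drop = FALSE]),
                           train$cancer_type, max_iter = 20L, seed = seed)
        if (length(bs$confirmed)) ent_markers <- bs$confirmed
    }
    vu <- featureValues(ura)[, train$sample_id, drop = FALSE]
    ura_lists <- kwDunnSelect(t(vu), train$cancer_type, seed = seed)
    ura_markers <- unique(unlist(ura_lists))
    list(entropy = ent_markers, ura = ura_markers, ura_by_type = ura_lists)
}

#' Run the full detection study on a cohort in memory
#'
#' End-to-end orchestration: entropy and URA matrices, depth/missingness
#' preprocessing, the binary feature-selection cascade (training split
#' only), fragmentation profiles with training-fitted bin filter and PCA,
#' per-modality binary models, out-of-fold score fusion (E-M and E-M-F),
#' held-out evaluation, and optionally the tissue-of-origin models.
#' Test-split samples never enter selection, imputation, standardisation,
#' PCA or fitting.
#'
#' @param cohort a \linkS4class{SyntheticCohort} (or a list with elements
#'   \code{epireads}, \code{fragments}, \code{labels}, \code{regions}).
#' @param seed integer seed for all stochastic stages.
#' @param too also train/evaluate the tissue-of-origin models.
#' @return list with matrices, selected features, fitted bundles, test
#'   scores and \linkS4class{EvalReport}s.
#' @export
runStudy <- function(cohort, seed = 1L, too = FALSE) {
    if (is(cohort, "SyntheticCohort"))
        cohort <- list(epireads = cohort@epireads,
                       fragments = cohort@fragments,
                       labels = cohort@labels, regions = cohort@regions,
                       config = cohort@config)
    labels <- cohort$labels
    regions <- cohort$regions
    train_ids <- labels$sample_id[labels$split == "train"]
    test_ids <- labels$sample_id[labels$split == "test"]
    ent <- entropyMatrix(cohort$epireads, regions, labels$sample_id)
    ura <- uraMatrix(cohort$epireads, regions, labels$sample_id)
    ent <- .preprocess_split(ent, train_ids)
    ura <- .preprocess_split(ura, train_ids)
    cfg_e <- selectionConfig("entropy", seed)
    cfg_u <- selectionConfig("ura", seed)
    sel_e <- .select_modality(ent, labels, cfg_e)
    sel_u <- .select_modality(ura, labels, cfg_u)
    if (!length(sel_e$selected) || !length(sel_u$selected))
        stop("feature selection returned an empty set")
    grp <- function(idx) labels$group[match(idx, labels$sample_id)]
    Xe <- t(featureValues(ent)[sel_e$selected, , drop = FALSE])
    Xu <- t(featureValues(ura)[sel_u$selected, , drop = FALSE])
    ## fragmentation: bin filter fitted on training coverage
    chrom_sizes <- cohort$config$chrom_sizes
    if (is.null(chrom_sizes))
        chrom_sizes <- vapply(split(cohort$fragments$end,
                                    cohort$fragments$chrom), max, numeric(1))
    gb <- makeBins(chrom_sizes)
    frag_train <- cohort$fragments[cohort$fragments$sample_id %in% train_ids, ]
    key <- sprintf("%s:%d", frag_train$chrom,
                   (((frag_train$start + frag_train$end) %/% 2L) %/%
                        gb$width) * gb$width)
    cov <- as.numeric(table(factor(key, levels = gb$bins$bin_id)))
    gb <- filterBins(gb, cov)
    prof <- coverageProfile(cohort$fragments, gb, labels$sample_id)
    Xf <- prof$features
    ## per-modality models fitted on the training split
    b_e <- trainBinary(Xe[train_ids, , drop = FALSE], grp(train_ids),
                       "logistic", "entropy", seed)
    b_u <- trainBinary(Xu[train_ids, , drop = FALSE], grp(train_ids),
                       "logistic", "ura", seed)
    pca <- suppressWarnings(pcaFeatures(Xf[train_ids, , drop = FALSE]))
    b_f <- trainBinary(Xf[train_ids, , drop = FALSE], grp(train_ids),
                       "elastic_net", "fragmentation", seed, pca = pca)
    ## out-of-fold training scores feed the fusion stage
    oof_e <- oofScores(Xe[train_ids, , drop = FALSE], grp(train_ids),
                       "logistic", seed = seed)
    oof_u <- oofScores(Xu[train_ids, , drop = FALSE], grp(train_ids),
                       "logistic", seed = seed)
    oof_f <- oofScores(Xf[train_ids, , drop = FALSE], grp(train_ids),
                       "elastic_net", seed = seed, use_pca = TRUE)
    fus_em <- fuseEmced(oof_e, oof_u, NULL, grp(train_ids), seed)
    fus_emf <- fuseEmced(oof_e, oof_u, oof_f, grp(train_ids), seed)
    ## held-out scores
    ts_e <- predictScore(b_e, Xe[test_ids, , drop = FALSE])
    ts_u <- predictScore(b_u, Xu[test_ids, , drop = FALSE])
    ts_f <- predictScore(b_f, Xf[test_ids, , drop = FALSE])
    S_em <- cbind(entropy = ts_e, ura = ts_u)
    S_emf <- cbind(entropy = ts_e, ura = ts_u, fragmentation = ts_f)
    ts_em <- predictScore(fus_em, S_em)
    ts_emf <- predictScore(fus_emf, S_emf)
    reports <- list(
        entropy = evaluateModel(ts_e, grp(test_ids), b_e@threshold),
        ura = evaluateModel(ts_u, grp(test_ids), b_u@threshold),
        fragmentation = evaluateModel(ts_f, grp(test_ids), b_f@threshold),
        e_m = evaluateModel(ts_em, grp(test_ids), fus_em@threshold),
        e_m_f = evaluateModel(ts_emf, grp(test_ids), fus_emf@threshold))
    out <- list(entropy_matrix = ent, ura_matrix = ura,
                fragment_profile = prof,
                selected = list(entropy = sel_e$selected,
                                ura = sel_u$selected),
                selection_stats = list(entropy = sel_e$stats,
                                       ura = sel_u$stats),
                bundles = list(entropy = b_e, ura = b_u,
                               fragmentation = b_f,
                               e_m = fus_em, e_m_f = fus_emf),
                test_scores = list(entropy = ts_e, ura = ts_u,
                                   fragmentation = ts_f, e_m = ts_em,
                                   e_m_f = ts_emf),
                reports = reports,
                train_ids = train_ids, test_ids = test_ids, seed = seed)
    if (too) {
        mk <- .too_markers(ent, ura, labels, seed)
        if (!length(mk$entropy) || !length(mk$ura))
            stop("tissue-of-origin marker discovery returned an empty set")
        ca_tr <- labels[labels$split == "train" & labels$group == "cancer", ]
        ca_te <- labels[labels$split == "test" & labels$group == "cancer", ]
        blocks_tr <- list(
            entropy = Xe_too <- t(featureValues(ent)[mk$entropy,
                                                     ca_tr$sample_id,
                                                     drop = FALSE]),
            ura = t(featureValues(ura)[mk$ura, ca_tr$sample_id,
                                       drop = FALSE]),
            fragmentation = Xf[ca_tr$sample_id, , drop = FALSE])
        too_model <- trainToo(blocks_tr, ca_tr$cancer_type, ca_tr$sex, seed)
        blocks_te <- list(
            entropy = t(featureValues(ent)[mk$entropy, ca_te$sample_id,
                                           drop = FALSE]),
            ura = t(featureValues(ura)[mk$ura, ca_te$sample_id,
                                       drop = FALSE]),
            fragmentation = Xf[ca_te$sample_id, , drop = FALSE])
        pred <- predictToo(too_model, blocks_te, ca_te$sex, "e_m_f")
        out$too <- list(markers = mk, model = too_model,
                        prediction = pred,
                        report = evaluateToo(pred$prob, ca_te$cancer_type))
    }
    out
}

#' Run the pipeline from a config, writing a run directory
#'
#' File-level orchestration: simulates (or reads) the inputs, runs
#' \code{\link{runStudy}}, and writes matrices, selected features, model
#' bundles, evaluation reports and a machine-readable manifest (package
#' version, seeds, MD5 checksums) into \code{outdir}.  Deterministic
#' stages are bitwise-stable under a fixed config and seed.
#'
#' @param config a list - or path to a YAML file - with elements
#'   \code{seed}, \code{outdir}, \code{too} (logical) and either
#'   \code{preset} (a \code{\link{scenarioPresets}} name) or the input
#'   paths \code{epireads}, \code{fragments}, \code{labels},
#'   \code{cpgs}.
#' @return invisibly, the \code{\link{runStudy}} result.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(!is.null(config$outdir), !is.null(config$seed))
    seed <- as.integer(config$seed)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(config$preset)) {
        cfg <- scenarioPresets(seed)[[config$preset]]
        if (is.null(cfg)) stop("unknown preset: ", config$preset)
        cohort <- simulateCohort(cfg, outdir = file.path(outdir, "inputs"))
    } else {
        for (f in c("epireads", "fragments", "labels", "cpgs"))
            if (is.null(config[[f]]) || !file.exists(config[[f]]))
                stop("input file missing for stage '", f, "'")
        cohort <- list(epireads = readEpireads(config$epireads),
                       fragments = readFragments(config$fragments),
                       labels = readLabels(config$labels),
                       regions = buildSegments(readCpgBed(config$cpgs)),
                       config = list())
    }
    res <- tryCatch(
        runStudy(cohort, seed = seed, too = isTRUE(config$too)),
        error = function(e) stop("pipeline stage failed: ",
                                 conditionMessage(e), call. = FALSE))
    writeFeatureMatrix(res$entropy_matrix,
                       file.path(outdir, "entropy_matrix.tsv"))
    writeFeatureMatrix(res$ura_matrix, file.path(outdir, "ura_matrix.tsv"))
    jsonlite::write_json(res$selected,
                         file.path(outdir, "selected_features.json"))
    writeModelBundle(res$bundles, file.path(outdir, "models.bin"))
    rep_list <- lapply(res$reports, function(r)
        list(auc = r@auc, sensitivity = r@sensitivity,
             specificity = r@specificity,
             sens_ci = r@sens_ci, spec_ci = r@spec_ci))
    if (!is.null(res$too))
        rep_list$too <- res$too$report@extras[c("top1_accuracy",
                                                "top2_accuracy")]
    jsonlite::write_json(rep_list, file.path(outdir, "reports.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    manifest <- list(
        package = "cfEntropy",
        version = as.character(utils::packageVersion("cfEntropy")),
        seed = seed,
        selection_seeds = c(entropy = seed, ura = seed),
        files = as.list(tools::md5sum(
            files[!grepl("manifest[.]json$", files)])))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(res)
}
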