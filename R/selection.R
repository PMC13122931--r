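#' Default selection configuration per modality
#'
#' Thresholds of the feature-selection cascade: candidate regions must show
#' |delta| >= 0.02, sensitivity at 80\% specificity >= 0.4 (entropy) or
#' 0.5 (URA/methylation), and P < 0.01; the random-forest importance filter
#' keeps features with normalised impurity importance > 0.006 (entropy) or
#' > 0.0055 (URA).  Cells with effective depth < 50 are treated as missing
#' and regions missing in > 90\% of samples are dropped.
#'
#' @param modality "entropy" or "ura".
#' @param rng_seed integer seed recorded in the config.
#' @return list of thresholds.
#' @export
selectionConfig <- function(modality = c("entropy", "ura"), rng_seed = 1L) {
    modality <- match.arg(modality)
    list(modality = modality,
         specificity = 0.80,
         min_abs_delta = 0.02,
         min_sensitivity = if (modality == "entropy") 0.4 else 0.5,
         max_p = 0.01,
         importance_threshold = if (modality == "entropy") 0.006 else 0.0055,
         min_depth = 50L,
         max_na_fraction = 0.90,
         rng_seed = as.integer(rng_seed))
}

#' Depth / missingness preprocessing of a region matrix
#'
#' Cells with effective depth below \code{min_depth} (default 50) are set
#' to NA; regions that are then missing in more than \code{max_na_fraction}
#' (default 90\%) of samples are dropped entirely.  Applied to entropy and
#' URA matrices only, never to fragmentation profiles.
#'
#' @param x a \linkS4class{RegionMatrix}.
#' @param min_depth minimum effective read depth per cell.
#' @param max_na_fraction maximum tolerated NA fraction per region.
#' @return a filtered \linkS4class{RegionMatrix}.
#' @export
preprocessRegions <- function(x, min_depth = 50L, max_na_fraction = 0.90) {
    v <- featureValues(x)
    d <- featureDepths(x)
    v[d < min_depth] <- NA_real_
    na_frac <- rowMeans(is.na(v))
    keep <- na_frac <= max_na_fraction
    if (!any(keep))
        stop("all regions dropped by depth/missingness preprocessing")
    RegionMatrix(v[keep, , drop = FALSE], d[keep, , drop = FALSE])
}

#' Case/control statistics for one region at fixed specificity
#'
#' The cutoff is the order statistic ceiling(specificity * n) of the
#' control values in the favourable direction (the direction of the sign of
#' delta = case mean - control mean); sensitivity is the fraction of cases
#' strictly beyond the cutoff; the P-value is a two-sided Wilcoxon
#' rank-sum test.  NA values are excluded per group.
#'
#' @param case_values,control_values numeric vectors (NA allowed).
#' @param specificity target specificity in (0, 1).
#' @return one-row data.frame with delta, cutoff, sensitivity_at_spec,
#'   p_value, direction; or NULL when either group has < 2 non-missing
#'   values.
#' @export
regionStats <- function(case_values, control_values, specificity = 0.80) {
    ca <- case_values[!is.na(case_values)]
    co <- control_values[!is.na(control_values)]
    if (length(ca) < 2L || length(co) < 2L) return(NULL)
    delta <- mean(ca) - mean(co)
    direction <- if (delta >= 0) "up" else "down"
    k <- ceiling(specificity * length(co))
    if (direction == "up") {
        cutoff <- sort(co)[k]
        sens <- mean(ca > cutoff)
    } else {
        cutoff <- sort(co, decreasing = TRUE)[k]
        sens <- mean(ca < cutoff)
    }
    p <- suppressWarnings(
        stats::wilcox.test(ca, co, exact = FALSE)$p.value)
    data.frame(delta = delta, cutoff = cutoff, sensitivity_at_spec = sens,
               p_value = p, direction = direction,
               stringsAsFactors = FALSE)
}

#' Region statistics for every region of a matrix
#'
#' @param x a \linkS4class{RegionMatrix} (training samples only).
#' @param labels data.frame label sheet covering the matrix samples.
#' @param specificity target specificity.
#' @return data.frame with one row per computable region (region_id, delta,
#'   cutoff, sensitivity_at_spec, p_value, direction); skipped regions are
#'   reported in attribute \code{"skipped"}.
#' @export
regionStatsAll <- function(x, labels, specificity = 0.80) {
    v <- featureValues(x)
    grp <- labels$group[match(colnames(v), labels$sample_id)]
    if (anyNA(grp)) stop("matrix contains samples absent from the label sheet")
    rows <- vector("list", nrow(v))
    skipped <- character(0)
    for (i in seq_len(nrow(v))) {
        st <- regionStats(v[i, grp == "cancer"], v[i, grp == "non_cancer"],
                          specificity)
        if (is.null(st)) skipped <- c(skipped, rownames(v)[i])
        else rows[[i]] <- cbind(region_id = rownames(v)[i], st)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(region_id = character(0), delta = numeric(0),
                          cutoff = numeric(0),
                          sensitivity_at_spec = numeric(0),
                          p_value = numeric(0), direction = character(0))
    attr(out, "skipped") <- skipped
    out
}

#' Threshold stage of the binary feature-selection cascade
#'
#' Applies |delta| >= min_abs_delta, sensitivity >= min_sensitivity and
#' P < max_p conjunctively.
#'
#' @param stats data.frame from \code{\link{regionStatsAll}}.
#' @param cfg a \code{\link{selectionConfig}} list.
#' @return character vector of passing region ids (possibly empty, with a
#'   warning).
#' @export
selectBinaryFeatures <- function(stats, cfg) {
    keep <- abs(stats$delta) >= cfg$min_abs_delta &
            stats$sensitivity_at_spec >= cfg$min_sensitivity &
            stats$p_value < cfg$max_p
    ids <- stats$region_id[keep]
    if (!length(ids)) warning("no regions pass the threshold stage")
    ids
}

## median-impute a samples x features matrix (training statistics)
.impute_median <- function(X, medians = NULL) {
    if (is.null(medians))
        medians <- apply(X, 2, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
    for (j in seq_len(ncol(X))) {
        na <- is.na(X[, j])
        if (any(na)) X[na, j] <- medians[j]
    }
    list(X = X, medians = medians)
}

#' Random-forest importance filter
#'
#' Grows a random forest with a fixed seed on the candidate features and
#' retains those whose impurity (Gini) importance, normalised to sum to 1,
#' exceeds \code{threshold}.  Only two split candidates are drawn per node
#' (\code{mtry = 2}, with a raised minimum node size): candidate regions
#' surviving the threshold stage are typically strongly correlated with
#' the class and with each other, and greedy split selection over larger
#' candidate draws concentrates the impurity importance on arbitrary
#' representatives of a correlated group, starving equally informative
#' regions below any fixed threshold; small draws spread importance over
#' informative features while uninformative ones still gain essentially
#' nothing.
#'
#' @param X numeric matrix, samples x candidate features (NA cells are
#'   median-imputed).
#' @param labels factor/character of class labels, one per sample.
#' @param threshold importance threshold (exceeded strictly).
#' @param seed integer seed.
#' @param num_trees forest size.
#' @param mtry split candidates drawn per node.
#' @param min_node_size minimum node size (limits importance accrued from
#'   spurious deep splits).
#' @return list with \code{selected} (feature names), \code{importance}
#'   (named, normalised) and \code{seed}.
#' @export
importanceFilter <- function(X, labels, threshold, seed = 1L,
                             num_trees = 500L, mtry = 2L,
                             min_node_size = 10L) {
    stopifnot(ncol(X) >= 1)
    X <- .impute_median(X)$X
    df <- data.frame(X, check.names = FALSE)
    df$.label <- factor(labels)
    rf <- ranger::ranger(dependent.variable.name = ".label", data = df,
                         importance = "impurity", num.trees = num_trees,
                         mtry = min(mtry, ncol(X)),
                         min.node.size = min_node_size,
                         seed = as.integer(seed), num.threads = 1L)
    imp <- rf$variable.importance
    imp <- imp / sum(imp)
    list(selected = names(imp)[imp > threshold], importance = imp,
         seed = as.integer(seed))
}

## Dunn's rank-based pairwise z-test, all pairs of groups, tie-corrected
.dunn_pairwise <- function(values, groups) {
    ok <- !is.na(values)
    x <- values[ok]; g <- droplevels(factor(groups[ok]))
    N <- length(x)
    r <- rank(x)
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    mean_r <- tapply(r, g, mean)
    n_g <- table(g)
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    z <- p <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                   (1 / n_g[[a]] + 1 / n_g[[b]]))
        z[j] <- (mean_r[[a]] - mean_r[[b]]) / se
        p[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
    data.frame(g1 = pairs[1, ], g2 = pairs[2, ], z = z, p = p,
               stringsAsFactors = FALSE)
}

#' Kruskal-Wallis / Dunn / Boruta cascade for type-specific markers
#'
#' Stage 1: Kruskal-Wallis test of each region across the cancer types,
#' Benjamini-Hochberg FDR at \code{q}.  Stage 2: Dunn's pairwise rank
#' z-tests; a candidate region is attributed to a type when that type
#' separates from every other type (all its pairwise comparisons
#' BH-significant at \code{alpha_dunn} within the region, with a consistent
#' direction).  Stage 3: per-type shadow-feature (Boruta) importance
#' ranking of the attributed regions, truncated to the \code{top_k} with
#' the highest mean importance history.
#'
#' @param X numeric matrix, samples x regions (NA allowed).
#' @param types character/factor of cancer types, one per sample.
#' @param q FDR level for the Kruskal-Wallis stage.
#' @param top_k maximum markers per type.
#' @param alpha_dunn per-region BH level for Dunn's comparisons.
#' @param seed integer seed for the Boruta stage.
#' @param boruta_iter iterations of the shadow-feature scheme.
#' @return named list (one element per type) of marker region ids.
#' @export
kwDunnSelect <- function(X, types, q = 0.05, top_k = 30L,
                         alpha_dunn = 0.05, seed = 1L, boruta_iter = 20L) {
    types <- factor(types)
    if (any(table(types) < 2))
        stop("every cancer type needs at least 2 samples")
    kw_p <- apply(X, 2, function(v) {
        ok <- !is.na(v)
        if (length(unique(types[ok])) < 2) return(NA_real_)
        suppressWarnings(stats::kruskal.test(v[ok], types[ok])$p.value)
    })
    qv <- stats::p.adjust(kw_p, method = "BH")
    cand <- colnames(X)[!is.na(qv) & qv < q]
    out <- stats::setNames(vector("list", nlevels(types)), levels(types))
    if (!length(cand)) return(lapply(out, function(x) character(0)))
    attributed <- stats::setNames(
        vector("list", nlevels(types)), levels(types))
    for (rg in cand) {
        dn <- .dunn_pairwise(X[, rg], types)
        dn$p_adj <- stats::p.adjust(dn$p, method = "BH")
        for (tp in levels(types)) {
            rows <- dn$g1 == tp | dn$g2 == tp
            zz <- ifelse(dn$g1[rows] == tp, dn$z[rows], -dn$z[rows])
            if (all(dn$p_adj[rows] < alpha_dunn) &&
                (all(zz > 0) || all(zz < 0)))
                attributed[[tp]] <- c(attributed[[tp]], rg)
        }
    }
    for (tp in levels(types)) {
        ids <- attributed[[tp]]
        if (is.null(ids)) { out[[tp]] <- character(0); next }
        if (length(ids) > top_k) {
            bs <- borutaSelect(X[, ids, drop = FALSE],
                               factor(ifelse(types == tp, tp, "rest")),
                               max_iter = boruta_iter, seed = seed)
            rank_imp <- sort(bs$importance_mean, decreasing = TRUE)
            ids <- names(rank_imp)[seq_len(min(top_k, length(rank_imp)))]
        }
        out[[tp]] <- ids
    }
    out
}
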