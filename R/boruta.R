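#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Each iteration appends a permuted ("shadow") copy of every feature,
#' grows a random forest, and scores a hit for every real feature whose
#' impurity importance exceeds the best shadow importance.  After
#' \code{max_iter} iterations a feature is confirmed when its hit count is
#' significantly above chance (one binomial test per feature against 0.5,
#' two-sided, at \code{alpha} with Bonferroni correction) and rejected when
#' significantly below; everything else is tentative and excluded from the
#' confirmed set.
#'
#' @param X numeric matrix, samples x features (NA cells median-imputed).
#' @param labels factor/character class labels, one per sample.
#' @param max_iter number of shadow iterations.
#' @param seed integer seed (controls both permutations and forests).
#' @param alpha familywise significance level for the binomial decision.
#' @param num_trees trees per forest.
#' @return list with \code{confirmed}, \code{tentative}, \code{rejected}
#'   (feature name vectors), \code{hits}, \code{importance_mean} (mean
#'   importance history, used for ranking) and \code{seed}.
#' @export
borutaSelect <- function(X, labels, max_iter = 30L, seed = 1L,
                         alpha = 0.01, num_trees = 300L) {
    stopifnot(ncol(X) >= 1)
    X <- .impute_median(X)$X
    feats <- colnames(X)
    if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(ncol(X)))
    labels <- factor(labels)
    set.seed(as.integer(seed))
    hits <- stats::setNames(integer(length(feats)), feats)
    imp_sum <- stats::setNames(numeric(length(feats)), feats)
    for (it in seq_len(max_iter)) {
        shadow <- apply(X, 2, sample)
        colnames(shadow) <- paste0(".shadow_", feats)
        df <- data.frame(cbind(X, shadow), check.names = FALSE)
        df$.label <- labels
        rf <- ranger::ranger(dependent.variable.name = ".label", data = df,
                             importance = "impurity",
                             num.trees = num_trees,
                             seed = as.integer(seed) + it, num.threads = 1L)
        imp <- rf$variable.importance
        real <- imp[feats]
        best_shadow <- max(imp[paste0(".shadow_", feats)])
        hits <- hits + (real > best_shadow)
        imp_sum <- imp_sum + real
    }
    thr <- alpha / length(feats)   # Bonferroni over features
    p_hi <- stats::pbinom(hits - 1L, max_iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits, max_iter, 0.5)
    confirmed <- feats[2 * p_hi < thr]
    rejected <- feats[2 * p_lo < thr]
    tentative <- setdiff(feats, c(confirmed, rejected))
    list(confirmed = confirmed, tentative = tentative, rejected = rejected,
         hits = hits, importance_mean = imp_sum / max_iter,
         seed = as.integer(seed))
}
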