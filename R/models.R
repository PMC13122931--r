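## ---- shared design-matrix preparation -------------------------------------

.prep_fit <- function(X) {
    imp <- .impute_median(X)
    X <- imp$X
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0 | is.na(scl)] <- Inf   # constant columns contribute 0
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    list(X = Xs, imputation = imp$medians, center = ctr, scale = scl)
}

.prep_predict <- function(bundle, X) {
    miss <- setdiff(bundle@features, colnames(X))
    if (length(miss))
        stop("missing feature column(s): ", paste(miss, collapse = ", "))
    X <- X[, bundle@features, drop = FALSE]
    X <- .impute_median(X, bundle@imputation)$X
    sweep(sweep(X, 2, bundle@center), 2, bundle@scale, "/")
}

.youden_threshold <- function(scores, y) {
    cuts <- sort(unique(scores))
    if (length(cuts) > 1L)
        cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
    j <- vapply(cuts, function(cc) {
        mean(scores[y == 1L] >= cc) + mean(scores[y == 0L] < cc) - 1
    }, numeric(1))
    cuts[which.max(j)]
}

.binary_y <- function(labels, positive = "cancer") {
    labels <- as.character(labels)
    if (all(labels %in% c("0", "1"))) return(as.integer(labels))
    as.integer(labels == positive)
}

.stratifiedFolds <- function(y, k, seed) {
    set.seed(as.integer(seed))
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

## ---- binary models --------------------------------------------------------

#' Train a binary cancer / non-cancer classifier
#'
#' Logistic regression for the entropy and URA modalities; elastic net for
#' the (PCA-projected) fragmentation modality.  All preprocessing -
#' median imputation, standardisation, optional PCA projection - is fitted
#' on the supplied (training) samples only and frozen into the returned
#' bundle.  The decision threshold is Youden's J on the training scores.
#'
#' @param X numeric matrix, training samples x features.  When \code{pca}
#'   is supplied, \code{X} holds the raw fragmentation features and is
#'   projected first.
#' @param labels sample labels ("cancer"/"non_cancer", or 0/1).
#' @param kind "logistic" or "elastic_net".
#' @param modality label stored in the bundle.
#' @param seed integer seed (elastic-net fold assignment).
#' @param pca optional \code{PCFeatures} object for fragmentation input.
#' @param alphas elastic-net mixing grid searched by internal 5-fold CV.
#' @return a \linkS4class{ModelBundle}.
#' @export
trainBinary <- function(X, labels, kind = c("logistic", "elastic_net"),
                        modality = "entropy", seed = 1L, pca = NULL,
                        alphas = c(0.2, 0.5, 0.8)) {
    kind <- match.arg(kind)
    y <- .binary_y(labels)
    if (length(unique(y)) < 2L) stop("training labels contain a single class")
    if (!is.null(pca)) X <- projectPca(pca, X)
    prep <- .prep_fit(X)
    fit <- .fit_linear(prep$X, y, kind, seed, alphas)
    scores <- .linear_scores(fit, prep$X)
    bundle <- new("ModelBundle", kind = kind, modality = modality,
                  features = colnames(X), fit = fit,
                  imputation = prep$imputation, center = prep$center,
                  scale = prep$scale,
                  pca = if (is.null(pca)) list() else unclass(pca),
                  threshold = .youden_threshold(scores, y),
                  seed = as.integer(seed),
                  meta = list(train_scores = stats::setNames(scores, rownames(X)),
                              positive = "cancer"))
    validObject(bundle)
    bundle
}

.fit_linear <- function(Xs, y, kind, seed, alphas) {
    if (kind == "logistic") {
        fit <- suppressWarnings(
            stats::glm.fit(cbind(`(Intercept)` = 1, Xs), y,
                           family = stats::binomial()))
        list(kind = "logistic", coef = fit$coefficients)
    } else {
        set.seed(as.integer(seed))
        foldid <- .stratifiedFolds(y, 5L, seed)
        fits <- lapply(alphas, function(a)
            glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = a,
                              foldid = foldid, standardize = FALSE))
        best <- which.min(vapply(fits, function(f)
            min(f$cvm), numeric(1)))
        list(kind = "elastic_net", fit = fits[[best]],
             alpha = alphas[best])
    }
}

.linear_scores <- function(fit, Xs) {
    if (fit$kind == "logistic") {
        cf <- fit$coef
        cf[is.na(cf)] <- 0
        eta <- drop(cbind(1, Xs) %*% cf)
        stats::plogis(eta)
    } else {
        drop(stats::predict(fit$fit, newx = Xs, s = "lambda.min",
                            type = "response"))
    }
}

#' Score samples with a fitted bundle
#'
#' Applies the bundle's stored PCA projection (if any), imputation,
#' standardisation and coefficients; never refits.  Scores depend only on
#' the bundle and the corresponding input rows - row order is irrelevant.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param X numeric matrix, samples x features (raw fragmentation features
#'   when the bundle embeds a PCA).
#' @return named numeric vector of scores in [0, 1].
#' @export
predictScore <- function(bundle, X) {
    if (length(bundle@pca)) {
        pc <- structure(bundle@pca, class = "PCFeatures")
        X <- projectPca(pc, X)
    }
    Xs <- .prep_predict(bundle, X)
    stats::setNames(.linear_scores(bundle@fit, Xs), rownames(X))
}

#' Out-of-fold cross-validated scores
#'
#' Stratified k-fold refitting of \code{\link{trainBinary}} (including any
#' per-fold PCA) so that every training sample receives a score from a
#' model that never saw it.  These are the inputs the score-fusion stage
#' expects for its training samples.
#'
#' @inheritParams trainBinary
#' @param k number of folds.
#' @param use_pca fit a per-fold PCA (fragmentation) before the model.
#' @param var_frac PCA cumulative-variance target.
#' @return named numeric vector of OOF scores (rownames of \code{X}).
#' @export
oofScores <- function(X, labels, kind = "logistic", k = 5L, seed = 1L,
                      use_pca = FALSE, var_frac = 0.98) {
    y <- .binary_y(labels)
    fold <- .stratifiedFolds(y, k, seed)
    out <- stats::setNames(rep(NA_real_, nrow(X)), rownames(X))
    for (f in seq_len(k)) {
        tr <- fold != f
        pca <- if (use_pca)
            suppressWarnings(pcaFeatures(X[tr, , drop = FALSE], var_frac))
        else NULL
        b <- trainBinary(X[tr, , drop = FALSE], y[tr], kind = kind,
                         seed = seed + f, pca = pca)
        out[!tr] <- predictScore(b, X[!tr, , drop = FALSE])
    }
    out
}

#' Late fusion of modality scores (EMCED stacking)
#'
#' Fits a logistic stacking model over the per-sample scores of the
#' available modalities (entropy, URA/methylation, fragmentation).  For
#' training samples the supplied scores must be out-of-fold
#' (\code{\link{oofScores}}) to avoid leakage.  A missing (NULL) modality
#' degrades the stack gracefully to the remaining ones; an all-constant
#' score vector carries no weight.
#'
#' @param e_scores,m_scores,f_scores named per-sample score vectors on a
#'   common sample set (NULL to omit a modality).
#' @param labels sample labels aligned with the score names.
#' @param seed integer seed.
#' @return a \linkS4class{ModelBundle} with modality "fusion"; its feature
#'   names are the modality score columns.
#' @export
fuseEmced <- function(e_scores, m_scores = NULL, f_scores = NULL,
                      labels, seed = 1L) {
    mods <- list(entropy = e_scores, ura = m_scores,
                 fragmentation = f_scores)
    mods <- mods[!vapply(mods, is.null, logical(1))]
    ids <- names(mods[[1]])
    for (m in mods)
        if (!identical(sort(names(m)), sort(ids)))
            stop("misaligned sample ids across modality scores")
    S <- do.call(cbind, lapply(mods, function(m) m[ids]))
    colnames(S) <- names(mods)
    rownames(S) <- ids
    trainBinary(S, labels, kind = "logistic", modality = "fusion",
                seed = seed)
}

## ---- evaluation -----------------------------------------------------------

.clopper_pearson <- function(x, n, conf = 0.95) {
    a <- (1 - conf) / 2
    lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
    c(lo, hi)
}

.auc_rank <- function(scores, y) {
    r <- rank(scores)   # ties averaged
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate binary scores against labels
#'
#' AUC by the rank statistic (ties averaged), sensitivity/specificity at
#' the threshold with Clopper-Pearson 95\% CIs, and the confusion matrix.
#' A sample is called positive when its score is >= the threshold.
#'
#' @param scores named numeric score vector.
#' @param labels sample labels aligned with \code{scores}.
#' @param threshold decision cutoff.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(scores, labels, threshold = 0.5) {
    y <- .binary_y(labels)
    if (length(unique(y)) < 2L)
        stop("AUC undefined: test labels contain a single class")
    auc <- .auc_rank(scores, y)
    pred <- as.integer(scores >= threshold)
    tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
    tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
    cm <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(c("predicted_positive", "predicted_negative"),
                                 c("positive", "negative")))
    new("EvalReport", auc = auc,
        sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
        sens_ci = .clopper_pearson(tp, tp + fn),
        spec_ci = .clopper_pearson(tn, tn + fp),
        confusion = cm, threshold = threshold, extras = list())
}

#' Evaluate tissue-of-origin predictions
#'
#' TOP1 accuracy counts the true type ranked first; TOP2 counts it within
#' the two highest fused probabilities.  Ties in the ranking are broken by
#' the fixed alphabetical type order.
#'
#' @param prob matrix of per-sample type probabilities (samples x types).
#' @param true_types character vector of true types.
#' @return an \linkS4class{EvalReport} whose \code{extras} carry
#'   \code{top1_accuracy}, \code{top2_accuracy} and the per-type confusion
#'   matrix.
#' @export
evaluateToo <- function(prob, true_types) {
    stopifnot(nrow(prob) == length(true_types))
    ord <- apply(prob, 1, function(p)
        colnames(prob)[order(-p, colnames(prob))], simplify = FALSE)
    top1 <- vapply(ord, `[`, character(1), 1L)
    top2 <- vapply(ord, `[`, character(1), 2L)
    acc1 <- mean(top1 == true_types)
    acc2 <- mean(top1 == true_types | top2 == true_types)
    cm <- table(predicted = factor(top1, levels = colnames(prob)),
                truth = factor(true_types, levels = colnames(prob)))
    new("EvalReport", auc = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, sens_ci = c(NA_real_, NA_real_),
        spec_ci = c(NA_real_, NA_real_),
        confusion = matrix(numeric(0), 0, 0), threshold = NA_real_,
        extras = list(top1_accuracy = acc1, top2_accuracy = acc2,
                      type_confusion = unclass(cm)))
}

#' Stratified k-fold cross-validation of a binary model
#'
#' @inheritParams trainBinary
#' @param k number of folds; every class must have at least k members.
#' @return list with \code{fold} (assignment vector), \code{fold_auc},
#'   \code{pooled_auc} and \code{oof_scores}.
#' @export
crossValidate <- function(X, labels, k = 5L, seed = 1L, kind = "logistic",
                          use_pca = FALSE) {
    y <- .binary_y(labels)
    if (any(table(y) < k))
        stop("each class needs at least k samples for k-fold CV")
    fold <- .stratifiedFolds(y, k, seed)
    oof <- stats::setNames(rep(NA_real_, nrow(X)), rownames(X))
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
        tr <- fold != f
        pca <- if (use_pca)
            suppressWarnings(pcaFeatures(X[tr, , drop = FALSE])) else NULL
        b <- trainBinary(X[tr, , drop = FALSE], y[tr], kind = kind,
                         seed = seed + f, pca = pca)
        sc <- predictScore(b, X[!tr, , drop = FALSE])
        oof[!tr] <- sc
        fold_auc[f] <- .auc_rank(sc, y[!tr])
    }
    list(fold = fold, fold_auc = fold_auc,
         pooled_auc = .auc_rank(oof, y), oof_scores = oof)
}
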