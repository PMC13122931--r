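## one-vs-rest logistic probabilities for the entropy TOO block; the sex
## covariate enters only the ovarian-vs-rest model
.fit_ovr_logistic <- function(Xs, types, sex_num) {
    lev <- levels(types)
    fits <- lapply(lev, function(tp) {
        XX <- if (tp == "ovarian") cbind(Xs, .sex = sex_num) else Xs
        y <- as.integer(types == tp)
        fit <- suppressWarnings(
            stats::glm.fit(cbind(1, XX), y, family = stats::binomial()))
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        cf
    })
    stats::setNames(fits, lev)
}

.predict_ovr_logistic <- function(fits, Xs, sex_num) {
    p <- sapply(names(fits), function(tp) {
        XX <- if (tp == "ovarian") cbind(Xs, .sex = sex_num) else Xs
        stats::plogis(drop(cbind(1, XX) %*% fits[[tp]]))
    })
    p <- matrix(p, nrow = nrow(Xs), dimnames = list(rownames(Xs), names(fits)))
    p / rowSums(p)
}

#' Train the tissue-of-origin classifiers
#'
#' Fits one multiclass probability model per modality on cancer training
#' samples: one-vs-rest logistic regression on the entropy markers (the
#' sex covariate enters the ovarian-vs-rest model), multinomial elastic
#' net on the URA markers plus sex, and multinomial elastic net on the
#' top-98\%-variance principal components of the fragmentation features
#' plus sex.  Any modality block may be NULL and is then skipped.
#'
#' @param blocks named list with elements \code{entropy}, \code{ura}
#'   (samples x marker matrices) and \code{fragmentation} (samples x raw
#'   fragmentation features); NULL entries are skipped.
#' @param types character vector of cancer types (all seven must appear).
#' @param sex character vector "male"/"female" aligned with the samples.
#' @param seed integer seed.
#' @param var_frac PCA cumulative-variance target for fragmentation.
#' @return object of class \code{TooModel}.
#' @export
trainToo <- function(blocks, types, sex, seed = 1L, var_frac = 0.98) {
    types <- factor(types, levels = CANCER_TYPES)
    if (anyNA(types)) stop("unknown cancer type in labels")
    missing_types <- CANCER_TYPES[!CANCER_TYPES %in% types]
    if (length(missing_types))
        stop("cancer type(s) absent from training data: ",
             paste(missing_types, collapse = ", "))
    sex_num <- as.numeric(sex == "female")
    model <- list(types = CANCER_TYPES, seed = as.integer(seed),
                  modalities = list())
    if (!is.null(blocks$entropy)) {
        prep <- .prep_fit(blocks$entropy)
        model$modalities$entropy <- list(
            kind = "ovr_logistic", features = colnames(blocks$entropy),
            prep = prep[c("imputation", "center", "scale")],
            fits = .fit_ovr_logistic(prep$X, types, sex_num))
    }
    if (!is.null(blocks$ura)) {
        prep <- .prep_fit(blocks$ura)
        set.seed(as.integer(seed))
        fit <- glmnet::cv.glmnet(cbind(prep$X, .sex = sex_num), types,
                                 family = "multinomial", alpha = 0.5,
                                 nfolds = 5L, standardize = FALSE)
        model$modalities$ura <- list(
            kind = "multinomial_enet", features = colnames(blocks$ura),
            prep = prep[c("imputation", "center", "scale")], fit = fit)
    }
    if (!is.null(blocks$fragmentation)) {
        pca <- suppressWarnings(pcaFeatures(blocks$fragmentation, var_frac))
        pcs <- pca$scores
        prep <- .prep_fit(pcs)
        set.seed(as.integer(seed) + 1L)
        fit <- glmnet::cv.glmnet(cbind(prep$X, .sex = sex_num), types,
                                 family = "multinomial", alpha = 0.5,
                                 nfolds = 5L, standardize = FALSE)
        model$modalities$fragmentation <- list(
            kind = "multinomial_enet", features = colnames(pcs),
            prep = prep[c("imputation", "center", "scale")],
            pca = unclass(pca), fit = fit)
    }
    structure(model, class = "TooModel")
}

.too_block_prob <- function(mod, X, sex_num) {
    if (!is.null(mod$pca))
        X <- projectPca(structure(mod$pca, class = "PCFeatures"), X)
    miss <- setdiff(mod$features, colnames(X))
    if (length(miss))
        stop("missing feature column(s): ", paste(head(miss, 3), collapse = ", "))
    X <- X[, mod$features, drop = FALSE]
    X <- .impute_median(X, mod$prep$imputation)$X
    Xs <- sweep(sweep(X, 2, mod$prep$center), 2, mod$prep$scale, "/")
    if (mod$kind == "ovr_logistic") {
        .predict_ovr_logistic(mod$fits, Xs, sex_num)
    } else {
        p <- stats::predict(mod$fit, newx = cbind(Xs, .sex = sex_num),
                            s = "lambda.min", type = "response")[, , 1]
        p <- matrix(p, nrow = nrow(Xs),
                    dimnames = list(rownames(Xs), colnames(p)))
        p[, CANCER_TYPES, drop = FALSE]
    }
}

#' Predict tissue of origin
#'
#' Computes per-modality 7-class probability vectors, fuses the requested
#' modalities by arithmetic mean followed by renormalisation, and ranks
#' types by fused probability (ties broken by the fixed alphabetical type
#' order).
#'
#' @param model a \code{TooModel} from \code{\link{trainToo}}.
#' @param blocks named list of sample blocks matching the trained
#'   modalities (raw fragmentation features where a PCA is embedded).
#' @param sex character vector "male"/"female" per sample.
#' @param fusion which modalities to fuse: "e_m_f" (all available), "e_m",
#'   or "entropy_only".
#' @return list with \code{prob} (samples x types, rows sum to 1),
#'   \code{top1} and \code{top2} character vectors.
#' @export
predictToo <- function(model, blocks, sex,
                       fusion = c("e_m_f", "e_m", "entropy_only")) {
    fusion <- match.arg(fusion)
    use <- switch(fusion,
                  entropy_only = "entropy",
                  e_m = c("entropy", "ura"),
                  e_m_f = c("entropy", "ura", "fragmentation"))
    use <- intersect(use, names(model$modalities))
    if (!length(use)) stop("requested modalities are not available")
    sex_num <- as.numeric(sex == "female")
    probs <- lapply(use, function(m)
        .too_block_prob(model$modalities[[m]], blocks[[m]], sex_num))
    p <- Reduce(`+`, probs) / length(probs)
    p <- p / rowSums(p)
    ord <- apply(p, 1, function(pr)
        colnames(p)[order(-pr, colnames(p))], simplify = FALSE)
    list(prob = p,
         top1 = vapply(ord, `[`, character(1), 1L),
         top2 = vapply(ord, `[`, character(1), 2L))
}
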