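#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges IntegerList
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
NULL

#' MethBin regions
#'
#' Genomic intervals obtained by merging CpG clusters that lie less than
#' \code{merge_gap} (default 400 bp) apart and keeping only clusters with at
#' least \code{min_cpg} (default 3) CpG sites.  These intervals are the
#' feature unit for methylation entropy and U-reads abundance.  The class
#' extends \linkS4class{GRanges}; each range carries its member CpG
#' coordinates in \code{mcols()$cpg_positions} (an \code{IntegerList}) and a
#' stable \code{region_id}.
#'
#' @slot .  inherits all \code{GRanges} slots.
#' @seealso \code{\link{buildSegments}}, \code{\link{assignFragments}}
#' @export
setClass("MethBinRegions", contains = "GRanges")

setValidity("MethBinRegions", function(object) {
    mc <- mcols(object)
    if (!all(c("region_id", "cpg_positions") %in% colnames(mc)))
        return("mcols must contain 'region_id' and 'cpg_positions'")
    if (anyDuplicated(mc$region_id))
        return("region_id values must be unique")
    ncpg <- lengths(mc$cpg_positions)
    if (length(object) && any(ncpg < 3L))
        return("every region must contain at least 3 CpG sites")
    for (i in seq_along(object)) {
        p <- mc$cpg_positions[[i]]
        if (is.unsorted(p, strictly = TRUE))
            return("cpg_positions must be strictly increasing within a region")
        # 0-based half-open: positions live in [start-1, end-1) of the 1-based range
        if (p[1L] < start(object)[i] - 1L || p[length(p)] >= end(object)[i])
            return("cpg_positions must lie within [start, end)")
    }
    TRUE
})

#' Samples-by-regions feature matrix
#'
#' A \linkS4class{SummarizedExperiment} with regions as rows and samples as
#' columns, carrying two parallel assays: \code{values} (methylation entropy
#' or URA per region per sample; \code{NA} where unobserved) and
#' \code{depths} (effective read counts, non-negative integers).  Missing
#' values are always explicit \code{NA}, never 0.
#'
#' @seealso \code{\link{entropyMatrix}}, \code{\link{uraMatrix}},
#'   \code{\link{featureValues}}, \code{\link{featureDepths}}
#' @export
setClass("RegionMatrix", contains = "SummarizedExperiment")

setValidity("RegionMatrix", function(object) {
    an <- assayNames(object)
    if (!all(c("values", "depths") %in% an))
        return("assays 'values' and 'depths' are required")
    d <- assay(object, "depths")
    if (any(!is.na(d) & d < 0))
        return("depths must be non-negative")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        return("region (row) and sample (column) names are required")
    TRUE
})

#' Fitted classifier bundle
#'
#' Self-contained description of one fitted model: the feature set it was
#' trained on, per-feature imputation medians and standardisation parameters
#' estimated on the training split, the fitted coefficients, the decision
#' threshold, and the seed.  Predicting with a bundle never refits anything.
#'
#' @slot kind "logistic" or "elastic_net".
#' @slot modality one of "entropy", "ura", "fragmentation", "fusion", "too".
#' @slot features character vector of feature ids (or PC names).
#' @slot fit the fitted model object (glm coefficients or glmnet fit).
#' @slot imputation named numeric, training medians per feature.
#' @slot center,scale named numerics for standardisation.
#' @slot pca list with rotation/center/scale when the bundle projects raw
#'   fragmentation features onto stored principal components, else empty.
#' @slot threshold decision cutoff on the score scale.
#' @slot seed integer seed used during fitting.
#' @slot meta free-form list (training score range, class levels, ...).
#' @export
setClass("ModelBundle", representation(
    kind = "character", modality = "character", features = "character",
    fit = "ANY", imputation = "numeric", center = "numeric",
    scale = "numeric", pca = "list", threshold = "numeric",
    seed = "integer", meta = "list"))

setValidity("ModelBundle", function(object) {
    if (!object@kind %in% c("logistic", "elastic_net"))
        return("kind must be 'logistic' or 'elastic_net'")
    if (!object@modality %in% c("entropy", "ura", "fragmentation", "fusion", "too"))
        return("unknown modality")
    TRUE
})

#' Evaluation report
#'
#' Classification metrics for a score vector against labels: AUC (rank
#' statistic, ties averaged), sensitivity and specificity at the decision
#' threshold with Clopper-Pearson 95\% CIs, and the confusion matrix.  For
#' tissue-of-origin rankings the \code{extras} list carries TOP1/TOP2
#' accuracies and the per-type confusion matrix.
#'
#' @export
setClass("EvalReport", representation(
    auc = "numeric", sensitivity = "numeric", specificity = "numeric",
    sens_ci = "numeric", spec_ci = "numeric", confusion = "matrix",
    threshold = "numeric", extras = "list"))

setValidity("EvalReport", function(object) {
    cm <- object@confusion
    if (length(cm)) {
        tp <- cm["predicted_positive", "positive"]
        fn <- cm["predicted_negative", "positive"]
        tn <- cm["predicted_negative", "negative"]
        fp <- cm["predicted_positive", "negative"]
        if (tp + fn > 0 &&
            abs(object@sensitivity - tp / (tp + fn)) > 1e-9)
            return("sensitivity inconsistent with confusion matrix")
        if (tn + fp > 0 &&
            abs(object@specificity - tn / (tn + fp)) > 1e-9)
            return("specificity inconsistent with confusion matrix")
    }
    TRUE
})

#' Stage cohort for the interception simulator
#'
#' Per-stage (I-IV) original counts, cumulative and marginal screening
#' sensitivities, the screening schedule, and - after
#' \code{\link{runInterception}} - the detectable, intercepted and slipped
#' tallies plus the final stage-at-diagnosis distribution.
#'
#' @export
setClass("StageCohort", representation(
    stages = "character", original = "numeric", cumulative = "numeric",
    marginal = "numeric", screened = "logical", detectable = "numeric",
    intercepted = "numeric", slipped = "numeric", final = "numeric",
    variant = "character"))

setValidity("StageCohort", function(object) {
    if (!identical(object@stages, c("I", "II", "III", "IV")))
        return("stages must be I, II, III, IV in order")
    if (any(object@original < 0)) return("original counts must be non-negative")
    cu <- object@cumulative
    if (any(cu < 0 | cu > 1)) return("cumulative sensitivities must be in [0,1]")
    if (is.unsorted(cu)) return("cumulative sensitivities must be non-decreasing")
    m <- object@marginal
    if (max(abs(m - diff(c(0, cu)))) > 1e-9)
        return("marginal sensitivities inconsistent with cumulative")
    TRUE
})

#' Synthetic cfDNA cohort
#'
#' Output of \code{\link{simulateCohort}}: epiread table, fragment table,
#' label sheet, the MethBin regions the reads were generated in, the truth
#' set of planted informative regions, and the generating configuration.
#'
#' @export
setClass("SyntheticCohort", representation(
    epireads = "data.frame", fragments = "data.frame", labels = "data.frame",
    regions = "MethBinRegions", truth = "list", config = "list"))
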