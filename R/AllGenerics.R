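#' @rdname RegionMatrix-class
#' @param x a \linkS4class{RegionMatrix}
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname RegionMatrix-class
#' @export
setGeneric("featureDepths", function(x) standardGeneric("featureDepths"))

#' @rdname RegionMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname RegionMatrix-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Values assay (regions x samples)
#' @rdname RegionMatrix-class
#' @export
setMethod("featureValues", "RegionMatrix", function(x) assay(x, "values"))

#' @rdname RegionMatrix-class
#' @export
setMethod("featureDepths", "RegionMatrix", function(x) assay(x, "depths"))

#' @rdname RegionMatrix-class
#' @export
setMethod("sampleIds", "RegionMatrix", function(x) colnames(x))

#' @rdname RegionMatrix-class
#' @export
setMethod("regionIds", "RegionMatrix", function(x) rownames(x))

#' @rdname MethBinRegions-class
#' @param x a \linkS4class{MethBinRegions}
#' @export
setMethod("regionIds", "MethBinRegions", function(x) mcols(x)$region_id)

#' CpG positions per region (0-based)
#' @rdname MethBinRegions-class
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname MethBinRegions-class
#' @export
setMethod("cpgPositions", "MethBinRegions", function(x) mcols(x)$cpg_positions)

setMethod("show", "MethBinRegions", function(object) {
    cat("MethBinRegions with", length(object), "regions,",
        sum(lengths(cpgPositions(object))), "CpG sites\n")
    callNextMethod()
})

setMethod("show", "RegionMatrix", function(object) {
    v <- featureValues(object)
    cat("RegionMatrix:", nrow(object), "regions x", ncol(object), "samples;",
        sprintf("%.1f%% NA\n", 100 * mean(is.na(v))))
})

setMethod("show", "ModelBundle", function(object) {
    cat("ModelBundle<", object@kind, "/", object@modality, "> ",
        length(object@features), " features, threshold ",
        signif(object@threshold, 4), "\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport: AUC %.3f, sens %.3f (%.3f-%.3f), spec %.3f (%.3f-%.3f)\n",
                object@auc, object@sensitivity, object@sens_ci[1], object@sens_ci[2],
                object@specificity, object@spec_ci[1], object@spec_ci[2]))
    if (length(object@extras))
        cat("  extras:", paste(names(object@extras), collapse = ", "), "\n")
})

setMethod("show", "StageCohort", function(object) {
    cat("StageCohort (variant:", object@variant, ")\n")
    print(data.frame(stage = object@stages, original = object@original,
                     cumulative = object@cumulative, marginal = object@marginal,
                     intercepted = object@intercepted, slipped = object@slipped))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", nrow(object@labels), "samples,",
        length(object@regions), "regions,", nrow(object@epireads), "epireads,",
        nrow(object@fragments), "fragments\n")
})

#' Accessors for SyntheticCohort
#' @rdname SyntheticCohort-class
#' @param x a \linkS4class{SyntheticCohort}
#' @export
setGeneric("epireads", function(x) standardGeneric("epireads"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("epireads", "SyntheticCohort", function(x) x@epireads)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("fragmentRecords", function(x) standardGeneric("fragmentRecords"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("fragmentRecords", "SyntheticCohort", function(x) x@fragments)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("labelSheet", function(x) standardGeneric("labelSheet"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("labelSheet", "SyntheticCohort", function(x) x@labels)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("truthSet", "SyntheticCohort", function(x) x@truth)
#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortRegions", function(x) standardGeneric("cohortRegions"))
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortRegions", "SyntheticCohort", function(x) x@regions)
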