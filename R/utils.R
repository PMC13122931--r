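CANCER_TYPES <- c("colorectal", "esophageal", "gastric", "liver",
                  "lung", "ovarian", "thyroid")

#' Construct a RegionMatrix
#'
#' @param values numeric matrix, regions x samples (NA allowed).
#' @param depths integer matrix of effective read counts, same dimensions.
#' @return a \linkS4class{RegionMatrix}
#' @export
RegionMatrix <- function(values, depths) {
    stopifnot(identical(dim(values), dim(depths)))
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("values must carry region rownames and sample colnames")
    dimnames(depths) <- dimnames(values)
    new("RegionMatrix", SummarizedExperiment(
        assays = list(values = values, depths = depths)))
}

## stable interaction index used by the matrix builders
.grid_index <- function(row_f, col_f) {
    (as.integer(col_f) - 1L) * nlevels(row_f) + as.integer(row_f)
}

.assert_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(what, " is missing required column(s): ",
             paste(miss, collapse = ", "))
}

## split "110,205,330" into integer vectors; vectorised
.split_positions <- function(s) {
    lapply(strsplit(s, ",", fixed = TRUE), function(x) as.integer(x))
}

.stop_line <- function(i, field, msg) {
    stop(sprintf("line %d, field '%s': %s", i, field, msg), call. = FALSE)
}
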