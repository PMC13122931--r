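#' Read per-read CpG methylation patterns (epireads)
#'
#' The epiread TSV carries one sequenced bisulfite fragment per line:
#' \code{sample_id}, \code{chrom}, \code{frag_start}, \code{frag_end}
#' (0-based, half-open), \code{cpg_positions} (comma-joined, strictly
#' increasing, within \code{[frag_start, frag_end)}) and \code{calls}, a
#' string over \code{M} (methylated), \code{U} (unmethylated) and \code{.}
#' (missing) with one character per CpG position.
#'
#' Malformed lines are rejected with the line number and offending field;
#' nothing is silently coerced.
#'
#' @param path path to a tab-separated epiread file (no header).
#' @return a data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{frag_start}, \code{frag_end}, \code{cpg_positions} (character,
#'   comma-joined) and \code{calls}.
#' @export
readEpireads <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "character",
                                           "integer", "integer",
                                           "character", "character"),
                            col.names = c("sample_id", "chrom", "frag_start",
                                          "frag_end", "cpg_positions", "calls"),
                            quote = "", comment.char = "")
    validateEpireads(df)
    df
}

#' Validate an epiread table in place
#' @param df data.frame as returned by \code{readEpireads}.
#' @return invisibly \code{df}
#' @export
validateEpireads <- function(df) {
    .assert_cols(df, c("sample_id", "chrom", "frag_start", "frag_end",
                       "cpg_positions", "calls"), "epiread table")
    bad <- which(is.na(df$frag_start) | is.na(df$frag_end) |
                 df$frag_start >= df$frag_end)
    if (length(bad))
        .stop_line(bad[1], "frag_end", "frag_start must be < frag_end")
    bad <- which(!grepl("^[MU.]+$", df$calls))
    if (length(bad))
        .stop_line(bad[1], "calls", "calls must be a string over {M,U,.}")
    n_pos <- lengths(regmatches(df$cpg_positions,
                                gregexpr(",", df$cpg_positions, fixed = TRUE))) + 1L
    n_call <- nchar(df$calls)
    bad <- which(n_pos != n_call)
    if (length(bad))
        .stop_line(bad[1], "calls",
                   sprintf("%d CpG positions but %d calls",
                           n_pos[bad[1]], n_call[bad[1]]))
    pos <- .split_positions(df$cpg_positions)
    for (i in seq_along(pos)) {
        p <- pos[[i]]
        if (anyNA(p))
            .stop_line(i, "cpg_positions", "non-integer position")
        if (length(p) > 1L && is.unsorted(p, strictly = TRUE))
            .stop_line(i, "cpg_positions", "positions must be strictly increasing")
        if (p[1L] < df$frag_start[i] || p[length(p)] >= df$frag_end[i])
            .stop_line(i, "cpg_positions",
                       "positions must lie within [frag_start, frag_end)")
    }
    invisible(df)
}

#' Write an epiread table
#' @param df epiread data.frame (validated before writing).
#' @param path output path.
#' @export
writeEpireads <- function(df, path) {
    validateEpireads(df)
    utils::write.table(
        df[, c("sample_id", "chrom", "frag_start", "frag_end",
               "cpg_positions", "calls")],
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read cfDNA fragment records from a BED3+name file
#'
#' BED conventions: 0-based, half-open.  Column 4 is the sample id.
#' Fragment length is computed as \code{end - start}.
#'
#' @param path BED file path.
#' @return data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{length}.
#' @export
readFragments <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "integer",
                                           "integer", "character"),
                            col.names = c("chrom", "start", "end", "sample_id"),
                            quote = "", comment.char = "#")
    bad <- which(df$end <= df$start)
    if (length(bad))
        .stop_line(bad[1], "end", "fragment end must exceed start")
    data.frame(sample_id = df$sample_id, chrom = df$chrom,
               start = df$start, end = df$end,
               length = df$end - df$start)
}

#' Write fragment records as BED3+name
#' @param df data.frame with sample_id, chrom, start, end.
#' @param path output path.
#' @export
writeFragments <- function(df, path) {
    .assert_cols(df, c("sample_id", "chrom", "start", "end"), "fragment table")
    if (any(df$end <= df$start)) stop("fragment end must exceed start")
    utils::write.table(df[, c("chrom", "start", "end", "sample_id")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read a sample label sheet
#'
#' TSV with header; columns \code{sample_id}, \code{group} (cancer /
#' non_cancer), \code{cancer_type} (one of the seven study types, or empty
#' for non-cancer), \code{sex} (male / female), \code{stage} (I-IV or
#' unknown, may be empty) and \code{split} (train / test).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readLabels <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "", na.strings = NULL)
    validateLabels(df)
}

#' @rdname readLabels
#' @param df label data.frame to validate.
#' @export
validateLabels <- function(df) {
    .assert_cols(df, c("sample_id", "group", "sex", "split"), "label sheet")
    if (!"cancer_type" %in% names(df)) df$cancer_type <- ""
    if (!"stage" %in% names(df)) df$stage <- ""
    df$cancer_type[is.na(df$cancer_type)] <- ""
    df$stage[is.na(df$stage)] <- ""
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id: ",
             df$sample_id[duplicated(df$sample_id)][1])
    if (!all(df$group %in% c("cancer", "non_cancer")))
        stop("group must be 'cancer' or 'non_cancer'")
    if (!all(df$sex %in% c("male", "female")))
        stop("sex must be 'male' or 'female'")
    if (!all(df$split %in% c("train", "test")))
        stop("split must be 'train' or 'test'")
    bad_type <- df$cancer_type != "" & !df$cancer_type %in% CANCER_TYPES
    if (any(bad_type))
        stop("unknown cancer_type token: ", df$cancer_type[bad_type][1])
    if (any(df$group == "cancer" & df$cancer_type == ""))
        stop("cancer samples must carry a cancer_type")
    if (any(df$group == "non_cancer" & df$cancer_type != ""))
        stop("non-cancer samples must not carry a cancer_type")
    if (!all(df$stage %in% c("", "I", "II", "III", "IV", "unknown")))
        stop("stage must be I, II, III, IV or unknown")
    df
}

#' @rdname readLabels
#' @export
writeLabels <- function(df, path) {
    validateLabels(df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read / write a region feature matrix
#'
#' On disk a feature matrix is a pair of TSV files: \code{path} holds the
#' values (sample rows x region columns, first column \code{sample_id},
#' missing cells written as the literal token \code{NA}) and a sibling file
#' \code{<path>.depths.tsv} holds the effective read counts on the same
#' grid.  Values round-trip at full double precision; missingness is
#' preserved exactly.
#'
#' @param x a \linkS4class{RegionMatrix}.
#' @param path path of the values TSV.
#' @return \code{readFeatureMatrix} returns a \linkS4class{RegionMatrix}.
#' @export
writeFeatureMatrix <- function(x, path) {
    stopifnot(is(x, "RegionMatrix"))
    .write_grid <- function(m, p, fmt) {
        tab <- t(m)   # samples x regions on disk
        out <- cbind(sample_id = rownames(tab),
                     as.data.frame(apply(tab, 2, function(col)
                         ifelse(is.na(col), "NA", sprintf(fmt, col)))))
        colnames(out) <- c("sample_id", colnames(tab))
        utils::write.table(out, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    }
    .write_grid(featureValues(x), path, "%.17g")
    .write_grid(featureDepths(x), paste0(path, ".depths.tsv"), "%d")
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
    .read_grid <- function(p, as_int = FALSE) {
        tab <- utils::read.table(p, sep = "\t", header = TRUE,
                                 check.names = FALSE, quote = "",
                                 na.strings = "NA",
                                 colClasses = "character")
        ids <- tab$sample_id
        m <- as.matrix(tab[, -1, drop = FALSE])
        storage.mode(m) <- if (as_int) "integer" else "double"
        rownames(m) <- ids
        t(m)    # back to regions x samples
    }
    v <- .read_grid(path)
    dpath <- paste0(path, ".depths.tsv")
    if (!file.exists(dpath))
        stop("depths file not found: ", dpath)
    d <- .read_grid(dpath, as_int = TRUE)
    stopifnot(identical(dimnames(v), dimnames(d)))
    RegionMatrix(v, d)
}

.BUNDLE_FORMAT <- "cfEntropy-model-bundle-1"

#' Serialize / restore a fitted model bundle
#'
#' A bundle is written as a single portable file with an embedded format
#' version tag; reading verifies the tag.
#'
#' @param bundle a \linkS4class{ModelBundle} (or list of them).
#' @param path file path.
#' @export
writeModelBundle <- function(bundle, path) {
    saveRDS(list(format = .BUNDLE_FORMAT, bundle = bundle), path)
    invisible(path)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
    obj <- readRDS(path)
    if (!is.list(obj) || !identical(obj$format, .BUNDLE_FORMAT))
        stop("not a cfEntropy model bundle (missing/unknown format tag)")
    obj$bundle
}
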