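#' Classify reads by methylation fraction
#'
#' Missing calls ('.') are excluded from both counts; reads with fewer than
#' \code{min_cpg} (default 4) observed CpG calls are rejected.  For the
#' rest, u = C / (C + T) with C methylated and T unmethylated calls, and
#' the class is U (mostly unmethylated) when u <= 1/4, M (mostly
#' methylated) when u >= 3/4, X (mixed) otherwise; both boundaries are
#' inclusive.
#'
#' @param calls character vector of call strings over \{M, U, .\}.
#' @param min_cpg minimum observed CpG calls to retain a read.
#' @return data.frame with columns \code{C}, \code{T}, \code{u},
#'   \code{klass} (factor U/X/M, NA when rejected) and \code{retained}.
#' @export
classifyReads <- function(calls, min_cpg = 4L) {
    C <- nchar(calls) - nchar(gsub("M", "", calls, fixed = TRUE)) # nolint
    C <- nchar(gsub("[^M]", "", calls))
    T_ <- nchar(gsub("[^U]", "", calls))
    tot <- C + T_
    retained <- tot >= min_cpg
    u <- ifelse(retained, C / tot, NA_real_)
    klass <- rep(NA_character_, length(calls))
    klass[retained & u <= 1 / 4] <- "U"
    klass[retained & u >= 3 / 4] <- "M"
    klass[retained & u > 1 / 4 & u < 3 / 4] <- "X"
    data.frame(C = C, T = T_, u = u,
               klass = factor(klass, levels = c("U", "X", "M")),
               retained = retained)
}

#' Per-region U-reads abundance
#'
#' URA = U / (U + X + M), defined only when the effective read count
#' U + X + M reaches \code{min_reads} (default 50); otherwise missing.
#'
#' @param U,X,M class counts for one (sample, region) pair.
#' @param min_reads minimum effective reads for a defined URA.
#' @return list with \code{ura} (NA when under-covered), \code{U},
#'   \code{X}, \code{M} and \code{depth} = U + X + M.
#' @export
regionUra <- function(U, X, M, min_reads = 50L) {
    stopifnot(U >= 0, X >= 0, M >= 0)
    depth <- U + X + M
    list(ura = if (depth >= min_reads) U / depth else NA_real_,
         U = U, X = X, M = M, depth = depth)
}

#' Per-sample, per-region URA matrix
#'
#' Classifies reads (>= 4 observed CpGs) and tallies U/X/M per (sample,
#' region).  The value is U/(U+X+M) where the effective read count reaches
#' \code{min_reads}, NA elsewhere; depths always carry U+X+M.
#'
#' @inheritParams entropyMatrix
#' @param min_reads minimum effective reads for a defined URA.
#' @return a \linkS4class{RegionMatrix}
#' @export
uraMatrix <- function(reads, regions, samples = NULL, min_reads = 50L) {
    fr <- .matrix_frame(reads, regions, samples)
    keep <- fr$keep
    cls <- classifyReads(reads$calls[keep])
    sel <- which(keep)[cls$retained]
    if (!length(sel))
        return(.assemble_matrix(numeric(0), integer(0), fr))
    is_u <- as.integer(cls$klass[cls$retained] == "U")
    region_f <- factor(fr$rid[sel], levels = fr$region_levels)
    sample_f <- factor(reads$sample_id[sel], levels = fr$sample_levels)
    idx <- .grid_index(region_f, sample_f)
    u_cnt <- rowsum(is_u, idx)
    tot <- rowsum(rep(1L, length(is_u)), idx)
    vals <- ifelse(tot[, 1] >= min_reads, u_cnt[, 1] / tot[, 1], NA_real_)
    names(vals) <- rownames(tot)
    .assemble_matrix(vals, as.integer(tot[, 1]), fr)
}
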