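## binary Shannon entropy with the 0*log0 := 0 convention, vectorised
.H <- function(p) {
    out <- numeric(length(p))
    ok <- p > 0 & p < 1
    q <- p[ok]
    out[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
    out
}

#' Binary derivative of a bit sequence
#'
#' The k-th binary derivative underlies the BiEntropy recurrence: the first
#' derivative is the XOR of each bit with its successor; higher derivatives
#' iterate the construction.
#'
#' @param bits integer/logical vector of 0s and 1s, length >= 2.
#' @return integer vector of length \code{length(bits) - 1}.
#' @export
binaryDerivative <- function(bits) {
    bits <- as.integer(bits)
    n <- length(bits)
    if (n < 2L) stop("binary derivative requires at least 2 bits")
    if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
    as.integer(xor(bits[-n], bits[-1L]))
}

#' BiEntropy of a binary methylation pattern
#'
#' For a pattern s of n CpG calls (1 = methylated, 0 = unmethylated) let
#' p(k) be the proportion of ones in the k-th binary derivative of s (k = 0
#' is s itself).  Then
#' \deqn{BiEn(s) = \frac{1}{2^{n-1}-1} \sum_{k=0}^{n-2} H(p(k))\, 2^k}
#' with H the binary Shannon entropy and 0 log 0 := 0.  The weighting makes
#' periodic, highly ordered patterns score near 0 and genuinely disordered
#' ones near 1; a constant pattern scores exactly 0.
#'
#' @param bits 0/1 vector (length >= 2), or a character string like
#'   \code{"111100"}.
#' @return entropy in [0, 1].
#' @examples
#' bien("111100")   # 0.4422
#' bien("111111")   # 0
#' @export
bien <- function(bits) {
    if (is.character(bits)) {
        stopifnot(length(bits) == 1L)
        bits <- as.integer(strsplit(bits, "")[[1]])
    }
    bits <- as.integer(bits)
    n <- length(bits)
    if (n < 2L) stop("BiEn requires at least 2 CpG sites")
    if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
    acc <- 0
    x <- bits
    for (k in 0:(n - 2L)) {
        acc <- acc + .H(mean(x)) * 2^k
        if (length(x) > 1L) x <- as.integer(xor(x[-length(x)], x[-1L]))
    }
    acc / (2^(n - 1L) - 1)
}

## BiEn for many patterns at once.  `patterns` is a character vector of
## equal-length 0/1 strings; evaluated column-wise on a bit matrix so the
## per-read cost is a handful of matrix operations.
.bien_group <- function(patterns) {
    n <- nchar(patterns[1L])
    M <- matrix(as.integer(unlist(strsplit(patterns, "")) == "1"),
                nrow = length(patterns), ncol = n, byrow = TRUE)
    acc <- numeric(nrow(M))
    for (k in 0:(n - 2L)) {
        acc <- acc + .H(rowMeans(M)) * 2^k
        if (ncol(M) > 1L)
            M <- abs(M[, -ncol(M), drop = FALSE] - M[, -1L, drop = FALSE])
    }
    acc / (2^(n - 1L) - 1)
}

#' BiEntropy for a vector of pattern strings
#'
#' Vectorised convenience wrapper: deduplicates patterns, groups them by
#' length and evaluates \code{\link{bien}} via matrix recurrences.
#'
#' @param patterns character vector of 0/1 strings, each of length >= 2.
#' @return numeric vector of entropies, one per input pattern.
#' @export
bienVector <- function(patterns) {
    if (!length(patterns)) return(numeric(0))
    u <- unique(patterns)
    if (any(nchar(u) < 2L)) stop("BiEn requires at least 2 CpG sites")
    e_u <- numeric(length(u))
    for (n in unique(nchar(u))) {
        idx <- which(nchar(u) == n)
        e_u[idx] <- .bien_group(u[idx])
    }
    e_u[match(patterns, u)]
}

#' Filter inserted fragments for entropy analysis
#'
#' A fragment qualifies when, after trimming leading/trailing missing calls
#' ('.'), it has between \code{min_cpg} and \code{max_cpg} CpG calls
#' (defaults 3 and 32) and no missing call strictly inside the trimmed
#' pattern.  Fragments with internal missing calls, too few or too many
#' CpGs are excluded.
#'
#' @param calls character vector of call strings over \{M, U, .\} (already
#'   restricted to the CpGs of the fragment's assigned region).
#' @param min_cpg,max_cpg inclusive bounds on the trimmed CpG count.
#' @return data.frame with columns \code{keep} (logical), \code{pattern}
#'   (0/1 string, NA when dropped) and \code{reason} (one of "ok",
#'   "internal_missing", "too_few_cpgs", "too_many_cpgs").
#' @export
fragmentFilter <- function(calls, min_cpg = 3L, max_cpg = 32L) {
    trimmed <- gsub("^\\.+|\\.+$", "", calls)
    n <- nchar(trimmed)
    internal <- grepl(".", trimmed, fixed = TRUE)
    reason <- rep("ok", length(calls))
    reason[n < min_cpg] <- "too_few_cpgs"
    reason[n > max_cpg] <- "too_many_cpgs"
    reason[internal] <- "internal_missing"
    keep <- reason == "ok"
    pattern <- rep(NA_character_, length(calls))
    pattern[keep] <- chartr("MU", "10", trimmed[keep])
    data.frame(keep = keep, pattern = pattern, reason = reason,
               stringsAsFactors = FALSE)
}

#' Region-level methylation entropy
#'
#' The entropy value of a region is the arithmetic mean of the BiEntropy of
#' its qualified inserted fragments: value = (e1 + ... + eN) / N.  With no
#' qualified fragments the value is missing (NA) and N = 0.
#'
#' @param patterns character vector of 0/1 pattern strings for one
#'   (sample, region) pair, after \code{\link{fragmentFilter}}.
#' @return list with \code{value}, \code{N} and \code{fragment_entropies}.
#' @export
regionEntropy <- function(patterns) {
    if (!length(patterns))
        return(list(value = NA_real_, N = 0L,
                    fragment_entropies = numeric(0)))
    e <- bienVector(patterns)
    list(value = mean(e), N = length(e), fragment_entropies = e)
}

## shared scaffolding for entropy / URA matrices: resolve region assignment
## and the (region x sample) factor grid
.matrix_frame <- function(reads, regions, samples) {
    rid <- if ("region_id" %in% names(reads)) reads$region_id
           else assignFragments(reads, regions)
    region_levels <- regionIds(regions)
    sample_levels <- if (is.null(samples)) sort(unique(reads$sample_id))
                     else as.character(samples)
    extra <- setdiff(unique(reads$sample_id), sample_levels)
    if (length(extra)) {
        warning("samples present in reads but not in the sample sheet: ",
                paste(extra, collapse = ", "), " (retained)")
        sample_levels <- c(sample_levels, extra)
    }
    keep <- !is.na(rid) & rid %in% region_levels
    list(rid = rid, keep = keep,
         region_levels = region_levels, sample_levels = sample_levels)
}

.assemble_matrix <- function(values, counts, frame) {
    nr <- length(frame$region_levels); ns <- length(frame$sample_levels)
    v <- matrix(NA_real_, nr, ns,
                dimnames = list(frame$region_levels, frame$sample_levels))
    d <- matrix(0L, nr, ns,
                dimnames = list(frame$region_levels, frame$sample_levels))
    if (length(values)) {
        idx <- as.integer(names(values))
        v[idx] <- values
        d[idx] <- counts
    }
    RegionMatrix(v, d)
}

#' Per-sample, per-region methylation entropy matrix
#'
#' Assigns reads to regions (using an existing \code{region_id} column when
#' present), applies the 3-32 CpG / internal-missingness fragment filter,
#' and averages BiEntropy per (sample, region).  Unobserved pairs are NA
#' with depth 0.  The result is order-invariant in the read stream.
#'
#' @param reads epiread data.frame.
#' @param regions a \linkS4class{MethBinRegions}.
#' @param samples optional character vector of expected sample ids (e.g.
#'   from the label sheet); reads from unknown samples are retained with a
#'   warning.
#' @return a \linkS4class{RegionMatrix} (assay \code{values} = entropy,
#'   \code{depths} = qualified fragment count N).
#' @export
entropyMatrix <- function(reads, regions, samples = NULL) {
    fr <- .matrix_frame(reads, regions, samples)
    keep <- fr$keep
    filt <- fragmentFilter(reads$calls[keep])
    sel <- which(keep)[filt$keep]
    if (!length(sel))
        return(.assemble_matrix(numeric(0), integer(0), fr))
    e <- bienVector(filt$pattern[filt$keep])
    region_f <- factor(fr$rid[sel], levels = fr$region_levels)
    sample_f <- factor(reads$sample_id[sel], levels = fr$sample_levels)
    idx <- .grid_index(region_f, sample_f)
    sums <- rowsum(e, idx)
    cnts <- rowsum(rep(1L, length(e)), idx)
    vals <- sums[, 1] / cnts[, 1]
    names(vals) <- rownames(sums)
    .assemble_matrix(vals, as.integer(cnts[, 1]), fr)
}
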