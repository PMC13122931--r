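#' Build MethBin regions from CpG positions
#'
#' Merges neighbouring CpG clusters into analysis regions: clusters (or the
#' supplied seed intervals) that are less than \code{merge_gap} bp apart are
#' merged, and merged regions with fewer than \code{min_cpg} CpG sites are
#' dropped.  "Less than \code{merge_gap} apart" is measured end-to-start
#' between neighbouring intervals with strict inequality, so two intervals
#' exactly \code{merge_gap} bp apart stay separate.  Merging is exhaustive
#' and the operation is idempotent: feeding the output intervals back as
#' seeds reproduces them.
#'
#' When \code{seed_regions} is absent, seeds are the maximal runs of CpGs
#' whose consecutive sites are less than \code{merge_gap} apart; a CpG site
#' at position p (0-based) occupies \code{[p, p+2)}.
#'
#' @param cpg_positions data.frame with columns \code{chrom} and \code{pos}
#'   (0-based CpG coordinates), or a named list of sorted position vectors.
#' @param seed_regions optional data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) giving pre-defined intervals to merge.
#' @param merge_gap minimum separation (bp) below which intervals merge.
#' @param min_cpg minimum CpG count per retained region.
#' @return a \linkS4class{MethBinRegions}
#' @export
buildSegments <- function(cpg_positions, seed_regions = NULL,
                          merge_gap = 400L, min_cpg = 3L) {
    if (is.data.frame(cpg_positions)) {
        .assert_cols(cpg_positions, c("chrom", "pos"), "cpg_positions")
        cpg_positions <- split(as.integer(cpg_positions$pos),
                               cpg_positions$chrom)
    }
    for (ch in names(cpg_positions)) {
        p <- cpg_positions[[ch]]
        if (is.unsorted(p, strictly = TRUE))
            stop("CpG positions on ", ch, " must be sorted and unique")
    }
    out <- list()
    chroms <- names(cpg_positions)
    for (ch in chroms) {
        pos <- as.integer(cpg_positions[[ch]])
        if (!length(pos)) next
        if (is.null(seed_regions)) {
            ## seed with maximal runs of CpGs spaced < merge_gap
            ## (distance between CpG intervals [p,p+2) is next - (prev+2))
            brk <- which(diff(pos) - 2L >= merge_gap)
            grp <- cumsum(c(1L, seq_along(pos)[-1] %in% (brk + 1L)))
            st <- tapply(pos, grp, min)
            en <- tapply(pos, grp, max) + 2L
        } else {
            sr <- seed_regions[seed_regions$chrom == ch, , drop = FALSE]
            if (!nrow(sr)) next
            sr <- sr[order(sr$start), , drop = FALSE]
            st <- en <- integer(0)
            for (i in seq_len(nrow(sr))) {
                if (length(en) && sr$start[i] - en[length(en)] < merge_gap) {
                    en[length(en)] <- max(en[length(en)], sr$end[i])
                } else {
                    st <- c(st, sr$start[i]); en <- c(en, sr$end[i])
                }
            }
        }
        for (i in seq_along(st)) {
            inside <- pos[pos >= st[i] & pos < en[i]]
            if (length(inside) >= min_cpg)
                out[[length(out) + 1L]] <- list(
                    chrom = ch, start = as.integer(st[i]),
                    end = as.integer(max(en[i], max(inside) + 2L)),
                    cpgs = inside)
        }
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr)$region_id <- character(0)
        mcols(gr)$cpg_positions <- IntegerList()
        return(new("MethBinRegions", gr))
    }
    chrom <- vapply(out, `[[`, character(1), "chrom")
    st0 <- vapply(out, `[[`, integer(1), "start")
    en0 <- vapply(out, `[[`, integer(1), "end")
    gr <- GRanges(chrom, IRanges(st0 + 1L, en0))
    mcols(gr)$region_id <- sprintf("%s:%d-%d", chrom, st0, en0)
    mcols(gr)$cpg_positions <- IntegerList(lapply(out, `[[`, "cpgs"))
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    new("MethBinRegions", gr)
}

#' Assign epireads to MethBin regions
#'
#' Each read is assigned to the region containing the majority of its CpG
#' positions; ties go to the leftmost region; reads whose CpGs fall in no
#' region are unassigned (\code{NA}).  Only CpGs inside the assigned region
#' contribute downstream.
#'
#' @param reads epiread data.frame (see \code{\link{readEpireads}}).
#' @param regions a \linkS4class{MethBinRegions}.
#' @return character vector of region ids (NA = unassigned), one per read.
#' @export
assignFragments <- function(reads, regions) {
    n <- nrow(reads)
    res <- rep(NA_character_, n)
    if (!n || !length(regions)) return(res)
    frag <- GRanges(reads$chrom, IRanges(reads$frag_start + 1L, reads$frag_end))
    hits <- GenomicRanges::findOverlaps(frag, regions, ignore.strand = TRUE)
    if (!length(hits)) return(res)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    nhits <- tabulate(qh, nbins = n)
    contained <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
        frag, regions, type = "within", ignore.strand = TRUE))
    easy <- intersect(which(nhits == 1L), contained)
    res[easy] <- regionIds(regions)[sh[match(easy, qh)]]
    hard <- setdiff(unique(qh), easy)
    if (length(hard)) {
        pos <- .split_positions(reads$cpg_positions[hard])
        rid <- regionIds(regions)
        rs <- start(regions) - 1L; re <- end(regions)
        ord <- order(as.character(seqnames(regions)), rs)
        for (j in seq_along(hard)) {
            i <- hard[j]
            cand <- sh[qh == i]
            cnt <- vapply(cand, function(r)
                sum(pos[[j]] >= rs[r] & pos[[j]] < re[r]), integer(1))
            if (max(cnt) == 0L) next
            best <- cand[cnt == max(cnt)]
            ## ties to the leftmost region
            best <- best[which.min(match(best, ord))]
            res[i] <- rid[best]
        }
    }
    res
}

#' Write MethBin regions as BED4+count
#'
#' BED columns: chrom, 0-based start, end, region id, CpG count.
#' @param regions a \linkS4class{MethBinRegions}.
#' @param path output path.
#' @export
writeRegionsBed <- function(regions, path) {
    utils::write.table(
        data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = regionIds(regions),
                   n_cpg = lengths(cpgPositions(regions))),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a CpG position BED (chrom, start, end) into a position table
#' @param path BED path; the 0-based start of each record is the CpG site.
#' @return data.frame with chrom, pos.
#' @export
readCpgBed <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                            comment.char = "#",
                            colClasses = c("character", "integer", "integer"))
    data.frame(chrom = df[[1]], pos = df[[2]])
}
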