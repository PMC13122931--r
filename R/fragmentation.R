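## autosome naming: numbered chromosomes plus single-letter toy contigs
## (chrA, chrB, ...); X/Y/M are recognised but excluded as non-autosomal
.AUTOSOME_RE <- "^(chr)?[0-9]+$|^chr[A-W]$"
.KNOWN_RE <- "^(chr)?([0-9]+|X|Y|M|MT)$|^chr[A-W]$"

#' Tile autosomes into fixed-width coverage bins
#'
#' Splits each autosome into adjacent non-overlapping bins of
#' \code{width} bp (default 100 kb); the last partial bin per chromosome is
#' kept at reduced width.  Sex chromosomes and the mitochondrial contig are
#' excluded; unrecognised chromosome names are an error.  Each bin carries
#' the id of the 1 Mb super-bin it will be merged into.
#'
#' @param chrom_sizes named integer vector (chrom -> size in bp) or
#'   data.frame with columns \code{chrom}, \code{size}.
#' @param width bin width in bp.
#' @param merge_width width of the merged super-bins (default 1 Mb).
#' @return object of class \code{GenomeBins}: a list with \code{bins}
#'   (data.frame chrom/start/end/bin_id/merged_id/retained), \code{width}
#'   and \code{merge_width}.
#' @export
makeBins <- function(chrom_sizes, width = 100000L, merge_width = 1000000L) {
    if (is.data.frame(chrom_sizes)) {
        sizes <- stats::setNames(as.numeric(chrom_sizes$size),
                                 chrom_sizes$chrom)
    } else sizes <- chrom_sizes
    bad <- names(sizes)[!grepl(.KNOWN_RE, names(sizes))]
    if (length(bad))
        stop("unknown chromosome naming: ", paste(bad, collapse = ", "))
    sizes <- sizes[grepl(.AUTOSOME_RE, names(sizes))]
    if (!length(sizes)) stop("no autosomes in chrom_sizes")
    rows <- lapply(names(sizes), function(ch) {
        st <- seq(0L, sizes[[ch]] - 1L, by = width)
        data.frame(chrom = ch, start = st,
                   end = pmin(st + width, sizes[[ch]]))
    })
    bins <- do.call(rbind, rows)
    bins$bin_id <- sprintf("%s:%d", bins$chrom, bins$start)
    bins$merged_id <- sprintf("%s:%d", bins$chrom,
                              (bins$start %/% merge_width) * merge_width)
    bins$retained <- TRUE
    structure(list(bins = bins, width = width, merge_width = merge_width),
              class = "GenomeBins")
}

#' Filter coverage bins by blacklist and low coverage
#'
#' Removes bins overlapping any blacklist interval, then drops the
#' \code{drop_fraction} (default 10\%) of remaining bins with the lowest
#' reference coverage; coverage ties are broken by genomic order (earlier
#' bins dropped first).
#'
#' @param gbins a \code{GenomeBins} from \code{\link{makeBins}}.
#' @param coverage numeric vector of reference coverage, one per bin (in
#'   \code{gbins$bins} order).
#' @param blacklist optional data.frame with chrom/start/end (0-based
#'   half-open) of regions to exclude.
#' @param drop_fraction fraction of (non-blacklisted) bins to drop.
#' @return the \code{GenomeBins} with updated \code{retained} flags.
#' @export
filterBins <- function(gbins, coverage, blacklist = NULL,
                       drop_fraction = 0.10) {
    b <- gbins$bins
    stopifnot(length(coverage) == nrow(b))
    keep <- rep(TRUE, nrow(b))
    if (!is.null(blacklist) && nrow(blacklist)) {
        bl <- GRanges(blacklist$chrom,
                      IRanges(blacklist$start + 1L, blacklist$end))
        gr <- GRanges(b$chrom, IRanges(b$start + 1L, b$end))
        keep[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, bl))] <- FALSE
    }
    idx <- which(keep)
    k <- floor(length(idx) * drop_fraction)
    if (k > 0) {
        ord <- idx[order(coverage[idx], idx)]   # ties: earlier bins first
        keep[ord[seq_len(k)]] <- FALSE
    }
    gbins$bins$retained <- keep
    gbins
}

#' Fragment length class
#'
#' Classes partition [100, 320]: short = [100, 150), middle = [150, 260),
#' long = [260, 320]; lengths outside [100, 320] are "none" and excluded
#' from all coverages.
#'
#' @param length fragment length(s) in bp; must be positive.
#' @return character vector over \{"short", "middle", "long", "none"\}.
#' @export
lengthClass <- function(length) {
    if (any(length <= 0)) stop("fragment length must be positive")
    out <- rep("none", length(length))
    out[length >= 100 & length < 150] <- "short"
    out[length >= 150 & length < 260] <- "middle"
    out[length >= 260 & length <= 320] <- "long"
    out
}

#' Per-sample fragmentation coverage profile
#'
#' Each fragment with a defined length class is assigned by its midpoint to
#' exactly one retained 100 kb bin, and counted in exactly one class of
#' that bin's 1 Mb super-bin.  nfrags is the sum of the three class
#' coverages.  Fragments on chromosomes absent from the bin set are counted
#' and reported via a warning.
#'
#' @param fragments fragment data.frame (see \code{\link{readFragments}}).
#' @param gbins a filtered \code{GenomeBins}.
#' @param samples optional character vector fixing the sample set/order.
#' @return object of class \code{FragmentProfile}: list with \code{profile}
#'   (long data.frame sample_id/bin/short_cov/middle_cov/long_cov/nfrags),
#'   \code{features} (samples x 4*bins numeric matrix) and
#'   \code{n_unknown_chrom}.
#' @export
coverageProfile <- function(fragments, gbins, samples = NULL) {
    b <- gbins$bins
    merged_ids <- unique(b$merged_id[b$retained])
    sample_levels <- if (is.null(samples)) sort(unique(fragments$sample_id))
                     else as.character(samples)
    cls <- lengthClass(fragments$length)
    mid <- (fragments$start + fragments$end) %/% 2L
    key <- sprintf("%s:%d", fragments$chrom,
                   (mid %/% gbins$width) * gbins$width)
    bin_idx <- match(key, b$bin_id)
    unknown <- !fragments$chrom %in% unique(b$chrom)
    if (any(unknown))
        warning(sum(unknown), " fragment(s) on chromosomes absent from the bin set")
    ok <- cls != "none" & !is.na(bin_idx) & b$retained[pmax(bin_idx, 1L)] &
          fragments$sample_id %in% sample_levels
    ok[is.na(ok)] <- FALSE
    mb <- factor(b$merged_id[bin_idx[ok]], levels = merged_ids)
    sf <- factor(fragments$sample_id[ok], levels = sample_levels)
    cf <- factor(cls[ok], levels = c("short", "middle", "long"))
    counts <- table(sf, mb, cf)
    prof <- do.call(rbind, lapply(sample_levels, function(s) {
        data.frame(sample_id = s, bin = merged_ids,
                   short_cov = as.integer(counts[s, , "short"]),
                   middle_cov = as.integer(counts[s, , "middle"]),
                   long_cov = as.integer(counts[s, , "long"]))
    }))
    prof$nfrags <- prof$short_cov + prof$middle_cov + prof$long_cov
    feat <- cbind(
        matrix(prof$short_cov, nrow = length(sample_levels), byrow = TRUE),
        matrix(prof$middle_cov, nrow = length(sample_levels), byrow = TRUE),
        matrix(prof$long_cov, nrow = length(sample_levels), byrow = TRUE),
        matrix(prof$nfrags, nrow = length(sample_levels), byrow = TRUE))
    colnames(feat) <- c(paste0(merged_ids, "_short"),
                        paste0(merged_ids, "_middle"),
                        paste0(merged_ids, "_long"),
                        paste0(merged_ids, "_nfrags"))
    rownames(feat) <- sample_levels
    structure(list(profile = prof, features = feat,
                   n_unknown_chrom = sum(unknown)),
              class = "FragmentProfile")
}

#' PCA feature extraction for fragmentation profiles
#'
#' Fits a principal component analysis on the training samples only
#' (per-feature centering and unit-variance scaling), retains the smallest
#' number of components whose cumulative explained variance reaches
#' \code{var_frac} (default 0.98), and stores the projection so test
#' samples are mapped without refitting.  Zero-variance features are
#' dropped with a warning; an (almost) zero total variance is an error.
#'
#' @param features numeric matrix, training samples x raw features.
#' @param var_frac cumulative explained-variance target in (0, 1].
#' @return object of class \code{PCFeatures}: list with \code{scores}
#'   (training samples x k), \code{rotation}, \code{center}, \code{scale},
#'   \code{var_explained}, \code{k}, \code{kept_features}.
#' @export
pcaFeatures <- function(features, var_frac = 0.98) {
    stopifnot(nrow(features) >= 2)
    v <- apply(features, 2, stats::var)
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance feature(s) dropped before PCA")
        features <- features[, v > 0, drop = FALSE]
    }
    if (!ncol(features) || sum(v) < 1e-12)
        stop("degenerate input: no variance left for PCA")
    pc <- stats::prcomp(features, center = TRUE, scale. = TRUE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    k <- which(cumsum(ve) >= var_frac)[1]
    if (is.na(k)) k <- length(ve)
    structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                   rotation = pc$rotation[, seq_len(k), drop = FALSE],
                   center = pc$center, scale = pc$scale,
                   var_explained = ve[seq_len(k)], k = k,
                   kept_features = colnames(features)),
              class = "PCFeatures")
}

#' Project new samples onto stored principal components
#' @param pc a \code{PCFeatures} object.
#' @param features numeric matrix, new samples x raw features (must contain
#'   the fitted feature columns).
#' @return matrix of PC scores (samples x k).
#' @export
projectPca <- function(pc, features) {
    miss <- setdiff(pc$kept_features, colnames(features))
    if (length(miss))
        stop("missing feature column(s): ", paste(head(miss, 3), collapse = ", "))
    x <- features[, pc$kept_features, drop = FALSE]
    scale(x, center = pc$center, scale = pc$scale) %*% pc$rotation
}
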