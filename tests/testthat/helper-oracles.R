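## Independent oracles, deliberately naive and separate from the package's
## vectorised code paths.

## direct BiEntropy: recompute the k-th derivative from the original string
## every time, by definition
naive_bien <- function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    n <- length(bits)
    H <- function(p) if (p <= 0 || p >= 1) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
    total <- 0
    for (k in 0:(n - 2)) {
        d <- bits
        if (k > 0) for (j in seq_len(k)) {
            d2 <- integer(length(d) - 1)
            for (i in seq_along(d2)) d2[i] <- if (d[i] != d[i + 1]) 1L else 0L
            d <- d2
        }
        total <- total + H(sum(d) / length(d)) * 2^k
    }
    total / (2^(n - 1) - 1)
}

## brute-force AUC by pair counting (ties count half)
pairwise_auc <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

all_bitstrings <- function(n) {
    m <- as.matrix(expand.grid(rep(list(0:1), n)))
    apply(m, 1, paste0, collapse = "")
}

## small epiread table generator for round-trip properties
random_epireads <- function(n, seed) {
    set.seed(seed)
    rows <- lapply(seq_len(n), function(i) {
        k <- sample(2:8, 1)
        start <- sample(1000:5000, 1)
        pos <- sort(sample(start:(start + 300), k))
        data.frame(sample_id = paste0("S", sample(1:3, 1)),
                   chrom = sample(c("chr1", "chr2"), 1),
                   frag_start = start - 5L,
                   frag_end = max(pos) + sample(1:20, 1),
                   cpg_positions = paste(pos, collapse = ","),
                   calls = paste(sample(c("M", "U", "."), k, replace = TRUE,
                                        prob = c(0.45, 0.45, 0.1)),
                                 collapse = ""),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

## toy two-region segmentation used across tests
toy_regions <- function() {
    cpgs <- data.frame(
        chrom = "chr1",
        pos = c(100L, 150L, 200L, 2000L, 2050L, 2100L, 2150L))
    buildSegments(cpgs)
}
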