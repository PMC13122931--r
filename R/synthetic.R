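#' Simulation configuration for synthetic cfDNA cohorts
#'
#' Defines the conditions the generator emulates: cohort sizes and splits,
#' region count and planted informative regions, sequencing depth, CpG
#' counts per fragment, and the planted effect sizes.  Methylation
#' patterns come from a two-state Markov chain over the CpGs of a read
#' whose stationary methylation level and switching intensity are
#' decoupled: the baseline intensity (0.05) yields mostly-ordered blocks
#' (low BiEntropy); in entropy-informative regions cancer samples draw
#' with intensity raised by \code{entropy_effect}, which raises expected
#' BiEntropy while leaving mean methylation unchanged.  In
#' URA-informative regions cancer samples have the stationary
#' unmethylated fraction shifted by \code{ura_effect}, which shifts the
#' region's U-reads abundance by about the same amount.  Note that
#' disorder genuinely perturbs U-read abundance as well (U reads are
#' ordered, mostly-unmethylated patterns), so entropy-informative regions
#' also carry a real URA signal - as they would in tumours.  Fragment
#' lengths come from a
#' truncated three-component mixture on [100, 320] bp with
#' \code{frag_short_shift} probability mass moved into the short class
#' (100-150 bp) for cancer samples.
#'
#' @param n_cancer_train,n_control_train,n_cancer_test,n_control_test
#'   cohort split sizes.
#' @param type_counts_train,type_counts_test optional named per-type cancer
#'   counts (names from the seven study types); by default cancer samples
#'   are spread over the types proportionally.
#' @param n_regions number of MethBin regions (each 20 CpGs).
#' @param n_informative_binary planted cancer-vs-control regions per
#'   modality (disjoint entropy and URA sets).
#' @param n_informative_per_type planted type-specific regions per type.
#' @param depth_mean mean Poisson read depth per (sample, region).
#' @param cpg_range inclusive range of CpG counts per fragment.
#' @param entropy_effect increase of the Markov switching intensity in
#'   affected regions (baseline 0.05).
#' @param ura_effect shift of the stationary unmethylated fraction.
#' @param frag_short_shift probability mass moved into [100,150) for cases.
#' @param n_frags_per_sample cfDNA fragments per sample for the
#'   fragmentation profile.
#' @param chrom_sizes named toy-autosome sizes.
#' @param sex_ratio male fraction among non-ovarian samples.
#' @param seed mandatory integer seed.
#' @return validated config list (class \code{SimulationConfig}).
#' @export
simulationConfig <- function(n_cancer_train = 60L, n_control_train = 60L,
                             n_cancer_test = 30L, n_control_test = 30L,
                             type_counts_train = NULL,
                             type_counts_test = NULL,
                             n_regions = 48L,
                             n_informative_binary = 10L,
                             n_informative_per_type = 0L,
                             depth_mean = 70,
                             cpg_range = c(4L, 14L),
                             entropy_effect = 0.45,
                             ura_effect = 0.20,
                             frag_short_shift = 0.08,
                             n_frags_per_sample = 2000L,
                             chrom_sizes = c(chr1 = 10000000L,
                                             chr2 = 10000000L),
                             sex_ratio = 0.5,
                             seed) {
    if (missing(seed)) stop("seed is mandatory")
    cfg <- list(n_cancer_train = n_cancer_train,
                n_control_train = n_control_train,
                n_cancer_test = n_cancer_test,
                n_control_test = n_control_test,
                type_counts_train = type_counts_train,
                type_counts_test = type_counts_test,
                n_regions = as.integer(n_regions),
                n_informative_binary = as.integer(n_informative_binary),
                n_informative_per_type = as.integer(n_informative_per_type),
                depth_mean = depth_mean, cpg_range = as.integer(cpg_range),
                entropy_effect = entropy_effect, ura_effect = ura_effect,
                frag_short_shift = frag_short_shift,
                n_frags_per_sample = as.integer(n_frags_per_sample),
                chrom_sizes = chrom_sizes, sex_ratio = sex_ratio,
                psw_base = 0.05, n_cpg_per_region = 20L,
                seed = as.integer(seed))
    with(cfg, {
        stopifnot(n_cancer_train > 0, n_control_train > 0,
                  n_cancer_test >= 0, n_control_test >= 0,
                  n_regions > 0, depth_mean > 0,
                  cpg_range[1] >= 3L, cpg_range[2] <= 32L,
                  cpg_range[1] <= cpg_range[2],
                  sex_ratio >= 0, sex_ratio <= 1)
    })
    if (cfg$psw_base + cfg$entropy_effect > 1 || cfg$entropy_effect < 0)
        stop("infeasible entropy_effect: switch probability out of [0,1]")
    if (cfg$ura_effect < 0 || cfg$ura_effect > 1)
        stop("infeasible ura_effect: probability shift out of [0,1]")
    if (cfg$frag_short_shift < 0 || cfg$frag_short_shift > 0.5)
        stop("infeasible frag_short_shift")
    n_inf <- 2L * cfg$n_informative_binary +
        7L * cfg$n_informative_per_type
    if (n_inf > cfg$n_regions)
        stop("more informative regions requested than regions available")
    class(cfg) <- "SimulationConfig"
    cfg
}

## distribute n cancer samples over the seven types proportionally to the
## study's test-set volumes
.default_type_counts <- function(n) {
    w <- c(colorectal = 21, lung = 17, gastric = 12, ovarian = 13,
           liver = 10, esophageal = 10, thyroid = 8)
    cnt <- floor(w / sum(w) * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
        top <- order(-(w / sum(w) * n - cnt))[seq_len(rem)]
        cnt[top] <- cnt[top] + 1L
    }
    cnt[cnt > 0]
}

## Markov-chain methylation patterns with methylation level and disorder
## decoupled: the chain over a read's CpGs has stationary distribution
## (p1, 1-p1) for every switching intensity s (transitions 1->0 with
## probability s*(1-p1), 0->1 with probability s*p1), so raising s raises
## BiEntropy while leaving expected mean methylation unchanged.  Returns a
## character vector of call strings ("M"/"U").
.markov_calls <- function(n, p1, s) {
    stopifnot(length(p1) == length(s))
    N <- length(p1)
    b <- matrix(0L, N, n)
    cur <- as.integer(stats::runif(N) < p1)
    b[, 1] <- cur
    if (n > 1L) {
        for (j in seq_len(n - 1L)) {
            p_next <- cur * (1 - s * (1 - p1)) + (1L - cur) * (s * p1)
            cur <- as.integer(stats::runif(N) < p_next)
            b[, j + 1L] <- cur
        }
    }
    cols <- lapply(seq_len(n), function(j) c("U", "M")[b[, j] + 1L])
    do.call(paste0, cols)
}

#' Generate a fully synthetic cfDNA cohort
#'
#' Produces epireads, fragment records and a label sheet with planted
#' case/control and per-cancer-type structure, plus the truth set of
#' planted informative regions.  Reproducible from the config seed; when
#' \code{outdir} is given the three artifacts are also written
#' (\code{epireads.tsv}, \code{fragments.bed}, \code{labels.tsv},
#' \code{regions.bed}).
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param outdir optional output directory.
#' @return a \linkS4class{SyntheticCohort}.
#' @export
simulateCohort <- function(cfg, outdir = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    ## ---- samples ----------------------------------------------------------
    n_cancer <- cfg$n_cancer_train + cfg$n_cancer_test
    n_control <- cfg$n_control_train + cfg$n_control_test
    S <- n_cancer + n_control
    ids <- sprintf("S%04d", seq_len(S))
    group <- c(rep("cancer", n_cancer), rep("non_cancer", n_control))
    split <- c(rep("train", cfg$n_cancer_train),
               rep("test", cfg$n_cancer_test),
               rep("train", cfg$n_control_train),
               rep("test", cfg$n_control_test))
    tc_tr <- if (is.null(cfg$type_counts_train))
        .default_type_counts(cfg$n_cancer_train) else cfg$type_counts_train
    tc_te <- if (is.null(cfg$type_counts_test))
        .default_type_counts(cfg$n_cancer_test) else cfg$type_counts_test
    type <- c(rep(names(tc_tr), tc_tr), rep(names(tc_te), tc_te),
              rep("", n_control))
    sex <- ifelse(stats::runif(S) < cfg$sex_ratio, "male", "female")
    sex[type == "ovarian"] <- "female"
    stage <- rep("", S)
    stage[group == "cancer"] <- sample(
        c("I", "II", "III", "IV", "unknown"), n_cancer, replace = TRUE,
        prob = c(0.208, 0.228, 0.325, 0.066, 0.173))
    labels <- data.frame(sample_id = ids, group = group,
                         cancer_type = type, sex = sex, stage = stage,
                         split = split, stringsAsFactors = FALSE)
    ## ---- regions ----------------------------------------------------------
    R <- cfg$n_regions
    ncpg <- cfg$n_cpg_per_region
    chroms <- names(cfg$chrom_sizes)
    region_chrom <- chroms[(seq_len(R) - 1L) %% length(chroms) + 1L]
    region_start <- 10000L + ((seq_len(R) - 1L) %/% length(chroms)) * 5000L
    cpg_mat <- matrix(0L, R, ncpg)
    for (i in seq_len(R))
        cpg_mat[i, ] <- region_start[i] + (seq_len(ncpg) - 1L) * 15L
    cpg_tab <- data.frame(chrom = rep(region_chrom, each = ncpg),
                          pos = as.integer(t(cpg_mat)))
    cpg_tab <- cpg_tab[order(cpg_tab$chrom, cpg_tab$pos), ]
    regions <- buildSegments(cpg_tab)
    ## map generator region index -> canonical region_id
    rid_of <- sprintf("%s:%d-%d", region_chrom, region_start,
                      region_start + (ncpg - 1L) * 15L + 2L)
    stopifnot(all(rid_of %in% regionIds(regions)))
    ## ---- planted structure -------------------------------------------------
    k <- cfg$n_informative_binary
    ent_inf <- seq_len(k)
    ura_inf <- k + seq_len(k)
    type_regions <- list()
    if (cfg$n_informative_per_type > 0) {
        base <- 2L * k
        for (j in seq_along(CANCER_TYPES)) {
            type_regions[[CANCER_TYPES[j]]] <-
                base + (j - 1L) * cfg$n_informative_per_type +
                seq_len(cfg$n_informative_per_type)
        }
    }
    p1_base <- stats::runif(R, 0.35, 0.65)
    ## effect matrices (sample x region)
    is_cancer <- group == "cancer"
    d_ura <- matrix(0, S, R)
    d_ent <- matrix(0, S, R)
    if (k > 0) {
        d_ura[is_cancer, ura_inf] <- cfg$ura_effect
        d_ent[is_cancer, ent_inf] <- cfg$entropy_effect
    }
    for (tp in names(type_regions)) {
        rows <- type == tp
        d_ura[rows, type_regions[[tp]]] <- cfg$ura_effect
        d_ent[rows, type_regions[[tp]]] <- cfg$entropy_effect
    }
    P1 <- pmax(matrix(p1_base, S, R, byrow = TRUE) - d_ura, 0.02)
    PSW <- cfg$psw_base + d_ent
    ## ---- epireads ----------------------------------------------------------
    D <- matrix(stats::rpois(S * R, cfg$depth_mean), S, R)
    counts <- as.vector(D)                      # column-major: region-major
    samp_v <- rep(rep(seq_len(S), R), counts)
    reg_v <- rep(rep(seq_len(R), each = S), counts)
    N <- length(samp_v)
    p1_v <- rep(as.vector(P1), counts)
    psw_v <- rep(as.vector(PSW), counts)
    n_v <- sample(seq(cfg$cpg_range[1], cfg$cpg_range[2]), N, replace = TRUE)
    off_v <- floor(stats::runif(N) * (ncpg - n_v + 1))
    calls <- character(N)
    pos_str <- character(N)
    fs <- fe <- integer(N)
    for (n in sort(unique(n_v))) {
        gi <- which(n_v == n)
        calls[gi] <- .markov_calls(n, p1_v[gi], psw_v[gi])
        for (o in sort(unique(off_v[gi]))) {
            gio <- gi[off_v[gi] == o]
            pm <- cpg_mat[reg_v[gio], (o + 1):(o + n), drop = FALSE]
            pos_str[gio] <- do.call(paste, c(as.data.frame(pm), sep = ","))
            fs[gio] <- pm[, 1] - 10L
            fe[gio] <- pm[, n] + 12L
        }
    }
    reads <- data.frame(sample_id = ids[samp_v],
                        chrom = region_chrom[reg_v],
                        frag_start = fs, frag_end = fe,
                        cpg_positions = pos_str, calls = calls,
                        region_id = rid_of[reg_v],
                        stringsAsFactors = FALSE)
    ## ---- fragments ---------------------------------------------------------
    nf <- cfg$n_frags_per_sample
    w_short <- ifelse(is_cancer, 0.12 + cfg$frag_short_shift, 0.12) +
        stats::rnorm(S, 0, 0.01)
    w_short <- pmin(pmax(w_short, 0.01), 0.6)
    w_long <- 0.08
    NF <- S * nf
    fsamp <- rep(seq_len(S), each = nf)
    comp_u <- stats::runif(NF)
    comp <- ifelse(comp_u < w_short[fsamp], 1L,
                   ifelse(comp_u < w_short[fsamp] + w_long, 3L, 2L))
    len <- numeric(NF)
    len[comp == 1L] <- stats::rnorm(sum(comp == 1L), 130, 8)
    len[comp == 2L] <- stats::rnorm(sum(comp == 2L), 168, 20)
    len[comp == 3L] <- stats::rnorm(sum(comp == 3L), 285, 12)
    len <- as.integer(pmin(pmax(round(len), 100L), 320L))
    fchrom_i <- sample(seq_along(cfg$chrom_sizes), NF, replace = TRUE,
                       prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
    fstart <- floor(stats::runif(NF) *
                    (cfg$chrom_sizes[fchrom_i] - len))
    fragments <- data.frame(sample_id = ids[fsamp],
                            chrom = names(cfg$chrom_sizes)[fchrom_i],
                            start = as.integer(fstart),
                            end = as.integer(fstart + len),
                            length = len, stringsAsFactors = FALSE)
    truth <- list(binary_entropy = rid_of[ent_inf],
                  binary_ura = rid_of[ura_inf],
                  per_type = lapply(type_regions, function(ix) rid_of[ix]),
                  labels = labels)
    cohort <- new("SyntheticCohort", epireads = reads,
                  fragments = fragments, labels = labels,
                  regions = regions, truth = truth, config = unclass(cfg))
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeEpireads(reads[, 1:6], file.path(outdir, "epireads.tsv"))
        writeFragments(fragments, file.path(outdir, "fragments.bed"))
        writeLabels(labels, file.path(outdir, "labels.tsv"))
        writeRegionsBed(regions, file.path(outdir, "regions.bed"))
    }
    cohort
}

#' Named scenario presets
#'
#' Ships three study scenarios: \code{null} (no planted effects, small
#' cohort), \code{strong-signal} (cohort sized like the study's training /
#' testing split - 197/157 train and 91/76 test - with planted effects
#' comfortably beyond the selection thresholds) and \code{seven-type}
#' (same split with per-type counts matching the testing-set volumes and
#' planted type-specific regions for tissue-of-origin analysis).
#'
#' @param seed integer seed stored in each config.
#' @return named list of \code{\link{simulationConfig}} objects.
#' @export
scenarioPresets <- function(seed = 1L) {
    tc_te <- c(colorectal = 21L, lung = 17L, gastric = 12L, ovarian = 13L,
               liver = 10L, esophageal = 10L, thyroid = 8L)
    tc_tr <- c(colorectal = 45L, lung = 37L, gastric = 26L, ovarian = 28L,
               liver = 22L, esophageal = 22L, thyroid = 17L)
    list(
        "null" = simulationConfig(
            n_cancer_train = 40L, n_control_train = 40L,
            n_cancer_test = 20L, n_control_test = 20L,
            n_regions = 30L, n_informative_binary = 0L,
            entropy_effect = 0, ura_effect = 0, frag_short_shift = 0,
            seed = seed),
        "strong-signal" = simulationConfig(
            n_cancer_train = 197L, n_control_train = 157L,
            n_cancer_test = 91L, n_control_test = 76L,
            n_regions = 48L, n_informative_binary = 10L,
            seed = seed),
        "seven-type" = simulationConfig(
            n_cancer_train = 197L, n_control_train = 157L,
            n_cancer_test = 91L, n_control_test = 76L,
            type_counts_train = tc_tr, type_counts_test = tc_te,
            n_regions = 60L, n_informative_binary = 5L,
            n_informative_per_type = 5L,
            seed = seed))
}
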