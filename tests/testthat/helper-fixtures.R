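# Fixtures are generated in code; nothing is stored on disk.

randomDNA <- function(n) {
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# In-memory community with one record per genome.
makeCommunity <- function(lengths, molarities, seed = 1) {
    set.seed(seed)
    ids <- sprintf("g%02d", seq_along(lengths))
    recs <- Biostrings::DNAStringSet(vapply(lengths, randomDNA, character(1)))
    names(recs) <- paste0(ids, "_rec1")
    communityProfile(ids, molarities, records = recs, recordGenome = ids)
}

# Independent clustering oracle: connected components of the graph whose
# edges join alignment intervals with pairwise gap <= maxGap, per
# (barcode, reference). Union-find over all pairs -- no sorting, no greedy
# scan, deliberately different from the implementation.
oracleClusters <- function(df, maxGap) {
    out <- list()
    for (key in unique(paste(df$barcode, df$ref, sep = "\r"))) {
        sub <- df[paste(df$barcode, df$ref, sep = "\r") == key, , drop = FALSE]
        n <- nrow(sub)
        parent <- seq_len(n)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (i < j) {
                gap <- max(sub$start[j] - sub$end[i],
                           sub$start[i] - sub$end[j], 0)
                if (gap <= maxGap) {
                    ri <- find(i); rj <- find(j)
                    if (ri != rj) parent[ri] <- rj
                }
            }
        }
        roots <- vapply(seq_len(n), find, integer(1))
        for (r in unique(roots)) {
            m <- sub[roots == r, , drop = FALSE]
            out[[length(out) + 1L]] <- data.frame(
                barcode = m$barcode[1], ref = m$ref[1],
                start = min(m$start), end = max(m$end),
                n_pairs = length(unique(m$pair_id)), n_reads = nrow(m),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res[order(res$barcode, res$ref, res$start, res$end), , drop = FALSE]
}

alignmentsFromDf <- function(df) {
    gr <- GenomicRanges::GRanges(
        seqnames = df$ref,
        ranges = IRanges::IRanges(start = df$start, end = df$end))
    S4Vectors::mcols(gr)$barcode <- df$barcode
    S4Vectors::mcols(gr)$pair_id <- df$pair_id
    gr
}

reconAsDf <- function(gr) {
    df <- data.frame(
        barcode = S4Vectors::mcols(gr)$barcode,
        ref = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
        n_pairs = S4Vectors::mcols(gr)$n_read_pairs,
        n_reads = S4Vectors::mcols(gr)$n_reads,
        stringsAsFactors = FALSE)
    df[order(df$barcode, df$ref, df$start, df$end), , drop = FALSE]
}

# Bin records engineered to land in each quality tier.
makeTierBins <- function(high = 0, medium = 0, low = 0, other = 0) {
    one <- function(n, completeness, contamination, rrna, trna) {
        if (n == 0) return(NULL)
        data.frame(bin_id = replicate(n, paste0("b", paste0(sample(letters, 6),
                                                            collapse = ""))),
                   size_bp = rep(2e6, n), depth = rep(50, n),
                   completeness = rep(completeness, n),
                   contamination = rep(contamination, n),
                   has_5S = rep(rrna, n), has_16S = rep(rrna, n),
                   has_23S = rep(rrna, n), n_tRNA = rep(trna, n),
                   stringsAsFactors = FALSE)
    }
    do.call(rbind, list(one(high, 95, 3, TRUE, 20),
                        one(medium, 70, 6, FALSE, 10),
                        one(low, 30, 5, FALSE, 4),
                        one(other, 60, 15, FALSE, 4)))
}

# Brute-force N50: scan every candidate threshold.
bruteN50 <- function(lengths) {
    half <- sum(as.numeric(lengths)) / 2
    cand <- sort(unique(lengths), decreasing = TRUE)
    for (L in cand) if (sum(as.numeric(lengths[lengths >= L])) >= half) return(L)
    min(lengths)
}

# A small simulated library shared by several tests (cached per session).
.simCache <- new.env()
sharedSim <- function() {
    if (!is.null(.simCache$sim)) return(.simCache$sim)
    comm <- makeCommunity(c(150000, 150000), c(1, 1), seed = 42)
    cfg <- simulationConfig(CF = 30, CR = 0.3, muFL = 10000, NFP = 10,
                            seed = 11L)
    dir <- tempfile("sharedsim")
    sim <- simulateLinkedReads(comm, cfg, dir)
    .simCache$sim <- list(community = comm, cfg = cfg, sim = sim, dir = dir)
    .simCache$sim
}
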