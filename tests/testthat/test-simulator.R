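test_that("fragment sampling honours the depth budget and length model", {
    expect_length(drawFragments(c(rec = 1e6), 0, 10000), 0L)
    expect_error(drawFragments(c(rec = 1e6), 10, 500, minLen = 1000),
                 "muFL must exceed")

    set.seed(31)
    fr <- drawFragments(c(rec = 1e6), CFi = 10, muFL = 10000, minLen = 1000)
    total <- sum(GenomicRanges::width(fr))
    # budget-stopping: cumulative length crosses 1e7 by at most ~one fragment
    expect_gte(total, 1e7)
    expect_lt(abs(total - 1e7) / 1e7, 0.02)
    # fragments stay inside the record
    expect_true(all(GenomicRanges::start(fr) >= 1))
    expect_true(all(GenomicRanges::end(fr) <= 1e6))
    expect_true(all(GenomicRanges::width(fr) >= 1000))

    # law of large numbers on the mean length at n = 10,000
    set.seed(32)
    big <- drawFragments(c(rec = 5e7), CFi = 2, muFL = 10000, minLen = 1000)
    expect_gte(length(big), 9000)
    expect_lt(abs(mean(GenomicRanges::width(big)) - 10000) / 10000, 0.05)
})

test_that("partition assignment matches the N_F/P occupancy model", {
    fr <- GenomicRanges::GRanges("rec",
        IRanges::IRanges(start = seq(1, by = 100, length.out = 10000),
                         width = 50))
    S4Vectors::mcols(fr)$genome_id <- "g"

    # N_FP = 1: one partition per fragment
    p1 <- assignPartitions(fr[1:100], NFP = 1, seed = 5)
    expect_equal(nrow(S4Vectors::metadata(p1)$partitions), 100L)

    # floor case: fewer fragments than N_FP -> a single co-barcoded partition
    p2 <- assignPartitions(fr[1:3], NFP = 10, seed = 5)
    expect_equal(nrow(S4Vectors::metadata(p2)$partitions), 1L)
    expect_length(unique(S4Vectors::mcols(p2)$barcode), 1L)

    # multinomial occupancy ~ Poisson(N_FP) at 10,000 fragments
    p3 <- assignPartitions(fr, NFP = 10, seed = 5)
    occ <- S4Vectors::metadata(p3)$partitions$n_fragments
    expect_equal(length(occ), 1000L)
    expect_equal(mean(occ), 10)
    expect_lt(abs(var(occ) - 10) / 10, 0.25)  # Poisson: variance ~ mean

    # barcodes are distinct 16-mers over ACGT
    bc <- S4Vectors::metadata(p3)$partitions$barcode
    expect_false(anyDuplicated(bc) > 0)
    expect_true(all(grepl("^[ACGT]{16}$", bc)))

    empty <- assignPartitions(fr[0], NFP = 10, seed = 5)
    expect_length(empty, 0L)
})

test_that("read generation hits the configured per-fragment depth", {
    comm <- makeCommunity(20000, 1, seed = 77)
    cfg <- simulationConfig(CF = 1, CR = 0.3, muFL = 10000, seed = 1L)
    fr <- GenomicRanges::GRanges("g01_rec1",
        IRanges::IRanges(start = rep(1000, 400), width = 10000))
    S4Vectors::mcols(fr)$fragment_id <- sprintf("F%03d", 1:400)
    S4Vectors::mcols(fr)$barcode <- strrep("A", 16)

    # C_R = 0 -> no pairs at all
    cfg0 <- simulationConfig(CR = 0, seed = 1L)
    expect_equal(nrow(generateReads(fr, comm@records, cfg0, seed = 2)), 0L)

    # Poisson mean C_R * L / (2 * readLength) = 10 pairs per 10 kb fragment
    reads <- generateReads(fr, comm@records, cfg, seed = 2)
    perFrag <- nrow(reads) / 400
    se <- sqrt(10 / 400)
    expect_lt(abs(perFrag - 10), 4 * se)

    # containment: every mate lies fully inside its parent fragment
    expect_true(all(reads$mate1_start >= 1000))
    expect_true(all(reads$mate2_start + 150 - 1 <= 1000 + 10000 - 1))
    expect_true(all(reads$mate2_start >= reads$mate1_start))

    # substitution rate is realized in the emitted sequences
    ref <- comm@records[["g01_rec1"]]
    refStr <- as.character(Biostrings::subseq(
        rep(Biostrings::DNAStringSet(ref), nrow(reads)),
        start = reads$mate1_start, width = 150))
    mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 refStr[1:200], reads$seq1[1:200])
    rate <- sum(mm) / (200 * 150)
    expect_lt(abs(rate - 0.001) / 0.001, 1)  # loose binomial check

    # fragments too short for one pair warn and emit nothing
    tiny <- GenomicRanges::GRanges("g01_rec1",
        IRanges::IRanges(start = 1, width = 200))
    S4Vectors::mcols(tiny)$fragment_id <- "Ftiny"
    S4Vectors::mcols(tiny)$barcode <- strrep("C", 16)
    expect_warning(r0 <- generateReads(tiny, comm@records, cfg, seed = 2),
                   "shorter than one read pair")
    expect_equal(nrow(r0), 0L)
})

test_that("simulation conserves depth and is byte-deterministic", {
    sh <- sharedSim()
    sim <- sh$sim
    # realized total depth ~ C = C_R * C_F = 9X (uniform 2-genome community)
    expect_lt(abs(sim$stats@C - 9) / 9, 0.15)
    # physical depth within ~ one fragment length per genome budget
    expect_lt(abs(sim$stats@CF - 30) / 30, 0.05)
    # distinct barcodes = round(total fragments / N_FP)
    expect_equal(sim$stats@nBarcodes,
                 nrow(S4Vectors::metadata(sim$fragments)$partitions))
    expect_equal(nrow(S4Vectors::metadata(sim$fragments)$partitions),
                 round(length(sim$fragments) / sh$cfg@NFP))
    # length-weighted mean fragment length dominates the unweighted mean
    expect_gte(sim$stats@WmuFL, sim$stats@muFL)
    # manifest records the implied total depth
    expect_equal(sim$manifest$config$implied_C, 9)

    # per-genome read depth ~ C_R * C_Fi
    reads <- sim$reads
    gid <- S4Vectors::mcols(sim$fragments)$genome_id[
        match(reads$fragment_id, S4Vectors::mcols(sim$fragments)$fragment_id)]
    for (g in unique(gid)) {
        depth <- sum(gid == g) * 2 * 150 / 150000
        expect_lt(abs(depth - 9) / 9, 0.2)
    }

    # identical seed + config + input -> byte-identical outputs
    dir2 <- tempfile("rerun")
    sim2 <- simulateLinkedReads(sh$community, sh$cfg, dir2)
    for (k in c("r1", "r2", "fragments", "readOrigins")) {
        expect_equal(unname(tools::md5sum(sim$paths[[k]])),
                     unname(tools::md5sum(sim2$paths[[k]])), info = k)
    }
})

test_that("multi-replicon genomes split the budget across records", {
    recs <- Biostrings::DNAStringSet(c(chr = randomDNA(50000),
                                       plasmid = randomDNA(10000)))
    set.seed(9)
    fr <- drawFragments(c(chr = 50000, plasmid = 10000), CFi = 20,
                        muFL = 2000, minLen = 500)
    byRec <- tapply(GenomicRanges::width(fr),
                    as.character(GenomicRanges::seqnames(fr)), sum)
    # each record receives ~ CFi x its own length of fragment bases
    expect_lt(abs(byRec[["chr"]] - 20 * 50000) / (20 * 50000), 0.05)
    expect_lt(abs(byRec[["plasmid"]] - 20 * 10000) / (20 * 10000), 0.05)
})
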