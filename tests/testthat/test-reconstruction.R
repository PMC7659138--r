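# External (0-based) coordinates are used to build the TSV-dialect inputs;
# in-memory GRanges are 1-based.

.alnTsv <- function(df) {
    f <- tempfile(fileext = ".tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}

test_that("greedy extension applies the 50 kb gap and the pair/length filters", {
    # hand-traced case: p1/p2 cluster, p3 at 60 kb splits off and is dropped
    df <- data.frame(
        barcode = "B1", reference_id = "ref1",
        start = c(1000, 2000, 3000, 3050, 60000),
        end = c(1150, 2150, 3150, 3200, 60150),
        pair_id = c("p1", "p1", "p2", "p2", "p3"),
        mate_index = c(1, 2, 1, 2, 1))
    fr <- reconstructFragments(readAlignments(.alnTsv(df), "tsv"))
    expect_length(fr, 1L)
    expect_equal(GenomicRanges::start(fr), 1001L)  # [1000, 3200) externally
    expect_equal(GenomicRanges::end(fr), 3200L)
    expect_equal(GenomicRanges::width(fr), 2200L)
    expect_equal(S4Vectors::mcols(fr)$n_read_pairs, 2L)

    # single cluster of three pairs spanning 9 kb
    df2 <- data.frame(
        barcode = "B1", reference_id = "ref1",
        start = c(0, 400, 4000, 4400, 8000, 8850),
        end = c(150, 550, 4150, 4550, 8150, 9000),
        pair_id = rep(c("p1", "p2", "p3"), each = 2),
        mate_index = rep(c(1, 2), 3))
    fr2 <- reconstructFragments(readAlignments(.alnTsv(df2), "tsv"))
    expect_length(fr2, 1L)
    expect_equal(S4Vectors::mcols(fr2)$n_read_pairs, 3L)
    expect_equal(GenomicRanges::width(fr2), 9000L)

    # a 1.5 kb cluster fails the 2 kb minimum length
    df3 <- data.frame(
        barcode = "B1", reference_id = "ref1",
        start = c(0, 300, 700, 1350), end = c(150, 450, 850, 1500),
        pair_id = rep(c("p1", "p2"), each = 2), mate_index = rep(c(1, 2), 2))
    expect_length(reconstructFragments(readAlignments(.alnTsv(df3), "tsv")), 0L)

    # empty input
    expect_length(reconstructFragments(
        readAlignments(.alnTsv(df[0, ]), "tsv")), 0L)
})

test_that("reads on different references or barcodes never share a fragment", {
    df <- data.frame(
        barcode = c("B1", "B1", "B2", "B2"),
        ref = c("ref1", "ref2", "ref1", "ref1"),
        start = c(100, 150, 120, 2500), end = c(250, 300, 270, 2650),
        pair_id = c("p1", "p2", "p3", "p4"), stringsAsFactors = FALSE)
    fr <- reconstructFragments(alignmentsFromDf(df),
                               reconstructionParams(maxGap = 1000,
                                                    minPairs = 1L,
                                                    minLength = 1))
    expect_length(fr, 4L)
    expect_length(unique(paste(S4Vectors::mcols(fr)$barcode,
                               GenomicRanges::seqnames(fr))), 3L)
})

test_that("a pair with mates in different clusters counts in both", {
    df <- data.frame(
        barcode = "B1", ref = "ref1",
        start = c(100, 100000, 100200, 150, 400),
        end = c(250, 100150, 100350, 300, 550),
        pair_id = c("pSplit", "pSplit", "pFar", "pA", "pA"),
        stringsAsFactors = FALSE)
    fr <- reconstructFragments(alignmentsFromDf(df),
                               reconstructionParams(minPairs = 2L,
                                                    minLength = 100))
    expect_length(fr, 2L)
    expect_equal(S4Vectors::mcols(fr)$n_read_pairs, c(2L, 2L))
})

test_that("greedy clustering equals the connected-components oracle", {
    set.seed(61)
    nAgree <- 0L
    trials <- 300
    for (t in seq_len(trials)) {
        nb <- sample(1:3, 1)
        rows <- list()
        for (b in seq_len(nb)) {
            k <- sample(1:12, 1)
            start <- sort(sample.int(200000, k))
            len <- sample(50:500, k, replace = TRUE)
            rows[[b]] <- data.frame(
                barcode = paste0("B", b),
                ref = sample(c("r1", "r2"), k, replace = TRUE),
                start = start, end = start + len,
                pair_id = paste0("p", b, "_", sample(ceiling(k / 2), k,
                                                     replace = TRUE)),
                stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, rows)
        maxGap <- sample(c(500, 5000, 50000), 1)
        got <- reconAsDf(reconstructFragments(
            alignmentsFromDf(df),
            reconstructionParams(maxGap = maxGap, minPairs = 1L,
                                 minLength = 1)))
        want <- oracleClusters(df, maxGap)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
        nAgree <- nAgree + identical(got, want)
    }
    expect_equal(nAgree, trials)
})

test_that("fragment calls respond monotonically to the filter parameters", {
    set.seed(62)
    start <- sort(sample.int(500000, 400))
    df <- data.frame(barcode = sample(c("B1", "B2", "B3"), 400, replace = TRUE),
                     ref = "r1", start = start, end = start + 150,
                     pair_id = paste0("p", seq_len(400)),
                     stringsAsFactors = FALSE)
    aln <- alignmentsFromDf(df)
    nFrag <- function(maxGap, minPairs = 1L, minLength = 1) {
        length(reconstructFragments(aln,
            reconstructionParams(maxGap, minPairs, minLength)))
    }
    gaps <- c(1000, 5000, 20000, 50000)
    counts <- vapply(gaps, nFrag, integer(1))
    expect_true(all(diff(counts) <= 0))  # wider gap never adds fragments
    expect_gte(nFrag(5000, minPairs = 1L), nFrag(5000, minPairs = 2L))
    expect_gte(nFrag(5000, minLength = 1), nFrag(5000, minLength = 5000))

    # gap property: consecutive read starts inside one fragment stay <= maxGap
    fr <- reconstructFragments(aln, reconstructionParams(20000, 1L, 1))
    for (i in seq_along(fr)) {
        sub <- df$start[df$barcode == S4Vectors::mcols(fr)$barcode[i] &
                        df$start >= GenomicRanges::start(fr)[i] &
                        df$start < GenomicRanges::end(fr)[i]]
        if (length(sub) > 1)
            expect_lte(max(diff(sort(sub))), 20000)
    }
})

test_that("recall scoring uses reciprocal overlap with matched barcodes", {
    tr <- GenomicRanges::GRanges("r1", IRanges::IRanges(1, 10000))
    S4Vectors::mcols(tr)$barcode <- "B1"

    same <- tr
    S4Vectors::mcols(same)$n_read_pairs <- 5L
    r <- reconstructionRecall(tr, same, 0.8)
    expect_equal(r$recall, 1)
    expect_equal(r$precision, 1)

    emptyRec <- GenomicRanges::GRanges()
    S4Vectors::mcols(emptyRec)$barcode <- character()
    expect_equal(reconstructionRecall(tr, emptyRec, 0.8)$recall, 0)

    # truth [0, 10000) vs reconstruction [500, 9500): reciprocal overlap 0.9
    shrunk <- GenomicRanges::GRanges("r1", IRanges::IRanges(501, 9500))
    S4Vectors::mcols(shrunk)$barcode <- "B1"
    r2 <- reconstructionRecall(tr, shrunk, 0.8)
    expect_equal(r2$recall, 1)
    expect_equal(r2$length_bias, 0.9)

    # same span, different barcode -> not recovered
    S4Vectors::mcols(shrunk)$barcode <- "B2"
    expect_equal(reconstructionRecall(tr, shrunk, 0.8)$recall, 0)
})
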