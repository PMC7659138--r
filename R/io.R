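# Readers and writers shared by all modules. External TSV interfaces use
# 0-based half-open coordinates; everything in memory is a 1-based closed
# GRanges, converted only here at the boundary.

.RAW10X_SPACER <- "CAGTGCA"  # 7 bp spacer after the 16 bp barcode (R1)

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased and record ids are truncated at the first
#' whitespace. Gzipped files are handled transparently.
#'
#' @param path FASTA path.
#' @return \code{DNAStringSet} with one element per record.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
    if (length(x) == 0) stop("empty FASTA: ", path)
    names(x) <- sub("\\s.*$", "", names(x))
    Biostrings::DNAStringSet(toupper(x))
}

#' Read barcode-tagged alignments
#'
#' Loads alignment records carrying a fragment barcode from a SAM/BAM file
#' (barcode in the \code{BX} tag, the linked-read convention) or from the
#' package's plain TSV dialect with header
#' \code{barcode, reference_id, start, end, pair_id, mate_index}
#' (0-based half-open coordinates). Unmapped, secondary and supplementary
#' SAM records are skipped; mapped records without a barcode are dropped and
#' counted in \code{metadata()$n_dropped_no_barcode}.
#'
#' @param path input path.
#' @param dialect \code{"tsv"}, \code{"sam"} or \code{"bam"}.
#' @return \code{GRanges} (1-based) with metadata columns \code{barcode},
#'   \code{pair_id}, \code{mate_index}.
#' @export
readAlignments <- function(path, dialect = c("tsv", "sam", "bam")) {
    dialect <- match.arg(dialect)
    if (dialect == "tsv") .readAlignmentsTsv(path) else .readAlignmentsBam(path, dialect)
}

.readAlignmentsTsv <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("barcode", "reference_id", "start", "end", "pair_id", "mate_index")
    if (!all(need %in% names(tab)))
        stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(tab$start >= tab$end)
    if (length(bad))
        stop("coordinate inversion (start >= end) at line ", bad[1] + 1L)
    keep <- !is.na(tab$barcode) & nzchar(tab$barcode)
    dropped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = tab$reference_id,
        ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end))
    S4Vectors::mcols(gr)$barcode <- tab$barcode
    S4Vectors::mcols(gr)$pair_id <- as.character(tab$pair_id)
    S4Vectors::mcols(gr)$mate_index <- as.integer(tab$mate_index)
    S4Vectors::metadata(gr)$n_dropped_no_barcode <- dropped
    gr
}

.readAlignmentsBam <- function(path, dialect) {
    if (dialect == "sam") {
        bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
    } else bam <- path
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flag, tag = "BX",
            what = c("qname", "flag", "rname", "pos", "cigar"))
    res <- Rsamtools::scanBam(bam, param = p)[[1]]
    bx <- res$tag$BX
    if (is.null(bx)) bx <- rep(NA_character_, length(res$pos))
    keep <- !is.na(bx) & nzchar(bx)
    dropped <- sum(!keep)
    refWidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(res$rname[keep]),
        ranges = IRanges::IRanges(start = res$pos[keep],
                                  width = refWidth))
    # strip the 10x "-1" GEM-group suffix so barcodes compare as plain strings
    S4Vectors::mcols(gr)$barcode <- sub("-\\d+$", "", bx[keep])
    S4Vectors::mcols(gr)$pair_id <- res$qname[keep]
    S4Vectors::mcols(gr)$mate_index <-
        ifelse(bitwAnd(res$flag[keep], 64L) > 0L, 1L,
        ifelse(bitwAnd(res$flag[keep], 128L) > 0L, 2L, 1L))
    S4Vectors::metadata(gr)$n_dropped_no_barcode <- dropped
    gr
}

#' Write / read a barcoded paired FASTQ
#'
#' Two barcode dialects are supported. \code{"bx"} appends the barcode to
#' the read name as \code{BX:Z:<barcode>-1} (the aligner-ready convention).
#' \code{"raw10x"} mimics a Chromium v1 library: the first 16 bp of R1 are
#' the barcode, followed by a 7 bp spacer, then the genomic sequence.
#' \code{readFastqPair(writeFastqPair(x))} is the identity for both.
#'
#' @param pairs data.frame with columns \code{read_id}, \code{barcode},
#'   \code{seq1}, \code{seq2}, \code{qual1}, \code{qual2} (character).
#' @param paths character(2): R1 and R2 output paths (gzipped).
#' @param dialect \code{"bx"} or \code{"raw10x"}.
#' @return \code{paths}, invisibly.
#' @export
writeFastqPair <- function(pairs, paths, dialect = c("bx", "raw10x")) {
    dialect <- match.arg(dialect)
    stopifnot(length(paths) == 2)
    if (nrow(pairs) == 0) {
        for (p in paths) {
            con <- gzfile(p, "wb"); close(con)
        }
        return(invisible(paths))
    }
    if (dialect == "bx") {
        nm1 <- paste0(pairs$read_id, " BX:Z:", pairs$barcode, "-1")
        s1 <- pairs$seq1; q1 <- pairs$qual1
    } else {
        nm1 <- pairs$read_id
        s1 <- paste0(pairs$barcode, .RAW10X_SPACER, pairs$seq1)
        qpad <- strrep("I", 16L + nchar(.RAW10X_SPACER))
        q1 <- paste0(qpad, pairs$qual1)
    }
    nm2 <- if (dialect == "bx") nm1 else pairs$read_id
    x1 <- Biostrings::DNAStringSet(s1); names(x1) <- nm1
    x2 <- Biostrings::DNAStringSet(pairs$seq2); names(x2) <- nm2
    Biostrings::writeXStringSet(x1, paths[1], compress = TRUE,
        format = "fastq", qualities = Biostrings::BStringSet(q1))
    Biostrings::writeXStringSet(x2, paths[2], compress = TRUE,
        format = "fastq", qualities = Biostrings::BStringSet(pairs$qual2))
    invisible(paths)
}

#' @rdname writeFastqPair
#' @export
readFastqPair <- function(paths, dialect = c("bx", "raw10x")) {
    dialect <- match.arg(dialect)
    stopifnot(length(paths) == 2)
    x1 <- Biostrings::readDNAStringSet(paths[1], format = "fastq",
                                       with.qualities = TRUE)
    x2 <- Biostrings::readDNAStringSet(paths[2], format = "fastq",
                                       with.qualities = TRUE)
    if (length(x1) != length(x2))
        stop("I/O error: mate-count mismatch between R1 and R2")
    if (length(x1) == 0)
        return(data.frame(read_id = character(), barcode = character(),
                          seq1 = character(), seq2 = character(),
                          qual1 = character(), qual2 = character(),
                          stringsAsFactors = FALSE))
    q1 <- as.character(S4Vectors::mcols(x1)$qualities)
    q2 <- as.character(S4Vectors::mcols(x2)$qualities)
    s1 <- as.character(x1); s2 <- as.character(x2)
    if (dialect == "bx") {
        nm <- names(x1)
        readId <- sub("\\s+BX:Z:.*$", "", nm)
        barcode <- sub("-\\d+$", "", sub("^.*BX:Z:", "", nm))
    } else {
        readId <- names(x1)
        pre <- 16L + nchar(.RAW10X_SPACER)
        barcode <- substr(s1, 1L, 16L)
        s1 <- substring(s1, pre + 1L)
        q1 <- substring(q1, pre + 1L)
    }
    data.frame(read_id = unname(readId), barcode = unname(barcode),
               seq1 = unname(s1), seq2 = unname(s2),
               qual1 = unname(q1), qual2 = unname(q2),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Ground-truth fragment table I/O
#'
#' Columns \code{fragment_id, genome_id, record_id, start, end,
#' partition_id, barcode}; coordinates 0-based half-open on disk.
#'
#' @param fragments \code{GRanges} of simulated fragments (seqnames are
#'   record ids) with metadata columns \code{fragment_id}, \code{genome_id},
#'   \code{partition_id}, \code{barcode}.
#' @param path output TSV path.
#' @return \code{path} / a fragments \code{GRanges}, invisibly for the writer.
#' @export
writeFragmentTruth <- function(fragments, path) {
    df <- data.frame(
        fragment_id = S4Vectors::mcols(fragments)$fragment_id,
        genome_id = S4Vectors::mcols(fragments)$genome_id,
        record_id = as.character(GenomicRanges::seqnames(fragments)),
        start = GenomicRanges::start(fragments) - 1L,
        end = GenomicRanges::end(fragments),
        partition_id = S4Vectors::mcols(fragments)$partition_id,
        barcode = S4Vectors::mcols(fragments)$barcode,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFragmentTruth
#' @export
readFragmentTruth <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
        seqnames = tab$record_id,
        ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end))
    for (col in c("fragment_id", "genome_id", "partition_id", "barcode"))
        S4Vectors::mcols(gr)[[col]] <- tab[[col]]
    gr
}

#' Read-origin truth table I/O
#'
#' Columns \code{read_id, fragment_id, mate1_start, mate2_start}
#' (0-based mate start coordinates on the reference record).
#'
#' @param reads data.frame of simulated read pairs.
#' @param path TSV path.
#' @export
writeReadOrigins <- function(reads, path) {
    df <- data.frame(read_id = reads$read_id, fragment_id = reads$fragment_id,
                     mate1_start = reads$mate1_start - 1L,
                     mate2_start = reads$mate2_start - 1L,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReadOrigins
#' @export
readReadOrigins <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    tab$mate1_start <- tab$mate1_start + 1L
    tab$mate2_start <- tab$mate2_start + 1L
    tab
}

#' Write reconstructed fragments as TSV
#'
#' Columns \code{barcode, reference_id, start, end, length, n_read_pairs}
#' (0-based half-open on disk).
#'
#' @param fragments \code{GRanges} from \code{\link{reconstructFragments}}.
#' @param path output TSV path.
#' @export
writeReconstructedFragments <- function(fragments, path) {
    df <- data.frame(
        barcode = S4Vectors::mcols(fragments)$barcode,
        reference_id = as.character(GenomicRanges::seqnames(fragments)),
        start = GenomicRanges::start(fragments) - 1L,
        end = GenomicRanges::end(fragments),
        length = GenomicRanges::width(fragments),
        n_read_pairs = S4Vectors::mcols(fragments)$n_read_pairs,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
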