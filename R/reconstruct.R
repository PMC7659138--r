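#' Reconstruction parameter set
#'
#' Defaults follow the standard linked-read fragment-calling rule: a growing
#' fragment is terminated when the nearest co-barcoded read is more than
#' 50 kb away, and a called fragment must contain at least two co-barcoded
#' read pairs and span at least 2 kb.
#'
#' @param maxGap termination gap (bp).
#' @param minPairs minimum distinct read pairs per fragment.
#' @param minLength minimum fragment span (bp).
#' @return a \linkS4class{ReconstructionParams}.
#' @export
reconstructionParams <- function(maxGap = 50000, minPairs = 2L,
                                 minLength = 2000) {
    new("ReconstructionParams", maxGap = maxGap,
        minPairs = as.integer(minPairs), minLength = minLength)
}

#' Reconstruct long DNA fragments from co-barcoded alignments
#'
#' Reads are sorted by barcode, then reference, then mapping coordinate,
#' and clustered by greedy extension: a read joins the current cluster when
#' its start is within \code{maxGap} of the cluster's right edge (the
#' rightmost aligned base so far), otherwise it starts a new cluster. Reads
#' of one barcode on different references never share a cluster. Each
#' cluster becomes a fragment spanning its leftmost to rightmost aligned
#' base; clusters with fewer than \code{minPairs} distinct pair ids or a
#' span below \code{minLength} are discarded. A pair whose mates fall into
#' different clusters counts toward both.
#'
#' @param alignments \code{GRanges} with \code{barcode} and \code{pair_id}
#'   metadata columns (from \code{\link{readAlignments}} or
#'   \code{\link{truthAlignments}}); may be unsorted.
#' @param params a \linkS4class{ReconstructionParams}.
#' @return \code{GRanges} of fragments sorted by (reference, start) with
#'   metadata columns \code{barcode}, \code{n_read_pairs}, \code{n_reads}.
#' @export
reconstructFragments <- function(alignments, params = reconstructionParams()) {
    emptyOut <- function() {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$barcode <- character()
        S4Vectors::mcols(gr)$n_read_pairs <- integer()
        S4Vectors::mcols(gr)$n_reads <- integer()
        gr
    }
    if (length(alignments) == 0L) return(emptyOut())
    dt <- data.table::data.table(
        barcode = S4Vectors::mcols(alignments)$barcode,
        ref = as.character(GenomicRanges::seqnames(alignments)),
        start = GenomicRanges::start(alignments),
        end = GenomicRanges::end(alignments),
        pair_id = S4Vectors::mcols(alignments)$pair_id)
    data.table::setorder(dt, barcode, ref, start, end)
    start <- end <- barcode <- ref <- cluster <- pair_id <- NULL # NSE guards
    dt[, cluster := {
        edge <- cummax(data.table::shift(cummax(end), fill = end[1]))
        newc <- c(TRUE, (start - edge)[-1] > params@maxGap)
        cumsum(newc)
    }, by = c("barcode", "ref")]
    agg <- dt[, list(start = min(start), end = max(end),
                     n_read_pairs = length(unique(pair_id)),
                     n_reads = .N),
              by = c("barcode", "ref", "cluster")]
    agg <- agg[agg$n_read_pairs >= params@minPairs &
               (agg$end - agg$start + 1L) >= params@minLength, ]
    data.table::setorder(agg, ref, start)
    if (nrow(agg) == 0L) return(emptyOut())
    gr <- GenomicRanges::GRanges(
        seqnames = agg$ref,
        ranges = IRanges::IRanges(start = agg$start, end = agg$end))
    S4Vectors::mcols(gr)$barcode <- agg$barcode
    S4Vectors::mcols(gr)$n_read_pairs <- agg$n_read_pairs
    S4Vectors::mcols(gr)$n_reads <- agg$n_reads
    gr
}

#' Compare reconstructed fragments with simulation truth
#'
#' A truth fragment counts as recovered when some reconstructed fragment
#' with the same barcode on the same reference overlaps it reciprocally by
#' at least \code{overlapFraction} (the overlap is at least that fraction
#' of both spans). Because reconstruction can only reach the outermost
#' aligned reads, recovered fragments are systematically slightly shorter
#' than the molecules they estimate; \code{length_bias} reports the mean
#' reconstructed/truth length ratio over matched pairs.
#'
#' @param truth \code{GRanges} of true fragments (with \code{barcode}).
#' @param reconstructed \code{GRanges} from
#'   \code{\link{reconstructFragments}}.
#' @param overlapFraction reciprocal overlap threshold in (0, 1].
#' @return list with \code{recall}, \code{precision}, \code{length_bias},
#'   \code{n_truth}, \code{n_reconstructed}.
#' @export
reconstructionRecall <- function(truth, reconstructed,
                                 overlapFraction = 0.8) {
    stopifnot(overlapFraction > 0, overlapFraction <= 1)
    if (length(truth) == 0L)
        return(list(recall = NA_real_, precision = NA_real_,
                    length_bias = NA_real_, n_truth = 0L,
                    n_reconstructed = length(reconstructed)))
    if (length(reconstructed) == 0L)
        return(list(recall = 0, precision = NA_real_, length_bias = NA_real_,
                    n_truth = length(truth), n_reconstructed = 0L))
    hits <- GenomicRanges::findOverlaps(truth, reconstructed)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    sameBc <- S4Vectors::mcols(truth)$barcode[qi] ==
        S4Vectors::mcols(reconstructed)$barcode[si]
    ovl <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(truth)[qi],
        GenomicRanges::ranges(reconstructed)[si]))
    recip <- sameBc &
        ovl >= overlapFraction * GenomicRanges::width(truth)[qi] &
        ovl >= overlapFraction * GenomicRanges::width(reconstructed)[si]
    qi <- qi[recip]; si <- si[recip]
    ratio <- GenomicRanges::width(reconstructed)[si] /
        GenomicRanges::width(truth)[qi]
    list(recall = length(unique(qi)) / length(truth),
         precision = length(unique(si)) / length(reconstructed),
         length_bias = if (length(ratio)) mean(ratio) else NA_real_,
         n_truth = length(truth),
         n_reconstructed = length(reconstructed))
}
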