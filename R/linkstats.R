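#' Estimate the linked-read parameter vector from a fragment set
#'
#' Works on either simulation-truth fragments or reconstructed fragments
#' (any \code{GRanges} with \code{barcode} and \code{n_read_pairs} metadata
#' columns, or a data.frame with \code{length}, \code{barcode},
#' \code{n_read_pairs}). Estimators:
#' \itemize{
#'   \item \code{muFL} — unweighted mean fragment length;
#'   \item \code{WmuFL} — length-weighted mean \eqn{\sum l^2 / \sum l};
#'   \item \code{CF} — \eqn{\sum l / \mathrm{genome\ size}};
#'   \item \code{CR} — unweighted mean over fragments of
#'     \eqn{2 \cdot \mathrm{pairs} \cdot \mathrm{readLength} / l}; the
#'     length-weighted variant \eqn{\sum \mathrm{read\ bases} / \sum l} is
#'     reported as \code{CRWeighted};
#'   \item \code{NFP} — fragments per distinct barcode;
#'   \item \code{C} — total read bases / genome size. The identity
#'     \code{C = CRWeighted * CF} is exact.
#' }
#'
#' @param fragments \code{GRanges} or data.frame as above.
#' @param readLength mate length (bp).
#' @param genomeSize total reference size (bp).
#' @return a \linkS4class{LinkedReadStats}.
#' @export
estimateStats <- function(fragments, readLength, genomeSize) {
    if (genomeSize <= 0) stop("genomeSize must be positive")
    if (is(fragments, "GRanges")) {
        len <- GenomicRanges::width(fragments)
        bc <- S4Vectors::mcols(fragments)$barcode
        np <- S4Vectors::mcols(fragments)$n_read_pairs
    } else {
        len <- fragments$length
        bc <- fragments$barcode
        np <- fragments$n_read_pairs
    }
    n <- length(len)
    if (n == 0L)
        return(new(Class = "LinkedReadStats", C = 0, CR = NA_real_,
                   CRWeighted = NA_real_, CF = 0, muFL = NA_real_,
                   WmuFL = NA_real_, NFP = NA_real_, nFragments = 0L,
                   nReadPairs = 0L, nBarcodes = 0L,
                   genomeSize = genomeSize,
                   readLength = as.integer(readLength)))
    if (is.null(np)) np <- rep(0L, n)
    readBases <- 2 * as.numeric(np) * readLength
    new(Class = "LinkedReadStats",
        C = sum(readBases) / genomeSize,
        CR = mean(readBases / len),
        CRWeighted = sum(readBases) / sum(len),
        CF = sum(len) / genomeSize,
        muFL = mean(len),
        WmuFL = sum(as.numeric(len)^2) / sum(len),
        NFP = n / length(unique(bc)),
        nFragments = as.integer(n),
        nReadPairs = as.integer(sum(np)),
        nBarcodes = length(unique(bc)),
        genomeSize = as.numeric(genomeSize),
        readLength = as.integer(readLength))
}

#' Subsample read pairs
#'
#' Keeps each read pair independently with probability \code{fraction};
#' mates are never separated and barcodes are untouched, so the expected
#' per-fragment read depth \code{C_R} scales by \code{fraction} while the
#' fragment physical depth \code{C_F} is approximately preserved (fragments
#' losing all their reads vanish from any subsequent reconstruction).
#'
#' @param reads data.frame of read pairs (one row per pair, e.g. from
#'   \code{\link{generateReads}} or \code{\link{readFastqPair}}).
#' @param fraction keep probability in [0, 1].
#' @param seed integer seed.
#' @return the subsampled data.frame.
#' @export
subsampleReads <- function(reads, fraction, seed = 1L) {
    if (fraction < 0 || fraction > 1)
        stop("config error: fraction must be in [0, 1]")
    if (fraction == 1) return(reads)
    keep <- withSeed(seed, stats::runif(nrow(reads)) < fraction)
    reads[keep, , drop = FALSE]
}

#' Subsample barcodes (fragment-level subsampling)
#'
#' Keeps each distinct barcode with probability \code{fraction}; all reads
#' of kept barcodes are retained and all reads of dropped barcodes removed.
#' Expected fragment physical depth \code{C_F} scales by \code{fraction}
#' while per-fragment read depth \code{C_R} is unchanged.
#'
#' @inheritParams subsampleReads
#' @param reads data.frame of read pairs with a \code{barcode} column.
#' @export
subsampleBarcodes <- function(reads, fraction, seed = 1L) {
    if (fraction < 0 || fraction > 1)
        stop("config error: fraction must be in [0, 1]")
    if (fraction == 1) return(reads)
    bc <- unique(reads$barcode)
    keepBc <- bc[withSeed(seed, stats::runif(length(bc)) < fraction)]
    reads[reads$barcode %in% keepBc, , drop = FALSE]
}

#' Subsample a FASTQ pair on disk
#'
#' File-level convenience wrapper around \code{\link{subsampleReads}} /
#' \code{\link{subsampleBarcodes}}: reads a barcoded FASTQ pair, subsamples
#' in the requested mode, and writes a new pair in the same dialect.
#'
#' @param inPaths,outPaths character(2) R1/R2 paths.
#' @param mode \code{"reads"} or \code{"barcodes"}.
#' @param fraction keep probability in [0, 1].
#' @param seed integer seed.
#' @param dialect FASTQ barcode dialect.
#' @return number of pairs written, invisibly.
#' @export
subsampleFastqPair <- function(inPaths, outPaths, mode = c("reads", "barcodes"),
                               fraction = 0.5, seed = 1L,
                               dialect = c("bx", "raw10x")) {
    mode <- match.arg(mode)
    dialect <- match.arg(dialect)
    pairs <- readFastqPair(inPaths, dialect)
    out <- if (mode == "reads") subsampleReads(pairs, fraction, seed)
           else subsampleBarcodes(pairs, fraction, seed)
    writeFastqPair(out, outPaths, dialect)
    invisible(nrow(out))
}

#' LinkedReadStats as a plain list (for JSON/manifest output)
#'
#' @param stats a \linkS4class{LinkedReadStats}.
#' @return named list of the estimates and counts.
#' @export
statsAsList <- function(stats) {
    list(C = stats@C, C_R = stats@CR, C_R_weighted = stats@CRWeighted,
         C_F = stats@CF, mu_FL = stats@muFL, W_mu_FL = stats@WmuFL,
         N_FP = stats@NFP, n_fragments = stats@nFragments,
         n_read_pairs = stats@nReadPairs, n_barcodes = stats@nBarcodes,
         genome_size = stats@genomeSize, read_length = stats@readLength)
}
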