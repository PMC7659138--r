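#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Community profile: genomes with molarities and normalized abundances
#'
#' Holds the reference genomes of a defined microbial community together with
#' their input molarities and the relative abundances \eqn{A_i} obtained by
#' normalizing molarity to sum to one. A genome may consist of several
#' replicons (chromosome plus plasmids); \code{records} stores every replicon
#' sequence and \code{recordGenome} maps each record back to its genome.
#' Sequences are optional: lengths alone support depth-budget arithmetic,
#' sequences are required only for read simulation.
#'
#' @slot genomeId character, one id per genome (opaque strings).
#' @slot lengthBp numeric, genome size \eqn{L_i} in bp (sum over records).
#' @slot molarity numeric, input molar concentration per genome.
#' @slot abundance numeric, normalized relative abundance \eqn{A_i}.
#' @slot records \code{DNAStringSet} of replicon sequences (may be empty).
#' @slot recordGenome character mapping each record to a genome id.
#'
#' @export
setClass("CommunityProfile",
    representation(
        genomeId = "character",
        lengthBp = "numeric",
        molarity = "numeric",
        abundance = "numeric",
        records = "DNAStringSet",
        recordGenome = "character"
    )
)

setValidity("CommunityProfile", function(object) {
    msg <- character()
    n <- length(object@genomeId)
    if (length(object@lengthBp) != n || length(object@molarity) != n ||
        length(object@abundance) != n)
        msg <- c(msg, "genomeId, lengthBp, molarity, abundance must be parallel")
    if (anyDuplicated(object@genomeId))
        msg <- c(msg, "duplicated genome ids")
    if (any(object@molarity < 0))
        msg <- c(msg, "molarities must be nonnegative")
    if (n > 0 && !any(object@molarity > 0))
        msg <- c(msg, "at least one molarity must be positive")
    if (any(object@lengthBp < 1))
        msg <- c(msg, "genome lengths must be >= 1 bp")
    if (n > 0 && abs(sum(object@abundance) - 1) > 1e-9)
        msg <- c(msg, "abundances must sum to 1 (within 1e-9)")
    if (length(object@records) > 0) {
        if (length(object@recordGenome) != length(object@records))
            msg <- c(msg, "recordGenome must be parallel to records")
        if (!all(object@recordGenome %in% object@genomeId))
            msg <- c(msg, "recordGenome refers to unknown genome ids")
        seqLen <- tapply(Biostrings::width(object@records),
                         factor(object@recordGenome, levels = object@genomeId),
                         sum, default = NA_real_)
        have <- !is.na(seqLen)
        if (any(object@lengthBp[have] != seqLen[have]))
            msg <- c(msg, "lengthBp disagrees with record sequence lengths")
    }
    if (length(msg)) msg else TRUE
})

#' Linked-read simulation configuration
#'
#' The parameter vector of a linked-read library: global fragment physical
#' depth \code{CF} (X), per-fragment short-read depth \code{CR} (X), mean
#' unweighted fragment length \code{muFL} (bp), mean fragments per partition
#' \code{NFP}, read geometry and the substitution error rate. The implied
#' total read depth is \code{C = CR * CF}.
#'
#' @slot CF numeric, fragment physical depth in X.
#' @slot CR numeric, average short-read depth per fragment in X.
#' @slot muFL numeric, mean (unweighted) fragment length in bp.
#' @slot NFP numeric, mean fragments per barcode partition.
#' @slot readLength integer, mate length in bp (default 150).
#' @slot insertMean integer, mean insert size in bp.
#' @slot insertSd numeric, insert size standard deviation in bp.
#' @slot errorRate numeric, per-base substitution probability.
#' @slot minFragmentLength integer, lower truncation of fragment lengths (bp).
#' @slot fragLenDist "exponential" (truncated) or "lognormal".
#' @slot seed integer, master seed; module sub-streams are derived from it.
#'
#' @export
setClass("SimulationConfig",
    representation(
        CF = "numeric", CR = "numeric", muFL = "numeric", NFP = "numeric",
        readLength = "integer", insertMean = "integer", insertSd = "numeric",
        errorRate = "numeric", minFragmentLength = "integer",
        fragLenDist = "character", seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@CF < 0 || object@CR < 0) msg <- c(msg, "depths must be >= 0")
    if (object@readLength < 1L) msg <- c(msg, "readLength must be >= 1")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must be in [0, 1)")
    if (object@NFP < 1) msg <- c(msg, "NFP must be >= 1")
    if (object@muFL <= object@minFragmentLength)
        msg <- c(msg, "muFL must exceed minFragmentLength")
    if (!object@fragLenDist %in% c("exponential", "lognormal"))
        msg <- c(msg, "fragLenDist must be 'exponential' or 'lognormal'")
    if (length(msg)) msg else TRUE
})

#' Greedy fragment-reconstruction parameters
#'
#' @slot maxGap numeric, termination gap in bp: a co-barcoded read farther
#'   than this from the growing cluster's right edge starts a new fragment
#'   (default 50 kb).
#' @slot minPairs integer, minimum distinct read pairs per fragment
#'   (default 2).
#' @slot minLength numeric, minimum fragment span in bp (default 2 kb).
#'
#' @export
setClass("ReconstructionParams",
    representation(maxGap = "numeric", minPairs = "integer",
                   minLength = "numeric")
)

setValidity("ReconstructionParams", function(object) {
    if (object@maxGap <= 0 || object@minPairs <= 0L || object@minLength <= 0)
        "maxGap, minPairs and minLength must all be positive"
    else TRUE
})

#' Estimated linked-read parameter vector
#'
#' Summary statistics of a fragment set: total read depth \code{C}, the
#' per-fragment read depth \code{CR} (unweighted mean over fragments) and its
#' length-weighted variant \code{CRWeighted}, fragment physical depth
#' \code{CF}, unweighted and length-weighted mean fragment lengths
#' \code{muFL} / \code{WmuFL}, and mean fragments per barcode \code{NFP}.
#' The identity \code{C == CRWeighted * CF} is exact by construction;
#' \code{WmuFL >= muFL} always (Cauchy-Schwarz).
#'
#' @export
setClass("LinkedReadStats",
    representation(
        C = "numeric", CR = "numeric", CRWeighted = "numeric", CF = "numeric",
        muFL = "numeric", WmuFL = "numeric", NFP = "numeric",
        nFragments = "integer", nReadPairs = "integer", nBarcodes = "integer",
        genomeSize = "numeric", readLength = "integer"
    )
)

setMethod("show", "CommunityProfile", function(object) {
    cat("CommunityProfile with", length(object@genomeId), "genomes,",
        length(object@records), "sequence records\n")
    cat("  total size:", format(sum(object@lengthBp), big.mark = ","), "bp\n")
    cls <- classifyAbundance(object@molarity)
    for (g in seq_along(object@genomeId))
        cat(sprintf("  %-12s L=%10.0f  molarity=%.3g  A=%.4f  [%s]\n",
                    object@genomeId[g], object@lengthBp[g], object@molarity[g],
                    object@abundance[g], as.character(cls[g])))
    invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  C_F = %gX, C_R = %gX  (implied C = %gX)\n",
                object@CF, object@CR, object@CF * object@CR))
    cat(sprintf("  mu_FL = %g bp (%s, min %d bp), N_F/P = %g\n",
                object@muFL, object@fragLenDist, object@minFragmentLength,
                object@NFP))
    cat(sprintf("  reads 2 x %d bp, insert %d +/- %g bp, error %g, seed %d\n",
                object@readLength, object@insertMean, object@insertSd,
                object@errorRate, object@seed))
    invisible(object)
})

setMethod("show", "ReconstructionParams", function(object) {
    cat(sprintf(
        "ReconstructionParams: maxGap = %g bp, minPairs = %d, minLength = %g bp\n",
        object@maxGap, object@minPairs, object@minLength))
    invisible(object)
})

setMethod("show", "LinkedReadStats", function(object) {
    cat("LinkedReadStats\n")
    cat(sprintf("  C    = %8.3fX   (total read bases / genome size)\n", object@C))
    cat(sprintf("  C_R  = %8.3fX   (unweighted; length-weighted %.3fX)\n",
                object@CR, object@CRWeighted))
    cat(sprintf("  C_F  = %8.3fX\n", object@CF))
    cat(sprintf("  mu_FL = %7.0f bp  W_mu_FL = %7.0f bp\n",
                object@muFL, object@WmuFL))
    cat(sprintf("  N_F/P = %7.2f    (%d fragments / %d barcodes, %d read pairs)\n",
                object@NFP, object@nFragments, object@nBarcodes,
                object@nReadPairs))
    invisible(object)
})
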