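#' Classify assembly bins into draft-genome quality tiers
#'
#' MIMAG-style triage, evaluated in strict precedence order:
#' \itemize{
#'   \item \strong{HIGH}: completeness > 90\%, contamination < 5\%, at
#'     least one each of the 5S, 16S and 23S rRNAs, and >= 18 tRNAs;
#'   \item \strong{MEDIUM}: completeness >= 50\% and contamination < 10\%;
#'   \item \strong{LOW}: completeness < 50\% and contamination < 10\%;
#'   \item \strong{OTHER}: everything else (in practice, contamination
#'     >= 10\% bins that fail HIGH).
#' }
#' HIGH, MEDIUM and LOW bins count as draft genomes. The precedence makes
#' the mapping total: a 95\%-complete, 3\%-contaminated bin missing an rRNA
#' is MEDIUM, not unclassified.
#'
#' @param bins data.frame with columns \code{completeness},
#'   \code{contamination}, \code{has_5S}, \code{has_16S}, \code{has_23S}
#'   (logical), \code{n_tRNA}.
#' @return factor with levels HIGH, MEDIUM, LOW, OTHER.
#' @examples
#' classifyBin(data.frame(completeness = 95, contamination = 3,
#'   has_5S = TRUE, has_16S = TRUE, has_23S = TRUE, n_tRNA = 20))
#' @export
classifyBin <- function(bins) {
    if (any(bins$completeness < 0 | bins$completeness > 100))
        stop("validation error: completeness outside [0, 100]")
    if (any(bins$contamination < 0))
        stop("validation error: negative contamination")
    high <- bins$completeness > 90 & bins$contamination < 5 &
        bins$has_5S & bins$has_16S & bins$has_23S & bins$n_tRNA >= 18
    medium <- !high & bins$completeness >= 50 & bins$contamination < 10
    low <- !high & !medium & bins$completeness < 50 & bins$contamination < 10
    out <- rep("OTHER", nrow(bins))
    out[low] <- "LOW"; out[medium] <- "MEDIUM"; out[high] <- "HIGH"
    factor(out, levels = c("HIGH", "MEDIUM", "LOW", "OTHER"))
}

#' Bin abundance statistic
#'
#' \deqn{\mathrm{abundance} = \frac{\mathrm{size(bin)} \cdot
#' \mathrm{dp(bin)}}{\mathrm{len(read)} \cdot \mathrm{sum(read)}}}
#' where size(bin) is the bin's total nucleotides, dp(bin) its read depth,
#' len(read) the short-read length and sum(read) the total number of
#' aligned reads.
#'
#' @param sizeBp bin size in bp.
#' @param depth bin read depth (X).
#' @param readLength read length (bp).
#' @param totalAlignedReads total aligned reads in the sample.
#' @return numeric abundance.
#' @export
binAbundance <- function(sizeBp, depth, readLength, totalAlignedReads) {
    if (any(readLength <= 0) || any(totalAlignedReads <= 0))
        stop("validation error: zero denominator in bin abundance")
    if (any(sizeBp < 0) || any(depth < 0))
        stop("validation error: negative bin size or depth")
    sizeBp * depth / (readLength * totalAlignedReads)
}

#' Assembly contiguity statistics N50 / NG50
#'
#' N50 is the largest length \code{L} such that contigs of length >= L sum
#' to at least half of the total assembly length; NG50 uses half of a
#' reference size instead, and is reported as 0 when the assembly does not
#' reach half the reference.
#'
#' @param contigLengths positive contig lengths (bp).
#' @param referenceSize optional reference size for NG50 (bp).
#' @return list with \code{N50} and \code{NG50} (NA when no reference is
#'   given).
#' @export
computeN50 <- function(contigLengths, referenceSize = NULL) {
    if (length(contigLengths) == 0)
        return(list(N50 = NA_real_, NG50 = NA_real_))
    if (any(contigLengths <= 0)) stop("contig lengths must be positive")
    s <- sort(contigLengths, decreasing = TRUE)
    cs <- cumsum(as.numeric(s))
    n50 <- s[which(cs >= sum(as.numeric(s)) / 2)[1]]
    ng50 <- NA_real_
    if (!is.null(referenceSize)) {
        i <- which(cs >= referenceSize / 2)
        ng50 <- if (length(i)) s[i[1]] else 0
    }
    list(N50 = as.numeric(n50), NG50 = as.numeric(ng50))
}

#' Summarize an assembly's bins by quality tier
#'
#' Per-tier counts with percentages of total bins (rounded half-up to two
#' decimals), total bin length in Mb, and the draft-genome proportion
#' (HIGH + MEDIUM + LOW over total).
#'
#' @param bins data.frame of bin records (see \code{\link{classifyBin}});
#'   a \code{size_bp} column contributes the total length.
#' @param config optional configuration label for the output row.
#' @return one-row data.frame with columns \code{config, n_bins,
#'   total_length_mb, high, medium, low, other, high_pct, medium_pct,
#'   low_pct, other_pct, draft_pct}.
#' @export
summarizeAssembly <- function(bins, config = NA_character_) {
    tier <- classifyBin(bins)
    n <- nrow(bins)
    cnt <- table(tier)
    pct <- if (n > 0) roundHalfUp(100 * as.numeric(cnt) / n, 2) else rep(NA_real_, 4)
    draft <- if (n > 0)
        roundHalfUp(100 * sum(tier != "OTHER") / n, 2) else NA_real_
    totalMb <- if ("size_bp" %in% names(bins))
        sum(bins$size_bp) / 1e6 else NA_real_
    data.frame(config = config, n_bins = n, total_length_mb = totalMb,
               high = as.integer(cnt[["HIGH"]]),
               medium = as.integer(cnt[["MEDIUM"]]),
               low = as.integer(cnt[["LOW"]]),
               other = as.integer(cnt[["OTHER"]]),
               high_pct = pct[1], medium_pct = pct[2], low_pct = pct[3],
               other_pct = pct[4], draft_pct = draft,
               stringsAsFactors = FALSE)
}

#' Read a bin report TSV
#'
#' Neutral tabular bin report with header \code{bin_id, size_bp, depth,
#' completeness, contamination, has_5S, has_16S, has_23S, n_tRNA}.
#'
#' @param path TSV path.
#' @return data.frame of bin records.
#' @export
readBinTsv <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("bin_id", "size_bp", "depth", "completeness", "contamination",
              "has_5S", "has_16S", "has_23S", "n_tRNA")
    if (!all(need %in% names(tab)))
        stop("bin TSV must have columns: ", paste(need, collapse = ", "))
    for (col in c("has_5S", "has_16S", "has_23S"))
        tab[[col]] <- as.logical(tab[[col]])
    tab
}
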