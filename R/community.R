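#' Normalize molarities to relative abundances
#'
#' Converts per-genome molar concentrations to relative abundances
#' \eqn{A_i = m_i / \sum_j m_j}, so that \eqn{\sum A_i = 1}. This is the
#' molarity-first convention of defined mock communities, where staggered
#' molarities span several orders of magnitude.
#'
#' @param molarities numeric vector of nonnegative molarities, at least one
#'   positive.
#' @return numeric vector of abundances summing to 1.
#' @examples
#' normalizeAbundance(c(2e-15, 2e-15, 6e-15))
#' @export
normalizeAbundance <- function(molarities) {
    if (!is.numeric(molarities) || length(molarities) == 0)
        stop("invalid community: molarities must be a nonempty numeric vector")
    if (any(molarities < 0))
        stop("invalid community: negative molarity")
    s <- sum(molarities)
    if (s <= 0)
        stop("invalid community: all molarities are zero")
    molarities / s
}

#' Per-genome fragment physical depth
#'
#' Spreads a predefined global physical depth \code{CF} over the genomes of a
#' community: \eqn{C_{Fi} = C_F \times A_i \times G}, where \eqn{G} is the
#' number of genomes. Under uniform abundance every genome receives exactly
#' \code{CF}; the mean of the per-genome depths equals \code{CF} for any
#' normalized abundance vector.
#'
#' @param CF nonnegative global fragment physical depth (X).
#' @param abundances normalized abundance vector.
#' @param G number of genomes; must equal \code{length(abundances)}.
#' @return numeric vector of per-genome depths \eqn{C_{Fi}} (X).
#' @export
perGenomePhysicalDepth <- function(CF, abundances, G = length(abundances)) {
    if (CF < 0) stop("config error: CF must be >= 0")
    if (G != length(abundances))
        stop("config error: G does not match the abundance vector")
    if (abs(sum(abundances) - 1) > 1e-6)
        stop("config error: abundances are not normalized")
    CF * abundances * G
}

#' Per-genome fragment length budget
#'
#' Total long-fragment length to simulate for each genome:
#' \eqn{M_i = C_{Fi} \times L_i} (bp).
#'
#' @param CFi per-genome physical depths (X).
#' @param lengths genome sizes \eqn{L_i} (bp).
#' @return numeric vector of budgets \eqn{M_i} in bp.
#' @export
fragmentBudget <- function(CFi, lengths) {
    if (length(CFi) != length(lengths))
        stop("config error: CFi and lengths differ in length")
    if (any(CFi < 0) || any(lengths < 0))
        stop("config error: negative input")
    CFi * lengths
}

#' Estimated input nucleotides of a community library
#'
#' \eqn{\sum_i A_i \times L_i \times G}: the expected nucleotide input
#' implied by the abundance-weighted genome sizes.
#'
#' @param abundances normalized abundance vector.
#' @param lengths genome sizes (bp).
#' @param G number of genomes.
#' @return total estimated input nucleotides (bp).
#' @export
estimatedInputNucleotides <- function(abundances, lengths,
                                      G = length(abundances)) {
    if (length(abundances) != length(lengths))
        stop("config error: abundances and lengths differ in length")
    sum(abundances * lengths * G)
}

#' Classify genomes into abundance classes
#'
#' Two presets. \code{"molarity"} buckets simulated-community members by
#' input molarity: LOW below 1e-15, MEDIUM between 1e-15 and 1e-14, HIGH
#' above 1e-14. Boundary values (exactly 1e-15 or 1e-14) fall to the lower
#' class. \code{"mockPercent"} buckets mock-community members by mixture
#' percentage: UH at >= 18, H at >= 1.8, M at >= 0.18, else L.
#'
#' @param x numeric vector: molarities, or percentages for the mock preset.
#' @param preset \code{"molarity"} or \code{"mockPercent"}.
#' @return factor of class labels.
#' @examples
#' classifyAbundance(c(5e-16, 5e-15, 5e-14))
#' classifyAbundance(c(18, 1.8, 0.18, 0.02), preset = "mockPercent")
#' @export
classifyAbundance <- function(x, preset = c("molarity", "mockPercent")) {
    preset <- match.arg(preset)
    if (any(x < 0)) stop("invalid input: negative abundance value")
    if (preset == "molarity") {
        labels <- c("LOW", "MEDIUM", "HIGH")
        out <- ifelse(x > 1e-14, "HIGH", ifelse(x > 1e-15, "MEDIUM", "LOW"))
    } else {
        labels <- c("L", "M", "H", "UH")
        out <- ifelse(x >= 18, "UH",
               ifelse(x >= 1.8, "H",
               ifelse(x >= 0.18, "M", "L")))
    }
    factor(out, levels = labels)
}

#' Construct a community profile
#'
#' @param genomeId character ids, one per genome.
#' @param molarity molarities (or already-normalized abundances; they are
#'   renormalized either way).
#' @param lengthBp genome sizes in bp; derived from \code{records} when
#'   those are given.
#' @param records optional \code{DNAStringSet} of replicon sequences.
#' @param recordGenome genome id for each record; defaults to record names
#'   when they match genome ids.
#' @return a \linkS4class{CommunityProfile}.
#' @export
communityProfile <- function(genomeId, molarity, lengthBp = NULL,
                             records = NULL, recordGenome = NULL) {
    if (is.null(records)) {
        records <- Biostrings::DNAStringSet()
        recordGenome <- character()
        if (is.null(lengthBp))
            stop("either lengthBp or records must be supplied")
    } else {
        if (is.null(recordGenome)) recordGenome <- names(records)
        lens <- tapply(Biostrings::width(records),
                       factor(recordGenome, levels = genomeId), sum)
        if (anyNA(lens))
            stop("missing sequence records for some genomes")
        lengthBp <- as.numeric(lens)
    }
    new("CommunityProfile", genomeId = as.character(genomeId),
        lengthBp = as.numeric(lengthBp), molarity = as.numeric(molarity),
        abundance = normalizeAbundance(as.numeric(molarity)),
        records = records, recordGenome = as.character(recordGenome))
}

#' Read a community table (TSV) and its genome FASTAs
#'
#' Expects a tab-separated file with header columns \code{genome_id},
#' \code{fasta_path} and \code{molarity} (an \code{abundance} column is
#' accepted in place of molarity; if both are present molarity wins and is
#' renormalized). Relative FASTA paths are resolved against the TSV's
#' directory. A genome's size is the sum of its record lengths.
#'
#' @param path community TSV path.
#' @param loadSequences read the FASTA files (required for simulation);
#'   if \code{FALSE} only lengths are loaded.
#' @return a \linkS4class{CommunityProfile}.
#' @export
readCommunityTsv <- function(path, loadSequences = TRUE) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!"genome_id" %in% names(tab) || !"fasta_path" %in% names(tab))
        stop("community TSV needs 'genome_id' and 'fasta_path' columns")
    if ("molarity" %in% names(tab)) {
        mol <- as.numeric(tab$molarity)
    } else if ("abundance" %in% names(tab)) {
        mol <- as.numeric(tab$abundance)
    } else {
        stop("community TSV needs a 'molarity' or 'abundance' column")
    }
    fa <- tab$fasta_path
    rel <- !grepl("^(/|[A-Za-z]:)", fa)
    fa[rel] <- file.path(dirname(path), fa[rel])
    allRec <- Biostrings::DNAStringSet()
    recGenome <- character()
    for (i in seq_len(nrow(tab))) {
        recs <- readFasta(fa[i])
        allRec <- c(allRec, recs)
        recGenome <- c(recGenome, rep(tab$genome_id[i], length(recs)))
    }
    cp <- communityProfile(tab$genome_id, mol, records = allRec,
                           recordGenome = recGenome)
    if (!loadSequences) {
        cp@records <- Biostrings::DNAStringSet()
        cp@recordGenome <- character()
        validObject(cp)
    }
    cp
}

#' Depth and fragment budgets for a community
#'
#' Bundles the per-genome arithmetic for a global physical depth: per-genome
#' depths \eqn{C_{Fi}}, fragment-length budgets \eqn{M_i}, and the estimated
#' input nucleotides of the library.
#'
#' @param community a \linkS4class{CommunityProfile}.
#' @param CF global fragment physical depth (X).
#' @return a \code{DataFrame} with columns \code{genome_id}, \code{length_bp},
#'   \code{abundance}, \code{CFi}, \code{Mi}; the estimated input nucleotides
#'   and global CF are stored in \code{metadata()}.
#' @export
depthBudget <- function(community, CF) {
    G <- length(community@genomeId)
    CFi <- perGenomePhysicalDepth(CF, community@abundance, G)
    Mi <- fragmentBudget(CFi, community@lengthBp)
    out <- S4Vectors::DataFrame(genome_id = community@genomeId,
                                length_bp = community@lengthBp,
                                abundance = community@abundance,
                                CFi = CFi, Mi = Mi)
    S4Vectors::metadata(out) <- list(
        CF = CF,
        input_nucleotides = estimatedInputNucleotides(
            community@abundance, community@lengthBp, G))
    out
}
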