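#' Build a simulation configuration
#'
#' Defaults follow the common linked-read regime: 2 x 150 bp paired-end
#' reads, shallow per-fragment depth, fragment lengths from a truncated
#' exponential with the requested mean. \code{CR * CF} is the implied total
#' read depth \code{C}.
#'
#' @param CF fragment physical depth (X).
#' @param CR per-fragment read depth (X).
#' @param muFL mean unweighted fragment length (bp).
#' @param NFP mean fragments per partition.
#' @param readLength mate length (bp).
#' @param insertMean,insertSd insert-size model (bp).
#' @param errorRate per-base substitution probability.
#' @param minFragmentLength lower truncation of fragment length (bp).
#' @param fragLenDist \code{"exponential"} or \code{"lognormal"}.
#' @param seed master seed; all module streams derive from it.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(CF = 30, CR = 0.3, muFL = 10000, NFP = 10,
                             readLength = 150L, insertMean = 400L,
                             insertSd = 50, errorRate = 0.001,
                             minFragmentLength = 1000L,
                             fragLenDist = "exponential", seed = 1L) {
    new("SimulationConfig", CF = CF, CR = CR, muFL = muFL, NFP = NFP,
        readLength = as.integer(readLength),
        insertMean = as.integer(insertMean), insertSd = insertSd,
        errorRate = errorRate,
        minFragmentLength = as.integer(minFragmentLength),
        fragLenDist = fragLenDist, seed = as.integer(seed))
}

# Fragment lengths with mean muFL. The truncated exponential is
# minLen + Exp(1/(muFL - minLen)), whose mean is exactly muFL; the lognormal
# alternative matches the mean before truncation at minLen.
.drawFragmentLengths <- function(n, muFL, minLen, dist = "exponential") {
    if (n == 0L) return(numeric())
    if (dist == "exponential") {
        len <- minLen + stats::rexp(n, rate = 1 / (muFL - minLen))
    } else {
        sdlog <- 0.5
        len <- pmax(minLen, stats::rlnorm(n, meanlog = log(muFL) - sdlog^2 / 2,
                                          sdlog = sdlog))
    }
    round(len)
}

#' Sample long fragments for one genome
#'
#' Draws fragments record by record until the cumulative fragment length
#' reaches the record's share of the genome's budget
#' \eqn{M_i = C_{Fi} \times L_i} (the budget is split across replicons
#' proportionally to record length; fragments never span records). The
#' fragment that crosses the budget is kept in full, so realized physical
#' depth is unbiased up to one fragment length. Starts are uniform over
#' valid positions; fragments may overlap. Lengths longer than the record
#' are clipped to the whole record.
#'
#' @param recordLengths named numeric vector: length of each replicon record.
#' @param CFi per-genome physical depth (X).
#' @param muFL mean fragment length (bp); must exceed \code{minLen}.
#' @param minLen minimum fragment length (bp).
#' @param dist \code{"exponential"} or \code{"lognormal"}.
#' @param genomeId genome id stored on the output.
#' @return \code{GRanges} on the records with metadata columns
#'   \code{fragment_id} (filled in later by the orchestrator when missing)
#'   and \code{genome_id}.
#' @export
drawFragments <- function(recordLengths, CFi, muFL, minLen = 1000L,
                          dist = "exponential", genomeId = "genome") {
    if (muFL <= minLen)
        stop("config error: muFL must exceed the minimum fragment length")
    if (CFi < 0) stop("config error: CFi must be >= 0")
    L <- sum(recordLengths)
    Mi <- CFi * L
    starts <- integer(); lens <- integer(); recs <- character()
    for (r in seq_along(recordLengths)) {
        recLen <- recordLengths[[r]]
        budget <- Mi * recLen / L
        if (budget <= 0) next
        total <- 0
        while (total < budget) {
            chunk <- max(16L, ceiling((budget - total) / muFL * 1.5))
            ln <- .drawFragmentLengths(chunk, muFL, minLen, dist)
            ln <- pmin(ln, recLen)
            cum <- total + cumsum(ln)
            take <- which(cum - ln < budget)   # keep the crossing fragment
            ln <- ln[take]
            st <- 1L + floor(stats::runif(length(ln)) * (recLen - ln + 1))
            starts <- c(starts, as.integer(st))
            lens <- c(lens, as.integer(ln))
            recs <- c(recs, rep(names(recordLengths)[r], length(ln)))
            total <- if (length(take)) cum[take[length(take)]] else budget
        }
    }
    gr <- GenomicRanges::GRanges(
        seqnames = recs,
        ranges = IRanges::IRanges(start = starts, width = lens))
    S4Vectors::mcols(gr)$genome_id <- rep(genomeId, length(gr))
    gr
}

#' Group fragments into barcoded partitions
#'
#' The number of partitions is \code{round(n / NFP)} (at least 1) and each
#' fragment is assigned to one partition uniformly at random, so partition
#' occupancy is approximately Poisson with mean \code{NFP}. Every partition
#' receives a distinct random 16-mer barcode.
#'
#' @param fragments \code{GRanges} of fragments over all genomes.
#' @param NFP mean fragments per partition (>= 1).
#' @param seed integer seed for assignment and barcode generation.
#' @return the input \code{GRanges} with added \code{partition_id} and
#'   \code{barcode} metadata columns; the partition table (partition_id,
#'   barcode, n_fragments) is in \code{metadata()$partitions}.
#' @export
assignPartitions <- function(fragments, NFP, seed = 1L) {
    if (NFP < 1) stop("config error: NFP must be >= 1")
    n <- length(fragments)
    if (n == 0L) {
        S4Vectors::metadata(fragments)$partitions <-
            data.frame(partition_id = character(), barcode = character(),
                       n_fragments = integer(), stringsAsFactors = FALSE)
        return(fragments)
    }
    withSeed(seed, {
        P <- max(1L, as.integer(round(n / NFP)))
        assn <- sample.int(P, n, replace = TRUE)
        barcodes <- randomBarcodes(P)
    })
    pid <- sprintf("P%06d", seq_len(P))
    S4Vectors::mcols(fragments)$partition_id <- pid[assn]
    S4Vectors::mcols(fragments)$barcode <- barcodes[assn]
    S4Vectors::metadata(fragments)$partitions <-
        data.frame(partition_id = pid, barcode = barcodes,
                   n_fragments = tabulate(assn, nbins = P),
                   stringsAsFactors = FALSE)
    fragments
}

# Truncated-normal insert sizes on [lo, hi] via inverse CDF.
.truncNorm <- function(n, mean, sd, lo, hi) {
    if (n == 0L) return(numeric())
    Fa <- stats::pnorm(lo, mean, sd)
    Fb <- stats::pnorm(hi, mean, sd)
    u <- Fa + stats::runif(n) * (Fb - Fa)
    pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
}

# Substitution errors: each A/C/G/T base replaced, with probability `rate`,
# by one of the three other bases uniformly (cyclic shift by 1..3). N passes
# through unchanged. Operates on a character matrix of equal-width reads.
.addSubstitutions <- function(seqMat, rate) {
    if (rate <= 0) return(seqMat)
    bases <- c("A", "C", "G", "T")
    hit <- stats::runif(length(seqMat)) < rate
    ix <- match(seqMat, bases)           # NA for N
    hit <- which(hit & !is.na(ix))
    if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        seqMat[hit] <- bases[(ix[hit] - 1L + shift) %% 4L + 1L]
    }
    seqMat
}

.qualityChar <- function(errorRate) {
    Q <- if (errorRate > 0) min(41L, as.integer(round(-10 * log10(errorRate)))) else 41L
    rawToChar(as.raw(33L + Q))
}

#' Generate paired-end reads from fragments
#'
#' Each fragment is sequenced to a shallow depth: the number of read pairs
#' is Poisson with mean \code{CR * length / (2 * readLength)}; insert sizes
#' are normal, truncated to \code{[2 * readLength, fragment length]}; the
#' pair is placed uniformly within the fragment, so both mates always lie
#' inside the fragment span. Bases are copied from the reference with iid
#' substitutions at \code{errorRate} (reference N bases pass through); R2
#' carries the reverse complement of the right mate. Fragments too short
#' for one pair (\code{< 2 * readLength + 1}) yield zero pairs and are
#' counted in \code{attr(, "n_too_short")}.
#'
#' @param fragments \code{GRanges} with \code{fragment_id} and \code{barcode}
#'   metadata columns.
#' @param records \code{DNAStringSet} of the reference records the fragment
#'   seqnames refer to.
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return data.frame with one row per pair: \code{read_id, fragment_id,
#'   record_id, barcode, mate1_start, mate2_start} (1-based leftmost base of
#'   each mate on the record) and sequence/quality strings
#'   \code{seq1, seq2, qual1, qual2}.
#' @export
generateReads <- function(fragments, records, cfg, seed = 1L) {
    rl <- cfg@readLength
    w <- GenomicRanges::width(fragments)
    tooShort <- w < 2L * rl + 1L
    if (any(tooShort))
        warning(sum(tooShort), " fragment(s) shorter than one read pair; ",
                "zero pairs generated for them")
    out <- withSeed(seed, {
        lambda <- ifelse(tooShort, 0, cfg@CR * w / (2 * rl))
        np <- stats::rpois(length(fragments), lambda)
        idx <- rep(seq_along(fragments), np)
        if (length(idx) == 0L) {
            data.frame(read_id = character(), fragment_id = character(),
                       record_id = character(), barcode = character(),
                       mate1_start = integer(), mate2_start = integer(),
                       seq1 = character(), seq2 = character(),
                       qual1 = character(), qual2 = character(),
                       stringsAsFactors = FALSE)
        } else {
            ins <- round(.truncNorm(length(idx), cfg@insertMean, cfg@insertSd,
                                    2 * rl, w[idx]))
            fs <- GenomicRanges::start(fragments)[idx]
            s <- fs + floor(stats::runif(length(idx)) * (w[idx] - ins + 1))
            m1s <- as.integer(s)
            m2s <- as.integer(s + ins - rl)
            rec <- as.character(GenomicRanges::seqnames(fragments))[idx]
            fid <- S4Vectors::mcols(fragments)$fragment_id[idx]
            ord <- order(idx)
            within <- sequence(np[np > 0L])
            readId <- character(length(idx))
            readId[ord] <- sprintf("%s:%04d", fid[ord], within)
            seq1 <- .extractReadSeqs(records, rec, m1s, rl, cfg@errorRate)
            seq2 <- .extractReadSeqs(records, rec, m2s, rl, cfg@errorRate)
            seq2 <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(seq2)))
            qc <- strrep(.qualityChar(cfg@errorRate), rl)
            data.frame(read_id = readId, fragment_id = fid, record_id = rec,
                       barcode = S4Vectors::mcols(fragments)$barcode[idx],
                       mate1_start = m1s, mate2_start = m2s,
                       seq1 = seq1, seq2 = seq2,
                       qual1 = qc, qual2 = qc, stringsAsFactors = FALSE)
        }
    })
    attr(out, "n_too_short") <- sum(tooShort)
    out
}

.extractReadSeqs <- function(records, rec, starts, rl, errorRate) {
    seqs <- character(length(rec))
    for (r in unique(rec)) {
        i <- which(rec == r)
        v <- Biostrings::extractAt(records[[r]],
                IRanges::IRanges(start = starts[i], width = rl))
        seqs[i] <- as.character(v)
    }
    if (errorRate > 0 && length(seqs)) {
        m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(seqs), byrow = TRUE)
        m <- .addSubstitutions(m, errorRate)
        seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    seqs
}

#' Simulate a linked-read library for a community
#'
#' End-to-end driver: computes the per-genome depth budget, samples long
#' fragments, groups them into barcoded partitions, generates error-bearing
#' paired-end reads, and writes the library to \code{outDir}: gzipped R1/R2
#' FASTQ in the chosen barcode dialect, ground-truth fragment and
#' read-origin TSVs, and a JSON manifest echoing the configuration alongside
#' the realized parameter values (C, C_R, C_F, mu_FL, W_mu_FL, N_F/P).
#'
#' @param community a \linkS4class{CommunityProfile} with sequences loaded.
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if needed).
#' @param dialect FASTQ barcode dialect, \code{"bx"} or \code{"raw10x"}.
#' @return invisibly, a list with the truth \code{fragments} (GRanges), the
#'   \code{reads} data.frame, the \code{manifest} list and output
#'   \code{paths}.
#' @export
simulateLinkedReads <- function(community, cfg, outDir,
                                dialect = c("bx", "raw10x")) {
    dialect <- match.arg(dialect)
    if (length(community@records) == 0)
        stop("community has no sequences loaded; simulation needs them")
    .assertWritableDir(outDir)
    budget <- depthBudget(community, cfg@CF)

    frags <- withSeed(subSeed(cfg@seed, "fragments"), {
        res <- GenomicRanges::GRangesList(lapply(
            seq_along(community@genomeId), function(g) {
                recIdx <- community@recordGenome == community@genomeId[g]
                recLen <- structure(
                    as.numeric(Biostrings::width(community@records[recIdx])),
                    names = names(community@records)[recIdx])
                drawFragments(recLen, budget$CFi[g], cfg@muFL,
                              cfg@minFragmentLength, cfg@fragLenDist,
                              genomeId = community@genomeId[g])
            }))
        unlist(res, use.names = FALSE)
    })
    if (length(frags))
        S4Vectors::mcols(frags)$fragment_id <- sprintf("F%07d", seq_along(frags))
    frags <- assignPartitions(frags, cfg@NFP, subSeed(cfg@seed, "partitions"))
    reads <- generateReads(frags, community@records, cfg,
                           subSeed(cfg@seed, "reads"))

    # realized per-fragment pair counts -> realized parameter vector
    npairs <- integer(length(frags))
    tab <- table(factor(reads$fragment_id,
                        levels = S4Vectors::mcols(frags)$fragment_id))
    npairs <- as.integer(tab)
    S4Vectors::mcols(frags)$n_read_pairs <- npairs
    genomeSize <- sum(community@lengthBp)
    realized <- estimateStats(frags, cfg@readLength, genomeSize)

    paths <- list(
        r1 = file.path(outDir, "reads_R1.fastq.gz"),
        r2 = file.path(outDir, "reads_R2.fastq.gz"),
        fragments = file.path(outDir, "fragments_truth.tsv"),
        readOrigins = file.path(outDir, "read_origins.tsv"),
        manifest = file.path(outDir, "manifest.json"))
    writeFastqPair(reads, c(paths$r1, paths$r2), dialect)
    writeFragmentTruth(frags, paths$fragments)
    writeReadOrigins(reads, paths$readOrigins)

    manifest <- list(
        tool = "LinkedReadTools",
        version = as.character(utils::packageVersion("LinkedReadTools")),
        dialect = dialect,
        seed = cfg@seed,
        config = list(CF = cfg@CF, CR = cfg@CR, muFL = cfg@muFL,
                      NFP = cfg@NFP, readLength = cfg@readLength,
                      insertMean = cfg@insertMean, insertSd = cfg@insertSd,
                      errorRate = cfg@errorRate,
                      minFragmentLength = cfg@minFragmentLength,
                      fragLenDist = cfg@fragLenDist,
                      implied_C = cfg@CR * cfg@CF),
        community = list(G = length(community@genomeId),
                         genome_ids = community@genomeId,
                         input_nucleotides =
                             S4Vectors::metadata(budget)$input_nucleotides),
        realized = list(C = realized@C, C_R = realized@CR,
                        C_R_weighted = realized@CRWeighted,
                        C_F = realized@CF, mu_FL = realized@muFL,
                        W_mu_FL = realized@WmuFL, N_FP = realized@NFP,
                        n_fragments = realized@nFragments,
                        n_read_pairs = realized@nReadPairs,
                        n_barcodes = realized@nBarcodes))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(fragments = frags, reads = reads, manifest = manifest,
                   paths = paths, stats = realized))
}

#' Alignment records from simulation ground truth
#'
#' Turns the simulator's read-origin table into the alignment representation
#' the reconstruction module consumes (two records per pair, at the true
#' mate coordinates) — the idealized error-free aligner.
#'
#' @param reads read-pair data.frame from \code{\link{generateReads}}.
#' @param readLength mate length (bp).
#' @return \code{GRanges} with \code{barcode}, \code{pair_id},
#'   \code{mate_index} metadata columns.
#' @export
truthAlignments <- function(reads, readLength = 150L) {
    n <- nrow(reads)
    gr <- GenomicRanges::GRanges(
        seqnames = rep(reads$record_id, 2L),
        ranges = IRanges::IRanges(
            start = c(reads$mate1_start, reads$mate2_start),
            width = readLength))
    S4Vectors::mcols(gr)$barcode <- rep(reads$barcode, 2L)
    S4Vectors::mcols(gr)$pair_id <- rep(reads$read_id, 2L)
    S4Vectors::mcols(gr)$mate_index <- rep(c(1L, 2L), each = n)
    gr
}
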