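# Deterministic sub-stream seeding: one master seed fans out to named module
# streams so that e.g. re-running read generation alone reproduces its draws.

.streamOffsets <- c(fragments = 101L, partitions = 211L, reads = 307L,
                    barcodes = 401L, subsample = 503L, community = 601L,
                    demo = 701L)

subSeed <- function(seed, stream) {
    stopifnot(stream %in% names(.streamOffsets))
    # keep strictly below 2^31 - 1
    as.integer((as.numeric(seed) %% 65011) * 33029 +
               .streamOffsets[[stream]])
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Half-up decimal rounding (R's round() is banker's rounding).
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# n distinct random barcodes (k-mers over ACGT), mimicking 16-mer GEM barcodes.
randomBarcodes <- function(n, k = 16L) {
    if (n == 0L) return(character())
    bases <- c("A", "C", "G", "T")
    draw <- function(m) {
        mat <- matrix(sample(bases, m * k, replace = TRUE), nrow = m)
        apply(mat, 1L, paste0, collapse = "")
    }
    bc <- unique(draw(n))
    while (length(bc) < n)
        bc <- unique(c(bc, draw(n - length(bc))))
    bc[seq_len(n)]
}

.assertWritableDir <- function(dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    if (file.access(dir, 2L) != 0L)
        stop("output directory not writable: ", dir)
    invisible(dir)
}
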