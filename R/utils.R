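# Internal helpers shared across modules.

# Evaluate `code` under a private PRNG stream seeded with `seed`,
# restoring the caller's random-number state afterwards. Every
# generator routine funnels its randomness through this so that
# identical seed + parameters give byte-identical output regardless of
# the surrounding session state.
withSeed <- function(seed, code) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

# Derive k child seeds from one parent seed; keeps all derived seeds
# well inside 32-bit integer range.
deriveSeeds <- function(seed, k) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Scalar argument checks with informative messages.
checkScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("'", name, "' must be a single finite number", call. = FALSE)
    if (positive && x <= 0)
        stop("'", name, "' must be > 0", call. = FALSE)
    if (nonneg && x < 0)
        stop("'", name, "' must be >= 0", call. = FALSE)
    invisible(x)
}

# 0-based midpoint of a 0-based half-open interval [start0, end0):
# floor((start0 + end0) / 2). Used for fragments and for interval
# annotation alike so the convention cannot drift.
midpoint0 <- function(start0, end0) {
    as.integer(floor((as.numeric(start0) + as.numeric(end0)) / 2))
}

# Convert a GRanges (1-based closed) to 0-based half-open columns.
grToBed0 <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}
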