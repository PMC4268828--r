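# Shared fixtures: all inputs are built in code at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# Write tab-separated lines to a temp file.
writeTempLines <- function(lines, ext = ".bed") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

bedLine <- function(...) paste(..., sep = "\t")

# Small test genome.
testSeqinfo <- function(lengths = c(chrA = 50000L, chrB = 30000L)) {
    GenomeInfoDb::Seqinfo(names(lengths), unname(lengths))
}

# Midpoint GRanges from 0-based positions.
midGR <- function(pos0, chrom = "chrA", si = testSeqinfo()) {
    GRanges(rep(chrom, length(pos0)), IRanges(pos0 + 1L, pos0 + 1L),
            seqinfo = si)
}

# Stranded gene GRanges from 0-based half-open coordinates.
geneGR <- function(start0, end0, strand = "+", chrom = "chrA",
                   si = testSeqinfo(), class = NULL) {
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                  seqinfo = si)
    gr$name <- sprintf("g%02d", seq_along(gr))
    if (!is.null(class)) gr$class <- class
    gr
}

# Brute-force empirical p-value (independent of findInterval).
bruteEmpiricalP <- function(x, null, side) {
    m <- length(null)
    vapply(x, function(xi) {
        cnt <- if (side == "depletion") sum(null >= xi)
               else sum(null <= xi)
        (1 + cnt) / (1 + m)
    }, numeric(1))
}

# Exhaustive two-sided Fisher p for a 2x2 table via log-choose
# enumeration (independent of fisher.test / dhyper).
bruteFisherP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
    support <- max(0L, c1 - r2):min(r1, c1)
    logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
        lchoose(n, c1)
    p <- exp(logp)
    pObs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
    sum(p[p <= pObs * (1 + 1e-7)])
}
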