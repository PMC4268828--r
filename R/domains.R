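# Multi-scale depletion/enrichment domains, peak embedding, genomic
# annotation, IUPAC motif occurrence and Fisher association tests.

#' Multi-scale differential occupancy
#'
#' Runs the windowed occupancy statistic independently at several
#' window sizes (5, 25, 50 and 100 kbp by default) from the same
#' midpoint inputs; per-scale outputs share label semantics.
#'
#' @param t1,t2 Fragment or midpoint GRanges.
#' @param genome Seqinfo.
#' @param scales Window sizes in bp.
#' @param ... Passed to [occupancyLLR()].
#' @return Named list of \linkS4class{OccupancyResult}, one per scale.
#' @export
multiscaleDomains <- function(t1, t2, genome,
                              scales = c(5000, 25000, 50000, 1e5),
                              ...) {
    if (any(scales <= 0))
        stop("scales must be positive")
    t1 <- asMidpoints(t1)
    t2 <- asMidpoints(t2)
    res <- lapply(scales, function(w)
        occupancyLLR(t1, t2, genome = genome, windowSize = w, ...))
    names(res) <- as.character(scales)
    res
}

#' Peak embedding in domains by overlap fraction
#'
#' For every peak, the fraction of its length covered by the union of
#' the domains; a peak is embedded when that fraction reaches
#' \code{minFrac} (25%% by default). With \code{relative =
#' "domain"} the fraction is computed relative to the overlapped
#' domain length instead of the peak length.
#'
#' @param peaks GRanges of peaks (positive width required).
#' @param domains GRanges of domains (for example
#'   [depletedWindows()]).
#' @param minFrac Embedding threshold in (0, 1\].
#' @param relative Denominator of the overlap fraction.
#' @return List with \code{peaks} (input plus metadata
#'   \code{overlapFraction}, \code{embedded}), \code{nEmbedded},
#'   \code{nPeaks} and the 2x2 \code{contingency} of embedded vs not.
#' @export
overlapEmbedded <- function(peaks, domains, minFrac = 0.25,
                            relative = c("peak", "domain")) {
    relative <- match.arg(relative)
    if (minFrac <= 0 || minFrac > 1)
        stop("'minFrac' must be in (0, 1]")
    if (any(GenomicRanges::width(peaks) == 0L))
        stop("zero-length peak")
    dom <- GenomicRanges::reduce(GenomicRanges::granges(domains),
                                 ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(peaks, dom, ignore.strand = TRUE)
    inter <- GenomicRanges::pintersect(
        peaks[S4Vectors::queryHits(ov)], dom[S4Vectors::subjectHits(ov)],
        ignore.strand = TRUE)
    covered <- rep(0L, length(peaks))
    if (length(ov)) {
        agg <- tapply(GenomicRanges::width(inter),
                      S4Vectors::queryHits(ov), sum)
        covered[as.integer(names(agg))] <- as.integer(agg)
    }
    denom <- if (relative == "peak") {
        GenomicRanges::width(peaks)
    } else {
        # length of overlapped domain bases, capped at peak coverage;
        # fall back to peak width where no domain is hit
        pmax(covered, GenomicRanges::width(peaks))
    }
    frac <- covered / denom
    out <- peaks
    GenomicRanges::mcols(out)$overlapFraction <- frac
    GenomicRanges::mcols(out)$embedded <- frac >= minFrac
    nEmb <- sum(frac >= minFrac)
    list(peaks = out, nEmbedded = nEmb, nPeaks = length(peaks),
         contingency = matrix(c(nEmb, length(peaks) - nEmb), nrow = 1,
             dimnames = list(NULL, c("embedded", "notEmbedded"))))
}

#' Classify intervals as promoter, intragenic or intergenic
#'
#' Classification is by interval midpoint: \code{promoter} when the
#' midpoint lies within \code{promoterFlank} bp of a TSS (taking
#' precedence over intragenic), \code{intragenic} when inside a gene
#' body, otherwise \code{intergenic}.
#'
#' @param intervals GRanges to classify.
#' @param genes Stranded gene GRanges.
#' @param promoterFlank Promoter half-width around the TSS in bp.
#' @return Factor with levels promoter, intragenic, intergenic.
#' @export
annotateLocation <- function(intervals, genes, promoterFlank = 1000) {
    mids0 <- midpoint0(GenomicRanges::start(intervals) - 1L,
                       GenomicRanges::end(intervals))
    midGr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(intervals),
        IRanges::IRanges(mids0 + 1L, width = 1L))
    tss <- geneTSS(genes)
    prom <- GenomicRanges::resize(tss, width = 2 * promoterFlank + 1,
                                  fix = "center")
    GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
    isProm <- IRanges::overlapsAny(midGr, prom, ignore.strand = TRUE)
    isGenic <- IRanges::overlapsAny(midGr, genes, ignore.strand = TRUE)
    cls <- ifelse(isProm, "promoter",
                  ifelse(isGenic, "intragenic", "intergenic"))
    factor(cls, levels = c("promoter", "intragenic", "intergenic"))
}

#' Exact two-sided p-value of a 2x2 table
#'
#' Conditional on both margins, the first cell is hypergeometric; the
#' two-sided p-value sums the probabilities of all tables whose
#' probability does not exceed that of the observed table (with the
#' customary 1 + 1e-7 relative guard against floating-point ties, as
#' in \code{fisher.test}). Vectorized over tables.
#'
#' @param a,b First row of the table (hits, misses of set A).
#' @param c,d Second row (hits, misses of set B).
#' @return Numeric p-values in (0, 1\].
#' @export
fisherExactP <- function(a, b, c, d) {
    n <- length(a)
    stopifnot(length(b) == n, length(c) == n, length(d) == n)
    p <- numeric(n)
    for (i in seq_len(n)) {
        m1 <- a[i] + b[i]
        m2 <- c[i] + d[i]
        k <- a[i] + c[i]
        lo <- max(0L, k - m2)
        hi <- min(k, m1)
        dens <- stats::dhyper(lo:hi, m1, m2, k)
        p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] *
                                    (1 + 1e-7)]))
    }
    p
}

#' Fisher's exact association between two hit rates
#'
#' Builds the 2x2 table \code{[[aHits, aTotal - aHits], [bHits,
#' bTotal - bHits]]}, reports the sample odds ratio (cross-product
#' ratio) and the exact two-sided hypergeometric p-value
#' ([fisherExactP()]).
#'
#' @param aHits,aTotal Hits and total for set A (for example embedded
#'   peaks of all peaks).
#' @param bHits,bTotal Hits and total for the reference set B (for
#'   example depleted windows of all windows).
#' @return List with \code{oddsRatio}, \code{p} and the \code{table}.
#' @export
fisherAssociation <- function(aHits, aTotal, bHits, bTotal) {
    if (aTotal <= 0 || bTotal <= 0)
        stop("totals must be positive")
    if (aHits > aTotal || bHits > bTotal || aHits < 0 || bHits < 0)
        stop("hits must lie in [0, total]")
    tab <- matrix(c(aHits, aTotal - aHits, bHits, bTotal - bHits),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("hit", "miss")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("empty margin in the 2x2 table")
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    p <- fisherExactP(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    list(oddsRatio = or, p = p, table = tab)
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every 0-based start position where the pattern matches on
#' the forward strand and every position where its reverse complement
#' matches (reported on the minus strand); a palindromic consensus is
#' therefore reported once per strand.
#'
#' @param sequence A DNAString or character sequence.
#' @param pattern IUPAC consensus (default the NF-kB consensus
#'   GGRRNNYYCC).
#' @param bothStrands Scan the reverse complement as well.
#' @return data.frame with 0-based \code{start} and \code{strand}.
#' @export
motifScan <- function(sequence, pattern = "GGRRNNYYCC",
                      bothStrands = TRUE) {
    letters <- strsplit(toupper(pattern), "")[[1L]]
    bad <- setdiff(letters, names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
        stop("invalid IUPAC letter(s) in pattern: ",
             paste(unique(bad), collapse = ", "))
    subject <- if (is(sequence, "DNAString")) sequence
               else Biostrings::DNAString(sequence)
    pat <- Biostrings::DNAString(toupper(pattern))
    fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    res <- data.frame(start = BiocGenerics::start(fwd) - 1L,
                      strand = rep("+", length(fwd)))
    if (bothStrands) {
        rcp <- Biostrings::reverseComplement(pat)
        rev <- Biostrings::matchPattern(rcp, subject, fixed = FALSE)
        res <- rbind(res,
            data.frame(start = BiocGenerics::start(rev) - 1L,
                       strand = rep("-", length(rev))))
    }
    res[order(res$start, res$strand), , drop = FALSE]
}
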