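# Gene expression classification from two-time-point counts and
# length-normalized metagene occupancy profiles.

#' Classify genes from two-time-point counts
#'
#' Libraries are normalized with median-of-ratios size factors, the
#' log2 fold-change (later vs earlier) computed on normalized counts,
#' and genes classified by the printed thresholds: \code{up} when
#' log2FC > \code{upCut}, \code{down} when < \code{downCut},
#' \code{constitutive} when |log2FC| <= \code{constBand}. Genes with
#' \code{minReads} raw reads or fewer at either time point are
#' \code{unclassified}.
#'
#' @param countsT1,countsT2 Non-negative count vectors (equal length;
#'   names carried through).
#' @param upCut,downCut,constBand Log2 fold-change thresholds.
#' @param minReads Expression floor (strictly more than this many reads
#'   required at each time point).
#' @return data.frame with \code{gene}, \code{class}, \code{log2FC}
#'   (NA when undefined), \code{readsT1}, \code{readsT2}.
#' @export
classifyGenes <- function(countsT1, countsT2, upCut = 0.6,
                          downCut = -0.6, constBand = 0.01,
                          minReads = 100) {
    if (length(countsT1) != length(countsT2))
        stop("count vectors must have equal length")
    if (any(countsT1 < 0) || any(countsT2 < 0))
        stop("counts must be non-negative")
    if (sum(countsT1) == 0 || sum(countsT2) == 0)
        stop("a library has zero total counts")
    m <- cbind(t1 = countsT1, t2 = countsT2)
    sf <- tryCatch(DESeq2::estimateSizeFactorsForMatrix(m),
        error = function(e) colSums(m) / mean(colSums(m)))
    norm <- sweep(m, 2, sf, "/")
    log2FC <- log2(norm[, "t2"] / norm[, "t1"])
    log2FC[!is.finite(log2FC)] <- NA_real_
    pass <- countsT1 > minReads & countsT2 > minReads
    cls <- rep("unclassified", length(countsT1))
    cls[pass & !is.na(log2FC) & log2FC > upCut] <- "up"
    cls[pass & !is.na(log2FC) & log2FC < downCut] <- "down"
    cls[pass & !is.na(log2FC) & abs(log2FC) <= constBand] <- "constitutive"
    nm <- names(countsT1)
    if (is.null(nm)) nm <- sprintf("gene_%03d", seq_along(countsT1))
    data.frame(gene = nm, class = cls, log2FC = unname(log2FC),
               readsT1 = unname(countsT1), readsT2 = unname(countsT2))
}

# Midpoint counts of one chromosome in 50-bp (flankBin) windows over
# [from0, to0), half-open per window; smid must be the sorted 0-based
# midpoints.
binCounts <- function(smid, from0, to0, binSize) {
    edges <- seq(from0, to0, by = binSize)
    if (edges[length(edges)] < to0) edges <- c(edges, to0)
    diff(findInterval(edges - 0.5, smid))
}

# Area-weighted rescaling of a piecewise-constant bin vector onto nOut
# bins: each output bin averages the input bins it overlaps, with
# fractional weights. Conserves flat inputs exactly and keeps the mass
# of narrow features when downscaling (unlike point sampling).
rescaleBins <- function(v, nOut) {
    k <- length(v)
    if (k == nOut) return(as.numeric(v))
    cum <- c(0, cumsum(as.numeric(v)))   # integral at input-bin edges
    at <- function(x) {                  # integral of v over [0, x]
        i <- pmin(pmax(floor(x), 0), k - 1)
        cum[i + 1] + (x - i) * v[i + 1]
    }
    edges <- seq(0, k, length.out = nOut + 1)
    diff(at(edges)) / (k / nOut)
}

#' Length-normalized metagene occupancy profile
#'
#' Genes are aligned at their TSS and TTS. Unscaled flanks of
#' \code{flank} bp in \code{flankBin}-bp bins precede and follow the
#' gene body, whose \code{flankBin}-bp window counts are rescaled onto
#' a fixed \code{bodyBins}-bin axis by area-weighted averaging (which
#' preserves flat profiles exactly and conserves the mass of narrow
#' features). Minus-strand genes
#' are reversed so the TSS is always leftmost. Per-bin counts are
#' summed over genes (set \code{perMillion} for reads-per-million
#' scaling); flank bins beyond a chromosome end are masked and skipped.
#'
#' @param midpoints GRanges of fragment midpoints (or fragments).
#' @param genes Stranded gene GRanges; bodies shorter than
#'   \code{bodyBins} bp are skipped with a warning.
#' @param bodyBins Number of scaled body bins.
#' @param flank Flank length in bp.
#' @param flankBin Flank (and body pre-scaling) bin size in bp.
#' @param perMillion Scale the profile to reads per million midpoints.
#' @return data.frame with \code{bin} (1-based profile position),
#'   \code{zone} (upstream/body/downstream), \code{signal} and
#'   \code{nGenes} (genes contributing to the bin); attribute
#'   \code{nGenesUsed} records how many genes entered the profile.
#' @export
metageneProfile <- function(midpoints, genes, bodyBins = 100,
                            flank = 5000, flankBin = 50,
                            perMillion = FALSE) {
    if (!length(genes))
        stop("empty gene set")
    midpoints <- asMidpoints(midpoints)
    nFlank <- as.integer(flank / flankBin)
    total <- nFlank + bodyBins + nFlank
    perChrom <- lapply(
        split(GenomicRanges::start(midpoints) - 1L,
              GenomicRanges::seqnames(midpoints)), sort)
    sl <- GenomeInfoDb::seqlengths(midpoints)
    profile <- numeric(total)
    nGenes <- integer(total)
    used <- 0L
    skipped <- 0L
    for (i in seq_along(genes)) {
        cn <- as.character(GenomicRanges::seqnames(genes[i]))
        smid <- perChrom[[cn]]
        if (is.null(smid)) smid <- integer(0)
        s0 <- GenomicRanges::start(genes[i]) - 1L
        e0 <- GenomicRanges::end(genes[i])
        minus <- as.character(GenomicRanges::strand(genes[i])) == "-"
        bodyLen <- e0 - s0
        if (bodyLen < bodyBins) {
            skipped <- skipped + 1L
            next
        }
        # body: 50-bp window counts rescaled onto bodyBins positions
        v <- binCounts(smid, s0, e0, flankBin)
        body <- rescaleBins(v, bodyBins)
        # flanks: absolute coordinates, truncated at chromosome ends
        flankVec <- function(from0, to0) {
            full <- rep(NA_real_, nFlank)
            lo <- max(from0, 0L)
            hi <- to0
            if (!is.na(sl[cn])) hi <- min(hi, sl[[cn]])
            if (hi <= lo) return(full)
            # offset of the first complete-range bin
            firstBin <- as.integer((lo - from0) / flankBin) + 1L
            cnts <- binCounts(smid, lo, hi, flankBin)
            nb <- min(length(cnts), nFlank - firstBin + 1L)
            full[firstBin:(firstBin + nb - 1L)] <- cnts[seq_len(nb)]
            full
        }
        up <- flankVec(s0 - flank, s0)
        down <- flankVec(e0, e0 + flank)
        if (minus) {
            gene <- c(rev(down), rev(body), rev(up))
        } else {
            gene <- c(up, body, down)
        }
        okBin <- !is.na(gene)
        profile[okBin] <- profile[okBin] + gene[okBin]
        nGenes[okBin] <- nGenes[okBin] + 1L
        used <- used + 1L
    }
    if (skipped)
        warning(skipped, " gene(s) shorter than the body-bin count ",
                "were skipped")
    if (!used)
        stop("no usable genes for the metagene profile")
    if (perMillion)
        profile <- profile * 1e6 / length(midpoints)
    out <- data.frame(bin = seq_len(total),
        zone = rep(c("upstream", "body", "downstream"),
                   c(nFlank, bodyBins, nFlank)),
        signal = profile, nGenes = nGenes)
    attr(out, "nGenesUsed") <- used
    out
}
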