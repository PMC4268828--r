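# Windowed normalized log-likelihood-ratio statistic for differential
# nucleosome occupancy between two MNase-seq time points, with an
# empirical null built from transcriptionally inert windows.
#
# Sign convention: q = log2(R/S) with R the counts at the earlier time
# point, so a positive centred value means lower occupancy at the
# later time (depletion); the right tail of the null tests depletion,
# the left tail enrichment. The display-oriented fold-change track
# (later vs earlier) is the negated centred value.

#' Tile a genome into constant-size windows
#'
#' Each chromosome is tiled from position 0 in non-overlapping windows
#' of \code{windowSize} bp; a terminal remainder window is kept and
#' flagged \code{partial}. Windows never span chromosome boundaries.
#'
#' @param genome A Seqinfo or named vector of chromosome lengths.
#' @param windowSize Window size in bp (> 0).
#' @return GRanges of windows, sorted, with logical metadata column
#'   \code{partial}.
#' @export
tileWindows <- function(genome, windowSize) {
    checkScalar(windowSize, "windowSize", positive = TRUE)
    sl <- if (is(genome, "Seqinfo")) GenomeInfoDb::seqlengths(genome)
          else genome
    grid <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(windowSize),
        cut.last.tile.in.chrom = TRUE)
    GenomicRanges::mcols(grid)$partial <-
        GenomicRanges::width(grid) < windowSize
    grid
}

#' Count fragment midpoints per window
#'
#' Midpoints are assigned to windows half-open: a midpoint at the exact
#' boundary between two windows belongs to the right one. The counts
#' sum to the number of midpoints.
#'
#' @param midpoints Width-1 GRanges of fragment midpoints (fragments of
#'   width > 1 are converted via [fragmentMidpoints()]).
#' @param grid Window GRanges from [tileWindows()].
#' @return Integer count vector, one entry per window.
#' @export
countMidpoints <- function(midpoints, grid) {
    midpoints <- asMidpoints(midpoints)
    sl <- GenomeInfoDb::seqlengths(grid)
    chr <- as.character(GenomicRanges::seqnames(midpoints))
    if (!all(chr %in% names(sl)))
        stop("midpoints on chromosomes absent from the grid: ",
             paste(unique(setdiff(chr, names(sl))), collapse = ", "))
    if (any(GenomicRanges::end(midpoints) > sl[chr]))
        stop("midpoint beyond chromosome end")
    GenomicRanges::countOverlaps(grid, midpoints)
}

#' Per-window log ratio with low-coverage masking
#'
#' Computes q_i = log2((r_i + c) / (k s_i + c)) where c is the
#' pseudocount and k = sum(R)/sum(S) rescales the later library to the
#' depth of the earlier one (\code{normalize = TRUE}, the default).
#' The rescaling makes every downstream quantity exactly invariant to
#' uniform depth changes in either library; with \code{normalize =
#' FALSE} the raw-count ratio of the Methods formula is used and depth
#' differences are absorbed (approximately) by the centring step only.
#' Windows with fewer than \code{minCount} combined (depth-adjusted)
#' reads are masked \code{low_coverage} and excluded from the mean, the
#' null and the labels.
#'
#' @param r,s Integer count vectors at the earlier (t1) and later (t2)
#'   time point.
#' @param pseudocount Pseudocount c >= 0 added to both counts.
#' @param minCount Low-coverage floor on r_i + k s_i.
#' @param normalize Rescale S to R's total depth before the ratio.
#' @return List with \code{q}, logical \code{lowCoverage} mask and the
#'   depth ratio \code{sizeRatio}.
#' @export
logRatio <- function(r, s, pseudocount = 0.5, minCount = 20,
                     normalize = TRUE) {
    checkScalar(pseudocount, "pseudocount", nonneg = TRUE)
    checkScalar(minCount, "minCount", nonneg = TRUE)
    if (length(r) != length(s))
        stop("count vectors must have equal length")
    if (any(r < 0) || any(s < 0))
        stop("counts must be non-negative")
    k <- 1
    if (normalize) {
        if (sum(r) == 0 || sum(s) == 0)
            stop("cannot depth-normalize: a library has zero total counts")
        k <- sum(as.numeric(r)) / sum(as.numeric(s))
    }
    sAdj <- s * k
    lowCoverage <- (r + sAdj) < minCount
    if (pseudocount == 0 &&
        any(r[!lowCoverage] == 0 | sAdj[!lowCoverage] == 0))
        stop("pseudocount = 0 with zero counts in unmasked windows")
    q <- log2((r + pseudocount) / (sAdj + pseudocount))
    list(q = q, lowCoverage = lowCoverage, sizeRatio = k)
}

#' Centre log ratios on their mean
#'
#' Subtracts the mean of q over unmasked windows (Q_mean), so the
#' centred values over scored windows are mean-zero. A uniform library
#' scaling shifts all q by a constant and is absorbed here.
#'
#' @param q Log-ratio vector.
#' @param lowCoverage Logical mask of windows excluded from the mean.
#' @return List with \code{centered} (same length as q) and
#'   \code{qMean}.
#' @export
centerLogRatios <- function(q, lowCoverage = rep(FALSE, length(q))) {
    keep <- !lowCoverage
    if (!any(keep))
        stop("all windows are masked; nothing to centre")
    qMean <- mean(q[keep])
    list(centered = q - qMean, qMean = qMean)
}

#' Build the empirical null from inert windows
#'
#' The null is the empirical distribution of centred values in
#' transcriptionally inert, adequately covered windows; both signs are
#' retained, so the same null serves the depletion (right) and
#' enrichment (left) tails.
#'
#' @param centered Centred log-ratio vector.
#' @param inert Logical vector marking inert windows.
#' @param lowCoverage Logical low-coverage mask.
#' @param minInert Minimum number of usable inert windows.
#' @return An \linkS4class{InertNull}.
#' @export
buildInertNull <- function(centered, inert,
                           lowCoverage = rep(FALSE, length(centered)),
                           minInert = 100) {
    if (length(inert) != length(centered))
        stop("'inert' must be one flag per window")
    use <- inert & !lowCoverage & is.finite(centered)
    n <- sum(use)
    if (n < minInert)
        stop("only ", n, " usable inert windows (need >= ", minInert,
             "); provide a larger genome or more inert regions")
    v <- sort(centered[use])
    if (v[1L] == v[n])
        stop("degenerate null: all inert values identical")
    new("InertNull", values = v, nInert = n)
}

#' One-sided empirical p-values against the inert null
#'
#' Right tail (depletion at the later time point):
#' p = (1 + #\{null >= x\}) / (1 + m); left tail symmetric with <=.
#' The add-one smoothing keeps p in (0, 1\] and recovers the plain
#' 1 - N_cum(x) as the null grows.
#'
#' @param centered Centred values to score.
#' @param null An \linkS4class{InertNull}.
#' @param side \code{"depletion"} (right tail) or \code{"enrichment"}
#'   (left tail).
#' @return Numeric p-values in (0, 1\].
#' @export
empiricalPvalue <- function(centered, null,
                            side = c("depletion", "enrichment")) {
    side <- match.arg(side)
    stopifnot(is(null, "InertNull"))
    v <- null@values
    m <- length(v)
    count <- if (side == "depletion") {
        m - findInterval(centered, v, left.open = TRUE)  # null >= x
    } else {
        findInterval(centered, v)                        # null <= x
    }
    (1 + count) / (1 + m)
}

#' Label windows from two one-sided p-values
#'
#' A window is \code{depleted} when the right-tail p is significant and
#' \code{enriched} when the left-tail p is; otherwise
#' \code{unchanged}. With \code{correction = "BH"} the
#' Benjamini-Hochberg step-up is applied per tail over unmasked windows
#' (rejection at adjusted p <= alpha); with \code{"none"} raw p < alpha
#' is used. Low-coverage windows keep the label \code{low_coverage}.
#'
#' @param pRight,pLeft One-sided p-value vectors.
#' @param alpha Significance level in (0, 1).
#' @param correction \code{"BH"} or \code{"none"}.
#' @param lowCoverage Logical low-coverage mask.
#' @return Character vector of labels.
#' @export
labelWindows <- function(pRight, pLeft, alpha = 0.05,
                         correction = c("BH", "none"),
                         lowCoverage = rep(FALSE, length(pRight))) {
    correction <- match.arg(correction)
    if (alpha <= 0 || alpha >= 1)
        stop("'alpha' must be in (0, 1)")
    stopifnot(length(pRight) == length(pLeft))
    keep <- !lowCoverage
    sigR <- sigL <- logical(length(pRight))
    if (correction == "BH") {
        sigR[keep] <- p.adjust(pRight[keep], method = "BH") <= alpha
        sigL[keep] <- p.adjust(pLeft[keep], method = "BH") <= alpha
    } else {
        sigR[keep] <- pRight[keep] < alpha
        sigL[keep] <- pLeft[keep] < alpha
    }
    # Opposite tails of one value cannot both be significant: the two
    # p-values sum to > 1.
    stopifnot(!any(sigR & sigL))
    label <- rep("unchanged", length(pRight))
    label[sigR] <- "depleted"
    label[sigL] <- "enriched"
    label[lowCoverage] <- "low_coverage"
    label
}

#' Centred running mean
#'
#' Moving average with an odd span; at the edges the window shrinks to
#' the available neighbours. NA values propagate unless
#' \code{na.rm = TRUE}.
#'
#' @param values Numeric vector.
#' @param span Odd window span in array elements (>= 1).
#' @param na.rm Drop NAs from each local mean.
#' @return Smoothed vector of the same length.
#' @export
runningMean <- function(values, span = 5, na.rm = FALSE) {
    checkScalar(span, "span", positive = TRUE)
    if (span %% 2 == 0)
        stop("'span' must be odd")
    n <- length(values)
    if (n == 0L || span == 1)
        return(values)
    h <- (span - 1) / 2
    v <- values
    ok <- rep(1, n)
    if (na.rm) {
        ok <- as.numeric(!is.na(v))
        v[is.na(v)] <- 0
    }
    cs <- c(0, cumsum(v))
    cn <- c(0, cumsum(ok))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1] - cs[lo]) / (cn[hi + 1] - cn[lo])
}

#' Mark inert windows on a grid
#'
#' A window counts as inert when it lies entirely within the supplied
#' inert regions (for example the complement of expressed genes as
#' assessed by RNA-seq, or the ground-truth inert regions of a
#' synthetic experiment).
#'
#' @param grid Window GRanges.
#' @param inertRegions GRanges of inert regions, or a logical vector
#'   (returned unchanged after length-checking), or NULL meaning all
#'   windows are eligible.
#' @return Logical vector, one flag per window.
#' @export
inertMask <- function(grid, inertRegions = NULL) {
    if (is.null(inertRegions))
        return(rep(TRUE, length(grid)))
    if (is.logical(inertRegions)) {
        if (length(inertRegions) != length(grid))
            stop("logical inert mask must match the grid length")
        return(inertRegions)
    }
    IRanges::overlapsAny(grid, GenomicRanges::reduce(inertRegions),
                         type = "within")
}

#' Windows not overlapping expressed genes
#'
#' Convenience inert selector when no explicit inert regions are
#' available: every window overlapping an expressed gene (optionally
#' extended by \code{flank}) is excluded.
#'
#' @param grid Window GRanges.
#' @param expressedGenes GRanges of expressed genes.
#' @param flank Extension of each gene in bp.
#' @return Logical vector, one flag per window.
#' @export
inertFromGenes <- function(grid, expressedGenes, flank = 0) {
    if (!length(expressedGenes))
        return(rep(TRUE, length(grid)))
    !IRanges::overlapsAny(grid,
        GenomicRanges::reduce(expressedGenes + flank,
                              ignore.strand = TRUE),
        ignore.strand = TRUE)
}

#' Differential nucleosome occupancy between two time points
#'
#' Runs the full windowed statistic: count fragment midpoints on a
#' constant-size grid at both time points, form the depth-normalized
#' log2 ratio, centre it on its mean, build the empirical null from
#' inert windows, score both tails and label each window as depleted,
#' enriched, unchanged or low_coverage.
#'
#' @param t1,t2 Fragment or midpoint GRanges for the earlier and later
#'   time point.
#' @param genome Seqinfo (ignored when \code{grid} is given).
#' @param windowSize Window size in bp.
#' @param grid Optional precomputed window GRanges.
#' @param inert Inert regions (GRanges), a logical per-window mask, or
#'   NULL (all windows eligible -- appropriate for landscapes known to
#'   be transcriptionally inert throughout).
#' @param pseudocount,minCount,normalize See [logRatio()].
#' @param alpha,correction See [labelWindows()].
#' @param minInert Minimum usable inert windows for the null.
#' @return An \linkS4class{OccupancyResult}.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrS1", 2e6)
#' spec <- landscapeSpec(chromLengths = c(chrS1 = 2e6), seed = 7,
#'                       baseOccupancy = 10)
#' tr <- simulateLandscape(spec)
#' f1 <- sampleFragments(tr, spec, seed = 1)
#' f2 <- sampleFragments(tr, spec, seed = 2)
#' res <- occupancyLLR(f1, f2, genome = si, windowSize = 5000)
#' table(windowLabels(res))
#' @export
occupancyLLR <- function(t1, t2, genome = NULL, windowSize = 5000,
                         grid = NULL, inert = NULL, pseudocount = 0.5,
                         minCount = 20, normalize = TRUE, alpha = 0.05,
                         correction = c("BH", "none"), minInert = 100) {
    correction <- match.arg(correction)
    if (is.null(grid)) {
        if (is.null(genome))
            stop("supply either 'grid' or 'genome'")
        grid <- tileWindows(genome, windowSize)
    }
    r <- countMidpoints(t1, grid)
    s <- countMidpoints(t2, grid)
    lr <- logRatio(r, s, pseudocount = pseudocount,
                   minCount = minCount, normalize = normalize)
    ctr <- centerLogRatios(lr$q, lr$lowCoverage)
    inertFlag <- inertMask(grid, inert) & !grid$partial
    null <- buildInertNull(ctr$centered, inertFlag, lr$lowCoverage,
                           minInert = minInert)
    pRight <- empiricalPvalue(ctr$centered, null, "depletion")
    pLeft <- empiricalPvalue(ctr$centered, null, "enrichment")
    label <- labelWindows(pRight, pLeft, alpha = alpha,
                          correction = correction,
                          lowCoverage = lr$lowCoverage)
    rr <- grid
    GenomicRanges::mcols(rr) <- S4Vectors::DataFrame(
        partial = grid$partial, q = lr$q, centered = ctr$centered,
        pRight = pRight, pLeft = pLeft, label = label,
        lowCoverage = lr$lowCoverage, inert = inertFlag)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cbind(t1 = r, t2 = s)),
        rowRanges = rr,
        metadata = list(qMean = ctr$qMean, null = null,
            params = list(windowSize = windowSize,
                pseudocount = pseudocount, minCount = minCount,
                normalize = normalize, alpha = alpha,
                correction = correction, sizeRatio = lr$sizeRatio)))
    new("OccupancyResult", se)
}

#' Smoothed fold-change track for display
#'
#' The negated centred log-ratio (later vs earlier time point, matching
#' the orientation of browser fold-change tracks: depletion negative),
#' smoothed with a running mean. Low-coverage windows are NA and are
#' skipped by the smoother.
#'
#' @param x An \linkS4class{OccupancyResult}.
#' @param span Odd running-mean span in windows.
#' @return Numeric vector, one value per window.
#' @export
foldChangeTrack <- function(x, span = 5) {
    stopifnot(is(x, "OccupancyResult"))
    v <- -centeredRatios(x)
    v[SummarizedExperiment::rowData(x)$lowCoverage] <- NA_real_
    runningMean(v, span = span, na.rm = TRUE)
}

#' Write the per-window occupancy table as TSV
#'
#' @param x An \linkS4class{OccupancyResult}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeOccupancyTable <- function(x, path) {
    stopifnot(is(x, "OccupancyResult"))
    bed <- grToBed0(SummarizedExperiment::rowRanges(x))
    cnt <- windowCounts(x)
    rd <- SummarizedExperiment::rowData(x)
    tab <- data.frame(bed, t1 = cnt[, "t1"], t2 = cnt[, "t2"],
        q = rd$q, centered = rd$centered, pRight = rd$pRight,
        pLeft = rd$pLeft, label = rd$label, inert = rd$inert,
        partial = rd$partial)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
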