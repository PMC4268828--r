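# Viewpoint contact analysis: binary fragment-end signal scored in
# multi-scale sliding windows against a randomized background, with a
# permutation-derived FDR threshold, and association of significant
# contacts with nucleosome-depleted windows.

#' Construct a viewpoint contact profile
#'
#' @param chrom Chromosome name.
#' @param ends 0-based fragment-end positions (sorted and unique after
#'   construction).
#' @param reads Read count per end.
#' @param viewpoint 0-based viewpoint position (must be one of the
#'   ends).
#' @return A \linkS4class{ContactProfile}.
#' @export
contactProfile <- function(chrom, ends, reads, viewpoint) {
    ends <- as.integer(ends)
    reads <- as.integer(reads)
    if (anyDuplicated(ends))
        stop("fragment ends must be unique")
    o <- order(ends)
    ends <- ends[o]
    reads <- reads[o]
    viewpoint <- as.integer(viewpoint)
    if (!viewpoint %in% ends)
        stop("viewpoint is not among the fragment ends")
    new("ContactProfile", chrom = as.character(chrom),
        viewpoint = viewpoint, ends = ends, reads = reads,
        binary = binarizeReads(reads))
}

#' Binarize read counts
#'
#' An end is contact-positive iff it carries at least one read;
#' idempotent on binary input.
#'
#' @param reads Non-negative integer vector.
#' @return Integer 0/1 vector.
#' @export
binarizeReads <- function(reads) {
    if (any(reads < 0))
        stop("read counts must be non-negative")
    as.integer(reads >= 1L)
}

# Geometric ladder of window sizes from wmin to wmax.
windowSizeLadder <- function(wmin, wmax, nSizes) {
    unique(as.integer(round(exp(seq(log(wmin), log(wmax),
                                    length.out = nSizes)))))
}

# Index bounds of the ends falling in each sliding window; returns a
# data.frame of windows plus lo/hi indices into the sorted end vector.
slidingWindowIndex <- function(ends, sizes, stepFrac) {
    lo <- min(ends); hi <- max(ends)
    res <- lapply(sizes, function(w) {
        step <- max(1L, as.integer(round(w * stepFrac)))
        starts <- seq(lo, max(lo, hi - w), by = step)
        data.frame(size = w, start = starts, end = starts + w)
    })
    tab <- do.call(rbind, res)
    tab$loIdx <- findInterval(tab$start, ends, left.open = TRUE) + 1L
    tab$hiIdx <- findInterval(tab$end - 1L, ends)  # ends in [start, end)
    tab$nEnds <- tab$hiIdx - tab$loIdx + 1L
    tab
}

# Positive counts per window from a binary vector via prefix sums.
windowPositives <- function(binary, loIdx, hiIdx) {
    cs <- c(0L, cumsum(binary))
    cs[hiIdx + 1L] - cs[loIdx]
}

#' Sliding-window contact enrichment scores
#'
#' For every window of a geometric size ladder (2-200 kbp by default)
#' slid in steps of a tenth of its size, the positive-end fraction is
#' divided by the background positive rate estimated from
#' \code{nBackground} fragment ends sampled uniformly without
#' replacement (all ends when fewer exist). Windows containing fewer
#' than \code{minEnds} ends are masked.
#'
#' @param profile A \linkS4class{ContactProfile} (>= 2 ends).
#' @param wmin,wmax Smallest and largest window size in bp.
#' @param nSizes Number of sizes on the geometric ladder.
#' @param stepFrac Step as a fraction of the window size.
#' @param nBackground Background sample size (fragment ends).
#' @param minEnds Mask windows with fewer ends than this.
#' @param seed Seed for the background sample.
#' @return A \linkS4class{Domainogram} (no significance threshold yet;
#'   see [permutationFDR()]).
#' @export
slidingEnrichment <- function(profile, wmin = 2000, wmax = 200000,
                              nSizes = 12, stepFrac = 0.1,
                              nBackground = 3000, minEnds = 3,
                              seed = 1) {
    stopifnot(is(profile, "ContactProfile"))
    ends <- profile@ends
    if (length(ends) < 2L)
        stop("need at least 2 fragment ends")
    sizes <- windowSizeLadder(wmin, wmax, nSizes)
    tab <- slidingWindowIndex(ends, sizes, stepFrac)
    bgIdx <- withSeed(seed,
        sample.int(length(ends), min(nBackground, length(ends))))
    bgRate <- mean(profile@binary[bgIdx])
    tab$nPos <- windowPositives(profile@binary, tab$loIdx, tab$hiIdx)
    tab$masked <- tab$nEnds < minEnds
    tab$score <- ifelse(tab$masked | bgRate == 0, NA_real_,
                        (tab$nPos / tab$nEnds) / bgRate)
    new("Domainogram", table = tab, chrom = profile@chrom,
        backgroundRate = bgRate, threshold = numeric(0),
        fdr = NA_real_, nPerm = 0L)
}

#' Permutation FDR threshold for a domainogram
#'
#' The binary labels are permuted over the fragment ends \code{nPerm}
#' times and every window rescored exactly as observed (including a
#' background rate re-estimated from the same sampled end indices).
#' The significance threshold is the smallest observed score t such
#' that (mean permuted windows >= t) / (observed windows >= t) falls
#' below \code{fdr}; observed windows at or above it are flagged
#' significant. Degenerate profiles (all ends positive or none) admit
#' no threshold and return an empty significant set with a warning.
#'
#' @param profile The \linkS4class{ContactProfile} that was scored.
#' @param dgram The \linkS4class{Domainogram} from
#'   [slidingEnrichment()].
#' @param nPerm Number of permutations (>= 100).
#' @param fdr Target false discovery rate.
#' @param seed Seed for the permutations (and background re-sampling).
#' @return The \linkS4class{Domainogram} with \code{significant} flags
#'   and the threshold filled in.
#' @export
permutationFDR <- function(profile, dgram, nPerm = 200, fdr = 0.01,
                           seed = 1) {
    stopifnot(is(profile, "ContactProfile"), is(dgram, "Domainogram"))
    if (nPerm < 100)
        stop("need at least 100 permutations")
    tab <- dgram@table
    tab$significant <- FALSE
    binary <- profile@binary
    n <- length(binary)
    if (all(binary == 1L) || all(binary == 0L)) {
        warning("degenerate all-", if (all(binary == 1L)) "positive"
                else "negative", " signal: no threshold determined")
        dgram@table <- tab
        dgram@nPerm <- as.integer(nPerm)
        dgram@fdr <- fdr
        return(dgram)
    }
    open <- !tab$masked
    obs <- tab$score[open]
    permScores <- withSeed(seed, {
        bgN <- min(3000L, n)
        unlist(lapply(seq_len(nPerm), function(k) {
            pb <- sample(binary)
            bgRate <- mean(pb[sample.int(n, bgN)])
            if (bgRate == 0) return(numeric(0))
            pos <- windowPositives(pb, tab$loIdx[open], tab$hiIdx[open])
            (pos / tab$nEnds[open]) / bgRate
        }))
    })
    permSorted <- sort(permScores)
    obsSorted <- sort(obs)
    cand <- sort(unique(obs), decreasing = FALSE)
    nObsGE <- length(obsSorted) -
        findInterval(cand, obsSorted, left.open = TRUE)
    nPermGE <- (length(permSorted) -
        findInterval(cand, permSorted, left.open = TRUE)) / nPerm
    est <- nPermGE / nObsGE
    okIdx <- which(est < fdr)
    if (!length(okIdx)) {
        warning("no score threshold attains FDR < ", fdr)
        dgram@table <- tab
    } else {
        thr <- cand[min(okIdx)]
        tab$significant <- !tab$masked & !is.na(tab$score) &
            tab$score >= thr
        dgram@table <- tab
        dgram@threshold <- thr
    }
    dgram@nPerm <- as.integer(nPerm)
    dgram@fdr <- fdr
    dgram
}

#' Associate significant contacts with depleted windows
#'
#' Counts significant and non-significant contact windows whose
#' midpoint lies in a nucleosome-depleted window and tests the
#' association with Fisher's exact test.
#'
#' @param dgram A \linkS4class{Domainogram} after [permutationFDR()].
#' @param depleted GRanges of depleted windows (same genome).
#' @return List with the 2x2 \code{table}, \code{oddsRatio},
#'   \code{p}, and per-group embedded fractions; NULL (with a message)
#'   when there are no significant contacts.
#' @export
contactsVsDepletion <- function(dgram, depleted) {
    stopifnot(is(dgram, "Domainogram"))
    tab <- dgram@table
    if (!"significant" %in% colnames(tab) ||
        !any(tab$significant, na.rm = TRUE)) {
        message("no significant contacts; association test skipped")
        return(NULL)
    }
    open <- !tab$masked
    mids0 <- midpoint0(tab$start[open], tab$end[open])
    midGr <- GenomicRanges::GRanges(dgram@chrom,
        IRanges::IRanges(mids0 + 1L, width = 1L))
    inDep <- IRanges::overlapsAny(midGr,
        GenomicRanges::reduce(GenomicRanges::granges(depleted),
                              ignore.strand = TRUE),
        ignore.strand = TRUE)
    sig <- tab$significant[open]
    fa <- fisherAssociation(sum(sig & inDep), sum(sig),
                            sum(!sig & inDep), sum(!sig))
    list(table = fa$table, oddsRatio = fa$oddsRatio, p = fa$p,
         fracSignificantInDepleted = mean(inDep[sig]),
         fracOtherInDepleted = mean(inDep[!sig]))
}
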