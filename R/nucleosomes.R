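# Single-nucleosome dyad calling from fragment midpoints and
# classification of repositioning between time points by the >10 bp
# dyad-shift criterion.

#' Kernel-smoothed dyad density
#'
#' Tabulates fragment midpoints per bp and convolves with a discrete
#' Gaussian kernel (normalized to unit sum, truncated at 4 sd), so the
#' total density mass equals the number of midpoints.
#'
#' @param midpoints Integer vector of 0-based midpoint positions on one
#'   chromosome.
#' @param bandwidth Kernel sd in bp (> 0).
#' @param from,to Optional 0-based range to evaluate over (defaults to
#'   the data range extended by 4 bandwidths).
#' @return List of class \code{DyadDensity} with \code{pos} (0-based
#'   positions) and \code{density}.
#' @export
dyadDensity <- function(midpoints, bandwidth = 30, from = NULL,
                        to = NULL) {
    checkScalar(bandwidth, "bandwidth", positive = TRUE)
    midpoints <- as.integer(midpoints)
    half <- as.integer(ceiling(4 * bandwidth))
    if (!length(midpoints)) {
        out <- list(pos = integer(0), density = numeric(0),
                    bandwidth = bandwidth)
        class(out) <- "DyadDensity"
        return(out)
    }
    if (is.null(from)) from <- min(midpoints) - half
    if (is.null(to)) to <- max(midpoints) + half
    from <- as.integer(from); to <- as.integer(to)
    n <- to - from + 1L
    counts <- tabulate(midpoints - from + 1L, nbins = n)
    kern <- dnorm(seq(-half, half), sd = bandwidth)
    kern <- kern / sum(kern)
    # FFT convolution at a 2-3-smooth padded length (an arbitrary
    # length can be near-prime and degrade the FFT badly)
    m <- stats::nextn(n + 2L * half, c(2L, 3L))
    cx <- ck <- numeric(m)
    cx[seq_len(n)] <- counts
    ck[seq_len(2L * half + 1L)] <- kern
    sm <- Re(stats::fft(stats::fft(cx) * stats::fft(ck),
                        inverse = TRUE)) / m
    sm <- sm[seq_len(n + 2L * half)]   # full open convolution
    edge <- sm[c(seq_len(half), half + n + seq_len(half))]
    dens <- sm[(half + 1L):(half + n)]
    # fold truncated tails back so total mass is conserved exactly
    dens[1L] <- dens[1L] + sum(edge[seq_len(half)])
    dens[n] <- dens[n] + sum(edge[half + seq_len(half)])
    dens[dens < 0] <- 0   # FFT round-off
    out <- list(pos = from:to, density = dens, bandwidth = bandwidth)
    class(out) <- "DyadDensity"
    out
}

# Leftmost point of every local maximum (plateaus collapse to their
# left edge).
localMaxima <- function(y) {
    n <- length(y)
    if (n == 0L) return(integer(0))
    r <- rle(y)
    k <- length(r$values)
    starts <- cumsum(r$lengths) - r$lengths + 1L
    leftOK <- c(TRUE, r$values[-1L] > r$values[-k])
    rightOK <- c(r$values[-k] > r$values[-1L], TRUE)
    starts[leftOK & rightOK]
}

#' Greedy dyad calling from a smoothed density
#'
#' Local maxima are visited in order of decreasing height (ties broken
#' by leftmost coordinate); a maximum closer than \code{minSeparation}
#' to an already accepted call is suppressed.
#'
#' @param density A \code{DyadDensity} from [dyadDensity()].
#' @param minSeparation Minimum distance between calls in bp (the
#'   nucleosome footprint, 147 bp, by default).
#' @param minHeight Minimum density height for a candidate maximum.
#' @return data.frame with 0-based \code{dyad} and \code{height},
#'   sorted by position.
#' @export
callDyads <- function(density, minSeparation = 147, minHeight = 0) {
    checkScalar(minSeparation, "minSeparation", positive = TRUE)
    y <- density$density
    if (!length(y))
        return(data.frame(dyad = integer(0), height = numeric(0)))
    cand <- localMaxima(y)
    cand <- cand[y[cand] >= minHeight & y[cand] > 0]
    if (!length(cand))
        return(data.frame(dyad = integer(0), height = numeric(0)))
    ord <- order(-y[cand], density$pos[cand])
    cand <- cand[ord]
    # greedy exclusion via a suppression bitmap over array indices:
    # accepting a call blocks every index closer than minSeparation
    sep <- as.integer(ceiling(minSeparation))
    n <- length(y)
    suppressed <- logical(n)
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
        idx <- cand[i]
        if (!suppressed[idx]) {
            keep[i] <- TRUE
            lo <- max(1L, idx - sep + 1L)
            hi <- min(n, idx + sep - 1L)
            suppressed[lo:hi] <- TRUE
        }
    }
    acc <- cand[keep]
    o <- order(acc)
    data.frame(dyad = as.integer(density$pos[acc[o]]),
               height = y[acc[o]])
}

#' Call nucleosome dyads from fragment midpoints
#'
#' High-level caller: smooths midpoints per chromosome, extracts
#' greedy-separated density maxima, and (by default) refines each dyad
#' coordinate as the intensity-weighted centroid of the raw midpoints
#' within half a nucleosome of the summit -- a sub-grid summit estimate
#' that sharpens shift detection without changing which peaks are
#' called.
#'
#' @param midpoints GRanges of fragment midpoints (or fragments).
#' @param bandwidth Kernel sd in bp.
#' @param minSeparation Minimum call spacing in bp.
#' @param minHeight Minimum smoothed height.
#' @param refine Refine summits by local midpoint centroid.
#' @param refineRadius Centroid radius in bp.
#' @return GRanges of width-1 dyad calls with metadata \code{height}.
#' @export
callNucleosomes <- function(midpoints, bandwidth = 30,
                            minSeparation = 147, minHeight = 0,
                            refine = TRUE, refineRadius = 73) {
    midpoints <- asMidpoints(midpoints)
    perChrom <- split(GenomicRanges::start(midpoints) - 1L,
                      GenomicRanges::seqnames(midpoints))
    out <- lapply(names(perChrom), function(cn) {
        mids <- perChrom[[cn]]
        if (!length(mids)) return(NULL)
        dens <- dyadDensity(mids, bandwidth = bandwidth)
        calls <- callDyads(dens, minSeparation = minSeparation,
                           minHeight = minHeight)
        if (!nrow(calls)) return(NULL)
        dy <- calls$dyad
        if (refine && length(mids)) {
            smid <- sort(mids)
            lo <- findInterval(dy - refineRadius, smid,
                               left.open = TRUE) + 1L
            hi <- findInterval(dy + refineRadius, smid)
            cs <- c(0, cumsum(as.numeric(smid)))
            cnt <- hi - lo + 1L
            use <- cnt > 0L
            dy[use] <- as.integer(round(
                (cs[hi[use] + 1L] - cs[lo[use]]) / cnt[use]))
        }
        GenomicRanges::GRanges(cn, IRanges::IRanges(dy + 1L, width = 1L),
                               height = calls$height)
    })
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out))
        return(GenomicRanges::GRanges())
    sort(do.call(c, out))
}

# Mutual-nearest-neighbour matching of two sorted position vectors
# within maxMatch; returns index pairs.
mutualNearest <- function(a, b, maxMatch) {
    if (!length(a) || !length(b))
        return(cbind(i = integer(0), j = integer(0)))
    nearestIn <- function(x, v) {
        k <- findInterval(x, v)
        lo <- pmax(k, 1L)
        hi <- pmin(k + 1L, length(v))
        ifelse(abs(x - v[lo]) <= abs(v[hi] - x), lo, hi)
    }
    jOfI <- nearestIn(a, b)
    iOfJ <- nearestIn(b, a)
    i <- which(iOfJ[jOfI] == seq_along(a) &
               abs(a - b[jOfI]) <= maxMatch)
    cbind(i = i, j = jOfI[i])
}

#' Match dyad calls between time points and classify repositioning
#'
#' Calls are paired by mutual nearest neighbour within
#' \code{maxMatch} bp (half a nucleosome by default, preventing
#' cross-array matches). Matched pairs with a dyad shift strictly
#' greater than \code{shiftThreshold} are \code{repositioned},
#' otherwise \code{stable}; unmatched t0 calls are \code{lost} and
#' unmatched t calls \code{gained}.
#'
#' @param calls0,calls1 Dyad GRanges from [callNucleosomes()] for the
#'   reference (0 min) and later time point.
#' @param maxMatch Matching radius in bp.
#' @param shiftThreshold Repositioning criterion in bp (shift >
#'   threshold).
#' @return data.frame with columns \code{chrom}, \code{dyad_t0},
#'   \code{dyad_t} (NA when absent), \code{shift} and \code{status}.
#' @export
matchDyads <- function(calls0, calls1, maxMatch = 73,
                       shiftThreshold = 10) {
    chroms <- union(
        as.character(unique(GenomicRanges::seqnames(calls0))),
        as.character(unique(GenomicRanges::seqnames(calls1))))
    res <- lapply(chroms, function(cn) {
        a <- GenomicRanges::start(calls0[
            GenomicRanges::seqnames(calls0) == cn]) - 1L
        b <- GenomicRanges::start(calls1[
            GenomicRanges::seqnames(calls1) == cn]) - 1L
        m <- mutualNearest(a, b, maxMatch)
        shift <- abs(a[m[, "i"]] - b[m[, "j"]])
        matched <- data.frame(chrom = cn,
            dyad_t0 = a[m[, "i"]], dyad_t = b[m[, "j"]],
            shift = shift,
            status = ifelse(shift > shiftThreshold, "repositioned",
                            "stable"))
        lost <- setdiff(seq_along(a), m[, "i"])
        gained <- setdiff(seq_along(b), m[, "j"])
        rbind(matched,
            if (length(lost)) data.frame(chrom = cn, dyad_t0 = a[lost],
                dyad_t = NA_integer_, shift = NA_integer_,
                status = "lost"),
            if (length(gained)) data.frame(chrom = cn,
                dyad_t0 = NA_integer_, dyad_t = b[gained],
                shift = NA_integer_, status = "gained"))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Differentially unmasked regions around moved or lost nucleosomes
#'
#' Returns one nucleosome footprint (+/- \code{radius} bp around the
#' 0-min dyad, half-open) for every repositioned or lost call, merged
#' when overlapping. These are the regions whose DNA became accessible
#' relative to 0 min, suitable for export and external annotation.
#'
#' @param events Repositioning table from [matchDyads()].
#' @param radius Half-width in bp (73 = half a nucleosome footprint).
#' @return GRanges of merged unmasked regions.
#' @export
unmaskedRegions <- function(events, radius = 73) {
    sel <- events$status %in% c("repositioned", "lost")
    if (!any(sel))
        return(GenomicRanges::GRanges())
    d <- events$dyad_t0[sel]
    gr <- GenomicRanges::GRanges(events$chrom[sel],
        IRanges::IRanges(pmax(d - radius, 0L) + 1L, d + radius + 1L))
    GenomicRanges::reduce(gr)
}
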