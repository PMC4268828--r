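# Accessors for OccupancyResult, Domainogram and SyntheticTruth.
# Slot access stays internal; user code goes through these.

#' @rdname OccupancyResult-class
#' @param x An \linkS4class{OccupancyResult}.
#' @return \code{windowCounts} returns the two-column count matrix.
#' @export
windowCounts <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    SummarizedExperiment::assay(x, "counts")
}

#' @rdname OccupancyResult-class
#' @return \code{logRatios} returns the per-window log2 ratio q.
#' @export
logRatios <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    SummarizedExperiment::rowData(x)$q
}

#' @rdname OccupancyResult-class
#' @return \code{centeredRatios} returns q minus the genome-wide mean.
#' @export
centeredRatios <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    SummarizedExperiment::rowData(x)$centered
}

#' @rdname OccupancyResult-class
#' @return \code{pValues} returns a data.frame with columns
#'   \code{pRight} (depletion at the later time) and \code{pLeft}
#'   (enrichment).
#' @export
pValues <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    rd <- SummarizedExperiment::rowData(x)
    data.frame(pRight = rd$pRight, pLeft = rd$pLeft)
}

#' @rdname OccupancyResult-class
#' @return \code{windowLabels} returns the per-window label factor.
#' @export
windowLabels <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    factor(SummarizedExperiment::rowData(x)$label,
           levels = OCCUPANCY_LABELS)
}

#' @rdname OccupancyResult-class
#' @return \code{qMean} returns the mean log-ratio over scored windows.
#' @export
qMean <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    S4Vectors::metadata(x)$qMean
}

#' @rdname OccupancyResult-class
#' @return \code{inertNull} returns the \linkS4class{InertNull} used.
#' @export
inertNull <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    S4Vectors::metadata(x)$null
}

#' @rdname OccupancyResult-class
#' @return \code{depletedWindows}/\code{enrichedWindows} return the
#'   GRanges of windows labelled depleted/enriched.
#' @export
depletedWindows <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    SummarizedExperiment::rowRanges(x)[
        SummarizedExperiment::rowData(x)$label == "depleted"]
}

#' @rdname OccupancyResult-class
#' @export
enrichedWindows <- function(x) {
    stopifnot(is(x, "OccupancyResult"))
    SummarizedExperiment::rowRanges(x)[
        SummarizedExperiment::rowData(x)$label == "enriched"]
}

#' @rdname InertNull-class
#' @param null An \linkS4class{InertNull}.
#' @return \code{nullValues} returns the sorted null values.
#' @export
nullValues <- function(null) {
    stopifnot(is(null, "InertNull"))
    null@values
}

#' Empirical cumulative distribution of the inert null
#'
#' \code{nullCDF(null, x)} evaluates the empirical CDF N_cum of the
#' inert-window centred values at \code{x} (proportion of null values
#' \code{<= x}).
#'
#' @param null An \linkS4class{InertNull}.
#' @param x Numeric vector of centred values.
#' @return Numeric vector in \[0, 1\].
#' @export
nullCDF <- function(null, x) {
    stopifnot(is(null, "InertNull"))
    findInterval(x, null@values) / length(null@values)
}

#' @rdname Domainogram-class
#' @param x A \linkS4class{Domainogram}.
#' @return \code{domainogramTable} returns the per-window score table.
#' @export
domainogramTable <- function(x) {
    stopifnot(is(x, "Domainogram"))
    x@table
}

#' @rdname Domainogram-class
#' @return \code{significantWindows} returns a GRanges of windows above
#'   the permutation-FDR threshold (empty before/without one).
#' @export
significantWindows <- function(x) {
    stopifnot(is(x, "Domainogram"))
    tab <- x@table
    if (!"significant" %in% colnames(tab) || !length(x@threshold))
        return(GenomicRanges::GRanges())
    sig <- tab[!is.na(tab$significant) & tab$significant, , drop = FALSE]
    GenomicRanges::GRanges(x@chrom,
        IRanges::IRanges(sig$start + 1L, sig$end),
        size = sig$size, score = sig$score)
}

#' @rdname SyntheticTruth-class
#' @param truth A \linkS4class{SyntheticTruth}.
#' @return The corresponding ground-truth component.
#' @export
truthEvents <- function(truth) { stopifnot(is(truth, "SyntheticTruth")); truth@events }

#' @rdname SyntheticTruth-class
#' @export
truthGenes <- function(truth) { stopifnot(is(truth, "SyntheticTruth")); truth@genes }

#' @rdname SyntheticTruth-class
#' @export
truthCounts <- function(truth) { stopifnot(is(truth, "SyntheticTruth")); truth@counts }

#' @rdname SyntheticTruth-class
#' @export
truthPeaks <- function(truth) { stopifnot(is(truth, "SyntheticTruth")); truth@peaks }

#' @rdname SyntheticTruth-class
#' @export
truthInert <- function(truth) { stopifnot(is(truth, "SyntheticTruth")); truth@inert }

#' @rdname SyntheticTruth-class
#' @export
truthContactTargets <- function(truth) { stopifnot(is(truth, "SyntheticTruth")); truth@contactTargets }

#' @rdname ContactProfile-class
#' @param x A \linkS4class{ContactProfile}.
#' @return \code{contactEnds} returns a data.frame of 0-based end
#'   positions, read counts and binary signal.
#' @export
contactEnds <- function(x) {
    stopifnot(is(x, "ContactProfile"))
    data.frame(chrom = x@chrom, pos = x@ends, reads = x@reads,
               binary = x@binary)
}
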