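#' Empirical null distribution from inert windows
#'
#' Holds the sorted centred log-ratio values observed in
#' transcriptionally inert windows. Their empirical cumulative
#' distribution is the null against which every window's centred value
#' is ranked to obtain a p-value.
#'
#' @slot values Sorted numeric vector of centred log-ratios from inert,
#'   adequately covered windows.
#' @slot nInert Number of inert windows contributing to the null.
#' @exportClass InertNull
setClass("InertNull",
    representation(values = "numeric", nInert = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@values) < 1L)
            msg <- c(msg, "empty null distribution")
        if (is.unsorted(object@values))
            msg <- c(msg, "null values must be sorted")
        if (anyNA(object@values))
            msg <- c(msg, "null values must be finite")
        if (is.null(msg)) TRUE else msg
    })

#' Windowed differential-occupancy result
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are the
#' constant-size genome windows and whose single assay \code{counts}
#' holds the fragment-midpoint counts at the two time points (columns
#' \code{t1}, \code{t2}). Row metadata carries the per-window log-ratio
#' \code{q}, its centred value, the one-sided empirical p-values and the
#' depleted/enriched/unchanged/low_coverage label. Experiment metadata
#' stores the mean log-ratio \code{qMean}, the \linkS4class{InertNull}
#' object and the analysis parameters.
#'
#' @exportClass OccupancyResult
setClass("OccupancyResult", contains = "RangedSummarizedExperiment")

OCCUPANCY_LABELS <- c("depleted", "enriched", "unchanged", "low_coverage")

setValidity("OccupancyResult", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' missing")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("q", "centered", "pRight", "pLeft", "label",
              "lowCoverage", "inert", "partial")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste("rowData columns missing:",
                            paste(miss, collapse = ", ")))
    if (!length(msg)) {
        lab <- rd$label
        if (!all(lab %in% OCCUPANCY_LABELS))
            msg <- c(msg, "invalid window label")
        scored <- !rd$lowCoverage
        if (any(scored)) {
            m <- mean(rd$centered[scored])
            if (!is.finite(m) || abs(m) > 1e-9)
                msg <- c(msg, "centred values not mean-zero over scored windows")
        }
        p <- c(rd$pRight[scored], rd$pLeft[scored])
        if (length(p) && (any(p <= 0) || any(p > 1)))
            msg <- c(msg, "p-values must lie in (0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' Viewpoint contact profile
#'
#' Fragment-end positions along one chromosome with per-end read counts
#' from a chromosome-conformation-capture viewpoint library. Reads are
#' binarized (an end is contact-positive iff it carries at least one
#' read), which makes the downstream enrichment scores invariant to
#' sequencing depth.
#'
#' @slot chrom Chromosome name.
#' @slot viewpoint 0-based position of the viewpoint fragment end.
#' @slot ends Sorted, unique 0-based fragment-end positions.
#' @slot reads Integer read count per end.
#' @slot binary Integer 0/1 signal per end (\code{reads >= 1}).
#' @exportClass ContactProfile
setClass("ContactProfile",
    representation(chrom = "character", viewpoint = "integer",
                   ends = "integer", reads = "integer",
                   binary = "integer"),
    validity = function(object) {
        msg <- NULL
        n <- length(object@ends)
        if (length(object@reads) != n || length(object@binary) != n)
            msg <- c(msg, "ends, reads and binary must have equal length")
        if (n && (is.unsorted(object@ends, strictly = TRUE)))
            msg <- c(msg, "fragment ends must be sorted and unique")
        if (any(object@reads < 0))
            msg <- c(msg, "read counts must be non-negative")
        if (!identical(object@binary, as.integer(object@reads >= 1L)))
            msg <- c(msg, "binary signal inconsistent with read counts")
        if (is.null(msg)) TRUE else msg
    })

#' Multi-scale contact domainogram
#'
#' Per (window size, window position) enrichment scores of a
#' \linkS4class{ContactProfile} relative to a randomized background,
#' plus, after permutation testing, the score threshold controlling the
#' false discovery rate and the significant-window flags.
#'
#' @slot table data.frame with columns \code{size}, \code{start},
#'   \code{end}, \code{nEnds}, \code{nPos}, \code{score}, \code{masked}
#'   and (after \code{\link{permutationFDR}}) \code{significant}.
#' @slot chrom Chromosome of the profile.
#' @slot backgroundRate Positive-end rate of the sampled background.
#' @slot threshold Score threshold at the requested FDR (length 0 until
#'   permutation testing, length 0 with a warning when degenerate).
#' @slot fdr Target false discovery rate.
#' @slot nPerm Number of permutations used.
#' @exportClass Domainogram
setClass("Domainogram",
    representation(table = "data.frame", chrom = "character",
                   backgroundRate = "numeric", threshold = "numeric",
                   fdr = "numeric", nPerm = "integer"))

#' Synthetic nucleosome landscape specification
#'
#' Parameters of the synthetic genome generator: chromosome sizes, the
#' nucleosome repeat length of phased arrays, the fragment-length
#' distribution of the simulated mononucleosome library, the positional
#' spread of midpoints around each dyad, the expected number of
#' fragments recovered per nucleosome, and the seed.
#'
#' @slot chromLengths Named integer vector of chromosome lengths (bp).
#' @slot nrl Nucleosome repeat length (bp).
#' @slot fragLenMean,fragLenSd Fragment length distribution (bp).
#' @slot dyadSd Positional sd of fragment midpoints around a dyad (bp).
#' @slot baseOccupancy Expected fragments per nucleosome.
#' @slot seed Integer seed.
#' @exportClass LandscapeSpec
setClass("LandscapeSpec",
    representation(chromLengths = "integer", nrl = "integer",
                   fragLenMean = "numeric", fragLenSd = "numeric",
                   dyadSd = "numeric", baseOccupancy = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@chromLengths) < 1L ||
            is.null(names(object@chromLengths)) ||
            anyDuplicated(names(object@chromLengths)))
            msg <- c(msg, "chromLengths must be named, names unique")
        if (any(object@chromLengths < 10L * object@nrl))
            msg <- c(msg, "each chromosome must span at least 10 nucleosome repeats")
        if (object@fragLenSd < 0)
            msg <- c(msg, "fragLenSd must be >= 0")
        if (object@baseOccupancy <= 0)
            msg <- c(msg, "baseOccupancy must be > 0")
        if (is.null(msg)) TRUE else msg
    })

#' Ground truth of a synthetic experiment
#'
#' Everything the generator planted, for joining against in recovery
#' tests: occupancy-change and shift events, gene models with their
#' expression class and true log2 fold-change, the two-time-point
#' per-gene count table, TF peaks, transcriptionally inert regions and
#' viewpoint contact targets.
#'
#' @slot events GRanges with metadata \code{kind} (depletion,
#'   enrichment, shift), \code{factor}, \code{shift}.
#' @slot genes GRanges with metadata \code{name}, \code{class},
#'   \code{trueLog2FC}.
#' @slot counts Gene-by-time-point count matrix (columns t1, t2).
#' @slot peaks GRanges of planted TF peaks.
#' @slot inert GRanges of transcriptionally inert regions.
#' @slot contactTargets GRanges of planted viewpoint contact targets.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(events = "GRanges", genes = "GRanges",
                   counts = "matrix", peaks = "GRanges",
                   inert = "GRanges", contactTargets = "GRanges"))
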