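# Reading and writing the standard formats the pipeline touches.
# All internal coordinates are GRanges (1-based closed); conversion to
# the 0-based half-open convention of BED/bedGraph happens only here,
# at the format boundary.

#' Read a chrom.sizes file into a Seqinfo
#'
#' @param path Two-column tab-delimited file: chromosome name, length.
#' @return A [GenomeInfoDb::Seqinfo] object (the package's genome
#'   index: ordered chromosome names with lengths).
#' @export
readChromSizes <- function(path) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "length"),
                      colClasses = c("character", "integer"))
    if (anyDuplicated(tab$chrom))
        stop("duplicate chromosome names in ", path)
    if (any(tab$length <= 0L))
        stop("non-positive chromosome length in ", path)
    GenomeInfoDb::Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' Write a Seqinfo as a chrom.sizes file
#'
#' @param genome A Seqinfo.
#' @param path Output path.
#' @export
writeChromSizes <- function(genome, path) {
    write.table(data.frame(GenomeInfoDb::seqnames(genome),
                           GenomeInfoDb::seqlengths(genome)),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# Pre-scan a BED-like file so coordinate violations are reported with
# their line number (rtracklayer would reject them, but anonymously).
validateBedLines <- function(path, genome = NULL) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    for (i in which(keep)) {
        f <- strsplit(lines[[i]], "[ \t]+")[[1]]
        if (length(f) < 3L)
            stop(path, " line ", i, ": fewer than 3 fields")
        s <- suppressWarnings(as.numeric(f[2L]))
        e <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(s) || is.na(e))
            stop(path, " line ", i, ": non-numeric coordinates")
        if (s >= e)
            stop(path, " line ", i, ": start >= end (", f[2L], " >= ",
                 f[3L], ")")
        if (!is.null(genome)) {
            sl <- GenomeInfoDb::seqlengths(genome)
            if (!f[1L] %in% names(sl))
                stop(path, " line ", i, ": unknown chromosome '", f[1L], "'")
            if (e > sl[[f[1L]]])
                stop(path, " line ", i, ": interval ends beyond chromosome ",
                     f[1L], " (", e, " > ", sl[[f[1L]]], ")")
        }
    }
    invisible(TRUE)
}

#' Read intervals from BED, BED12 or narrowPeak
#'
#' Coordinates are validated before parsing; violations (start >= end,
#' unknown chromosome, interval beyond the chromosome end) are reported
#' with the offending line number. Parsing itself is done with
#' rtracklayer.
#'
#' @param path Input file.
#' @param format One of \code{"bed"} (BED3/6 and BED12) or
#'   \code{"narrowPeak"}.
#' @param genome Optional Seqinfo to validate against and attach.
#' @return A GRanges (strand and any name/score columns preserved;
#'   narrowPeak adds signalValue/pValue/qValue/peak).
#' @export
readIntervals <- function(path, format = c("bed", "narrowPeak"),
                          genome = NULL) {
    format <- match.arg(format)
    validateBedLines(path, genome)
    gr <- if (format == "narrowPeak") {
        rtracklayer::import(path, format = "BED",
            extraCols = c(signalValue = "numeric", pValue = "numeric",
                          qValue = "numeric", peak = "integer"))
    } else {
        rtracklayer::import(path, format = "BED")
    }
    if (!is.null(genome)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
        GenomeInfoDb::seqinfo(gr) <- genome
    }
    gr
}

#' Transcription start / termination sites of gene models
#'
#' The TSS is the leftmost base of a plus-strand gene and the rightmost
#' base of a minus-strand gene; the TTS is the opposite terminus.
#'
#' @param genes GRanges of gene bodies with strand.
#' @return Width-1 GRanges at the TSS (or TTS).
#' @export
geneTSS <- function(genes) {
    if (any(GenomicRanges::strand(genes) == "*"))
        stop("gene models must be stranded")
    GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' @rdname geneTSS
#' @export
geneTTS <- function(genes) {
    if (any(GenomicRanges::strand(genes) == "*"))
        stop("gene models must be stranded")
    GenomicRanges::resize(genes, width = 1L, fix = "end")
}

#' Read mononucleosome fragments
#'
#' @param path BED file of fragment intervals.
#' @param genome Optional Seqinfo for validation.
#' @return GRanges of fragments (duplicates preserved; zero-length
#'   intervals are rejected by validation).
#' @export
readFragments <- function(path, genome = NULL) {
    readIntervals(path, format = "bed", genome = genome)
}

#' Fragment midpoints
#'
#' Midpoint of a 0-based half-open fragment \[start, end) is
#' floor((start + end) / 2); even-length fragments round down. Counts
#' (duplicate fragments) are preserved.
#'
#' @param fragments GRanges of fragments.
#' @return Width-1 GRanges at the midpoints, one per input fragment.
#' @export
fragmentMidpoints <- function(fragments) {
    if (any(GenomicRanges::width(fragments) < 1L))
        stop("zero-length fragment interval")
    mid0 <- midpoint0(GenomicRanges::start(fragments) - 1L,
                      GenomicRanges::end(fragments))
    GenomicRanges::GRanges(GenomicRanges::seqnames(fragments),
        IRanges::IRanges(mid0 + 1L, width = 1L),
        seqinfo = GenomeInfoDb::seqinfo(fragments))
}

# Coerce input to width-1 midpoint GRanges: fragments of width > 1 are
# converted; width-1 input passes through.
asMidpoints <- function(x) {
    if (all(GenomicRanges::width(x) == 1L)) x else fragmentMidpoints(x)
}

#' Write intervals as BED
#'
#' @param gr GRanges to write (name/score/strand written when present).
#' @param path Output path.
#' @export
writeIntervals <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Write TF peaks as narrowPeak
#'
#' @param gr GRanges with (optional) metadata columns signalValue,
#'   pValue, qValue, peak; missing columns are filled with the format's
#'   placeholder values.
#' @param path Output path.
#' @export
writeNarrowPeak <- function(gr, path) {
    bed <- grToBed0(gr)
    mc <- GenomicRanges::mcols(gr)
    getcol <- function(nm, default) {
        if (nm %in% colnames(mc)) mc[[nm]] else
            rep(default, length(gr))
    }
    tab <- data.frame(bed$chrom, bed$start, bed$end,
        name = getcol("name", paste0("peak_", seq_along(gr))),
        score = getcol("score", 0L),
        strand = ".",
        signalValue = getcol("signalValue", 0),
        pValue = getcol("pValue", -1),
        qValue = getcol("qValue", -1),
        peak = getcol("peak", -1L))
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a per-window track as bedGraph
#'
#' One line per window, in grid order; adjacent windows with equal
#' values are deliberately not merged, so window identity survives a
#' round trip.
#'
#' @param grid GRanges of windows (see [tileWindows()]).
#' @param values One numeric value per window.
#' @param path Output path.
#' @param name Track name for the header line.
#' @export
writeBedGraph <- function(grid, values, path, name = "track") {
    if (length(values) != length(grid))
        stop("need exactly one value per window (got ", length(values),
             " for ", length(grid), " windows)")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
    if (length(grid)) {
        bed <- grToBed0(grid)
        writeLines(sprintf("%s\t%d\t%d\t%.6g", bed$chrom, bed$start,
                           bed$end, values), con)
    }
    invisible(path)
}

#' Read a bedGraph written by [writeBedGraph()]
#'
#' @param path bedGraph file.
#' @return List with \code{grid} (GRanges) and \code{values}.
#' @export
readBedGraph <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
    if (!length(lines))
        return(list(grid = GenomicRanges::GRanges(), values = numeric(0)))
    tab <- read.table(text = lines, sep = "\t",
        col.names = c("chrom", "start", "end", "value"))
    list(grid = GenomicRanges::GRanges(tab$chrom,
             IRanges::IRanges(tab$start + 1L, tab$end)),
         values = tab$value)
}

#' Read a tab-delimited count table
#'
#' @param path Tab-delimited file with a header row; first column gene
#'   identifiers, remaining columns counts.
#' @return Integer matrix with gene rownames.
#' @export
readCountTable <- function(path) {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    storage.mode(m) <- "integer"
    m
}

#' Read a viewpoint fragment-end table
#'
#' @param path Tab-delimited file with header columns \code{chrom},
#'   \code{pos} (0-based fragment-end position) and \code{reads}.
#' @param viewpoint 0-based viewpoint position (must be one of the
#'   ends).
#' @return A \linkS4class{ContactProfile}.
#' @export
readContactEnds <- function(path, viewpoint) {
    tab <- read.table(path, sep = "\t", header = TRUE)
    need <- c("chrom", "pos", "reads")
    if (!all(need %in% colnames(tab)))
        stop("contact-end table needs columns: ",
             paste(need, collapse = ", "))
    contactProfile(chrom = tab$chrom[[1L]], ends = tab$pos,
                   reads = tab$reads, viewpoint = viewpoint)
}

#' Write a ContactProfile as a fragment-end table
#'
#' @param profile A \linkS4class{ContactProfile}.
#' @param path Output path.
#' @export
writeContactEnds <- function(profile, path) {
    write.table(contactEnds(profile), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
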