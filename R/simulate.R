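# Seeded synthetic-data generator. The generator plants exactly the
# structures the statistics are meant to detect: phased nucleosome
# arrays downstream of expressed TSSs on a homogeneous background,
# kilobase-scale occupancy changes, dyad shifts, expression-classed
# genes, TF peaks enriched in depleted domains, inert regions and
# viewpoint contact profiles. All coordinates in the dyad tracks and
# event tables are 0-based half-open, matching BED; GRanges outputs use
# the usual 1-based convention.

#' Construct a landscape specification
#'
#' Defaults describe the reference synthetic experiment used throughout
#' the package's validation: a 10-Mbp chromosome, 190-bp nucleosome
#' repeat length, 147 +/- 10 bp mononucleosome fragments whose
#' midpoints scatter around the dyad with sd 10 bp, and 30 recovered
#' fragments per nucleosome.
#'
#' @param chromLengths Named vector of chromosome lengths in bp.
#' @param nrl Nucleosome repeat length in bp.
#' @param fragLenMean,fragLenSd Fragment-length distribution in bp.
#' @param dyadSd Positional sd of midpoints around each dyad in bp.
#' @param baseOccupancy Expected fragments per nucleosome.
#' @param seed Integer seed.
#' @return A \linkS4class{LandscapeSpec}.
#' @export
landscapeSpec <- function(chromLengths = c(chrS1 = 1e7), nrl = 190,
                          fragLenMean = 147, fragLenSd = 10,
                          dyadSd = 10, baseOccupancy = 30, seed = 1) {
    new("LandscapeSpec",
        chromLengths = setNames(as.integer(chromLengths),
                                names(chromLengths)),
        nrl = as.integer(nrl), fragLenMean = fragLenMean,
        fragLenSd = fragLenSd, dyadSd = dyadSd,
        baseOccupancy = baseOccupancy, seed = as.integer(seed))
}

#' Seqinfo of a landscape specification
#' @param spec A \linkS4class{LandscapeSpec}.
#' @return A Seqinfo.
#' @export
specSeqinfo <- function(spec) {
    stopifnot(is(spec, "LandscapeSpec"))
    GenomeInfoDb::Seqinfo(names(spec@chromLengths),
                          unname(spec@chromLengths))
}

#' Simulate a dyad-probability landscape
#'
#' Builds one per-bp dyad-weight track per chromosome. The background
#' is homogeneous at one nucleosome per repeat length (weight 1/nrl per
#' bp, i.e. unit mass per nucleosome footprint). Within each expressed
#' gene body the background is replaced by a phased array: unit-mass
#' Gaussian bumps (sd \code{dyadSd}) at dyads spaced \code{nrl} apart
#' starting half a repeat downstream of the TSS. The construction is
#' deterministic: randomness enters only at fragment sampling.
#'
#' @param spec A \linkS4class{LandscapeSpec}.
#' @param genes Optional stranded GRanges of genes; a metadata column
#'   \code{class} restricts arrays to expressed genes (class not
#'   \code{"unexpressed"}); without it all genes count as expressed.
#' @return Named list of numeric per-bp tracks (0-based position i is
#'   element i + 1).
#' @export
simulateLandscape <- function(spec, genes = NULL) {
    stopifnot(is(spec, "LandscapeSpec"))
    sl <- spec@chromLengths
    if (!is.null(genes) && length(genes)) {
        chr <- as.character(GenomicRanges::seqnames(genes))
        if (!all(chr %in% names(sl)))
            stop("gene on unknown chromosome")
        if (any(GenomicRanges::end(genes) > sl[chr]) ||
            any(GenomicRanges::start(genes) < 1L))
            stop("gene outside genome")
    }
    nrl <- spec@nrl
    sdv <- spec@dyadSd
    tracks <- lapply(names(sl), function(cn) rep(1 / nrl, sl[[cn]]))
    names(tracks) <- names(sl)
    if (is.null(genes) || !length(genes))
        return(tracks)
    expressed <- if ("class" %in% colnames(GenomicRanges::mcols(genes)))
        genes$class != "unexpressed" else rep(TRUE, length(genes))
    g <- genes[expressed]
    for (i in seq_along(g)) {
        cn <- as.character(GenomicRanges::seqnames(g[i]))
        L <- sl[[cn]]
        s0 <- GenomicRanges::start(g[i]) - 1L   # 0-based body [s0, e0)
        e0 <- GenomicRanges::end(g[i])
        minus <- as.character(GenomicRanges::strand(g[i])) == "-"
        # dyads phased from the TSS into the body
        if (!minus) {
            dyads <- seq(s0 + nrl / 2, e0 - 1, by = nrl)
        } else {
            dyads <- seq(e0 - 1 - nrl / 2, s0, by = -nrl)
        }
        tr <- tracks[[cn]]
        tr[(s0 + 1L):e0] <- 0
        half <- ceiling(4 * sdv)
        for (d in dyads) {
            lo <- max(0, floor(d - half))
            hi <- min(L - 1, ceiling(d + half))
            idx <- lo:hi
            tr[idx + 1L] <- tr[idx + 1L] + dnorm(idx, mean = d, sd = sdv)
        }
        tracks[[cn]] <- tr
    }
    tracks
}

#' Construct a planted-event table
#'
#' @param chrom,start,end Event intervals (0-based half-open).
#' @param kind One of \code{"depletion"}, \code{"enrichment"},
#'   \code{"shift"} per event.
#' @param factor Occupancy multiplier (< 1 for depletion, > 1 for
#'   enrichment; ignored for shifts).
#' @param shift Signed dyad shift in bp (shift events only, non-zero).
#' @return GRanges with metadata \code{kind}, \code{factor},
#'   \code{shift}.
#' @export
plantedEvents <- function(chrom, start, end, kind, factor = NA_real_,
                          shift = NA_integer_) {
    n <- length(start)
    kind <- rep_len(kind, n)
    factor <- rep_len(factor, n)
    shift <- rep_len(as.integer(shift), n)
    if (!all(kind %in% c("depletion", "enrichment", "shift")))
        stop("event kind must be depletion, enrichment or shift")
    if (any(kind == "depletion" & !(factor > 0 & factor < 1)))
        stop("depletion events need 0 < factor < 1")
    if (any(kind == "enrichment" & !(factor > 1)))
        stop("enrichment events need factor > 1")
    if (any(kind == "shift" & (is.na(shift) | shift == 0L)))
        stop("shift events need a non-zero shift")
    GenomicRanges::GRanges(rep_len(chrom, n),
        IRanges::IRanges(start + 1L, end),
        kind = kind, factor = factor, shift = shift)
}

#' Apply planted events to a landscape
#'
#' Depletion/enrichment events multiply the dyad track within the
#' event interval by \code{factor} (so the interval's track mass
#' changes by exactly that factor); shift events translate the track
#' within the interval by \code{shift} bp (edges clamped). Overlapping
#' events are contradictory and rejected.
#'
#' @param tracks Named list of per-bp tracks from
#'   [simulateLandscape()].
#' @param events GRanges from [plantedEvents()] (empty = identity).
#' @return Modified track list.
#' @export
applyEvents <- function(tracks, events) {
    if (is.null(events) || !length(events))
        return(tracks)
    if (any(GenomicRanges::countOverlaps(events, events) > 1L))
        stop("overlapping planted events are contradictory")
    chr <- as.character(GenomicRanges::seqnames(events))
    if (!all(chr %in% names(tracks)))
        stop("event on unknown chromosome")
    for (i in seq_along(events)) {
        cn <- chr[[i]]
        L <- length(tracks[[cn]])
        s0 <- GenomicRanges::start(events[i]) - 1L
        e0 <- GenomicRanges::end(events[i])
        if (s0 < 0L || e0 > L)
            stop("event outside genome")
        idx <- (s0 + 1L):e0
        kind <- events$kind[[i]]
        if (kind == "shift") {
            sh <- events$shift[[i]]
            seg <- tracks[[cn]][idx]
            src <- pmin(pmax(seq_along(seg) - sh, 1L), length(seg))
            tracks[[cn]][idx] <- seg[src]
        } else {
            tracks[[cn]][idx] <- tracks[[cn]][idx] * events$factor[[i]]
        }
    }
    tracks
}

#' Sample mononucleosome fragments from a landscape
#'
#' The number of fragments per chromosome is Poisson with mean
#' \code{occupancy} times the track mass (tracks are scaled so one
#' nucleosome carries unit mass, making \code{occupancy} the expected
#' fragments per nucleosome). Midpoints are drawn proportional to the
#' per-bp track; fragment lengths are normal draws clipped at 50 bp;
#' fragments are shifted inward where they would protrude past a
#' chromosome end.
#'
#' @param tracks Named list of per-bp tracks.
#' @param spec A \linkS4class{LandscapeSpec} (fragment-length model).
#' @param occupancy Expected fragments per nucleosome (defaults to the
#'   spec's \code{baseOccupancy}).
#' @param seed Integer seed (defaults to the spec's).
#' @return Sorted GRanges of fragments with the spec's Seqinfo.
#' @export
sampleFragments <- function(tracks, spec, occupancy = NULL,
                            seed = NULL) {
    stopifnot(is(spec, "LandscapeSpec"))
    if (is.null(occupancy)) occupancy <- spec@baseOccupancy
    if (is.null(seed)) seed <- spec@seed
    checkScalar(occupancy, "occupancy", positive = TRUE)
    si <- specSeqinfo(spec)
    withSeed(seed, {
        grs <- lapply(names(tracks), function(cn) {
            tr <- tracks[[cn]]
            L <- length(tr)
            mass <- sum(tr)
            n <- rpois(1L, occupancy * mass)
            if (n == 0L)
                return(GenomicRanges::GRanges(seqinfo = si))
            mids0 <- sample.int(L, n, replace = TRUE, prob = tr) - 1L
            len <- pmax(50L, as.integer(round(rnorm(n,
                spec@fragLenMean, spec@fragLenSd))))
            start0 <- mids0 - as.integer(floor(len / 2))
            start0 <- pmax(0L, pmin(start0, L - len))
            GenomicRanges::GRanges(cn,
                IRanges::IRanges(start0 + 1L, width = len),
                seqinfo = si)
        })
        sort(do.call(c, grs))
    })
}

# Place n non-overlapping intervals of the given widths uniformly on
# the genome, avoiding `avoid` (GRanges) plus a margin. Rejection
# sampling; errors out when the genome is too crowded.
placeIntervals <- function(sl, widths, avoid = NULL, margin = 0,
                           maxTries = 10000L) {
    placed <- GenomicRanges::GRanges()
    blocked <- if (is.null(avoid) || !length(avoid))
        GenomicRanges::GRanges()
    else GenomicRanges::reduce(avoid + margin, ignore.strand = TRUE)
    chrProb <- sl / sum(sl)
    for (w in widths) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            cn <- sample(names(sl), 1L, prob = chrProb)
            if (sl[[cn]] < w) next
            s0 <- sample.int(sl[[cn]] - w + 1L, 1L) - 1L
            cand <- GenomicRanges::GRanges(cn,
                IRanges::IRanges(s0 + 1L, s0 + w))
            if (!IRanges::overlapsAny(cand, blocked,
                                      ignore.strand = TRUE) &&
                !IRanges::overlapsAny(cand, placed + margin,
                                      ignore.strand = TRUE)) {
                placed <- c(placed, cand)
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("could not place ", length(widths),
                 " intervals: genome too crowded")
    }
    placed
}

#' Simulate gene models, classes, counts, TF peaks and inert regions
#'
#' Places non-overlapping genes, assigns expression classes by the
#' given fractions (the remainder is unexpressed), draws a
#' two-time-point count table whose true log2 fold-changes respect the
#' class definitions (up > 0.6, down < -0.6, constitutive exactly 0,
#' Poisson noise on top), optionally generates planted
#' depletion/enrichment/shift events, plants TF peaks inside depletion
#' events with the stated odds multiplier, and derives inert regions as
#' the genome minus expressed genes and events (with a buffer).
#'
#' @param spec A \linkS4class{LandscapeSpec}.
#' @param nGenes Number of genes.
#' @param classFractions Named fractions for \code{up}, \code{down},
#'   \code{constitutive}; must sum to <= 1.
#' @param events Either a GRanges from [plantedEvents()], or NULL to
#'   generate \code{nDepletion} depletion events automatically.
#' @param nDepletion,eventWidth,eventFactor Automatic event generation:
#'   number, width (bp) and occupancy factor of planted depletions.
#' @param bodyEvents Plant per-gene body events: depletion (factor
#'   \code{bodyDepletionFactor}) over up-regulated gene bodies and
#'   enrichment (\code{bodyEnrichmentFactor}) over down-regulated ones,
#'   emulating the occupancy changes seen along regulated genes.
#' @param bodyDepletionFactor,bodyEnrichmentFactor Body event factors.
#' @param nPeaks Number of TF peaks.
#' @param tfEnrichmentOdds Odds multiplier for placing a peak inside a
#'   depletion event rather than outside.
#' @param peakWidth TF peak width in bp.
#' @param geneLengthRange Min/max gene length in bp.
#' @param exprRate Expected reads per bp for expressed genes at t1.
#' @param nContactTargets Number of viewpoint contact targets (placed
#'   inside depletion events when possible).
#' @param seed Integer seed (defaults to the spec's).
#' @return A \linkS4class{SyntheticTruth}.
#' @export
simulateAnnotations <- function(spec, nGenes = 60,
        classFractions = c(up = 0.15, down = 0.1, constitutive = 0.25),
        events = NULL, nDepletion = 0, eventWidth = 25000,
        eventFactor = 0.5, bodyEvents = FALSE,
        bodyDepletionFactor = 0.5, bodyEnrichmentFactor = 2,
        nPeaks = 0, tfEnrichmentOdds = 1, peakWidth = 300,
        geneLengthRange = c(8000, 30000), exprRate = 0.5,
        nContactTargets = 3, seed = NULL) {
    stopifnot(is(spec, "LandscapeSpec"))
    if (is.null(seed)) seed <- spec@seed
    cf <- classFractions[c("up", "down", "constitutive")]
    cf[is.na(cf)] <- 0
    names(cf) <- c("up", "down", "constitutive")
    if (sum(cf) > 1 + 1e-12)
        stop("class fractions must sum to <= 1")
    sl <- spec@chromLengths
    si <- specSeqinfo(spec)
    withSeed(seed, {
        ## gene models
        glen <- as.integer(round(runif(nGenes, geneLengthRange[1L],
                                       geneLengthRange[2L])))
        if (sum(as.numeric(glen)) > 0.6 * sum(as.numeric(sl)))
            stop("gene set exceeds genome capacity")
        genes <- placeIntervals(sl, glen, margin = 2000)
        GenomicRanges::strand(genes) <-
            sample(c("+", "-"), nGenes, replace = TRUE)
        nUp <- round(cf[["up"]] * nGenes)
        nDown <- round(cf[["down"]] * nGenes)
        nConst <- round(cf[["constitutive"]] * nGenes)
        cls <- c(rep("up", nUp), rep("down", nDown),
                 rep("constitutive", nConst))
        cls <- c(cls, rep("unexpressed", nGenes - length(cls)))
        genes$class <- sample(cls)
        genes$name <- sprintf("gene_%03d", seq_len(nGenes))
        ## true fold-changes and counts
        fc <- numeric(nGenes)
        fc[genes$class == "up"] <- runif(sum(genes$class == "up"), 0.8, 2)
        fc[genes$class == "down"] <- -runif(sum(genes$class == "down"),
                                            0.8, 2)
        genes$trueLog2FC <- fc
        lambda1 <- ifelse(genes$class == "unexpressed", 0,
                          exprRate * GenomicRanges::width(genes))
        lambda2 <- lambda1 * 2^fc
        counts <- cbind(t1 = rpois(nGenes, lambda1),
                        t2 = rpois(nGenes, lambda2))
        rownames(counts) <- genes$name
        ## planted events
        if (is.null(events)) {
            events <- GenomicRanges::GRanges()
            if (nDepletion > 0) {
                ev <- placeIntervals(sl, rep(eventWidth, nDepletion),
                    avoid = genes, margin = 5000)
                events <- plantedEvents(
                    as.character(GenomicRanges::seqnames(ev)),
                    GenomicRanges::start(ev) - 1L,
                    GenomicRanges::end(ev),
                    kind = "depletion", factor = eventFactor)
            }
            if (bodyEvents) {
                reg <- genes[genes$class %in% c("up", "down")]
                if (length(reg)) {
                    bev <- plantedEvents(
                        as.character(GenomicRanges::seqnames(reg)),
                        GenomicRanges::start(reg) - 1L,
                        GenomicRanges::end(reg),
                        kind = ifelse(reg$class == "up", "depletion",
                                      "enrichment"),
                        factor = ifelse(reg$class == "up",
                                        bodyDepletionFactor,
                                        bodyEnrichmentFactor))
                    events <- c(events, bev)
                }
            }
        }
        ## TF peaks: odds-weighted placement inside depletion events
        depleted <- GenomicRanges::reduce(
            events[events$kind == "depletion"], ignore.strand = TRUE)
        peaks <- GenomicRanges::GRanges(seqinfo = si)
        if (nPeaks > 0) {
            depBp <- sum(as.numeric(GenomicRanges::width(depleted)))
            totBp <- sum(as.numeric(sl))
            dFrac <- depBp / totBp
            pIn <- tfEnrichmentOdds * dFrac /
                (tfEnrichmentOdds * dFrac + (1 - dFrac))
            inside <- runif(nPeaks) < pIn
            samplePosIn <- function(n, regions) {
                if (n == 0L)
                    return(list(chrom = character(0),
                                start = integer(0)))
                w <- GenomicRanges::width(regions)
                ri <- sample.int(length(regions), n, replace = TRUE,
                                 prob = w)
                off <- floor(runif(n) * (w[ri] - peakWidth + 1))
                list(chrom = as.character(
                         GenomicRanges::seqnames(regions))[ri],
                     start = GenomicRanges::start(regions)[ri] + off)
            }
            outside <- GenomicRanges::gaps(depleted)
            outside <- outside[GenomicRanges::strand(outside) == "*"]
            if (!length(outside))
                outside <- GenomicRanges::GRanges(names(sl),
                    IRanges::IRanges(1L, unname(sl)))
            outside <- outside[GenomicRanges::width(outside) > peakWidth]
            inP <- samplePosIn(sum(inside), depleted)
            outP <- samplePosIn(sum(!inside), outside)
            peaks <- GenomicRanges::GRanges(
                c(inP$chrom, outP$chrom),
                IRanges::IRanges(c(inP$start, outP$start),
                                 width = peakWidth),
                seqinfo = si)
            peaks <- sort(peaks)
            peaks$name <- sprintf("peak_%04d", seq_along(peaks))
            peaks$signalValue <- round(runif(nPeaks, 5, 50), 2)
        }
        ## inert regions: genome minus expressed genes and events
        expressedGenes <- genes[genes$class != "unexpressed"]
        blocked <- GenomicRanges::reduce(c(
            GenomicRanges::granges(expressedGenes) + 2000,
            GenomicRanges::granges(events) + 5000),
            ignore.strand = TRUE)
        GenomeInfoDb::seqlevels(blocked) <- GenomeInfoDb::seqlevels(si)
        GenomeInfoDb::seqinfo(blocked) <- si
        inert <- GenomicRanges::gaps(blocked)
        inert <- inert[GenomicRanges::strand(inert) == "*"]
        inert <- inert[GenomicRanges::width(inert) >= 10000]
        ## contact targets: inside depletion events when available
        targets <- GenomicRanges::GRanges(seqinfo = si)
        if (nContactTargets > 0 && length(depleted)) {
            k <- min(nContactTargets, length(depleted))
            pick <- sample.int(length(depleted), k)
            targets <- GenomicRanges::resize(depleted[pick],
                width = pmin(GenomicRanges::width(depleted[pick]),
                             20000L),
                fix = "center")
        }
        new("SyntheticTruth", events = events, genes = genes,
            counts = counts, peaks = peaks, inert = inert,
            contactTargets = targets)
    })
}

#' Simulate a viewpoint contact profile
#'
#' Each fragment end is read-positive independently with
#' \code{backgroundRate}, or \code{signalRate} when it falls inside a
#' contact target; positive ends receive 1 + Poisson(2) reads.
#'
#' @param viewpoint 0-based viewpoint position; must be one of
#'   \code{fragmentEnds}.
#' @param fragmentEnds Sorted unique 0-based fragment-end positions.
#' @param contactTargets GRanges (or NULL) of true contact regions.
#' @param signalRate,backgroundRate Positive-end probabilities in
#'   \[0, 1\] with \code{signalRate >= backgroundRate}.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A \linkS4class{ContactProfile}.
#' @export
simulateContacts <- function(viewpoint, fragmentEnds,
                             contactTargets = NULL, signalRate,
                             backgroundRate, chrom = "chrS1",
                             seed = 1) {
    if (signalRate < 0 || signalRate > 1 || backgroundRate < 0 ||
        backgroundRate > 1)
        stop("rates must lie in [0, 1]")
    if (signalRate < backgroundRate)
        stop("signalRate must be >= backgroundRate")
    ends <- sort(unique(as.integer(fragmentEnds)))
    if (!viewpoint %in% ends)
        stop("viewpoint is not among the fragment ends")
    inTarget <- rep(FALSE, length(ends))
    if (!is.null(contactTargets) && length(contactTargets)) {
        endGr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(ends + 1L, width = 1L))
        tg <- contactTargets
        GenomeInfoDb::seqlevels(tg) <- unique(c(
            GenomeInfoDb::seqlevels(tg), chrom))
        inTarget <- IRanges::overlapsAny(endGr, tg,
                                         ignore.strand = TRUE)
    }
    withSeed(seed, {
        p <- ifelse(inTarget, signalRate, backgroundRate)
        pos <- rbinom(length(ends), 1L, p)
        reads <- ifelse(pos == 1L, 1L + rpois(length(ends), 2), 0L)
        contactProfile(chrom = chrom, ends = ends, reads = reads,
                       viewpoint = viewpoint)
    })
}

#' Simulate restriction fragment ends
#'
#' Fragment-end positions along a chromosome with exponential spacing
#' (frequent 4-bp cutter), always including the viewpoint.
#'
#' @param length Chromosome length in bp.
#' @param n Approximate number of ends.
#' @param viewpoint 0-based viewpoint position to include.
#' @param seed Integer seed.
#' @return Sorted integer vector of 0-based positions.
#' @export
simulateFragmentEnds <- function(length, n, viewpoint, seed = 1) {
    withSeed(seed, {
        ends <- sort(unique(c(as.integer(viewpoint),
            sample.int(length, n) - 1L)))
        ends
    })
}

#' Simulate a full two-time-point experiment
#'
#' Orchestrates the generator: annotations (genes, classes, counts,
#' events, peaks, inert regions, contact targets), the t1 landscape,
#' the t2 landscape with events applied, and fragment sets for both
#' time points.
#'
#' @param spec A \linkS4class{LandscapeSpec}.
#' @param ... Passed to [simulateAnnotations()].
#' @param occupancy Fragments per nucleosome (default: the spec's).
#' @param seed Master seed (defaults to the spec's); per-stage seeds
#'   are derived from it.
#' @param keepTracks Also return the two per-bp tracks (large).
#' @return List with \code{truth} (\linkS4class{SyntheticTruth}),
#'   \code{t1}, \code{t2} (fragment GRanges) and optionally
#'   \code{trackT1}, \code{trackT2}.
#' @export
simulateExperiment <- function(spec, ..., occupancy = NULL,
                               seed = NULL, keepTracks = FALSE) {
    stopifnot(is(spec, "LandscapeSpec"))
    if (is.null(seed)) seed <- spec@seed
    seeds <- deriveSeeds(seed, 3L)
    truth <- simulateAnnotations(spec, ..., seed = seeds[[1L]])
    trackT1 <- simulateLandscape(spec, truthGenes(truth))
    trackT2 <- applyEvents(trackT1, truthEvents(truth))
    t1 <- sampleFragments(trackT1, spec, occupancy = occupancy,
                          seed = seeds[[2L]])
    t2 <- sampleFragments(trackT2, spec, occupancy = occupancy,
                          seed = seeds[[3L]])
    out <- list(truth = truth, t1 = t1, t2 = t2)
    if (keepTracks) {
        out$trackT1 <- trackT1
        out$trackT2 <- trackT2
    }
    out
}
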