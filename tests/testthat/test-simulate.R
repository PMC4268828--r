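smallSpec <- function(len = 2e5, seed = 4, ...) {
    landscapeSpec(chromLengths = c(chrS1 = len), seed = seed, ...)
}

test_that("landscape specification enforces its invariants", {
    expect_error(landscapeSpec(chromLengths = c(chrS1 = 1000)),
                 "10 nucleosome repeats")
    expect_error(landscapeSpec(chromLengths = c(chrS1 = 1e5),
                               fragLenSd = -1), "fragLenSd")
    spec <- smallSpec()
    expect_s4_class(spec, "LandscapeSpec")
    expect_equal(GenomeInfoDb::seqlengths(specSeqinfo(spec)),
                 c(chrS1 = 2e5))
})

test_that("phased arrays appear downstream of expressed TSSs", {
    spec <- smallSpec()
    genes <- GRanges("chrS1", IRanges(50001, 100000), strand = "+")
    tr <- simulateLandscape(spec, genes)[[1]]
    # autocorrelation of the array region peaks at the repeat length
    seg <- tr[50001:90000]
    ac <- stats::acf(seg, lag.max = 250, plot = FALSE)$acf[-1]
    lagPeak <- which.max(ac[150:250]) + 149
    expect_true(abs(lagPeak - 190) <= 5)
    # background untouched outside the gene
    expect_equal(unique(tr[1:40000]), 1 / 190)
    expect_error(simulateLandscape(spec,
        GRanges("chrS1", IRanges(199000, 300000), strand = "+")),
        "outside genome")
})

test_that("empty gene set gives a homogeneous landscape", {
    tr <- simulateLandscape(smallSpec())[[1]]
    bins <- colMeans(matrix(tr, nrow = 1000))
    cv <- sd(bins) / mean(bins)
    expect_lt(cv, 0.01)
})

test_that("landscape and fragment generation are deterministic", {
    spec <- smallSpec()
    genes <- geneGR(10000, 40000, chrom = "chrS1",
                    si = specSeqinfo(spec))
    expect_identical(simulateLandscape(spec, genes),
                     simulateLandscape(spec, genes))
    tr <- simulateLandscape(spec, genes)
    f1 <- sampleFragments(tr, spec, seed = 9)
    f2 <- sampleFragments(tr, spec, seed = 9)
    expect_identical(as.data.frame(f1), as.data.frame(f2))
    p1 <- tempfile(fileext = ".bed"); p2 <- tempfile(fileext = ".bed")
    writeIntervals(f1, p1); writeIntervals(f2, p2)
    expect_identical(readLines(p1), readLines(p2))
})

test_that("events modify the track multiplicatively or by shift", {
    spec <- smallSpec()
    tr <- simulateLandscape(spec)
    ev <- plantedEvents("chrS1", 0, 25000, "depletion", factor = 0.5)
    tr2 <- applyEvents(tr, ev)
    expect_equal(mean(tr2[[1]][1:25000]), 0.5 * mean(tr[[1]][1:25000]))
    expect_equal(tr2[[1]][25001:2e5], tr[[1]][25001:2e5])

    # shift: cross-correlation of old vs new maximal at the shift lag
    genes <- GRanges("chrS1", IRanges(50001, 100000), strand = "+")
    trg <- simulateLandscape(spec, genes)
    sh <- plantedEvents("chrS1", 50000, 100000, "shift", shift = 15)
    trs <- applyEvents(trg, sh)
    old <- trg[[1]][52001:98000]
    new <- trs[[1]][52001:98000]
    cc <- vapply(0:30, function(l)
        sum(old[1:(length(old) - 30)] * new[(1 + l):(length(old) - 30 + l)]),
        numeric(1))
    expect_equal(which.max(cc) - 1L, 15L)

    expect_identical(applyEvents(tr, GRanges()), tr)
    over <- plantedEvents("chrS1", c(0, 10000), c(20000, 30000),
                          c("depletion", "enrichment"),
                          factor = c(0.5, 2))
    expect_error(applyEvents(tr, over), "contradictory")
    expect_error(plantedEvents("chrS1", 0, 10, "depletion", factor = 2),
                 "factor < 1")
    expect_error(plantedEvents("chrS1", 0, 10, "shift", shift = 0),
                 "non-zero shift")
})

test_that("fragment counts follow the Poisson sampling law", {
    spec <- landscapeSpec(chromLengths = c(chrS1 = 2e6), seed = 1)
    tr <- simulateLandscape(spec)
    # homogeneous track: expectation = occupancy x nucleosome count
    occ <- 4
    expN <- occ * sum(tr[[1]])
    frags <- sampleFragments(tr, spec, occupancy = occ, seed = 31)
    expect_lt(abs(length(frags) - expN), 4 * sqrt(expN))
    # variance/mean over disjoint regions at expectation >= 50
    mids <- fragmentMidpoints(frags)
    grid <- tileWindows(specSeqinfo(spec), 10000)
    counts <- countMidpoints(mids, grid)
    expect_gte(mean(counts), 50)
    expect_gt(var(counts) / mean(counts), 0.8)
    expect_lt(var(counts) / mean(counts), 1.2)
    expect_error(sampleFragments(tr, spec, occupancy = 0), "occupancy")
})

test_that("a point-mass track collapses all midpoints onto the dyad", {
    spec <- smallSpec()
    tr <- list(chrS1 = numeric(2e5))
    tr[[1]][100001] <- 1   # all mass at 0-based position 100000
    frags <- sampleFragments(tr, spec, occupancy = 200, seed = 5)
    mids <- start(fragmentMidpoints(frags)) - 1L
    expect_true(all(abs(mids - 100000) <= 1))
})

test_that("annotations honour class fractions and truth invariants", {
    spec <- landscapeSpec(chromLengths = c(chrS1 = 2e6), seed = 3)
    truth <- simulateAnnotations(spec, nGenes = 30,
        classFractions = c(up = 0, down = 0, constitutive = 0),
        seed = 8)
    expect_true(all(truthGenes(truth)$class == "unexpressed"))
    expect_true(all(truthCounts(truth) == 0L))

    truth2 <- simulateAnnotations(spec, nGenes = 30, nDepletion = 8,
        eventWidth = 25000, nPeaks = 60, tfEnrichmentOdds = 4,
        seed = 9)
    genes <- truthGenes(truth2)
    expressed <- genes[genes$class != "unexpressed"]
    # inert regions never overlap expressed genes or planted events
    expect_false(any(overlapsAny(truthInert(truth2), expressed,
                                 ignore.strand = TRUE)))
    expect_false(any(overlapsAny(truthInert(truth2),
                                 truthEvents(truth2),
                                 ignore.strand = TRUE)))
    # every planted event appears exactly once
    ev <- truthEvents(truth2)
    expect_equal(length(ev), 8L)
    expect_equal(anyDuplicated(as.data.frame(ev)), 0L)
    # true fold-changes respect the class thresholds
    expect_true(all(genes$trueLog2FC[genes$class == "up"] > 0.6))
    expect_true(all(genes$trueLog2FC[genes$class == "down"] < -0.6))
    expect_true(all(genes$trueLog2FC[genes$class == "constitutive"] == 0))
    expect_error(simulateAnnotations(spec, nGenes = 200,
        geneLengthRange = c(25000, 30000), seed = 1), "capacity")
})

test_that("TF peak placement follows the odds arithmetic", {
    # odds 4 with 20% of the genome depleted => expected in-share
    # 4*0.2 / (4*0.2 + 0.8) = 0.5
    spec <- landscapeSpec(chromLengths = c(chrS1 = 1e7), seed = 2)
    truth <- simulateAnnotations(spec, nGenes = 0, nDepletion = 40,
        eventWidth = 50000, nPeaks = 200, tfEnrichmentOdds = 4,
        seed = 12)
    dep <- reduce(granges(truthEvents(truth)))
    frac <- sum(width(dep)) / 1e7
    expect_equal(frac, 0.2, tolerance = 0.01)
    inDep <- mean(overlapsAny(truthPeaks(truth), dep))
    expect_lt(abs(inDep - 0.5), 4 * sqrt(0.25 / 200))

    # odds 1: in-depletion share matches the depleted fraction
    truth1 <- simulateAnnotations(spec, nGenes = 0, nDepletion = 40,
        eventWidth = 50000, nPeaks = 400, tfEnrichmentOdds = 1,
        seed = 13)
    dep1 <- reduce(granges(truthEvents(truth1)))
    in1 <- mean(overlapsAny(truthPeaks(truth1), dep1))
    expect_lt(abs(in1 - 0.2), 4 * sqrt(0.2 * 0.8 / 400))
})

test_that("contact simulation follows the stated rates", {
    ends <- simulateFragmentEnds(2e6, 10000, viewpoint = 1e6, seed = 6)
    expect_true(1e6 %in% ends)
    expect_false(is.unsorted(ends, strictly = TRUE))

    # background only: positive count within 4 sigma of n * rate
    prof <- simulateContacts(1e6, ends, NULL, signalRate = 0.05,
                             backgroundRate = 0.05, seed = 7)
    n <- length(ends)
    expect_lt(abs(sum(contactEnds(prof)$binary) - 0.05 * n),
              4 * sqrt(n * 0.05 * 0.95))

    # zero background, one target: positives only inside the target
    tgt <- GRanges("chrS1", IRanges(500001, 540000))
    prof2 <- simulateContacts(1e6, ends, tgt, signalRate = 0.9,
                              backgroundRate = 0, seed = 8)
    posEnds <- contactEnds(prof2)$pos[contactEnds(prof2)$binary == 1]
    expect_true(all(posEnds >= 500000 & posEnds < 540000))
    expect_gt(length(posEnds), 0)

    expect_error(simulateContacts(123, ends, NULL, 0.5, 0.1),
                 "viewpoint")
    expect_error(simulateContacts(1e6, ends, NULL, 0.1, 0.5),
                 "signalRate")
    # determinism
    prof3 <- simulateContacts(1e6, ends, tgt, 0.9, 0, seed = 8)
    expect_identical(contactEnds(prof2), contactEnds(prof3))
})

test_that("full experiment simulation is seed-reproducible", {
    spec <- landscapeSpec(chromLengths = c(chrS1 = 1e6),
                          baseOccupancy = 8, seed = 14)
    a <- simulateExperiment(spec, nGenes = 10, nDepletion = 3,
                            eventWidth = 20000, nPeaks = 20)
    b <- simulateExperiment(spec, nGenes = 10, nDepletion = 3,
                            eventWidth = 20000, nPeaks = 20)
    expect_identical(as.data.frame(a$t1), as.data.frame(b$t1))
    expect_identical(as.data.frame(truthGenes(a$truth)),
                     as.data.frame(truthGenes(b$truth)))
    expect_identical(truthCounts(a$truth), truthCounts(b$truth))
})
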