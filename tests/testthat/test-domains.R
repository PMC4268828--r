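test_that("peak embedding uses the covered-fraction rule", {
    dom <- GRanges("chrA", IRanges(c(1, 5001), c(5000, 10000)))
    peaks <- GRanges("chrA", IRanges(c(1001, 4901, 4801),
                                     c(1200, 5500, 5200)))
    rep <- overlapEmbedded(peaks, dom[1])
    expect_equal(rep$peaks$overlapFraction[1], 1)      # fully inside
    expect_equal(rep$peaks$overlapFraction[2], 100 / 600,
                 tolerance = 1e-12)                    # partial
    expect_true(rep$peaks$embedded[1])
    expect_false(rep$peaks$embedded[2])
    # spanning two adjacent domains: the union covers it fully
    rep2 <- overlapEmbedded(peaks[3], dom)
    expect_equal(rep2$peaks$overlapFraction, 1)
    expect_true(rep2$peaks$embedded)
    expect_equal(rep$nEmbedded + sum(!rep$peaks$embedded), rep$nPeaks)
    expect_error(overlapEmbedded(GRanges("chrA", IRanges(5, 4)), dom),
                 "zero-length")
})

test_that("embedding is monotone in the threshold", {
    set.seed(15)
    dom <- GRanges("chrA", IRanges(seq(1, 40000, 4000), width = 2000))
    peaks <- GRanges("chrA",
        IRanges(sample.int(45000, 100), width = sample(100:800, 100,
                                                       replace = TRUE)))
    fr <- c(0.1, 0.25, 0.5, 0.9, 1)
    emb <- vapply(fr, function(f)
        overlapEmbedded(peaks, dom, minFrac = f)$nEmbedded, numeric(1))
    expect_true(all(diff(emb) <= 0))
})

test_that("location classes partition intervals with promoter precedence", {
    genes <- geneGR(c(10000, 30000), c(20000, 40000),
                    strand = c("+", "-"))
    iv <- GRanges("chrA", IRanges(
        c(9401, 15001, 25001, 39801, 10501),
        c(9600, 15200, 25200, 40000, 10700)))
    loc <- annotateLocation(iv, genes)
    # midpoint 500 bp upstream of the + TSS
    expect_equal(as.character(loc[1]), "promoter")
    expect_equal(as.character(loc[2]), "intragenic")
    expect_equal(as.character(loc[3]), "intergenic")
    # minus-strand TSS sits at the gene end
    expect_equal(as.character(loc[4]), "promoter")
    # inside the gene but within 1 kbp of its TSS: promoter wins
    expect_equal(as.character(loc[5]), "promoter")
    expect_equal(sum(table(loc)), length(iv))
})

test_that("Fisher association reports the cross-product odds ratio", {
    fa <- fisherAssociation(5, 10, 5, 90)
    expect_equal(fa$oddsRatio, 17)
    bal <- fisherAssociation(10, 20, 10, 20)
    expect_equal(bal$oddsRatio, 1)
    expect_equal(bal$p, 1)
    expect_error(fisherAssociation(0, 10, 0, 20), "empty margin")
    expect_error(fisherAssociation(5, 4, 1, 2), "hits")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
    expect_equal(fisherAssociation(3, 10, 10, 90)$p,
                 bruteFisherP(3, 7, 10, 80), tolerance = 1e-12)
    set.seed(16)
    for (i in 1:50) {
        n <- sample(4:60, 1)
        a <- sample.int(n - 3, 1)
        b <- sample.int(n - a - 2, 1)
        c <- sample.int(n - a - b - 1, 1)
        d <- n - a - b - c
        got <- fisherAssociation(a, a + b, c, c + d)$p
        expect_equal(got, bruteFisherP(a, b, c, d), tolerance = 1e-12)
        # independent cross-check against the reference implementation
        expect_equal(got,
            fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
            tolerance = 1e-9)
    }
})

test_that("IUPAC motif scan reports both strands", {
    hits <- motifScan("GGAAATTCCC")
    expect_equal(hits$start, c(0L, 0L))      # palindromic consensus:
    expect_setequal(hits$strand, c("+", "-"))  # once per strand
    expect_equal(nrow(motifScan("GGGGGGGGGG")), 0L)
    seq <- paste0("TTTT", "GGAAATTCCC", "TTTT")
    expect_equal(unique(motifScan(seq)$start), 4L)
    fwdOnly <- motifScan("GGAAATTCCC", bothStrands = FALSE)
    expect_equal(fwdOnly$strand, "+")
    expect_error(motifScan("ACGT", pattern = "GGXRNNYYCC"),
                 "invalid IUPAC")
    # non-palindromic pattern: reverse-complement hits on minus strand
    hits2 <- motifScan("TTGACGTT", pattern = "AACGTCAA")
    expect_equal(hits2$strand, "-")
    expect_equal(hits2$start, 0L)
})

test_that("multi-scale analysis detects broad events at every scale", {
    spec <- landscapeSpec(chromLengths = c(chrS1 = 1e7),
                          baseOccupancy = 10, seed = 18)
    si <- specSeqinfo(spec)
    tr <- simulateLandscape(spec)
    big <- plantedEvents("chrS1", 4e6, 4e6 + 1e5, "depletion",
                         factor = 0.5)
    tr2 <- applyEvents(tr, big)
    f1 <- sampleFragments(tr, spec, seed = 41)
    f2 <- sampleFragments(tr2, spec, seed = 42)
    inertR <- gaps(big + 10000)
    inertR <- inertR[strand(inertR) == "*"]
    GenomeInfoDb::seqinfo(inertR) <- si
    ms <- multiscaleDomains(f1, f2, si,
        scales = c(5000, 25000, 50000, 1e5), inert = inertR,
        correction = "none", minInert = 30)
    expect_named(ms, c("5000", "25000", "50000", "1e+05"))
    for (sc in names(ms)) {
        dep <- depletedWindows(ms[[sc]])
        expect_gt(sum(overlapsAny(dep, big)), 0)
    }
})

test_that("small events dilute away at coarse scales", {
    spec <- landscapeSpec(chromLengths = c(chrS1 = 1e7),
                          baseOccupancy = 8, seed = 19)
    si <- specSeqinfo(spec)
    tr <- simulateLandscape(spec)
    starts <- seq(5e5, 9.5e6, by = 1e6)
    small <- plantedEvents("chrS1", starts, starts + 5000, "depletion",
                           factor = 0.5)
    tr2 <- applyEvents(tr, small)
    f1 <- sampleFragments(tr, spec, seed = 43)
    f2 <- sampleFragments(tr2, spec, seed = 44)
    mkInert <- function(w) !overlapsAny(tileWindows(si, w), small)
    fine <- occupancyLLR(f1, f2, genome = si, windowSize = 5000,
        inert = mkInert(5000), correction = "none")
    coarse <- occupancyLLR(f1, f2, genome = si, windowSize = 1e5,
        inert = mkInert(1e5), correction = "none", minInert = 30)
    hitFine <- sum(overlapsAny(small, depletedWindows(fine)))
    hitCoarse <- sum(overlapsAny(small, depletedWindows(coarse)))
    expect_equal(hitFine, 10L)      # all recovered at the native scale
    expect_lte(hitCoarse, 5L)       # diluted 20-fold at 100 kbp
})
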