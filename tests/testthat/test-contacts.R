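test_that("read binarization is a threshold at one read", {
    expect_equal(binarizeReads(c(0, 3, 1, 0)), c(0L, 1L, 1L, 0L))
    expect_equal(binarizeReads(rep(0, 5)), rep(0L, 5))
    b <- c(0L, 1L, 1L, 0L)
    expect_identical(binarizeReads(b), b)   # idempotent
    expect_error(binarizeReads(c(-1, 2)), "non-negative")
})

test_that("contact profiles validate and sort their ends", {
    prof <- contactProfile("chrA", ends = c(30L, 10L, 20L),
                           reads = c(1L, 0L, 2L), viewpoint = 10L)
    expect_equal(contactEnds(prof)$pos, c(10L, 20L, 30L))
    expect_equal(contactEnds(prof)$reads, c(0L, 2L, 1L))
    expect_error(contactProfile("chrA", c(1L, 1L, 2L), c(0L, 0L, 0L),
                                1L), "unique")
    expect_error(contactProfile("chrA", c(1L, 2L), c(0L, 0L), 99L),
                 "viewpoint")
})

# Deterministic profile: 500 ends 1 kb apart; positives clustered.
clusterProfile <- function(posIdx) {
    ends <- seq(0L, by = 1000L, length.out = 500L)
    reads <- integer(500)
    reads[posIdx] <- 2L
    contactProfile("chrA", ends, reads, viewpoint = ends[250])
}

test_that("sliding enrichment is the window rate over background", {
    prof <- clusterProfile(c(101:110, sample(300:500, 10)))
    dg <- slidingEnrichment(prof, wmin = 2000, wmax = 50000,
                            nSizes = 6, seed = 1)
    tab <- domainogramTable(dg)
    # background sampled without replacement covers all 500 ends
    expect_equal(dg@backgroundRate, mean(contactEnds(prof)$binary))
    # a 10-kb window fully inside the positive cluster scores 1/bg
    w <- tab[tab$size == 10000 & tab$start >= 100000 &
             tab$end <= 110000, ]
    expect_true(all(abs(w$score - 1 / dg@backgroundRate) < 1e-9))
    # windows with fewer than 3 ends are masked
    expect_true(all(is.na(tab$score[tab$masked])))
    expect_true(all(tab$nEnds[!tab$masked] >= 3))
    expect_error(slidingEnrichment(contactProfile("chrA", 5L, 1L, 5L)),
                 "at least 2")
})

test_that("window scores match a brute-force recount", {
    set.seed(31)
    ends <- sort(sample.int(5e5, 400))
    reads <- rbinom(400, 1, 0.2)
    reads[1] <- 1L   # keep the profile non-degenerate at the viewpoint
    prof <- contactProfile("chrA", ends, reads, viewpoint = ends[1])
    dg <- slidingEnrichment(prof, wmin = 5000, wmax = 100000,
                            nSizes = 5, seed = 2)
    tab <- domainogramTable(dg)
    bin <- contactEnds(prof)$binary
    for (k in sample(which(!tab$masked), 50)) {
        inWin <- ends >= tab$start[k] & ends < tab$end[k]
        expect_equal(tab$nEnds[k], sum(inWin))
        expect_equal(tab$score[k],
                     (sum(bin[inWin]) / sum(inWin)) / dg@backgroundRate)
    }
})

test_that("end counts are monotone in window size at a fixed start", {
    prof <- clusterProfile(1:20)
    dg <- slidingEnrichment(prof, wmin = 2000, wmax = 64000,
                            nSizes = 6, seed = 3)
    tab <- domainogramTable(dg)
    common <- Reduce(intersect, split(tab$start, tab$size))
    for (s in head(common, 10)) {
        sub <- tab[tab$start == s, ]
        sub <- sub[order(sub$size), ]
        expect_true(all(diff(sub$nEnds) >= 0))
    }
})

test_that("permutation FDR recovers a strong target and is reproducible", {
    ends <- simulateFragmentEnds(1e6, 2500, viewpoint = 5e5, seed = 4)
    tgt <- GRanges("chrS1", IRanges(200001, 240000))
    prof <- simulateContacts(5e5, ends, tgt, signalRate = 0.9,
                             backgroundRate = 0.05, seed = 5)
    dg <- slidingEnrichment(prof, wmax = 100000, seed = 6)
    dg <- permutationFDR(prof, dg, nPerm = 100, fdr = 0.01, seed = 7)
    sig <- significantWindows(dg)
    expect_gt(length(sig), 0)
    expect_true(any(overlapsAny(sig, GRanges("chrS1",
        IRanges(200001, 240000)))))
    dg2 <- permutationFDR(prof, slidingEnrichment(prof, wmax = 100000,
        seed = 6), nPerm = 100, fdr = 0.01, seed = 7)
    expect_identical(domainogramTable(dg),
                     domainogramTable(dg2))
    expect_error(permutationFDR(prof, dg, nPerm = 10), "100")
})

test_that("null profiles stay near the nominal FDR", {
    ends <- simulateFragmentEnds(1e6, 2500, viewpoint = 5e5, seed = 8)
    prof <- simulateContacts(5e5, ends, NULL, signalRate = 0.05,
                             backgroundRate = 0.05, seed = 9)
    dg <- suppressWarnings(permutationFDR(prof,
        slidingEnrichment(prof, wmax = 100000, seed = 10),
        nPerm = 100, fdr = 0.01, seed = 11))
    tab <- domainogramTable(dg)
    expect_lte(mean(tab$significant[!tab$masked]), 0.02)
})

test_that("degenerate signal yields no threshold, with a warning", {
    ends <- seq(0L, by = 1000L, length.out = 300L)
    prof <- contactProfile("chrA", ends, rep(1L, 300), ends[1])
    dg <- slidingEnrichment(prof, wmax = 50000, seed = 1)
    expect_warning(dg <- permutationFDR(prof, dg, nPerm = 100),
                   "degenerate")
    expect_length(significantWindows(dg), 0L)
})

test_that("contact association with depleted windows runs Fisher", {
    ends <- simulateFragmentEnds(1e6, 2500, viewpoint = 5e5, seed = 12)
    dep <- GRanges("chrS1", IRanges(200001, 240000))
    prof <- simulateContacts(5e5, ends, dep, signalRate = 0.9,
                             backgroundRate = 0.04, seed = 13)
    dg <- permutationFDR(prof,
        slidingEnrichment(prof, wmax = 100000, seed = 14),
        nPerm = 100, fdr = 0.01, seed = 15)
    depA <- GRanges("chrS1", ranges(dep))
    res <- contactsVsDepletion(dg, depA)
    expect_gt(res$oddsRatio, 1)
    expect_lt(res$p, 0.05)
    expect_gt(res$fracSignificantInDepleted, res$fracOtherInDepleted)

    # no significant contacts: no test is run
    null <- simulateContacts(5e5, ends, NULL, 0.05, 0.05, seed = 16)
    dgn <- suppressWarnings(permutationFDR(null,
        slidingEnrichment(null, wmax = 100000, seed = 17),
        nPerm = 100, seed = 18))
    if (!any(domainogramTable(dgn)$significant, na.rm = TRUE)) {
        expect_message(out <- contactsVsDepletion(dgn, depA),
                       "no significant")
        expect_null(out)
    }
    # depleted set covering every scored window: empty margin
    whole <- GRanges("chrS1", IRanges(1, 1e6))
    expect_error(contactsVsDepletion(dg, whole), "empty margin")
})
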