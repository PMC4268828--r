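test_that("genome tiling keeps flagged terminal remainders", {
    grid <- tileWindows(c(chrA = 12000L), 5000)
    expect_equal(start(grid) - 1L, c(0L, 5000L, 10000L))
    expect_equal(end(grid), c(5000L, 10000L, 12000L))
    expect_equal(grid$partial, c(FALSE, FALSE, TRUE))

    exact <- tileWindows(c(chrA = 5000L), 5000)
    expect_length(exact, 1L)
    expect_false(exact$partial)

    two <- tileWindows(c(chrA = 7000L, chrB = 6000L), 5000)
    expect_true(all(end(two) <= GenomeInfoDb::seqlengths(two)[
        as.character(seqnames(two))]))
    expect_equal(as.vector(table(seqnames(two))), c(2L, 2L))
    expect_error(tileWindows(c(chrA = 1000L), 0), "windowSize")
})

test_that("midpoint counting is half-open and mass-preserving", {
    si <- GenomeInfoDb::Seqinfo("chrA", 10000L)
    grid <- tileWindows(si, 5000)
    mids <- midGR(c(100, 4999, 5000), si = si)
    expect_equal(countMidpoints(mids, grid), c(2L, 1L))
    expect_equal(countMidpoints(midGR(integer(0), si = si), grid),
                 c(0L, 0L))
    expect_error(
        countMidpoints(GRanges("chrA", IRanges(10001, width = 1)), grid),
        "beyond chromosome end")
})

test_that("midpoint counting matches a per-midpoint scan", {
    set.seed(11)
    si <- GenomeInfoDb::Seqinfo("chrA", 50000L)
    grid <- tileWindows(si, 3000)
    pos0 <- sample.int(50000L, 1000, replace = TRUE) - 1L
    got <- countMidpoints(midGR(pos0, si = si), grid)
    brute <- integer(length(grid))
    for (p in pos0) {
        w <- which(p >= start(grid) - 1L & p < end(grid))
        brute[w] <- brute[w] + 1L
    }
    expect_identical(got, brute)
    expect_equal(sum(got), 1000L)
})

test_that("log ratio follows the stated formula and masking", {
    expect_equal(logRatio(100, 100, 0.5, 0, normalize = FALSE)$q, 0)
    expect_equal(logRatio(8, 2, pseudocount = 0, minCount = 0,
                          normalize = FALSE)$q, 2)
    expect_equal(logRatio(0, 0, 0.5, 0, normalize = FALSE)$q, 0)
    expect_error(logRatio(c(4, 0), c(2, 3), pseudocount = 0,
                          minCount = 0, normalize = FALSE),
                 "pseudocount = 0")
    lr <- logRatio(c(100, 5), c(100, 5), minCount = 20,
                   normalize = FALSE)
    expect_equal(lr$lowCoverage, c(FALSE, TRUE))
})

test_that("centring is exact and absorbs library scaling", {
    expect_equal(centerLogRatios(c(1, 2, 3))$centered, c(-1, 0, 1))
    expect_equal(centerLogRatios(c(5, 5, 5))$centered, c(0, 0, 0))
    expect_error(centerLogRatios(c(1, 2), lowCoverage = c(TRUE, TRUE)),
                 "all windows are masked")
    set.seed(3)
    r <- rpois(500, 100)
    s <- rpois(500, 100)
    a <- centerLogRatios(logRatio(r, s)$q)$centered
    b <- centerLogRatios(logRatio(r, 3L * s)$q)$centered
    expect_equal(a, b)   # depth scaling absorbed exactly
    expect_lt(abs(mean(a)), 1e-9)
})

test_that("inert null is an empirical CDF with guard rails", {
    null <- buildInertNull(c(-1, 0, 1), rep(TRUE, 3), minInert = 1)
    expect_equal(nullCDF(null, 0), 2 / 3)
    expect_equal(nullCDF(null, c(-2, 2)), c(0, 1))
    expect_error(buildInertNull(rep(0.3, 50), rep(TRUE, 50),
                                minInert = 10), "degenerate")
    expect_error(buildInertNull(rnorm(50), rep(TRUE, 50),
                                minInert = 100), "inert windows")
})

test_that("empirical p-values follow the add-one rank convention", {
    null <- buildInertNull(c(0.1, 0.2, 0.3, 0.4), rep(TRUE, 4),
                           minInert = 1)
    expect_equal(empiricalPvalue(0.35, null, "depletion"), 0.4)
    expect_equal(empiricalPvalue(0.05, null, "depletion"), 1.0)
    expect_equal(empiricalPvalue(0.5, null, "depletion"), 0.2)
    expect_equal(empiricalPvalue(0.25, null, "enrichment"),
                 (1 + 2) / 5)
    expect_error(empiricalPvalue(0, null, "sideways"))
})

test_that("empirical p-values match the brute-force rank count", {
    set.seed(7)
    for (rep in 1:3) {
        nullVals <- round(rnorm(200), 2)   # ties included
        x <- c(round(rnorm(100), 2), sample(nullVals, 20))
        null <- buildInertNull(nullVals, rep(TRUE, 200), minInert = 1)
        for (side in c("depletion", "enrichment")) {
            expect_equal(empiricalPvalue(x, null, side),
                         bruteEmpiricalP(x, nullVals, side))
        }
    }
})

test_that("right-tail p is monotone non-increasing in the statistic", {
    set.seed(8)
    null <- buildInertNull(rnorm(500), rep(TRUE, 500), minInert = 1)
    x <- sort(rnorm(300))
    p <- empiricalPvalue(x, null, "depletion")
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0 & p <= 1))
})

test_that("window labelling applies BH per tail", {
    pr <- c(0.01, 0.02, 0.04, 0.05)
    pl <- 1 - pr + 0.2
    lab <- labelWindows(pr, pmin(pl, 1), alpha = 0.05,
                        correction = "BH")
    expect_equal(lab, rep("depleted", 4))  # BH step-up rejects all
    expect_equal(labelWindows(rep(1, 4), rep(1, 4)),
                 rep("unchanged", 4))
    pr2 <- c(0.01, 0.2, 0.9)
    lab2 <- labelWindows(pr2, rep(0.8, 3), correction = "none")
    expect_equal(lab2 == "depleted", pr2 < 0.05)
    lab3 <- labelWindows(pr2, rep(0.8, 3), correction = "none",
                         lowCoverage = c(TRUE, FALSE, FALSE))
    expect_equal(lab3[1], "low_coverage")
})

test_that("running mean shrinks at the edges", {
    expect_equal(runningMean(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
    expect_equal(runningMean(1:5, 1), 1:5)
    expect_equal(runningMean(rep(2.5, 10), 5), rep(2.5, 10))
    expect_error(runningMean(1:5, 2), "odd")
    expect_equal(runningMean(c(1, NA, 3), 3, na.rm = TRUE), c(1, 2, 3))
})

test_that("scaling one library leaves the full result unchanged", {
    # exact depth invariance: counts scaled 3x at t2 change nothing
    set.seed(21)
    r <- rpois(400, 120)
    s <- rpois(400, 120)
    run <- function(s) {
        lr <- logRatio(r, s)
        ct <- centerLogRatios(lr$q, lr$lowCoverage)
        null <- buildInertNull(ct$centered, rep(TRUE, 400),
                               lr$lowCoverage)
        pR <- empiricalPvalue(ct$centered, null, "depletion")
        pL <- empiricalPvalue(ct$centered, null, "enrichment")
        list(centered = ct$centered, pR = pR, pL = pL,
             label = labelWindows(pR, pL, lowCoverage = lr$lowCoverage),
             mask = lr$lowCoverage)
    }
    a <- run(s)
    b <- run(3L * s)
    expect_identical(a$label, b$label)
    expect_identical(a$mask, b$mask)
    expect_equal(a$centered, b$centered, tolerance = 1e-12)
    expect_equal(a$pR, b$pR, tolerance = 1e-12)
    expect_equal(a$pL, b$pL, tolerance = 1e-12)
})

test_that("occupancyLLR assembles a valid annotated object", {
    spec <- landscapeSpec(chromLengths = c(chrS1 = 6e5),
                          baseOccupancy = 10, seed = 2)
    tr <- simulateLandscape(spec)
    f1 <- sampleFragments(tr, spec, seed = 11)
    f2 <- sampleFragments(tr, spec, seed = 12)
    res <- occupancyLLR(f1, f2, genome = specSeqinfo(spec),
                        windowSize = 5000)
    expect_s4_class(res, "OccupancyResult")
    expect_true(validObject(res))
    expect_equal(nrow(res), 120L)
    expect_equal(sum(windowCounts(res)[, "t1"]), length(f1))
    expect_lt(abs(mean(centeredRatios(res)[
        !rowData(res)$lowCoverage])), 1e-9)
    expect_equal(logRatios(res) - qMean(res), centeredRatios(res))
    # null windows exclude the flagged partial remainder
    expect_false(any(rowData(res)$inert & rowData(res)$partial))
    # fold-change track is the smoothed negated centred value
    expect_equal(foldChangeTrack(res, span = 1),
                 -centeredRatios(res))
    # table export keeps one row per window
    path <- tempfile(fileext = ".tsv")
    writeOccupancyTable(res, path)
    expect_equal(nrow(read.table(path, header = TRUE, sep = "\t")),
                 length(res))
})
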