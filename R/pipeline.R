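# End-to-end pipeline on synthetic data: simulate -> occupancy ->
# multi-scale domains / repositioning / metagene -> peak embedding and
# annotation -> contacts. Every run writes its resolved parameters and
# output checksums to a manifest so reruns are verifiably identical.

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a two-time-point experiment, runs every analysis stage in
#' dependency order and writes all inputs, outputs, a summary and a
#' manifest (resolved parameters, seed and md5 checksum per output)
#' into \code{outdir}. All randomness derives from the single
#' \code{seed}.
#'
#' @param outdir Output directory (created; must be empty or absent
#'   unless \code{overwrite}).
#' @param seed Global seed.
#' @param spec A \linkS4class{LandscapeSpec}.
#' @param windowSize Primary occupancy window size in bp.
#' @param scales Window sizes for the multi-scale stage.
#' @param nGenes,classFractions,geneLengthRange Gene generation (see
#'   [simulateAnnotations()]).
#' @param nDepletion,eventWidth,eventFactor Planted depletion events.
#' @param nPeaks,tfEnrichmentOdds TF peak generation.
#' @param alpha,correction Window labelling parameters.
#' @param minInert Minimum usable inert windows per scale for the
#'   empirical null.
#' @param bandwidth Dyad-calling kernel sd in bp.
#' @param shiftThreshold Repositioning criterion in bp.
#' @param nPerm Domainogram permutations.
#' @param contactFdr Domainogram FDR threshold.
#' @param signalRate,backgroundRate Contact simulation rates.
#' @param nEnds Fragment ends in the contact profile.
#' @param verbose Log stage progress to standard error.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(outdir, seed = 1,
        spec = landscapeSpec(chromLengths = c(chrS1 = 2e6),
                             baseOccupancy = 20),
        windowSize = 5000, scales = c(5000, 25000, 50000, 1e5),
        nGenes = 25,
        classFractions = c(up = 0.2, down = 0.15, constitutive = 0.35),
        geneLengthRange = c(8000, 20000),
        nDepletion = 8, eventWidth = 25000, eventFactor = 0.5,
        nPeaks = 100, tfEnrichmentOdds = 4, alpha = 0.05,
        correction = "BH", minInert = 100, bandwidth = 30,
        shiftThreshold = 10,
        nPerm = 200, contactFdr = 0.01, signalRate = 0.9,
        backgroundRate = 0.05, nEnds = 3000, verbose = TRUE,
        overwrite = FALSE) {
    checkScalar(windowSize, "windowSize", positive = TRUE)
    if (any(scales <= 0))
        stop("invalid configuration: scales must be positive")
    if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
        stop("output directory not empty: ", outdir)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (verbose) message("[nucleodyn] ", ...)
    pt <- function(f) file.path(outdir, f)
    seeds <- deriveSeeds(seed, 6L)
    si <- specSeqinfo(spec)

    say("stage simulate")
    sim <- simulateExperiment(spec, nGenes = nGenes,
        classFractions = classFractions,
        geneLengthRange = geneLengthRange, nDepletion = nDepletion,
        eventWidth = eventWidth, eventFactor = eventFactor,
        nPeaks = nPeaks, tfEnrichmentOdds = tfEnrichmentOdds,
        seed = seeds[[1L]])
    truth <- sim$truth
    writeChromSizes(si, pt("genome.chrom.sizes"))
    writeIntervals(sim$t1, pt("fragments_t1.bed"))
    writeIntervals(sim$t2, pt("fragments_t2.bed"))
    writeIntervals(truthGenes(truth), pt("genes.bed"))
    if (length(truthPeaks(truth)))
        writeNarrowPeak(truthPeaks(truth), pt("peaks.narrowPeak"))
    writeIntervals(truthInert(truth), pt("inert.bed"))
    ev <- truthEvents(truth)
    evTab <- cbind(grToBed0(ev), kind = ev$kind, factor = ev$factor,
                   shift = ev$shift)
    write.table(evTab, pt("truth_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cnt <- truthCounts(truth)
    write.table(data.frame(gene = rownames(cnt), cnt,
                           class = truthGenes(truth)$class),
                pt("gene_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    say("stage occupancy (", windowSize, " bp windows)")
    mid1 <- fragmentMidpoints(sim$t1)
    mid2 <- fragmentMidpoints(sim$t2)
    occ <- occupancyLLR(mid1, mid2, genome = si,
        windowSize = windowSize, inert = truthInert(truth),
        alpha = alpha, correction = correction, minInert = minInert)
    writeOccupancyTable(occ, pt("occupancy_windows.tsv"))
    writeBedGraph(SummarizedExperiment::rowRanges(occ),
        foldChangeTrack(occ), pt("occupancy_foldchange.bedGraph"),
        name = "log2FC_smoothed")
    writeIntervals(depletedWindows(occ), pt("depleted_windows.bed"))
    writeIntervals(enrichedWindows(occ), pt("enriched_windows.bed"))

    say("stage multiscale domains")
    ms <- multiscaleDomains(mid1, mid2, si, scales = scales,
        inert = truthInert(truth), alpha = alpha,
        correction = correction, minInert = minInert)
    msTab <- do.call(rbind, lapply(names(ms), function(sc) {
        tb <- table(factor(windowLabels(ms[[sc]]),
                           levels = OCCUPANCY_LABELS))
        data.frame(scale = as.integer(sc), label = names(tb),
                   windows = as.integer(tb))
    }))
    write.table(msTab, pt("multiscale_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    say("stage repositioning")
    calls0 <- callNucleosomes(mid1, bandwidth = bandwidth)
    calls1 <- callNucleosomes(mid2, bandwidth = bandwidth)
    events <- matchDyads(calls0, calls1,
                         shiftThreshold = shiftThreshold)
    write.table(events, pt("repositioning_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    unm <- unmaskedRegions(events)
    if (length(unm)) writeIntervals(unm, pt("unmasked_regions.bed"))

    say("stage metagene")
    classes <- classifyGenes(cnt[, "t1"], cnt[, "t2"])
    write.table(classes, pt("gene_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    genes <- truthGenes(truth)
    profs <- list()
    for (cl in c("up", "down", "constitutive")) {
        g <- genes[genes$class == cl]
        if (!length(g)) next
        p1 <- metageneProfile(mid1, g)
        p2 <- metageneProfile(mid2, g)
        profs[[cl]] <- data.frame(class = cl, bin = p1$bin,
            zone = p1$zone, t1 = p1$signal, t2 = p2$signal)
    }
    metagene <- do.call(rbind, profs)
    if (!is.null(metagene))
        write.table(metagene, pt("metagene_profiles.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)

    say("stage peak embedding and annotation")
    embed <- NULL
    if (length(truthPeaks(truth))) {
        embed <- overlapEmbedded(truthPeaks(truth),
                                 depletedWindows(occ))
        loc <- annotateLocation(truthPeaks(truth), genes)
        fa <- if (embed$nEmbedded > 0 &&
                  length(depletedWindows(occ)) > 0) {
            fisherAssociation(embed$nEmbedded, embed$nPeaks,
                length(depletedWindows(occ)), length(occ))
        } else {
            say("no depleted windows or embedded peaks; ",
                "association test skipped")
            list(oddsRatio = NA_real_, p = NA_real_)
        }
        assoc <- data.frame(
            nPeaks = embed$nPeaks, nEmbedded = embed$nEmbedded,
            nDepletedWindows = length(depletedWindows(occ)),
            nWindows = length(occ), oddsRatio = fa$oddsRatio,
            p = fa$p)
        write.table(assoc, pt("peak_association.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(as.data.frame(table(location = loc)),
                    pt("peak_locations.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    say("stage contacts")
    L <- GenomeInfoDb::seqlengths(si)[[1L]]
    viewpoint <- as.integer(L / 2)
    fragEnds <- simulateFragmentEnds(L, nEnds, viewpoint,
                                     seed = seeds[[2L]])
    cprof <- simulateContacts(viewpoint, fragEnds,
        truthContactTargets(truth), signalRate = signalRate,
        backgroundRate = backgroundRate,
        chrom = names(spec@chromLengths)[[1L]], seed = seeds[[3L]])
    writeContactEnds(cprof, pt("contact_ends.tsv"))
    wmax <- min(200000, as.integer(L / 5))
    dg <- slidingEnrichment(cprof, wmax = wmax, seed = seeds[[4L]])
    dg <- permutationFDR(cprof, dg, nPerm = nPerm, fdr = contactFdr,
                         seed = seeds[[5L]])
    write.table(domainogramTable(dg), pt("domainogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- significantWindows(dg)
    if (length(sig)) writeIntervals(sig, pt("contact_windows.bed"))
    cvd <- if (length(depletedWindows(occ))) {
        tryCatch(contactsVsDepletion(dg, depletedWindows(occ)),
            error = function(e) {
                say("contact association degenerate: ",
                    conditionMessage(e))
                NULL
            })
    } else NULL
    if (!is.null(cvd))
        write.table(data.frame(oddsRatio = cvd$oddsRatio, p = cvd$p,
            fracSignificantInDepleted = cvd$fracSignificantInDepleted,
            fracOtherInDepleted = cvd$fracOtherInDepleted),
            pt("contact_association.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

    say("writing manifest")
    params <- list(seed = seed, windowSize = windowSize,
        scales = scales, nGenes = nGenes,
        classFractions = as.list(classFractions),
        geneLengthRange = geneLengthRange, nDepletion = nDepletion,
        eventWidth = eventWidth, eventFactor = eventFactor,
        nPeaks = nPeaks, tfEnrichmentOdds = tfEnrichmentOdds,
        alpha = alpha, correction = correction, minInert = minInert,
        bandwidth = bandwidth,
        shiftThreshold = shiftThreshold, nPerm = nPerm,
        contactFdr = contactFdr, signalRate = signalRate,
        backgroundRate = backgroundRate, nEnds = nEnds,
        chromLengths = as.list(spec@chromLengths), nrl = spec@nrl,
        fragLenMean = spec@fragLenMean, fragLenSd = spec@fragLenSd,
        dyadSd = spec@dyadSd, baseOccupancy = spec@baseOccupancy)
    outputs <- setdiff(dir(outdir), "manifest.json")
    manifest <- list(
        package = "nucleodyn",
        version = as.character(utils::packageVersion("nucleodyn")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
        params = params,
        checksums = as.list(tools::md5sum(file.path(outdir, outputs))))
    names(manifest$checksums) <- outputs
    jsonlite::write_json(manifest, pt("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(truth = truth, occupancy = occ, multiscale = ms,
        repositioning = events, metagene = metagene, classes = classes,
        embedding = embed, domainogram = dg, contactAssociation = cvd,
        manifest = manifest))
}

#' Summarize a completed pipeline run
#'
#' Regenerates a one-page summary from the output directory alone (no
#' recomputation): windows per label per scale, peak-embedding
#' fraction, association tables, metagene and domainogram file
#' pointers.
#'
#' @param outdir Directory written by [runPipeline()].
#' @param path Output TSV (default \code{summary.tsv} inside
#'   \code{outdir}).
#' @param plot Also render \code{report.pdf} (metagene profiles per
#'   class and the contact domainogram) beside the summary.
#' @return The summary data.frame, invisibly.
#' @export
pipelineReport <- function(outdir, path = file.path(outdir,
                                                    "summary.tsv"),
                           plot = FALSE) {
    need <- function(f) {
        fp <- file.path(outdir, f)
        if (!file.exists(fp))
            stop("missing stage output: ", f)
        fp
    }
    rows <- list()
    add <- function(metric, value)
        rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                                 value = as.character(value))
    ms <- read.table(need("multiscale_labels.tsv"), header = TRUE,
                     sep = "\t")
    for (i in seq_len(nrow(ms)))
        add(sprintf("windows_%s_%dbp", ms$label[i], ms$scale[i]),
            ms$windows[i])
    occ <- read.table(need("occupancy_windows.tsv"), header = TRUE,
                      sep = "\t")
    add("windows_total_primary", nrow(occ))
    add("windows_depleted_primary", sum(occ$label == "depleted"))
    add("windows_enriched_primary", sum(occ$label == "enriched"))
    rp <- read.table(need("repositioning_events.tsv"), header = TRUE,
                     sep = "\t")
    for (st in c("stable", "repositioned", "lost", "gained"))
        add(paste0("nucleosomes_", st), sum(rp$status == st))
    if (file.exists(file.path(outdir, "peak_association.tsv"))) {
        pa <- read.table(file.path(outdir, "peak_association.tsv"),
                         header = TRUE, sep = "\t")
        add("peaks_total", pa$nPeaks)
        add("peaks_embedded", pa$nEmbedded)
        add("peak_embedding_odds_ratio", signif(pa$oddsRatio, 4))
        add("peak_embedding_p", signif(pa$p, 4))
    }
    dg <- read.table(need("domainogram.tsv"), header = TRUE,
                     sep = "\t")
    add("contact_windows_scored", sum(!dg$masked))
    add("contact_windows_significant",
        if ("significant" %in% colnames(dg))
            sum(dg$significant, na.rm = TRUE) else 0L)
    if (file.exists(file.path(outdir, "contact_association.tsv"))) {
        ca <- read.table(file.path(outdir, "contact_association.tsv"),
                         header = TRUE, sep = "\t")
        add("contact_association_odds_ratio", signif(ca$oddsRatio, 4))
        add("contact_association_p", signif(ca$p, 4))
    }
    if (file.exists(file.path(outdir, "metagene_profiles.tsv")))
        add("metagene_profiles", "metagene_profiles.tsv")
    if (plot) {
        pdfPath <- file.path(outdir, "report.pdf")
        grDevices::pdf(pdfPath, width = 7, height = 5)
        on.exit(grDevices::dev.off(), add = TRUE)
        if (file.exists(file.path(outdir, "metagene_profiles.tsv"))) {
            mg <- read.table(file.path(outdir,
                "metagene_profiles.tsv"), header = TRUE, sep = "\t")
            for (cl in unique(mg$class))
                plotMetagene(mg[mg$class == cl, ],
                             main = paste("metagene:", cl))
        }
        dgTab <- dg
        dgObj <- new("Domainogram", table = dgTab,
            chrom = "domainogram", backgroundRate = NA_real_,
            threshold = numeric(0), fdr = NA_real_, nPerm = 0L)
        plotDomainogram(dgObj)
        add("report_pdf", "report.pdf")
    }
    out <- do.call(rbind, rows)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(out)
}
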