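setMethod("show", "InertNull", function(object) {
    v <- object@values
    cat("InertNull with", length(v), "values from", object@nInert,
        "inert windows\n")
    cat(sprintf("  range [%.4g, %.4g], sd %.4g\n", min(v), max(v),
                stats::sd(v)))
})

setMethod("show", "OccupancyResult", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    cat("OccupancyResult:", nrow(object), "windows of",
        S4Vectors::metadata(object)$params$windowSize, "bp\n")
    tab <- table(factor(rd$label, levels = OCCUPANCY_LABELS))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
    cat(sprintf("  qMean = %.4g; null from %d inert windows\n",
        S4Vectors::metadata(object)$qMean,
        S4Vectors::metadata(object)$null@nInert))
})

setMethod("show", "ContactProfile", function(object) {
    cat("ContactProfile on", object@chrom, "with", length(object@ends),
        "fragment ends\n")
    cat(sprintf("  viewpoint %d; positive ends %d (%.1f%%)\n",
        object@viewpoint, sum(object@binary),
        100 * mean(object@binary)))
})

setMethod("show", "Domainogram", function(object) {
    tab <- object@table
    cat("Domainogram:", nrow(tab), "windows across",
        length(unique(tab$size)), "sizes on", object@chrom, "\n")
    cat(sprintf("  background rate %.4g\n", object@backgroundRate))
    if (length(object@threshold)) {
        cat(sprintf("  FDR %.3g threshold %.4g; %d significant windows\n",
            object@fdr, object@threshold,
            sum(tab$significant, na.rm = TRUE)))
    } else {
        cat("  (no permutation threshold computed)\n")
    }
})

setMethod("show", "LandscapeSpec", function(object) {
    cat("LandscapeSpec:",
        paste0(names(object@chromLengths), ":",
               object@chromLengths, collapse = ", "), "\n")
    cat(sprintf(paste0("  nrl %d bp, fragments %g±%g bp, dyad sd %g bp, ",
                       "occupancy %g frags/nucleosome, seed %d\n"),
        object@nrl, object@fragLenMean, object@fragLenSd, object@dyadSd,
        object@baseOccupancy, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@events), "events,",
        length(object@genes), "genes,", length(object@peaks), "peaks,",
        length(object@inert), "inert regions,",
        length(object@contactTargets), "contact targets\n")
    if (length(object@genes))
        print(table(object@genes$class))
})
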