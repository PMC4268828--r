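# Base-graphics displays for the two figure-style outputs: metagene
# profiles per gene class and the contact domainogram.

#' Plot metagene profiles for one gene class
#'
#' Draws the two time-point profiles over the upstream flank, scaled
#' gene body and downstream flank, with dashed guides at the TSS and
#' TTS.
#'
#' @param profile data.frame with columns \code{bin}, \code{zone} and
#'   signal columns \code{t1}, \code{t2} (as written by
#'   [runPipeline()]), or a single-profile data.frame from
#'   [metageneProfile()] (column \code{signal}).
#' @param main Plot title.
#' @param col Two line colours (t1, t2).
#' @return Invisibly, NULL.
#' @export
plotMetagene <- function(profile, main = "metagene",
                         col = c("grey40", "darkgreen")) {
    two <- all(c("t1", "t2") %in% colnames(profile))
    y1 <- if (two) profile$t1 else profile$signal
    ylim <- range(0, y1, if (two) profile$t2)
    plot(profile$bin, y1, type = "l", col = col[1L], lwd = 2,
         xlab = "profile bin (TSS to TTS, scaled body)",
         ylab = "summed midpoints", main = main, ylim = ylim)
    if (two)
        graphics::lines(profile$bin, profile$t2, col = col[2L],
                        lwd = 2)
    bodyBins <- range(profile$bin[profile$zone == "body"])
    graphics::abline(v = bodyBins, lty = 2, col = "grey60")
    if (two)
        graphics::legend("topright", legend = c("t1", "t2"),
                         col = col, lwd = 2, bty = "n")
    invisible(NULL)
}

#' Plot a contact domainogram
#'
#' Renders the (window size x position) enrichment-score matrix as an
#' image, window sizes on the vertical axis; significant windows (when
#' a permutation threshold exists) are outlined along the top.
#'
#' @param dgram A \linkS4class{Domainogram}.
#' @param nBins Horizontal resolution of the image.
#' @return Invisibly, NULL.
#' @export
plotDomainogram <- function(dgram, nBins = 200) {
    stopifnot(is(dgram, "Domainogram"))
    tab <- domainogramTable(dgram)
    sizes <- sort(unique(tab$size))
    lo <- min(tab$start); hi <- max(tab$end)
    edges <- seq(lo, hi, length.out = nBins + 1L)
    mat <- matrix(NA_real_, nrow = nBins, ncol = length(sizes))
    for (j in seq_along(sizes)) {
        sub <- tab[tab$size == sizes[j] & !tab$masked, ]
        if (!nrow(sub)) next
        mid <- (sub$start + sub$end) / 2
        bin <- pmin(pmax(findInterval(mid, edges), 1L), nBins)
        mat[, j] <- vapply(seq_len(nBins), function(b) {
            v <- sub$score[bin == b]
            if (length(v)) mean(v) else NA_real_
        }, numeric(1))
    }
    graphics::image(x = (edges[-1L] + edges[-length(edges)]) / 2,
        y = seq_along(sizes), z = mat,
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = paste("position on", dgram@chrom),
        ylab = "window size (kbp)", yaxt = "n",
        main = "contact enrichment")
    graphics::axis(2, at = seq_along(sizes),
                   labels = round(sizes / 1000, 1), las = 1)
    if (length(dgram@threshold) &&
        "significant" %in% colnames(tab)) {
        sig <- tab[!is.na(tab$significant) & tab$significant, ]
        if (nrow(sig))
            graphics::points((sig$start + sig$end) / 2,
                match(sig$size, sizes), pch = ".", cex = 2,
                col = "blue")
    }
    invisible(NULL)
}
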