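## Basic diagnostic graphics (base R): a histogram render with fitted peaks
## and the genome-size vs endoreplicated-part scatter.

#' Plot a fluorescence histogram with fitted peaks
#'
#' @param hist an [FcmHistogram-class].
#' @param peaks optional [PeakSet-class]; fitted Gaussians are overdrawn and
#'   peaks annotated with their role / endocycle index.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotHistogram <- function(hist, peaks = NULL, ...) {
  x <- channelCenters(hist)
  y <- channelCounts(hist)
  graphics::plot(x, y, type = "h", col = "grey60",
                 xlab = "fluorescence (channel units)", ylab = "events", ...)
  if (!is.null(peaks)) {
    p <- peakData(peaks)
    for (i in seq_len(nrow(p))) {
      xx <- seq(p$position[i] - 4 * p$sd[i], p$position[i] + 4 * p$sd[i],
                length.out = 120)
      yy <- p$height[i] * exp(-0.5 * ((xx - p$position[i]) / p$sd[i])^2)
      graphics::lines(xx * histGain(hist), yy, col = "firebrick", lwd = 1.5)
      lab <- if (p$role[i] == "standard") "*"
             else if (!is.na(p$k[i])) sprintf("2C+%dP", p$k[i]) else ""
      if (nzchar(lab))
        graphics::text(p$position[i] * histGain(hist), p$height[i], lab,
                       pos = 3, cex = 0.8)
    }
  }
  invisible(NULL)
}

#' Genome size vs endoreplicated-part scatter
#'
#' The joint delineation view: diploids share a P band while polyploids sit
#' at integer multiples of it; homoploid lineages separate horizontally.
#'
#' @param measurements data.frame with `two_c_pg`, `p_pg` and optionally
#'   `ploidy` (symbol) and `taxon` (color).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotGenomeSizeP <- function(measurements, ...) {
  m <- measurements
  pch <- if (!is.null(m$ploidy)) 14 + pmin(pmax(m$ploidy, 1), 8) else 16
  col <- if (!is.null(m$taxon)) as.integer(factor(m$taxon)) + 1L else "black"
  graphics::plot(m$two_c_pg, m$p_pg, pch = pch, col = col,
                 xlab = "genome size 2C (pg)",
                 ylab = "endoreplicated part P (pg)", ...)
  if (!is.null(m$taxon))
    graphics::legend("topleft", legend = levels(factor(m$taxon)),
                     col = seq_along(levels(factor(m$taxon))) + 1L,
                     pch = 16, cex = 0.7, bty = "n")
  invisible(NULL)
}
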