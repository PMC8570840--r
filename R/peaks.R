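## Peak detection and single-Gaussian fitting on 1D fluorescence histograms.
##
## Candidates are local maxima of a Savitzky-Golay (moving-window quadratic)
## smoothed histogram; each candidate is refined by a weighted least-squares
## single-Gaussian fit on a window of +/- 3 preliminary sd. Quality gates:
## fitted area >= minPeakEvents, fitted cv <= cvMax. Overlapping fits
## (centers closer than 2 * (sd1 + sd2)) are flagged merged, never
## force-split — resolving a standard/sample overlap is the job of a
## secondary standard, not of deconvolution.

#' Gate events on rectangular fluorescence / side-scatter ranges
#'
#' Keeps the events inside the half-open rectangle
#' `[flRange[1], flRange[2]) x [sscRange[1], sscRange[2])`. The gate is
#' recorded in the metadata.
#'
#' @param events an [FcmSample-class].
#' @param flRange,sscRange ordered numeric pairs, or `NULL` for no gate on
#'   that axis; `sscRange` requires a side-scatter channel.
#' @return the gated [FcmSample-class].
#' @export
gateEvents <- function(events, flRange = NULL, sscRange = NULL) {
  stopifnot(is(events, "FcmSample"))
  checkRange <- function(r, what) {
    if (!is.null(r) && (length(r) != 2L || r[1] > r[2]))
      stopf("%s must be an ordered pair", what,
            class = "flowPE_parameter_error")
  }
  checkRange(flRange, "flRange")
  checkRange(sscRange, "sscRange")
  keep <- rep(TRUE, nEvents(events))
  fl <- fluorescence(events)
  if (!is.null(flRange)) keep <- keep & fl >= flRange[1] & fl < flRange[2]
  if (!is.null(sscRange)) {
    ssc <- sideScatter(events)
    if (!length(ssc))
      stopf("sscRange given but events carry no side-scatter channel",
            class = "flowPE_parameter_error")
    keep <- keep & ssc >= sscRange[1] & ssc < sscRange[2]
  }
  if (!any(keep))
    stopf("gate excludes all %d events", nEvents(events),
          class = "flowPE_empty_gate_error")
  meta <- sampleMeta(events)
  meta$gate <- list(fl = flRange, ssc = sscRange,
                    kept = sum(keep), of = nEvents(events))
  FcmSample(fl[keep],
            sideScatter = if (length(sideScatter(events)))
              sideScatter(events)[keep] else numeric(0),
            metadata = meta)
}

## Core weighted single-Gaussian fit on (x = channel centers, y = counts).
## Approximate Poisson weighting 1/max(y, 1).
.gaussFit <- function(x, y, w = 1 / pmax(y, 1)) {
  y0 <- pmax(y, 0)
  mu0 <- weighted.mean(x, y0)
  s0 <- sqrt(max(weighted.mean((x - mu0)^2, y0), 0.25))
  a0 <- max(y)
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-0.5 * ((x - mu) / s)^2),
    start = list(a = a0, mu = mu0, s = s0),
    lower = c(a = 1e-9, mu = min(x), s = 0.1),
    upper = c(a = Inf, mu = max(x), s = diff(range(x)) + 1),
    weights = w, control = nls.control(maxiter = 200, warnOnly = FALSE))
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[["s"]] <= 0 || cf[["a"]] <= 0)
    stopf("degenerate Gaussian fit", class = "flowPE_fit_error")
  list(position = cf[["mu"]], sd = cf[["s"]], height = cf[["a"]],
       area = cf[["a"]] * cf[["s"]] * sqrt(2 * pi))
}

#' Fit a single Gaussian peak in a histogram window
#'
#' Weighted least-squares fit of `a * exp(-(x - mu)^2 / (2 s^2))` to the
#' channel counts in `window`. The returned area is the Gaussian integral
#' (in events, since channels have unit width), not the raw window sum.
#'
#' @param hist an [FcmHistogram-class].
#' @param window integer channel indices (1-based), or a length-2 range
#'   `c(lo, hi)`; must contain at least 5 channels with nonzero counts.
#' @return one-row data.frame: `position`, `sd`, `cv`, `area`, `height`
#'   (position and sd in continuous channel units).
#' @export
fitPeak <- function(hist, window) {
  stopifnot(is(hist, "FcmHistogram"))
  if (length(window) == 2L && window[2] > window[1] + 1)
    window <- seq(window[1], window[2])
  window <- window[window >= 1 & window <= length(channelCounts(hist))]
  y <- channelCounts(hist)[window]
  if (sum(y > 0) < 5L)
    stopf("fit window needs >= 5 channels with nonzero counts",
          class = "flowPE_fit_error")
  x <- window - 0.5  # channel centers, channel units
  g <- tryCatch(.gaussFit(x, y), error = function(e)
    stopf("Gaussian fit failed: %s", conditionMessage(e),
          class = "flowPE_fit_error"))
  data.frame(position = g$position, sd = g$sd, cv = g$sd / g$position,
             area = g$area, height = g$height)
}

## Moment fallback for delta-like peaks occupying < 5 channels, where a
## 3-parameter Gaussian fit is degenerate. sd is floored at 0.15 channel
## (sub-quantization spread is unobservable).
.momentPeak <- function(counts, window) {
  y <- counts[window]
  x <- window - 0.5
  pos <- weighted.mean(x, y)
  s <- sqrt(max(weighted.mean((x - pos)^2, y), 0))
  data.frame(position = pos, sd = max(s, 0.15),
             cv = max(s, 0.15) / pos, area = sum(y), height = max(y))
}

#' Detect and fit peaks in a 1D histogram
#'
#' @param hist an [FcmHistogram-class].
#' @param minPeakEvents minimum fitted area (events) to keep a peak.
#' @param smoothWindow Savitzky-Golay window width in channels (odd, >= 3).
#' @param cvMax maximum fitted cv to keep a peak.
#' @param maxCandidates cap on candidate maxima examined (highest first).
#' @return a [PeakSet-class], peaks sorted by position, roles unassigned.
#'   Peaks whose centers are closer than `2 * (sd1 + sd2)` are flagged
#'   `merged`. Deterministic: identical input gives identical output.
#' @export
detectPeaks <- function(hist, minPeakEvents = 100, smoothWindow = 9,
                        cvMax = 0.10, maxCandidates = 25) {
  stopifnot(is(hist, "FcmHistogram"))
  if (minPeakEvents < 1)
    stopf("minPeakEvents must be >= 1", class = "flowPE_parameter_error")
  if (smoothWindow < 3 || smoothWindow %% 2 == 0)
    stopf("smoothWindow must be odd and >= 3", class = "flowPE_parameter_error")
  counts <- channelCounts(hist)
  if (sum(counts) == 0)
    stopf("histogram is empty: no peaks", class = "flowPE_no_peaks_error")
  s <- pmax(signal::sgolayfilt(counts, p = 2, n = smoothWindow), 0)
  n <- length(s)
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  ## ties between equal-height adjacent maxima resolve to the lower channel
  cand <- which(s > left & s >= right & s > 0)
  if (!length(cand))
    stopf("no candidate peaks found", class = "flowPE_no_peaks_error")
  cand <- cand[order(s[cand], decreasing = TRUE)]
  ## the tallest candidate is fit first to learn the typical peak width of
  ## this preparation (cv = sd/position); real peaks cannot sit closer than
  ## about 2 cv of their position, so nearer candidates are noise maxima of
  ## one peak
  cvTyp <- 0.05
  {
    i1 <- cand[1]
    h1 <- s[i1]
    l <- i1; while (l > 1 && s[l] > h1 / 2) l <- l - 1L
    r <- i1; while (r < n && s[r] > h1 / 2) r <- r + 1L
    w1 <- max((r - l) / 2.355, 1)
    win1 <- seq(max(1L, floor(i1 - 3 * w1)), min(n, ceiling(i1 + 3 * w1)))
    if (sum(counts[win1] > 0) >= 5L) {
      g1 <- tryCatch(.gaussFit(win1 - 0.5, counts[win1]),
                     error = function(e) NULL)
      if (!is.null(g1))
        cvTyp <- min(max(g1$sd / g1$position, 0.01), 0.08)
    }
  }
  ## candidates belong to the same peak if they are within 2 cv of each
  ## other, or if the smoothed curve has no real valley between them (below
  ## 75% of the lower maximum AND below it by more than ~1.5 Poisson sd on
  ## the smoothed scale; noise maxima on a broad peak top fail this,
  ## genuinely resolved peaks pass)
  taken <- integer(0)
  for (i in cand) {
    distinct <- all(vapply(taken, function(j) {
      if (abs(i - j) < 2 * cvTyp * (i + j) / 2) return(FALSE)
      v <- min(s[min(i, j):max(i, j)])
      minH <- min(s[i], s[j])
      v <= 0.75 * minH && v <= minH - 1.5 * sqrt(v + 1)
    }, logical(1)))
    if (distinct) taken <- c(taken, i)
    if (length(taken) >= maxCandidates) break
  }
  fits <- list()
  sortedTaken <- sort(taken)
  for (i in taken) {
    h <- s[i]
    l <- i; while (l > 1 && s[l] > h / 2) l <- l - 1L
    r <- i; while (r < n && s[r] > h / 2) r <- r + 1L
    prelimSd <- max((r - l) / 2.355, 1)
    lo <- max(1L, floor(i - 3 * prelimSd))
    hi <- min(n, ceiling(i + 3 * prelimSd))
    ## clip at midpoints to neighbouring candidates so no fit window
    ## bridges two resolved peaks
    leftN <- sortedTaken[sortedTaken < i]
    rightN <- sortedTaken[sortedTaken > i]
    if (length(leftN)) lo <- max(lo, ceiling((i + max(leftN)) / 2))
    if (length(rightN)) hi <- min(hi, floor((i + min(rightN)) / 2))
    win <- seq(lo, hi)
    fit <- if (sum(counts[win] > 0) < 5L) .momentPeak(counts, win)
           else tryCatch(fitPeak(hist, win), flowPE_fit_error = function(e) {
             warnf("dropping candidate at channel %d: %s", i,
                   conditionMessage(e), class = "flowPE_drop_warning")
             NULL
           })
    ## a fitted sd comparable to the whole window is extrapolation, not a
    ## peak (typically the flat bridge between two real peaks)
    if (!is.null(fit) && fit$sd > 0.6 * length(win)) fit <- NULL
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (!length(fits))
    stopf("no candidate peak could be fitted", class = "flowPE_no_peaks_error")
  p <- do.call(rbind, fits)
  ## collapse duplicate fits that converged to the same center
  p <- p[order(-p$area), , drop = FALSE]
  dup <- rep(FALSE, nrow(p))
  for (i in seq_len(nrow(p))[-1])
    dup[i] <- any(abs(p$position[seq_len(i - 1)][!dup[seq_len(i - 1)]] -
                      p$position[i]) < pmax(1, p$sd[i]))
  p <- p[!dup, , drop = FALSE]
  ## refinement: refit each peak on the residual after subtracting the
  ## current fits of all other peaks, so neighbouring tails (which pull
  ## centers toward bigger neighbours and bias the P slope) cancel out
  for (pass in 1:2) {
    for (i in order(-p$area)) {
      lo <- max(1L, floor(p$position[i] - 3 * p$sd[i] + 0.5))
      hi <- min(n, ceiling(p$position[i] + 3 * p$sd[i] + 0.5))
      win <- lo:hi
      contrib <- rep(0, length(win))
      for (j in setdiff(seq_len(nrow(p)), i))
        contrib <- contrib + p$height[j] *
          exp(-0.5 * ((win - 0.5 - p$position[j]) / p$sd[j])^2)
      yres <- pmax(counts[win] - contrib, 0)
      if (sum(yres > 0) < 5L) next
      g <- tryCatch(.gaussFit(win - 0.5, yres), error = function(e) NULL)
      if (!is.null(g) && g$sd > 0.6 * length(win)) g <- NULL
      if (!is.null(g)) {
        p$position[i] <- g$position
        p$sd[i] <- g$sd
        p$height[i] <- g$height
        p$area[i] <- g$area
        p$cv[i] <- g$sd / g$position
      }
    }
  }
  drop <- p$area < minPeakEvents | p$cv > cvMax
  if (any(drop))
    message(sprintf("detectPeaks: dropped %d peak(s): %s", sum(drop),
                    paste(sprintf("pos %.1f (area %.0f, cv %.3f)",
                                  p$position[drop], p$area[drop],
                                  p$cv[drop]), collapse = "; ")))
  p <- p[!drop, , drop = FALSE]
  if (!nrow(p))
    stopf("all candidate peaks failed the area/cv quality gates",
          class = "flowPE_no_peaks_error")
  p <- p[order(p$position), , drop = FALSE]
  merged <- rep(FALSE, nrow(p))
  if (nrow(p) > 1) {
    gap <- diff(p$position)
    lim <- 2 * (p$sd[-nrow(p)] + p$sd[-1])
    close <- gap < lim
    merged[which(close)] <- TRUE
    merged[which(close) + 1L] <- TRUE
  }
  p$merged <- merged
  PeakSet(p, gain = histGain(hist), metadata = sampleMeta(hist))
}
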