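## The computational core: assign detected peaks to roles (standard vs the
## sample series 2C + k*P), calibrate positions to picograms against the
## internal standard, and estimate the genome size 2C and the
## endoreplicated-part size P.
##
## Under partial endoreplication only a fixed genome fraction P re-replicates
## per endocycle, so nuclei populate fluorescence peaks at 2C, 2C + P,
## 2C + 2P, ... — an arithmetic progression whose common difference is P.
## That progression is both how sample peaks are recognized and how P is
## estimated (a weighted regression of peak position on endocycle index,
## which for two peaks reduces to the plain difference between the 2C and
## 2C + P peaks).

## Ordinary least squares of y on x returning max relative residual.
.progressionResid <- function(pos) {
  m <- length(pos)
  if (m < 2L) return(0)
  k <- 0:(m - 1)
  fit <- lm(pos ~ k)
  max(abs(fit$residuals) / pos)
}

#' Assign detected peaks to standard / sample roles
#'
#' Each peak in turn is considered as the internal-standard peak; the
#' remaining peaks, taken in ascending position as endocycle indices
#' k = 0..K, must fit positions 2C + k*P with relative residual below
#' `progressionTol` each. The accepted candidate is the peak whose exclusion
#' leaves the best-fitting arithmetic progression (i.e. the peak that is the
#' worst member of the series). When several candidates fit equally well —
#' unavoidable with only two sample peaks, since any two points are collinear
#' — an expected-2C `hint` range resolves the ambiguity, mirroring practice:
#' the operator knows roughly where the sample should fall.
#'
#' Positions are converted to pg via the standard once roles are set.
#'
#' @param peaks a [PeakSet-class] with >= 2 peaks.
#' @param standard the [FcmStandard-class] run in the tube.
#' @param hint optional numeric pair: plausible range for the sample 2C in pg.
#' @param progressionTol per-peak relative residual tolerance (default 0.02).
#' @return the [PeakSet-class] with roles, `k` and `position_pg` filled.
#' @export
assignPeaks <- function(peaks, standard, hint = NULL, progressionTol = 0.02) {
  stopifnot(is(peaks, "PeakSet"), is(standard, "FcmStandard"))
  p <- peakData(peaks)
  n <- nrow(p)
  if (n < 2L)
    stopf("need at least 2 peaks to assign roles (got %d)", n,
          class = "flowPE_assignment_error")
  if (n == 2L && abs(diff(p$position)) < 2 * sum(p$sd))
    stopf(paste0("the two peaks overlap (ratio ~ 1): sample and standard are ",
                 "indistinguishable; use a secondary standard of different size"),
          class = "flowPE_overlap_error")
  ## progression check for a candidate standard: the remaining peaks,
  ## ascending, must fit 2C + k*P within progressionTol each; if the full
  ## set fails, up to two trailing (highest, lowest-count) peaks may be set
  ## aside — a merged or poorly fit last endocycle peak must not invalidate
  ## an otherwise clean series (the model-guided refinement recovers it)
  evalCand <- function(i) {
    pos <- sort(p$position[-i])
    m <- length(pos)
    if (m < 2L) return(list(ok = TRUE, resid = 0, dropped = 0L))
    for (dropTrailing in 0:min(2L, m - 2L)) {
      use <- pos[seq_len(m - dropTrailing)]
      k <- seq_along(use) - 1
      fit <- lm(use ~ k)
      if (coef(fit)[["k"]] <= 0) next
      rel <- abs(fit$residuals) / use
      if (all(rel < progressionTol))
        return(list(ok = TRUE, resid = max(rel), dropped = dropTrailing))
    }
    list(ok = FALSE, resid = Inf, dropped = NA_integer_)
  }
  ev <- lapply(seq_len(n), evalCand)
  resid <- vapply(ev, `[[`, numeric(1), "resid")
  dropped <- vapply(ev, `[[`, integer(1), "dropped")
  cand <- which(vapply(ev, `[[`, logical(1), "ok"))
  if (length(cand) > 1L) cand <- cand[dropped[cand] == min(dropped[cand])]
  if (length(cand) > 1L && !is.null(hint)) {
    impliedK0 <- vapply(cand, function(i)
      min(p$position[-i]) / p$position[i] * standard@size, numeric(1))
    cand <- cand[impliedK0 >= hint[1] & impliedK0 <= hint[2]]
  }
  if (length(cand) > 1L) {
    best <- cand[resid[cand] < min(resid[cand]) + 1e-12]
    if (length(best) > 1L)
      stopf(paste0("%d peak subsets fit an arithmetic progression equally ",
                   "well; supply an expected-2C hint to identify the standard"),
            length(best), class = "flowPE_assignment_error")
    cand <- best
  }
  if (!length(cand))
    stopf("no peak subset fits positions 2C + k*P within %.1f%% per peak",
          100 * progressionTol, class = "flowPE_assignment_error")
  stdIdx <- cand
  p$role <- "sample"
  p$role[stdIdx] <- "standard"
  ord <- order(p$position)
  sampleRows <- ord[ord != stdIdx]
  nDrop <- dropped[stdIdx]
  if (nDrop > 0L) {
    aside <- sampleRows[(length(sampleRows) - nDrop + 1L):length(sampleRows)]
    p$role[aside] <- "unassigned"
    sampleRows <- sampleRows[seq_len(length(sampleRows) - nDrop)]
  }
  p$k <- NA_integer_
  p$k[sampleRows] <- seq_along(sampleRows) - 1L
  p$position_pg <- p$position / p$position[stdIdx] * standard@size
  k0 <- which(p$k == 0L)
  if (abs(p$position[k0] - p$position[stdIdx]) <
      2 * (p$sd[k0] + p$sd[stdIdx]))
    stopf(paste0("sample 2C peak (%.1f) overlaps the standard peak (%.1f); ",
                 "use a secondary standard of different size"),
          p$position[k0], p$position[stdIdx], class = "flowPE_overlap_error")
  out <- PeakSet(p, gain = histGain(peaks), metadata = sampleMeta(peaks))
  out@metadata$standard_used <- standard@name
  out
}

## Model-guided refinement of the assigned sample series. Initial
## detection fits peaks independently, which leaves closely spaced high-k
## peaks biased by their neighbours' tails or merged into one broad fit.
## Knowing which peaks form the series, all of them are refit JOINTLY as a
## sum of Gaussians (positions free, standard's fitted peak subtracted)
## by weighted least squares over the series region; missing trailing
## endocycle peaks are recovered when enough events sit at the predicted
## 2C + k*P position. Joint fitting is what removes the neighbour-tail
## bias that single-peak windows cannot.
.refineSeries <- function(hist, peaks, minPeakEvents = 100, cvMax = 0.10,
                          progressionTol = 0.02) {
  counts <- channelCounts(hist)
  n <- length(counts)
  p <- peakData(peaks)
  sp <- p[p$role == "sample", , drop = FALSE]
  std <- p[p$role == "standard", , drop = FALSE]
  if (nrow(sp) < 2L || any(sp$sd < 0.5)) return(peaks)
  ## anchor the initial progression on the 2C and 2C + P peaks — the two
  ## largest, best-measured members; higher-k detected positions may carry
  ## merged neighbours and would poison a regression-based start
  pos0 <- sp$position[sp$k == 0L]
  pCh <- sp$position[sp$k == 1L] - pos0
  cv0 <- sp$cv[sp$k == 0L]
  if (pCh <= 0) return(peaks)

  ## extend the series by predicted peaks that plainly hold enough events
  kMaxTry <- max(sp$k)
  while (kMaxTry < 8L) {
    pred <- pos0 + (kMaxTry + 1L) * pCh
    sdp <- cv0 * pred
    if (pred + 2 * sdp > n - 1) break
    mass <- sum(counts[max(1L, floor(pred - 2 * sdp)):ceiling(pred + 2 * sdp)])
    if (mass < minPeakEvents) break
    kMaxTry <- kMaxTry + 1L
  }
  ks <- 0:kMaxTry
  init <- lapply(ks, function(k) {
    pred <- pos0 + k * pCh
    row <- sp[!is.na(sp$k) & sp$k == k, , drop = FALSE]
    ## trust a detected fit only where it agrees with the progression; a
    ## merged blob assigned to this k would otherwise misplace the start
    if (nrow(row) == 1L && abs(row$position - pred) < 0.25 * pCh &&
        row$sd < 1.5 * cv0 * pred + 1)
      c(a = row$height, mu = row$position, s = row$sd)
    else
      c(a = max(counts[max(1L, floor(pred - 3)):min(n, ceiling(pred + 3))], 1),
        mu = pred, s = cv0 * pred)
  })
  a0 <- vapply(init, `[[`, numeric(1), "a")
  mu0 <- vapply(init, `[[`, numeric(1), "mu")
  s0 <- vapply(init, `[[`, numeric(1), "s")
  lo <- max(1L, floor(mu0[1] - 4 * s0[1]))
  hi <- min(n, ceiling(mu0[length(ks)] + 4 * s0[length(ks)]))
  x <- (lo:hi) - 0.5
  y <- counts[lo:hi] -
    std$height[1] * exp(-0.5 * ((x - std$position[1]) / std$sd[1])^2)
  sw <- sqrt(1 / pmax(counts[lo:hi], 1))
  m <- length(ks)
  ## one shared cv: every series peak is broadened by the same staining /
  ## instrument variability, so sd_k = cv * mu_k — fewer parameters and
  ## markedly more stable positions for the small high-k peaks
  model <- function(par) {
    out <- numeric(length(x))
    for (j in seq_len(m))
      out <- out + par[j] *
        exp(-0.5 * ((x - par[m + j]) / (par[2 * m + 1] * par[m + j]))^2)
    out
  }
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(a0, mu0, cv0),
    fn = function(par) (model(par) - y) * sw,
    lower = c(rep(0, m), mu0 - 0.45 * pCh, 0.002),
    upper = c(rep(Inf, m), mu0 + 0.45 * pCh, 1.2 * cvMax),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5)) return(peaks)
  par <- fit$par
  series <- data.frame(position = par[m + seq_len(m)],
                       sd = par[2 * m + 1] * par[m + seq_len(m)],
                       height = par[seq_len(m)], k = ks)
  series$area <- series$height * series$sd * sqrt(2 * pi)
  series$cv <- series$sd / series$position
  ## components from the first failed one onward are dropped (dropping a
  ## middle component would break the k spacing); a failed core component
  ## (k <= 1) means the joint fit is untrustworthy and the original peaks
  ## stand
  bad <- series$area < minPeakEvents | series$cv > cvMax |
    series$position <= 0
  if (any(bad[1:2])) return(peaks)
  firstBad <- which(bad)[1]
  if (!is.na(firstBad))
    series <- series[seq_len(firstBad - 1L), , drop = FALSE]
  if (nrow(series) < 2L || is.unsorted(series$position)) return(peaks)
  series$k <- seq_len(nrow(series)) - 1L
  ## sanity: a component that slid to its position bound, or a refined
  ## series that no longer fits the arithmetic progression, signals a
  ## mis-converged joint fit — keep the original peaks then
  atBound <- abs(series$position - mu0[seq_len(nrow(series))]) >
    0.44 * pCh
  if (any(atBound)) return(peaks)
  refit <- lm(position ~ k, data = series, weights = series$area)
  if (coef(refit)[["k"]] <= 0 ||
      any(abs(refit$residuals) / series$position >= progressionTol))
    return(peaks)
  series$role <- "sample"
  out <- rbind(std[, c("position", "sd", "cv", "area", "height", "k", "role")],
               series[, c("position", "sd", "cv", "area", "height", "k",
                          "role")])
  out$k <- ifelse(out$role == "sample", out$k, NA_integer_)
  out$position_pg <- out$position / std$position[1] * std$position_pg[1]
  out$merged <- FALSE
  if (nrow(out) > 1) {
    ord <- order(out$position)
    gap <- diff(out$position[ord])
    lim <- 2 * (out$sd[ord][-nrow(out)] + out$sd[ord][-1])
    close <- gap < lim
    mm <- rep(FALSE, nrow(out))
    mm[ord[which(close)]] <- TRUE
    mm[ord[which(close) + 1L]] <- TRUE
    out$merged <- mm
  }
  PeakSet(out, gain = histGain(peaks), metadata = sampleMeta(peaks))
}

#' Estimate genome size from the sample/standard peak ratio
#'
#' 2C (pg) = (sample 2C peak position / standard peak position) * standard 2C.
#'
#' @param samplePeak,standardPeak one-row data.frames (or lists) with a
#'   `position` element, e.g. rows of [peakData()].
#' @param standard the [FcmStandard-class].
#' @return estimated 2C in pg.
#' @export
estimateGenomeSize <- function(samplePeak, standardPeak, standard) {
  ps <- samplePeak$position
  pr <- standardPeak$position
  if (!is.finite(ps) || !is.finite(pr) || ps <= 0 || pr <= 0)
    stopf("peak positions must be positive", class = "flowPE_parameter_error")
  ps / pr * standard@size
}

#' Estimate the endoreplicated-part size P from the sample peak series
#'
#' Weighted least-squares line of peak position (pg) on endocycle index k,
#' weighted by peak area (later endocycle peaks hold fewer nuclei and carry
#' less information). The slope is P; the intercept is a consistency estimate
#' of 2C. With exactly two peaks this reduces to the plain difference between
#' the 2C and 2C + P peaks. `pMode = "first_two"` forces that two-peak
#' difference even when more peaks exist.
#'
#' @param samplePeaks data.frame of sample-role peaks with columns
#'   `position_pg`, `k`, `area` (e.g. the sample rows of [peakData()]).
#' @param pMode `"regression"` (default) or `"first_two"`.
#' @return list with `p_pg`, `intercept_pg`, `k_used`.
#' @export
estimateP <- function(samplePeaks, pMode = c("regression", "first_two")) {
  pMode <- match.arg(pMode)
  sp <- samplePeaks[!is.na(samplePeaks$k), , drop = FALSE]
  sp <- sp[order(sp$k), , drop = FALSE]
  if (length(unique(sp$k)) < 2L)
    stopf("P is undefined with a single sample peak",
          class = "flowPE_insufficient_peaks_error")
  if (pMode == "first_two") sp <- sp[sp$k %in% c(0L, 1L), , drop = FALSE]
  if (nrow(sp) == 2L) {
    slope <- diff(sp$position_pg) / diff(sp$k)
    intercept <- sp$position_pg[1] - slope * sp$k[1]
  } else {
    fit <- lm(position_pg ~ k, data = sp, weights = sp$area)
    slope <- coef(fit)[["k"]]
    intercept <- coef(fit)[["(Intercept)"]]
  }
  if (slope <= 0)
    stopf("non-increasing peak series: fitted P = %.3g pg <= 0", slope,
          class = "flowPE_model_violation_error")
  list(p_pg = slope, intercept_pg = intercept, k_used = nrow(sp))
}

#' Endoreplicated fraction of the genome, in percent
#'
#' @param p endoreplicated-part size P in pg.
#' @param twoC genome size 2C in pg; requires `0 < p < twoC`.
#' @return `100 * p / twoC`.
#' @examples
#' percentP(7.06, 19.46) # 36.28...
#' @export
percentP <- function(p, twoC) {
  if (any(!is.finite(p)) || any(!is.finite(twoC)) ||
      any(p <= 0) || any(p >= twoC))
    stopf("need 0 < P < 2C", class = "flowPE_parameter_error")
  100 * p / twoC
}

#' Calibrate a secondary standard against a primary
#'
#' The secondary's 2C is the mean secondary/primary peak-position ratio over
#' replicate co-runs, times the primary 2C. The provenance note records the
#' primary, the number of replicates and the sd of the ratios.
#'
#' @param ratios secondary/primary peak-position ratios (>= 1, all > 0).
#' @param primary the primary [FcmStandard-class].
#' @param name name for the new standard.
#' @return an [FcmStandard-class] with role `"secondary"`.
#' @export
calibrateSecondaryStandard <- function(ratios, primary, name = "secondary") {
  if (!length(ratios) || any(!is.finite(ratios)) || any(ratios <= 0))
    stopf("need at least one positive ratio", class = "flowPE_parameter_error")
  size <- mean(ratios) * primary@size
  FcmStandard(name, size, role = "secondary",
              provenance = sprintf(
                "calibrated against %s (2C = %.2f pg); n = %d, ratio sd = %.4g",
                primary@name, primary@size, length(ratios),
                if (length(ratios) > 1) sd(ratios) else 0))
}

#' Measure one sample end to end
#'
#' Bins the events, detects and fits peaks, assigns roles against the
#' standard, and estimates 2C, P and P%. Flags collected along the way:
#' `merged-peaks` (overlapping fits), `low-peak-count` (fewer than 3 sample
#' peaks), `intercept-mismatch` (regression intercept off the 2C peak by
#' more than 5%).
#'
#' @param events an [FcmSample-class].
#' @param standard the [FcmStandard-class] run in the tube.
#' @param nChannels,gain binning parameters, see [binEvents()].
#' @param minPeakEvents,smoothWindow,cvMax detection parameters, see
#'   [detectPeaks()].
#' @param pMode,progressionTol model parameters, see [estimateP()] and
#'   [assignPeaks()].
#' @param hint optional expected-2C range in pg, see [assignPeaks()].
#' @return list with `measurement` (one-row data.frame: `sample_id`,
#'   `taxon`, `region`, `two_c_pg`, `p_pg`, `p_percent`, `k_used`,
#'   `intercept_pg`, `ploidy` (`NA` until delineation), `flags`) and
#'   `peaks` (the assigned [PeakSet-class]).
#' @export
measureSample <- function(events, standard, nChannels = 1024, gain = 1,
                          minPeakEvents = 100, smoothWindow = 9, cvMax = 0.10,
                          pMode = "regression", progressionTol = 0.02,
                          hint = NULL) {
  stopifnot(is(events, "FcmSample"))
  hist <- binEvents(events, nChannels = nChannels, gain = gain)
  peaks <- detectPeaks(hist, minPeakEvents = minPeakEvents,
                       smoothWindow = smoothWindow, cvMax = cvMax)
  peaks <- assignPeaks(peaks, standard, hint = hint,
                       progressionTol = progressionTol)
  peaks <- .refineSeries(hist, peaks, minPeakEvents = minPeakEvents,
                         cvMax = cvMax, progressionTol = progressionTol)
  p <- peakData(peaks)
  sp <- p[p$role == "sample", , drop = FALSE]
  stdRow <- p[p$role == "standard", , drop = FALSE]
  ## a "standard" peak much broader than the sample series is two unresolved
  ## peaks: the sample 2C sitting on top of the standard. Reporting a number
  ## from it would silently shift every quantity by one endocycle; refuse
  ## and advise a secondary standard instead (the N. maculata-type workflow)
  seriesCv <- median(sp$cv)
  if (stdRow$cv > 1.4 * seriesCv)
    stopf(paste0("standard peak is %.1fx broader (cv %.3f) than the sample ",
                 "series (cv %.3f): suspected unresolved overlap between the ",
                 "standard and the sample 2C peak; use a secondary standard ",
                 "of different size"),
          stdRow$cv / seriesCv, stdRow$cv, seriesCv,
          class = "flowPE_overlap_error")
  twoC <- estimateGenomeSize(sp[sp$k == 0L, ], stdRow, standard)
  est <- estimateP(sp, pMode = pMode)
  flags <- character()
  if (any(p$merged)) flags <- c(flags, "merged-peaks")
  if (est$k_used < 3L) flags <- c(flags, "low-peak-count")
  if (est$k_used >= 2L && abs(est$intercept_pg - twoC) / twoC > 0.05)
    flags <- c(flags, "intercept-mismatch")
  meta <- sampleMeta(events)
  measurement <- data.frame(
    sample_id = if (is.null(meta$sample_id)) NA_character_
                else as.character(meta$sample_id),
    taxon = if (is.null(meta$taxon)) NA_character_ else meta$taxon,
    region = if (is.null(meta$region)) NA_character_ else meta$region,
    two_c_pg = twoC, p_pg = est$p_pg,
    p_percent = percentP(est$p_pg, twoC),
    k_used = est$k_used, intercept_pg = est$intercept_pg,
    ploidy = NA_integer_,
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
  list(measurement = measurement, peaks = peaks)
}
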