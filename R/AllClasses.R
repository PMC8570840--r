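#' @import methods
#' @importFrom stats aov coef dnorm lm median nls.control pf ptukey qnorm
#'   rbinom rexp rmultinom rnorm runif sd setNames TukeyHSD weighted.mean
#' @importFrom utils head modifyList read.csv read.delim write.csv
NULL

## ---------------------------------------------------------------------------
## FcmStandard -- an internal DNA-content size standard
## ---------------------------------------------------------------------------

#' Internal size standard
#'
#' An internal standard is a reference species of known nuclear DNA content
#' (2C, in pg) co-chopped and co-stained with the sample so that fluorescence
#' can be calibrated to picograms. A *secondary* standard is one whose 2C was
#' itself calibrated by repeated measurement against a primary standard and
#' must therefore record that provenance.
#'
#' @slot name single character, e.g. `"Pisum sativum 'Ctirad'"`.
#' @slot size 2C DNA amount in pg; must be positive.
#' @slot role `"primary"` or `"secondary"`.
#' @slot provenance free-text calibration note; required (non-empty) for
#'   secondary standards, where it must name the primary standard used.
#'
#' @examples
#' FcmStandard("Pisum sativum 'Ctirad'", 8.76)
#' @export
setClass("FcmStandard",
  representation(name = "character", size = "numeric", role = "character",
                 provenance = "character"),
  prototype(role = "primary", provenance = ""))

setValidity("FcmStandard", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@size) != 1L || !is.finite(object@size) || object@size <= 0)
    msg <- c(msg, "'size' (2C in pg) must be a single positive number")
  if (length(object@role) != 1L || !object@role %in% c("primary", "secondary"))
    msg <- c(msg, "'role' must be \"primary\" or \"secondary\"")
  if (identical(object@role, "secondary") &&
      (length(object@provenance) != 1L || !nzchar(object@provenance)))
    msg <- c(msg, paste0("a secondary standard must carry a provenance note ",
                         "naming the primary it was calibrated against"))
  if (length(msg)) msg else TRUE
})

#' @rdname FcmStandard-class
#' @param name,size,role,provenance see slots.
#' @export
FcmStandard <- function(name, size, role = c("primary", "secondary"),
                        provenance = "") {
  new("FcmStandard", name = name, size = as.numeric(size),
      role = match.arg(role), provenance = provenance)
}

#' @describeIn FcmStandard-class 2C size in pg.
#' @param object,x an `FcmStandard`.
#' @export
standardSize <- function(x) {
  stopifnot(is(x, "FcmStandard"))
  x@size
}

#' @describeIn FcmStandard-class standard name.
#' @export
standardName <- function(x) {
  stopifnot(is(x, "FcmStandard"))
  x@name
}

setMethod("show", "FcmStandard", function(object) {
  cat(sprintf("FcmStandard: %s (%s), 2C = %.2f pg\n",
              object@name, object@role, object@size))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

## ---------------------------------------------------------------------------
## FcmSample -- event-level data for one tube
## ---------------------------------------------------------------------------

#' Event-level flow cytometry data for one tube
#'
#' Linear-scale fluorescence intensities (arbitrary units, one value per
#' recorded event) with an optional parallel side-scatter channel and a free
#' metadata list. Synthetic samples carry a `truth` block in the metadata
#' (nominal 2C, P, K, CV, seed) so downstream estimates can be scored.
#'
#' @slot fluorescence numeric vector, all values >= 0.
#' @slot sideScatter numeric vector, either empty or the same length as
#'   `fluorescence`.
#' @slot metadata named list; conventional entries are `sample_id`,
#'   `standard` (name), `note`, `truth`.
#'
#' @export
setClass("FcmSample",
  representation(fluorescence = "numeric", sideScatter = "numeric",
                 metadata = "list"),
  prototype(sideScatter = numeric(0), metadata = list()))

setValidity("FcmSample", function(object) {
  msg <- character()
  if (anyNA(object@fluorescence) || any(object@fluorescence < 0))
    msg <- c(msg, "all fluorescence intensities must be non-negative and non-NA")
  nssc <- length(object@sideScatter)
  if (nssc > 0L && nssc != length(object@fluorescence))
    msg <- c(msg, "side_scatter, when present, must parallel fluorescence")
  if (length(msg)) msg else TRUE
})

#' @rdname FcmSample-class
#' @param fluorescence,sideScatter,metadata see slots.
#' @export
FcmSample <- function(fluorescence, sideScatter = numeric(0),
                      metadata = list()) {
  new("FcmSample", fluorescence = as.numeric(fluorescence),
      sideScatter = as.numeric(sideScatter), metadata = metadata)
}

#' @describeIn FcmSample-class number of recorded events.
#' @param object,x an `FcmSample`.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname FcmSample-class
#' @export
setMethod("nEvents", "FcmSample", function(x) length(x@fluorescence))

#' @describeIn FcmSample-class fluorescence vector.
#' @export
fluorescence <- function(x) {
  stopifnot(is(x, "FcmSample"))
  x@fluorescence
}

#' @describeIn FcmSample-class side-scatter vector (length 0 when absent).
#' @export
sideScatter <- function(x) {
  stopifnot(is(x, "FcmSample"))
  x@sideScatter
}

#' @describeIn FcmSample-class metadata list.
#' @export
sampleMeta <- function(x) {
  stopifnot(is(x, "FcmSample") || is(x, "FcmHistogram") || is(x, "PeakSet"))
  x@metadata
}

#' @describeIn FcmSample-class the `sample_id` metadata entry (or `NA`).
#' @export
sampleID <- function(x) {
  id <- sampleMeta(x)$sample_id
  if (is.null(id)) NA_character_ else as.character(id)
}

setMethod("show", "FcmSample", function(object) {
  cat(sprintf("FcmSample: %d events%s\n", nEvents(object),
              if (length(object@sideScatter)) " (+ side scatter)" else ""))
  id <- object@metadata$sample_id
  if (!is.null(id)) cat("  sample_id:", id, "\n")
  if (!is.null(object@metadata$standard))
    cat("  standard: ", object@metadata$standard, "\n")
  if (!is.null(object@metadata$truth))
    cat("  synthetic sample with truth block\n")
})

## ---------------------------------------------------------------------------
## FcmHistogram -- binned counts on a linear fluorescence axis
## ---------------------------------------------------------------------------

#' Binned 1D fluorescence histogram
#'
#' Channel counts on a linear axis. Channel `i` (0-based) spans
#' `[i * gain, (i + 1) * gain)` intensity units, so its center is
#' `(i + 0.5) * gain`. Events at or beyond the axis end are accumulated in the
#' top channel and tallied in `overflow`.
#'
#' @slot counts non-negative integer counts, one per channel.
#' @slot gain units-per-channel scale factor (> 0). When the histogram was
#'   built from a simulated sample whose intensities are in pg, `gain` is in
#'   pg per channel.
#' @slot overflow number of events folded into the top channel.
#' @slot metadata named list carried over from the events.
#'
#' @export
setClass("FcmHistogram",
  representation(counts = "numeric", gain = "numeric", overflow = "numeric",
                 metadata = "list"),
  prototype(overflow = 0, metadata = list()))

setValidity("FcmHistogram", function(object) {
  msg <- character()
  if (length(object@counts) < 1L)
    msg <- c(msg, "histogram needs at least one channel")
  if (anyNA(object@counts) || any(object@counts < 0) ||
      any(object@counts != round(object@counts)))
    msg <- c(msg, "channel counts must be non-negative integers")
  if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain <= 0)
    msg <- c(msg, "gain must be a single positive number")
  if (length(object@overflow) != 1L || object@overflow < 0)
    msg <- c(msg, "overflow tally must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @describeIn FcmHistogram-class per-channel counts.
#' @param object,x an `FcmHistogram`.
#' @export
channelCounts <- function(x) {
  stopifnot(is(x, "FcmHistogram"))
  x@counts
}

#' @describeIn FcmHistogram-class channel center positions in intensity units.
#' @export
channelCenters <- function(x) {
  stopifnot(is(x, "FcmHistogram"))
  (seq_along(x@counts) - 0.5) * x@gain
}

#' @describeIn FcmHistogram-class units-per-channel scale.
#' @export
histGain <- function(x) {
  stopifnot(is(x, "FcmHistogram") || is(x, "PeakSet"))
  x@gain
}

#' @describeIn FcmHistogram-class events folded into the top channel.
#' @export
overflowCount <- function(x) {
  stopifnot(is(x, "FcmHistogram"))
  x@overflow
}

setMethod("nEvents", "FcmHistogram", function(x) sum(x@counts))

setMethod("show", "FcmHistogram", function(object) {
  cat(sprintf("FcmHistogram: %d channels, gain %.4g, %d events (%d overflow)\n",
              length(object@counts), object@gain, sum(object@counts),
              as.integer(object@overflow)))
})

## ---------------------------------------------------------------------------
## PeakSet -- fitted peaks from one histogram
## ---------------------------------------------------------------------------

.peakColumns <- c("position", "sd", "cv", "area", "role", "k",
                  "position_pg", "merged", "height")

#' Fitted peaks of one histogram
#'
#' A set of single-Gaussian peak fits. Positions and spreads are in continuous
#' channel units (channel `i`, 0-based, has center `i + 0.5`); `position_pg`
#' is filled once roles are assigned against a standard. `role` is one of
#' `"unassigned"`, `"standard"`, `"sample"`; `k` is the endocycle index
#' (0 = the 2C peak) and is non-`NA` exactly for sample peaks.
#'
#' @slot peaks data.frame with columns `position`, `sd`, `cv`, `area`,
#'   `role`, `k`, `position_pg`, `merged`, `height`, one row per peak,
#'   ordered by ascending position.
#' @slot gain units-per-channel scale of the source histogram.
#' @slot metadata list carried over from the histogram.
#'
#' @export
setClass("PeakSet",
  representation(peaks = "data.frame", gain = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  msg <- character()
  if (!all(.peakColumns %in% names(p)))
    msg <- c(msg, paste("peaks data.frame must have columns:",
                        paste(.peakColumns, collapse = ", ")))
  else {
    if (nrow(p)) {
      if (any(p$position <= 0)) msg <- c(msg, "peak positions must be > 0")
      if (any(p$cv <= 0)) msg <- c(msg, "peak cv must be > 0")
      if (any(p$area <= 0)) msg <- c(msg, "peak areas must be > 0")
      if (!all(p$role %in% c("unassigned", "standard", "sample")))
        msg <- c(msg, "roles must be unassigned/standard/sample")
      if (any(is.na(p$k) & p$role == "sample") ||
          any(!is.na(p$k) & p$role != "sample"))
        msg <- c(msg, "endocycle index k must be present iff role == \"sample\"")
      if (is.unsorted(p$position, strictly = FALSE))
        msg <- c(msg, "peaks must be sorted by ascending position")
    }
  }
  if (length(object@gain) != 1L || object@gain <= 0)
    msg <- c(msg, "gain must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname PeakSet-class
#' @param peaks,gain,metadata see slots.
#' @export
PeakSet <- function(peaks, gain, metadata = list()) {
  for (col in setdiff(.peakColumns, names(peaks))) {
    peaks[[col]] <- switch(col,
      role = "unassigned", k = NA_integer_, position_pg = NA_real_,
      merged = FALSE, height = NA_real_, NA_real_)
  }
  peaks <- peaks[order(peaks$position), .peakColumns, drop = FALSE]
  rownames(peaks) <- NULL
  new("PeakSet", peaks = peaks, gain = as.numeric(gain), metadata = metadata)
}

#' @describeIn PeakSet-class the peak table (data.frame).
#' @param object,x a `PeakSet`.
#' @export
peakData <- function(x) {
  stopifnot(is(x, "PeakSet"))
  x@peaks
}

#' @describeIn PeakSet-class number of peaks.
#' @export
nPeaks <- function(x) {
  stopifnot(is(x, "PeakSet"))
  nrow(x@peaks)
}

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peaks (gain %.4g)\n", nrow(object@peaks),
              object@gain))
  if (nrow(object@peaks))
    print(format(object@peaks[, c("position", "cv", "area", "role", "k",
                                  "position_pg")], digits = 4))
})

## ---------------------------------------------------------------------------
## DelineationRule -- thresholds for the joint (2C, P) marker
## ---------------------------------------------------------------------------

#' Rule set for joint (2C, P) delineation
#'
#' Thresholds for the joint cytometric marker: DNA-ploidy is inferred from the
#' fold change of P relative to a diploid reference, homoploid lineages are
#' separated by 2C shifts at constant P, and hybrid suspects are flagged by
#' large 2C deviation from their taxon mean.
#'
#' @slot pDiploidRef reference diploid P in pg; `NA` means "derive from the
#'   data" (median implied diploid P, see [inferPloidy()]).
#' @slot basePloidy ploidy of the reference (default 2).
#' @slot pTol relative tolerance for "same P" / clean integer fold
#'   (default 0.10).
#' @slot gsHybridDev relative 2C deviation from the (leave-one-out) taxon mean
#'   that flags an individual as homoploid-divergent (default 0.15; chosen so
#'   a deviation of ~18 percent flags while ordinary within-taxon scatter does not —
#'   a heuristic, not biology).
#' @slot diploidPBound upper bound (pg) that all diploid P values are expected
#'   to stay under (default 4).
#'
#' @export
setClass("DelineationRule",
  representation(pDiploidRef = "numeric", basePloidy = "numeric",
                 pTol = "numeric", gsHybridDev = "numeric",
                 diploidPBound = "numeric"),
  prototype(pDiploidRef = NA_real_, basePloidy = 2, pTol = 0.10,
            gsHybridDev = 0.15, diploidPBound = 4))

setValidity("DelineationRule", function(object) {
  msg <- character()
  if (!is.na(object@pDiploidRef) && object@pDiploidRef <= 0)
    msg <- c(msg, "pDiploidRef must be positive (or NA to derive from data)")
  if (object@basePloidy < 1 || object@basePloidy != round(object@basePloidy))
    msg <- c(msg, "basePloidy must be a positive integer")
  if (object@pTol <= 0 || object@pTol >= 0.5)
    msg <- c(msg, "pTol must be in (0, 0.5)")
  if (object@gsHybridDev <= 0 || object@gsHybridDev >= 1)
    msg <- c(msg, "gsHybridDev must be in (0, 1)")
  if (object@diploidPBound <= 0)
    msg <- c(msg, "diploidPBound must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname DelineationRule-class
#' @param pDiploidRef,basePloidy,pTol,gsHybridDev,diploidPBound see slots.
#' @export
DelineationRule <- function(pDiploidRef = NA_real_, basePloidy = 2,
                            pTol = 0.10, gsHybridDev = 0.15,
                            diploidPBound = 4) {
  new("DelineationRule", pDiploidRef = as.numeric(pDiploidRef),
      basePloidy = as.numeric(basePloidy), pTol = pTol,
      gsHybridDev = gsHybridDev, diploidPBound = diploidPBound)
}

setMethod("show", "DelineationRule", function(object) {
  cat("DelineationRule:\n")
  cat(sprintf("  diploid reference P: %s pg (base ploidy %d)\n",
              if (is.na(object@pDiploidRef)) "derived from data"
              else sprintf("%.2f", object@pDiploidRef),
              as.integer(object@basePloidy)))
  cat(sprintf("  P fold tolerance %.2f, 2C hybrid deviation %.2f, diploid P bound %.1f pg\n",
              object@pTol, object@gsHybridDev, object@diploidPBound))
})
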