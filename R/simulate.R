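## Event-level simulator for partial-endoreplication flow cytometry.
##
## The mixture emulates what the analysis assumes about a real tube: a
## Gaussian internal-standard peak, a sample peak series at 2C + k*P for
## k = 0..K (partial endoreplication adds a constant genome fraction P per
## endocycle, unlike whole-genome endopolyploidy which doubles), geometric
## decay of peak areas with k, and an exponential debris background below
## the standard.

#' Simulation parameters for one synthetic tube
#'
#' @slot twoC nominal sample 2C in pg (> P).
#' @slot p nominal endoreplicated-part size P in pg (0 < P < 2C).
#' @slot kMax highest endocycle index K (>= 0); K = 3 gives the four-peak
#'   sample series commonly seen in ovary tissue.
#' @slot peakWeights relative areas of the sample peaks k = 0..K; default a
#'   geometric decay with ratio 0.5 (later endocycles hold fewer nuclei).
#' @slot cv per-peak coefficient of variation (sd/mean) as a fraction;
#'   default 0.03, typical of good plant preparations (2-5 percent).
#' @slot standard the internal size standard co-run in the tube.
#' @slot standardFraction fraction of non-debris events in the standard peak.
#' @slot debrisFraction fraction of all events that are debris.
#' @slot nEvents total events to record (>= 1; 5000 is a usual minimum).
#' @slot gain pg per fluorescence unit: an event representing `x` pg is
#'   recorded at intensity `x / gain`. Default 0.05 pg/unit puts a 2C = 40 pg
#'   nucleus at intensity 800, inside a 1024-channel axis at unit binning.
#' @slot seed integer seed making the draw fully reproducible.
#'
#' @export
setClass("SimParams",
  representation(twoC = "numeric", p = "numeric", kMax = "numeric",
                 peakWeights = "numeric", cv = "numeric",
                 standard = "FcmStandard", standardFraction = "numeric",
                 debrisFraction = "numeric", nEvents = "numeric",
                 gain = "numeric", seed = "numeric"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (!(object@p > 0 && object@p < object@twoC))
    msg <- c(msg, "need 0 < P < 2C")
  if (object@kMax < 0 || object@kMax != round(object@kMax))
    msg <- c(msg, "kMax must be a non-negative integer")
  if (length(object@peakWeights) != object@kMax + 1 ||
      any(object@peakWeights <= 0))
    msg <- c(msg, "peakWeights must be kMax + 1 positive values")
  if (object@cv <= 0) msg <- c(msg, "cv must be > 0")
  if (object@standardFraction < 0 || object@standardFraction >= 1)
    msg <- c(msg, "standardFraction must be in [0, 1)")
  if (object@debrisFraction < 0 || object@debrisFraction >= 1)
    msg <- c(msg, "debrisFraction must be in [0, 1)")
  if (object@nEvents < 1) msg <- c(msg, "nEvents must be >= 1")
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimParams-class
#' @param twoC,p,kMax,peakWeights,cv,standard,standardFraction,debrisFraction,nEvents,gain,seed
#'   see slots.
#' @export
simParams <- function(twoC, p, standard = FcmStandard("Pisum sativum 'Ctirad'", 8.76),
                      kMax = 3, peakWeights = 0.5^(0:kMax), cv = 0.03,
                      standardFraction = 0.3, debrisFraction = 0.05,
                      nEvents = 5000, gain = 0.05, seed = 1L) {
  new("SimParams", twoC = as.numeric(twoC), p = as.numeric(p),
      kMax = as.numeric(kMax), peakWeights = as.numeric(peakWeights),
      cv = as.numeric(cv), standard = standard,
      standardFraction = as.numeric(standardFraction),
      debrisFraction = as.numeric(debrisFraction),
      nEvents = as.numeric(nEvents), gain = as.numeric(gain),
      seed = as.numeric(seed))
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: 2C = %.2f pg, P = %.2f pg (K = %d), cv = %.3f\n",
              object@twoC, object@p, as.integer(object@kMax), object@cv))
  cat(sprintf("  standard %s (%.2f pg), %d events, seed %d\n",
              object@standard@name, object@standard@size,
              as.integer(object@nEvents), as.integer(object@seed)))
})

## Inverse-CDF draw from an exponential truncated to [0, hi]; `scale` is the
## untruncated mean.
rtexp <- function(n, scale, hi) {
  u <- runif(n)
  -scale * log(1 - u * (1 - exp(-hi / scale)))
}

#' Simulate one partial-endoreplication tube
#'
#' Draws `nEvents` fluorescence events from the mixture of debris
#' (exponential, restricted below the standard position), the standard peak
#' (Gaussian, mean proportional to the standard 2C, sd = cv * mean) and the
#' sample peak series (Gaussians at 2C + k*P, k = 0..K, areas per
#' `peakWeights`). Event order is randomized; the nominal truth is stored in
#' the metadata `truth` block. Identical parameters and seed give a
#' bit-identical result.
#'
#' If the sample 2C peak lies within `2 * cv` (relative) of the standard peak
#' an overlap warning is emitted — the situation in which a secondary
#' standard of different size is needed — but data are still generated.
#'
#' @param params a [SimParams-class] object.
#' @param sampleID identifier stored in the metadata.
#' @param sideScatter logical; also draw a side-scatter channel (debris low,
#'   nuclei higher, both lognormal-ish)?
#' @return an [FcmSample-class].
#' @examples
#' ev <- simulateSample(simParams(twoC = 10.46, p = 3.53, seed = 42))
#' nEvents(ev)
#' @export
simulateSample <- function(params, sampleID = "synthetic", sideScatter = FALSE) {
  validObject(params)
  std <- params@standard
  if (abs(params@twoC - std@size) / std@size < 2 * params@cv)
    warnf(paste0("sample 2C (%.2f pg) overlaps the standard peak (%s, %.2f pg);",
                 " consider a secondary standard of different size"),
          params@twoC, std@name, std@size, class = "flowPE_overlap_warning")

  kMax <- as.integer(params@kMax)
  meansPg <- c(std@size, params@twoC + (0:kMax) * params@p)
  w <- params@peakWeights / sum(params@peakWeights)
  probs <- c(params@debrisFraction,
             (1 - params@debrisFraction) * params@standardFraction,
             (1 - params@debrisFraction) * (1 - params@standardFraction) * w)

  fl <- withSeed(params@seed, {
    n <- as.integer(params@nEvents)
    comp <- sample.int(length(probs), n, replace = TRUE, prob = probs)
    x <- numeric(n)
    debris <- comp == 1L
    stdPos <- std@size / params@gain
    if (any(debris))
      x[debris] <- rtexp(sum(debris), scale = stdPos / 5, hi = stdPos)
    for (j in seq_along(meansPg)) {
      sel <- comp == j + 1L
      if (any(sel)) {
        mu <- meansPg[j] / params@gain
        x[sel] <- abs(rnorm(sum(sel), mean = mu, sd = params@cv * mu))
      }
    }
    list(x = x, comp = comp,
         ssc = if (sideScatter) abs(rnorm(n, mean = ifelse(debris, 40, 110),
                                          sd = ifelse(debris, 15, 20)))
               else numeric(0))
  })

  truth <- list(two_c = params@twoC, p = params@p, k_max = kMax,
                cv = params@cv, peak_weights = w,
                standard = std@name, standard_pg = std@size,
                standard_fraction = params@standardFraction,
                debris_fraction = params@debrisFraction,
                gain = params@gain, n_events = as.integer(params@nEvents),
                seed = as.integer(params@seed),
                nominal_positions = meansPg / params@gain,
                component = fl$comp)
  FcmSample(fl$x, sideScatter = fl$ssc,
            metadata = list(sample_id = sampleID, standard = std@name,
                            note = "synthetic", truth = truth))
}

#' Draw per-individual nominal (2C, P) values for a cohort
#'
#' For each taxon row, draws `n` individuals' nominal 2C and P from normal
#' distributions truncated at zero with the given means and sds. A draw with
#' P >= 2C is rejected and redrawn, up to 100 attempts per individual.
#'
#' @param taxa data.frame with columns `taxon`, `gs_mean`, `gs_sd`, `p_mean`,
#'   `p_sd`, `n` and optionally `ploidy`, `region`, `standard`.
#' @param seed integer seed.
#' @return data.frame, one row per individual: `sample_id`, `taxon`,
#'   (`ploidy`, `region`, `standard` when given,) `two_c`, `p`.
#' @export
drawCohortParams <- function(taxa, seed = 1L) {
  need <- c("taxon", "gs_mean", "gs_sd", "p_mean", "p_sd", "n")
  if (!all(need %in% names(taxa)))
    stopf("cohort table needs columns: %s", paste(need, collapse = ", "),
          class = "flowPE_parameter_error")
  if (any(taxa$gs_sd < 0) || any(taxa$p_sd < 0) || any(taxa$n < 1))
    stopf("need sd >= 0 and n >= 1 in every cohort row",
          class = "flowPE_parameter_error")
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(taxa)), function(i) {
      r <- taxa[i, ]
      draws <- vapply(seq_len(r$n), function(j) {
        for (attempt in 1:100) {
          g <- rnorm(1, r$gs_mean, r$gs_sd)
          p <- rnorm(1, r$p_mean, r$p_sd)
          if (g > 0 && p > 0 && p < g) return(c(g, p))
        }
        stopf("could not draw 0 < P < 2C for taxon '%s' in 100 attempts",
              r$taxon, class = "flowPE_parameter_error")
      }, numeric(2))
      out <- data.frame(taxon = r$taxon, two_c = draws[1, ], p = draws[2, ],
                        stringsAsFactors = FALSE)
      for (col in c("ploidy", "region", "standard"))
        if (col %in% names(taxa)) out[[col]] <- r[[col]]
      out
    })
    out <- do.call(rbind, rows)
    out$sample_id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", out$taxon),
                             stats::ave(seq_len(nrow(out)), out$taxon,
                                        FUN = seq_along))
    out[, c("sample_id", setdiff(names(out), "sample_id"))]
  })
}

#' Simulate a cohort of individuals across taxa
#'
#' Draws nominal (2C, P) per individual with [drawCohortParams()], then
#' simulates each individual's events with [simulateSample()] under an
#' individual child seed. A `standard` column in `taxa` selects the standard
#' per taxon from `standards` (the secondary-standard route used when a
#' sample would overlap the primary).
#'
#' @inheritParams drawCohortParams
#' @param base a [SimParams-class] supplying everything except 2C, P and the
#'   per-taxon standard.
#' @param standards named list of [FcmStandard-class] objects for lookup by
#'   the `standard` column; defaults to the base standard only.
#' @return named list of [FcmSample-class] objects (names = sample ids), with
#'   the drawn nominal values in each sample's truth block.
#' @export
simulateCohort <- function(taxa, base = simParams(10, 3), seed = 1L,
                           standards = NULL) {
  ind <- drawCohortParams(taxa, seed = seed)
  seeds <- childSeeds(seed + 1L, nrow(ind))
  if (is.null(standards))
    standards <- setNames(list(base@standard), base@standard@name)
  out <- lapply(seq_len(nrow(ind)), function(i) {
    std <- base@standard
    if (!is.null(ind$standard) && !is.na(ind$standard[i])) {
      std <- standards[[ind$standard[i]]]
      if (is.null(std))
        stopf("unknown standard '%s'", ind$standard[i],
              class = "flowPE_parameter_error")
    }
    p <- simParams(twoC = ind$two_c[i], p = ind$p[i], standard = std,
                   kMax = base@kMax, peakWeights = base@peakWeights,
                   cv = base@cv, standardFraction = base@standardFraction,
                   debrisFraction = base@debrisFraction,
                   nEvents = base@nEvents, gain = base@gain,
                   seed = seeds[i])
    s <- simulateSample(p, sampleID = ind$sample_id[i])
    s@metadata$taxon <- ind$taxon[i]
    if (!is.null(ind$ploidy)) s@metadata$ploidy <- ind$ploidy[i]
    if (!is.null(ind$region)) s@metadata$region <- ind$region[i]
    s
  })
  names(out) <- ind$sample_id
  attr(out, "individuals") <- ind
  out
}
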