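# Shared fixture builders. Everything is generated in code; no data files.

pisum <- FcmStandard("Pisum sativum 'Ctirad'", 8.76)
solanum <- FcmStandard("Solanum pseudocapsicum", 2.57, role = "secondary",
                       provenance = "calibrated against Pisum sativum 'Ctirad'")

# A PeakSet with peaks at the given pg positions (converted to channels at
# `gain` pg/channel), tight Gaussians of relative width `cv`.
makePeakSet <- function(positionsPg, gain = 0.05, cv = 0.02, areas = NULL) {
  pos <- positionsPg / gain
  if (is.null(areas)) areas <- rep(1000, length(pos))
  PeakSet(data.frame(position = pos, sd = cv * pos, cv = cv,
                     area = areas, height = areas / (cv * pos * sqrt(2 * pi))),
          gain = 1)
}

# Cohort table of the leaf reference rows (regional/variant level; the two
# pooled aggregate rows excluded so individuals are not duplicated).
leafCohort <- function() {
  ref <- neotineaReference()
  leaf <- ref[!ref$aggregate, ]
  data.frame(
    taxon = paste0(leaf$taxon,
                   ifelse(leaf$region == "", "", paste0(" | ", leaf$region))),
    gs_mean = leaf$gs_mean, gs_sd = leaf$gs_sd,
    p_mean = leaf$p_mean, p_sd = leaf$p_sd, n = leaf$n,
    ploidy = leaf$ploidy, region = leaf$region, standard = leaf$standard,
    stringsAsFactors = FALSE)
}

# The polyploid series of the N. tridentata group: diploids, DNA-triploids
# and the tetraploid N. commutata, at reference means/sds.
ploidySeriesCohort <- function(nDip = 4L, nTri = 2L, nTet = 3L) {
  data.frame(taxon = c("N. tridentata", "N. tridentata 3x", "N. commutata"),
             gs_mean = c(10.49, 16.16, 19.46), gs_sd = c(0.38, 1.14, 0.39),
             p_mean = c(3.55, 5.27, 7.06), p_sd = c(0.16, 0.17, 0.09),
             n = c(nDip, nTri, nTet), ploidy = c(2L, 3L, 4L),
             stringsAsFactors = FALSE)
}

quietMeasure <- function(events, standard, ...) {
  suppressMessages(suppressWarnings(measureSample(events, standard, ...)))
}

quietDetect <- function(hist, ...) {
  suppressMessages(suppressWarnings(detectPeaks(hist, ...)))
}
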