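test_that("rectangular gates keep exactly the events inside", {
  ev <- FcmSample(c(1, 5, 2, 8, 3), sideScatter = c(10, 20, 30, 40, 50))
  expect_equal(fluorescence(gateEvents(ev, flRange = c(0, Inf))),
               fluorescence(ev))
  med <- median(fluorescence(ev))
  low <- gateEvents(ev, flRange = c(0, med))
  expect_setequal(fluorescence(low), c(1, 2))  # strictly below the median
  both <- gateEvents(ev, flRange = c(0, 9), sscRange = c(15, 45))
  expect_equal(fluorescence(both), c(5, 2, 8))
  expect_error(gateEvents(ev, flRange = c(100, 200)),
               class = "flowPE_empty_gate_error")
  expect_error(gateEvents(FcmSample(1:3), sscRange = c(0, 1)),
               class = "flowPE_parameter_error")
})

test_that("gating out the debris band retains about 1 - debris_fraction", {
  p <- simParams(twoC = 17.52, p = 4, debrisFraction = 0.2, seed = 9)
  ev <- simulateSample(p)
  gate <- gateEvents(ev, flRange = c(0.8 * 8.76 / 0.05, Inf))
  frac <- nEvents(gate) / nEvents(ev)
  expect_equal(frac, 0.8, tolerance = 0.02)
})

test_that("empty histograms and all-noise histograms give no-peaks errors", {
  h0 <- binEvents(FcmSample(numeric(0)), nChannels = 64, gain = 1)
  expect_error(detectPeaks(h0), class = "flowPE_no_peaks_error")
})

test_that("two well-separated Gaussians are found at their positions", {
  ev <- simulateSample(simParams(twoC = 17.52, p = 3, kMax = 0,
                                 peakWeights = 1, debrisFraction = 0,
                                 seed = 5))
  pk <- quietDetect(binEvents(ev, 1024, 1))
  expect_equal(nPeaks(pk), 2L)
  expect_lt(max(abs(peakData(pk)$position -
                    sampleMeta(ev)$truth$nominal_positions)), 0.5)
})

test_that("a standard-plus-four-peak series is recovered in full", {
  # large genome, shallow endoreplication: the hardest of the reference
  # patterns, with four sample peaks above one standard
  ev <- simulateSample(simParams(twoC = 28.65, p = 3.59, seed = 1))
  pk <- quietDetect(binEvents(ev, 1024, 1))
  expect_equal(nPeaks(pk), 5L)
})

test_that("single-peak fits return center, spread and Gaussian area", {
  ev <- simulateSample(simParams(twoC = 17.52, p = 3, kMax = 0,
                                 peakWeights = 1, debrisFraction = 0,
                                 standardFraction = 0, cv = 0.03, seed = 4))
  h <- binEvents(ev, 1024, 1)
  nominal <- 17.52 / 0.05
  fit <- fitPeak(h, c(round(nominal - 40), round(nominal + 40)))
  expect_lt(abs(fit$position - nominal), 0.5)
  expect_equal(fit$cv, 0.03, tolerance = 0.1)
  expect_equal(fit$area, 5000, tolerance = 0.05)

  h2 <- binEvents(FcmSample(rep(100.2, 50)), nChannels = 1024, gain = 1)
  expect_error(fitPeak(h2, c(90, 110)), class = "flowPE_fit_error")
})

test_that("detection is idempotent and equivariant under gain rescaling", {
  ev <- simulateSample(simParams(twoC = 10.46, p = 3.53, seed = 6))
  h <- binEvents(ev, 1024, 1)
  a <- quietDetect(h)
  b <- quietDetect(h)
  expect_identical(peakData(a), peakData(b))

  # doubling gain halves channel-space positions...
  h2 <- binEvents(ev, 1024, 2)
  c2 <- quietDetect(h2)
  shared <- min(nPeaks(a), nPeaks(c2))
  expect_equal(peakData(c2)$position[seq_len(shared)],
               peakData(a)$position[seq_len(shared)] / 2, tolerance = 0.01)
  # ...and leaves pg-space results unchanged downstream
  m1 <- quietMeasure(ev, pisum, gain = 1)$measurement
  m2 <- quietMeasure(ev, pisum, gain = 2)$measurement
  expect_equal(m2$two_c_pg, m1$two_c_pg, tolerance = 0.005)
  expect_equal(m2$p_pg, m1$p_pg, tolerance = 0.01)
})

test_that("noiseless input yields K + 2 delta peaks at exact positions", {
  # positions chosen at exact channel centers; binning quantization would
  # otherwise dominate the sub-0.1% check
  std <- FcmStandard("center-standard", 10.025)
  ev <- simulateSample(simParams(twoC = 15.025, p = 2.5, cv = 1e-6,
                                 debrisFraction = 0, standard = std,
                                 seed = 1))
  pk <- quietDetect(binEvents(ev, 1024, 1))
  expect_equal(nPeaks(pk), 5L)  # K + 2 with K = 3
  nominal <- sampleMeta(ev)$truth$nominal_positions
  expect_lt(max(abs(peakData(pk)$position - nominal) / nominal), 0.001)
})

test_that("quality gates drop weak or ragged candidates with a message", {
  ev <- simulateSample(simParams(twoC = 10.46, p = 3.53, seed = 42))
  h <- binEvents(ev, 1024, 1)
  # an impossible area floor drops every candidate, with a logged reason
  expect_message(
    expect_error(suppressWarnings(detectPeaks(h, minPeakEvents = 1e6)),
                 class = "flowPE_no_peaks_error"),
    "dropped")
  pkStrict <- quietDetect(h, minPeakEvents = 400)
  expect_true(all(peakData(pkStrict)$area >= 400))
  expect_error(detectPeaks(h, smoothWindow = 4),
               class = "flowPE_parameter_error")
})
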