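test_that("CSV events parse directly and round-trip bit-exactly", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("fl", "10", "20", "30"), f)
  ev <- readEvents(f)
  expect_equal(nEvents(ev), 3L)
  expect_equal(fluorescence(ev), c(10, 20, 30))

  set.seed(99)
  vals <- runif(200) * 1000
  ssc <- runif(200) * 300
  ev2 <- FcmSample(vals, sideScatter = ssc,
                   metadata = list(sample_id = "rt"))
  f2 <- tempfile(fileext = ".csv")
  writeEvents(ev2, f2)
  back <- readEvents(f2)
  expect_identical(fluorescence(back), vals)
  expect_identical(sideScatter(back), ssc)
})

test_that("CSV edge cases raise typed errors", {
  expect_error(readEvents(tempfile()), class = "flowPE_io_error")
  f <- tempfile(fileext = ".csv")
  writeLines("fl", f)
  expect_error(readEvents(f), class = "flowPE_empty_input_error")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("fl", "a", "b"), f2)
  expect_error(readEvents(f2), class = "flowPE_format_error")
})

test_that("minimal FCS files round-trip events and metadata", {
  set.seed(7)
  vals <- round(runif(500) * 1000, 3)
  ev <- FcmSample(vals, sideScatter = round(runif(500) * 200, 3),
                  metadata = list(sample_id = "tube1", standard = pisum@name))
  f <- tempfile(fileext = ".fcs")
  writeFCS(ev, f)
  back <- readEvents(f)  # auto-detects FCS magic
  expect_equal(fluorescence(back), vals, tolerance = 1e-6)
  expect_equal(length(sideScatter(back)), 500L)
  expect_equal(sampleID(back), "tube1")
  expect_equal(sampleMeta(back)$standard, pisum@name)
})

test_that("log-scale FCS parameters are rejected as unsupported", {
  ev <- FcmSample(runif(50) * 100)
  f <- tempfile(fileext = ".fcs")
  writeFCS(ev, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  i <- grepRaw("$P1E/0,0", raw, fixed = TRUE)
  raw[i + 5L] <- charToRaw("4")  # $P1E/4,0 = 4-decade log amplification
  writeBin(raw, f)
  expect_error(readFCS(f), class = "flowPE_unsupported_scale_error")
})

test_that("binning conserves counts, folds overflow into the top channel", {
  h <- binEvents(FcmSample(c(0.4, 1.6)), nChannels = 64, gain = 1)
  expect_equal(channelCounts(h)[1:2], c(1, 1))
  expect_equal(sum(channelCounts(h)), 2)

  h0 <- binEvents(FcmSample(numeric(0)), nChannels = 64, gain = 1)
  expect_true(all(channelCounts(h0) == 0))

  ev <- simulateSample(simParams(twoC = 10.46, p = 3.53, seed = 3))
  h1 <- binEvents(ev, nChannels = 1024, gain = 1)
  expect_equal(sum(channelCounts(h1)), 5000)

  hov <- binEvents(FcmSample(c(10, 2000, 3000)), nChannels = 1024, gain = 1)
  expect_equal(overflowCount(hov), 2)
  expect_equal(sum(channelCounts(hov)), 3)  # conserved incl. overflow
  expect_equal(channelCounts(hov)[1024], 2)

  expect_error(binEvents(ev, gain = 0), class = "flowPE_parameter_error")
  expect_error(binEvents(ev, nChannels = 32), class = "flowPE_parameter_error")
})

test_that("peak tables hold one row per peak plus summary rows and round-trip", {
  ps <- makePeakSet(c(8.76, 10.46), cv = 0.03)
  meas <- data.frame(sample_id = "s1", two_c_pg = 10.4632, p_pg = 3.52718,
                     p_percent = 100 * 3.52718 / 10.4632,
                     k_used = 2L, intercept_pg = 10.4629)
  f <- tempfile(fileext = ".tsv")
  writePeakTable(ps, meas, f, provenance = c(seed = "1"))
  expect_error(writePeakTable(ps@peaks[0, ], meas, f),
               class = "flowPE_parameter_error")

  back <- readPeakTable(f)
  expect_equal(nrow(back$peaks), 2L)
  expect_equal(back$provenance[["seed"]], "1")
  # positions round-trip at 6 significant digits
  expect_equal(back$peaks$position_channels, peakData(ps)$position,
               tolerance = 1e-6)
  # the stored P% agrees with 100 * P / 2C recomputed from the same rows
  expect_equal(back$summary[["P_pct"]],
               100 * back$summary[["P_pg"]] / back$summary[["2C_pg"]],
               tolerance = 1e-5)
})

test_that("a measured synthetic sample writes an internally consistent table", {
  ev <- simulateSample(simParams(twoC = 10.46, p = 3.53, seed = 11),
                       sampleID = "ust11")
  res <- quietMeasure(ev, pisum)
  f <- tempfile(fileext = ".tsv")
  writePeakTable(res$peaks, res$measurement, f)
  back <- readPeakTable(f)
  expect_equal(nrow(back$peaks), 5L)  # standard + four-peak sample series
  expect_equal(back$summary[["P_pct"]],
               100 * back$summary[["P_pg"]] / back$summary[["2C_pg"]],
               tolerance = 1e-5)
})
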