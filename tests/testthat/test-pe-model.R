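test_that("peak roles follow the arithmetic-progression heuristic", {
  # standard + four-peak series built from reference values
  # (2C = 10.46, P = 3.53 against Pisum 8.76)
  ps <- makePeakSet(c(8.76, 10.46, 13.99, 17.52, 21.05))
  out <- peakData(assignPeaks(ps, pisum))
  expect_equal(out$role, c("standard", rep("sample", 4)))
  expect_equal(out$k, c(NA, 0L, 1L, 2L, 3L))
  expect_equal(out$position_pg, c(8.76, 10.46, 13.99, 17.52, 21.05),
               tolerance = 1e-9)
})

test_that("coincident peaks give an overlap error, collinear ones need a hint", {
  two <- makePeakSet(c(8.76, 8.76))
  expect_error(assignPeaks(two, pisum), class = "flowPE_overlap_error")

  # secondary-standard case: three peaks are always collinear after any
  # exclusion, so the expected-2C hint identifies the standard
  three <- makePeakSet(c(2.57, 7.12, 10.01))
  expect_error(assignPeaks(three, solanum),
               class = "flowPE_assignment_error")
  out <- peakData(assignPeaks(three, solanum, hint = c(4, 9)))
  expect_equal(out$role, c("standard", "sample", "sample"))
  expect_equal(out$position_pg, c(2.57, 7.12, 10.01), tolerance = 1e-9)
  est <- estimateP(out[out$role == "sample", ])
  expect_equal(est$p_pg, 2.89, tolerance = 1e-9)
})

test_that("ambiguous or unmatchable peak sets are refused", {
  # non-progression triple: every exclusion leaves two collinear points,
  # so without prior knowledge the standard cannot be identified
  ps <- makePeakSet(c(8.76, 11, 19))
  expect_error(assignPeaks(ps, pisum), class = "flowPE_assignment_error")
  # a hint that matches no candidate leaves no viable subset at all
  expect_error(assignPeaks(ps, pisum, hint = c(100, 200)),
               class = "flowPE_assignment_error")
})

test_that("genome size is the calibrated peak ratio", {
  mk <- function(pos) list(position = pos)
  expect_equal(estimateGenomeSize(mk(100), mk(100), pisum), 8.76)
  expect_equal(estimateGenomeSize(mk(200), mk(100), pisum), 17.52)
  # back-computed ratio against the secondary standard
  expect_equal(round(estimateGenomeSize(mk(2.7704), mk(1), solanum), 2),
               7.12)
  expect_error(estimateGenomeSize(mk(0), mk(100), pisum),
               class = "flowPE_parameter_error")
})

test_that("P estimation reduces to differences and matches normal equations", {
  sp <- data.frame(position_pg = c(10, 13, 16, 19), k = 0:3,
                   area = c(800, 400, 200, 100))
  est <- estimateP(sp)
  expect_equal(est$p_pg, 3)
  expect_equal(est$intercept_pg, 10)

  # reference tetraploid series: 2C = 19.46, meanP = 7.06
  sp2 <- data.frame(position_pg = c(19.46, 26.52, 33.58), k = 0:2,
                    area = c(4, 2, 1))
  expect_equal(estimateP(sp2)$p_pg, 7.06, tolerance = 1e-9)

  # exact two-peak reduction
  sp3 <- data.frame(position_pg = c(11.2, 14.9), k = 0:1, area = c(9, 2))
  expect_identical(estimateP(sp3)$p_pg, 14.9 - 11.2)
  expect_equal(estimateP(sp, pMode = "first_two")$p_pg, 3)

  expect_error(estimateP(sp[1, ]), class = "flowPE_insufficient_peaks_error")
  dec <- data.frame(position_pg = c(10, 7), k = 0:1, area = c(1, 1))
  expect_error(estimateP(dec), class = "flowPE_model_violation_error")

  # brute-force weighted normal equations oracle
  set.seed(31)
  for (rep in 1:25) {
    m <- sample(2:6, 1)
    d <- data.frame(position_pg = sort(runif(m, 5, 40)), k = 0:(m - 1),
                    area = runif(m, 10, 1000))
    est <- estimateP(d)
    W <- diag(d$area)
    X <- cbind(1, d$k)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% d$position_pg)
    if (beta[2] > 0) {
      expect_equal(est$p_pg, beta[2], tolerance = 1e-10)
      expect_equal(est$intercept_pg, beta[1], tolerance = 1e-10)
    }
  }
})

test_that("percentP reproduces the published endoreplication percentages", {
  expect_equal(round(percentP(7.06, 19.46), 1), 36.3)
  expect_equal(round(percentP(2.89, 7.12), 1), 40.6)
  expect_equal(percentP(5, 10), 50)
  expect_error(percentP(10, 5), class = "flowPE_parameter_error")
  expect_error(percentP(0, 5), class = "flowPE_parameter_error")
})

test_that("secondary standards calibrate against the primary with provenance", {
  expect_equal(standardSize(calibrateSecondaryStandard(1.0, pisum)), 8.76)
  sec <- calibrateSecondaryStandard(c(0.29338, 0.29338), pisum, "Solanum")
  expect_equal(round(standardSize(sec), 2), 2.57)
  expect_equal(sec@role, "secondary")
  expect_match(sec@provenance, "Pisum")
  spread <- calibrateSecondaryStandard(c(0.5, 1.5), pisum)
  expect_equal(standardSize(spread), 8.76)
  expect_match(spread@provenance, "sd")
  expect_error(calibrateSecondaryStandard(numeric(0), pisum),
               class = "flowPE_parameter_error")
})

test_that("end-to-end measurement recovers 2C, P and a consistent intercept", {
  hits <- 0L
  for (seed in 1:20) {
    ev <- simulateSample(simParams(twoC = 10.46, p = 3.53, seed = seed))
    m <- quietMeasure(ev, pisum)$measurement
    expect_equal(m$two_c_pg, 10.46, tolerance = 0.02)
    expect_equal(m$p_pg, 3.53, tolerance = 0.02)
    if (abs(m$intercept_pg - m$two_c_pg) / m$two_c_pg < 0.01)
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("an unresolved standard overlap is refused, not silently measured", {
  # sample 2C drawn into the standard's flank: one blob plus three higher
  # peaks; a naive reading would shift every k by one
  ev <- suppressWarnings(
    simulateSample(simParams(twoC = 9.5, p = 3.55, seed = 2)))
  expect_error(quietMeasure(ev, pisum), class = "flowPE_overlap_error")
})
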