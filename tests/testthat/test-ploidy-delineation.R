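test_that("ploidy follows the integer fold of P over the diploid reference", {
  rule <- DelineationRule(pDiploidRef = 3.55)
  r <- inferPloidy(c(3.55, 5.27, 7.06), rule)
  expect_equal(r$ploidy, c(2L, 3L, 4L))
  expect_equal(r$residual[1], 0)
  expect_equal(round(5.27 / 3.55, 1), 1.5)   # the DNA-triploid fold
  expect_equal(round(7.06 / 3.55), 2)        # the tetraploid fold
  expect_false(any(r$ambiguous))
  off <- inferPloidy(3.55 * 1.25, rule)      # halfway between folds
  expect_true(off$ambiguous)
})

test_that("inferPloidy is monotone and jointly scale-invariant", {
  rule <- DelineationRule(pDiploidRef = 3.5)
  p <- seq(1, 15, by = 0.05)
  pl <- inferPloidy(p, rule)$ploidy
  expect_true(all(diff(pl) >= 0))
  for (c in c(0.1, 3, 42)) {
    ruleC <- DelineationRule(pDiploidRef = 3.5 * c)
    expect_identical(inferPloidy(p * c, ruleC)$ploidy, pl)
  }
})

test_that("the diploid reference is recovered without majority diploids", {
  # reference diploid meanP values plus the polyploid levels
  dip <- c(2.89, 3.64, 3.59, 3.55, 3.69, 3.55, 3.27, 3.55, 3.53, 3.51)
  ref <- deriveDiploidRef(c(dip, 5.27, 7.06))
  expect_equal(ref, 3.55, tolerance = 0.05)
  # polyploid-dominated set: median P is NOT the diploid level
  mix <- c(3.4, 3.5, 5.2, 5.3, 5.25, 7.0, 7.1, 7.05)
  ref2 <- deriveDiploidRef(mix)
  expect_equal(ref2, 3.5, tolerance = 0.1)
})

test_that("joint classification flags the 18%-deviant hybrid suspect", {
  m <- data.frame(
    taxon = c(rep("A", 5), rep("B", 3)),
    two_c_pg = c(23.8, 28.0, 28.2, 28.1, 28.1, 13.9, 13.95, 13.91),
    p_pg = c(3.59, 3.6, 3.58, 3.59, 3.6, 3.69, 3.7, 3.68))
  out <- jointClassify(m, DelineationRule(pDiploidRef = 3.55))
  expect_equal(out$class[1], "homoploid-divergent")
  expect_equal(round(out$hybrid_dev_pct[1]), 18)  # (28.1 - 23.8) / 23.8
  expect_match(out$flags[1], "hybrid-suspect")    # intermediate toward B
  expect_true(all(out$class[2:8] == "consistent"))
})

test_that("exact-at-mean individuals are consistent with zero deviation", {
  m <- data.frame(taxon = rep("A", 3), two_c_pg = rep(10, 3),
                  p_pg = rep(3.5, 3))
  out <- jointClassify(m, DelineationRule(pDiploidRef = 3.5))
  expect_true(all(out$class == "consistent"))
  expect_true(all(out$deviation_pct == 0))
})

test_that("a 1.5-fold shift in P is a ploidy variant", {
  m <- data.frame(taxon = rep("A", 4),
                  two_c_pg = c(10, 10.1, 9.9, 15),
                  p_pg = c(3.5, 3.52, 3.48, 5.25))
  out <- jointClassify(m, DelineationRule(pDiploidRef = 3.5))
  expect_equal(out$class[4], "ploidy-variant")
  expect_equal(out$ploidy[4], 3L)
})

test_that("deviation uses the leave-one-out mean so outliers cannot self-mask", {
  m <- data.frame(taxon = rep("A", 3), two_c_pg = c(10, 10, 11.8),
                  p_pg = rep(3.5, 3))
  out <- jointClassify(m, DelineationRule(pDiploidRef = 3.5))
  # vs leave-one-out mean 10 the outlier deviates 18%; the full-taxon mean
  # (10.6) would have diluted it to ~11% and missed the default threshold
  expect_equal(out$deviation_pct[3], 18, tolerance = 1e-9)
  expect_equal(out$class[3], "homoploid-divergent")
})

test_that("unknown labels and missing columns are labeling errors", {
  m <- data.frame(taxon = c("A", NA), two_c_pg = c(10, 10), p_pg = c(3, 3))
  expect_error(jointClassify(m), class = "flowPE_labeling_error")
  expect_error(jointClassify(data.frame(x = 1)),
               class = "flowPE_labeling_error")
})

test_that("diploid P values stay under the common band", {
  dip <- data.frame(
    p_pg = c(2.89, 3.64, 3.59, 3.55, 3.69, 3.55, 3.27, 3.55, 3.53, 3.51),
    ploidy = 2L)
  band <- diploidPBand(dip)
  expect_equal(band$max, 3.69)
  expect_true(band$pass)

  one <- diploidPBand(data.frame(p_pg = 3, ploidy = 2L))
  expect_equal(c(one$min, one$max), c(3, 3))
  expect_true(one$pass)

  tet <- data.frame(p_pg = 7.06, ploidy = 4L)
  expect_error(diploidPBand(tet), class = "flowPE_empty_set_error")
})
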