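test_that("group statistics use sample sd and recompute the percentage", {
  one <- summarizeTaxa(data.frame(taxon = "t", two_c_pg = 10, p_pg = 3))
  expect_equal(one$gs_mean, 10)
  expect_true(is.na(one$gs_sd))
  expect_equal(one$p_percent, 30.0)

  two <- summarizeTaxa(data.frame(taxon = "t", two_c_pg = c(19.0, 19.92),
                                  p_pg = c(7, 7.12)))
  expect_equal(two$gs_mean, 19.46)
  expect_equal(two$gs_sd, sd(c(19.0, 19.92)))
  expect_equal(two$p_percent, round(100 * 7.06 / 19.46, 1))

  expect_equal(nrow(summarizeTaxa(data.frame(taxon = character(),
                                             two_c_pg = numeric(),
                                             p_pg = numeric()))), 0L)
})

test_that("row order is deterministic: taxon, ploidy, region", {
  m <- data.frame(taxon = c("b", "a", "a", "b"), ploidy = c(2L, 4L, 2L, 2L),
                  region = c("x", "", "", "y"),
                  two_c_pg = c(1, 2, 3, 4) + 9, p_pg = rep(3, 4))
  s <- summarizeTaxa(m)
  expect_equal(s$taxon, c("a", "a", "b", "b"))
  expect_equal(s$ploidy, c(2L, 4L, 2L, 2L))
  expect_equal(s$region, c("", "", "x", "y"))
})

test_that("the printed endoreplication percentages are exactly reproduced", {
  ref <- neotineaReference()
  expect_equal(round(100 * ref$p_mean / ref$gs_mean, 1), ref$p_pct)
})

test_that("a simulated taxon reproduces its nominal summary statistics", {
  # reference row: 28.14 +/- 0.58, 3.64 +/- 0.15, n = 31
  taxa <- data.frame(taxon = "N. conica", gs_mean = 28.14, gs_sd = 0.58,
                     p_mean = 3.64, p_sd = 0.15, n = 31)
  ind <- drawCohortParams(taxa, seed = 8)
  s <- summarizeTaxa(data.frame(taxon = ind$taxon, two_c_pg = ind$two_c,
                                p_pg = ind$p))
  expect_lt(abs(s$gs_mean - 28.14), 3 * 0.58 / sqrt(31))
  expect_lt(abs(s$p_mean - 3.64), 3 * 0.15 / sqrt(31))
  expect_equal(s$n, 31L)
})

test_that("HSD letters separate clear groups and share letters otherwise", {
  same <- tukeyGroups(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(unname(same[c("a", "b")]), c("a", "a"))

  set.seed(2)
  v <- c(rnorm(10, 0, 1), rnorm(10, 100, 1))
  g <- rep(c("lo", "hi"), each = 10)
  lt <- tukeyGroups(v, g)
  expect_equal(unname(lt[c("lo", "hi")]), c("a", "b"))

  # zero within-group variance with unequal means: all pairs separated
  z <- tukeyGroups(c(1, 1, 2, 2, 3, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(z[c("a", "b", "c")]), c("a", "b", "c"))

  expect_warning(
    out <- tukeyGroups(c(1, 1.1, 2, 2.1, 5), c("a", "a", "b", "b", "c")),
    class = "flowPE_hsd_warning")
  expect_true(is.na(out[["c"]]))
})

test_that("letters are invariant to input order and location shifts", {
  set.seed(14)
  v <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 8))
  g <- rep(c("x", "y", "z"), each = 8)
  base <- tukeyGroups(v, g)
  perm <- sample(length(v))
  expect_equal(tukeyGroups(v[perm], g[perm])[names(base)],
               base[names(base)], ignore_attr = TRUE)
  expect_equal(tukeyGroups(v + 1000, g)[names(base)], base[names(base)],
               ignore_attr = TRUE)
})

test_that("letter sharing matches a brute-force studentized-range oracle", {
  for (seed in c(3, 9, 27)) {
    set.seed(seed)
    k <- sample(3:5, 1)
    n <- sample(4:9, k, replace = TRUE)
    g <- rep(letters[1:k], times = n)
    v <- rnorm(length(g), mean = rep(runif(k, 0, 4), times = n))
    lt <- tukeyGroups(v, g)
    # oracle: Tukey-Kramer adjusted p for every pair, from first principles
    means <- tapply(v, g, mean)
    ns <- tapply(v, g, length)
    mse <- sum((v - ave(v, g))^2) / (length(v) - k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[i] - means[j]) / se
      p <- 1 - ptukey(q, k, length(v) - k)
      share <- any(strsplit(lt[[letters[i]]], "")[[1]] %in%
                   strsplit(lt[[letters[j]]], "")[[1]])
      expect_equal(share, unname(p >= 0.05),
                   label = sprintf("seed %d pair %s-%s share", seed,
                                   letters[i], letters[j]))
    }
  }
})

test_that("compact letters agree with the multcomp reference implementation", {
  set.seed(5)
  v <- c(rnorm(6, 0), rnorm(6, 0.5), rnorm(6, 4), rnorm(6, 4.4))
  g <- factor(rep(c("g1", "g2", "g3", "g4"), each = 6))
  lt <- tukeyGroups(v, as.character(g))
  fit <- multcomp::glht(aov(v ~ g), linfct = multcomp::mcp(g = "Tukey"))
  cld <- multcomp::cld(fit, level = 0.05)$mcletters$Letters
  share <- function(x, a, b) any(strsplit(x[[a]], "")[[1]] %in%
                                 strsplit(x[[b]], "")[[1]])
  for (a in levels(g)) for (b in levels(g))
    if (a < b)
      expect_equal(share(lt, a, b), share(cld, a, b),
                   label = paste("pair", a, b))
})

test_that("simulated diploid lineages separate P as the reference groups do", {
  ref <- neotineaReference()
  dip <- ref[!ref$aggregate & ref$ploidy == 2, ]
  for (seed in 1:3) {
    ind <- drawCohortParams(data.frame(taxon = paste(dip$taxon, dip$region),
                                       gs_mean = dip$gs_mean,
                                       gs_sd = dip$gs_sd,
                                       p_mean = dip$p_mean, p_sd = dip$p_sd,
                                       n = dip$n), seed = seed)
    lt <- suppressWarnings(tukeyGroups(ind$p, ind$taxon))
    macu <- lt[[grep("maculata", names(lt), value = TRUE)]]
    coni <- lt[[grep("conica", names(lt), value = TRUE)]]
    # the smallest and largest diploid endoreplicated parts: printed groups
    # "a" vs "d", i.e. no shared letter
    expect_false(any(strsplit(macu, "")[[1]] %in% strsplit(coni, "")[[1]]))
  }
})
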