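## Taxon-level aggregation and Tukey HSD letter groups.
##
## Produces per-(taxon, ploidy, region) rows with mean +/- sd of 2C and P,
## the endoreplicated percentage recomputed from the stored means, group
## sizes, and compact letter display of Tukey HSD multiple comparisons
## (groups sharing a letter are not significantly different).

#' Aggregate measurements into taxon summary rows
#'
#' Arithmetic means and sample sd (n - 1 denominator) of 2C and P per
#' (taxon, ploidy, region) group; `p_percent` is always recomputed as
#' `100 * p_mean / gs_mean` (1 decimal), never copied. sd is `NA` for
#' singleton groups. Rows are ordered by taxon (alphabetical), ploidy
#' (ascending), region.
#'
#' @param measurements data.frame with columns `taxon`, `two_c_pg`, `p_pg`
#'   and optionally `ploidy`, `region`.
#' @param gsLetters,pLetters optional named letter vectors (names = group
#'   keys `taxon/ploidy/region`) as returned by [tukeyGroups()].
#' @return data.frame with columns `taxon`, `ploidy`, `region`, `gs_mean`,
#'   `gs_sd`, `p_mean`, `p_sd`, `p_percent`, `n`, `gs_group`, `p_group`.
#' @export
summarizeTaxa <- function(measurements, gsLetters = NULL, pLetters = NULL) {
  m <- measurements
  if (!nrow(m))
    return(data.frame(taxon = character(), ploidy = integer(),
                      region = character(), gs_mean = numeric(),
                      gs_sd = numeric(), p_mean = numeric(),
                      p_sd = numeric(), p_percent = numeric(),
                      n = integer(), gs_group = character(),
                      p_group = character(), stringsAsFactors = FALSE))
  if (!all(c("taxon", "two_c_pg", "p_pg") %in% names(m)) || anyNA(m$taxon))
    stopf("measurements need non-missing taxon labels and 2C/P columns",
          class = "flowPE_labeling_error")
  if (is.null(m$ploidy)) m$ploidy <- NA_integer_
  if (is.null(m$region)) m$region <- ""
  m$region[is.na(m$region)] <- ""
  key <- groupKey(m)
  groups <- split(m, key)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(taxon = g$taxon[1], ploidy = g$ploidy[1], region = g$region[1],
               gs_mean = mean(g$two_c_pg),
               gs_sd = if (n > 1) sd(g$two_c_pg) else NA_real_,
               p_mean = mean(g$p_pg),
               p_sd = if (n > 1) sd(g$p_pg) else NA_real_,
               p_percent = roundPct(100 * mean(g$p_pg) / mean(g$two_c_pg)),
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon, out$ploidy, out$region), , drop = FALSE]
  rownames(out) <- NULL
  outKey <- paste(out$taxon, out$ploidy, out$region, sep = "/")
  out$gs_group <- if (is.null(gsLetters)) NA_character_
                  else unname(gsLetters[outKey])
  out$p_group <- if (is.null(pLetters)) NA_character_
                 else unname(pLetters[outKey])
  out
}

#' @describeIn summarizeTaxa the `taxon/ploidy/region` key used to match
#'   letter vectors to summary rows.
#' @export
groupKey <- function(measurements) {
  ploidy <- if (is.null(measurements$ploidy)) NA_integer_
            else measurements$ploidy
  region <- if (is.null(measurements$region)) "" else measurements$region
  region[is.na(region)] <- ""
  paste(measurements$taxon, ploidy, region, sep = "/")
}

## Compact letter display by the greedy insert-and-absorb algorithm.
## `signif` is a logical matrix (TRUE = significantly different); groups are
## ordered by ascending mean before lettering, so letters read in mean order.
.compactLetters <- function(signif, means) {
  g <- names(means)
  ord <- order(means, g)
  g <- g[ord]
  sets <- list(g)
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  labels <- rownames(signif)
  for (r in seq_len(nrow(pairs))) {
    a <- labels[pairs[r, 1]]
    b <- labels[pairs[r, 2]]
    newSets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s)
        newSets <- c(newSets, list(setdiff(s, a), setdiff(s, b)))
      else newSets <- c(newSets, list(s))
    }
    newSets <- newSets[lengths(newSets) > 0]
    ## absorb: drop sets contained in another set
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets))
      for (j in seq_along(newSets))
        if (i != j && keep[j] &&
            all(newSets[[i]] %in% newSets[[j]]) &&
            (length(newSets[[i]]) < length(newSets[[j]]) || i > j))
          keep[i] <- FALSE
    sets <- newSets[keep]
  }
  ## letters in order of the smallest member mean of each set
  setRank <- vapply(sets, function(s) min(match(s, g)), numeric(1))
  sets <- sets[order(setRank)]
  out <- setNames(rep("", length(g)), g)
  for (i in seq_along(sets))
    for (member in sets[[i]])
      out[member] <- paste0(out[member], letters[i])
  out[names(means)]
}

#' Tukey HSD compact letter groups
#'
#' One-way ANOVA followed by Tukey's HSD (Tukey-Kramer for unbalanced
#' groups, via [stats::TukeyHSD()]) at level `alpha`, then compact letter
#' display: groups not significantly different share a letter; letters are
#' assigned in ascending order of group means by a deterministic greedy
#' insert-and-absorb algorithm. Groups with fewer than 2 observations are
#' excluded with a warning (they cannot contribute a variance) and get `NA`.
#' If every group has zero within-group variance, pairs with unequal means
#' are all significant and pairs with equal means are not.
#'
#' @param values numeric observations.
#' @param groups parallel group labels (>= 2 groups with >= 2 observations).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group level
#'   (`NA` for excluded groups), with the HSD p-value matrix in
#'   `attr(, "pvalues")`.
#' @export
tukeyGroups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  n <- table(groups)
  small <- names(n)[n < 2]
  if (length(small))
    warnf("excluding group(s) with < 2 observations from HSD: %s",
          paste(small, collapse = ", "), class = "flowPE_hsd_warning")
  keep <- !groups %in% small
  values <- values[keep]
  groups <- groups[keep]
  lev <- sort(unique(groups))
  if (length(lev) < 2L)
    stopf("need >= 2 groups with >= 2 observations",
          class = "flowPE_parameter_error")
  means <- tapply(values, groups, mean)[lev]
  f <- factor(groups, levels = lev)
  fit <- aov(values ~ f)
  mse <- sum(fit$residuals^2) / fit$df.residual
  k <- length(lev)
  pm <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  if (mse > 0) {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$f
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_len(nrow(tk))) {
      a <- cmp[[r]][1]; b <- cmp[[r]][2]
      pm[a, b] <- pm[b, a] <- tk[r, "p adj"]
    }
  } else {
    ## all groups internally constant: unequal means are exactly separated
    for (a in lev) for (b in lev)
      if (a != b) pm[a, b] <- if (means[a] == means[b]) 1 else 0
  }
  diag(pm) <- 1
  out <- .compactLetters(pm < alpha, means)
  if (length(small)) out <- c(out, setNames(rep(NA_character_, length(small)),
                                            small))
  attr(out, "pvalues") <- pm
  out
}
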