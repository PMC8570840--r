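## The joint (2C, P) marker.
##
## Under partial endoreplication the endoreplicated-part size P scales with
## ploidy: polyploids show P increased by the same fold as their ploidy
## level, while homoploid lineages shift in 2C at essentially constant P.
## That separation is what makes the pair (2C, P) a delineation marker:
## a different integer fold of P signals a DNA-ploidy variant; a 2C shift at
## the same fold signals a cryptic homoploid lineage or a hybrid.

#' Derive the reference diploid P from observed values
#'
#' Every observation is tried as a member of every plausible ploidy level
#' (base ploidy up to 8C-equivalents), each giving a candidate diploid
#' reference `basePloidy * p / ploidy`; the candidate minimizing the total
#' relative distance of all observations to their nearest integer fold wins.
#' Halving a reference never improves that score (each observation keeps
#' the same residual at twice the fold), so ties are broken toward the
#' largest reference; a final median pass over the implied diploid values
#' polishes the winner. No assumption that diploids form the majority.
#'
#' @param p observed P values (pg).
#' @param basePloidy ploidy of the reference level (default 2).
#' @return reference diploid P in pg.
#' @export
deriveDiploidRef <- function(p, basePloidy = 2) {
  stopifnot(length(p) >= 1, all(p > 0))
  folds <- basePloidy:(4 * basePloidy)
  cand <- sort(unique(as.vector(outer(p, folds / basePloidy, `/`))),
               decreasing = TRUE)
  ## the reference level must actually be present: the smallest observed P
  ## has to sit at the base fold (otherwise a finer grid of fractional
  ## folds can out-score the true one on dispersed data)
  cand <- cand[round(basePloidy * min(p) / cand) == basePloidy]
  score <- function(r) {
    pred <- outer(r * folds / basePloidy, rep(1, length(p)))
    sum(apply(abs(t(pred) - p) / t(pred), 1, min))
  }
  sc <- vapply(cand, score, numeric(1))
  ref <- cand[which.min(sc)]  # which.min takes the first (= largest) on ties
  fold <- pmax(round(basePloidy * p / ref), 1)
  median(basePloidy * p / fold)
}

#' Infer DNA-ploidy from the fold change of P
#'
#' `ploidy = round(basePloidy * p / pDiploidRef)` (at least 1). The residual
#' is the relative deviation of `p` from the nearest integer-fold value
#' `(ploidy / basePloidy) * pDiploidRef`; a residual above `pTol` sets the
#' `ambiguous-ploidy` flag. Monotone non-decreasing in `p` and invariant to
#' joint rescaling of `p` and the reference.
#'
#' @param p observed P in pg (> 0); vectorized.
#' @param rule a [DelineationRule-class]; its `pDiploidRef` must be set
#'   (use [deriveDiploidRef()] first when it is `NA`).
#' @return data.frame with columns `ploidy`, `residual`, `ambiguous`.
#' @examples
#' rule <- DelineationRule(pDiploidRef = 3.55)
#' inferPloidy(c(3.55, 5.27, 7.06), rule)$ploidy # 2 3 4
#' @export
inferPloidy <- function(p, rule) {
  stopifnot(is(rule, "DelineationRule"), all(p > 0))
  ref <- rule@pDiploidRef
  if (is.na(ref))
    stopf("rule has no diploid reference P; derive one with deriveDiploidRef()",
          class = "flowPE_parameter_error")
  ploidy <- pmax(round(rule@basePloidy * p / ref), 1)
  nearest <- ploidy / rule@basePloidy * ref
  residual <- abs(p - nearest) / nearest
  data.frame(ploidy = as.integer(ploidy), residual = residual,
             ambiguous = residual > rule@pTol)
}

## Leave-one-out group means: mean of the other members of x's group.
.looMean <- function(x, group) {
  s <- stats::ave(x, group, FUN = sum)
  n <- stats::ave(x, group, FUN = length)
  ifelse(n > 1, (s - x) / (n - 1), NA_real_)
}

#' Classify individuals jointly on (2C, P)
#'
#' Labels each measurement relative to its taxon:
#' \describe{
#'   \item{`consistent`}{P at the taxon's integer fold and 2C within
#'     `gsHybridDev` of the leave-one-out taxon mean.}
#'   \item{`ploidy-variant`}{P at a different integer fold than the taxon's
#'     (a DNA-ploidy shift).}
#'   \item{`homoploid-divergent`}{P at the taxon fold but 2C deviating by
#'     more than `gsHybridDev` from the leave-one-out taxon mean — the
#'     cryptic-lineage / hybrid signal. Such individuals additionally get a
#'     `hybrid-suspect` flag when their 2C lies between their own taxon mean
#'     and another taxon's mean (intermediacy).}
#' }
#' Deviations are computed against the leave-one-out taxon mean so an
#' outlier cannot mask itself; the reported `hybrid_dev_pct` uses the
#' individual's own 2C as denominator (how far the taxon mean sits above or
#' below the individual), and both are returned.
#'
#' @param measurements data.frame with columns `taxon`, `two_c_pg`, `p_pg`
#'   (e.g. rbind-ed [measureSample()] rows); every taxon needs >= 2 rows.
#' @param rule a [DelineationRule-class]; an `NA` `pDiploidRef` is derived
#'   from the data with [deriveDiploidRef()].
#' @return the measurements with added columns `ploidy`, `ploidy_residual`,
#'   `class`, `deviation_pct` (vs leave-one-out mean), `hybrid_dev_pct`
#'   (individual-denominator), `flags` (augmented).
#' @export
jointClassify <- function(measurements, rule = DelineationRule()) {
  m <- measurements
  need <- c("taxon", "two_c_pg", "p_pg")
  if (!all(need %in% names(m)))
    stopf("measurements need columns: %s", paste(need, collapse = ", "),
          class = "flowPE_labeling_error")
  if (anyNA(m$taxon))
    stopf("every measurement needs a taxon label",
          class = "flowPE_labeling_error")
  counts <- table(m$taxon)
  if (any(counts < 2))
    stopf("taxa with < 2 measurements cannot provide deviation statistics: %s",
          paste(names(counts)[counts < 2], collapse = ", "),
          class = "flowPE_labeling_error")
  if (is.na(rule@pDiploidRef))
    rule@pDiploidRef <- deriveDiploidRef(m$p_pg, rule@basePloidy)
  pl <- inferPloidy(m$p_pg, rule)
  m$ploidy <- pl$ploidy
  m$ploidy_residual <- pl$residual

  looGS <- .looMean(m$two_c_pg, m$taxon)
  looP <- .looMean(m$p_pg, m$taxon)
  taxonFold <- inferPloidy(looP, rule)$ploidy
  m$deviation_pct <- 100 * abs(m$two_c_pg - looGS) / looGS
  m$hybrid_dev_pct <- 100 * abs(looGS - m$two_c_pg) / m$two_c_pg

  taxonMeans <- tapply(m$two_c_pg, m$taxon, mean)
  m$class <- "consistent"
  m$class[m$ploidy != taxonFold] <- "ploidy-variant"
  homo <- m$ploidy == taxonFold &
    m$deviation_pct > 100 * rule@gsHybridDev
  m$class[homo] <- "homoploid-divergent"

  if (!"flags" %in% names(m)) m$flags <- ""
  addFlag <- function(flags, sel, flag)
    ifelse(sel, ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag),
           flags)
  m$flags <- addFlag(m$flags, pl$ambiguous, "ambiguous-ploidy")
  ## intermediacy: 2C between own leave-one-out mean and some other taxon mean
  suspect <- vapply(seq_len(nrow(m)), function(i) {
    if (m$class[i] != "homoploid-divergent") return(FALSE)
    others <- taxonMeans[names(taxonMeans) != m$taxon[i]]
    any((m$two_c_pg[i] - looGS[i]) * (m$two_c_pg[i] - others) < 0)
  }, logical(1))
  m$flags <- addFlag(m$flags, suspect, "hybrid-suspect")
  m
}

#' Range of P across inferred diploids
#'
#' All diploid taxa are expected to keep P under a common bound (default
#' 4 pg) regardless of their overall genome size; polyploids break it by the
#' fold of their ploidy.
#'
#' @param measurements data.frame with columns `p_pg` and `ploidy`.
#' @param bound upper bound in pg (default 4).
#' @return list with `min`, `max` (pg, over diploids) and `pass`
#'   (`max < bound`).
#' @export
diploidPBand <- function(measurements, bound = 4) {
  d <- measurements[!is.na(measurements$ploidy) & measurements$ploidy == 2L, ,
                    drop = FALSE]
  if (!nrow(d))
    stopf("no diploid measurements", class = "flowPE_empty_set_error")
  list(min = min(d$p_pg), max = max(d$p_pg), bound = bound,
       pass = max(d$p_pg) < bound)
}
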