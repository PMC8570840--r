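## Reference cytometric values for the orchid genus Neotinea.

#' Reference taxon-level cytometric values for *Neotinea*
#'
#' Taxon/lineage means and standard deviations of genome size (2C, pg) and
#' of the endoreplicated-part size (P, pg) from a flow-cytometric survey of
#' the genus *Neotinea* (349 individuals, 91 populations), together with the
#' endoreplicated percentage, group sizes and the Tukey HSD letter groups
#' reported for diploid lineages. Two rows (`aggregate = TRUE`) pool the
#' regional/variant rows beneath them and are redundant with their children.
#'
#' These values serve two purposes here: they parameterize the synthetic
#' cohort generator (each row gives a taxon's mean/sd for 2C and P), and
#' they provide fixed inputs for validating the summary arithmetic (e.g.
#' `p_pct` must equal `100 * p_mean / gs_mean` at 1 decimal). The `standard`
#' column records the internal standard used for that taxon: *Solanum
#' pseudocapsicum* for *N. maculata*, whose genome size nearly coincides
#' with *Pisum sativum*, and *Pisum* otherwise.
#'
#' @return data.frame with columns `taxon`, `ploidy`, `region`, `gs_mean`,
#'   `gs_sd`, `p_mean`, `p_sd`, `p_pct`, `n`, `gs_group`, `p_group`,
#'   `aggregate`, `standard`.
#' @examples
#' ref <- neotineaReference()
#' stopifnot(all(round(100 * ref$p_mean / ref$gs_mean, 1) == ref$p_pct))
#' @export
neotineaReference <- function() {
  df <- read.delim(text = paste(sep = "\n",
"taxon\tploidy\tregion\tgs_mean\tgs_sd\tp_mean\tp_sd\tp_pct\tn\tgs_group\tp_group\taggregate\tstandard",
"N. commutata\t4\t\t19.46\t0.39\t7.06\t0.09\t36.3\t7\t\t\tFALSE\tPisum sativum 'Ctirad'",
"N. conica\t2\t\t28.14\t0.58\t3.64\t0.15\t12.9\t31\te\td\tFALSE\tPisum sativum 'Ctirad'",
"N. lactea\t2\t\t28.65\t1.43\t3.59\t0.17\t12.5\t60\tf\tcd\tFALSE\tPisum sativum 'Ctirad'",
"N. maculata\t2\t\t7.12\t0.22\t2.89\t0.05\t40.6\t29\ta\ta\tFALSE\tSolanum pseudocapsicum",
"N. tridentata\t2\t\t11.24\t1.82\t3.55\t0.17\t31.6\t132\t\t\tTRUE\tPisum sativum 'Ctirad'",
"N. tridentata\t2\tCrete\t13.92\t0.52\t3.69\t0.20\t26.5\t9\tc\td\tFALSE\tPisum sativum 'Ctirad'",
"N. tridentata\t2\tE Mediterranean\t15.70\t0.54\t3.55\t0.10\t22.6\t13\td\tcd\tFALSE\tPisum sativum 'Ctirad'",
"N. tridentata\t2\tIsrael\t9.46\t0.30\t3.27\t0.19\t34.6\t4\tb\tb\tFALSE\tPisum sativum 'Ctirad'",
"N. tridentata\t2\trest of Europe\t10.49\t0.38\t3.55\t0.16\t33.8\t106\tb\tcd\tFALSE\tPisum sativum 'Ctirad'",
"N. tridentata\t3\t\t16.16\t1.14\t5.27\t0.17\t32.6\t2\t\t\tFALSE\tPisum sativum 'Ctirad'",
"N. ustulata\t2\t\t10.48\t0.36\t3.52\t0.09\t33.6\t88\t\t\tTRUE\tPisum sativum 'Ctirad'",
"N. ustulata\t2\tvar. ustulata\t10.46\t0.39\t3.53\t0.09\t33.7\t60\tb\tc\tFALSE\tPisum sativum 'Ctirad'",
"N. ustulata\t2\tvar. aestivalis\t10.52\t0.29\t3.51\t0.09\t33.4\t28\tb\tc\tFALSE\tPisum sativum 'Ctirad'"),
    stringsAsFactors = FALSE)
  df$region[is.na(df$region)] <- ""
  df$gs_group[is.na(df$gs_group)] <- NA_character_
  df
}

#' The default internal standards
#'
#' *Pisum sativum* 'Ctirad' (primary, 2C = 8.76 pg) and *Solanum
#' pseudocapsicum* (secondary, 2C = 2.57 pg, calibrated by repeated
#' measurement against the primary).
#'
#' @return named list of [FcmStandard-class] objects.
#' @export
defaultStandards <- function() {
  pisum <- FcmStandard("Pisum sativum 'Ctirad'", 8.76, role = "primary")
  solanum <- FcmStandard("Solanum pseudocapsicum", 2.57, role = "secondary",
                         provenance = paste("estimated by repeated measurement",
                                            "against Pisum sativum 'Ctirad'"))
  setNames(list(pisum, solanum), c(pisum@name, solanum@name))
}
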