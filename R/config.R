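## Pipeline configuration: a validated nested list, loadable from YAML.

.configDefaults <- function() {
  list(
    standards = list(
      list(name = "Pisum sativum 'Ctirad'", two_c_pg = 8.76,
           role = "primary", provenance = ""),
      list(name = "Solanum pseudocapsicum", two_c_pg = 2.57,
           role = "secondary",
           provenance = "estimated by repeated measurement against Pisum sativum 'Ctirad'")),
    binning = list(n_channels = 1024L, gain = 1),
    gate = list(fl = NULL, ssc = NULL),
    detection = list(smooth_window = 9L, min_peak_events = 100L,
                     cv_max = 0.10),
    pe = list(p_mode = "regression", progression_tol = 0.02),
    delineation = list(p_tol = 0.10, gs_hybrid_dev = 0.15,
                       diploid_p_bound = 4, base_ploidy = 2L,
                       p_diploid_ref = NULL),
    summary = list(alpha = 0.05, hsd_unit = "individuals"),
    simulate = list(k_max = 3L, cv = 0.03, standard_fraction = 0.3,
                    debris_fraction = 0.05, n_events = 5000L,
                    gain_pg_per_channel = 0.05, peak_decay = 0.5),
    seed = 1L)
}

#' Default pipeline configuration
#'
#' @return nested named list; see [readConfig()] for the schema.
#' @export
defaultConfig <- function() .configDefaults()

#' Read and validate a pipeline configuration
#'
#' YAML with top-level keys `standards`, `binning`, `gate`, `detection`,
#' `pe`, `delineation`, `summary`, `simulate`, `seed`. Omitted keys take
#' their defaults; unknown keys (at top level or inside a section) are
#' rejected so typos cannot silently fall back to defaults. Every threshold
#' is range-checked at load.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return validated config list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stopf("no such config file: %s", path, class = "flowPE_io_error")
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stopf("unknown config key(s): %s", paste(bad, collapse = ", "),
            class = "flowPE_config_error")
    for (sec in names(user)) {
      if (sec %in% c("standards", "seed")) { cfg[[sec]] <- user[[sec]]; next }
      badSub <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badSub))
        stopf("unknown config key(s) under '%s': %s", sec,
              paste(badSub, collapse = ", "), class = "flowPE_config_error")
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    }
  }
  validateConfig(cfg)
}

#' @rdname readConfig
#' @param config a config list to validate.
#' @export
validateConfig <- function(config) {
  chk <- function(ok, fmt, ...)
    if (!ok) stopf(fmt, ..., class = "flowPE_config_error")
  chk(length(config$standards) >= 1, "at least one standard is required")
  for (s in config$standards) {
    chk(!is.null(s$name) && !is.null(s$two_c_pg) && s$two_c_pg > 0,
        "every standard needs a name and a positive two_c_pg")
    if (identical(s$role, "secondary"))
      chk(!is.null(s$provenance) && nzchar(s$provenance),
          "secondary standard '%s' needs a provenance note", s$name)
  }
  chk(config$binning$n_channels >= 64, "binning$n_channels must be >= 64")
  chk(config$binning$gain > 0, "binning$gain must be > 0")
  chk(config$detection$smooth_window >= 3 &&
        config$detection$smooth_window %% 2 == 1,
      "detection$smooth_window must be odd and >= 3")
  chk(config$detection$min_peak_events >= 1,
      "detection$min_peak_events must be >= 1")
  chk(config$detection$cv_max > 0, "detection$cv_max must be > 0")
  chk(config$pe$p_mode %in% c("regression", "first_two"),
      "pe$p_mode must be 'regression' or 'first_two'")
  chk(config$pe$progression_tol > 0 && config$pe$progression_tol < 0.2,
      "pe$progression_tol must be in (0, 0.2)")
  chk(config$delineation$p_tol > 0 && config$delineation$p_tol < 0.5,
      "delineation$p_tol must be in (0, 0.5)")
  chk(config$delineation$gs_hybrid_dev > 0 &&
        config$delineation$gs_hybrid_dev < 1,
      "delineation$gs_hybrid_dev must be in (0, 1)")
  chk(config$delineation$diploid_p_bound > 0,
      "delineation$diploid_p_bound must be > 0")
  chk(config$summary$alpha > 0 && config$summary$alpha < 1,
      "summary$alpha must be in (0, 1)")
  chk(config$summary$hsd_unit %in% c("individuals", "populations"),
      "summary$hsd_unit must be 'individuals' or 'populations'")
  chk(config$simulate$cv > 0, "simulate$cv must be > 0")
  chk(config$simulate$n_events >= 1, "simulate$n_events must be >= 1")
  chk(config$simulate$gain_pg_per_channel > 0,
      "simulate$gain_pg_per_channel must be > 0")
  invisible(config)
}

#' Standards defined by a config
#'
#' @param config a config list.
#' @return named list of [FcmStandard-class] objects.
#' @export
configStandards <- function(config) {
  out <- lapply(config$standards, function(s)
    FcmStandard(s$name, s$two_c_pg,
                role = if (is.null(s$role)) "primary" else s$role,
                provenance = if (is.null(s$provenance)) "" else s$provenance))
  setNames(out, vapply(out, function(s) s@name, character(1)))
}

#' Delineation rule defined by a config
#'
#' @param config a config list.
#' @return a [DelineationRule-class].
#' @export
configRule <- function(config) {
  d <- config$delineation
  DelineationRule(
    pDiploidRef = if (is.null(d$p_diploid_ref)) NA_real_ else d$p_diploid_ref,
    basePloidy = d$base_ploidy, pTol = d$p_tol,
    gsHybridDev = d$gs_hybrid_dev, diploidPBound = d$diploid_p_bound)
}

## Short deterministic content hash for provenance headers (djb2 over the
## deparsed config).
configHash <- function(config) {
  s <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 5381
  for (x in s) h <- (h * 33 + x) %% 2^28
  sprintf("%07x", h)
}

provenanceFields <- function(config, seed) {
  c(tool = paste0("flowPE ", as.character(utils::packageVersion("flowPE"))),
    config_hash = configHash(config), seed = as.character(seed))
}
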