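## Pipeline stages tying the modules together: simulate -> analyze ->
## summarize. Each stage is an ordinary function (the CLI wrapper in
## inst/scripts/flowpe-cli.R is a thin shell over these), writes its data to
## files with a provenance header, logs to stderr via message(), and is
## deterministic for a fixed config + seed.

.writeTsv <- function(df, path, provenance = character()) {
  lines <- c(sprintf("# %s: %s", names(provenance), provenance),
             paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col)) ifelse(is.na(col), "NA",
                                           sprintf("%.6g", col))
               else ifelse(is.na(col), "NA", as.character(col))
             }), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a tab-delimited measurement (or manifest) table
#'
#' @param path TSV written by a pipeline stage ('#' comment lines allowed).
#' @return data.frame.
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "flowPE_io_error")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Simulate a cohort to event files plus a truth manifest
#'
#' Reads a cohort table (YAML list under key `taxa`, rows with `taxon`,
#' `gs_mean`, `gs_sd`, `p_mean`, `p_sd`, `n` and optional `ploidy`,
#' `region`, `standard`; or an equivalent data.frame), simulates every
#' individual with [simulateCohort()] under the config's simulation
#' parameters, and writes one event file per individual plus a tab-delimited
#' truth manifest `manifest.tsv` recording the drawn nominal values.
#'
#' @param config config list from [readConfig()].
#' @param cohort YAML path or data.frame.
#' @param outDir output directory (created if needed).
#' @param seed integer; defaults to `config$seed`.
#' @param format `"csv"` or `"fcs"` event files.
#' @return the manifest data.frame, invisibly.
#' @export
cmdSimulate <- function(config, cohort, outDir, seed = config$seed,
                        format = c("csv", "fcs")) {
  format <- match.arg(format)
  taxa <- if (is.character(cohort)) {
    y <- yaml::read_yaml(cohort)
    rows <- if (!is.null(y$taxa)) y$taxa else y
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else cohort
  if (is.null(taxa) || !nrow(taxa))
    stopf("cohort is empty", class = "flowPE_parameter_error")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  standards <- configStandards(config)
  sim <- config$simulate
  base <- simParams(twoC = 10, p = 3, standard = standards[[1]],
                    kMax = sim$k_max,
                    peakWeights = sim$peak_decay^(0:sim$k_max),
                    cv = sim$cv, standardFraction = sim$standard_fraction,
                    debrisFraction = sim$debris_fraction,
                    nEvents = sim$n_events, gain = sim$gain_pg_per_channel,
                    seed = seed)
  samples <- simulateCohort(taxa, base = base, seed = seed,
                            standards = standards)
  ind <- attr(samples, "individuals")
  files <- character(nrow(ind))
  for (i in seq_along(samples)) {
    files[i] <- file.path(outDir, paste0(ind$sample_id[i], ".", format))
    writeEvents(samples[[i]], files[i], format = format)
  }
  manifest <- ind
  manifest$file <- basename(files)
  if (is.null(manifest$standard)) manifest$standard <- standards[[1]]@name
  .writeTsv(manifest, file.path(outDir, "manifest.tsv"),
            provenanceFields(config, seed))
  message(sprintf("simulated %d individuals from %d taxa into %s",
                  nrow(manifest), length(unique(manifest$taxon)), outDir))
  invisible(manifest)
}

## Analyze one FcmSample under a config; standard resolved from metadata.
.analyzeOne <- function(events, config, standards) {
  stdName <- sampleMeta(events)$standard
  std <- if (!is.null(stdName) && stdName %in% names(standards))
    standards[[stdName]] else standards[[1]]
  if (!is.null(config$gate$fl) || !is.null(config$gate$ssc))
    events <- gateEvents(events, flRange = config$gate$fl,
                         sscRange = config$gate$ssc)
  measureSample(events, std,
                nChannels = config$binning$n_channels,
                gain = config$binning$gain,
                minPeakEvents = config$detection$min_peak_events,
                smoothWindow = config$detection$smooth_window,
                cvMax = config$detection$cv_max,
                pMode = config$pe$p_mode,
                progressionTol = config$pe$progression_tol)
}

#' Analyze event files into peak tables and a measurement table
#'
#' For each file: read events, gate (if configured), bin, detect and fit
#' peaks, assign roles against the standard named in the file metadata or
#' manifest (first configured standard otherwise), estimate 2C / P / P%,
#' and write a per-sample peak table. A per-file failure (overlap with the
#' standard, too few peaks, ...) is logged and recorded in the returned
#' `failures` table; it does not abort the run.
#'
#' @param config config list from [readConfig()].
#' @param files event files (CSV or FCS).
#' @param outDir output directory for peak tables and `measurements.tsv`.
#' @param manifest optional manifest data.frame (or path) supplying
#'   `sample_id`, `taxon`, `ploidy`, `region`, `standard` per file.
#' @return list with `measurements` (data.frame) and `failures`
#'   (data.frame: file, error class, message), invisibly.
#' @export
cmdAnalyze <- function(config, files, outDir, manifest = NULL) {
  if (!length(files))
    stopf("no input files", class = "flowPE_parameter_error")
  missing <- files[!file.exists(files)]
  if (length(missing))
    stopf("missing input file(s): %s", paste(missing, collapse = ", "),
          class = "flowPE_io_error")
  if (is.character(manifest)) manifest <- readMeasurements(manifest)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  standards <- configStandards(config)
  prov <- provenanceFields(config, config$seed)
  results <- list()
  failures <- list()
  for (f in files) {
    events <- readEvents(f)
    if (!is.null(manifest)) {
      row <- manifest[manifest$file == basename(f) |
                        manifest$sample_id == sampleID(events), , drop = FALSE]
      if (nrow(row) == 1L) {
        for (col in c("sample_id", "taxon", "ploidy", "region", "standard"))
          if (col %in% names(row))
            events@metadata[[col]] <- row[[col]]
      }
    }
    res <- tryCatch(.analyzeOne(events, config, standards),
                    flowPE_error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("analysis failed for %s: %s", basename(f),
                      conditionMessage(res)))
      failures[[length(failures) + 1L]] <- data.frame(
        file = basename(f), class = class(res)[1],
        message = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    meas <- res$measurement
    for (col in c("taxon", "region"))
      if (!is.null(events@metadata[[col]]) && (is.null(meas[[col]]) ||
                                               is.na(meas[[col]])))
        meas[[col]] <- events@metadata[[col]]
    ## nominal ploidy from the manifest is kept apart from the inferred one
    meas$ploidy_nominal <- if (!is.null(events@metadata$ploidy))
      as.integer(events@metadata$ploidy) else NA_integer_
    writePeakTable(res$peaks, meas,
                   file.path(outDir, paste0(meas$sample_id, ".peaks.tsv")),
                   provenance = prov)
    results[[length(results) + 1L]] <- meas
  }
  measurements <- if (length(results)) do.call(rbind, results)
                  else data.frame()
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(file = character(), class = character(),
                              message = character())
  if (nrow(measurements))
    .writeTsv(measurements, file.path(outDir, "measurements.tsv"), prov)
  message(sprintf("analyzed %d/%d files (%d failed)",
                  nrow(measurements), length(files), nrow(failures)))
  invisible(list(measurements = measurements, failures = failures))
}

#' Summarize measurements into a taxon table and a delineation report
#'
#' Runs the joint (2C, P) classification ([jointClassify()]) and the
#' taxon aggregation ([summarizeTaxa()]) with Tukey HSD letter groups
#' computed over diploid groups with >= 2 individuals (polyploid rows are
#' summarized but not lettered, since ploidy itself already separates them).
#' Taxa with a single measurement are excluded from classification with a
#' warning but still summarized.
#'
#' @param config config list from [readConfig()].
#' @param measurements data.frame or path to a `measurements.tsv`.
#' @param outDir output directory for `taxon_summary.tsv` and
#'   `delineation.tsv`.
#' @return list with `summary` and `classified` data.frames, invisibly.
#' @export
cmdSummarize <- function(config, measurements, outDir) {
  if (is.character(measurements))
    measurements <- readMeasurements(measurements)
  if (!nrow(measurements))
    stopf("no measurements to summarize", class = "flowPE_parameter_error")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rule <- configRule(config)
  counts <- table(measurements$taxon)
  single <- names(counts)[counts < 2]
  classifiable <- !measurements$taxon %in% single
  if (length(single))
    warnf("taxa with a single measurement are not classified: %s",
          paste(single, collapse = ", "), class = "flowPE_labeling_warning")
  classified <- measurements
  if (any(classifiable)) {
    cls <- jointClassify(measurements[classifiable, , drop = FALSE], rule)
    for (col in setdiff(names(cls), names(classified)))
      classified[[col]] <- NA
    classified[classifiable, names(cls)] <- cls
  }
  ## HSD letters on diploids, per group with n >= 2
  gsLetters <- pLetters <- NULL
  dip <- classified[!is.na(classified$ploidy) & classified$ploidy == 2, ,
                    drop = FALSE]
  keys <- groupKey(dip)
  if (length(unique(keys[duplicated(keys)])) >= 2) {
    gsLetters <- suppressWarnings(
      tukeyGroups(dip$two_c_pg, keys, alpha = config$summary$alpha))
    pLetters <- suppressWarnings(
      tukeyGroups(dip$p_pg, keys, alpha = config$summary$alpha))
  }
  summary <- summarizeTaxa(classified, gsLetters = gsLetters,
                           pLetters = pLetters)
  prov <- provenanceFields(config, config$seed)
  .writeTsv(summary, file.path(outDir, "taxon_summary.tsv"), prov)
  .writeTsv(classified, file.path(outDir, "delineation.tsv"), prov)
  message(sprintf("summarized %d measurements into %d taxon rows",
                  nrow(classified), nrow(summary)))
  invisible(list(summary = summary, classified = classified))
}
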