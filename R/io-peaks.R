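## Tab-delimited peak-description tables.
##
## Every detected peak is described in tab-delimited form, one row per peak,
## followed by summary rows carrying the derived per-sample quantities
## (2C, P, P%). Dialect: UTF-8, '.' decimal separator, one header line,
## '#'-prefixed provenance comments above it; numbers at 6 significant
## digits so the file round-trips losslessly at that precision.

.peakTableHeader <- c("sample", "type", "role", "k", "position_channels",
                      "position_pg", "cv", "area_fraction", "value")

.fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

#' Write a tab-delimited peak table
#'
#' @param peaks a [PeakSet-class] (or its `peakData()` data.frame); at least
#'   one peak.
#' @param measurement optional one-row data.frame as returned by
#'   [measureSample()]; written as trailing summary rows (`2C_pg`, `P_pg`,
#'   `P_pct`, `intercept_pg`, `k_used`).
#' @param path destination file.
#' @param provenance named character vector written as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @seealso [readPeakTable()]
#' @export
writePeakTable <- function(peaks, measurement = NULL, path,
                           provenance = character()) {
  p <- if (is(peaks, "PeakSet")) peakData(peaks) else peaks
  if (nrow(p) < 1L)
    stopf("peak table needs at least one peak", class = "flowPE_parameter_error")
  id <- if (is(peaks, "PeakSet")) sampleID(peaks) else NA_character_
  if ((is.na(id) || !nzchar(id)) && !is.null(measurement$sample_id))
    id <- measurement$sample_id
  areaFrac <- p$area / sum(p$area)
  rows <- sprintf("%s\tpeak\t%s\t%s\t%s\t%s\t%s\t%s\tNA",
                  id, p$role, ifelse(is.na(p$k), "NA", p$k),
                  .fmt6(p$position), .fmt6(p$position_pg), .fmt6(p$cv),
                  .fmt6(areaFrac))
  if (!is.null(measurement)) {
    m <- as.list(measurement)
    summ <- c("2C_pg" = m$two_c_pg, "P_pg" = m$p_pg, "P_pct" = m$p_percent,
              "intercept_pg" = m$intercept_pg, "k_used" = m$k_used)
    summ <- summ[!vapply(summ, is.null, logical(1))]
    rows <- c(rows, sprintf("%s\tsummary\t%s\tNA\tNA\tNA\tNA\tNA\t%s",
                            id, names(summ), .fmt6(unlist(summ))))
  }
  lines <- c(if (length(provenance))
               sprintf("# %s: %s", names(provenance), provenance),
             paste(.peakTableHeader, collapse = "\t"), rows)
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write '%s'", path, class = "flowPE_io_error")
  invisible(path)
}

#' Read a tab-delimited peak table back
#'
#' @param path file written by [writePeakTable()].
#' @return list with elements `peaks` (data.frame of peak rows), `summary`
#'   (named numeric vector from the summary rows) and `provenance`
#'   (named character vector from the comment lines).
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "flowPE_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  prov <- grep("^#", lines, value = TRUE)
  provenance <- if (length(prov)) {
    kv <- regmatches(prov, regexec("^# ([^:]+): (.*)$", prov))
    setNames(vapply(kv, `[`, character(1), 3),
             vapply(kv, `[`, character(1), 2))
  } else character()
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- .peakTableHeader
  peaks <- df[df$type == "peak", ]
  peaks$k <- suppressWarnings(as.integer(peaks$k))
  for (col in c("position_channels", "position_pg", "cv", "area_fraction"))
    peaks[[col]] <- suppressWarnings(as.numeric(peaks[[col]]))
  rownames(peaks) <- NULL
  summ <- df[df$type == "summary", ]
  list(peaks = peaks[, c("sample", "role", "k", "position_channels",
                         "position_pg", "cv", "area_fraction")],
       summary = setNames(suppressWarnings(as.numeric(summ$value)),
                          summ$role),
       provenance = provenance)
}
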