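## Event file I/O (CSV + minimal FCS) and histogram binning.
##
## CSV dialect: UTF-8, '.' decimal separator, one header line with columns
## `fl[, ssc]`. The FCS subset is defined in io-fcs.R.

#' Read event-level data from disk
#'
#' Reads one tube's events from a CSV file (columns `fl` and optionally
#' `ssc`) or from a minimal list-mode linear FCS 3.0/3.1 file. Event order is
#' preserved; metadata is populated from FCS keywords where available.
#'
#' @param path file to read.
#' @param format `"auto"` (sniff FCS magic, else CSV), `"csv"` or `"fcs"`.
#' @return an [FcmSample-class].
#' @seealso [writeEvents()], [readFCS()]
#' @export
readEvents <- function(path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "flowPE_io_error")
  if (format == "auto") {
    magic <- tryCatch(readBin(path, "raw", n = 6L), error = function(e) raw(0))
    format <- if (length(magic) == 6L &&
                  identical(rawToChar(magic[1:5]), "FCS3.")) "fcs" else "csv"
  }
  if (format == "fcs") return(readFCS(path))
  df <- tryCatch(read.csv(path, header = TRUE),
                 error = function(e)
                   stopf("cannot parse '%s' as event CSV: %s", path,
                         conditionMessage(e), class = "flowPE_format_error"))
  flcol <- if ("fl" %in% names(df)) "fl" else names(df)[1]
  if (nrow(df) == 0L)
    stopf("'%s' contains zero events", path, class = "flowPE_empty_input_error")
  if (is.null(flcol) || !is.numeric(df[[flcol]]))
    stopf("'%s' has no numeric fluorescence column", path,
          class = "flowPE_format_error")
  ssc <- if ("ssc" %in% names(df)) df$ssc else numeric(0)
  FcmSample(df[[flcol]], sideScatter = ssc,
            metadata = list(sample_id = sub("\\.[^.]*$", "", basename(path)),
                            source = path))
}

#' Write event-level data to disk
#'
#' @param events an [FcmSample-class].
#' @param path destination file.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(is(events, "FcmSample"))
  if (format == "fcs") return(writeFCS(events, path))
  ## %.17g so the CSV round trip is bit-exact for doubles
  fl <- sprintf("%.17g", fluorescence(events))
  lines <- if (length(sideScatter(events)))
    c("fl,ssc", paste(fl, sprintf("%.17g", sideScatter(events)), sep = ","))
  else c("fl", fl)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write '%s'", path, class = "flowPE_io_error")
  invisible(path)
}

#' Bin events into a 1D histogram
#'
#' Standard cytometric binning on a linear axis: an event with intensity `x`
#' falls into channel `floor(x / gain)` (0-based). Events at or beyond the
#' axis end accumulate in the top channel and are counted in the overflow
#' tally, so the total count is always conserved.
#'
#' @param events an [FcmSample-class].
#' @param nChannels number of channels (>= 64; default 1024).
#' @param gain intensity units per channel (> 0).
#' @return an [FcmHistogram-class].
#' @examples
#' h <- binEvents(FcmSample(c(0.4, 1.6)), nChannels = 64, gain = 1)
#' channelCounts(h)[1:2]
#' @export
binEvents <- function(events, nChannels = 1024, gain = 1) {
  stopifnot(is(events, "FcmSample"))
  if (length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stopf("gain must be a single positive number",
          class = "flowPE_parameter_error")
  if (nChannels < 64)
    stopf("nChannels must be >= 64", class = "flowPE_parameter_error")
  idx <- floor(fluorescence(events) / gain)
  over <- sum(idx >= nChannels)
  idx[idx >= nChannels] <- nChannels - 1L
  counts <- tabulate(idx + 1L, nbins = nChannels)
  new("FcmHistogram", counts = as.numeric(counts), gain = as.numeric(gain),
      overflow = as.numeric(over), metadata = sampleMeta(events))
}
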