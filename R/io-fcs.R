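## Minimal FCS 3.0 reader/writer.
##
## Deliberately restricted to the open subset the pipeline needs: a single
## dataset, list mode ($MODE L), linear parameters ($PnE 0,0) stored as
## 32-bit floats, 64-bit doubles, or 16/32-bit unsigned integers, with plain
## 1,2,3,4 or 4,3,2,1 byte order. Anything else is rejected loudly: log-scale
## parameters, multi-dataset files and exotic keywords are out of scope.

.fcsHeaderOffsets <- function(raw) {
  field <- function(from, to) {
    s <- trimws(rawToChar(raw[from:to]))
    if (!nzchar(s)) 0L else as.integer(s)
  }
  list(textBeg = field(11, 18), textEnd = field(19, 26),
       dataBeg = field(27, 34), dataEnd = field(35, 42))
}

.fcsParseText <- function(raw, beg, end) {
  delim <- rawToChar(raw[beg + 1L])
  body <- rawToChar(raw[(beg + 2L):(end + 1L)])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  setNames(as.list(vals), keys)
}

#' Read a minimal list-mode FCS file
#'
#' Supports the restricted FCS subset written by [writeFCS()] plus any
#' conforming single-dataset, list-mode, linear file with float, double or
#' 16/32-bit integer storage. The fluorescence parameter is the one whose
#' `$PnN` matches `FL` (case-insensitive), falling back to the first
#' parameter; a parameter named `SSC` is read as side scatter.
#'
#' @param path FCS file.
#' @return an [FcmSample-class] with keyword-derived metadata.
#' @export
readFCS <- function(path) {
  raw <- tryCatch(readBin(path, "raw", n = file.info(path)$size),
                  error = function(e)
                    stopf("cannot read '%s'", path, class = "flowPE_io_error"))
  if (length(raw) < 58L || !identical(rawToChar(raw[1:6]), "FCS3.0") &&
      !identical(rawToChar(raw[1:6]), "FCS3.1"))
    stopf("'%s' is not an FCS 3.0/3.1 file", path,
          class = "flowPE_format_error")
  off <- .fcsHeaderOffsets(raw)
  kw <- .fcsParseText(raw, off$textBeg, off$textEnd)
  getkw <- function(key, default = NULL) {
    v <- kw[[toupper(key)]]
    if (is.null(v)) default else v
  }
  if (!identical(getkw("$MODE"), "L"))
    stopf("only list-mode ($MODE L) FCS is supported",
          class = "flowPE_format_error")
  if (!is.null(getkw("$NEXTDATA")) && as.integer(getkw("$NEXTDATA")) != 0L)
    stopf("multi-dataset FCS files are not supported",
          class = "flowPE_format_error")
  dtype <- getkw("$DATATYPE")
  if (!dtype %in% c("F", "D", "I"))
    stopf("unsupported $DATATYPE '%s'", dtype, class = "flowPE_format_error")
  npar <- as.integer(getkw("$PAR"))
  ntot <- as.integer(getkw("$TOT"))
  if (is.na(ntot) || ntot == 0L)
    stopf("'%s' contains zero events", path,
          class = "flowPE_empty_input_error")
  byteord <- getkw("$BYTEORD", "1,2,3,4")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stopf("unsupported $BYTEORD '%s'", byteord,
                         class = "flowPE_format_error"))
  bits <- vapply(seq_len(npar), function(i)
    as.integer(getkw(sprintf("$P%dB", i))), integer(1))
  for (i in seq_len(npar)) {
    pe <- getkw(sprintf("$P%dE", i), "0,0")
    amp <- suppressWarnings(as.numeric(strsplit(pe, ",")[[1]]))
    if (length(amp) < 1L || is.na(amp[1]) || amp[1] != 0)
      stopf("parameter %d uses log amplification ($P%dE = %s); only linear is supported",
            i, i, pe, class = "flowPE_unsupported_scale_error")
  }
  if (dtype %in% c("F", "D") && !all(bits == if (dtype == "F") 32L else 64L))
    stopf("float data must use %d-bit parameters",
          if (dtype == "F") 32L else 64L, class = "flowPE_format_error")
  if (dtype == "I" && !all(bits %in% c(16L, 32L)))
    stopf("integer data must use 16- or 32-bit parameters",
          class = "flowPE_format_error")

  dataBeg <- off$dataBeg
  dataEnd <- off$dataEnd
  if (dataBeg == 0L) dataBeg <- as.integer(getkw("$BEGINDATA"))
  if (dataEnd == 0L) dataEnd <- as.integer(getkw("$ENDDATA"))
  dat <- raw[(dataBeg + 1L):(dataEnd + 1L)]
  nvals <- npar * ntot
  values <- if (dtype == "F")
    readBin(dat, "numeric", n = nvals, size = 4L, endian = endian)
  else if (dtype == "D")
    readBin(dat, "numeric", n = nvals, size = 8L, endian = endian)
  else {
    if (length(unique(bits)) != 1L)
      stopf("mixed integer widths are not supported",
            class = "flowPE_format_error")
    readBin(dat, "integer", n = nvals, size = bits[1] / 8L, endian = endian,
            signed = FALSE)
  }
  m <- matrix(values, nrow = ntot, ncol = npar, byrow = TRUE)
  pnames <- toupper(vapply(seq_len(npar), function(i)
    getkw(sprintf("$P%dN", i), sprintf("P%d", i)), character(1)))
  flIdx <- match("FL", pnames)
  if (is.na(flIdx)) flIdx <- 1L
  sscIdx <- match("SSC", pnames)
  FcmSample(m[, flIdx],
            sideScatter = if (!is.na(sscIdx)) m[, sscIdx] else numeric(0),
            metadata = list(
              sample_id = getkw("$SMNO",
                                sub("\\.[^.]*$", "", basename(path))),
              standard = getkw("FLOWPE_STANDARD"),
              note = getkw("$COM"), source = path))
}

#' Write a minimal list-mode FCS 3.0 file
#'
#' Writes the events as 32-bit floats, little-endian, linear scale, one
#' dataset — the same subset [readFCS()] reads. The sample id and standard
#' name from the metadata are stored in `$SMNO` / `FLOWPE_STANDARD`.
#'
#' @param events an [FcmSample-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(events, path) {
  stopifnot(is(events, "FcmSample"))
  fl <- fluorescence(events)
  ssc <- sideScatter(events)
  npar <- if (length(ssc)) 2L else 1L
  ntot <- length(fl)
  if (ntot == 0L)
    stopf("refusing to write an FCS file with zero events",
          class = "flowPE_empty_input_error")
  rng <- function(x) format(max(1024, ceiling(max(x) + 1)), scientific = FALSE)
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@BDBDBDBD@", "$ENDDATA", "@EDEDEDED@",
          "$NEXTDATA", "0", "$MODE", "L", "$DATATYPE", "F",
          "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(npar), "$TOT", as.character(ntot),
          "$P1N", "FL", "$P1B", "32", "$P1E", "0,0", "$P1R", rng(fl))
  if (npar == 2L)
    kv <- c(kv, "$P2N", "SSC", "$P2B", "32", "$P2E", "0,0", "$P2R", rng(ssc))
  meta <- sampleMeta(events)
  if (!is.null(meta$sample_id)) kv <- c(kv, "$SMNO", as.character(meta$sample_id))
  if (!is.null(meta$standard)) kv <- c(kv, "FLOWPE_STANDARD", as.character(meta$standard))
  delim <- "/"
  text <- paste0(delim, paste0(kv, collapse = delim), delim)
  textBeg <- 58L
  textEnd <- textBeg + nchar(text, type = "bytes") - 1L
  dataBeg <- textEnd + 1L
  dataEnd <- dataBeg + 4L * npar * ntot - 1L
  ## placeholders are exactly 10 bytes so substitution keeps offsets valid
  text <- sub("@BDBDBDBD@", sprintf("%010d", dataBeg), text, fixed = TRUE)
  text <- sub("@EDEDEDED@", sprintf("%010d", dataEnd), text, fixed = TRUE)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    textBeg, textEnd, dataBeg, dataEnd, 0L, 0L)
  dat <- if (npar == 2L) as.numeric(rbind(fl, ssc)) else as.numeric(fl)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stopf("cannot write '%s'", path, class = "flowPE_io_error"))
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(dat, con, size = 4L, endian = "little")
  invisible(path)
}
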