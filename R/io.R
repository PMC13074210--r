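## File formats: TSV tables with '#'-prefixed header metadata for curves,
## decays and burst tables; a compact columnar binary container for photon
## streams (three arrays plus a YAML header); YAML for configs.

.writeHeader <- function(con, meta) {
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
}

.readHeader <- function(path) {
  lines <- readLines(path, n = 50)
  hl <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(hl, regexec("^# ([^:]+): (.*)$", hl))
  meta <- lapply(kv, function(m) m[3])
  names(meta) <- vapply(kv, function(m) m[2], character(1))
  meta
}

#' Read and write correlation curves
#'
#' Three-column TSV (lag_ms, G, sigma) with a header naming the pair.
#'
#' @param curve a [CorrelationCurve-class].
#' @param path file path.
#' @export
writeCorrelationCurve <- function(curve, path) {
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, list(type = "CorrelationCurve", pair = curve@pair))
  writeLines("lag_ms\tG\tsigma", con)
  write.table(data.frame(curve@lag, curve@G, curve@sigma), con,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrelationCurve
#' @export
readCorrelationCurve <- function(path) {
  meta <- .readHeader(path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  correlationCurve(d[[1]], d[[2]], d[[3]],
                   pair = if (!is.null(meta$pair)) meta$pair else "GG")
}

#' Read and write decay histograms
#'
#' Two-column TSV (t_ns, counts).
#'
#' @param hist a [DecayHistogram-class].
#' @param path file path.
#' @export
writeDecay <- function(hist, path) {
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, list(type = "DecayHistogram"))
  writeLines("t_ns\tcounts", con)
  write.table(data.frame(hist@time, hist@counts), con, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeDecay
#' @export
readDecay <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  decayHistogram(d[[1]], d[[2]])
}

#' Read and write burst tables
#'
#' TSV with a named header row.
#'
#' @param bursts burst table from [detectBursts].
#' @param path file path.
#' @export
writeBurstTable <- function(bursts, path) {
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, list(type = "BurstTable"))
  suppressWarnings(write.table(bursts, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' @rdname writeBurstTable
#' @export
readBurstTable <- function(path)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")

#' Read and write photon streams
#'
#' Columnar binary container: a YAML text header (magic, counts, micro
#' range, provenance) terminated by a blank line, followed by three raw
#' blocks - macro times (float64, ms), channels (uint8), micro times
#' (float32, ns). [writePhotonStreamTsv] provides a plain-text export.
#'
#' @param stream a [PhotonStream-class].
#' @param path file path.
#' @param provenance optional named list stored in the header.
#' @export
writePhotonStream <- function(stream, path, provenance = list()) {
  n <- nPhotons(stream)
  hdr <- c(list(magic = "fkPhotonStream-v1", n = n,
                microRange = stream@microRange), provenance)
  con <- file(path, "wb"); on.exit(close(con))
  htxt <- yaml::as.yaml(hdr)
  writeBin(charToRaw(paste0(htxt, "\n")), con)
  writeBin(stream@macroTime, con, size = 8, endian = "little")
  writeBin(as.raw(stream@channel), con)
  writeBin(stream@microTime, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname writePhotonStream
#' @export
readPhotonStream <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  # read header up to the blank line
  htxt <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !nzchar(line)) break
    htxt <- c(htxt, line)
  }
  hdr <- yaml::yaml.load(paste(htxt, collapse = "\n"))
  if (!identical(hdr$magic, "fkPhotonStream-v1"))
    stop("not a photon stream container")
  n <- hdr$n
  macro <- readBin(con, "double", n, size = 8, endian = "little")
  chan <- as.integer(readBin(con, "raw", n))
  micro <- readBin(con, "double", n, size = 4, endian = "little")
  # float32 round-trip: snap micro times into [0, range)
  micro <- pmin(pmax(micro, 0), hdr$microRange * (1 - 1e-7))
  photonStream(macro, chan, micro, hdr$microRange)
}

#' @rdname writePhotonStream
#' @export
writePhotonStreamTsv <- function(stream, path) {
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, list(type = "PhotonStream",
                         microRange = stream@microRange))
  writeLines("macro_ms\tchannel\tmicro_ns", con)
  write.table(data.frame(stream@macroTime, stream@channel,
                         stream@microTime), con, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePhotonStream
#' @export
readPhotonStreamTsv <- function(path) {
  meta <- .readHeader(path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  photonStream(d[[1]], d[[2]], d[[3]],
               microRange = as.numeric(meta$microRange))
}

#' Export a FRET-line as a table
#'
#' Two-to-four column table (x, E, tauF, ds) for overlay on burst
#' histograms.
#'
#' @param line data.frame from [dynamicFretLine] or [staticFretLine].
#' @param path file path.
#' @export
writeFretLine <- function(line, path) {
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, list(type = "FretLine"))
  suppressWarnings(write.table(line, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}
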