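# Minimal 16-bit PCM mono RIFF/WAV input and output for synthetic songs,
# with an optional JSON sidecar carrying the ground-truth parameters.

#' Write a recording as 16-bit PCM mono WAV
#'
#' Samples are clipped to \[-1, 1\] and scaled to 16-bit integers. When
#' \code{sidecar} is TRUE and the recording carries ground truth, the
#' [SongParameters-class] are written next to the WAV as
#' \code{<path>.json}.
#'
#' @param recording a [SongRecording-class].
#' @param path output file path.
#' @param sidecar also write the ground-truth JSON sidecar (requires the
#'   jsonlite package).
#' @return \code{path}, invisibly.
#' @export
writeSongWav <- function(recording, path, sidecar = FALSE) {
  stopifnot(is(recording, "SongRecording"))
  x <- pmin(pmax(recording@samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(round(recording@samplingRate))
  dataBytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")    # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")   # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  if (sidecar && !is.null(recording@groundTruth)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write the ground-truth sidecar")
    gt <- recording@groundTruth
    jsonlite::write_json(
      list(dominantFrequency = gt@dominantFrequency,
           syllableDuration = gt@syllableDuration,
           syllablePeriod = gt@syllablePeriod,
           syllablesPerChirp = gt@syllablesPerChirp,
           chirpPeriod = gt@chirpPeriod,
           groupSize = gt@groupSize,
           groupPeriod = gt@groupPeriod,
           jitterCv = gt@jitterCv,
           temperature = gt@temperature),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path (16-bit PCM, single channel).
#' @param temperature recording temperature to attach, degrees C.
#' @param species species label to attach.
#' @return a [SongRecording-class] (without ground truth).
#' @export
readSongWav <- function(path, temperature = 25, species = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || !nzchar(id)) stop("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit WAV supported")
      if (size > 16L) invisible(readBin(con, raw(), n = size - 16L))
    } else if (id == "data") {
      if (is.null(sr)) stop("data chunk before fmt chunk in ", path)
      pcm <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(new("SongRecording", samples = pcm / 32767,
                 samplingRate = as.numeric(sr), temperature = temperature,
                 species = species, groundTruth = NULL))
    } else invisible(readBin(con, raw(), n = size))
  }
}
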