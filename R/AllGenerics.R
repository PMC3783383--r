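#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: waveform
#' samples, sampling rate, recording temperature, species label, ground
#' truth parameters, chirp periods and chirp count.
#'
#' @param object an S4 object from this package.
#' @return the slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))

#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(object) standardGeneric("speciesLabel"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("chirpPeriods", function(object) standardGeneric("chirpPeriods"))

#' @rdname accessors
#' @export
setGeneric("nChirps", function(object) standardGeneric("nChirps"))

#' @rdname accessors
#' @export
setGeneric("nSyllables", function(object) standardGeneric("nSyllables"))

#' Chirp duration implied by a parameter set
#'
#' Onset-to-offset length of one chirp in ms, derived as
#' \code{(syllablesPerChirp - 1) * syllablePeriod + syllableDuration}.
#'
#' @param object a [SongParameters-class] object.
#' @return chirp duration in ms.
#' @export
setGeneric("chirpDuration", function(object) standardGeneric("chirpDuration"))
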