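#' @rdname accessors
#' @aliases samples,SongRecording-method
setMethod("samples", "SongRecording", function(object) object@samples)

#' @rdname accessors
#' @aliases samplingRate,SongRecording-method
setMethod("samplingRate", "SongRecording", function(object) object@samplingRate)

#' @rdname accessors
#' @aliases temperature,SongRecording-method
setMethod("temperature", "SongRecording", function(object) object@temperature)

#' @rdname accessors
#' @aliases speciesLabel,SongRecording-method
setMethod("speciesLabel", "SongRecording", function(object) object@species)

#' @rdname accessors
#' @aliases groundTruth,SongRecording-method
setMethod("groundTruth", "SongRecording", function(object) object@groundTruth)

#' @rdname accessors
#' @aliases chirpPeriods,SegmentationResult-method
setMethod("chirpPeriods", "SegmentationResult",
          function(object) object@chirpPeriods)

#' @rdname accessors
#' @aliases nChirps,SegmentationResult-method
setMethod("nChirps", "SegmentationResult", function(object) {
  if (length(object@chirpIndex) == 0L) 0L else max(object@chirpIndex)
})

#' @rdname accessors
#' @aliases nSyllables,SegmentationResult-method
setMethod("nSyllables", "SegmentationResult",
          function(object) length(object@onsets))

#' @rdname chirpDuration
#' @aliases chirpDuration,SongParameters-method
setMethod("chirpDuration", "SongParameters", function(object) {
  (object@syllablesPerChirp - 1L) * object@syllablePeriod +
    object@syllableDuration
})

setMethod("show", "SongParameters", function(object) {
  cat("SongParameters:",
      sprintf("%.2f kHz carrier;", object@dominantFrequency),
      sprintf("%d syllable(s)/chirp (%.1f/%.1f ms dur/period);",
              object@syllablesPerChirp, object@syllableDuration,
              object@syllablePeriod),
      sprintf("chirp period %.1f ms", object@chirpPeriod), "\n")
  if (object@groupSize > 1L)
    cat("  superstructure: groups of", object@groupSize,
        sprintf("chirps, group period %.1f ms", object@groupPeriod), "\n")
  if (object@jitterCv > 0)
    cat(sprintf("  period jitter cv = %.3f\n", object@jitterCv))
})

setMethod("show", "SongRecording", function(object) {
  cat(sprintf("SongRecording: %.2f s at %g Hz, %.1f degC",
              length(object@samples) / object@samplingRate,
              object@samplingRate, object@temperature))
  if (!is.na(object@species)) cat(", species", object@species)
  cat("\n")
  if (!is.null(object@groundTruth)) cat("  (with ground truth)\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d syllable(s), %d chirp(s)",
              nSyllables(object), nChirps(object)))
  if (object@flagged) cat("  [flagged: nothing above threshold]")
  cat("\n")
})

setMethod("show", "DfaModel", function(object) {
  cat(sprintf("DfaModel: %d group(s), %d feature(s)%s\n",
              length(object@groups), ncol(object@means),
              if (object@ridge > 0)
                sprintf(", ridge %.3g applied", object@ridge) else ""))
})

setMethod("show", "BinomialGlmFit", function(object) {
  cat("Binomial GLM (logit link), taxa x character interaction\n")
  cat("  reference levels:",
      paste(names(object@referenceLevels), object@referenceLevels,
            sep = " = ", collapse = ", "), "\n")
  tab <- object@coefficients
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$z <- round(tab$z, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual deviance: %.2f on %d degrees of freedom\n",
              object@residualDeviance, object@residualDf))
  cat(sprintf("AIC: %.2f\n", object@aic))
})
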