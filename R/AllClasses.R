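#' @include AllGenerics.R
NULL

#' Ground-truth temporal parameters of a synthetic calling song
#'
#' Describes a stereotyped Gryllinae calling song as a three-level temporal
#' hierarchy: a sinusoidal carrier at the dominant frequency, gated into
#' syllables (one wing-stroke each), syllables grouped into chirps, and --
#' for superstructured songs -- chirps grouped into repeating chirp groups.
#'
#' @slot dominantFrequency carrier frequency in kHz.
#' @slot syllableDuration syllable (pulse) duration in ms.
#' @slot syllablePeriod onset-to-onset interval between syllables within a
#'   chirp, in ms.
#' @slot syllablesPerChirp number of syllables per chirp.
#' @slot chirpPeriod onset-to-onset interval between successive chirps in ms
#'   (within a chirp group, when superstructured).
#' @slot groupSize chirps per chirp group; \code{1L} means no superstructure.
#' @slot groupPeriod onset-to-onset interval between successive chirp groups
#'   in ms; \code{NA} when \code{groupSize == 1}.
#' @slot jitterCv coefficient of variation of the multiplicative jitter
#'   applied to every period (0 = perfectly regular song).
#' @slot temperatureSlopes optional named numeric vector of linear
#'   temperature responses (ms per degree C) keyed by feature name; used by
#'   the feature-table sampler to emulate poikilothermic temperature
#'   dependence.
#' @slot temperature recording temperature in degrees C.
#'
#' @seealso [synthesizeSong()], [songParametersFromProfile()]
#' @export
setClass("SongParameters",
  representation(
    dominantFrequency = "numeric",
    syllableDuration  = "numeric",
    syllablePeriod    = "numeric",
    syllablesPerChirp = "integer",
    chirpPeriod       = "numeric",
    groupSize         = "integer",
    groupPeriod       = "numeric",
    jitterCv          = "numeric",
    temperatureSlopes = "numeric",
    temperature       = "numeric"
  ),
  prototype(
    groupSize = 1L, groupPeriod = NA_real_, jitterCv = 0,
    temperatureSlopes = numeric(0), temperature = 25
  )
)

setValidity("SongParameters", function(object) {
  msg <- character(0)
  scalar <- function(x) length(x) == 1L && is.finite(x)
  if (!scalar(object@dominantFrequency) || object@dominantFrequency <= 0)
    msg <- c(msg, "dominantFrequency must be a positive scalar (kHz)")
  if (!scalar(object@syllableDuration) || object@syllableDuration <= 0)
    msg <- c(msg, "syllableDuration must be a positive scalar (ms)")
  if (!scalar(object@syllablePeriod) || object@syllablePeriod <= 0)
    msg <- c(msg, "syllablePeriod must be a positive scalar (ms)")
  if (length(msg) == 0L) {
    if (object@syllablesPerChirp < 1L)
      msg <- c(msg, "syllablesPerChirp must be >= 1")
    if (object@syllablesPerChirp > 1L &&
        object@syllableDuration >= object@syllablePeriod)
      msg <- c(msg, "syllableDuration must be < syllablePeriod")
    cd <- (object@syllablesPerChirp - 1L) * object@syllablePeriod +
      object@syllableDuration
    if (cd > object@chirpPeriod)
      msg <- c(msg, "chirp duration exceeds chirpPeriod")
    if (object@jitterCv < 0) msg <- c(msg, "jitterCv must be >= 0")
    if (object@groupSize < 1L) msg <- c(msg, "groupSize must be >= 1")
    if (object@groupSize > 1L) {
      if (!scalar(object@groupPeriod))
        msg <- c(msg, "groupPeriod required when groupSize > 1")
      else if (object@groupPeriod < object@groupSize * object@chirpPeriod)
        msg <- c(msg, "groupPeriod must be >= groupSize * chirpPeriod")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A (synthetic) calling-song recording
#'
#' A mono waveform with its sampling rate, the ambient temperature of the
#' recording, the species label, and -- for songs produced by
#' [synthesizeSong()] -- the ground-truth [SongParameters-class] used to
#' build it.
#'
#' @slot samples numeric waveform in \[-1, 1\].
#' @slot samplingRate sampling rate in Hz.
#' @slot temperature recording temperature in degrees C.
#' @slot species species label (may be \code{NA}).
#' @slot groundTruth a [SongParameters-class] object, or \code{NULL} for
#'   recordings of unknown provenance.
#' @export
setClass("SongRecording",
  representation(
    samples      = "numeric",
    samplingRate = "numeric",
    temperature  = "numeric",
    species      = "character",
    groundTruth  = "ANY"
  ),
  prototype(samplingRate = 44100, temperature = 25, species = NA_character_,
            groundTruth = NULL)
)

setValidity("SongRecording", function(object) {
  msg <- character(0)
  if (length(object@samples) < 1L) msg <- c(msg, "empty waveform")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar (Hz)")
  gt <- object@groundTruth
  if (!is.null(gt)) {
    if (!is(gt, "SongParameters"))
      msg <- c(msg, "groundTruth must be NULL or a SongParameters")
    else if (object@samplingRate <= 2 * gt@dominantFrequency * 1000)
      msg <- c(msg, "samplingRate must exceed twice the carrier frequency")
  }
  if (length(msg)) msg else TRUE
})

#' Syllable and chirp segmentation of a recording
#'
#' Syllable intervals detected from the amplitude envelope, their grouping
#' into chirps, and the resulting chirp-period sequence (onset-to-onset
#' intervals between successive chirps, in ms). For a song with N detected
#' chirps there are N - 1 chirp periods.
#'
#' @slot onsets syllable onsets in seconds, strictly increasing.
#' @slot offsets syllable offsets in seconds; \code{offsets > onsets}.
#' @slot chirpIndex integer chirp membership per syllable (1-based,
#'   non-decreasing); length 0 until [groupChirps()] has run.
#' @slot chirpPeriods onset-to-onset chirp intervals in ms.
#' @slot flagged \code{TRUE} when no event exceeded the detection threshold.
#' @export
setClass("SegmentationResult",
  representation(
    onsets       = "numeric",
    offsets      = "numeric",
    chirpIndex   = "integer",
    chirpPeriods = "numeric",
    flagged      = "logical"
  ),
  prototype(chirpIndex = integer(0), chirpPeriods = numeric(0),
            flagged = FALSE)
)

setValidity("SegmentationResult", function(object) {
  msg <- character(0)
  n <- length(object@onsets)
  if (length(object@offsets) != n)
    msg <- c(msg, "onsets and offsets must have equal length")
  else {
    if (n > 0L && any(object@offsets <= object@onsets))
      msg <- c(msg, "each offset must exceed its onset")
    if (n > 1L && any(diff(object@onsets) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    if (n > 1L && any(object@offsets[-n] > object@onsets[-1L]))
      msg <- c(msg, "syllable intervals must not overlap")
  }
  k <- length(object@chirpIndex)
  if (k > 0L) {
    if (k != n) msg <- c(msg, "chirpIndex must cover every syllable")
    else if (any(diff(object@chirpIndex) < 0L))
      msg <- c(msg, "chirpIndex must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Linear discriminant classifier with pooled within-group covariance
#'
#' Group mean vectors, the pooled within-group covariance matrix and group
#' priors of a discriminant function analysis. Observations are assigned to
#' the group minimizing squared Mahalanobis distance under the pooled
#' covariance minus twice the log prior.
#'
#' @slot groups group (species) labels.
#' @slot means groups x features matrix of group mean vectors.
#' @slot pooledCov pooled within-group covariance (features x features).
#' @slot priors prior probability per group; sums to 1.
#' @slot ridge ridge added to the covariance diagonal when the pooled
#'   estimate was numerically singular (0 when none was needed).
#' @export
setClass("DfaModel",
  representation(
    groups    = "character",
    means     = "matrix",
    pooledCov = "matrix",
    priors    = "numeric",
    ridge     = "numeric"
  ),
  prototype(ridge = 0)
)

setValidity("DfaModel", function(object) {
  msg <- character(0)
  g <- length(object@groups)
  p <- ncol(object@means)
  if (nrow(object@means) != g) msg <- c(msg, "one mean vector per group required")
  if (!all(dim(object@pooledCov) == c(p, p)))
    msg <- c(msg, "pooledCov must be features x features")
  if (length(object@priors) != g || abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1, one per group")
  if (any(abs(object@pooledCov - t(object@pooledCov)) > 1e-8))
    msg <- c(msg, "pooledCov must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Two-way binomial GLM fit on classification outcomes
#'
#' Result container for the logit-link binomial model of per-replicate
#' classification successes with a full taxa-group by character-set
#' interaction.
#'
#' @slot coefficients data.frame with columns \code{term}, \code{estimate},
#'   \code{se}, \code{z}, \code{p}.
#' @slot residualDeviance residual deviance of the fit.
#' @slot residualDf residual degrees of freedom.
#' @slot aic Akaike information criterion (binomial log-likelihood including
#'   the combinatorial terms).
#' @slot referenceLevels named character vector giving the reference level
#'   of the taxa and character factors.
#' @slot fit the underlying [stats::glm()] object.
#' @export
setClass("BinomialGlmFit",
  representation(
    coefficients     = "data.frame",
    residualDeviance = "numeric",
    residualDf       = "integer",
    aic              = "numeric",
    referenceLevels  = "character",
    fit              = "ANY"
  )
)
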