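# Segmentation of syllables and chirps from the amplitude envelope, and the
# seven acoustic characters: four temporal features and the dominant
# frequency (the five standard characters), plus the two chirp-period
# statistics that capture chirp-group superstructure.

#' Feature-extraction configuration
#'
#' Bundles the tunable parameters of segmentation and spectral analysis.
#' The defaults are validated by synthesizer round-trip tests: a 2 ms
#' envelope smoother, a detection threshold at 20 percent of the envelope
#' peak, 2 ms minimum event and gap lengths, a chirp-break factor of 1.5
#' median syllable periods, and a 2048-point Hamming-windowed FFT.
#'
#' @param smoothingMs moving-average window of the envelope smoother, ms.
#' @param thresholdFraction syllable detection threshold as a fraction of
#'   the envelope maximum.
#' @param minEventMs events shorter than this are dropped, ms.
#' @param minGapMs gaps shorter than this are merged, ms.
#' @param gapFactor a new chirp starts when the inter-syllable onset gap
#'   exceeds \code{gapFactor} times the median syllable period.
#' @param fftSize FFT window length, samples.
#' @param cfDenominator denominator convention of [constancyFactor()]:
#'   \code{"periods"} divides the summed absolute differences by the number
#'   N of chirp-period observations, \code{"differences"} by N - 1.
#' @return a named list of class \code{"featureConfig"}.
#' @export
featureConfig <- function(smoothingMs = 2, thresholdFraction = 0.2,
                          minEventMs = 2, minGapMs = 2, gapFactor = 1.5,
                          fftSize = 2048,
                          cfDenominator = c("periods", "differences")) {
  cfDenominator <- match.arg(cfDenominator)
  structure(list(smoothingMs = smoothingMs,
                 thresholdFraction = thresholdFraction,
                 minEventMs = minEventMs, minGapMs = minGapMs,
                 gapFactor = gapFactor, fftSize = fftSize,
                 cfDenominator = cfDenominator),
            class = "featureConfig")
}

# analytic signal via the frequency-domain construction, zero-padded to a
# fast FFT length
.analytic <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / m
  a[seq_len(n)]
}

#' Amplitude envelope of a recording
#'
#' Magnitude of the analytic signal, smoothed with a centred moving average.
#' The result is non-negative, has the length of the input, and is smooth on
#' the scale of the smoothing window.
#'
#' @param recording a [SongRecording-class] object, or a numeric waveform
#'   (then \code{samplingRate} must be given).
#' @param smoothingMs moving-average window, ms; should span several carrier
#'   cycles.
#' @param samplingRate sampling rate in Hz when \code{recording} is a bare
#'   numeric vector.
#' @return numeric envelope, same length as the input.
#' @export
amplitudeEnvelope <- function(recording, smoothingMs = 2,
                              samplingRate = NULL) {
  if (is(recording, "SongRecording")) {
    x <- recording@samples
    sr <- recording@samplingRate
  } else {
    x <- as.numeric(recording)
    if (is.null(samplingRate)) stop("samplingRate required for a bare vector")
    sr <- samplingRate
  }
  if (length(x) == 0L) stop("empty signal")
  env <- Mod(.analytic(x))
  w <- max(1L, round(smoothingMs / 1000 * sr))
  if (w > 1L) {
    sm <- stats::filter(env, rep(1 / w, w), sides = 2)
    sm <- as.numeric(sm)
    # extend the first/last defined value across the half-window edges
    ok <- which(!is.na(sm))
    if (length(ok)) {
      sm[seq_len(ok[1] - 1L)] <- sm[ok[1]]
      sm[seq(ok[length(ok)] + 1L, length.out = length(sm) - ok[length(ok)])] <-
        sm[ok[length(ok)]]
    } else sm <- env
    env <- sm
  }
  pmax(env, 0)
}

#' Detect syllables in an amplitude envelope
#'
#' Finds maximal runs of the envelope above a threshold set relative to the
#' envelope peak, merges runs separated by gaps shorter than
#' \code{minGapMs}, and drops runs shorter than \code{minEventMs}. When
#' nothing exceeds the threshold an empty, flagged result is returned.
#'
#' @param envelope numeric envelope from [amplitudeEnvelope()].
#' @param samplingRate sampling rate in Hz.
#' @param thresholdFraction threshold as a fraction of the envelope maximum
#'   (0 detects any strictly positive run).
#' @param minEventMs minimum event length, ms.
#' @param minGapMs gaps shorter than this are merged, ms.
#' @return a [SegmentationResult-class] with syllables only (chirps are
#'   assigned by [groupChirps()]).
#' @export
segmentSyllables <- function(envelope, samplingRate,
                             thresholdFraction = 0.2, minEventMs = 2,
                             minGapMs = 2) {
  stopifnot(thresholdFraction >= 0, thresholdFraction <= 1)
  peak <- max(envelope)
  thr <- thresholdFraction * peak
  above <- if (thr > 0) envelope >= thr else envelope > 0
  if (!any(above))
    return(new("SegmentationResult", onsets = numeric(0),
               offsets = numeric(0), flagged = TRUE))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  # merge events separated by short gaps
  if (length(on) > 1L) {
    gapSamp <- (on[-1L] - off[-length(off)] - 1L) / samplingRate * 1000
    keepGap <- gapSamp >= minGapMs
    grp <- cumsum(c(TRUE, keepGap))
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  # drop short events
  durMs <- (off - on + 1L) / samplingRate * 1000
  keep <- durMs >= minEventMs
  on <- on[keep]; off <- off[keep]
  if (length(on) == 0L)
    return(new("SegmentationResult", onsets = numeric(0),
               offsets = numeric(0), flagged = TRUE))
  new("SegmentationResult",
      onsets = as.numeric((on - 1L) / samplingRate),
      offsets = as.numeric(off / samplingRate),
      flagged = FALSE)
}

#' Group syllables into chirps
#'
#' A new chirp starts whenever the gap between successive syllable onsets
#' exceeds \code{gapFactor} times the median onset gap (the de facto
#' syllable period). Chirp periods are the onset-to-onset intervals between
#' the first syllables of successive chirps, in ms.
#'
#' @param seg a [SegmentationResult-class] from [segmentSyllables()].
#' @param gapFactor chirp-break multiple of the median syllable period.
#' @return the segmentation with \code{chirpIndex} and \code{chirpPeriods}
#'   filled in.
#' @export
groupChirps <- function(seg, gapFactor = 1.5) {
  stopifnot(is(seg, "SegmentationResult"))
  n <- nSyllables(seg)
  if (n == 0L) stop("no syllables to group")
  if (n == 1L) {
    seg@chirpIndex <- 1L
    seg@chirpPeriods <- numeric(0)
    return(seg)
  }
  gaps <- diff(seg@onsets)
  breakAt <- gaps > gapFactor * stats::median(gaps)
  idx <- cumsum(c(1L, as.integer(breakAt)))
  seg@chirpIndex <- as.integer(idx)
  firstOn <- seg@onsets[!duplicated(idx)]
  seg@chirpPeriods <- if (length(firstOn) > 1L)
    diff(firstOn) * 1000 else numeric(0)
  validObject(seg)
  seg
}

#' Temporal features of a segmented song
#'
#' Per-recording means of the four temporal characters: syllable duration
#' and syllable period (averaged over syllables; within-chirp onset gaps
#' only), call (chirp) duration (first onset to last offset per chirp), and
#' call period (mean chirp onset-to-onset interval). With a single detected
#' chirp the call period is undefined and reported as \code{NA}. When every
#' chirp holds a single syllable, the syllable period equals the call
#' period.
#'
#' @param seg a [SegmentationResult-class] with chirps assigned.
#' @return named numeric: \code{syllable_duration}, \code{syllable_period},
#'   \code{call_duration}, \code{call_period}, all ms.
#' @export
temporalFeatures <- function(seg) {
  stopifnot(is(seg, "SegmentationResult"))
  if (length(seg@chirpIndex) == 0L)
    stop("run groupChirps() before temporalFeatures()")
  sylDur <- mean(seg@offsets - seg@onsets) * 1000
  byChirp <- split(seq_len(nSyllables(seg)), seg@chirpIndex)
  withinGaps <- unlist(lapply(byChirp, function(i)
    if (length(i) > 1L) diff(seg@onsets[i]) else numeric(0)))
  callDur <- mean(vapply(byChirp, function(i)
    max(seg@offsets[i]) - min(seg@onsets[i]), numeric(1))) * 1000
  callPer <- if (length(seg@chirpPeriods)) mean(seg@chirpPeriods) else
    NA_real_
  sylPer <- if (length(withinGaps)) mean(withinGaps) * 1000 else callPer
  c(syllable_duration = sylDur, syllable_period = sylPer,
    call_duration = callDur, call_period = callPer)
}

#' Dominant frequency of a recording
#'
#' Frequency of the maximum of the Welch-style averaged power spectrum:
#' Hamming-windowed frames of \code{fftSize} samples with 50 percent
#' overlap, periodograms averaged over the whole recording. Field-cricket
#' calls are narrowband, so the estimate is insensitive to framing; the
#' resolution is one FFT bin (samplingRate / fftSize).
#'
#' @param recording a [SongRecording-class], or numeric waveform with
#'   \code{samplingRate}.
#' @param fftSize FFT window length in samples (default 2048).
#' @param samplingRate sampling rate in Hz for bare vectors.
#' @return dominant frequency in kHz.
#' @export
dominantFrequency <- function(recording, fftSize = 2048,
                              samplingRate = NULL) {
  if (is(recording, "SongRecording")) {
    x <- recording@samples
    sr <- recording@samplingRate
  } else {
    x <- as.numeric(recording)
    if (is.null(samplingRate)) stop("samplingRate required for a bare vector")
    sr <- samplingRate
  }
  if (length(x) < fftSize)
    stop("signal shorter than one FFT window (", fftSize, " samples)")
  if (all(x == 0)) stop("silent input: dominant frequency undefined")
  win <- signal::hamming(fftSize)
  hop <- fftSize %/% 2L
  starts <- seq(1L, length(x) - fftSize + 1L, by = hop)
  nb <- fftSize %/% 2L + 1L
  pow <- numeric(nb)
  for (s in starts) {
    X <- stats::fft(x[s:(s + fftSize - 1L)] * win)
    pow <- pow + Mod(X[seq_len(nb)])^2
  }
  freqs <- (seq_len(nb) - 1L) * sr / fftSize
  pow[1] <- 0  # exclude DC
  freqs[which.max(pow)] / 1000
}

#' Constancy factor of a chirp-period sequence
#'
#' Sum of absolute differences between successive chirp periods, normalized
#' by the number of chirp periods: large when the song carries a chirp-group
#' superstructure (alternating short and long intervals), near zero for a
#' regular chirper. Scales linearly with the time unit of the periods.
#'
#' @param periods chirp periods in ms (at least 2).
#' @param denominator \code{"periods"} (N, the default) or
#'   \code{"differences"} (N - 1).
#' @return constancy factor in the unit of \code{periods}.
#' @examples
#' constancyFactor(c(40, 60, 40, 60))  # (20+20+20)/4 = 15
#' @export
constancyFactor <- function(periods,
                            denominator = c("periods", "differences")) {
  denominator <- match.arg(denominator)
  n <- length(periods)
  if (n < 2L) stop("at least 2 chirp periods required")
  denom <- if (denominator == "periods") n else n - 1L
  sum(abs(diff(periods))) / denom
}

#' Relative variance of a chirp-period sequence
#'
#' Sample standard deviation (n - 1 denominator) of the natural logarithms
#' of the chirp periods: a scale-free variability measure, invariant to
#' rescaling the time unit.
#'
#' @param periods chirp periods (strictly positive, at least 2).
#' @return standard deviation of \code{log(periods)}.
#' @examples
#' relativeVariance(c(exp(1), exp(3)))  # sqrt(2)
#' @export
relativeVariance <- function(periods) {
  if (length(periods) < 2L) stop("at least 2 chirp periods required")
  if (any(periods <= 0)) stop("chirp periods must be strictly positive")
  stats::sd(log(periods))
}

#' Extract the seven acoustic characters from a recording
#'
#' Runs the full extraction chain -- envelope, syllable segmentation, chirp
#' grouping, temporal features, dominant frequency, and the two chirp-period
#' statistics -- and returns one feature-table row. The recording
#' temperature and species label are carried through.
#'
#' @param recording a [SongRecording-class] object.
#' @param config a [featureConfig()] list.
#' @param individualId optional identifier for the row.
#' @return one-row data.frame with \code{individual_id}, \code{species},
#'   \code{temperature} and the seven features of [allCharacters()].
#' @examples
#' p <- songParameters(5, 20, 40, 3, 500)
#' song <- synthesizeSong(p, duration = 3)
#' extractFeatures(song)
#' @export
extractFeatures <- function(recording, config = featureConfig(),
                            individualId = NA_character_) {
  stopifnot(is(recording, "SongRecording"))
  env <- amplitudeEnvelope(recording, smoothingMs = config$smoothingMs)
  seg <- segmentSyllables(env, samplingRate = recording@samplingRate,
                          thresholdFraction = config$thresholdFraction,
                          minEventMs = config$minEventMs,
                          minGapMs = config$minGapMs)
  if (seg@flagged) stop("no syllables detected above threshold")
  seg <- groupChirps(seg, gapFactor = config$gapFactor)
  tf <- temporalFeatures(seg)
  df <- dominantFrequency(recording, fftSize = config$fftSize)
  per <- chirpPeriods(seg)
  cf <- if (length(per) >= 2L)
    constancyFactor(per, denominator = config$cfDenominator) else NA_real_
  rv <- if (length(per) >= 2L) relativeVariance(per) else NA_real_
  data.frame(individual_id = individualId,
             species = recording@species,
             temperature = recording@temperature,
             call_period = unname(tf["call_period"]),
             call_duration = unname(tf["call_duration"]),
             syllable_period = unname(tf["syllable_period"]),
             syllable_duration = unname(tf["syllable_duration"]),
             dominant_frequency = df,
             relative_variance = rv,
             constancy_factor = cf,
             stringsAsFactors = FALSE)
}
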