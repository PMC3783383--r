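# Synthetic calling songs and feature tables with the statistical structure
# of the 14 reference species. The synthesizer is the package's source of
# ground truth: every temporal parameter of a synthetic song is known, so
# the segmentation/feature code can be validated by round trip.

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded at \code{seed}, restoring the
#' caller's RNG state afterwards. A \code{NULL} seed leaves the RNG alone.
#' @noRd
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Construct song parameters
#'
#' Direct constructor for [SongParameters-class]; see the class
#' documentation for units and invariants.
#'
#' @param dominantFrequency carrier frequency, kHz.
#' @param syllableDuration syllable duration, ms.
#' @param syllablePeriod syllable onset-to-onset period, ms.
#' @param syllablesPerChirp syllables per chirp.
#' @param chirpPeriod chirp onset-to-onset period, ms.
#' @param groupSize chirps per chirp group (1 = no superstructure).
#' @param groupPeriod group onset-to-onset period, ms (required when
#'   \code{groupSize > 1}).
#' @param jitterCv coefficient of variation of multiplicative period jitter.
#' @param temperatureSlopes named numeric, ms per degree C, per feature.
#' @param temperature recording temperature, degrees C.
#' @return a validated [SongParameters-class] object.
#' @examples
#' songParameters(5, 20, 40, 3, 500)
#' @export
songParameters <- function(dominantFrequency, syllableDuration,
                           syllablePeriod, syllablesPerChirp, chirpPeriod,
                           groupSize = 1L, groupPeriod = NA_real_,
                           jitterCv = 0, temperatureSlopes = numeric(0),
                           temperature = 25) {
  new("SongParameters",
      dominantFrequency = dominantFrequency,
      syllableDuration = syllableDuration,
      syllablePeriod = syllablePeriod,
      syllablesPerChirp = as.integer(syllablesPerChirp),
      chirpPeriod = chirpPeriod,
      groupSize = as.integer(groupSize),
      groupPeriod = as.numeric(groupPeriod),
      jitterCv = jitterCv,
      temperatureSlopes = temperatureSlopes,
      temperature = temperature)
}

#' Derive song parameters from a species profile
#'
#' Maps one row of [loadReferenceProfiles()] to a self-consistent
#' [SongParameters-class] set: syllables per chirp are derived from the call
#' duration, the chirp period is the call period, and for the two
#' superstructured species chirps are paired into groups whose long
#' between-group interval exceeds the within-group chirp period by the
#' profile's constancy factor (so the extracted constancy factor of a long
#' song approaches the profile value). Printed feature combinations that are
#' not physically expressible (syllable duration at or above the syllable
#' period) are clamped, with a warning.
#'
#' @param profile a single-row data.frame as returned by
#'   [loadReferenceProfiles()].
#' @param jitterCv period jitter to apply; default 0 (perfectly regular).
#' @param temperature recording temperature, degrees C.
#' @return a [SongParameters-class] object.
#' @export
songParametersFromProfile <- function(profile, jitterCv = 0,
                                      temperature = 25) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  sylDur <- profile$syllable_duration_mean
  sylPer <- profile$syllable_period_mean
  if (sylDur >= sylPer) {
    warning("profile ", profile$species, ": syllable duration >= period; ",
            "clamping duration to 0.8 * period")
    sylDur <- 0.8 * sylPer
  }
  k <- max(1L, as.integer(
    round((profile$call_duration_mean - sylDur) / sylPer)) + 1L)
  chirpPeriod <- profile$call_period_mean
  cd <- (k - 1L) * sylPer + sylDur
  if (cd > chirpPeriod) {
    k <- max(1L, as.integer(floor((chirpPeriod - sylDur) / sylPer)))
    cd <- (k - 1L) * sylPer + sylDur
  }
  groupSize <- 1L
  groupPeriod <- NA_real_
  if (isTRUE(profile$superstructured)) {
    groupSize <- 2L
    # alternating periods P and P + CF give |successive differences| = CF
    groupPeriod <- 2 * chirpPeriod + profile$constancy_factor_mean
  }
  songParameters(
    dominantFrequency = profile$dominant_frequency_mean,
    syllableDuration = sylDur,
    syllablePeriod = sylPer,
    syllablesPerChirp = k,
    chirpPeriod = chirpPeriod,
    groupSize = groupSize,
    groupPeriod = groupPeriod,
    jitterCv = jitterCv,
    temperature = temperature)
}

# one multiplicative jitter factor per interval, floored to stay positive
.jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  pmax(0.1, 1 + cv * stats::rnorm(n))
}

#' Synthesize a calling song
#'
#' Builds a waveform from [SongParameters-class]: a sine carrier at the
#' dominant frequency gated by raised-cosine-edged syllable envelopes,
#' syllables grouped into chirps and -- when a superstructure is set --
#' chirps grouped with alternating short (within-group) and long
#' (between-group) chirp intervals. Multiplicative jitter with the
#' parameters' \code{jitterCv} is applied independently to every syllable
#' and chirp interval. The ground truth is recorded on the returned object.
#'
#' @param params a [SongParameters-class] object.
#' @param duration recording length in seconds; must hold at least one full
#'   repetition unit (one chirp period, or one group period when
#'   superstructured).
#' @param samplingRate sampling rate in Hz (default 44100).
#' @param seed optional integer seed for the jitter; the caller's RNG state
#'   is untouched.
#' @param rampMs raised-cosine edge length of each syllable, ms (bounded by
#'   a quarter of the syllable duration).
#' @return a [SongRecording-class] object.
#' @examples
#' p <- songParameters(5, 20, 40, 3, 500)
#' song <- synthesizeSong(p, duration = 2)
#' @export
synthesizeSong <- function(params, duration, samplingRate = 44100,
                           seed = NULL, rampMs = 1) {
  stopifnot(is(params, "SongParameters"))
  validObject(params)
  unitMs <- if (params@groupSize > 1L) params@groupPeriod else
    params@chirpPeriod
  if (duration * 1000 < unitMs)
    stop("duration (", duration, " s) shorter than one repetition unit (",
         signif(unitMs / 1000, 4), " s)")
  .withSeed(seed, {
    cv <- params@jitterCv
    P <- params@chirpPeriod
    # chirp onset times (ms): draw intervals until the song is filled
    if (params@groupSize > 1L) {
      between <- params@groupPeriod - (params@groupSize - 1L) * P
      pattern <- c(rep(P, params@groupSize - 1L), between)
    } else pattern <- P
    totalMs <- duration * 1000
    nInt <- ceiling(totalMs / min(pattern)) + length(pattern)
    ints <- rep_len(pattern, nInt) * .jitter(nInt, cv)
    chirpOnsets <- cumsum(c(0, ints))
    # emit complete chirps only: a truncated trailing chirp would bias the
    # extracted call duration
    cd <- (params@syllablesPerChirp - 1L) * params@syllablePeriod +
      params@syllableDuration
    chirpOnsets <- chirpOnsets[chirpOnsets + cd * (1 + 4 * cv) < totalMs]
    # syllable onsets within each chirp
    k <- params@syllablesPerChirp
    sylOnsets <- unlist(lapply(chirpOnsets, function(on) {
      if (k == 1L) return(on)
      on + cumsum(c(0, params@syllablePeriod * .jitter(k - 1L, cv)))
    }))
    sylDurMs <- params@syllableDuration
    keep <- sylOnsets + sylDurMs <= totalMs
    sylOnsets <- sylOnsets[keep]
    if (length(sylOnsets) == 0L)
      stop("duration too short to hold a complete syllable")
    n <- round(duration * samplingRate)
    wave <- numeric(n)
    nSyl <- max(1L, round(sylDurMs / 1000 * samplingRate))
    ramp <- min(round(rampMs / 1000 * samplingRate), nSyl %/% 4L)
    env <- rep(1, nSyl)
    if (ramp > 0) {
      edge <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
      env[seq_len(ramp)] <- edge
      env[nSyl + 1L - seq_len(ramp)] <- edge
    }
    fHz <- params@dominantFrequency * 1000
    tAll <- (seq_len(n) - 1L) / samplingRate
    for (on in sylOnsets) {
      i0 <- round(on / 1000 * samplingRate) + 1L
      idx <- i0:min(i0 + nSyl - 1L, n)
      wave[idx] <- wave[idx] +
        0.9 * env[seq_along(idx)] * sin(2 * pi * fHz * tAll[idx])
    }
    new("SongRecording", samples = wave, samplingRate = samplingRate,
        temperature = params@temperature, species = NA_character_,
        groundTruth = params)
  })
}

#' Sample a synthetic feature table from species profiles
#'
#' Draws per-individual values of the seven acoustic characters
#' independently from normal distributions with each profile's mean and
#' SD = SE * sqrt(n), where n is the profile's number of individuals (the SE
#' is a standard error of the mean, so SE * sqrt(n) recovers the
#' among-individual SD). Values are truncated below at 1 percent of the
#' species mean so durations and frequencies stay positive. Optional linear
#' temperature responses can be injected for testing the temperature
#' correction.
#'
#' @param profiles data.frame from [loadReferenceProfiles()] (or any subset
#'   of its rows).
#' @param nPerSpecies \code{"as_profile"} to reproduce each species' sample
#'   size, or a single integer >= 2.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param temperature recording temperature: a scalar applied to everyone,
#'   or a length-2 range from which per-individual temperatures are drawn
#'   uniformly.
#' @param temperatureSlopes optional named numeric vector (ms per degree C,
#'   keyed by feature name); each individual's value gets
#'   \code{slope * (T - 25)} added before truncation.
#' @return data.frame with columns \code{individual_id}, \code{species},
#'   \code{temperature} and the seven features of [allCharacters()].
#' @examples
#' profiles <- loadReferenceProfiles()
#' tab <- sampleFeatureTable(profiles, seed = 1)
#' nrow(tab)  # 85 individuals
#' @export
sampleFeatureTable <- function(profiles, nPerSpecies = "as_profile",
                               seed = NULL, temperature = 25,
                               temperatureSlopes = NULL) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  if (!identical(nPerSpecies, "as_profile")) {
    nPerSpecies <- as.integer(nPerSpecies)
    if (is.na(nPerSpecies) || nPerSpecies < 2L)
      stop("nPerSpecies must be \"as_profile\" or an integer >= 2")
  }
  feats <- allCharacters()
  .withSeed(seed, {
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
      prof <- profiles[i, ]
      n <- if (identical(nPerSpecies, "as_profile"))
        prof$n_individuals else nPerSpecies
      temp <- if (length(temperature) == 2L)
        stats::runif(n, temperature[1], temperature[2])
      else rep(temperature[1], n)
      out <- data.frame(
        individual_id = sprintf("%s_%02d", prof$species, seq_len(n)),
        species = prof$species, temperature = temp,
        stringsAsFactors = FALSE)
      for (f in feats) {
        mu <- prof[[paste0(f, "_mean")]]
        sdv <- prof[[paste0(f, "_se")]] * sqrt(prof$n_individuals)
        v <- stats::rnorm(n, mu, sdv)
        if (!is.null(temperatureSlopes) && f %in% names(temperatureSlopes))
          v <- v + temperatureSlopes[[f]] * (temp - 25)
        out[[f]] <- pmax(v, 0.01 * mu)
      }
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
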