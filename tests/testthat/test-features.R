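test_that("envelope is non-negative, length-preserving and demodulating", {
  expect_error(amplitudeEnvelope(numeric(0), samplingRate = 44100), "empty")
  z <- amplitudeEnvelope(numeric(1000), samplingRate = 44100)
  expect_equal(z, numeric(1000))
  sr <- 44100
  tone <- sin(2 * pi * 5000 * (0:22049) / sr)
  env <- amplitudeEnvelope(tone, samplingRate = sr)
  expect_equal(length(env), length(tone))
  core <- env[1000:21000]
  expect_lt(max(abs(core - 1)), 0.05)
  expect_true(all(env >= 0))
})

test_that("syllable segmentation recovers duration and period", {
  # continuous syllable train: 20 ms syllables every 40 ms
  p <- songParameters(5, 20, 40, 5L, 200)
  song <- synthesizeSong(p, duration = 2)
  env <- amplitudeEnvelope(song)
  seg <- segmentSyllables(env, samplingRate(song))
  durs <- (seg@offsets - seg@onsets) * 1000
  expect_lt(max(abs(durs - 20)), 2)      # one smoothing window
  periods <- diff(seg@onsets) * 1000
  expect_lt(max(abs(periods - 40)), 2)
})

test_that("segmentation is threshold-relative and handles edge thresholds", {
  sr <- 44100
  tone <- abs(sin(2 * pi * 3 * (0:22049) / sr)) + 0.1  # positive envelope
  seg0 <- segmentSyllables(tone, sr, thresholdFraction = 0)
  expect_equal(nSyllables(seg0), 1L)
  expect_equal(seg0@onsets, 0)
  expect_equal(seg0@offsets, length(tone) / sr)

  p <- songParameters(5, 20, 40, 3L, 500)
  song <- synthesizeSong(p, duration = 2)
  env <- amplitudeEnvelope(song)
  seg1 <- segmentSyllables(env, samplingRate(song))
  seg2 <- segmentSyllables(2 * env, samplingRate(song))
  expect_identical(seg1@onsets, seg2@onsets)
  expect_identical(seg1@offsets, seg2@offsets)

  silent <- segmentSyllables(numeric(1000), sr)
  expect_true(silent@flagged)
  expect_equal(nSyllables(silent), 0L)
})

test_that("detected syllable count matches the synthesizer ground truth", {
  p <- songParameters(5, 20, 40, 3L, 500)
  song <- synthesizeSong(p, duration = 2.2)
  env <- amplitudeEnvelope(song)
  seg <- segmentSyllables(env, samplingRate(song))
  # 2.2 s holds complete chirps at 0, 0.5, ..., 2.0 s
  expect_equal(nSyllables(seg), 5L * 3L)
})

test_that("chirp grouping recovers chirp periods and superstructure", {
  p <- songParameters(5, 20, 40, 3L, 500)
  song <- synthesizeSong(p, duration = 4)
  seg <- groupChirps(segmentSyllables(amplitudeEnvelope(song),
                                      samplingRate(song)))
  expect_true(all(abs(chirpPeriods(seg) - 500) < 2))
  expect_equal(nChirps(seg), 8L)

  sup <- songParameters(5, 20, 40, 3L, 300, groupSize = 2L,
                        groupPeriod = 1100)  # alternating 300 / 800 ms
  song2 <- synthesizeSong(sup, duration = 5)
  seg2 <- groupChirps(segmentSyllables(amplitudeEnvelope(song2),
                                       samplingRate(song2)))
  per <- chirpPeriods(seg2)
  odd <- per[seq(1, length(per), 2)]
  even <- per[seq(2, length(per), 2)]
  expect_true(all(abs(odd - 300) < 2))
  expect_true(all(abs(even - 800) < 2))
})

test_that("chirp grouping is monotone in the gap factor", {
  # uniform train: large gap factor -> single trill, tiny -> chirp per syllable
  p <- songParameters(5, 20, 40, 5L, 200)
  song <- synthesizeSong(p, duration = 1)
  seg <- segmentSyllables(amplitudeEnvelope(song), samplingRate(song))
  expect_equal(nChirps(groupChirps(seg, gapFactor = 1.5)), 1L)
  expect_equal(nChirps(groupChirps(seg, gapFactor = 0.5)),
               nSyllables(seg))
})

test_that("temporal features match ground truth on a Gryllus-like song", {
  prof <- loadReferenceProfiles()
  p <- songParametersFromProfile(prof[prof$species == "Gryllus", ])
  song <- synthesizeSong(p, duration = 3)
  seg <- groupChirps(segmentSyllables(amplitudeEnvelope(song),
                                      samplingRate(song)))
  tf <- temporalFeatures(seg)
  expect_lt(abs(tf[["call_period"]] - 345.5), 2)
  expect_lt(abs(tf[["syllable_period"]] - 36.8), 2)
  expect_lt(abs(tf[["syllable_duration"]] - 20.6), 2)
  expect_lt(abs(tf[["call_duration"]] - chirpDuration(p)), 2)
})

test_that("degenerate chirp structures are reported as specified", {
  p <- songParameters(5, 20, 40, 5L, 200)
  song <- synthesizeSong(p, duration = 1)
  seg <- segmentSyllables(amplitudeEnvelope(song), samplingRate(song))
  one <- groupChirps(seg, gapFactor = 1.5)      # single trill
  tf <- temporalFeatures(one)
  expect_true(is.na(tf[["call_period"]]))        # single chirp
  each <- groupChirps(seg, gapFactor = 0.5)      # one syllable per chirp
  tf2 <- temporalFeatures(each)
  expect_equal(tf2[["syllable_period"]], tf2[["call_period"]])
})

test_that("temporal means are stable in the recording length", {
  p <- songParameters(5, 20, 40, 3L, 500)
  f1 <- temporalFeatures(groupChirps(segmentSyllables(
    amplitudeEnvelope(synthesizeSong(p, 2)), 44100)))
  f2 <- temporalFeatures(groupChirps(segmentSyllables(
    amplitudeEnvelope(synthesizeSong(p, 6)), 44100)))
  expect_lt(max(abs(f1 - f2)), 0.5)
})

test_that("dominant frequency is bin-accurate and scale-invariant", {
  sr <- 44100
  tone <- sin(2 * pi * 5000 * (0:44099) / sr)
  f <- dominantFrequency(tone, samplingRate = sr)
  expect_lt(abs(f - 5) * 1000, sr / 2048)
  expect_identical(dominantFrequency(0.01 * tone, samplingRate = sr), f)
  expect_error(dominantFrequency(numeric(5000), samplingRate = sr),
               "silent")
  expect_error(dominantFrequency(tone[1:100], samplingRate = sr), "shorter")

  tele <- songParameters(3.1, 41.2, 54.5, 2L, 305.9)
  song <- synthesizeSong(tele, duration = 2)
  expect_lt(abs(dominantFrequency(song) - 3.1) * 1000, sr / 2048)
})

test_that("constancy factor follows its definition and conventions", {
  expect_equal(constancyFactor(c(100, 100, 100)), 0)
  expect_equal(constancyFactor(c(40, 60, 40, 60)), 15)  # (20+20+20)/4
  expect_equal(constancyFactor(c(40, 60, 40, 60),
                               denominator = "differences"), 20)
  expect_error(constancyFactor(100), "at least 2")
  # linear in the time unit
  per <- c(30, 80, 45, 90)
  expect_equal(constancyFactor(per * 1000), 1000 * constancyFactor(per))
})

test_that("relative variance follows its definition and is scale-free", {
  expect_equal(relativeVariance(c(50, 50, 50)), 0)
  expect_equal(relativeVariance(c(exp(1), exp(3))), sqrt(2))
  per <- c(30, 80, 45, 90)
  expect_equal(relativeVariance(per * 17), relativeVariance(per))
  expect_error(relativeVariance(c(1, -1)), "positive")
  expect_error(relativeVariance(3), "at least 2")
})

test_that("CF and RV are zero iff chirp periods are constant", {
  set.seed(42)
  for (i in 1:20) {
    per <- exp(rnorm(sample(3:10, 1), log(300), 0.3))
    if (i %% 4 == 0) per <- rep(per[1], length(per))
    constant <- length(unique(per)) == 1L
    expect_identical(constancyFactor(per) == 0, constant)
    expect_identical(relativeVariance(per) == 0, constant)
  }
})

test_that("temporal parameters are recovered across a jitter-free grid", {
  grid <- expand.grid(sylDur = c(10, 25), sylPer = c(35, 60),
                      k = c(2L, 4L), chirpPer = c(400, 700))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- songParameters(4.5, g$sylDur, g$sylPer, g$k, g$chirpPer)
    song <- synthesizeSong(p, duration = 3, samplingRate = 22050)
    tf <- temporalFeatures(groupChirps(segmentSyllables(
      amplitudeEnvelope(song), 22050)))
    expect_lt(abs(tf[["syllable_duration"]] - g$sylDur), 2)
    expect_lt(abs(tf[["syllable_period"]] - g$sylPer), 2)
    expect_lt(abs(tf[["call_period"]] - g$chirpPer), 2)
    expect_lt(abs(tf[["call_duration"]] -
                    ((g$k - 1) * g$sylPer + g$sylDur)), 2)
  }
})

test_that("full extraction row has the documented schema", {
  p <- songParameters(5, 20, 40, 3L, 500)
  song <- synthesizeSong(p, duration = 3)
  row <- extractFeatures(song, individualId = "syn_01")
  expect_identical(row$individual_id, "syn_01")
  expect_true(all(allCharacters() %in% names(row)))
  expect_lt(row$constancy_factor, 0.5)   # jitter-free: CF ~ 0
  expect_lt(row$relative_variance, 0.01) # jitter-free: RV ~ 0
  # features computed from periods are amplitude-invariant
  louder <- new("SongRecording", samples = 0.5 * samples(song),
                samplingRate = samplingRate(song), temperature = 25,
                species = NA_character_, groundTruth = groundTruth(song))
  row2 <- extractFeatures(louder, individualId = "syn_01")
  expect_equal(row2, row)
})

test_that("batch extraction reproduces reference means by round trip", {
  prof <- loadReferenceProfiles()
  picks <- c("Gryllus", "Teleogryllus", "Plebiogryllus", "Platygryllus")
  set.seed(99)
  for (sp in picks) {
    pr <- prof[prof$species == sp, ]
    n <- 4L
    vals <- t(vapply(seq_len(n), function(i) {
      draw <- function(f) max(0.05 * pr[[paste0(f, "_mean")]],
        rnorm(1, pr[[paste0(f, "_mean")]],
              pr[[paste0(f, "_se")]] * sqrt(pr$n_individuals)))
      sylPer <- draw("syllable_period")
      sylDur <- min(draw("syllable_duration"), 0.8 * sylPer)
      p <- songParametersFromProfile(pr)
      k <- p@syllablesPerChirp
      chirpPer <- max(draw("call_period"), (k - 1) * sylPer + sylDur + 20)
      pInd <- songParameters(draw("dominant_frequency"), sylDur, sylPer,
                             k, chirpPer)
      song <- synthesizeSong(pInd, duration = 4 * chirpPer / 1000,
                             samplingRate = 44100)
      row <- extractFeatures(song)
      c(row$call_period, row$syllable_period, row$syllable_duration,
        row$dominant_frequency)
    }, numeric(4)))
    sem <- function(f) pr[[paste0(f, "_se")]] * sqrt(pr$n_individuals) /
      sqrt(n)
    expect_lt(abs(mean(vals[, 1]) - pr$call_period_mean),
              3 * sem("call_period") + 2)
    expect_lt(abs(mean(vals[, 2]) - pr$syllable_period_mean),
              3 * sem("syllable_period") + 2)
    expect_lt(abs(mean(vals[, 3]) - pr$syllable_duration_mean),
              3 * sem("syllable_duration") + 2)
    expect_lt(abs(mean(vals[, 4]) - pr$dominant_frequency_mean),
              3 * sem("dominant_frequency") + 44100 / 2048 / 1000)
  }
})
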