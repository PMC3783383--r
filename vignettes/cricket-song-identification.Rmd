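---
title: "Methods: song synthesis, feature extraction and the classification experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: song synthesis, feature extraction and the classification experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cricketsong)
```

## The problem

Field crickets (Gryllinae) advertise with species-specific calling songs:
a near-sinusoidal carrier (one dominant frequency, 3–7.5 kHz in the
reference species) gated into *syllables* (one wing-stroke each),
syllables grouped into *chirps* that repeat with a characteristic period,
and — in two of the fourteen reference call types — chirps grouped again
into repeating *chirp groups* (superstructure). Because songs diverge
faster than morphology in several cryptic complexes, song features are an
attractive non-invasive identification character. The package asks, on
fully controlled synthetic data: how well do two standard multivariate
methods — supervised discriminant function analysis (DFA) and unsupervised
single-linkage clustering — recover species from song features, how does
the answer change with the number of taxa analysed together (5–13) and
with the character set (5 standard features vs 5 + 2 superstructure
statistics), and do the superstructure statistics rescue the two species
whose songs carry a second level of temporal organization?

## The seven characters

Five standard features: call (chirp) period and duration, syllable period
and duration (ms), and dominant frequency (kHz). Two chirp-period
statistics computed on the sequence $P_1,\dots,P_N$ of onset-to-onset
chirp intervals:

* **Constancy factor** $\mathrm{CF} = \frac{1}{N}\sum_{i=1}^{N-1}
  |P_{i+1}-P_i|$. For a regular chirper CF is on the order of the period
  jitter; for a superstructured song with alternating within-group and
  between-group intervals it approaches the difference between the two,
  typically one to two orders of magnitude larger. The denominator is the
  number of chirp-period observations $N$; dividing by the number of
  differences $N-1$ is available via
  `featureConfig(cfDenominator = "differences")` since the two readings
  of "normalized by the total number of chirps" differ only by
  $(N-1)/N$.
* **Relative variance** $\mathrm{RV} = \mathrm{sd}(\ln P_i)$ (sample SD,
  $n-1$ denominator): scale-free, invariant to the time unit, zero iff the
  periods are constant. Both properties are tested.

A note on units: the reference profile table stores RV values up to 943
"ms", which is not consistent with an SD of logarithms (dimensionless,
typically below 1). The profiles ship the values verbatim and the sampler
treats them as plain feature values with no unit interpretation; only the
extractor's own RV obeys the definition above. This mirrors how the
numbers are used: as coordinates in a classification space, never as
physical durations.

## The synthesizer

`synthesizeSong()` renders a `SongParameters` object as a waveform:
syllables are raised-cosine-edged gates (1 ms edges, bounded by a quarter
of the syllable duration) on a sine carrier, placed at syllable periods
within chirps and chirp periods between chirps; a superstructure of
`groupSize` chirps alternates the within-group chirp period with the
longer between-group interval implied by `groupPeriod`. Every interval is
jittered multiplicatively with CV `jitterCv`. Two deliberate choices:

* **Only complete chirps are emitted.** A truncated trailing chirp would
  bias the mean extracted call duration by up to half a chirp; dropping it
  keeps the synthesizer→extractor round trip within one smoothing window.
* `songParametersFromProfile()` derives a self-consistent parameter set
  from a profile row (syllables per chirp from call duration; chirp period
  = call period; for superstructured species, groups of two chirps whose
  between-group interval exceeds the chirp period by the profile's CF, so
  a long song's extracted CF approaches the profile value). Two profiles
  are not physically expressible as printed (syllable duration ≥ period
  for *Gryllodes*; chirp period ≈ syllable period × syllables for
  *Phonarellus*, i.e. an undetectable chirp boundary); the constructor
  clamps and warns, and round-trip tests use structurally consistent
  species.

`sampleFeatureTable()` skips the audio: per-species, per-feature
independent normal draws with the profile mean and SD = SE·√n (SE is a
standard error of the mean at the profile's n), truncated below at 1 % of
the mean so durations stay positive. Independence across features is a
known fidelity limit — real song features covary (e.g. through body size
and temperature) — so synthetic tables are somewhat *harder* to cluster
than real ones: species spread along all seven axes instead of along a
few correlated ones. Optional per-feature linear temperature slopes
(ms/°C) emulate poikilothermic drift for testing the correction.

What passing tests show, and what they do not: round-trip and evaluation
results validate the algorithms on clean, single-singer,
noise-free signals with normally distributed features. They do not show
robustness to noise floors, reverberation, overlapping singers or
non-normal feature distributions, which the synthesizer deliberately does
not model.

## Feature extraction

The envelope is the magnitude of the analytic signal (frequency-domain
construction, zero-padded to a fast FFT length) smoothed by a centred
moving average (default 2 ms — several carrier cycles at ≥ 3 kHz, well
below the shortest syllable of interest). Syllables are maximal runs
above 20 % of the envelope peak (threshold relative, so segmentation is
amplitude-invariant); gaps shorter than 2 ms are merged, events shorter
than 2 ms dropped. Chirps start where the inter-onset gap exceeds 1.5×
the median onset gap. All five thresholds live in `featureConfig()` and
are validated by round-trip tests: on jitter-free songs every temporal
feature returns within one smoothing window (2 ms) of ground truth, with
onset-to-onset quantities (periods) essentially exact because edge shifts
cancel.

Dominant frequency uses the Welch-style average of Hamming-windowed
2048-point periodograms over the whole recording (50 % overlap), not a
single frame: cricket calls are narrowband, so the averaged-spectrum
argmax is frame-insensitive and bin-accurate (±sr/2048). The DC bin is
excluded. CF and RV are computed on the chirp periods of the whole
recording (not per bout); with fewer than three detected chirps they are
reported as missing, and a single chirp leaves the call period `NA`.

## Preprocessing

Temperature correction regresses each feature on recording temperature —
per species by default, since temperature responses are species-specific
and pooling would mix species differences into the slope — and, when the
slope is significant at α = 0.05, shifts each value parallel to the
fitted line to 25 °C (`v + b(25 − T)`), preserving residual individual
variation rather than collapsing onto the fit. Scopes with fewer than
three distinct temperatures are skipped with a warning. The gate makes
the operation idempotent in practice: corrected data have near-zero
slopes, so a second pass leaves them alone. Standardization is pooled
(over all selected individuals, not per species), as the clustering needs
one common scale; zero-variance columns are a hard error naming the
column.

## Classification

**DFA.** Group means plus pooled within-group covariance; assignment
minimizes squared Mahalanobis distance minus twice the log prior. Priors
default to equal: the design is near-balanced (4–8 individuals per
species) and the original software's default is not recoverable. Scoring
is resubstitution (one classification matrix per set), matching the
evaluation design. A numerically singular pooled covariance gets an
escalating ridge, recorded on the model. Tests pin the implementation to
a brute-force per-observation Mahalanobis oracle and to `MASS::lda` on
balanced data, and verify affine invariance.

**Clustering.** Pooled standardization → Euclidean distances →
single-linkage tree (`stats::hclust`; merge heights provably equal sorted
MST edge weights, which the tests check against a brute-force Prim
oracle) → cut at 0.4 of the *maximum* merge height. The cutoff is applied
to max-normalized heights because raw Euclidean distances on 5–7
standardized features are rarely below 0.4, so a fixed 0.4 criterion is
only coherent on a normalized linkage scale (as plotted by the software
the criterion originates from); `normalize = FALSE` retains the raw
reading. Correctness is scored at the taxon level — a species counts as
resolved iff some cluster contains exactly its individuals — because the
published per-replicate percentages are exact multiples of 100/taxa
count, a granularity individual-level scoring with 4–8 individuals per
species cannot produce. The proportion is therefore always a multiple of
1/taxa count (tested).

## The evaluation and its inference

`runRandomization()` draws one random species subset per (taxa count ∈
5..13, replicate ∈ 1..10) and evaluates both character sets and both
methods on the identical subset. `misclassifyLabels()` reassigns
round(f·N) randomly chosen individuals to one randomly chosen target
group (f ∈ {5, 10, 20} %), emulating a-priori misidentification; on
well-separated data DFA accuracy degrades to ≈ 100 − 100f, which the
tests verify.

**Binomial GLM.** The published per-replicate cluster percentages are
inverted to success counts — exact and unique for ≤ 13 taxa because the
rounding grid is coarser than 1 % — using half-up rounding (62.5 % prints
as 63, which banker's rounding would not produce). The model is
successes/failures ~ taxa × characters, logit link, treatment coding.
Reference levels are set explicitly; the character reference defaults to
the **seven**-character set because that is the parameterization under
which the published coefficient table reproduces (intercept z = 4.454 is
exactly the Wald z of the taxa5/7-character cell logit; with the
five-character reference it would be 3.481). Fitting the 180 rebuilt
counts gives residual deviance 214.53 on 162 df — within half a percent
of the published 215.35, with every taxa5- and taxa8-reference z
statistic except the two taxa6 terms matching to the printed three
decimals. The residue is a paper-internal inconsistency: a unique
single-count change (one 6-taxa/7-character replicate read as 6/6 rather
than the printed 5/6) reproduces deviance, AIC and the taxa6 statistics
exactly, which a dedicated test documents. The package reports the fit of
the table as printed.

**Bootstrap.** Replicate-level proportions (the 10 replicates are the
resampling units) are resampled 100 times; means are formed on the
arcsine-root scale and the normal interval (±1.96 SE) is back-transformed
through sin², so endpoints stay in [0, 1]. Two small-sample caveats,
both inherent to the transform-average-back-transform procedure and
documented by tests: the reported mean converges to
sin²(mean(arcsin√p)), which sits below the arithmetic mean when
proportions crowd 1 (Jensen gap ≈ 0.07 at the extreme published rows),
and empirical coverage at 10 replicates is ≈ 89 % rather than the nominal
95 %.

**Two-proportion tests.** `twoProportionTest()` is the Yates-corrected
chi-squared test on the 2×2 table (1 df, two-sided), with degenerate
margins returning p = 1. The superstructure experiment retains both
superstructured species in every subset (6, 7 and 10 taxa × 10
randomizations) and counts how often each is resolved with 5 vs 7
characters; on synthetic data the seven-character set resolves
*Coiblemmus* nearly always (≈ 30/30 across the three subset sizes) while
the five standard characters almost never do, reproducing the direction
and strength of the published contrast.

A null-simulation test verifies the GLM's per-contrast type-I rate is
nominal (≈ 0.05). Note that with eight correlated contrasts per fit the
familywise rate is necessarily ≈ 20–25 %; "no contrast significant in 90 %
of null runs" is not an achievable property of this (or any unadjusted)
parameterization.

## Numerical choices and degenerate inputs

* Truncation floor of the feature sampler: 1 % of the species mean
  (normal tails would otherwise produce non-positive durations).
* Ridge on a singular pooled covariance: starts at 10⁻⁸·mean diagonal,
  ×10 until Cholesky succeeds; logged and stored.
* Half-up rounding in `invertPercentage()`; failure to invert signals a
  transcription problem rather than returning a nearest match.
* Silent or empty signals: hard errors in `dominantFrequency()` and
  `amplitudeEnvelope()`; segmentation of a sub-threshold envelope returns
  an empty, flagged result.
* Ties in the DFA assignment break toward the first group in sorted
  label order (`ties.method = "first"`), which is only reachable on
  exactly symmetric synthetic inputs.

## Problem sizes used by the tests

The suite synthesizes a few dozen short songs (2–5 s at 22.05 or
44.1 kHz), samples feature tables of 85–500 rows, runs the randomized
evaluation at reduced replicate counts where full scale adds nothing, and
uses 60–300 simulation repetitions for the type-I and coverage checks —
sizes chosen so the whole suite runs in well under a minute while keeping
Monte-Carlo error far below every asserted tolerance. The acceptance
script runs the full 180-observation GLM and the full ten-replicate
five-taxa DFA cell.

## Known limitations

* Features are sampled independently; real covariance structure (and any
  benefit clustering might draw from it) is not emulated, so absolute
  cluster-accuracy levels on synthetic tables sit below those reported
  for the real recordings even though every qualitative contrast
  (taxa-count decline, superstructure rescue, DFA ceiling) reproduces.
* No noise, reverberation or overlapping singers; the segmenter is not
  noise-robust by design.
* Trills (continuous syllable trains) have no detectable chirp boundary;
  call-level features of such songs depend on the `gapFactor` convention,
  and bouts are treated as chirp groups.
* The profile table's RV/CF columns are used as printed, without unit
  interpretation (see above).
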