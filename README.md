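# cricketsong

Acoustic species identification for field crickets (Gryllinae), built
around the calling song: a sinusoidal carrier gated into syllables, the
syllables grouped into chirps, and — in some species — the chirps
themselves grouped into a repeating *superstructure*. The package is aimed
at bioacousticians and computational taxonomists who want to test how well
standard multivariate statistics recover species boundaries from song
features, on data whose ground truth is fully known.

It provides, end to end:

* a **song synthesizer** that generates waveforms with known temporal
  parameters (and a feature-table sampler that emulates the per-species
  means/SEs of the 14 reference call types, 85 individuals in total);
* **feature extraction**: amplitude-envelope segmentation of syllables and
  chirps, the five standard characters (call period, call duration,
  syllable period, syllable duration in ms; dominant frequency in kHz from
  a 2048-point Hamming-windowed averaged power spectrum), and two
  chirp-period statistics that capture superstructure,

  * constancy factor: `CF = (1/N) * Σ_{i=1}^{N-1} |P_{i+1} − P_i|` over the
    chirp periods `P_1..P_N`,
  * relative variance: `RV = sd(ln P_i)` (sample SD, scale-free);
* **preprocessing**: per-species linear temperature correction to 25 °C
  (significance-gated at α = 0.05) and pooled z-standardization;
* **classification**: discriminant function analysis (pooled within-group
  covariance, equal priors, resubstitution classification matrix) and
  single-linkage clustering cut at a normalized linkage distance of 0.4
  with taxon-level (pure-and-complete cluster) scoring;
* the **randomized evaluation**: random subsets of 5–13 taxa × 10
  replicates × {5, 7} characters, scored by both methods on identical
  subsets, with a two-way binomial logit GLM (taxa × character
  interaction, treatment contrasts), 100-iteration arcsine bootstrap CIs,
  and Yates-corrected two-proportion tests for the superstructure
  experiment.

## Worked example

Synthesize a jitter-lite chirper (3 syllables per chirp, 500 ms chirp
period, 5 kHz carrier) and extract its features:

```r
library(cricketsong)
p <- songParameters(dominantFrequency = 5, syllableDuration = 20,
                    syllablePeriod = 40, syllablesPerChirp = 3,
                    chirpPeriod = 500, jitterCv = 0.02)
song <- synthesizeSong(p, duration = 4, seed = 42)
round(extractFeatures(song)[, allCharacters()], 3)
#>   call_period call_duration syllable_period syllable_duration
#> 1     505.144       100.102          39.949            20.199
#>   dominant_frequency relative_variance constancy_factor
#> 1              4.996             0.015              7.83
```

Every temporal parameter comes back within the 2 ms envelope-smoothing
window of its ground truth (call duration: 2 × 40 + 20 = 100 ms), the
carrier within one FFT bin (44100/2048 ≈ 21.5 Hz), and the 2 % period
jitter shows up as a small relative variance.

Run the randomized evaluation on a feature table sampled from the 14
reference species and compare methods:

```r
prof <- loadReferenceProfiles()
tab <- sampleFeatureTable(prof, seed = 1)        # 85 individuals
out <- runRandomization(tab, taxaCounts = c(5, 11), replicates = 10,
                        seed = 2)
summarizeOutcomes(out)[, c("method", "taxa_count", "n_characters",
                           "average")]
#>    method taxa_count n_characters average
#> 1 cluster          5            7      68
#> 2 cluster          5            5      38
#> 3 cluster         11            7      33
#> 4 cluster         11            5      14
#> 5     dfa          5            7     100
#> 6     dfa          5            5     100
#> 7     dfa         11            7     100
#> 8     dfa         11            5     100
```

DFA sits at its ceiling while unsupervised clustering degrades with more
taxa and benefits from the two superstructure characters — the qualitative
pattern the method comparison is about.

Fit the two-way binomial GLM to the success counts rebuilt from the
published cluster-analysis replicate percentages (180 observations,
success counts recovered exactly by `invertPercentage()`):

```r
fit <- fitBinomialGlm(glmDataFromPrinted("table3"))
fit
#> Binomial GLM (logit link), taxa x character interaction
#>   reference levels: taxa = taxa5, characters = 7 characters
#>               term estimate    se      z        p
#>  taxa5 (intercept)    1.815 0.408  4.454 8.43e-06
#>             ...
#>             taxa11   -1.596 0.450 -3.544 3.95e-04
#>             ...
#> Residual deviance: 214.53 on 162 degrees of freedom
#> AIC: 586.65
```

The intercept z = 4.454 says the five-taxa/seven-character reference cell
classifies far better than chance; taxa11's z = −3.544 is the significant
drop in cluster accuracy beyond ten taxa.

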