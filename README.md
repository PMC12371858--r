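# renalTVF

Quantitative cartography of the renal tubular volume fraction (TVF) from
multi-echo T2-weighted MRI. The tubular fluid and the parenchyma/blood pool
have well separated transverse relaxation times, so the voxel-wise T2 decay
is modeled as a two-compartment bi-exponential with the long (tubular-fluid)
T2 fixed at 150 ms; the relative weight of the long component is the TVF.

The package provides:

- **EPG simulation** of CPMG/MESE echo trains with imperfect refocusing
  pulses (`epgEchoAmplitudes`), validated against an independent isochromat
  Bloch oracle (`blochEchoAmplitudes`).
- **Relaxometry fitting**: mono-exponential T2/T2\* fits (`fitMonoExp`),
  the constrained bi-exponential TVF fit (`fitBiExpFixedLong`), and the T2′
  relation `1/T2* = 1/T2 + 1/T2'` (`t2prime`).
- **T2 spectrum analysis** by free nonnegative least squares over a
  log-spaced grid with peak segmentation (`nnlsSpectrum`, `findPeaks`).
- **A Monte Carlo study** of the TVF error induced by fixing the long T2
  during fitting (`runTable2`).
- **Voxel-wise cartography** with per-layer ROI summaries and intervention
  time courses (`mapVoxelwise`, `roiMedian`, `intervalSummary`).
- **Synthetic layered kidney phantoms** so that every pipeline stage is
  testable without scanner data (`generateLayeredImage`,
  `generateInterventionSeries`, `generateMixtureSeries`).
- **NIfTI/CSV I/O and a CLI** (`runCLI`, installed script
  `inst/scripts/tvfmap`).

## Worked example

Simulate a kidney-like voxel at 50 % TVF, add noise, and fit it back:

```r
library(renalTVF)

p <- protocolPreset("short_te")
p
#> MESE protocol: 13 echoes, TE1 = dTE = 6.4 ms, TR = 500 ms, refocusing 170 deg

cs <- compartmentSet(t2Ms = c(150, 30), weight = c(0.5, 0.5),
                     t1Ms = c(2500, 1500))
s <- addGaussianNoise(composeSignal(cs, p), snr = 100, rngSeed = 42)
fitBiExpFixedLong(s)
#> BiExpFit: TVF = 50.85 %, T2short = 29.87 ms (T2long fixed 150 ms), valid
```

Quantify the error induced by fixing the long T2 at 150 ms when the true
value is 100, 150 or 200 ms (reduced to 200 trials here; the full study
uses 1000):

```r
cfg <- simulationConfig(tvfLevelsPercent = c(45, 50, 55), nTrials = 200L)
runTable2(cfg)
#> Long-T2 fixation error study: 3 scenario(s) x 3 level(s), 200 trials
#>   t2_long_true_ms tvf_true_percent rel_change_true_percent tvf_mean_percent
#> 1             100               45                      NA            28.47
#> 2             100               50                   11.11            31.51
#> 3             100               55                   10.00            34.55
#> 4             150               45                      NA            44.72
#> 5             150               50                   11.11            49.80
#> 6             150               55                   10.00            54.84
#> 7             200               45                      NA            53.72
#> 8             200               50                   11.11            59.56
#> 9             200               55                   10.00            65.38
#>   tvf_sd_percent rel_change_mean_percent rel_change_mae_percent
#> 1         0.4976                      NA                     NA
#> 2         0.5382                  10.724                 2.2003
#> ...
```

The absolute TVF is biased whenever the fixed long T2 is wrong, but the
*relative* change between consecutive TVF levels stays close to ground
truth in all three scenarios — the study's central observation.

Map a synthetic layered kidney phantom end to end:

```r
ph <- generateLayeredImage(phantomSpec())        # 96 x 96, SNR 100
maps <- mapVoxelwise(ph$image, "biexp_tvf")
round(roiMedian(maps$map, ph$labels), 1)
#>        cortex outer_medulla inner_medulla
#>          29.3          42.2          76.3
```

(the programmed layer TVFs are 29.8, 42.6 and 76.4 %).

Resolve the two water compartments spectrally on the long echo train:

```r
te <- echoTimes(protocolPreset("long_te"))
sp <- nnlsSpectrum(decaySignal(te, 0.4 * exp(-te / 150) + 0.6 * exp(-te / 30)))
findPeaks(sp)
#>   t2_low_ms t2_apex_ms t2_high_ms area_fraction
#> 1  29.65372   29.65372   30.82379      0.600096
#> 2 144.92886  150.64739  150.64739      0.399904

t2prime(45, 12)
#> [1] 16.36364
```

## Command line

The installed script `tvfmap` (in `inst/scripts/`) exposes the pipeline:

```sh
tvfmap simulate-table2 --seed 42 --out table2.csv
tvfmap phantom --out phantom/ --seed 11
tvfmap fit-maps --model tvf --in phantom/stack.nii.gz --out maps/
tvfmap spectrum --in decay.csv --out spectrum.csv --peaks peaks.csv
tvfmap t2prime --t2 50 --t2star 10
```

Exit codes: 0 success, 2 validation error, 3 fit-failure threshold exceeded.
Every output table carries a comment header with the package version, the
seed and a configuration hash.

## Acceptance metrics

`scripts/acceptance.R` computes the study's headline numbers against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Notes on fidelity

The fitted-TVF surface is reproduced within two reference SDs at nearly all
levels. Known deviations, analyzed in the test suite: at extreme TVF
(75–80 %) under incorrect long-T2 fixation the 10–40 ms short-T2 bound
clamps and shifts the mean by a few percentage points, and the
relative-change MAE of the correctly fixed scenario is smaller here
(≈2.9 at truth 20 %) than the reference value (≈5.0), consistent with this
implementation's lower per-fit variance.
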