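# gazeflow

Fixation, entropy, and Markov transition analysis of driver gaze.

When drivers take on a concurrent cognitive task (mental arithmetic,
phone conversations, in-vehicle systems), their visual attention
reorganises: glances concentrate on fewer areas, dwell differently, and
move between regions of the scene along different paths. gazeflow is for
human-factors and traffic-safety researchers who record gaze with wearable
eye trackers (50/100 Hz) and want a tested, reproducible pipeline from raw
samples to the two standard descriptions of that reorganisation:

* **Macroscopic — the fixation entropy rate.** With per-area occupancy
  probabilities $P_i$ (share of gaze time) and mean fixation durations
  $T_i$ (seconds) over $D$ areas of interest,

  $$E = -\sum_i P_i \log_2 P_i, \qquad E_{max} = \log_2 D, \qquad
  E_n = \sum_{i=1}^{D} \frac{E}{E_{max}\,D\,T_i}.$$

  $E_n$ is zero when gaze locks onto one area and grows with both
  dispersion and glance brevity — a single number for "how randomly was
  attention allocated".

* **Microscopic — Markov gaze transitions.** One-step transition
  probabilities $p_{ij}$ between the nine AOI regions (left
  distant/near/bottom A/B/C, front far/near D/E, in-vehicle F, right
  distant/near/bottom G/H/I), the *empirical* two-step (lag-2) matrix —
  deliberately not the matrix square $P^2$, so that their difference
  diagnoses "looking back" behaviour — stationary distributions
  $XP = X,\ \sum x_i = 1$, six-group region merging (A+B, C, D+E, F, G+H,
  I), and percent change proportions between one- and two-step
  probabilities.

Upstream of the statistics sit a velocity-threshold (I-VT) fixation
detector, sub-75 ms glance merging (blink healing), and configurable AOI
coding. Downstream sit tidy/glance methods, ggplot2 autoplots, and CSV/JSON
reports. A seeded synthetic generator (`simulate_aoi_sequence()`,
`simulate_gaze_stream()`, `workload_preset()`) produces label sequences
and raw gaze streams with known ground truth, so the whole chain runs and
is verified without any external data.

## Worked example

The package bundles per-area statistics for ten drivers (six male, four
female) from an on-road workload study. Recomputing the entropy rate per
driver and comparing groups:

```r
library(gazeflow)
report <- driver_entropy_report()
report
#> <gaze_driver_report> 10 drivers; mean E_n = 3.03915 (median 3.00245, SD 0.4886574)
#> # A tibble: 2 × 4
#>   sex        n mean_E_n sd_E_n
#>   <chr>  <int>    <dbl>  <dbl>
#> 1 female     4     2.64  0.347
#> 2 male       6     3.31  0.374
#> higher group exceeds lower by 25.55%
```

The sample mean 3.039 and SD 0.489 are the duration-weighted entropy rates
of the ten drivers; male drivers' mean exceeds the female mean by about a
quarter, i.e. male gaze in this sample was more dispersed and composed of
shorter glances. Four artefact duration cells (sub-millisecond "means")
are excluded with the area count adapted per driver; `tidy(report)` shows
the per-driver values and retained area counts.

A fully synthetic end-to-end run — simulate a normal-driving Markov chain,
render it as a 50 Hz gaze stream, and push it back through detection,
coding, merging, and the transition analysis:

```r
preset <- workload_preset("normal")
seq0   <- simulate_aoi_sequence(400, preset$P, seed = 7)
stream <- simulate_gaze_stream(seq0, seed = 8)
out    <- run_gaze_pipeline(stream)
out
#> <gaze_pipeline> 170 fixations, E_n = 2.3148
#> merged stationary distribution:
#>    A+B      C    D+E      F    G+H      I
#> 0.0119 0.0000 0.9167 0.0000 0.0714 0.0000
```

The 400 simulated fixations collapse to 170 detected ones (adjacent
same-area fixations are indistinguishable without an intervening saccade);
the merged stationary distribution recovers the front-dominant,
right-secondary structure the preset encodes, with exact zeros for areas
never visited. `autoplot(out$model_merged)` draws the transition heatmap;
`write_gaze_report()` (or `run_gaze_pipeline(..., output_dir=)`) writes
round-trippable CSV/JSON artifacts.

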