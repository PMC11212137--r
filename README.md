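# enantiopore

Single-molecule peptide sensing with a wild-type aerolysin nanopore can
tell apart the two enantiomers of arginine-vasopressin (l-AVP vs d-AVP
— the same peptide with a d-Arg at position 8). Each peptide entering
the pore produces a resistive pulse: the ionic current drops from the
open-pore level $I_0$ to a blocked level $I_b$ for a dwell time $T_t$.
`enantiopore` implements the full analysis chain for such recordings,
for electrophysiologists and analytical chemists working with protein
nanopore sensors:

* **Simulation** — current traces at 250 kHz with Poisson event
  arrivals, exponential dwell times, Gaussian blockade populations and
  a 5 kHz Gaussian low-pass, plus a ground-truth event ledger
  (`simulate_trace()`, `avp_sim_config()`).
* **Event analysis** — robust open-pore baseline estimation, event
  detection at an $I_0 - 7\sigma$ threshold, the five event parameters
  ($T_t$, $\Delta I_b = I_0 - I_b$, $\Delta I_{b,\min}$,
  $\Delta I_{b,\max}$, in-event noise $I_{bs}$), and the standard
  event filters (dwell ≥ 200 µs, $I_{bs}$ ≥ 1 pA, normalized blockade
  ≥ 0.2) (`detect_events()`, `filter_events()`).
* **Distribution fitting** — blockade-level histograms (0.005 bins)
  with Gaussian/bi-Gaussian peak fits, semilog dwell-time exponentials
  (30 bins/decade), and interevent-time exponentials for the event
  frequency, each averaged over three randomized-start repeats
  (`fit_blockade_peaks()`, `fit_dwell_time()`, `event_frequency()`).
* **Enantiomer classification** — PCA of the five standardized
  parameters using a fixed reference correlation matrix, a Gaussian
  band $[\mu - 3\sigma,\ \mu + 3\sigma]$ on PC2 per peptide, Monte
  Carlo label assignment for events in the band overlap (draw
  probability proportional to the two band densities), confusion-matrix
  evaluation, mixture-ratio estimation, and a logistic-regression
  baseline (`fit_pca_model()`, `fit_pc2_band()`,
  `monte_carlo_classify()`, `evaluate_confusion()`).
* **Orchestration** — `run_pipeline()` runs
  simulate → detect → filter → fit → classify → evaluate from a single
  seeded configuration (YAML/JSON or an R list);
  `inst/cli/enantiopore.R` is a thin command-line wrapper.

## Worked example

Simulate 20 s of the reduced (+TCEP) l-AVP condition, detect and filter
events, and fit the blockade-level peak:

```r
library(enantiopore)

cfg <- avp_sim_config("l_tcep", duration = 20, seed = 42)
trace <- simulate_trace(cfg)
events <- filter_events(detect_events(trace))
fit <- fit_blockade_peaks(blockade_histogram(events), "gaussian",
                          population_window("TCEP"), seed = 1)
print(attr(events, "baseline"))
print(fit)
```

```
<baseline_stats> I0 = 259.19 pA, sigma = 3.305 pA, threshold = I0 - 7 sigma = 236.06 pA
<blockade_fit> gaussian in window [0.4, 0.8] (TCEP)
  component 1 (dominant): mean 0.530 +/- 0.000, sd 0.020, amplitude 228.7
```

The baseline estimate recovers the configured open-pore current
(259.22 ± 3.33 pA for this condition) and the fitted most probable
normalized blockade level (0.530) recovers the population mean (0.53):
a reduced l-AVP blocks about 53% of the open-pore current. The
`+/- 0.000` is the spread over the three randomized-start fit repeats.

Classification works on the second principal component. Using the
reported per-peptide band parameters directly:

```r
band_D <- pc2_band(-0.039, 0.043, "D")
band_L <- pc2_band(0.047, 0.035, "L")
x_d <- simulate_pc2_samples(band_D, 4000, seed = 1)
labels <- monte_carlo_classify(x_d, band_D, band_L, seed = 2)
print(evaluate_confusion(labels, rep("D", 4000)))
```

```
<confusion_matrix>
    predicted
true    D    L unlabeled
   D 3193  799         8
   L    0    0         0
  success: D 79.8%, L NA%; overall 79.8%
  false positives: D NA%, L 20.0%
```

About 80% of d-class draws are labeled d under the
density-proportional band rule; the remainder mostly fall in the band
overlap and draw the other label. See the methods vignette
(`vignettes/enantiopore-methods.Rmd`) for why this ideal-draw rate
exceeds the recognition rates measured on real events.

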