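---
title: "Methods: simulation, event analysis and enantiomer classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, event analysis and enantiomer classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enantiopore)
```

## The problem

A wild-type aerolysin nanopore in a lipid bilayer can discriminate the
two enantiomers of arginine-vasopressin (l-AVP vs d-AVP, differing only
in the chirality of Arg8). Each peptide entering the pore transiently
blocks the ionic current; the blockade depth, its duration and its
internal fluctuations carry the discriminating signal. `enantiopore`
implements the complete analysis chain for such recordings — event
detection and featurization, distribution fitting, and PCA-based
enantiomer classification — together with a trace simulator so every
stage is testable without access to experimental data.

## The current-trace simulator

`simulate_trace()` builds a recording sample by sample at 250 kHz (4 us
per sample) around an open-pore current $I_0$ (≈250 pA at 110 mV in
4 M KCl). Events arrive as a Poisson process per population, dwell for
exponentially distributed times, and depress the current to
$I_0(1-g)$, where the normalized blockade $g$ is Gaussian per
population. The whole trace then passes a low-pass filter at 5 kHz.

Key modelling choices:

* **Filter family.** The acquisition chain reports only a 5 kHz
  low-pass. We use a Gaussian-response FIR with its −3 dB point at the
  cutoff (`lowpass_filter()`); it is linear, so simulating unfiltered
  and filtering afterwards is bit-identical to filtering inside the
  generator, and it is swappable for another kernel.
* **Noise amplitudes are post-filter.** Recorded noise figures (e.g.
  $I_0 = 243.82 \pm 1.77$ pA for native l-AVP) are measured on filtered
  traces, and the 1 pA bumping-rejection floor acts on filtered
  in-event noise. The generator therefore interprets
  `baseline_noise_sd` and `intra_event_noise_sd` as *measured*
  amplitudes and pre-amplifies the injected white noise by the filter's
  noise-bandwidth ratio (≈4.85 at 250 kHz/5 kHz). The defaults — the
  per-condition reported baseline sds, 3 pA in-event — keep simulated
  events comfortably above the rejection floor, as real events are.
* **Population parameters.** Blockade means, dwell scales and total
  event frequencies per condition are the reported per-condition values
  (`avp_populations()`). Three quantities are not reported and are
  package choices, fixed once: population blockade widths (sd 0.015
  for Type II, 0.02 for Type I and TCEP — read off the histogram peak
  widths), the TCEP dwell scale (900 us; only "long" is reported), and
  the within-condition rate split (15% Type I / 85% Type II, the
  Type II share split 70:30 IIa:IIb following the saddle:open conformer
  ratio known for l-AVP from NMR).
* **Overlaps and edges.** An arrival that would overlap an existing
  event is redrawn (duty cycles at the reported rates are low);
  configurations whose expected duty cycle exceeds 50% are rejected.
  Onsets sit on sample boundaries; sub-sample jitter is not modelled.
* **Ground truth.** Every simulated event is recorded in a ledger
  (population, onset, dwell, true blockade) that downstream recovery
  tests compare against.

What the generator does *not* emulate: baseline drift, capacitive
transients, multi-level event substructure, and — importantly — the
correlation structure that concentrates the measured PC2 distribution
(see "Limitations").

## Event detection and the five parameters

`estimate_baseline()` finds $I_0$ and $\sigma$ by iterative 3-sigma
clipping started at the dominant density mode, which tolerates heavy
event contamination; a trace whose dominant level holds less than ~55%
of samples is rejected as bimodal rather than silently averaged. The
detection threshold is $I_0 - 7\sigma$.

An event spans from the first to the last sample below threshold
(`detect_events()`); its dwell time is that span. Because the threshold
is crossed early on the filter-smoothed falling edge, the detected span
slightly exceeds the true dwell (by roughly the filter rise time); the
dwell-time fits are insensitive to this constant shift, and the ledger
tests bound it.

For the level statistics ($I_b$, $I_{b,\min}$, $I_{b,\max}$, $I_{bs}$),
`extract_features()` uses a *settled core*: event edges are relocated
to the half-amplitude crossings — which coincide with the true edges of
a filtered step — and three filter time-constants are trimmed inside
each edge. Without this, filter rise/fall samples bias the mean
blockade shallow by 1–2% of $I_0$. For events shorter than the
combined trim the core shrinks, leaving a small residual shallow bias
on sub-300 us events; the end-to-end recovery tests bound the effect on
fitted modes to below 0.005.

`filter_events()` applies the standard cuts: dwell ≥ 200 us
(inclusive), in-event sd ≥ 1 pA (bumping), normalized blockade ≥ 0.2.
Removal counts per criterion are logged and conservation is asserted in
the tests.

## Distribution fitting

* **Blockade histograms** are binned at 0.005 over [0, 1].
  `fit_blockade_peaks()` fits one or two Gaussians by
  Levenberg–Marquardt least squares inside a selection window (Type I:
  0.7–0.8, Type II: 0.35–0.55, TCEP: 0.4–0.8). Following the
  three-independent-fits convention, each fit is repeated from
  moment-based starts perturbed by ±20%; the reported value is the mean
  over repeats and the uncertainty their sd. Two numerical safeguards
  matter in sparse or truncated windows (the Type I peak at 0.71 sits
  at its window's edge): per-bin Poisson shot-noise weights
  (1/max(count, 1)), and rejection of repeats that stall in a clearly
  worse local minimum (weighted RSS > 1.5× the best repeat) before
  averaging. Bi-Gaussian starts come from the two strongest smoothed
  histogram maxima at least four bins apart, falling back to a moment
  split at the windowed weighted mean. A bi-Gaussian whose components
  collapse within one bin is flagged and refitted as a single Gaussian.
* **Dwell times** are binned logarithmically (30 bins/decade); the
  per-bin *density* (count/width) is fitted with $A e^{-t/\tau}$ over
  bins at or above 200 us, with empty bins up to the last occupied one
  retained (dropping them censors the tail and inflates $\tau$) and
  inverse-variance Poisson weights. $\tau$ is the decay constant of
  the surviving tail; no correction is applied for filter attenuation
  of short events. `dwell_mle()` (mean excess over the truncation
  point) is the closed-form cross-check.
* **Event frequency** comes from interevent start-to-start times binned
  at 2 ms and fitted with a single exponential (two-pass Poisson
  weights; the dead-time-depleted first bin is excluded). The fitted
  decay measures the capture intensity *while the pore is free*; the
  reported rate applies the dead-time correction
  $k = k_{decay}/(1 + k_{decay}\,\bar t_{dwell})$, below 2% at native
  rates but ~15% at the 153 Hz TCEP rate.

## PCA and Monte Carlo enantiomer classification

`fit_pca_model()` standardizes the five event parameters (dwell, mean /
minimum / maximum blockade, in-event sd) with the *reference* dataset's
mean and sd, eigen-decomposes their correlation matrix and keeps PC1
and PC2. Two sign conventions pin down the eigenvector ambiguity: the
dominant PC1 loading is positive, and PC2 is oriented so the reference
main peak has negative mean. Every later dataset — the other peptide,
mixtures — is standardized with the reference normalization and
projected through the same matrix (the reference-matrix convention;
without it, reusing the d-peptide correlation matrix would be
meaningless).

`fit_pc2_band()` fits a Gaussian to the dominant PC2 peak inside a
window of mode ± 2 robust sd (excluding the secondary shoulder), giving
the per-peptide band $[\mu - 3\sigma, \mu + 3\sigma]$ (closed
interval; ~99.7% of that peptide's events fall inside).

`monte_carlo_classify()` labels each event by where its PC2 falls:
outside both bands → unlabeled; inside exactly one band → that label;
inside both → a random draw with probability proportional to the two
band Gaussian densities at that point, with equal class priors (the
mixture composition is the unknown being estimated; a prior-weighted
variant is available via the `priors` argument). The closed-form
expectation of this rule — $\int f_c^2/(f_D+f_L)$ over the overlap plus
the single-band mass — is verified against simulation in the tests.
This density-proportional reading was chosen because the reported
success rates lie well below the MAP optimum for the reported band
separation, which rules out a deterministic density-comparison rule;
a coin-flip overlap rule was rejected as strictly worse than either.

For the reported band parameters ($\mu_D = -0.039$, $\sigma_D = 0.043$;
$\mu_L = 0.047$, $\sigma_L = 0.035$; a second, mutually inconsistent
pair of d-band values circulates for these recordings — it matches the
l-band values and violates the negative-mean orientation, so it is
treated as a transcription swap and not used) the rule's expected
per-class recall on ideal Gaussian draws is ≈81% with ≈19% false
positives. The reported recognition rates on measured events are
71–75% with ~22% false positives; measured PC2 distributions are not
exactly Gaussian, and the gap
between the ideal-draw expectation and those empirical rates is
documented in the acceptance tests rather than tuned away, since no
plausible stochastic band rule reproduces the empirical rates from
ideal Gaussian draws (the attainable range at this band separation is
~61% for coin-flip assignment up to ~86% for MAP).

`evaluate_confusion()` scores predictions against the true condition of
origin; per-class success is recall, the per-class false-positive rate
is the fraction of the *other* class labeled as this class, and overall
success counts correct labels over all evaluated events.
`estimate_mixture_ratio()` reports the L/D count ratio among labeled
events with an exact-binomial interval transformed to the ratio scale.
`logistic_baseline()` is the rejected comparison method: a linear
logistic classifier on PC1/PC2 trained on a 20% split.

## Problem sizes and reproducibility

The end-to-end recovery analyses simulate 20–180 s of recording per
condition (5–45 million samples), chosen so each condition retains at
least 1700 events after filtering — the per-experiment floor of the
study — while a full acceptance run stays within minutes on one CPU.
Every stochastic stage takes an explicit integer seed; the pipeline
derives one seed per stage from a master seed, and identical seeds
reproduce every reported number exactly.

## Known limitations

* The generator draws the five parameters of each event independently
  given its population. Real events couple them (conformational
  dynamics modulate depth, noise and dwell jointly), which is what
  concentrates the measured PC2 main peak into a narrow band. Simulated
  traces therefore separate enantiomers on PC2 much more weakly than
  measured ones, and full-trace classification success is near chance;
  classification performance is instead assessed on PC2-level
  simulations from the fitted or reported band Gaussians, which is also
  how the acceptance analyses are defined.
* Dwell times carry a constant detection inflation of roughly the
  filter rise time; dwell *scales* are unbiased but absolute dwell
  values near the 200 us cut are shifted.
* Baseline drift within a recording is not modelled and not corrected;
  $I_0$ is estimated once per recording.
* The ABF acquisition format is not read; traces exchange as raw
  float + JSON sidecar or CSV (`write_trace()`, `write_trace_csv()`).
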