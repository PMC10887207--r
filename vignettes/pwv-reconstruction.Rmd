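---
title: "Measuring pulse wave velocity from low-rate recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pulse wave velocity from low-rate recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvrecon)
```

## The measurement model

Pulse wave velocity is estimated from two pulse channels recorded a short
distance $d$ apart along an artery. Writing $t_p^{(k)}$ and $t_d^{(k)}$ for
the systolic peak times of beat $k$ on the proximal and distal channel, the
per-beat pulse transit time and velocity are

$$\mathrm{PTT}_k = t_d^{(k)} - t_p^{(k)}, \qquad
  \mathrm{PWV}_k = \frac{d}{\mathrm{PTT}_k}.$$

With $d$ of a few centimeters, $\mathrm{PTT}$ is a handful of milliseconds,
far below the sample period of a wearable-friendly acquisition rate. The
package's premise is that this does not matter: the pulse waveform is
band-limited well below half of even a 250 Hz rate, so by the sampling
theorem the continuous waveform — and hence the continuous-time peak
location — is fully determined by the low-rate samples. Reconstruction to a
fine grid (default 10 kHz) followed by on-grid peak picking recovers the
transit time at the fine grid's resolution.

Assumptions worth stating explicitly:

* the distal channel is, over one recording, a nearly pure delay of the
  proximal channel (the morphology change over 3.2 cm of artery is
  negligible relative to the peak width);
* all signal and interference content lies strictly below half the
  acquisition rate — this must be *engineered* (shielding, or choosing
  `fs` above twice the highest interference harmonic), because content above
  Nyquist folds into the pulse band where no later filter can remove it
  (see `alias_demo()`);
* beats are separated by more than 0.333 s (heart rate below ~180 BPM).

## Reconstruction: rational polyphase sinc interpolation

`resample_bandlimited()` changes the rate by a rational factor $p/q$
(both $\le 10^4$): zero-stuff by $p$, filter, keep every $q$-th sample. The
filter is a Blackman-windowed sinc low-pass with cutoff
$\min(f_s, f_{target})/2$ and $20\max(p,q)+1$ taps, giving a stopband of
roughly 74 dB — comfortably above the 60 dB floor a pulse signal with ~1%
noise needs. Two details matter for PTT work:

* **Zero phase.** The FIR is linear-phase with odd length, and exactly its
  integer group delay is discarded, so every waveform feature keeps its
  absolute time. Any uncompensated phase would bias PTT directly, which is
  the quantity of interest.
* **Exact DC.** The signal mean is removed before filtering and restored
  afterwards, so constants survive to machine precision (the polyphase
  branch sums would otherwise leave ~$10^{-4}$ ripple on a constant).

The output length convention is $\lceil n p / q \rceil$. Edges: a
windowed-sinc interpolator is unreliable within about half a filter length
of the ends; all fidelity comparisons trim 0.5 s per edge, and the 10 Hz
low-pass below has a 0.55 s half-length at 10 kHz, so beat-level tests treat
the first and last ~0.6 s as transient.

`lowpass10()` uses the same design (cutoff 10 Hz, transition 5 Hz, hence
$\approx 1.1 f_s$ taps), normalized to unit DC gain and group-delay
compensated. At 60 Hz its attenuation is ~74 dB; a 60 Hz tone at
$f_s = 250$ Hz leaves residual RMS below $10^{-7}$ of the input.

## Peak detection and pairing

Peaks are *grid* maxima, deliberately without sub-sample interpolation:
the resolution comparison between native-rate and reconstructed analyses is
meaningful only if both read timing off their sample grids. The detector:

1. collects strict local maxima (first index on plateaus);
2. computes each candidate's topographic prominence;
3. prunes to a minimum separation of 0.333 s, keeping taller peaks — this
   removes the dicrotic bump (~0.25 s after systole) and noise maxima near
   beats;
4. keeps candidates whose prominence is at least half the *median
   prominence of the pruned set*, a robust proxy for the typical beat
   amplitude.

Ordering note: pruning before thresholding is a deliberate choice. If the
median were taken over raw candidates, dicrotic peaks (prominence ~0.3 of
systolic) would sit right at the 0.5 threshold in clean signals, and in
noisy signals the many micro-maxima in the valleys would drag the median
toward zero, letting noise through. After distance pruning the surviving
population is essentially "one candidate per beat", and the median tracks
beat amplitude as intended.

Pairing walks the proximal peaks in order and takes, for each, the earliest
unused distal peak with delay in $(0, 100\,\mathrm{ms}]$. The window is an
order of magnitude above physiological PTT over 3.2 cm (2.5–10.7 ms for
PWV 3–13 m/s) yet far below the inter-beat interval, so cross-beat
mismatches are impossible at any plausible heart rate; unmatched peaks on
either side are dropped and counted.

Validity filtering keeps PWV in $(0, 20]$ m/s — exactly 20 is retained,
only values *exceeding* 20 (or non-positive) are omitted — and the trial
summary reports the mean over valid beats, the maximum deviation from that
mean, and the omitted fraction. Per-trial means are the primary output;
per-beat tables are available in the result for pooled analyses.

## The synthetic generator: what it emulates, and what it does not

No public recordings exist for this measurement configuration, so the test
suite is built on a generator whose ground truth is known exactly:

* **Beat kernel**: two Gaussians — systolic ($a_1 = 1$, $\mu_1 = 0.15$ s,
  $\sigma_1 = 0.05$ s) and dicrotic ($a_2 = 0.35$, $\mu_2 = 0.40$ s,
  $\sigma_2 = 0.09$ s). The real pulse morphology is not published for this
  setup; the kernel was chosen because it is smooth, has one dominant
  analytically locatable maximum per beat, and is effectively band-limited
  (Gaussian spectral magnitude at 10 Hz below 1% of peak for
  $\sigma_1 \ge 0.04$ s). Any kernel with those properties would do.
* **Rhythm**: onsets at mean interval $60/\mathrm{HR}$ with Gaussian jitter
  (default HR 75 BPM, jitter SD 30 ms — resting sinus variability),
  truncated at 20% of the interval so onsets stay ordered.
* **Channels**: the distal channel is the proximal model evaluated at
  $t - \mathrm{PTT_{true}}$ (default 8 ms, i.e. PWV 4 m/s over 3.2 cm).
  Because the model is continuous, sampling at any rate and grid phase is
  exact — there is no dense-grid decimation error, and the `grid_phase`
  parameter can place a true peak exactly on a low-rate sample.
* **Disturbances**: per-channel white noise (default SD 2% of systolic
  amplitude — a clean lab-grade bioimpedance channel), common-mode mains at
  60 Hz (5%) with a 120 Hz second harmonic (2.5%), and common-mode baseline
  wander (10% at 0.2 Hz, respiration-like). The second harmonic makes the
  aliasing demonstration self-consistent: at $f_s = 125$ Hz it folds to
  5 Hz inside the pulse band, while at 250 Hz every component is below
  Nyquist and removable by the 10 Hz low-pass. Mains phases are drawn after
  the other noise streams, so switching interference on or off does not
  change the white-noise realization (the additive-linearity property the
  tests rely on). Default duration is 19 s, matching the emulated
  acquisition sessions.

What the generator does **not** model: bioimpedance physics and electrode
geometry, beat-to-beat morphology variation, amplitude modulation by
respiration, pathological waveforms, or PWV drift within a recording. A
green test therefore establishes correctness of the *signal-processing
chain* under stated noise, not clinical validity on human data.

## Numerical choices and honest tolerances

* **ZNCC at zero lag**, not max-over-lags: the pipeline is zero-phase by
  construction, so lag search would hide exactly the timing errors the
  method must not commit.
* **PTT quantization.** Each detected peak time is quantized to ±half a
  sample; the PTT, being a *difference* of two quantized times, has a
  worst-case error of one full sample period (empirically 1.6 ms occurs for
  a 9.6 ms delay at 500 Hz). Reconstruction shrinks this bound from $1/f_s$
  to $1/10^4$ s; when the true delay is an integer number of fine-grid
  samples, the two channels' rounding errors cancel and interior beats
  recover PTT exactly.
* **Noise-limited per-beat accuracy.** With white noise at 2% of pulse
  amplitude, the in-band (10 Hz) noise after filtering has SD
  $\approx 0.006$; dividing its slope by the systolic curvature
  ($a_1/\sigma_1^2 = 400\,\mathrm{s}^{-2}$) gives per-channel peak-time
  jitter with SD ≈ 0.5 ms. Individual beats at that noise level therefore
  *cannot* be guaranteed to 0.5 ms; the trial-level estimate (median over
  ~15–24 beats) can, and that is the quantity the tests assert (observed
  ≤ 0.3 ms across the delay × rate sweep).
* **Ties and degenerate inputs**: plateau maxima take the first index;
  constant signals yield no peaks and an explicit undefined-correlation
  error in ZNCC; empty pairings raise a structured empty-result error
  that preserves the counts.
* **Dominant-frequency floor** 0.5 Hz in segment spectra, excluding DC and
  baseline wander from the search.
* **Test scaling**: property sweeps run on 10–12 s recordings rather than
  19 s to keep the default suite under ~20 s; the acceptance-grade 19 s
  scenarios are exercised in the acceptance tests and script.

## Known limitations

* The rate ratio must be rational with numerator and denominator ≤ $10^4$;
  arbitrary irrational ratios are refused rather than approximated silently.
* Peak-based fiducials assume a single dominant maximum per beat; waveforms
  whose dicrotic wave rivals the systolic peak (severe aortic regurgitation,
  some catheter artifacts) would need a different fiducial. The detector
  parameters are exposed so an alternative rule can be swapped in.
* The pipeline is offline and batch: no streaming, no IIR filtering, and no
  wavelet/compressed-sensing reconstruction.
* File I/O covers the package's own CSV dialect only; vendor formats (and
  EDF/WFDB) are out of scope.
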