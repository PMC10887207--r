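# pwvrecon

Pulse Wave Velocity (PWV) from low-sampling-rate pulse-pair recordings via
bandlimited signal reconstruction.

## The problem

PWV — the speed at which the arterial pressure pulse travels along an artery —
is a standard marker of arterial stiffness and cardiovascular risk. Measuring
it with two transducers spaced a few centimeters apart (e.g. bioimpedance
electrodes 3.2 cm apart over the radial artery) requires resolving a pulse
transit time (PTT) of only a few milliseconds: at PWV = 4 m/s over d = 3.2 cm
the delay is 8 ms. A 250 Hz acquisition has a 4 ms sample period — the entire
PTT spans two samples — so naive peak timing is hopeless, while sampling at
10 kHz strains wearable-device storage, bandwidth, and battery.

The way out is the Nyquist–Shannon sampling theorem: the pulse waveform is
band-limited (heart-rate fundamental 1–5 Hz plus harmonics, everything of
interest below ~10 Hz), so a 250 Hz acquisition already determines the
continuous signal exactly, provided all signal content (including interference
such as 60 Hz mains) lies below half the sampling rate. `pwvrecon` reconstructs
the signal on a 10 kHz grid by rational polyphase FIR resampling — a
finite-length realization of sinc interpolation — and recovers millisecond PTT
resolution from low-rate data.

## The method

For a proximal/distal channel pair sampled at `fs`:

1. **Reconstruct** both channels to a high rate (default 10 kHz):
   upsample by `p`, apply a Blackman-windowed sinc anti-imaging FIR with
   cutoff `min(fs, target)/2` (stopband > 70 dB, linear phase, integer group
   delay removed exactly), decimate by `q`, where `target/fs = p/q`.
2. **Filter** with a zero-phase 10 Hz FIR low-pass (Blackman-windowed sinc,
   ~5 Hz transition) to remove mains interference and wideband noise.
3. **Detect** systolic peaks as strict local maxima on the sample grid
   (prominence-gated, ≥ 0.333 s apart; no sub-sample interpolation — the
   timing resolution is the point being measured).
4. **Pair** each proximal peak with the earliest distal peak within
   (0, 100 ms], compute per-beat `PTT = t_dist − t_prox` and
   `PWV = d / PTT`.
5. **Validate**: PWV values exceeding 20 m/s or at/below 0 m/s are
   physiologically implausible and omitted; the mean PWV, maximum deviation,
   omitted fraction, and heart rate (60 / mean inter-beat interval) are
   reported.

Reconstruction fidelity is quantified by zero-lag zero-normalized
cross-correlation (ZNCC) between a high-rate reference and the
reconstruction, and by Blackman-windowed 5 s segment spectra; the
`alias_demo()` diagnostic shows how interference above `fs/2` (e.g. a 120 Hz
mains harmonic sampled at 125 Hz) folds irremovably into the pulse band.

A synthetic two-channel generator with exactly known ground truth (beat
onsets, true PTT, band content) backs the test suite: quasi-periodic
two-Gaussian pulses (systolic + dicrotic), a pure-delay distal channel, white
noise, 60 Hz mains with harmonics, and baseline wander.

## Worked example

```r
library(pwvrecon)

cfg <- synth_config(duration = 19, heart_rate_bpm = 75, ptt_true = 0.008, seed = 1)
rec <- generate_recording(cfg, fs = 250)   # 2 x 4750 samples, d = 0.032 m

raw <- analyze_recording(rec)              # native 250 Hz grid
head(1000 * raw$beat_pairs$ptt)
#> 12  8  8  8  8  8                        # PTT quantized to 4 ms steps

res <- analyze_recording(rec, reconstruct_to = 10000)
head(1000 * res$beat_pairs$ptt)
#> 9.6 8.4 7.9 8.4 7.3 7.6                  # millisecond resolution restored
res
#> <pwv_result> mean PWV 4.118 m/s (max deviation 1.043),
#>              24/24 beats valid (omitted 0.0%), HR 74.3 BPM
```

The true PWV here is `0.032 / 0.008 = 4 m/s`; at the native 250 Hz grid each
beat's PTT can only be a multiple of 4 ms, while after reconstruction the
per-beat values scatter around 8 ms with the configured measurement noise and
the trial mean lands within a few percent of truth.

The same pipeline is scriptable:

```sh
inst/cli/pwv synth --out rec.csv --fs 250 --duration 19 --seed 1
inst/cli/pwv analyze --in rec.csv --reconstruct-to 10000
inst/cli/pwv alias-demo --fs-list 125,250 --seed 1
```

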