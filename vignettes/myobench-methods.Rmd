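---
title: "Simulating surface-EMG measurement and myoelectric pattern recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating surface-EMG measurement and myoelectric pattern recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myobench)
```

## The problem

Myoelectric prostheses are driven by surface electromyography (sEMG):
voltages below 1 mV recorded on the skin over residual forearm muscles,
amplified differentially, filtered, and classified into motion commands.
Signal quality is dominated by the measurement chain rather than by the
classifier: the two inputs of the differential amplifier each see a *source
impedance* (tissue + skin-electrode interface + electrode), and any imbalance
between the two arms converts common-mode interference — mains radiation at
50 Hz and its harmonics, or the tone of an impedance meter — into a
differential error that the amplifier then treats as signal.

`myobench` provides a seeded, fully synthetic bench for this whole chain: a
stochastic muscle-source generator, electrode-transfer models for gelled
Ag/AgCl ("wet") and dry conductive-polymer fabric ("PPy") electrodes, an
instrumentation front end with impedance-imbalance-driven common-mode
coupling, filtering and rail saturation, a sliding-FFT + neural-network
motion classifier, and the evaluation analyses, together with packaged
reference tables whose printed summary statistics the analysis functions
reproduce exactly.

## The source model

No generative model of the human sEMG is given in the reference material, so
the generator uses the simplest process with the needed statistical
structure: band-pass-filtered Gaussian white noise (default 20–450 Hz at
1600 Hz sampling, a 4th-order zero-phase Butterworth), normalized to unit
RMS and scaled by a per-motion, per-channel activation amplitude with a
raised-cosine onset (default 100 ms). Five motion classes are modelled
(relax, close, open, flexion, extension). The default 5 × 3 envelope matrix
gives each active class a distinct dominant channel with amplitudes up to
1 mV RMS and sets the rest class two orders of magnitude lower (1 % of the
maximum), making the five classes separable by design. This is what passing
classifier tests demonstrate: that the pipeline recovers structure *that the
generator put in*. Real sEMG adds nonstationarity, electrode shift, fatigue
and crosstalk that this carrier model deliberately omits, so bench
accuracies say nothing about clinical accuracy — only about the correctness
of the pipeline.

The electrode views are linear: the wet view has a slightly larger broadband
gain (×1.1), the PPy view a +3 dB zero-phase shelf above 150 Hz, plus
independent white measurement noise (default 0.2 µV/√Hz). Published
comparisons of the two electrode types report these differences only
qualitatively ("slightly larger", "higher above 150 Hz"), so the magnitudes
are configuration defaults, not claims. The shelf is realized exactly in the
frequency domain; with zero tilt the transfer is exactly a scalar gain,
which makes power-conservation and identity contracts testable to machine
precision.

## Impedance imbalance and common-mode coupling

Each amplifier arm sees a complex source impedance, represented — as in the
switched measurement protocol it emulates — by a single magnitude/phase pair
at 300 Hz plus a series trimmer (0–200 kΩ). The imbalance indices are the
absolute difference of arm magnitudes and of arm phase angles. The packaged
per-level reference table gives mean/SD pairs of these indices at three
rest-state noise levels; `drawImpedanceStates()` samples imbalances from
zero-truncated normals *moment-matched* to those pairs and splits them
symmetrically around a 50 kΩ ∠ −20° baseline. Plain truncation of a
N(mean, SD) at zero would bias the level-1 sample mean upward by ~10 %, so
the parent parameters are solved numerically instead. One cell is
irreducible: the level-1 phase target (mean 1.14°, SD 1.32°) has a
coefficient of variation above 1, the supremum attainable by any
zero-truncated normal; the least-squares match (mean 1.23°, SD 1.20°) is
used and still keeps 1000-draw sample means within three standard errors of
the target.

Coupling follows the textbook potential-divider model: with common-mode
input impedance $Z_{in}$ and arm impedances $Z'_k = Z_k + R_k$, the
common-mode→differential conversion gain is

$$ g \;=\; Z_{in}\!\left(\frac{1}{Z_{in}+Z'_1} - \frac{1}{Z_{in}+Z'_2}\right)
   \;+\; 10^{-\mathrm{CMRR}/20}, $$

the intrinsic-CMRR term being the amplifier's own leakage floor. $|g|$ is
strictly increasing in the complex arm difference $|Z'_2 - Z'_1|$. Note the
distinction, kept explicit throughout: the *tabulated* imbalance indices are
differences of magnitudes and of phases, while the *coupling* depends on the
full complex difference.

## The front end

The simulated chain is
`clip( G2 · notch( bandpass( G1 · (v_diff + g · v_cm) ) ) )` with a 40 dB
preamplifier, a 1–1000 Hz band-pass, a 50 Hz notch (RBJ biquad, Q = 30),
a second stage, and hard ±9 V rails. Filters are applied forward-backward
for zero phase. Two numerical choices deserve note:

* **Band edge vs Nyquist.** At the 1600 Hz sampling rate the 1000 Hz analog
  band edge lies above the 800 Hz Nyquist frequency; a digital edge there is
  meaningless, so edges at or above Nyquist are treated as out of the
  sampled band and only the high-pass half plus the notch act. The default
  design keeps passband ripple below 1 dB from 10 to 500 Hz and attenuates a
  pure 50 Hz tone by more than 30 dB.
* **Second-stage gain.** Chosen (26 dB, total gain ×2000) so the ~3σ peak of
  the strongest 1 mV RMS class reaches about two thirds of the rails,
  leaving headroom for interference while keeping saturation rare in clean
  recordings.

Two defaults of the bench amplifier are engineering values rather than
reported ones. The intrinsic CMRR is set to 120 dB (typical of an
instrumentation amplifier at gain 100; the class default is a conservative
100 dB) because a 100 dB leakage floor would compress the three noise
levels' output bands together, contradicting their defining ranges. The
mains common-mode amplitudes (tens of volts, most of it in harmonics since
the 50 Hz fundamental is notched away) were calibrated once, analytically,
so that the *mean* per-level imbalances place a rest-state recording in the
three defined bands — peaks below ~1 V at level 1, within ±6 V at level 2,
reaching the ±9 V rails at level 3 — mirroring the observed dominance of the
100/200/300 Hz lines in rest-state spectra. Because level draws have large
spread, level recovery from single simulations is majoritarian, not certain;
that is inherent to the published per-level variability, not a bug.

The impedance-meter protocol is modelled by `applyMeterSchedule()`: during
each scheduled interval the 1 Vrms 300 Hz measurement tone is injected, and
since 1 Vrms × 40 dB exceeds the rails by an order of magnitude the output
saturates for the whole interval. The interval plus a 50 ms settling margin
per side is marked in the trace's exclusion mask; every analysis operation
skips masked samples. `excludeSaturated()` provides the data-driven
counterpart (run-length scan over a threshold).

## The classification pipeline

Traces are segmented into 128 ms epochs every 10 ms. At 1600 Hz that is a
205-sample window advanced by 16 samples; offline, a 2 s trace yields
⌊(3200−205)/16⌋+1 = 188 epochs, while the streaming convention (a decision
every stride using the trailing window, buffer pre-filled) yields exactly
200 decisions per 2 s — both conventions are implemented.

Features are smoothed FFT powers at 31, 55, 78, 102, 148, 195, 258 and
320 Hz per channel (24 values over 3 channels, channel-major). The epoch DFT
is taken at its native length of 205 samples, giving a bin width of
1600/205 = 7.80 Hz under which the eight frequencies fall within half a bin
of bins 4, 7, 10, 13, 19, 25, 33, 41 — the printed frequencies are almost
exact multiples of 1/0.128 s, which is why the native-length DFT was chosen
over zero-padding to 256 (6.25 Hz bins would scatter the same frequencies
between bins). The power spectrum is smoothed by a 3-bin moving average
(half-width 1, configurable; the width is not reported anywhere, the default
is ours) before the feature bins are read. Features scale as amplitude
squared and are non-negative by construction.

The classifier is a 24-32-5 feed-forward network with logistic activations,
trained by full-batch backpropagation on mean squared error against one-hot
targets (loss averaged over samples). Inputs are standardized with training
statistics stored in the model — raw band powers span orders of magnitude,
and a sigmoid network does not train on them directly. Learning rate 0.1,
2000 passes, seeded uniform(−0.5, 0.5) initialization; all configurable and
none a reported value. Ties in the output layer resolve to the lowest-index
class. Training is deterministic given the seed, and the loss trace is
non-increasing under the defaults.

## Evaluation analyses

* `rmsEnvelope()`: sliding RMS (default 100 ms window, 10 ms step — the
  window is a package default, not a reported value), skipping excluded
  samples; fully-excluded windows are `NA`.
* `pearsonCorr()`: product-moment correlation of two envelopes; zero
  variance is an error, not a silent `NA`.
* `meanSd()`: mean and n−1 sample SD. The n−1 convention is fixed
  package-wide because it reproduces the packaged tables' printed SD rows
  exactly.
* `classifyNoiseLevel()`: peak-amplitude banding of a rest trace (< 1 V /
  below 6 V / reaching ≥ 6 V). The 1 V level-1 bound is a default — the
  level is only described as "little noise" — and nothing downstream depends
  on its exact value.
* `reproduceTables()`: recomputes every printed Mean/SD summary cell from
  the packaged per-trial tables and compares at printed precision
  (half-away-from-zero rounding, applied only at comparison time). Two cells
  are known to disagree with exact decimal arithmetic because the published
  summaries were evidently computed from unrounded underlying data: the
  level-1 phase mean (values average 1.14, printed 1.2; compared with ±0.1)
  and the extension-task wet accuracy mean (exactly 83.35 from the printed
  cells, printed 83.3; covered by the half-unit tolerance). Both are
  flagged, neither is "corrected".

## The bench

`runBench()` ties the stages into one seeded experiment (a master seed fans
out deterministically into per-stage child seeds): correlation of wet/PPy
views of common sources; a classifier trained per electrode condition on
level-1 front-end output (default 4 s per class ≈ 1940 training epochs) and
evaluated on held-out 2 s segments (200 decisions per task) at levels 1–3;
imbalance summaries over 1000 draws per level; and rest-state noise
classification. Problem sizes are chosen so a full bench run takes seconds;
they are configuration, and the report records the seed and a configuration
fingerprint. The held-out segments are generated with a 189-sample lead-in
so each nominal 2 s task yields exactly 200 fully-windowed decisions.

Expected behaviour of the defaults, all covered by tests: level-1 held-out
accuracy ≥ 95 % with relax the most recognizable task; accuracy
non-increasing from level 1 to 3 for a fixed model; permuted labels at
~20 % chance; wet/PPy envelope correlation > 0.95 at low noise, decreasing
as independent noise grows; harmonic-band rest noise strictly ordered
level 1 < 2 < 3.

## Known limitations

The carrier model has no motor-unit structure, no fatigue, no electrode
shift, and a white (not 1/f) noise floor; the impedance model uses a single
300 Hz representative value rather than a spectrum; magnitude and phase
imbalances are drawn independently although they are likely correlated in
vivo; the meter tone is injected at the output stage rather than through the
full electrode divider. Each of these is a deliberate simplification: the
bench exists to make the measurement-chain computations testable, not to
replace recordings.
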