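---
title: "Compact continuous-time networks for 12-lead ECG abnormality detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact continuous-time networks for 12-lead ECG abnormality detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ncpecg` implements a compact multi-label classifier for six ECG
abnormalities — first-degree atrioventricular block (1dAVb), right and left
bundle branch block (RBBB, LBBB), sinus bradycardia (SB), atrial
fibrillation (AF) and sinus tachycardia (ST) — built from
neural-circuit-policy (NCP) wiring over continuous-time recurrent neurons.
This vignette documents the model, its assumptions, the tunable parameters,
the numerical choices, and what the bundled synthetic generator does and
does not establish.

## Preprocessing

Raw 12-lead recordings (millivolt traces, 400 or 500 Hz) pass through four
stages, in this order:

1. **Band-pass filtering.** A Butterworth band-pass with passband
   0.5–40 Hz retains the P wave, QRS complex and T wave while removing
   baseline drift and 50 Hz powerline interference. The order (default 4)
   is configurable. The filter is applied zero-phase — the squared
   magnitude of the designed transfer function is applied in the frequency
   domain with odd-reflection padding. Two reasons: zero phase keeps
   P/QRS/T timing unshifted, which matters because two of the six classes
   are defined by timing; and the 0.5 Hz lower edge places the filter's
   poles so close to the unit circle that direct-form time-domain
   recursions lose around six digits of accuracy, while the
   frequency-domain application stays linear to machine precision.
   Filtering precedes resampling so it also acts as an anti-aliasing
   guard.
2. **Resampling** to 500 Hz by the Fourier method (spectrum truncation or
   zero-extension), which is exact for band-limited content and processes
   all channels in two FFTs; the usual periodic-extension caveat applies
   near record edges.
3. **Length normalization** to exactly 4096 samples per channel: longer
   recordings keep their first 4096 samples (preserving the recording
   onset), shorter ones are zero-padded at the tail so no observed data is
   discarded. The operation is idempotent.
4. **Short-time Fourier transform.** Each channel is framed (default: 128
   samples per window, hop 64, periodic Hann taper) and the windowed DFT
   is taken per frame; the magnitude of the non-negative frequencies (65
   bins) forms the `12 × 65 × 63` spectrogram tensor. Window length, hop,
   taper and magnitude/complex output are configurable and recorded with
   every artifact. The defaults trade time resolution (128 ms hop) against
   frequency resolution (3.9 Hz bins): beats appear as broadband bursts
   one to two frames wide, which is the temporal granularity the recurrent
   cell consumes.

## Wiring

The NCP graph has four layers — 75 sensory, 6 inter, 8 command and 6 motor
neurons by default (the published architecture fixes 75 sensory, 14
inter+command, 6 motor; the 6/8 split of the 14 is this package's choice,
favoring command capacity because the command layer is the representation
the readout consumes).
Synapses are inserted by three seeded stochastic mechanisms: each source
draws `fanout_per_source` (default 4) distinct candidate targets in the
next layer, inserting each with probability `p2 = 0.5`; targets left with
no afferents receive a Binomial(`p3 = 0.6`)-sized bundle from the previous
layer, redrawn until at least one synapse lands, so no non-sensory neuron
is orphaned; and `n_recurrent_draws = 4` candidate command-to-command
recurrences are inserted with probability `p4 = 0.3` each. Candidate draws
without replacement make the mechanism-1 out-degree exactly
Binomial(fanout, p2), so its mean is `fanout * p2`. Duplicate synapses are
collapsed.

Polarities `E_ij ∈ {−1, +1}` are sampled uniformly at wiring time and
frozen — they are structural, not trained. One refinement proved necessary
in practice: when a target neuron's afferents all carry the same sign, its
input-driven response is locked to one direction (a motor neuron with only
inhibitory afferents can lower its score in response to input but never
raise it), which freezes part of the readout regardless of training. When
a target has at least two afferents, one randomly chosen synapse is
therefore flipped so both signs occur. Training runs without this guard
showed exactly the predicted pathology: classes whose motor neuron drew
single-sign afferents ended with inverted or flat score rankings.

A second readout refinement follows the same logic. With stochastic motor
fan-in, each motor neuron reads only two or three of the command neurons,
so whether a class is learnable depends on a wiring lottery: in stalled
training runs, linear probes of the command states recovered a class
essentially perfectly while the class's own motor neuron — wired to other
command neurons — stayed flat. The default wiring
(`motor_fanin = "full"`) therefore connects every motor neuron to every
command neuron; the trunk (sensory through command) keeps its stochastic
sparse wiring, and `motor_fanin = "sparse"` restores the fully stochastic
graph.

## Cells

**LTC.** Each state neuron follows the liquid time-constant dynamics: the
potential decays toward its resting value `x_leak` with time constant
`tau = Cm/gl`, while each afferent synapse contributes a conductance
`w · sigma(gamma (x_src − mu))` pulling the potential toward its polarity.
The solver is the semi-implicit Euler update — the new state is a
positively weighted average of the previous state, `x_leak`, and the
polarities, with weights `Cm/Δ`, `gl`, and the synaptic conductances. This
form is unconditionally stable and bounds the state by
`max(1, |x_leak|)`. Defaults: `Δ = 1` model time unit and `n_unfold = 6`
sub-steps per spectrogram frame.

Positivity of `Cm`, `gl` and `w` holds by construction through a softplus
reparameterization. Initialization: `Cm`, `gl` and `w` log-uniform in
`[0.4, 0.6]` (`cm_scale` rescales the capacitance draw; at the default
scale of 1 the membrane time constant is comparable to the step, so the
state settles near its frame-conditional fixed point within the
`n_unfold` sub-steps and the cell acts as a well-conditioned implicit
readout — temporal memory lives upstream in the ConvLSTM. A large
`cm_scale` instead turns the cell into a slow evidence integrator, which
in our experiments trained markedly worse); `x_leak` at zero.
Sigmoid midpoints are centered on the presynaptic operating range:
`[0.3, 0.8]` for sensory-sourced synapses (sensory values are sigmoid
outputs in (0, 1)) but `[−0.2, 0.2]` for state-sourced synapses, because
state potentials swing around zero and a midpoint outside the presynaptic
range leaves the synapse in the flat tail of its sigmoid, where it neither
transmits nor learns.

**CfC.** The closed-form cell avoids the ODE solve: the new state blends
two tanh-bounded affine compartments `g` and `h` through the gate
`sigma(−f t)`, with `f` softplus-positive and `t` the elapsed time. At
`t = 0` the blend is exactly `(g + h)/2`; for fixed `f > 0` the gate
closes toward `h` as `t` grows. When unrolling over a regularly sampled
frame sequence, `t` is the time elapsed over the step — the constant frame
spacing `Δ` — so the input-dependent gate stays active at every frame; a
cumulative `t` was tried first and drives the gate to zero within a few
frames, freezing the `g` compartment out of the model entirely. All three
compartments are single affine maps of the concatenated (state, input)
vector, masked by the wiring graph (plus self-connections), so structural
sparsity is shared between the variants.

## Classifier and training

A single ConvLSTM layer consumes the spectrogram: the 12 leads are input
channels, the cropped frequency axis is the (one-dimensional) spatial
grid, frames are time. Defaults: 8 filters, kernel 3, stride 1. Bins above
40 Hz are cropped before the network — after the band-pass they are
numerically empty, so they cost computation without carrying signal. The
per-frame spatial output is flattened and densely projected (sigmoid) to
the 75 sensory neurons; a per-frame global spatial average was tried first
and discarded, because averaging over frequency positions removes the
band-localized information (QRS bandwidth, P-band energy, lead asymmetry)
that separates the morphology classes. The recurrent cell unrolls over
frames and the final motor state passes through a sigmoid — six
independent scores, no softmax, since abnormalities co-occur. The
ConvLSTM forget-gate bias starts at +2 (about 0.88 retention per frame) so
rhythm information persists across roughly a second of frames.

Training follows the fixed published protocol: Adam at learning rate 0.01,
batch 128, binary cross-entropy (scores clipped at `1e-7`), 300 epochs at
full scale, positive-labeled training instances duplicated twice (three
total appearances), an 80/20 train/validation split, no early stopping and
no learning-rate schedule. Because no automatic-differentiation framework
is available to this package, the gradients are hand-derived reverse-mode
passes through the ConvLSTM, the dense projection and both cells, verified
against central finite differences in the test suite. Gradients are
clipped at global norm 5 as a numerical safeguard. The split is stratified
by the full label pattern so per-class validation prevalences track the
global ones; duplication is applied strictly after the split and only to
the training partition. A single scalar input standardization
(mean/standard deviation of `log1p` magnitudes) is fitted on the training
partition and stored with the model.

"Accuracy" in the per-epoch log is per-label binary accuracy at threshold
0.5, averaged over the six labels — the multi-label accuracy definition is
otherwise ambiguous. The operating threshold of the evaluation report
defaults to 0.5 and is recorded in the report; precision, recall and F1
with zero denominators return 0 with a `degenerate` flag rather than NaN;
AUROC is the Mann–Whitney statistic with ties counted one half, reported
as missing when a class has only one label value.

## Synthetic generator

The real training cohorts are private, so the package ships a seeded
generator whose records are sums of Gaussian bumps (P, Q, R, S, T, and an
R' for the bundle branch blocks) on a beat train, projected onto 12 leads
with random-but-seeded per-lead gains plus a 0.02 mV noise floor. The
label semantics drive the morphology: SB draws rates in 42–53 bpm, ST in
112–145; AF draws lognormal RR jitter with coefficient of variation about
0.25 and suppresses the P bump (plus a small 5–7 Hz fibrillatory wave);
1dAVb draws PR in 240–320 ms against 130–180 ms otherwise; the bundle
branch blocks double the QRS width (about 140 ms), add an R' bump, and
scale QRS amplitudes up on the right-facing (V1–V3) or left-facing (I,
aVL, V5, V6) leads respectively. SB+ST and 1dAVb+AF are rejected as
contradictory. Balanced seven-way sampling (six classes plus normal) is
the default, with a 10% chance of one compatible secondary label.

What this establishes — and what it does not: the generator's fidelity
target is *class separability under the stated label semantics*, not
clinical realism. Real ECGs have dipole-consistent lead projections,
beat-to-beat morphology variation, wandering baselines, muscle and
electrode artifacts, and far subtler class expressions. The end-to-end
tests therefore measure whether the pipeline can learn the stated
discriminative structure from spectrograms at a fixed, deliberately small
optimization budget; they do not certify clinical performance, and the
published cohort-level scores are not reproducible from synthetic data.

Two classes are intrinsically hard for this pathway by construction.
1dAVb's signature is a P-wave timing shift of roughly 100 ms, near the
STFT hop (128 ms) — mirroring its position as the weakest class in the
published validation tables. AF's signature is a second-order temporal
statistic (the dispersion of inter-beat intervals) plus a subtle spectral
cue (suppressed P-band energy): simple engineered features recover it
almost perfectly from the spectrogram (the RR-interval coefficient of
variation of energy-burst times separates AF essentially completely), but
discovering such a statistic by gradient descent takes far more updates
than the classes expressed as static spectro-spatial patterns. In the
scaled-down training runs of the test suite (600 records, 30 epochs,
about 390 Adam updates at the published batch size and learning rate),
the classes with strong static signatures — the rate classes and the
bundle branch blocks — typically reach per-class F1 near 1.0 while AF and
1dAVb remain below the 0.5 operating threshold despite above-chance score
rankings; longer schedules in our development experiments brought 1dAVb
across as well. The macro metrics the acceptance checks compute should be
read with this class composition in mind.

## Problem sizes and numerical choices

The test suite trains the full CLTC pipeline on 600 synthetic records for
30 epochs (about 390 Adam updates) and evaluates on 150 held-out records,
then runs the CfC variant under the identical configuration; the
reproduction script (`scripts/acceptance.R`) uses 500 records and 20
epochs per variant. These sizes were chosen so a complete run stays within
desk-scale compute while leaving the learning signal measurable.
Determinism: every stochastic component (wiring, initialization,
generator, shuffling, perturbation draws) takes an explicit seed, and
derived child seeds keep streams independent; repeated runs with equal
seeds are bit-identical. Degenerate inputs are rejected early — recordings
with missing readings, filters whose upper edge reaches Nyquist, windows
longer than the signal, contradictory label sets.

## Known limitations

Hand-written gradients cover exactly the shipped architecture; structural
changes require extending the backward pass. The CSV/WFDB readers cover
the common cases (format 16, single-segment records) rather than the full
WFDB specification. Robustness sweeps re-preprocess every perturbed
record, which is faithful to acquisition-time corruption but makes the
sweeps the slowest part of the harness. The LTC solver's accuracy is
first-order in `Δ`; the step-halving and explicit-integrator checks in the
test suite quantify the discretization error rather than eliminating it.
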