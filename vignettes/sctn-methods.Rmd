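---
title: "SCTN networks for sound processing: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SCTN networks for sound processing: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sctnsim)
```

This vignette is the package's account of the science it implements: the
SCTN neuron model and its conventions, the STDP learning module, the
17-neuron resonator and the design math behind it, the PDM codec, and the
scaled sound-classification study that the test suite runs. It also
records the numerical and design decisions that were genuinely open, and
what the synthetic experiments do and do not show about real data.

## The SCTN neuron

The SCTN is a digital leaky integrate-and-fire neuron engineered for
cheap hardware: its leak is a shift-subtract multiply by
$\alpha = 1 - 2^{-LF}$ applied on a schedule rather than every tick. The
membrane update implemented by `membrane_step()` is

$$V_m(t) = \begin{cases}
\alpha\,\bigl(V_m(t-1) + \sum_j w_j I_j + \phi\bigr) + \Theta, & t \bmod LP = 0\\
V_m(t-1) + \sum_j w_j I_j + \phi + \Theta, & \text{otherwise,}
\end{cases}$$

with binary synaptic inputs $I_j$, pre-leak bias $\phi$, post-leak bias
$\Theta$, and saturating arithmetic on a bounded membrane register.

**Leak-schedule convention.** Whether the leak fires every $LP$ or every
$LP+1$ ticks is the kind of off-by-one that matters here, because the
analog cutoff of the stage depends on the leak-cycle length $T$:
$f_0 = f_{pulses}\,2^{-LF} / (2\pi\,T/\text{tick})$. This package leaks
every $\max(LP, 1)$ ticks, so

$$f_0 = \frac{f_{pulses}\,2^{-LF}}{2\pi\,LP}.$$

Three independent checks pin this convention down. With $LF=5$, $LP=73$
and a 1.536 MHz pulse clock it gives 104.65 Hz, the worked design point
that `cutoff_frequency(5, 73, 1.536e6)` must reproduce to two decimals;
the $(LP+1)$ alternative gives 103.24 Hz. On the design grid
$LF \in \{4,5\}$, $LP \in 1..200$ it spans 38 Hz to 15.3 kHz, matching
the stated detection range of that grid; the $(LP+1)$ reading caps at
7.6 kHz and cannot reach 15 kHz. And the resulting single-stage phase
shift at $f_0$ measures $-44^\circ$ in simulation, consistent with the
$-45^\circ$ first-order-filter analogy (see below). `cutoff_frequency()`
treats $LP \le 1$ as leak-every-tick, so the degenerate $LP = 0$
configuration remains well defined.

**Activation modes.** `binary` compares the membrane with a threshold
(ties fire) and resets to `v_reset`; `stochastic_sigmoid` compares with a
fresh uniform draw over the membrane bounds, which yields a
saturating-linear firing-probability curve in the membrane level — the
shape, slope and centring of the intended sigmoid are not fixed by the
model, so the uniform-draw comparator, the simplest hardware-faithful
choice (a pseudo-random generator and a comparator), is used and is part
of the configuration; `identity` re-encodes the bounded membrane as a
deterministic first-order sigma-delta spike stream and never resets. The
initial membrane and the reset potential default to zero. A constant-leak
legacy mode (`legacy_mu`) reproduces the plain LIF recursion for
regression against that model.

**Numerics.** The reference implementation uses double-precision floats
with explicit saturation bounds; this keeps the arithmetic testable
against closed forms. The hardware's fixed-point registers are not
bit-emulated — the saturation bounds are the part of the register
behaviour that shapes the dynamics, and they are modelled exactly.

## STDP: analytic rule and event-matrix realisation

The pair-based rule implemented by `stdp_delta()` is the standard
exponential window: a pair at lag $\Delta t = t_{post} - t_{pre}$
contributes $+\eta_+ e^{-|\Delta t|/\tau_+}$ when causal and
$-\eta_- e^{-|\Delta t|/\tau_-}$ otherwise, summed over all pairs.
Following the textual description of causality (a presynaptic spike that
precedes the postsynaptic spike strengthens the synapse), the causal side
is $\Delta t \ge 0$; a `causality` switch flips the convention for
sensitivity analyses. Defaults are $\eta_+ = 0.005$, $\eta_- = 0.004$,
$\tau_\pm = 15$ ms, $L_w = 16$ learning ticks of 1 ms.

The hardware-style realisation keeps, per synapse, a shift register of
recent presynaptic bits and delays the postsynaptic spike by $L_w$ ticks;
when the delayed spike emerges, each weight is incremented by the
convolution of its register with a programmable B kernel indexed by lag
$u \in [-L_w, L_w]$. With the exponential kernel sampled at the learning
tick, this is exactly the windowed pair sum — the suite checks equality
to $10^{-9}$ on random trains whose lags fit the window. One register
detail was open: a $2L_w$-bit register can only cover $2L_w$ of the
$2L_w + 1$ kernel lags, so the registers here hold $2L_w + 1$ bits and
the equivalence holds on the full closed window.

The learning clock is a decimated pulse clock (default 1 ms per tick), so
$L_w = 16$ spans ±16 ms, commensurate with the 15 ms time constants.

## The resonator

A single identity-activation SCTN stage driven by a bipolar PDM stream is
a one-pole low-pass filter: at its cutoff it attenuates by $1/\sqrt 2$
and shifts phase by $-45^\circ$, mirroring a first-order RC circuit
(`rc_transfer()` is the closed-form oracle; `estimate_phase()` measures
the simulated stage against it). The resonator chains eight such stages
(one per layer), feeds the 4th stage's output — a $-180^\circ$ phase copy
at $f_0$ — back negatively into the first stage, and reads out four taps
at $90^\circ$ spacing through a blocker/rectifier layer into a summing
output neuron: 17 neurons in 10 layers.

Design choices the architecture description leaves open, and what this
package does:

* **Stage gain.** No synaptic weights are given for the chain. A one-pole
  stage attenuates by $1/\sqrt 2$ at cutoff, so the stage's membrane
  bound is derived from $(LF, LP)$ such that the stage has unit amplitude
  gain at $f_0$ (equivalently $\sqrt 2$ at DC):
  $V = \tfrac{w}{2}\,\alpha LP/(1-\alpha)/\sqrt 2$. The loop gain at
  $f_0$ then equals the feedback weight alone.
* **Feedback.** `feedback_gain = 0.9` by default: positive loop gain 0.9
  at $f_0$ (amplification $1/(1-g) = 10$) without self-oscillation;
  the constructor rejects $g \ge 1$. At DC the fed-back sign is negative
  (four stages shift $0^\circ$), so the zero-frequency component is
  actively suppressed — the band-pass shape comes from this asymmetry.
* **Input attenuation.** `input_gain = 0.1` keeps the resonant swing of a
  full-scale tone inside the membrane bounds (10x amplification times
  0.1 input is unity), trading a little quantisation-noise headroom for
  linearity.
* **Taps.** The four detected phases (0, 90, 180, 270 degrees) are read
  from stages 2, 4, 6, 8 — the multiples of $90^\circ$ along the chain.
  Blockers are binary neurons thresholded just above the bipolar
  midpoint; rectifiers are identity neurons whose membrane is bounded
  below at zero, so only the positive half-wave is re-encoded. The output
  neuron integrates the four rectified phases with a near-lossless leak
  and a threshold that scales with the clock (`clock/4800`), making
  output rates comparable across clocks.
* **Stage LF floor.** Phase stages require $LF \ge 4$ in the bank
  designer's default grid: for $LF \le 3$ the per-tick sigma-delta
  quantisation step is no longer small against the membrane bound and the
  re-injected quantisation noise, amplified by the feedback loop, swamps
  the tone response (measured directly in the development experiments as
  idle-rate versus tone-rate). $LF \ge 4$ keeps the idle rate one to two
  orders of magnitude below the resonant response.

The resonance peak sits slightly above the design $f_0$: the stage phase
at $f_0$ is $-43.7^\circ$ rather than exactly $-45^\circ$ (the discrete
pole is evaluated at a finite angle), so the zero-phase loop condition is
met about 2–3% above $f_0$. For the (5, 73) design the chirp-driven peak
falls at ~105–107.5 Hz, within one 5 Hz analysis bin of 104.65 Hz. This
detuning is a property of the discrete-time stage, not a tuning error,
and it shrinks with $LP$.

Settling: rate measurements discard $10/f_0$ seconds by default before
counting output spikes.

## PDM codec

`pdm_encode()` is a deterministic first-order sigma-delta modulator
(error-feedback form) with the project-wide bipolar convention: density
$(x+1)/2$, so density 0.5 encodes silence. The modulator order of the
emulated microphone is not specified anywhere; first order without
dithering was chosen for reproducibility — every simulation is
bit-identical for identical inputs. `pdm_decode()` is a linear-phase
windowed-sinc FIR low-pass (designed via `signal::fir1`) with decimation;
taps are centred on each output sample so the decoder adds no phase,
which matters for the phase-shift measurements. Round-trip RMS error on
band-limited signals (components at or below clock/100) is below 1%.

## The scaled classification study

The full-rate system runs a 1.536 MHz pulse clock with 100–200 resonators
over roughly 38 Hz–15 kHz and ten sound-event classes. Simulating that
end to end for 400 audio samples is a multi-hour computation, so the
package's default study is a uniformly scaled version of the same design;
everything scales with the pulse clock:

* pulse clock 96 kHz (1/16 of the full-rate clock); 16 kHz audio;
* bank of 200 resonators mel-spaced over 20–300 Hz, designed on the
  grid $LF \in 4..8$, $LP \in 1..200$ ($LF \ge 4$ for quantisation-noise
  reasons, above);
* synthetic sound events with harmonic class signatures — a fundamental
  log-placed in 28–100 Hz plus 1–3 integer partials with roughly $1/k$
  amplitudes and per-sample inharmonicity jitter — 0.5–1 s long, at
  15 dB SNR against white background noise. Harmonic stacks, rather than
  independently placed partials, are the realistic model for isolated
  tonal sound events (bells, horns, whistles), and they keep class
  spectra from colliding except at octave relations, where the
  fundamental channel still separates them;
* 10 classes x 40 samples, 20 train / 20 test per class, 3
  cross-validation rounds, 20 training epochs.

The mel placement at this scale produces banks whose neighbouring
resonators often share one $(LF, LP)$ design — the grid is coarser than
the mel spacing, exactly as it is at the top of the full-rate band. The
100- and 150-resonator comparisons therefore use nested subsets of the
200-resonator placement, so bank-size contrasts are paired rather than
confounded with placement.

**Feature conditioning.** How bank outputs are normalised before the
classifier is not fixed by the architecture. Each sample's feature matrix
is scaled to peak 1, floored at 0.25 of the peak, and columns whose
above-floor activity spans less than 65% of the sample's bins are zeroed.
The floor removes the resonators' residual idle activity; the persistence
gate distinguishes tone-driven columns (active across the whole event)
from background-noise excursions (isolated bins). Both matter for the
same reason: the event-matrix update touches only synapses with spikes in
the learning window, so a column that is exactly silent never drifts,
while with the default learning rates any recurring activity — however
weak — saturates its weight within a few hundred presentations and
erodes the class neurons' selectivity (observed directly in development:
without conditioning, 50–90% of every neuron's weights saturate and
accuracy collapses toward chance). The conditioning constants and the
classifier threshold (0.3 per synapse, i.e. 60 for a 200-synapse neuron,
with $LF=5$ leak at every tick) were fixed on development datasets before
the final held-out evaluation; all are exposed as arguments.

**What training does.** Each class neuron, initialised uniformly in
[0.4, 0.6] from a per-class seed, is exposed only to its own class's
rate-coded features. STDP with the default rates saturates the weights of
the synapses active for that class within a few epochs (the clamped
upper bound acts as the stable fixed point), leaving unstimulated
synapses at initialisation. Classification is winner-take-all on output
spike rates; exact ties (for example an all-silent input) resolve to the
lowest class index with a warning.

**What the synthetic study shows — and does not.** Passing it shows that
the whole chain (PDM front end, resonator frequency analysis, rate-coded
STDP learning, spike-rate readout) can separate spectrally distinct
transient sound events under realistic background noise, and that
accuracy is non-decreasing in bank size and training epochs at this
scale. It does not show performance on real recordings: the generator's
events are stationary tone mixtures with smooth envelopes, without the
broadband transients, reverberation, or within-class variability of real
corpora, and the scaled band covers two octaves rather than nine. The
full-rate replication entry points (`build_bank()` at 1.536 MHz with the
published 20-frequency list, `extract_snmfcc()` on user-supplied WAV
files) are the same code paths.

## Degenerate inputs and tie-breaks

* `design_for_frequency()` breaks exact grid ties toward smaller $LF$,
  then smaller $LP$, and reports the achievable span when a target is
  outside it.
* All-silent classifier input produces all-zero rates and a deterministic
  lowest-index decision with a warning.
* Membrane saturation is applied after every tick; thresholds tie-fire
  (`>=`).
* `spike_rate()` requires a window of at least one tick;
  `estimate_phase()` refuses probes below its amplitude floor rather
  than returning noise.

## Known limitations

* The resonance peak's 2–3% upward bias (discrete-pole phase) is
  inherent to the stage; designs needing exact centring should correct
  $LP$ by that factor.
* Low-$LF$ phase stages are quantisation-noise limited; the bank
  designer's grid floor ($LF \ge 4$) is a hard practical constraint at
  any clock.
* The classifier's unsupervised protocol cannot demote synapses shared
  between classes; strongly overlapping spectra (closer than the bank's
  local grid resolution) confuse it, which bounds accuracy on
  unfavourable class layouts.
* WAV I/O covers mono 16-bit PCM only.
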