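---
title: "Multi-dynamic coupled neural mass modelling of SSVEP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dynamic coupled neural mass modelling of SSVEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepnmm)
```

## The model

`ssvepnmm` simulates steady-state visual evoked potential (SSVEP) EEG with a
Jansen–Rit-type neural mass model. A cortical region is reduced to three
interacting subpopulations — pyramidal cells, excitatory interneurons and
inhibitory interneurons. Two transformations act in a loop:

* a static **potential-to-rate sigmoid**
  $S(v) = 2e_0 / (1 + e^{r(v_0 - v)})$, bounded in $(0, 2e_0)$, with
  half-maximum rate $e_0$ (s$^{-1}$) attained at potential $v_0$ (mV) and
  steepness $r$ (mV$^{-1}$);
* a linear **synaptic kernel** $h(t) = G\,\omega\,t\,e^{-\omega t}$
  ($t \ge 0$) that converts a presynaptic firing rate into a postsynaptic
  potential. Its transfer function $G\omega/(s+\omega)^2$ is equivalent to the
  second-order ODE $\ddot y = G\omega x - 2\omega \dot y - \omega^2 y$, which
  is what the integrator advances.

Intra-regional wiring follows the classic layout: the pyramidal branch is
driven by $S(y_1 - y_2)$, the excitatory-interneuron branch by
$n(t) + C_2 S(C_1 y_0)$, and the inhibitory branch by $C_4 S(C_3 y_0)$ through
the inhibitory kernel. The EEG-like output is $E(t) = y_1(t) - y_2(t)$.
External input $n(t)$ is Gaussian, $N(\mu, \sigma^2)$, drawn independently at
each step.

### The multi-dynamic extension

A single kernel pair produces a narrowband rhythm, but SSVEP spectra are
broad. Each subpopulation therefore carries **three parallel kernel branches**
— a delta, an alpha and a gamma pair — and the branch outputs are merged with
weights $w_\delta, w_\alpha, w_\gamma \in [0,1]$, $\sum_i w_i = 1$. The
presynaptic drives are computed once per step from the *weighted* branch
outputs, and every branch integrates the same drive through its own kernel:
weights act on outputs only, so branch dynamics are weight-independent, and a
one-hot weight vector with matching kernels reproduces the single-kernel model
to machine precision (this degeneracy is asserted in the test suite at
1e-12).

### Two coupled regions

SSVEP generation involves the occipital visual areas interacting with the
parietal cortex, so two multi-dynamic regions are coupled bidirectionally.
A source region's pyramidal output $x = \sum_i w_i y_1^i - \sum_i w_i y_2^i$
is de-meaned ($RM(x) = x - \overline{x}$), converted to a firing rate by the
sigmoid, scaled by the coupling gain ($o_p$ occipital→parietal, $p_o$
parietal→occipital), filtered by a **cross-regional encoder** (a weighted
parallel bank of excitatory kernels), and added to the target region's
external input at the same summing junction as its noise.

## Design choices in the coupling path

Several details of the coupling pathway are genuinely open; the package fixes
them as follows.

* **De-mean operator.** $RM$ uses a *causal running mean* of $x$ over the
  simulation so far (burn-in included), so the simulation streams in one
  pass. A whole-signal mean is acausal and cannot be streamed; for post-hoc
  replication of such a convention, `coupling_params(rm_mode = "fixed",
  rm_fixed = c(m_occ, m_par))` subtracts user-supplied constants instead
  (e.g. the signal means of a previous run).
* **Encoder normalization.** The encoder re-encodes a firing rate into a
  firing rate. A raw excitatory kernel has DC gain $G/\omega \approx 0.0325$,
  and the target's own input kernel applies that physiological gain again;
  routing the coupling signal through both attenuates it ~30-fold and lets
  the sigmoid's DC offset dominate, which inverts the expected
  coupling-induced spectral shift. The default encoder therefore keeps the
  source region's excitatory time constants and mixing weights but
  normalizes each branch to unit DC gain ($G = \omega$), leaving the
  coupling strength entirely to $o_p$/$p_o$. A user-supplied
  `encoder_bank` is used verbatim.
* **No extra time-constant factor.** Some statements of the coupling rule
  can be read as inserting a per-branch $\tau^{-1}$ factor; this is not
  implemented — the encoder branches are plain second-order kernels.
* **Conduction delay.** None by default; an integer-step delay is available
  (`coupling_params(delay = k)`).
* **Noise injection site.** External input enters the excitatory-interneuron
  branch (the classic wiring); `noise_site` can redirect it.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $G_e, \omega_e$ | 3.25, 100 | mV, s$^{-1}$ | excitatory (alpha-branch) kernel |
| $G_i, \omega_i$ | 22, 50 | mV, s$^{-1}$ | inhibitory (alpha-branch) kernel |
| $e_0, v_0, r$ | 2.5, 6, 0.56 | s$^{-1}$, mV, mV$^{-1}$ | sigmoid |
| $C_1..C_4$ | 135, 108, 33.75, 33.75 | — | connectivity ($C{=}135$ Jansen scheme) |
| $\mu, \sigma^2$ | 220, 100 | s$^{-1}$ | external input moments |
| $dt$ | 4/4096 | s | integration = sampling step (1024 Hz) |
| burn-in | 1 | s | transient discarded |

The delta and gamma kernel pairs are not standardized anywhere; the package
scales the alpha time constants so that each branch alone resonates near 2 Hz
($\omega_e = 20$, $\omega_i = 10$) and 40 Hz ($\omega_e = 400$,
$\omega_i = 200$), rescaling gains to preserve the gain × time-constant
product ($G' = G\,\omega'/\omega_\alpha$), the construction used throughout
the David–Friston lineage of multi-kinetics models. All six kernels are
user-configurable; these defaults are a documented convention, not empirical
values.

## Integration scheme

The integrator is fixed-step explicit Euler at $dt = 4/4096$ s, with one
independent Gaussian input draw per step and no $1/\sqrt{dt}$ rescaling: the
sampling step *is* the integration step, and per-step draws at the stated
$\mu$, $\sigma^2$ reproduce the intended input-regime phenomenology at this
rate. The price is that $\sigma^2$ is tied to this $dt$ — the package makes
no attempt to calibrate a continuous-time SDE across different steps, and
higher-order integrators are deliberately out of scope. First-order accuracy
is verified two ways: the simulated impulse response converges to
$h(t)$ with error halving as $dt$ halves, and the noise-free trajectory
converges linearly in $dt$ to an adaptive-solver (lsoda) reference.
Explicit Euler on the double pole $-\omega$ requires $dt\,\omega < 2$;
divergence (non-finite state) is detected per step and reported with the
step index and, in the coupled model, the region name.

## Spectral analysis and weight identification

`compute_psd()` is a plain rectangular-window periodogram of the de-meaned
signal — deliberately, since the weight-identification rule is defined on a
raw FFT PSD; Welch averaging would only change band energies by a common
smoothing and the identified weights are ratios, insensitive to the absolute
normalization. The PSD is a one-sided density scaled so that
$\sum P \cdot \Delta f$ equals the population variance (Parseval, asserted to
1e-6).

Band energies sum PSD bins over five contiguous half-open bands: δ [0,4),
θ [4,8), α [8,16), β [16,32), γ [32,64) Hz. Half-open intervals resolve the
shared printed boundaries (4, 16, 32 Hz each belong to exactly one band).
Oscillator weights are the δ/α/γ energies normalized by their three-band
total; θ and β are computed but excluded from the weights by construction.
The returned triple always lies on the unit simplex; an all-zero three-band
energy is an error rather than a silent 0/0.

## Swarm fitting

`fit_model()` fits free parameters of the coupled model to a target spectrum
by particle swarm optimization with the study settings: 50 particles, 70
iterations, inertia $k = 0.5$, learning factors $c_1 = c_2 = 1.5$
(so $0 < c_1 + c_2 < 4$), objective
$\mathrm{MSE} = \frac1n \sum_i (Y(f_i) - S(f_i;\theta))^2$. Default bounds:
$\mu \in [22, 2200]$, $\sigma^2 \in [2, 20000]$; coupling gains are unprinted
anywhere, so they default to $[0, 2000]$, wide enough to contain all fitted
values reported for 10–12 Hz stimulation. Positions are clipped to bounds
with the offending velocity component zeroed (common practice; the update
rule itself does not specify boundary handling).

Two choices deserve note:

* **Deterministic objective.** All evaluations within one fit share a single
  simulation seed; a stochastic objective would make personal-best
  bookkeeping ill-defined. `n_sim_seeds > 1` averages the model spectrum
  over several seeds per evaluation when a smoother objective is worth the
  cost.
* **Dimensionality.** The default free vector has the six parameters that
  are actually tabulated per stimulation frequency
  ($o_p, p_o, \mu_o, \sigma^2_o, \mu_p, \sigma^2_p$). An 18-dimensional
  search is sometimes quoted without its composition ever being given;
  the package honors larger searches via optional softmax-reparameterized
  oscillator-weight logits (`eta_*` dimensions), which keep the weights on
  the simplex by construction.

Exact recovery of $\theta^\ast$ from one noisy spectrum is not identifiable,
so the quantitative recovery surface is the objective itself: with a
model-generated target, the median fitted MSE over ten seeds falls by more
than half from the initial swarm best (asserted in the tests with a reduced
swarm of 12 particles × 10 iterations on 2-s simulations, which keeps the
whole check under ten seconds).

## The surrogate generator

No SSVEP recordings are publicly deposited, so `generate_surrogate()` stands
in for stimulus-locked signals: a fundamental at $f_0$ with second and third
harmonics (random phases) on $1/f^\beta$ colored noise synthesized by
spectral shaping, with exactly controllable band energies. It emulates the
frequency structure that the weight-identification, classification and demo
pipelines consume. It does **not** emulate non-stationarity, eye-movement or
blink artifacts, inter-subject variability, or channel structure — so tests
passing on surrogates certify the pipeline's arithmetic, not performance on
recorded EEG.

Default surrogate conditions: harmonic amplitudes (1, 0.5, 0.25) mV,
$\beta = 1$, broadband variance 0.5 mV², 4 s at 1024 Hz — a clearly
stimulus-locked but visibly noisy signal whose dominant-frequency
classification is near-perfect at tolerance 0.5 Hz, degrading as
`noise_power` grows.

## Augmentation operators

`augment_once()` applies one of five label-preserving operators, sampled
uniformly per application (a compose-all mode exists behind
`compose_all = TRUE`): circular shift (≤ fs/10 samples), smooth sinusoidal
amplitude envelope in [0.8, 1.2], zeroing of one window of fs/20–fs/5
samples, global gain in [0.7, 1.3], and additive Gaussian noise at 5% of the
signal RMS. The ranges are not standardized anywhere; these defaults are
conservative enough that a dominant spectral peak survives every operator.
`augment_dataset()` expands each input `ops_per_sample` times (100 by
default, so e.g. 270 inputs become 27,000 outputs) under a single seed.

## Problem sizes and reproducibility

The package-level checks simulate 4 s at 1024 Hz (the study step) for the
input-regime and sweep properties, 10 seeds per condition; fitting checks use
2-s simulations with a 12 × 10 swarm; everything completes in well under a
minute on one core. All randomness flows from explicit seeds;
multi-stream settings derive sub-seeds by the documented splitting scheme
(`derive_subseeds()`: seed the RNG once, draw integer sub-seeds), which is
what makes the zero-coupling factorization and region-relabelling symmetry
bit-exact rather than merely statistical.

## Known limitations

* Euler-only integration; $\sigma^2$ is meaningful only at the configured
  $dt$.
* Two regions only; no prefrontal/temporal extensions.
* The dominant-frequency classifier is a deliberate stand-in for trained
  sequence classifiers; no neural network training is included.
* Fitted parameters are not uniquely identifiable from a single spectrum;
  only the spectral fit quality is a supported claim.
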