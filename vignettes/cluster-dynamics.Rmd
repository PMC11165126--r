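---
title: "Delay-coupled heterogeneous neural masses: model, calibration, and detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-coupled heterogeneous neural masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmsim)
```

## The model

Each cortical area is a three-population neural mass: a pyramidal population
(`y0`), an excitatory population (`ye`) and an inhibitory population (`yi`),
each described by a mean membrane potential (mV).  Every population is a
*critically damped* second-order element,

$$ y'' + \frac{2}{\tau}\,y' + \frac{1}{\tau^2}\,y = F(t), $$

so on its own a population is a one-shot device: displaced and released, it
returns to rest without ringing.  Everything interesting comes from the
driving terms $F(t)$:

$$
\begin{aligned}
y_0'' &= \tfrac{A}{\tau_e} S(y_e - y_i) - \tfrac{2}{\tau_e} y_0' - \tfrac{y_0}{\tau_e^2},\\
y_e'' &= \tfrac{A}{\tau_e}\Big[C_2\,S(C_1 y_0) + p(t) + \mathrm{stim}(t)
        + G \textstyle\sum_j a_{kj}\, S_j\big(dy_j(t - d_{kj}/v)\big)\Big]
        - \tfrac{2}{\tau_e} y_e' - \tfrac{y_e}{\tau_e^2},\\
y_i'' &= \tfrac{B}{\tau_i}\,C_4\,S(C_3 y_0) - \tfrac{2}{\tau_i} y_i' - \tfrac{y_i}{\tau_i^2}.
\end{aligned}
$$

The node's output — read as a local field potential — is $dy = y_e - y_i$;
the cluster LFP is the unweighted mean across nodes.  Coupling is directed
and weighted ($a_{kj}$: weight of the link $j \to k$), and each link carries
a conduction delay $d_{kj}/v$ from the inter-node distance at a default
velocity of 1 m/s, typical of short unmyelinated cortical pathways.

## The voltage-to-rate transform

When synaptic weights in a population are normally distributed (mean
$w_{av}$, standard deviation $1/r$) around a common firing threshold $v_0$,
the fraction of targets driven over threshold by a presynaptic potential $v$
is a complementary-error-function of the weight tail, which is why the
transform here is an erfc rather than the classic logistic sigmoid.  The
printed compact notation for its argument admits three monotone readings,
all implemented and selectable through `transfer_params(arg_form = ...)`:

| `arg_form` | $S(v)$ for $v>0$ | behaviour at $v \to 0^+$ |
|---|---|---|
| `v_over_v0` | $q_m\,\mathrm{erfc}(-r(v/v_0 - w_{av}))$ | jump to $q_m\,\mathrm{erfc}(r w_{av})$ |
| `v0_times_v` | $q_m\,\mathrm{erfc}(-r(v_0 v - w_{av}))$ | jump to $q_m\,\mathrm{erfc}(r w_{av})$ |
| `v0_over_v` | $q_m\,\mathrm{erfc}(r(v_0/v - w_{av}))$ | continuous, $S \to 0$ |

All are clamped to zero for $v \le 0$ (a pulse rate cannot be negative).
The package's six-node preset uses the **ratio form** `v0_over_v`, for three
reasons established during development:

1. It is the form the weight-distribution derivation produces directly: a
   synapse of weight $w$ drives its target over threshold when $w\,v > v_0$,
   so the active fraction is the tail of the weight distribution above
   $v_0/v$.
2. It is the only reading that is continuous at $v = 0^+$.  The other two
   jump discontinuously, which in simulation lets an infinitesimally
   positive pyramidal potential sustain full feedback drive — nodes then
   latch into a spurious constant state with $dy < 0$ instead of resting or
   oscillating.
3. Under drive it yields self-organised limit cycles whose frequencies fall
   in each node's assigned band, whereas the `v_over_v0` reading has too
   shallow a slope (in mV units) ever to destabilise the critically damped
   skeleton: in scans across tonic drives from 0 to 3000 s$^{-1}$ it never
   oscillates, while the classic Jansen-Rit sigmoid run through the same
   integrator oscillates exactly in its known drive window (120–320
   s$^{-1}$), confirming that the integrator is not at fault.

Note that the ratio form saturates at $q_m\,\mathrm{erfc}(-r\,w_{av})$
(1.97 $q_m$ for $r = 0.5$, $w_{av} = 3$) rather than at the full $2 q_m$.

## The six-node preset and its calibration

`pfc_node_params()` carries the heterogeneous constants of the six
prefrontal areas (A10, A32V, A32, A9, A46D, A11), each tuned to a frequency
band:

| node | band | $C$ | $w_{av}$ | $\tau_e$ (ms) | $\tau_i$ (ms) | nominal $f$ (Hz) |
|---|---|---|---|---|---|---|
| A10 | gamma | 220 | 3 | 5 | 5 | 32.1 |
| A32V | theta | 200 | 5 | 25 | 25 | 5.3 |
| A32 | beta | 250 | 3 | 10 | 10 | 16.0 |
| A9 | alpha | 220 | 1.5 | 16 | 17 | 9.9 |
| A46D | theta | 200 | 3.5 | 25 | 25 | 5.9 |
| A11 | beta | 250 | 3 | 10 | 10 | 16.1 |

Shared constants follow Jansen-Rit usage: $A = 3.25$ mV, $B = 22$ mV,
$q_m = 2.5$ s$^{-1}$, feedback ratios $C_{1..4} = C\,(1, 0.8, 0.25, 0.25)$,
and $r = 0.5$ throughout.  Two constants are not fixed by that table and
were calibrated once, then frozen:

* **$v_0 = 8$ mV.**  The emergent limit-cycle frequency is locked mainly to
  $\tau_e$ (roughly $f \approx 1/(2\pi\tau_e)$, the frequency at which the
  two critically damped feedback filters together accumulate 180° of
  phase), but $v_0$ trims it by a few percent.  At $v_0 = 8$ a tonically
  driven single node reproduces the nominal frequencies almost exactly
  (32.0, 5.5, 16.0, 9.5, 6.0, 16.0 Hz).
* **Coupling scale.**  Tracer-derived link weights span roughly 70–2500, so
  the coupling sum is applied to the *raw* weights with one global gain
  $G = 0.04$.  Row-normalising the weights instead (so in-weights sum to
  $G$) bounds the entire inter-node drive by $2 q_m = 5$ s$^{-1}$ —
  negligible next to a 200 s$^{-1}$ stimulus — and silences every network
  effect; it remains available via
  `sim_config(coupling_scaling = "row_normalized")`.
* **Background noise, 175 s$^{-1}$.**  The resting cluster is bistable
  (quiescent vs collectively oscillating).  Zero-mean per-step Gaussian
  noise at this scale reliably carries the network from the zero state into
  the oscillating attractor within the first seconds and keeps all six
  nodes participating; much weaker noise leaves ignition to rare excursions
  and makes runs qualitatively seed-dependent.  The value is of the same
  order as the stimulus carrier, which is worth keeping in mind when
  interpreting stimulus-evoked changes.

With these defaults the resting cluster shows each node's dominant spectral
peak inside its assigned band (all six nodes, across many fixture seeds)
and a theta-dominant cluster spectrum (theta fraction typically 0.5–0.9).

## What the synthetic connectome emulates — and what it does not

`make_pfc_fixture()` draws a six-node directed weighted network with the
reported statistical signature of the prefrontal cluster: 29 of 30 possible
directed links (the absent pair uniform per seed), a heavy-tailed log-normal
weight draw rank-adjusted so that at least a third of links exceed weight
1000 and at least another quarter exceed 500, a square-pyramid geometry with
A10 apical and all nodes within 3.4 mm of it, and a hub structure in which
the strongest weights preferentially sit on A10's out-links and on A32V's
(and secondarily A11's) in-links.  It does **not** reproduce the true
tracer-derived weight matrix, which is not public.  Consequences observed in
testing: resting-state spectral organisation is robust to the drawn matrix,
but which stimuli induce amplitude transitions, and their latencies, vary
between fixture seeds — qualitatively the same situation as tuning the
original model, where only a minority of parameter draws produced
transition-capable dynamics.  Passing tests on the fixture therefore
demonstrate the mechanism, not a quantitative match to the real cluster.

## Numerics

The integrator is classic fixed-step RK4 at $dt = 0.1$ ms, with each
second-order equation recast as two first-order ones (36 state variables
for six nodes), implemented in C++.  Design choices:

* **Delays.**  Each link delay is rounded to an integer number of steps
  (3.4 mm at 1 m/s = 34 steps).  Delayed outputs $dy_j$ are read from the
  recorded trajectory and held constant across the four stage evaluations
  of a step; with delays of tens of steps, stage-level interpolation would
  change nothing at the reported precision.  History before $t = 0$ is
  zero.
* **Noise.**  One Gaussian draw per node per step (not per stage), scaled
  by `noise_scale`; with a fixed seed runs are bit-reproducible.  Uniform
  (variance-matched) and no-noise options exist; Gaussian-with-scale-zero
  and `none` produce identical trajectories.
* **Verification.**  The homogeneous critically damped node matches
  $(c_1 + c_2 t)e^{-t/\tau}$ to better than $10^{-6}$ relative error; the
  measured convergence order on a smooth probe is ≈ 4.1; the compiled
  delay path is checked sample-for-sample against a plain-R reference loop
  and a `deSolve` solution of the single-node system.
* **Blow-ups** abort with the offending step and node rather than
  returning NaNs.

## Rest, bistability, and what "one-shot" means here

The all-zero state with zero drive is an exact fixed point, and it is
locally stable: random perturbations within the rest basin decay below
$10^{-6}$ mV well inside 3 s.  The basin is bounded by the population firing
thresholds — roughly $v_0/w_{av}$ (1.6–5.3 mV) on the $dy$ pathway but only
$v_0/(w_{av} C_1)$ (tens of µV) on the pyramidal pathway, whose argument is
amplified by $C_1 \approx 200$.  Beyond those thresholds the regenerative
feedback captures the trajectory into a large-amplitude relaxation cycle
that persists without any external drive.  This multistability is not a
defect: persistent stimulus-evoked states that outlive a 100-ms burst by
seconds logically require coexisting attractors.  But it does mean the
"returns to rest from anywhere" intuition of the linear skeleton holds only
within the basin, and tests assert exactly that.

## Spectral and transition detectors

* `band_power()` uses a Hann-tapered one-sided periodogram; band fractions
  are normalised by total 4–100 Hz power, with band edges closed on the
  left (8 Hz counts as alpha).  Band powers plus out-of-band power
  reconstruct the total spectrum to $10^{-6}$ relative (Parseval).
* `detect_transition()` uses a sliding RMS envelope (default window 0.5 s;
  an amplitude transition must leave the pre-stimulus baseline envelope by
  more than 30% and stay out for at least 1 s; reversion is detected
  symmetrically).  RMS was preferred to the analytic-signal magnitude as it
  needs no band-limiting assumptions on relaxation-shaped waveforms.
  Calibration on planted amplitude drops across 100 seeded constructions
  locates the change point within one envelope window in well over 95% of
  cases, and the detector is exactly scale-invariant.
* `repeat_period()` takes the envelope autocorrelation's highest local
  maximum above 0.25, with a 2% modulation-depth floor below which `NA` is
  returned (a numerically flat envelope otherwise normalises its own
  ripple into spurious certainty).  A two-tone beat at $f_1, f_2$ is
  recovered as $1/|f_1 - f_2|$.

## Protocols

`run_protocol()` packages the experiment presets: `resting`;
`band_stim_<band>` (half-wave-rectified, sinusoidally modulated 200
s$^{-1}$ pulse train at the band's preset resonance — theta 5.3, alpha 9.9,
beta 16.0, gamma 32.1 Hz — applied to the in-hub pair A32V + A11 at 4 s,
after transients have settled); `beta_then_burst` (a 100-ms gamma burst to
all nodes at 10 s); `theta_then_gamma_wave` (continuous gamma wave at 10 s,
30-s horizon so late reversions are not censored); and
`repeated_aligned_bursts` (three 100-ms gamma bursts phase-aligned to
positive theta half-cycles of A32V's excitatory potential, computed from a
first pass of the same seed).  A burst is allowed to overhang its positive
half-cycle by up to 20% — a 100-ms burst against a 5.3 Hz rhythm (94-ms
half-cycle) is the canonical case.  Every run writes its resolved
configuration beside its outputs, and re-running from that sidecar
reproduces the outputs bit-for-bit.

## Known limitations

* The true weight matrix being unavailable, transition phenomenology
  (which bands switch A32V, latencies, repeat periods) is
  fixture-dependent; only its existence and detectability are asserted.
* A9's alpha rhythm is the most weakly expressed: its in-band peak relies
  on network drive, and in weakly coupled variants it entrains to its
  theta-band neighbours.
* The background-noise scale needed for reliable ignition is not "small"
  relative to the stimulus carrier; resting-state and evoked amplitudes
  are therefore closer in this implementation than the one-shot intuition
  suggests.
* Synaptic plasticity on $A$, $B$, $C$, spatially propagating stimuli, and
  phase-synchronisation metrics are out of scope.
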