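---
title: "Thermal neuristor networks: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal neuristor networks: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuristor)
```

## The model

A thermal neuristor is a thin vanadium dioxide (VO2) film in series with a
load resistor `R_load`, with a parasitic capacitance `C` across the film.
VO2 undergoes an insulator-to-metal transition (IMT) near 340 K with
hysteresis between heating and cooling. The circuit behaves like a leaky
integrate-and-fire neuron: the capacitor charges through the load, Joule
heating in the film raises its temperature, and when the IMT fires the film
resistance collapses, the capacitor dumps its charge as a current spike,
heating drops, and the film re-insulates. On a two-dimensional array the
devices are electrically isolated but exchange heat through the substrate,
so each site couples to its four nearest neighbours thermally.

Per site $i$ the package integrates

$$C\,\dot V_i = \frac{V^{\mathrm{in}}_i}{R^{\mathrm{load}}} -
  V_i\Big(\frac{1}{R_i} + \frac{1}{R^{\mathrm{load}}}\Big), \qquad
C_{\mathrm{th}}\,\dot T_i = \frac{V_i^2}{R_i} - S_e (T_i - T_0)
  + S_c \nabla^2 T_i + \sigma \eta_i(t),$$

with $\eta_i$ unit-intensity Gaussian white noise and $\nabla^2$ the
nearest-neighbour Laplacian with zero-flux boundaries (edge devices still
lose heat through $S_e$, as on an isolated patterned chip, but no heat
crosses the array boundary).

The film resistance is hysteretic:

$$R(T) = R_0\, e^{E_a/T} F(T) + R_m, \qquad
F(T) = \tfrac12 + \tfrac12 \tanh\!\Big(\beta\Big\{\delta\tfrac w2 + T_c -
  \big[T + T_{pr} P\big(\tfrac{T - T_r}{T_{pr}}\big)\big]\Big\}\Big),$$

where $\delta = +1$ on the heating branch and $-1$ on the cooling branch,
$T_r$ is the temperature of the most recent heating/cooling reversal, and
$P(x) = \tfrac12 (1 - \sin\gamma x)(1 + \tanh(\pi^2 - 2\pi x))$ blends the
post-reversal (minor-loop) curve into the major branch as $T$ moves away
from $T_r$. The offset $T_{pr} = \delta w/2 + T_c - (2F(T_r)-1)/\beta - T_r$
is fixed once per reversal from the insulating fraction cached at the
reversal, so each branch carries one level of reversal memory.

Three time scales organise the dynamics (`time_constants()`): the metallic
electrical time $\tau_{met} = R_m C \approx 187$ ns, the thermal time
$\tau_{th} = C_{\mathrm{th}}/(S_c + S_e) \approx 242$ ns, and the insulating
electrical time $\tau_{ins} = R_{ins}(T_0) C \approx 7.5\ \mu$s. Spiking and
avalanche dynamics run on the two fast scales while the slow recharge acts
as a memory, and this separation is what lets spatially distant sites build
up correlations far beyond the nearest-neighbour coupling range.

## Numerical choices in the hysteresis model

Three points in the resistance model are genuinely open and were fixed as
follows.

**Virgin branch.** Before any reversal there is no minor-loop memory, so
the virgin state evaluates the pure major branch. Internally this is the
exact limit $T_{pr} = 0$ (the memory term identically zero), rather than a
nominal far-away reversal temperature: $P$ decays on the scale
$|T_{pr}| \approx |T_c - T_r|$, so a literal distant $T_r$ would *not* make
the memory term vanish — it would shift the transition by tens of kelvin.

**Reversal anchor.** $T_{pr}$ grows linearly with the distance of the
reversal from the loop. A spike overshoots the film to roughly 400 K, and a
reversal anchored there would produce $T_{pr} \approx -65$ K and shift the
cooling transition *above* the heating one — an inverted loop. Physically
the memory term encodes the frozen mixture of insulating and metallic
domains at reversal, and that mixture only exists inside the transition
window; a reversal further out is fully saturated and its exact extremal
temperature carries no further information. The memory anchor therefore
saturates at the window edges $T_c \pm (w/2 + 2/\beta)$ ($2/\beta$ is where
the tanh is 96% saturated). Reversals inside the window are untouched.
$P$ is additionally clamped to $[0,1]$: full offset near the reversal, none
far away.

**Reversal detection under noise.** Branch direction is decided against the
running temperature extremum with a deadband: the branch flips only when
$T$ has retreated from the extremum by more than `deadband` (default
0.25 K). Raw sign-flip detection would reverse on essentially every step
under noise; and because each reversal re-caches $F(T_r)$ through the map
$F \mapsto \tfrac12 + \tfrac12\tanh(2F-1)$, which contracts towards $1/2$,
per-step thrashing measurably erodes the insulating fraction and with it
the spiking threshold. The default is a few per-step noise increments and
two orders of magnitude below genuine heating/cooling excursions.

## Units and the noise scale

Externally everything is in the device-scale units of the parameter table:
pF, kΩ, pJ/K, mW/K, µW/K, K, ns and µs. `params_si()` converts once to SI;
nothing else converts units.

The noise strength is the one constant whose nominal unit
(µJ s^-1/2^) is inconsistent with the model it feeds: inserted literally,
$\sigma = 1$ gives stationary temperature fluctuations
$\sigma/\sqrt{2 S_e C_{\mathrm{th}}} \approx 7$ K — as wide as the entire
hysteresis loop ($w = 7.19$ K) — and the simulated array then fires
noise-driven spikes at every drive voltage with no quiescent, synchronized
or boundary regime left. The package therefore treats the tabulated number
as a value in a calibrated noise unit, fixed once: 1 noise unit =
0.01 µJ s^-1/2^, i.e. $\sigma_T \approx 0.07$ K at the default thermal
constants. With this single calibration the model exhibits the expected
sequence along the voltage axis — quiescence at low drive, avalanching at
the activity boundary, near-global synchrony in the middle of the window,
decoherent spiking beyond it — and all relative noise settings (e.g. the
reservoir's $\sigma = 0.2$) are preserved.

## Integration and spike detection

The coupled equations are integrated with the explicit Euler–Maruyama
scheme at a fixed `dt = 10` ns: deterministic drift plus
$(\sigma/C_{\mathrm{th}})\sqrt{dt}\,\xi$ on the temperature only. The
compiled integrator (`simulate_lattice()`) and a pure-R single step
(`lattice_step()`) implement the same update and are cross-checked against
each other in the test suite; all randomness flows through R's RNG so a
`(config, seed)` pair reproduces results bit for bit. The standard initial
condition is a cold start ($V = 0$, $T = T_0$, virgin heating branch); the
first `t_transient` µs (default 2, about the slow recharge time; longer for
high-voltage runs whose cold-start transient includes a first discharge)
are discarded.

Spikes are strict local maxima of the per-site current $I_i = V_i/R_i$,
subject to a peak threshold (default 1 mA, between the ~0.2 mA insulating
leak and the several-mA discharge peaks) and a refractory separation
(default 200 ns $\approx \tau_{met}$) that rejects double counting on a
single discharge. The streaming detector inside the integrator and
`detect_spikes()` on recorded traces apply the identical rule.

## Avalanches

An avalanche is a set of spikes contiguous in space and time: events are
coarse-grained onto a (row, col, time-bin) lattice with half-open 400 ns
bins (`coarse_grain()`), and occupied cells are clustered with von Neumann
adjacency — nearest spatial neighbours in the same bin, same site in
adjacent bins; no diagonals — by a single raster scan with union–find label
merging (`label_avalanches()`, the Hoshen–Kopelman algorithm). An
avalanche's size is the number of spikes it contains (cell counts summed);
counting occupied cells instead is available as an option. The temporal
window should exceed the spike duration but stay below the inter-spike
interval; 400 ns sits between $\tau_{met}$ and the microsecond-scale
periods.

Size histograms use bins uniform in $\log_{10} s$ with Scott's normal
reference rule, $h = 3.49\,\hat\sigma\,n^{-1/3}$, applied to the
log-transformed sizes; densities are normalised per unit linear size.
`fit_power_law()` fits a least-squares line in log–log space after two tail
exclusions: sparse bins (count < 10 by default; the rule is configurable),
and bins past the terminal density minimum, which removes the finite-size
pile-up of system-spanning avalanches that accumulates at the upper end of
boundary-phase histograms. For a monotone power-law histogram the second
rule removes nothing, which the sampling-oracle test (truncated $s^{-2}$
draws via inverse-CDF, `synth_powerlaw_sizes()`) confirms. Fits with fewer
than three surviving bins are flagged unsuccessful. For phase-diagram
rendering, reported exponent magnitudes are capped at 6.

## Order parameters and phase labels

`order_parameters()` reduces a spike train to a firing rate
(spikes/site/µs) and a population coherence: with $a_i(t)$ the binary
400 ns-binned spike indicator of site $i$ and $A(t)$ its population mean,
the coherence is $\mathrm{Var}_t(A)/\langle\mathrm{Var}_t(a_i)\rangle_i$ —
1 for sites spiking in identical bins, $O(1/N)$ for independent trains, 0
when nothing spikes. `classify_phase()` then labels an operating point
quiescent (rate < 10^-3^ spikes/site/µs), rigid (coherence ≥ 0.8),
LRO-candidate (successful power-law fit with $r^2 \ge 0.98$ spanning ≥ 2
decades — the long-range-order signature), or uncorrelated. The two
thresholds are reported with every sweep and are deliberately conservative;
the boundary between travelling waves and uncorrelated spiking is visual in
nature and no automatic wave label is attempted. `phase_sweep()` runs one
independently seeded simulation per $(V^{\mathrm{in}}, c_{th})$ grid point,
so points can be recomputed or re-labelled without re-simulating the rest.

A caution from the model's own behaviour: with the tabulated constants the
single-oscillator spiking window closes only near 22–25 V. The
warm metallic state that should quench spiking at high drive is dynamically
fragile here — during the post-spike cool-down the soft resistance
transition (width $1/\beta \approx 4$ K) throttles Joule heating faster
than the discharged capacitor can recover, so the film re-insulates and
oscillates for drives well beyond the window observed in measured devices.
Upper-boundary behaviour (decoherence, then quiescence, in the 13.5–15 V
range) should therefore not be expected from this implementation; the
lower boundary, the synchronized phase and boundary avalanching are
reproduced.

## Reservoir computing

The array is used as a fixed, untrained dynamical reservoir. A grayscale
image in $[0,1]$ maps linearly to per-site input voltages between 10.5 and
12.2 V (`encode_image()`), a range inside the synchronized spiking regime
so intensity modulates spiking frequency and phase rather than gating sites
on and off. The reservoir runs with faster heat dissipation
(`cth_scale = 0.15`) and weak noise ($\sigma = 0.2$ noise units) for 10 µs
with *no* transient discard — the input-driven transient is the signal.
Spikes are binned at 500 ns and binarised per (site, bin), so a 28 × 28
image yields a 28 × 28 × 20 binary tensor, flattened to 15 680 features
(`extract_features()`).

The readout (`train_readout()`) is a single fully connected layer with
softmax activation trained by Adam (learning rate 10^-3^, 20 epochs,
minibatch 128, zero initialisation — the objective is convex, so
initialisation only affects the path) under the mean negative
log-likelihood; per-epoch train/test loss and accuracy curves are kept. A
closed-form kernel ridge regression on one-hot targets is available as an
alternative backend (with ~10^2^ training samples against 10^4^ features
the dual form is the cheap one); softmax + NLL remains the default.
Batch size and the zero initialisation are package choices.

## The synthetic data generators

`synth_images()` is the packaged stand-in for a handwritten-digit set: ten
deterministic geometric templates (bars, bands, blocks, frames at
class-specific positions) on a 28 × 28 canvas, plus seeded Gaussian pixel
noise (default sd 0.05, mild relative to the 0.85 foreground/background
contrast), clipped to $[0,1]$. It emulates what the pipeline needs —
class-conditional, linearly separable structure under a pixel-to-voltage
encoding — and deliberately not what real handwriting has: within-class
shape variability, stroke thickness variation, translation. A pipeline
accuracy on these fixtures therefore demonstrates that encoding,
simulation, feature extraction and readout compose correctly, not that the
reservoir solves handwriting recognition. `synth_powerlaw_sizes()` draws
integer sizes from a truncated power law by inverse-CDF sampling and is the
oracle for the histogram fitter.

## Problem sizes and determinism

The packaged experiments are desk-scale: 16 × 16 arrays over 200 µs for the
phase sequence, a 32 × 32 array over 500 µs for boundary avalanche
statistics (order 10^5^ spikes, enough for a multi-decade histogram), and
200 training / 100 test images at 10 µs each for the reservoir pipeline.
Grid sizes, durations and all thresholds are arguments, so the same code
scales to larger arrays and longer runs. Every stochastic path — thermal
noise, per-image reservoir seeds, minibatch shuffling, sweep sub-seeds — is
derived from explicit integer seeds.

## Known limitations

* The high-voltage quiescent boundary is not reproduced (see above); phase
  sweeps are reliable on the lower boundary and inside the spiking window.
* One level of reversal memory: nested minor loops re-anchor on each
  reversal rather than recalling older reversals.
* The noise unit is a calibration, not a measurement; only relative noise
  strengths are meaningful.
* Euler–Maruyama at 10 ns resolves the spike rise marginally (temperature
  moves tens of kelvin per step at the discharge peak); halving `dt`
  changes spike counts by at most one in the windows tested, but
  trajectories through a discharge are not step-size independent in detail.
* The avalanche labeller holds the full occupancy array in memory; for very
  long runs analyse in temporal chunks.
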