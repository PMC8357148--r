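---
title: "Modeling spatially heterogeneous cholinergic modulation of network rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatially heterogeneous cholinergic modulation of network rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(achnet)
```

## The scientific problem

Acetylcholine (ACh) release in cortex is spatially patchy: imaging and
amperometry show discrete "hotspots" of high cholinergic signaling tens of
micrometers across, adjacent to quiet territory. Through muscarinic
receptors, ACh blocks the slow M-type K+ current, so a spatial pattern of
ACh translates into a spatial pattern of the M-current's maximal
conductance, gKs: low gKs (high ACh) means high excitability and little
spike-frequency adaptation (SFA); high gKs (no ACh) means adapting,
sluggish cells. `achnet` asks what such a frozen gKs landscape does to the
rhythms of a cortical excitatory-inhibitory (E-I) network, and provides
everything needed to pose and answer that question in silico: the neuron
model, the network, the gKs map generator and a rhythm/coupling analysis
suite.

The headline phenomenon the package reproduces: gamma-band (about 40-60 Hz)
firing confined to low-gKs hotspots, slower theta-range modulation of that
gamma as activity drifts within and alternates between hotspots, and
theta-gamma phase-amplitude coupling that is strongest near hotspot centers.

## The neuron model

Each cell is a single-compartment Hodgkin-Huxley model with a fast Na+
current (instantaneous activation `m_inf(V)`, inactivation gate `h`), a
delayed-rectifier K+ current (gate `n`), a leak, and the M-type K+ current
`IKs = gKs * z * (V - VK)` with activation time constant `tau_z = 75` ms:

    C dV/dt = -gNa m_inf^3 h (V - VNa) - gKdr n^4 (V - VK)
              - gKs z (V - VK) - gL (V - VL) + I_drive - I_syn + I_noise

with C = 1 uF/cm^2, gNa = 24, gKdr = 3, gL = 0.02 mS/cm^2, VNa = 55,
VK = -90, VL = -60 mV. Gates relax first-order to voltage-dependent steady
states; all closed forms are in `steady_state_gates()` and
`gate_time_constants()`. `gKs` runs from 1.5 mS/cm^2 (no ACh) down to 0
(full muscarinic blockade); lowering it raises the f-I curve and removes
SFA (`f_I_curve()`, `sfa_profile()`).

Integration is fixed-step classical Runge-Kutta at dt = 0.05 ms. The step
was chosen by convergence checks: halving it moves single-cell spike times
of a 1 s run by well under 1 ms and changes network population rates by
under 3%. Spikes are detected as upward 0 mV crossings with a 2 ms
detection lockout (detection only; the dynamics are never reset).

## Network and synapses

400 E cells sit on a periodic 20 x 20 lattice, 100 I cells on a nested
periodic 10 x 10 lattice (each I cell at the center of a 2 x 2 E block).
Excitation is local: every E cell projects to its 40 nearest E cells and
10 nearest I cells under the minimum-image Euclidean metric. Inhibition is
global: every I cell projects to all E cells and all other I cells
(autapses excluded). Synapses are conductance-based with a single-
exponential 3 ms decay; strengths are 0.01 (E-E), 0.05 (E-I), 0.04 (I-I)
and 0.04 (I-E) mS/cm^2, reversals 0 mV (exc) and -75 mV (inh). Because
several nearest-neighbor ranks are degenerate on a lattice, ties are broken
deterministically by (distance, |angle to the +x axis|, cell ID); the
40-neighbor stencil necessarily splits an 8-fold-degenerate shell, so no
tie rule can make it fully reflection-symmetric - the 36-cell core is.

Rewired (`rewire_ee()`) and sparse-inhibition (`sparsify_inhibition()`)
variants implement the connectivity controls: rewiring replaces a fraction
p of each E cell's E targets with a uniform random draw (degree-preserving,
no autapses or duplicates), and sparsification keeps each inhibitory edge
with a given probability while re-weighting the survivors.

### Drive and noise

The constant background drive (default 3.0 uA/cm^2) targets the E
population; interneurons are recruited synaptically, the classic PING
arrangement. This is a deliberate design choice: when the same tonic drive
is also applied to all I cells, the resulting tonic global inhibition
either locks the network into full synchrony or suppresses it into a
2-3 Hz asynchronous state, and the spatial rhythms this package exists to
study do not emerge. A direct I-cell drive remains available
(`drive_config(I_base_I = )`) and is used, e.g., for the
activity-confinement experiment, where tonically active interneurons are
part of the mechanism that silences the periphery.

Per-cell Poisson trains of square current pulses (rate 1/150 per ms,
6 uA/cm^2, 1 ms; overlaps sum) provide the symmetry breaking. They matter
more than their size suggests: without them the deterministic network
converges onto a perfectly synchronized state in which every low-gKs cell
fires in lockstep and no spatial competition - hence no theta - can
develop. Scenario runs (`run_experiment()`) therefore enable the noise by
default; the raw `run_simulation()` API leaves it off unless asked.

## The gKs ("ACh") map generator

Maps are produced by a discrete diffusion-release-decay iteration on the E
lattice, started from the uniform ceiling 1.5 mS/cm^2:

    g[n+1] = g[n] + D * Laplacian(g[n]) - R + B * (1.5 - g[n])

with a 5-point periodic Laplacian, constant release R = R_amp at the
chosen hotspot sites, and decay back toward the ceiling. The iteration is
frozen at the step where a single isolated site first reaches the target
effective radius, defined as the area-equivalent radius of the region
under the 0.6 mS/cm^2 contour (`hotspot_radius()`); the frozen field is
clamped to [0.2, 1.5] and I cells receive the mean of their 2 x 2 E block.

Two numerical choices deserve comment. First, the bounds are imposed on
the frozen map, not per iteration step: a per-step floor clamp turns each
site into a saturating point sink whose 0.6-contour radius provably
plateaus near 4 lattice units on this lattice, so the larger radii the
experiments need (up to ~6.8) would be unreachable. Unclamped, the
iteration is linear, multi-site maps are exact superpositions of
single-site bowls, and the single-site calibration transfers. Second, the
defaults D = 0.2, B = 0.04, R_amp = 25 give compact bowls (Bessel-type
tails, background intact at the ceiling) whose transient sweeps effective
radii up to ~6.2; the radius-scan scenario uses B = 0.02, R_amp = 12
(saturation ~7) to cover its widest hotspots. Because a hotspot of radius
r covers pi r^2 cells, the multi-hotspot scenarios (9 sites at r = 4.2;
6 at r = 5.4) nominally exceed the lattice area and the maps are dominated
by overlapping, coalesced low-gKs territory - which is exactly the regime
the random-map experiments explore.

## Rhythm analysis

The network spectrum (`network_spectrum()`) is the Fourier transform of
the raster correlogram: spike trains are binned at 1 ms, and the
mean-subtracted autocorrelation (lags up to ~1 s, Hann window) of each
cell's train is summed across the population before the magnitude
spectrum is taken. Counting same-neuron spike pairs rather than all pairs
matters for symmetric geometries: when two hotspots alternate in
anti-phase, their pooled firing rate is nearly constant and the pooled
histogram cancels the very rhythm each cell expresses; the summed per-cell
correlogram keeps it. The pooled-histogram estimator remains available
(`correlogram = "population"`). Band peaks are searched at 2.5-20 Hz
(theta) and 25-100 Hz (gamma), and a peak is called significant when it
exceeds 4x the mean power over 2-100 Hz - one rule for cells and network.

Per-cell classification (`classify_cells()`) applies the same machinery to
individual trains after smoothing with a 3 ms Gaussian, labeling cells
`none` (under 5 spikes or no significant band), `theta`, `gamma` or
`mixed`. One guard is needed: a metronomic train (ISI coefficient of
variation < 0.2) carries exactly one rhythm - its firing rate - yet its
autocorrelation is a harmonic comb whose gamma-band harmonics scale with
its own mean power, so no threshold can discount them; such trains are
labeled by the band containing their firing rate.

## LFP proxy and theta-gamma coupling

A location's LFP proxy (`lfp_at()`) sums the Gaussian-smoothed
(sigma = 1.5 ms, unit area) spike trains of the 12 E cells nearest to the
location; a voltage mode sums recorded membrane potentials instead. The
trace is band-pass filtered (order-3 Butterworth, zero-phase
forward-backward; theta pass band = measured theta peak +/- 2 Hz, gamma
peak +/- 10 Hz), the theta phase and gamma amplitude envelope are taken
from FFT-constructed analytic signals (200 ms discarded at each end), and
the modulation index (`modulation_index()`) is the normalized entropy
deficit of the mean gamma amplitude over 18 theta-phase bins:
MI = (log N - H(P)) / log N, which is 0 for phase-uniform amplitude and 1
when all amplitude falls in one bin.

In the double-hotspot scenario the MI declines with distance from a
hotspot center overall (Spearman rho about -0.6 over a 10-point line),
with a shallow plateau just inside the hotspot edge where sparse but
tightly episode-locked firing concentrates the envelope in few phase
bins; the contrast between center and remote locations is robust.

## Experiments and reproducibility

`scenario_spec()` names the bundled configurations: the 9-hotspot random
map, single- and double-hotspot geometries, the radius and
hotspot-distance scans, homogeneous-map ladders, E-E rewiring, tau_z and
inhibitory-timescale scans, sparse inhibition, current-drive hotspots and
the stimulus-gating experiment. `run_experiment()` realizes maps,
topology and drive per replicate seed (4 replicates by default, matching
the replication convention of the analyses), simulates, and aggregates
spectra and label counts; `run_scan()` sweeps dotted-path parameter
overrides across a grid and tabulates band powers, peak frequencies and
label counts. All specs serialize to YAML and carry an MD5 hash that is
stamped on outputs.

Default problem sizes keep a full scenario (4 replicates x 5.5 s at
dt = 0.05 ms) around a minute on one core; the test suite and the
acceptance script use 2-4 replicates and 3.5-5.5 s windows, which pilot
runs showed to be enough for stable band peaks and label counts.

## What the model does and does not show

The synthetic maps emulate frozen snapshots of patchy muscarinic
modulation; they do not model receptor kinetics, ACh diffusion in real
tissue geometry, time-varying maps, nicotinic or presynaptic ACh targets,
synaptic plasticity, conduction delays or multi-compartment neurons. The
LFP is a spike-sum (or voltage-sum) proxy with no volume conduction.
Passing tests show that the stated network mechanisms produce the stated
rhythm phenomenology in this model class - not that cortex works this way.

Two quantitative notes. With the printed cellular parameters
(tau_z = 75 ms, drive 3.0 uA/cm^2) the hotspot-alternation rhythm runs at
3.9-4.6 Hz, at the slow edge of (and partly below) the canonical 5-12 Hz
theta band; it speeds up with smaller tau_z (7.2 Hz at 25 ms) and with
smaller hotspots, so the package reports the measured peak rather than
forcing it into the nominal band. And the gamma-cell count along the
radius scan peaks near r ~ 6.2 before reversing (mixed-rhythm cells take
over), somewhat above the turning point seen with other map profiles;
the reversal itself is robust.
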