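---
title: "Metastable E/I-clustered spiking networks: model, calibration and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable E/I-clustered spiking networks: model, calibration and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eiclust)
```

## The model

`eiclust` simulates balanced networks of leaky integrate-and-fire neurons
with exponential synaptic currents. The subthreshold membrane potential of
each neuron obeys

$$\frac{dV}{dt} = \frac{-(V - E_L)}{\tau_m} + \frac{I_{syn} + I_x}{C_m},$$

with a spike emitted when $V \ge V_{th}$, after which $V$ is clamped to
$V_R$ for an absolute refractory period $\tau_r$. Each neuron carries two
synaptic currents, one per source population, decaying with $\tau_{syn,E}$
and $\tau_{syn,I}$; an arriving spike from neuron $j$ increments the
matching current of its targets by the synaptic efficacy $J_{ij}$ (pA).
All external drive is a constant current $I_x$, so that every bit of
variability in the simulation is generated deterministically inside the
network rather than injected as external noise.

Networks come in four topologies. The *random balanced* network connects
every ordered pair independently with the probability of its population
pair. The *E-clustered* network divides the excitatory population into $Q$
equal clusters and potentiates within-cluster E→E weights by a factor
$J_{E+}$, depressing across-cluster weights by
$J_{E-} = (Q - J_{E+})/(Q - 1)$ so the mean weight of the class is
conserved. The *E/I-clustered* network also divides the inhibitory
population into $Q$ clusters and scales the EI, IE and II weights by
$J_{I+} = 1 + R_J (J_{E+} - 1)$ within a cluster pair (and $J_{I-}$
across), so that each excitatory cluster is held in check by its own
inhibitory partner. The *E+I variant* only potentiates the unidirectional
excitatory input onto the paired inhibitory pool, without selective
inhibitory output — it serves as a control showing that correlation alone,
without local balance, does not widen the metastable regime.

## Weight calibration

Synaptic weights are derived from first principles rather than fitted. The
response of the membrane to a single presynaptic spike is the
postsynaptic-potential kernel

$$PSP(t) = \frac{J}{C_m} \frac{\tau_m \tau_{syn}}{\tau_m - \tau_{syn}}
  \left(e^{-t/\tau_m} - e^{-t/\tau_{syn}}\right),$$

whose peak (at $t^* = \log(\tau_{syn}/\tau_m)/(1/\tau_m - 1/\tau_{syn})$)
differs per synapse type because it depends on the target's $\tau_m$ and
the source's $\tau_{syn}$. Scale-free weights are constructed so that about
$\sqrt{K}$ near-simultaneous excitatory spikes (with $K$ the excitatory
in-degree) drive the membrane from rest to threshold, with inhibition onto
each population scaled by the relative strength $g$ and by the ratio of
excitatory to inhibitory in-degree drive; the final weights divide by
$\sqrt{N}$:

```{r}
compute_weights(network_spec())       # 4000 E + 1000 I neurons
compute_weights(task_network_spec())  # 1200 E + 300 I task network
```

A note on conventions: the synaptic ODE can be written with the spike
increment scaled by $1/\tau_{syn}$ or not; we adopt the convention in which
a presynaptic spike increments the synaptic current by exactly $J$ pA,
because the PSP-based calibration above (and the parameter tables it
reproduces) is built on it. The $1/C_m$ factor in the kernel is carried
explicitly so units remain correct for $C_m \ne 1$ pF. The calibration has
a pole at $\tau_{syn} = \tau_m$; the parameter validator rejects such
degenerate settings rather than silently taking the limit.

The external drive is expressed in rheobase units,
$I_{th} = (V_{th} - E_L) C_m / \tau_m$: the 5000-neuron parameterization
uses $I_x = 2.13\,I_{th}$ (E) and $1.24\,I_{th}$ (I), which produces mean
firing rates near 3 and 5 spikes/s in the asynchronous-irregular state; the
1500-neuron task network uses 1.25 and 0.78.

## Numerical integration

The paper-level model definition leaves the integrator open, so the
package makes these choices explicit:

* **Exponential-Euler stepping** at `dt = 0.1` ms by default: membrane and
  synaptic updates use their exact exponential propagators under a
  piecewise-constant-input assumption. Halving `dt` changes population
  rates by only a few percent (this is asserted in the test suite).
* **One-step synaptic delay** by default. Spikes detected at step $k$ are
  delivered at step $k+1$ — the minimal causal choice; zero-delay same-step
  delivery would make the update order itself a hidden parameter. The delay
  is configurable (`simulate_network(..., delay = )`); longer delays
  (0.5–1 ms) measurably reduce cluster switching in the task network, which
  is why the minimal default stands.
* **Threshold test after the subthreshold update**, spike time recorded at
  the step end, no sub-`dt` interpolation.
* **Initial conditions**: membrane potentials are drawn uniformly on
  $[V_R, V_{th})$ to avoid start-up synchrony; this is the only randomness
  in a simulation, so runs are bit-reproducible given a seed.
* **Divergence guard**: non-finite potentials abort with a time stamp.

## Variability statistics

The Fano factor $FF = \sigma_c^2/\mu_c$ measures spike-count dispersion
across repeated trials; the local coefficient of variation
$CV_2 = 2\langle|\tau - \tau'|/(\tau + \tau')\rangle$ over consecutive
inter-spike intervals measures within-trial irregularity robustly against
slow rate modulation. Both are available in a sliding, *centered* window
(default 400 ms wide, 25 ms step), so a response to a trigger can begin to
show up to half a window before the trigger. Averaging follows the
per-unit-first order: the statistic is computed per unit (for FF, across
trials; for CV2, per trial then averaged over trials) and then averaged
across units. Windows or trains that do not admit the statistic (mean
count 0; fewer than 3 spikes) are excluded from the average, not
zero-filled. Variance estimators use the unbiased $n-1$ denominator
throughout, including inside the synchrony measure
$\chi = \sqrt{\sigma^2_{pop}/\langle\sigma_i^2\rangle}$ (computed on 20 ms
spike counts).

When trials with different stimulus sequences are pooled — as in the task,
where the cued target changes across trials — the across-trial FF must be
computed per (unit, stimulus-sequence) sample before averaging
(`time_resolved(..., groups = )`); pooling heterogeneous trials would
confound stimulus selectivity with trial-to-trial variability.

For stationary processes, interval and count statistics are linked by
$\lim_{T\to\infty} FF = CV^2 (1 + 2\xi)$ with $\xi$ the summed serial
interval correlations; `renewal_consistency()` estimates this with the sum
truncated at lag 10 (configurable) because the infinite sum is not
estimable from finite data.

## What the synthetic generators emulate

`gen_poisson()`, `gen_gamma()` and `gen_switching()` provide seeded
fixtures with known expectations: Poisson ($FF = CV_2 = 1$), equilibrium
gamma renewal ($CV^2 = 1/k$, limiting $FF = 1/k$) and a two-state Markov
telegraph rate ($FF > 1$ with $CV_2 \approx 1$), the latter mimicking the
count statistics of metastable cluster switching. They emulate only the
count/interval statistics of cortical data — not rate nonstationarity
within trials, unit heterogeneity, or cross-correlations — so tests passing
on them validate the estimators, not the realism of the network model.

## Scan protocols

The cluster-strength scan (`scan_cluster_strength()`) builds fresh network
realizations per grid point, simulates spontaneous activity and computes
the FF from 20 consecutive 400 ms trials. Trials are cut after a 2 s
settling transient: strongly E-clustered networks need that long to freeze
into their winner-takes-all state, and sampling the transient instead of
the stationary regime would inflate their FF. The default of 5
realizations per point keeps a desk-scale scan in minutes; the full-scale
protocol (50 realizations) is a documented long-running mode via the
`n_realizations` argument.

The stimulus-response scan (`scan_stimulus_response()`) stimulates 5 of 50
clusters for 1000 ms per trial, separated by relaxation gaps, and computes
the evoked changes in a network whose cluster strength must be chosen from
the metastable band. We use $J_{E+} = 6$ as the representative E/I
operating point: there, weak stimuli reliably lock the stimulated clusters
into their active state and trial-to-trial variability drops
($\Delta FF < 0$, consistently across network realizations). Deeper
attractors ($J_{E+} \gtrsim 10$) resist locking in our implementation — the
stimulated clusters keep competing among themselves and $\Delta FF$ can
turn positive — so the variability-quenching regime occupies the lower part
of the metastable band. For the E-clustered comparison the operating point
sits just below the switching ridge ($J_{E+} = 3.2$ at $Q = 50$): there,
spontaneous activity is quiescent and weak stimuli (0.05–0.1 pA) activate
clusters only in a fraction of trials, inflating the Fano factor — the
unreliable-activation signature. At the ridge itself ($J_{E+} \approx
3.5$) spontaneous winner states drift on tens-of-seconds timescales and
their huge spontaneous FF swamps the evoked change. The scan computes
per-neuron Δrate and ΔFF between matched 1000 ms spontaneous and evoked
epochs, averaged within stimulated and non-stimulated groups. Following
the active-period rule, the evoked rate of stimulated clusters counts only
time bins in which the trial-averaged cluster rate exceeds the median rate
of the non-stimulated clusters; on a perfectly flat process this rule
introduces a small upward selection bias (conditioning on upward
fluctuations), which is the price of excluding inactive periods when
cluster activation is intermittent. If no bin passes the mask the full
epoch is used.

## The task and the decoder

`make_task_protocol()` reproduces the delayed center-out protocol: TS at
$t_0$, PS at $t_0 + 500$ ms cueing 1, 2 or 3 adjacent directions
(Conditions 1–3; cue sets restricted to six singletons, the pairs 1-2,
3-4, 5-6, and the triples 6-1-2, 3-4-5), RS at $t_0 + 1500$ ms indicating
the final target (uniform over the cued set) for 400 ms, and inter-trial
intervals uniform on 1.5–1.7 s so that no periodicity builds up. Each
direction maps to one E/I cluster of the 6-cluster task network; cued
clusters' excitatory units receive a constant 0.1 pA stimulus (0.05 pA
reproduces a lower-attention regime via the same configuration switch).
Conditions run in blocks by default, like the experimental sessions; for
scaled runs (tens of trials per condition) `interleave = TRUE` randomly
interleaves conditions on the timeline, because the network state drifts
slowly over minutes and block-wise comparisons at small trial counts would
confound condition effects with that drift.

The stimulus amplitude deserves a caveat: it is, by the study's own
procedure, a calibration constant — chosen so that evoked rates and the
variability reduction match the recordings. In this implementation the
preparatory-period effects (cue-cluster dominance near 1, and the ordering
of the preparatory Fano factor by the number of cued targets) emerge
cleanly at 0.2 pA, while at 0.1 pA cue-cluster dominance is partial
(~0.5–0.85 across network realizations) and the FF ordering is not
resolved. Unpublished numerical details (integration step, synaptic delay,
spike handling) shift the effective calibration point between
implementations; the package keeps 0.1 pA as the default and exposes the
amplitude as the tuning parameter it is.

Reaction-time statistics are reported over successful trials only (the
experimental analysis likewise includes only correct trials).

The decoder integrates each cluster's instantaneous population spike count
with a leaky integrator ($\tau_I = 50$ ms, 1 ms bins; the bin width only
rescales the integrator, and its units are absorbed by the threshold) and
normalizes across directions to a decision variable
$DV_d = I_d / \sum_j I_j$. Design choices where the procedure was open:

* integration starts at PS onset, so a DV can already be above threshold
  at RS (an anticipatory decision with reaction time 0); threshold
  crossings are only *evaluated* from RS onward, within a 400 ms window;
* an all-zero denominator yields the uniform $DV = 1/Q$;
* simultaneous crossings break toward the lower direction index;
* the threshold $\theta$ is tuned on a grid (0.50–0.99, step 0.01) to
  maximize pooled decision accuracy, mirroring the adjustment of the
  behavioral threshold to maximize session-averaged performance.

Movement-direction decoding from population activity uses a multinomial
logistic (ridge-penalized, fixed small penalty) classifier on per-trial
spike-count vectors in a sliding 400 ms window with stratified 5-fold
cross-validation; accuracy is the per-direction correct fraction averaged
over directions, then folds. The plateau levels during the preparatory
period (1, 1/2, 1/3 for Conditions 1–3) reflect target uncertainty, not
classifier capacity, and are insensitive to the penalty choice.

## Problem sizes used in tests

The packaged tests and the acceptance script run at desk scale, chosen as
the package's own defaults: the 5000-neuron network for balanced-state and
metastability checks (5 realizations per scan point, 20 trials of 400 ms),
20 trials per amplitude for the stimulus scans, and 30 trials per
condition for the task model. These sizes leave the qualitative regime
boundaries and the calibration targets intact; full-scale runs (50
realizations, 150 trials per condition) use the same functions with larger
arguments.

## Known limitations

* Synapses are current-based and exponential; no conductance synapses,
  spike-frequency adaptation, axonal delay distributions, or heterogeneous
  per-neuron parameters.
* Connectivity is Bernoulli per ordered pair (no fixed in-degree), with
  autapses excluded and cluster membership assigned in contiguous index
  blocks.
* One cluster per movement direction means single units are sharply, not
  broadly, tuned.
* The fast transient dip of trial-to-trial variability right after a cue,
  attributed to cell-autonomous adaptation mechanisms, is outside the
  model class and is not reproduced.
* The decision stage is a readout; it does not feed back into the network.
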