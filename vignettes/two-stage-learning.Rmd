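---
title: "Two-stage tutor-student motor learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage tutor-student motor learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tutorsim)
```

## The model

`tutorsim` simulates learning in a three-part circuit modeled on the songbird
vocal system. A *conductor* population (the HVC analogue) provides a precise
timebase: each neuron fires a single burst at a fixed moment of a motor
program of duration $T$ (1 s by default, the scale of a song motif). A
*student* population (the RA analogue) receives plastic synapses $W_{ij}$
from the conductor, and its activity drives the motor output. A *tutor*
population (the LMAN analogue) supplies each student neuron with a guiding
signal $g_j(t)$ that both steers plasticity and injects exploration
variability.

In the linear rate model, student activity and output are

$$ s_j(t) = \sum_i W_{ij} c_i(t) + w\,g_j(t) - x_{\mathrm{inh}}, \qquad
   \tilde y_a(t) = \sum_j M_{aj} \int_0^t s_j(t')\,e^{-(t-t')/\tau_{\mathrm{out}}}\,dt', $$

with the output smoothing $\tau_{\mathrm{out}} = 25$ ms standing in for
muscle response times. Each student neuron feeds exactly one output channel
(two channels by default), so the map $M$ has one nonzero entry per column.
Performance is the quadratic loss
$L = \tfrac12\sum_a\int_0^T (y_a - \bar y_a)^2\,dt$ against a target
$\bar y_a(t)$.

Plasticity at the conductor-student synapses is heterosynaptic with two
timescales:

$$ \frac{dW_{ij}}{dt} = \eta\,\tilde c_i(t)\,(g_j(t) - \theta), \qquad
   \tilde c_i = K * c_i, \qquad
   K(t) = \alpha\,\tau_1^{-1} e^{-t/\tau_1} - \beta\,\tau_2^{-1} e^{-t/\tau_2}. $$

Setting $\alpha$ or $\beta$ to zero gives a rate rule (the sign of change is
set by the tutor rate against the threshold $\theta$); $\alpha/\beta \approx
1$ gives a timing rule where the relative ordering of conductor and tutor
activity decides the sign. The overall scale of $(\alpha,\beta)$ is absorbed
into $\eta$, so the package enforces $\alpha-\beta = 1$.

## The matching condition

Requiring that the accumulated per-rendition weight change follow the loss
gradient identifies the tutor signal

$$ g_j(t) = \theta - \frac{\zeta}{\alpha-\beta}\,\frac{1}{\tau_t}
   \int_0^t \epsilon_j(t')\, e^{-(t-t')/\tau_t}\, dt', \qquad
   \epsilon_j = \sum_a M_{aj}(y_a - \bar y_a), $$

with the error-integration timescale tied to the plasticity kernel:

$$ \tau_t^* = \frac{\alpha\tau_1 - \beta\tau_2}{\alpha-\beta}. $$

`optimal_timescale()` evaluates this; with $\tau_1 = 80$ ms and
$\tau_2 = 40$ ms, the rule $(\alpha,\beta) = (0,-1)$ is matched by a 40 ms
tutor, $(1,0)$ by 80 ms, and $(24,23)$ by 1000 ms. Mismatched tutors
degrade learning asymmetrically: timescales far *below* the optimum disrupt
it, timescales above slow it (`run_mismatch_sweep()` reproduces this
pattern on a 5x5 grid).

### Validity domain, and how the gradient test is set up

The matching derivation Taylor-expands the tutor signal across the kernel
width. Writing the accumulated update for a burst at $t_i$ as
$\eta[(\alpha-\beta)(g(t_i)-\theta) + (\alpha\tau_1-\beta\tau_2)g'(t_i) +
(\alpha\tau_1^2-\beta\tau_2^2)g''(t_i) + \dots]$, the neglected curvature
term is controlled by the ratio
$(\alpha\tau_1^2-\beta\tau_2^2)/\tau_t^* \cdot \omega$ at error frequency
$\omega$. For $\alpha \approx \beta$ this coefficient approaches
$\tau_1+\tau_2$ *independently of* $\alpha$, so gradient equivalence at the
percent level requires error features much slower than
$(\tau_1+\tau_2)\,2\pi$. Two further effects bias the comparison at the
boundaries: kernels of bursts within a few $\tau_1$ of the end of the
program are truncated, and the output filter shifts the gradient's
conductor profile by $\tau_{\mathrm{out}}$.

The package's gradient-equivalence test therefore probes the regime the
theory actually describes: a 5 s program, bursts tiling the interior with a
0.5 s margin, kernel timescales scaled to $\tau_1 = 20$ ms, $\tau_2 =
10$ ms with $(\alpha,\beta) = (24,23)$ (so $\tau_t^* = 250\ \mathrm{ms} \gg
\tau_{1,2}$), targets smooth at 1 s, and a 10 ms output filter. There the
cosine similarity between the tutor-driven update and the finite-difference
loss gradient exceeds 0.999. Outside this regime — in particular for
long-$\tau_t^*$ rules paired with targets carrying 50 ms structure — the
curvature term rotates updates at feature frequencies and matched learning
itself can deteriorate; the same insensitivity of the rule to structure
below ~100 ms is why short-timescale mismatches cost little.

## Engines

**Rate engine.** The error-integrating tutor runs in closed loop within each
rendition: at every time step the tutor state integrates the error produced
so far while its signal contributes to the very student activity that shapes
the output (a C++ time-stepper keeps this exact and fast). Weight updates
are applied once per rendition. The tutor gain in the student ($w = 0.5$) is
modest, so the output is dominated by what the student has learned, not by
the tutor's online correction.

**Spiking engine.** Students are leaky integrate-and-fire neurons with
current-based AMPA/NMDA synapses, magnesium-gated NMDA conductance,
activity-dependent global inhibition, and a 1.1 ms refractory period,
integrated with exponential-Euler steps at 0.1 ms (exact for inputs held
constant within a step; events are applied first, then the membrane update,
then the threshold test, so runs are bit-reproducible). Conductor neurons
fire jittered 5-6-spike bursts at 632 Hz; tutor neurons fire inhomogeneous
Poisson trains whose rate follows the saturating tutor formula. Firing
rates entering the plasticity rule and the motor output are estimated by
causal exponential filtering of spike trains (20 ms kernel, within the
5-40 ms range the estimator is designed for). The tutor rate program for a
rendition is computed from the motor error of the previous rendition —
biologically, the evaluation of the last attempt sets the corrective bias
for the next — which makes every rendition a clean feedforward pass; with
per-rendition weight changes small, this is gradient descent with a
one-step delay.

Synaptic currents are expressed in pA: the calibrated mean conductor
synapse of 32.6 pA (s.d. 17.4) then depolarizes a 353 MOhm membrane by
~11.5 mV per spike, the scale of strong HVC-RA synapses measured in slice,
and produces irregular juvenile-like firing (ISI CV ~ 0.8-1.0) in the
untrained network. Magnesium concentration defaults to 1 mM (the gating
formula fixes only the 3.57 mM scale, not the concentration itself).

## Synthetic data: what it emulates and what it does not

Targets (`generate_target()`) emulate air-sac-pressure-like recordings:
independent channels of white noise filtered twice at $\tau_s/2$ (so the
autocorrelation time is close to the nominal $\tau_s = 50$ ms), affinely
mapped into an amplitude range, and ramped up smoothly from zero at program
onset — pressure traces rise from the expiratory baseline, and the model's
causal output filter likewise starts from rest, so an onset ramp removes a
mismatch no synapse could fix. They are *not* real recordings: they have no
syllable structure, no cross-channel correlations, and no
rendition-to-rendition variability, so passing tests demonstrate the
learning machinery, not fidelity to any particular song.

Conductor rasters tile the program evenly (index-based windows, so even
tiling leaves no single-sample gaps), with amplitude scaled so the summed
drive is approximately constant. Spiking conductor bursts alternate 5 and 6
spikes deterministically (the observation "5-6 spikes" underdetermines the
draw) and jitter is uniform over the quoted half-ranges (0.3 ms onset,
0.2 ms per spike), the least-informative reading of a "+/-" range.

## Reinforcement tutor

When the tutor cannot see $\epsilon_j$ it learns its rate program $f_j(t)$
from a scalar reward. The packaged reward is the instantaneous negative
squared error $R(t) = -\sum_a (y_a-\bar y_a)^2$ (any per-time monotone
transform would do; this one integrates to $-2L$). The update correlates
reward deviations with the tutor's own activity fluctuations
$\xi_j = g_j - \bar g_j$:

$$ \Delta f_j(t) = \eta_t\,(R(t)-\bar R(t))\,\xi_j(t) $$

for the memory-less tutor, or its causal exponential filtering over
$\tau_t$ otherwise. $\bar R$ is the 1 s exponential average of the reward
seeded with the previous rendition's terminal reward; $\bar g$ decays by one
e-fold per five renditions. In the rate engine, where neurons are
deterministic, exploration is injected as low-pass-filtered Gaussian rate
noise (20 ms timescale, 20 Hz s.d.) standing in for the Poisson variability
that provides it in the spiking engine. An optional variant
(`reward_norm = TRUE`) divides reward deviations by their running RMS; the
default leaves them raw, because the shrinking reward scale then anneals
the tutor step as performance improves.

Two-stage reinforcement learning is much slower than tutoring with known
credit assignment: on the default rate network, loss falls below 10% of its
initial value after roughly 3,500 renditions (versus ~100 for the matched
tutor), after which consolidation of residual exploration noise and the
sticky tutor program can transiently overshoot the target — the same
overshoot that drives the rise-then-fall of the conductor-input count per
student neuron (`run_reinforcement()` records this pruning curve in the
spiking engine). Demonstrating the full overshoot-recovery-pruning cycle in
the spiking engine takes on the order of $10^4$ renditions and is left to
explicit long runs; the test suite exercises the mechanics at small scale.

## Problem sizes and tunables

Rate presets use 100 conductor and 20 student neurons on a 1 ms grid
(neither count is constrained by the biology; they are comfortable
desk-scale choices), initial weights uniform on $[0, 0.1]$, and the
inhibitory bias set so initial student activity is near zero. The learning
rate $\eta = 16$ and tutor gain $\zeta = 200$ were tuned once so that
matched learning converges below 1% of the initial loss within 1000
renditions — the quantity $\eta\zeta$ is the effective gradient step, so
only the product matters. The residual at convergence concentrates in the
last ~100 ms of the program, where plasticity-kernel truncation weakens the
updates of late-bursting conductors.

Spiking presets reduce the full 300x80 network to 150 conductor and 40
student neurons with the synapse count per student scaled to keep density
(74) and synaptic strengths doubled to keep per-student drive; the target
amplitude range is calibrated per run from an untrained baseline rendition
(5th-95th percentile of its output), so targets are reachable. $\eta =
4\times10^{-3}$ and $\zeta = 1200$ give a median halving of the loss well
within 600 renditions. The mismatch sweep preset (5x5 grid, 200 renditions,
3 seeds, medians) is the reduced analogue of the full 1000-cycle heatmap.

## Numerical choices

* Causal exponential filters use a recursion algebraically identical to
  trapezoid quadrature of the convolution integral (the kernel factorizes
  across samples), with zero initial state; filters can carry state across
  renditions where the reward baseline requires it.
* All quadratures (loss, weight updates, kernel moments) are trapezoid on
  the shared grid.
* The LIF integrator is exponential-Euler per state variable; subthreshold
  responses to constant current are exact to rounding, and constant-current
  inter-spike intervals match the analytic formula to one time step.
* Degenerate inputs are contracts, not surprises: empty spike trains yield
  zero rates and NA-flagged ISI statistics (excluded from the relative-error
  objective with a warning); $\alpha = \beta$ makes the optimal timescale
  undefined and errors out; divergent learning runs (loss exceeding 1000x
  initial) abort with the partial trace flagged.
* ISI coefficients of variation use the population (1/n) standard
  deviation, so small hand-checkable cases are exact.
* Burst statistics are computed per neuron and then averaged (a pooled
  variant is available), with the 80/40 Hz hysteresis segmentation applied
  to the exponential-kernel rate estimate.

## Known limitations

Tutor spiking is Poisson, not bursty, which understates the variability a
bursty tutor would inject through NMDA dynamics. The push-pull output
architecture and nonlinear student transfer functions are out of scope, as
is fitting spiking statistics to real juvenile/adult recordings — only the
descriptive statistics and the relative-error objective for such a fit are
implemented (an external optimizer can be pointed at
`relative_error(spike_statistics(...), obs)`). Long-memory matched rules
($\tau_t^* \gtrsim 0.4$ s) are reliable only for targets substantially
smoother than the default 50 ms, for the curvature reasons above.
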