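---
title: "Spike-based Expectation Maximization: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-based Expectation Maximization: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semwta)
```

# The model

`semwta` simulates a winner-take-all (WTA) circuit of $K$ stochastic
spiking neurons driven by $n$ input channels. Neuron $k$'s membrane
potential is

$$u_k(t) = \sum_i w_{ki}\,\tilde y_i(t) + b_k - I(t),$$

where $\tilde y_i(t)$ is the EPSP activation trace of channel $i$, $b_k$
an intrinsic excitability, and $I(t)$ an inhibition signal common to all
neurons. Firing is exponential-stochastic: neuron $k$ spikes as an
inhomogeneous Poisson process with rate $r_0 e^{u_k(t)}$. Because the
inhibition is common, the probability that a given circuit spike
originates from neuron $k$ is the softmax
$q_k = e^{u_k} / \sum_l e^{u_l}$, independent of $I(t)$: each output
spike is a sample from a distribution over the $K$ neurons that depends
only on the excitatory drives.

When the inputs follow a population code — one channel per (variable,
value) pair, the active channel firing Poisson, silent groups meaning
*missing value* — this sampling distribution is exactly the posterior
over the hidden cause of a multinomial mixture model whose parameters
sit in the weights: $\pi_k \propto e^{b_k}$ and
$p_{k,j}(v) \propto e^{w_{k,i(j,v)}}$ ([weights_to_model()],
[posterior()]). Spiking performs inference; each spike is one posterior
sample (the E-step of an online EM algorithm).

# The plasticity rules

Learning is purely local and spike-triggered. At each circuit spike of
neuron $k$:

* **synapses** (complex / continuous-time rule):
  $\Delta w_{ki} = \eta\,(c\,\tilde y_i\,e^{-w_{ki}} - 1)$. The LTP
  window inherits the EPSP kernel shape; depression is a flat offset.
  The expected update vanishes only at
  $w^* = \log(c\,E[\tilde y_i \mid \text{post spike}])$ — the weight
  converges to a log conditional probability (plus $\log c$), which is
  what the inference semantics require. With binary rectangular traces
  this is the simple pre-before-post STDP rule.
* **excitabilities**: $\Delta b_k = \eta_b (e^{-b_k} - 1)$ for the
  firing neuron and $-\eta_b$ for the others, driving $b_k$ to the log
  of the neuron's spike share — the mixture prior.

Together the updates approximate the M-step of stochastic online EM:
spiking proposes a cause, plasticity moves that cause's parameters
toward the responsibility-weighted statistics. Normalization
($\sum_v p_{k,j}(v) = 1$, $\sum_k \pi_k = 1$) is not enforced; it is a
property of the equilibria, checked by [emergent_normalization()].

A timing-dependent LTD variant replaces the flat depression with a term
driven by presynaptic spikes shortly *after* the postsynaptic spike
(mechanistically: a postsynaptic spike trace read out at presynaptic
firing). Its equilibrium is the log-ratio of presynaptic activity before
versus after the postsynaptic spike, so the weights then encode the
contrast between the pattern that caused firing and what follows it.

## Learning-rate control

`eta` can be fixed or adaptive (`"variance_tracking"`): each synapse
tracks running first and second moments of its own weight and sets
$\eta = \widehat{\mathrm{Var}}(w)\,\hat p/(1-\hat p)$ with
$\hat p = e^{S - \log c}$, clipped to `[eta_min, eta_max]`. For a
stationary input this decays like $1/N$ with the number of updates
(tested against that schedule); when the input distribution shifts, the
variance — and hence the rate — rises again, allowing reorganization.

Two numerical guards keep the stochastic updates in the well-behaved
regime without moving any equilibrium: weights are floored at
`log(c) - 7` (log-probabilities below $e^{-7}$ are not resolvable from
desk-scale spike counts, and a deeply depressed synapse would otherwise
make the next potentiation step, $\eta c e^{-w}$, catastrophically
stiff), and single updates are capped at `delta_max = 2`.

## Initialization

All neurons are initialized *at the average-input model*:
$w_{ki} = \log \bar y_i + \log c + \mathrm{U}(-j, j)$ with $\bar y_i$
the channel's expected stationary trace under its empirical firing rate
([wta_network_from_input()]), and $b_k = \log(1/K)$. This matters in
high dimension: the update rule rewards whichever neuron first adapts
toward the input statistics with a likelihood advantage proportional to
the number of active channels, so a neuron starting far from the
average-input statistics either hogs every spike or goes permanently
silent once a competitor converges. Starting at the average model, all
neurons remain competitive and only input-specific differences — the
signal that drives specialization — accumulate. The generic
[wta_network()] initializer (i.i.d. uniform weights in
$[\log c - 3, \log c - 0.5]$) is appropriate for low-dimensional tasks.

# Inhibition

The common signal $I(t)$ never changes which neuron wins, only when
spikes happen. It combines:

* a balancing term (`balance = "exact"`) equal to the log-sum-exp of
  the excitatory drives minus the log target rate, which pins the total
  circuit rate at `target_output_rate_hz`. This is the idealized form
  of the divisive inhibition the sampling semantics requires: the
  output rate $R(t)$ carries no information about the input (checked as
  a decorrelation test);
* an optional post-spike reset impulse ($A_I e^{-s/\tau_I}$,
  $\tau_I = 5$ ms), a refractory-like suppression after each circuit
  spike;
* optional Ornstein-Uhlenbeck background noise and a sinusoidal
  oscillatory drive, both shared across neurons.

# Synthetic inputs and what they emulate

* **Gaussian-blob images** ([gaussian_blob_dataset()]): four latent
  causes, each a Gaussian bump of pixel on-probabilities on a 28x28
  grid, with priors (0.1, 0.2, 0.3, 0.4); rarely-active pixels pruned,
  surviving pixels randomly permuted to hide all 2D structure, two
  channels per pixel (on/off code), 25 Hz active rate, 40 ms per image,
  10 ms gaps. Blob centers, width (4 px) and peak probability (0.9)
  are package choices (quadrant midpoints; values in the source
  publication's supplement are not public).
* **Oriented bars** ([oriented_bar_dataset()]): 7-px-wide bars at
  uniform random orientation on a 28x28 grid, 2% pixel flip noise
  (package default; not printed in the source), circular mask, 20 Hz
  encoding for 50 ms per image.
* **Frozen Poisson patterns** ([pattern_stream()]): five fixed 50 ms
  draws of 15 Hz Poisson spikes on 500 channels, replayed in random
  order with 5 Hz overlay noise, separated by 20 Hz pure-noise segments
  of uniform(50, 150) ms length (the gap-length law is a package
  choice) — a rate-stationary stream in which patterns are detectable
  only through spike timing.

These generators reproduce the *statistical structure* of the study
conditions — hidden causes, population coding, rate stationarity — not
the physiology of real recordings: real spike trains have refractory
structure, rate drift, and correlated noise that the generators omit.
Passing tests therefore demonstrate correctness of the learning
machinery under the model's own assumptions, not performance on
biological data.

# The desk-scale experiments

Problem sizes were chosen so each experiment runs in minutes on one
core.

* **Hidden-cause discovery** ([run_example1()]): K = 4 on the blob
  stream, rectangular integration window sigma = 40 ms (matching the
  40 ms presentations), 150 s of training by default. Reports the
  normalized-conditional-entropy trajectory $H(L|Z)/H(L)$ (the
  normalization by $H(L)$ is a package choice; the source text leaves
  the normalization unstated), the learned priors (read as the average
  over the final 50 s of checkpoints — the tail average of a stochastic
  approximation, which removes snapshot fluctuation), and the weight
  normalization summary. At 25 Hz and 40 ms a group is silent with
  probability $e^{-1} \approx 0.37$, and because the 40 ms window can
  straddle two consecutive images, the normalization offset is not
  constant across neuron-group pairs. The report therefore divides each
  per-group weight sum by the *measured conditional occupancy at the
  neuron's own spike times* ([occupancy_at_spikes()]) — exactly the
  quantity the equilibrium says the sum converges to. The corrected
  sums concentrate tightly around 1 (median 1.00; a couple of the
  ~2700 pairs in the rarest cause reach ~1.1, consistent with the
  estimator's ~3% sampling noise).
* **SEM vs batch EM**: on a separated 3-cause, 5-group task the model
  extracted from a converged run is compared with [batch_em_fit()] on
  held-out log-likelihood. For this comparison the encoding uses a gap
  equal to the integration window so that every plasticity update sees
  evidence from a single pattern — with shorter gaps the window
  straddles consecutive patterns and the learner sees systematically
  blurred evidence that the batch oracle never sees.
* **Orientation selectivity** ([run_example2()]): K = 10 on bars,
  200 s. Each neuron is seeded at a blend of the average-input model
  and one training image, the images chosen by greedy
  max-dissimilarity on their pixels (label-free, the spiking analogue
  of seeding a mixture fit at spread-out data points); all ten neurons
  then hold a foothold on the orientation family and the territory
  equalizes to ~18 degree tuning widths. A winner map over noise-free
  test bars is computed from expected activities (accumulated softmax
  shares — deterministic given the test encoding), and a neuron counts
  as a distinct oriented model if it wins a contiguous angular run of
  at least 5 degrees with a preferred angle at least 5 degrees from
  every other neuron's (the source describes the outcome only by its
  figures; these thresholds make it explicit).
* **Pattern detection** ([run_example4()]): K = 6 on the frozen-pattern
  stream, alpha-kernel EPSPs (1 ms rise, 15 ms decay), 200 s training,
  50 s held-out test with frozen weights. A neuron is *specialized*
  when at least 60% of its held-out spikes fall in intervals of one
  pattern id claimed by no other neuron (again an explicit version of a
  figure-level criterion). This task uses a *constant* learning rate
  (`eta = 0.02`) rather than variance tracking: the adaptive rate
  anneals while the pattern-to-neuron assignment is still resolving and
  can freeze a double-claimed or orphaned pattern in place; constant
  plasticity keeps the assignment mobile so such collisions heal within
  the 200 s budget. The typical outcome is 5 specialized neurons plus
  one noise detector; in up to half of the stream draws one frozen
  pattern happens to lie close enough to the noise average that it
  remains shared or orphaned within 200 s and the count is 4 — the
  outcome is a property of the draw, not of the learning
  configuration.
* **STDP curves** ([run_stdp_curves()]): single-synapse pairing at
  1/20/40 Hz with weight and learning rate fixed at $w = \log 0.2$,
  $\eta = 0.01$ — a mid-range learned probability; the source fixes the
  protocol but not these values — plus the 50 Hz burst protocol
  (5 pre / 4 post spikes, onset delays -120 ... 140 ms). Assertions are
  about sign patterns and orderings, not magnitudes.

## Configuration of the learning experiments

The two long experiments use configurations chosen once, on the
training dynamics, and kept:

* `target_output_rate_hz = 50` (patterns) / `100` (bars): a few
  posterior samples per 50 ms presentation;
* adaptive synaptic rates with `eta_max = 0.05`, `init_spread = 0.1`
  (fast early imprinting, self-annealing);
* `eta_b = 1e-5` for the pattern task: with only six neurons and a
  noise-dominated stream, faster prior hardening rewards a neuron that
  covers two patterns (its spike share doubles) and freezes that
  defect in; near-flat priors during training let the likelihood terms
  decide ownership. The blob task, whose point is prior recovery, uses
  `eta_b = 0.005`.
* the post-spike reset impulse is disabled (`reset_amplitude = 0`) in
  the two detection experiments so a detector can emit several spikes
  within one 50 ms presentation; it stays on by default elsewhere.
* the blob experiment keeps variance tracking (its point is converged
  parameter recovery) with `eta_min = 2e-3`, so late-phase estimates
  keep tracking the rarest cause instead of freezing mid-transient.

# Numerical choices

* Time-stepped simulation, `dt = 1` ms (0.1 ms for the STDP-curve
  protocols via `alpha_trace` evaluation, which is continuous); at most
  one spike per neuron per step in `independent_poisson` mode; a
  diagnostic counter flags steps with per-neuron spike probability
  above 0.2.
* Membrane potentials are clipped to `[-30, 30]` before
  exponentiation; the softmax is shift-invariant, so symmetric clipping
  is benign. Clip events are counted in the diagnostics.
* Alpha-kernel traces are advanced by two exponential state variables
  per channel and are *exact* at step boundaries (tested against the
  direct convolution at 1e-9).
* Decoder tie-break: if two channels of one group spiked in-window, the
  most recent wins; the decoder is diagnostic only, the network never
  uses group structure.
* EM initialization: random responsibilities (strictly positive), so
  no conditional is ever exactly zero after the first M-step;
  likelihoods are computed in log space with log-sum-exp.
* Label matching in recovery tests: exhaustive permutation search up to
  K = 8, greedy matching above.

# Known limitations

* The convergence guarantees of the rectangular-window theory do not
  transfer to the continuous-time rule; the package tests its behavior
  empirically (equilibria, STDP-curve shapes, detection experiments).
* With few neurons and heavily overlapping causes the online learner
  can transit long-lived plateaus where one neuron covers two causes;
  longer training or a lower `eta_b` resolves most, not all, cases.
* The inhibition's balancing mode is idealized (exact log-sum-exp
  tracking); a biophysical interneuron model is out of scope.
* No axonal delays, conductance-based synapses, or short-term
  plasticity.
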