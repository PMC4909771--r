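---
title: "Structural plasticity, effectual connectivity, and associative memory capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural plasticity, effectual connectivity, and associative memory capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptica)
```

## The model

Cortical networks are sparsely connected: within a macrocolumn of about
$n = 10^5$ neurons, only about $P = 0.1$ of neuron pairs are joined by an
actual synapse, while roughly $P_{pot} = 0.5$ of pairs are close enough in
the neuropil that a synapse *could* be grown (a *potential* synapse). If
memories are Hebbian cell assemblies — groups of $k$ coactive neurons wired
by potentiated synapses — then what limits storage is not the anatomical
connectivity at any instant but the fraction of the *required* synapses that
have been realized. This package implements that idea end to end:

* **Associative storage and retrieval** (`generate_patterns`,
  `store_willshaw`, `store_zipnet`, `retrieve`, `output_noise`). Binary
  pattern pairs $(u^\mu, v^\mu)$ are stored by clipped Hebbian learning
  ($W_{ij} = 1$ iff $\omega_{ij} = \sum_\mu u_i^\mu v_j^\mu \ge 1$, the
  Willshaw rule) or by a *zip net*: real-valued covariance or homosynaptic
  potentials binarized by per-neuron homeostatic thresholds that keep the
  fraction $p_1$ of 1-synapses fixed. One-step retrieval thresholds the
  dendritic sums $x_j = \sum_i \tilde u_i W_{ij}$; output quality is the
  noise $\hat\epsilon = \mathrm{Hamming}(\hat v, v^\mu)/l$.

* **Connectivity measures** (`measure_connectivity`,
  `consolidation_signal`). Four statistics describe a structurally plastic
  network: anatomical connectivity $P$, potential connectivity $P_{pot}$,
  the consolidation load $P_{1S}$ (fraction of neuron pairs whose synapse is
  *required* by the memory set, i.e. tagged by the consolidation signal
  $S$), and the effectual connectivity
  $P_{eff} = \sum H(W_{ij} S_{ij}) / \sum H(S_{ij}^2)$ — the fraction of
  required synapses already realized. Retrieval performance of the memory
  set depends on the network only through $P_{eff}$.

* **Synapse dynamics** (`step_micro`, `run_protocol_micro`, `step_macro`,
  `run_protocol_macro`). Each potential synapse is a three-state Markov
  chain: potential-only ($\pi$), realized but silent ($0$), potentiated and
  consolidated ($1$). Consolidation $0 \to 1$ (probability $p_{c|s}$),
  elimination $0 \to \pi$ ($p_{e|s}$), deconsolidation $1 \to 0$ (model A)
  or $1 \to \pi$ (model B) ($p_{d|s}$), and synaptogenesis $\pi \to 0$
  ($p_g$) are modulated by the consolidation signal $s = S_{ij}$; tags act
  only during rehearsal. Synaptogenesis is homeostatic by default:
  generation balances elimination so $P(t)$ is constant.

* **Capacity analyses** (`pattern_capacity`, `bayesian_capacity`,
  `zipnet_capacity`, `asymptotic_willshaw_capacity`). Exact finite-size
  binomial analysis of the diluted Willshaw network, and a Gaussian
  signal-to-noise analysis of covariance-rule networks with the
  binarization (zip) factor $\zeta(p_1)$.

* **Information flow** (`channel_bounds`, `estimate_te_retrieval`).
  Transfer entropy between the two populations, reduced over i.i.d. memory
  bits, is bounded below by the normalized storage capacity
  $CN = T(q, q_{01}, q_{10})$ and above by the output entropy
  $OE = H_b(\hat q)$; the bounds are attained for noisy and deterministic
  retrieval respectively.

* **Spacing effect** (`peff_after_gap`, `optimal_gap`,
  `run_cepeda_protocol`). Closed-form model-B theory of two-session
  learning: the performance reached by a brief re-study after a gap
  $\Delta t$, and the gap that maximizes retention.

## The exact Willshaw error analysis

For i.i.d. Bernoulli pattern components ($p = k/m$, $q = l/n$), a noiseless
query with $k$ active units, and each required synapse present independently
with probability $P_{eff}$:

* a *high* unit ($v_j^\mu = 1$) receives $X \sim \mathrm{Binom}(k, P_{eff})$
  potentiated inputs, so the miss rate at threshold $\Theta$ is
  $q_{10} = \Pr[X < \Theta]$;
* a *low* unit is potentiated onto by an active address unit with
  probability $\pi_1(B) = 1 - (1 - k/m)^B$ given its *unit usage*
  $B \sim \mathrm{Binom}(M-1, q)$ (the number of other memories containing
  it), so $q_{01} = \sum_B \Pr[B]\,\Pr[\mathrm{Binom}(k, P_{eff}\pi_1(B))
  \ge \Theta]$.

The usage sum is truncated where the binomial tail mass drops below
$10^{-14}$ and renormalized; binomial weights are evaluated in log space.
Output noise $\hat\epsilon = q_{10} + (1/q - 1)q_{01}$ is minimized over the
integer thresholds $0..k$, and the pattern capacity $M_\epsilon$ is the
largest $M$ keeping that minimum at or below $\epsilon$, found by
exponential bracketing plus integer bisection. Monotonicity of
$\hat\epsilon$ in $M$ is asserted on every evaluated bracket rather than
assumed. The Bernoulli component model is chosen (over exactly-$k$ patterns)
because it makes the usage-conditional independence across address units
exact; the Monte-Carlo tests therefore store one fixed-size target pair
among $M-1$ Bernoulli pairs, which realizes the analysis assumptions
exactly.

From the optimum the analysis reports the 1-synapse fraction
$p_1 = 1 - (1 - kl/mn)^M$, the minimal pruned connectivity
$P_1 = p_1 P_{eff}$, the stored information
$C_{abs} = M\,n\,T(q, q_{01}, q_{10})$, the weight-plasticity capacity
$C^{wp} = C_{abs}/(P_{eff} mn)$ and the total capacity per non-silent
synapse $C^{tot} = C_{abs}/(P_1 mn)$. In the asymptotic high-fidelity limit
$C^{wp}(p_1) = \log_2(p_1)\ln(1 - p_1)$, maximal at $p_1 = 1/2$ with
$\ln 2 \approx 0.69$ bit/synapse, while $C^{tot} = C^{wp}/p_1$ grows without
bound for sparse potentiation — the capacity argument for structural
plasticity.

```{r capacity}
pattern_capacity(50, 50, 1e5, 1e5, P_eff = 0.5, eps = 0.01)
```

## The Gaussian zip-net analysis

The covariance rule attains, to leading order at sparse activity, the
optimal (Bayesian) signal-to-noise ratio
$r^2 = mP(1 - p)/((M - 1)q(1 - q))$. Error rates follow Gaussian tails,
$q_{10} = \Phi(-(1-\gamma)r)$ and $q_{01} = \Phi(-\gamma r)$, with the
threshold split $\gamma \in (0,1)$ optimized by golden-section search
(`optimize`, tolerance $10^{-10}$; the objective is strictly unimodal in
practice). Binarizing the Gaussian weights at their $(1-p_1)$-quantile —
what the zip net's homeostatic synaptic thresholds do — retains the squared
SNR fraction
$\zeta(p_1) = \phi(\Phi^{-1}(1 - p_1))^2 / (p_1(1 - p_1))$, maximal
$2/\pi \approx 0.64$ at $p_1 = 1/2$. A zip net with realized connectivity
$P_1$ and potential connectivity $P_{pot}$ therefore stores
$M_\epsilon \approx \zeta(P_1/P_{pot}) \cdot M_\epsilon^{Gauss}(P_{pot})$
memories, with error rates re-evaluated at the reduced SNR
$r\sqrt{\zeta}$ and capacity counted per realized synapse.

Accuracy of this analysis: it reproduces the macrocolumn-scale benchmarks
(see `scripts/acceptance.R`), and small-net simulations at the canonical
configuration ($p_1 = 0.5$, full potential connectivity) confirm its noise
prediction conservatively. Under strong dilution at small $n$ (e.g.
$m = n = 2000$, $P_1 = 0.1$, $P_{pot} = 0.5$) the Gaussian point prediction
becomes optimistic by a factor of several: dendritic counts are small and
skewed there, and the $1/q$ weighting amplifies tail errors the Gaussian
underestimates. The analysis is intended for macrocolumn-scale parameters.

## Synapse dynamics: update order and homeostasis

One step applies all transitions synchronously from the start-of-step
snapshot, matching the three-term recursions
$p_1^{(s)}(t) = (1 - p_{d|s})p_1^{(s)}(t-1) + p_{c|s}p_0^{(s)}(t-1)$, etc.
The macroscopic solver partitions potential synapses into groups by signal
value, iterates the recursion per group, and aggregates pair-level
connectivities through the synapse-count distribution
$\mathfrak{p}(\mathfrak{n})$ per connected pair (Eq.-level default: one
potential synapse per pair; the aggregation supports general
distributions, e.g. groups of four synapses per pair).

The homeostatic synaptogenesis rate is computed from the pre-step state as
$p_g = \sum_s w_s(p_{e|s} p_0^{(s)} + [\text{model B}]\ p_{d|s} p_1^{(s)})
/ \sum_s w_s p_\pi^{(s)}$ (clipped to $[0,1]$), which conserves anatomical
connectivity to machine precision until the $\pi$ pool depletes — the
depleted case raises a warning and lets $P$ drop. The microscopic simulator
offers exact-count replacement (regrow exactly as many synapses as were
eliminated, at uniformly chosen start-of-step $\pi$ locations; $P(t)$ is
then constant *exactly*) and a probabilistic mode that balances only in
expectation. Initial consolidated synapses are placed uniformly among the
actual synapses, independent of tags, and tag placement is treated as
independent of potential-synapse placement — random memory patterns carry
no information about anatomy.

Randomness: every stochastic function takes a single integer seed and draws
sequentially from R's generator, so trajectories are bit-reproducible;
parallel seeds are handled by giving each replicate its own seed.

## Spacing-effect theory

During a gap, untagged dynamics decay the consolidated fraction by
$(1 - p_{d|0})$ per step while turnover ($p_{e|0}$, with homeostatic
regrowth) redistributes silent synapses — some of them onto tagged
locations, where the next rehearsal instantly consolidates them
($p_{c|1} = 1$, $p_{e|1} = p_{d|1} = 0$). The model-B closed form for the
performance reached by a brief second study after a gap $\Delta t$ is

$$P_{eff}^{(2)} \approx \frac{P P_{pot} + [(P_{pot}-P)P_{eff}^{(1)} -
P_{pot}P_1(t_1)]x_d - P_{pot}(P - P_1(t_1))x_e}
{P_{pot} - P_1(t_1)x_d - (P - P_1(t_1))x_e},$$

with $x_d = (1-p_{d|0})^{\Delta t}$, $x_e = (1-p_{e|0})^{\Delta t}$ and
$P_1(t_1) = P_1(t_0)(1-P_{1S})(1-p_{d|0})^{t_1} + P_{1S}P_{eff}^{(1)}$. It
is exact at $\Delta t = 0$ and accurate to a few percent against the full
group recursion (it summarizes the end-of-study state by $P_{eff}^{(1)}$
alone, neglecting tagged silent synapses present at $t_1$). Retention only
rescales the curve ($P_{eff}^{(3)} = P_{eff}^{(2)}(1-p_{d|0})^{RI}$), so the
optimal gap is independent of the retention interval — the model's known
deviation from behavioral data, which report optimal gaps growing with
retention; capturing that requires mixing synapse populations with
different rates, which is out of scope here.

The stationarity condition for the optimal gap,
$$\frac{P_{eff}^{(1)} - P_1(t_1)}{P - P_1(t_1)} + (\alpha - 1)
\frac{P_{eff}^{(1)}}{P_{pot}}x^\alpha - \alpha x^{\alpha-1} = 0, \qquad
\alpha = \frac{\ln(1-p_{e|0})}{\ln(1-p_{d|0})},$$
is solved for $x \in (0,1)$ by safeguarded Newton iteration with a
bisection fallback (tolerance $10^{-12}$). The sign convention: $g(x) > 0$
where the gap curve falls with $\Delta t$, $g(x) < 0$ where it rises; if no
sign change exists the optimum is at a boundary (gap 0 for $g > 0$
everywhere — e.g. when turnover is no faster than deconsolidation,
$\alpha \le 1$ — and unbounded otherwise). Both the continuous optimum and
the best integer gap are returned.

```{r spacing}
cfg <- cepeda_params(p_e0 = 0.01, p_d0 = 2e-4, model = "B")
st <- init_macro(cfg$P, cfg$P_pot, cfg$P1_t0, cfg$P_1S)
for (t in 1:10) st <- step_macro(st, cfg$params, rehearsing = TRUE)
sp <- spacing_params(p_e0 = 0.01, p_d0 = 2e-4,
                     Peff1 = network_connectivities(st)$P_eff, t1 = 10)
optimal_gap(sp)[c("alpha", "dt_opt", "dt_int")]
```

Default protocol constants ($P_{pot} = 0.4$, $P = 0.1$, $P_1(t_0) = 0.02$,
$P_{1S} = 0.001$, one step = one hour, retention intervals in days mapped as
$24 \times$ days) reflect the physiological estimates for cortex: potential
connectivity from neurite-apposition estimates, anatomical connectivity from
paired recordings, about 20% of synapses in the potentiated "up" state, and
a novel fact set that is small against the standing memory store.

## What the synthetic generator does and does not emulate

`generate_patterns` draws i.i.d. memory patterns, either with exactly
$k$ active units or as Bernoulli($k/m$) components; potential-synapse masks
are i.i.d. Bernoulli($P_{pot}$); consolidation signals derive from stored
pattern sets. This matches the theory's assumptions exactly, which is the
point: passing tests certify the implementation of the model, not the
realism of cortex. Real networks have correlated memory patterns,
distance-dependent and clustered connectivity, multi-synapse contacts with
narrow count distributions, and graded rather than binary consolidation
signals — none of which the generator produces. The multi-synapse
aggregation and real-valued signal support are the extension points for
such data.

## Numerical choices and limitations

* Binomial sums: tails truncated at $10^{-14}$ cumulative mass and
  renormalized; log-space weights; thresholds scanned exhaustively over
  $0..k$ (ties to the smaller threshold).
* Capacity searches: integer bisection, with monotonicity of noise in load
  asserted at the evaluated points.
* Zip-net storage tie-breaks: potentials sorted by (value descending, row
  index ascending); each postsynaptic neuron realizes
  $\lceil (P_1/P_{pot}) \cdot n_{pot,j} \rceil$ synapses, so realized
  connectivity matches the target up to per-column quantization.
* l-winner retrieval returns the maximal integer threshold activating at
  least $l$ units; an all-zero-potential query yields the empty pattern
  with a warning flag rather than "all units tied at zero". Pattern-part
  retrieval fires unit $j$ iff $x_j \ge \sum_i \tilde u_i \,
  \mathrm{mask}_{ij}$, which guarantees zero misses on noiseless queries.
* Dense weight matrices are limited to $mn \le 10^8$; macrocolumn-scale
  results come from the analytic modules, never from materialized matrices.
* Self-connections are allowed in auto-associative mode (zero the diagonal
  yourself if needed); iterative-retrieval capacity scaling for
  auto-association is not implemented.
* Transfer entropy is estimated through the i.i.d.-bit channel reduction,
  not over full $2^n$ output histograms; with $N_{max} = 0$ the estimate is
  the empirical output entropy, otherwise the empirical channel capacity.

## Problem sizes used in the test suite

The suite exercises simulation-scale networks chosen to keep the full run
in the minutes range while leaving the statistical checks well-powered:
exact-vs-Monte-Carlo error rates on $500 \times 500$ nets (400 networks),
micro-vs-macro agreement on the $1000 \times 1000$ spaced-rehearsal
benchmark over 20 seeds, zip-net validation at $m = n = 1500$, and
macrocolumn-scale ($n = 10^5$) runs of the analytic capacity modules, which
take seconds.
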