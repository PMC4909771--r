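# synaptica

Associative memory capacity under structural synaptic plasticity, for
computational neuroscientists studying how cortical networks store Hebbian
cell assemblies.

Cortical tissue is sparsely wired — within a macrocolumn of $n \approx 10^5$
neurons only about $P = 0.1$ of neuron pairs have an actual synapse, while
about $P_{pot} = 0.5$ have a *potential* synapse (axon and dendrite close
enough to grow one). A memory is modeled as a cell assembly of $k$ coactive
neurons stored in a binary associative network: the Willshaw rule sets
$W_{ij} = 1$ once $\omega_{ij} = \sum_\mu u_i^\mu v_j^\mu \ge 1$, and
one-step retrieval thresholds the dendritic sums
$x_j = \sum_i \tilde u_i W_{ij}$. What limits retrieval is the **effectual
connectivity**

$$P_{eff} = \frac{\sum_{ij} H(W_{ij} S_{ij})}{\sum_{ij} H(S_{ij}^2)},$$

the fraction of the synapses *required* by the memory set (the
consolidation signal $S$) that are actually realized. Ongoing structural
plasticity — synaptic turnover with homeostatic synaptogenesis, modeled as a
three-state Markov chain per potential synapse
($\pi \leftrightarrow 0 \leftrightarrow 1$) — raises $P_{eff}$ from the
anatomical level $P$ toward $P_{pot}$, and the package quantifies what that
is worth:

* exact finite-size error rates and pattern capacity $M_\epsilon$ of the
  diluted Willshaw network (binomial unit-usage analysis, no Gaussian
  approximation);
* Gaussian signal-to-noise capacity of covariance-rule ("Bayesian")
  networks and of binary **zip nets**, whose homeostatic synaptic thresholds
  fix the potentiated fraction $p_1$ and which retain a fraction
  $\zeta(p_1) = \phi(\Phi^{-1}(1-p_1))^2/(p_1(1-p_1)) \le 2/\pi$ of the
  optimal squared SNR;
* microscopic (per-synapse) and macroscopic (per-signal-group) simulators
  of consolidation dynamics under rehearsal schedules;
* transfer-entropy bounds linking storage capacity to functional
  connectivity measures;
* the closed-form spacing-effect theory: how long to wait between two study
  sessions to maximize retention.

## Worked example

How many assemblies of $k = 50$ neurons fit in a macrocolumn at output-noise
level $\epsilon = 0.01$?

```r
library(synaptica)
pattern_capacity(50, 50, 1e5, 1e5, P_eff = 0.5, eps = 0.01)
#> capacity_result (k = 50, m = n = 100000, P_eff = 0.5, eps = 0.01):
#>   M_eps = 799686 at theta = 17 (q01 = 1.16e-06, q10 = 0.00767)
#>   p1 = 0.1812, P_1 = 0.0906, C_wp = 0.09784, C_tot = 0.54 bit/synapse
```

At the potential-connectivity level a macrocolumn holds about 800,000 such
assemblies, storing 0.54 bit per non-silent synapse; the same network held
at the anatomical level stores essentially nothing
(`pattern_capacity(50, 50, 1e5, 1e5, P_eff = 0.1, eps = 0.01)$M_eps` is 2).
Structural plasticity is what makes small-assembly storage possible at all.
The zip net, which decouples $p_1$ from the memory load, does even better at
the same anatomical cost:

```r
zipnet_capacity(50, 50, 1e5, 1e5, P1 = 0.1, P_pot = 0.5, eps = 0.01)
#> gaussian_capacity_result: M_eps = 965681 (zeta = 0.4899)
#>   C_tot = 0.5914 bit/synapse  C_wp = 0.1183 bit/synapse, r = 7.12, gamma = 0.65
```

And the optimal gap between two study sessions, for slow cortical turnover
($p_{e|0} = 0.01$, $p_{d|0} = 2\times10^{-4}$ per hour-long step, study
until $P_{eff}^{(1)} = 0.107$):

```r
cfg <- cepeda_params(p_e0 = 0.01, p_d0 = 2e-4, model = "B")
st <- init_macro(cfg$P, cfg$P_pot, cfg$P1_t0, cfg$P_1S)
for (t in 1:10) st <- step_macro(st, cfg$params, rehearsing = TRUE)
sp <- spacing_params(p_e0 = 0.01, p_d0 = 2e-4,
                     Peff1 = network_connectivities(st)$P_eff, t1 = 10)
optimal_gap(sp)[c("alpha", "dt_opt", "dt_int")]
#> $alpha
#> [1] 50.24665
#> $dt_opt
#> [1] 360.7397
#> $dt_int
#> [1] 361
```

Wait about 361 hours (15 days): long enough for turnover to regrow silent
synapses at tagged locations, short enough that already-consolidated ones
have not decayed. The optimum is independent of the retention interval.

See `vignettes/structural-plasticity.Rmd` for the models, assumptions,
numerical choices and limitations.

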