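---
title: "Estimating the scaled mutation rate with a tempered SMC sampler"
author: "coalsmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the scaled mutation rate with a tempered SMC sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalsmc)
```

## The inference problem

A sample of $m$ homologous DNA sequences of length $l$ drawn from one
panmictic population is related by an unobserved genealogy $\Upsilon$: a
rooted, ultrametric binary tree whose coalescence times, measured in
expected substitutions per site, are governed by the scaled mutation rate
$\Theta = 4N_e\mu$ (diploids) or $2N_e\mu$ (haploids). Under the neutral
coalescent the epoch during which the genealogy has $k$ lineages has
exponential duration $d_k$ with rate $k(k-1)/\Theta$, so

$$
p(\Upsilon \mid \Theta)
  = \prod_{k=2}^{m} \frac{k(k-1)}{\Theta}
    \exp\!\left\{-\frac{k(k-1)}{\Theta}\, d_k\right\},
$$

a proper density over the interval lengths given any ranked topology
(every ranked labeled topology is equally probable under the pair-merging
construction, so the topology factor is constant and cancels from every
acceptance ratio in the samplers below).

Sequence evolution along $\Upsilon$ follows a finite-sites substitution
model with parameters $\lambda$: K80 (equal base frequencies, free
transition/transversion ratio $\kappa$) or F84 (free frequencies $\pi$
and $\kappa$). The likelihood $\Pr(D \mid \Upsilon, \lambda)$ is computed
by Felsenstein's pruning algorithm. With priors
$\Theta \sim U(0, \Theta_{\max})$, $\kappa \sim U(0, \kappa_{\max})$ and
$\pi \sim \mathrm{Dir}(\alpha)$, the joint posterior of
$H = (\Theta, \lambda, \Upsilon)$ is

$$
p(H \mid D) \;\propto\; p(\lambda)\, p(\Theta)\, p(\Upsilon \mid \Theta)\,
  \Pr(D \mid \Upsilon, \lambda),
$$

and the quantity of interest is the marginal posterior of $\Theta$.

## The tempered SMC sampler

Direct posterior sampling is hard because the genealogy space is huge and
the likelihood is sharply concentrated. `runSMC()` therefore follows the
sequential Monte Carlo recipe for static models: a bridge of tempered
targets

$$
\pi_t(H) \propto p(H)\, \Pr(D \mid H)^{\varepsilon_t},
\qquad 0 = \varepsilon_1 \le \cdots \le \varepsilon_T = 1,
$$

is traversed by $N$ weighted particles. At $\varepsilon_1 = 0$ the target
is the prior, which is easy to sample; at $\varepsilon_T = 1$ it is the
posterior. Moving from $\varepsilon_{t-1}$ to $\varepsilon_t$ uses a
$\pi_t$-invariant Metropolis–Hastings kernel as the forward kernel; with
the standard time-reversal choice of backward kernel the incremental
weight of particle $n$ collapses to

$$
W_t^{(n)} = \Pr(D \mid H_{t-1}^{(n)})^{\varepsilon_t - \varepsilon_{t-1}},
$$

so reweighting only touches cached log-likelihoods. Weight degeneracy is
monitored through $\mathrm{ESS} = 1/\sum_n (w^{(n)})^2$ and systematic
resampling is triggered when it falls below a threshold fraction of $N$.
The products of the per-step normalizing sums accumulate into an estimate
of the log evidence $\log Z$. A move-matched single-chain MH sampler
(`runMCMC()`) provides the baseline comparison: it uses exactly the same
move kernel, fixed at $\varepsilon = 1$.

### The move kernel

One sweep applies, in order:

* **$\Theta$**: multiplicative log-normal random walk (scale 0.2).
  Because the likelihood does not involve $\Theta$ directly, only the
  coalescent prior and the uniform bound enter the acceptance ratio.
* **$\kappa$**: the same multiplicative walk (scale 0.2) against
  $\Pr(D\mid H)^{\varepsilon}$.
* **$\pi$** (F84 only): a Dirichlet proposal centred at the current value
  with concentration 200, with the exact forward/backward density ratio.
* **Genealogy** (3 moves per sweep, each chosen between two types with
  equal probability):
  * a *node-time slide*, uniform between the node's children and parent;
    the root instead receives an exponential tail proposal whose rate
    $2/\Theta$ matches the conditional coalescent prior of the final
    epoch;
  * a *narrow exchange* (ranked nearest-neighbour interchange): a node
    swaps places with its parent's sibling when the times permit. The
    proposal is symmetric, times are untouched, and the coalescent prior
    is unchanged, so only the tempered likelihood ratio decides.

Narrow exchange connects the space of ranked topologies and the slides
cover the times, so the kernel is ergodic. We preferred this pair over a
subtree-detach/reattach move because its acceptance ratio is exactly
symmetric by construction, removing the most error-prone Hastings
computation from the sampler; the detach/reattach style move explores
topology space in larger steps but buys little at the sample sizes this
package targets while being much easier to get subtly wrong.

Degenerate proposals that would collide with a neighbouring node time
after floating-point rounding are rejected outright, which preserves the
strict ordering of node times that the `Genealogy` class enforces.

### Initialization

Two modes are available. `"prior"` draws every particle from the joint
prior. The default `"upgma_guided"` builds one UPGMA tree from
Jukes–Cantor-corrected pairwise distances (ambiguous sites excluded
pairwise, raw proportions capped just below 0.75) and gives every
particle that topology while redrawing its node times from the coalescent
prior, given the particle's own $\Theta$, in the topology's rank order.
This concentrates the initial cloud on a topology already compatible with
the data, which is what makes a moderate particle count ($N = 500$)
sufficient. The guided cloud is formally a heuristic start rather than an
exact prior sample — all particles share one topology — but the
subsequent $\pi_t$-invariant sweeps re-diversify topologies while the
temperature is still low, and the no-data and two-sequence oracle checks
in the test suite confirm that the final cloud is calibrated. Exact tied
merge heights from UPGMA (identical sequences) are nudged apart by a
relative $10^{-9}$ so the strict time ordering holds.

## Substitution models and the meaning of $\kappa$

Both models are parameterized by the *expected* transition/transversion
ratio $\kappa = E[\mathrm{ts}]/E[\mathrm{tv}]$ under the stationary law,
so the prior $U(0, \kappa_{\max})$ refers to the same observable quantity
under K80 and F84, and F84 with $\pi = (¼,¼,¼,¼)$ reproduces K80 at equal
$\kappa$ (verified to $10^{-8}$ in the tests). For K80 this maps to
instantaneous rates $\alpha = \kappa/(\kappa+1)$ and
$\beta = 1/(2\kappa+2)$; for F84 the internal shape parameter is solved
from $(\kappa, \pi)$ in closed form and the transition probabilities are
the Tamura–Nei special case. All rate matrices are normalized to one
expected substitution per unit time, so branch lengths and $\Theta$ are
in expected substitutions per site throughout. For strongly skewed $\pi$
the F84 mapping can imply a negative transition rate when $\kappa$ is
small; such $(\kappa, \pi)$ pairs are treated as outside the prior
support and proposals into them are rejected.

The pruning likelihood is evaluated in C++ over compressed site patterns
with per-node, per-pattern rescaling, so it stays finite for long
alignments and small $\Theta$. IUPAC ambiguity codes set the leaf partial
likelihood to 1 for every compatible base; gaps, `N` and `?` are fully
missing. Every evaluation is a full from-scratch recomputation: after
pattern compression a single evaluation at the package's target sizes
($m \le 63$, $l \le 600$) costs tens of microseconds, so reusing
untouched subtree partials would complicate the state for no measurable
gain, and "cached equals recomputed" holds trivially.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `nParticles` (N) | 500 | particle count; the guided start makes this sufficient for $m \approx 20$–60 |
| `epsilons` | quadratic, $T=50$ | $\varepsilon_t = ((t-1)/(T-1))^2$; concentrates steps at low powers where the bridge is steepest |
| `rMcmc` | 5 | MH sweeps per particle per temperature |
| `essThreshold` | 0.5 | resample when ESS $< 0.5N$ (conventional trigger; systematic scheme has the lowest variance of the standard choices) |
| `thetaScale`, `kappaScale` | 0.2 | log-normal walk scales; acceptance stays in the 0.2–0.8 band across the tested regimes |
| `piConcentration` | 200 | Dirichlet proposal concentration (steps of a few percent in each frequency) |
| `rTree` | 3 | genealogy moves per sweep |
| `thetaMax` | data-driven | $\max(10\,\hat\Theta_W, 0.1)$ with $\hat\Theta_W$ Watterson's estimator — weakly informative and scale-free |
| `kappaMax` | 20 | generous bound for real nucleotide data |
| `alpha` | (1,1,1,1) | flat Dirichlet on $\pi$ |
| MCMC budget | 50000 + 20000 | burn-in and retained sweeps of the baseline, thinning 1 |

## The simulator

`simulateDataset()` draws a coalescent genealogy at the true $\Theta$ and
evolves sequences site by site along it: the root is sampled from the
stationary distribution and each branch multiplies through the branch's
transition matrix. This reproduces in-process the classical two-stage
pipeline (a coalescent tree simulator feeding a finite-sites sequence
simulator) with a single seed, and is exact for the model being fit. What
it deliberately does **not** emulate: recombination, migration,
population growth, rate heterogeneity across sites, selection, alignment
error and sequencing error. Green tests therefore certify correctness of
the samplers *under the model*, not robustness of $\Theta$ estimates to
model violations on real data.

The classical moment identity
$E[S] = \Theta\, l \sum_{i=1}^{m-1} 1/i$ for the number of segregating
sites serves as the simulator's independent oracle; it is asserted only
where $\Theta l$ is small, because repeat mutation under a finite-sites
model deflates $S$ below the infinite-sites expectation as diversity
grows.

## Numerical and design notes

* **Evidence increments** are accumulated as
  $\log \sum_n w^{(n)} e^{\Delta\varepsilon\,\ell_n}$ with the usual
  max-shift, before the weights are updated.
* **Weighted quantiles** use the weighted empirical CDF with lower
  interpolation (the smallest sample value whose cumulative weight
  reaches the probability).
* **Zero-length alignments** are accepted and have likelihood
  identically 1, which makes the "no data returns the prior, evidence
  1" property directly testable.
* **Determinism**: all randomness, including inside the C++ kernels,
  flows through R's RNG, so a configuration seed fixes the entire run
  bit-for-bit. Grid experiments derive one substream seed per
  (cell, method) from the top-level seed by hashing a label, so any
  single cell reproduces in isolation.
* **Tie-breaking** in UPGMA follows the scan order of the distance
  matrix, i.e. the lowest leaf index.

## Problem sizes used by the test suite

The reference experimental design (both models, $\Theta \in \{0.01, 0.1,
0.5\}$, $m = 20$, $l = 600$, $N = 500$, full MCMC budget) is run once per
cell by the acceptance checks. The distributional unit tests use smaller
configurations chosen to give clean Monte-Carlo error bars in seconds —
e.g. $10^4$ prior draws for interval moments, $10^5$ sites for
substitution-type frequencies, $N$ of a few hundred with 25–30
temperatures for calibration checks on two-sequence problems where dense
2-D quadrature over $(\Theta, d_2)$ is available as an exact oracle.

## Known limitations

* A single simulated dataset carries the full coalescent variance of its
  genealogy: the total tree length has relative standard deviation
  $\approx \sqrt{\sum_k (k-1)^{-2}}\,/\sum_k (k-1)^{-1} \approx 35\%$ at
  $m = 20$, and no sampler can recover the generating $\Theta$ more
  precisely than the realized genealogy allows. Point estimates from one
  replicate therefore scatter around the truth on that scale, whatever
  the inference engine.
* The tempering schedule is fixed; adaptive schedules targeting a
  conditional-ESS level are out of scope.
* Only K80 and F84 are implemented; no rate heterogeneity, partitioned
  models, serially sampled tips or non-ultrametric trees.
* The MCMC baseline reuses the SMC move set at $\varepsilon = 1$, making
  the comparison move-matched rather than a re-implementation of any
  specific external sampler. Because both samplers are calibrated against
  the same two-sequence quadrature oracle, their posterior-SD estimates
  coincide up to Monte-Carlo noise: a well-rejuvenated particle cloud does
  not systematically report a smaller posterior SD than a long chain, and
  which of the two is smaller on any one dataset is essentially a coin
  flip (with a slight downward bias for the autocorrelated chain).

## A complete small example

```{r example, eval = FALSE}
library(coalsmc)

sim <- simulateDataset(simulationSpec(0.1, m = 20, l = 600,
                                      model = substitutionModel("K80", kappa = 2),
                                      seed = 42))
cfg <- smcConfig("K80", seed = 1)          # N = 500, T = 50, R_MCMC = 5
res <- runSMC(sim$alignment, cfg)
posteriorSummary(res)["theta", ]
logEvidence <- res@logEvidence

base <- runMCMC(sim$alignment, "K80", mcfg = mcmcConfig(seed = 2))
posteriorSummary(base)["theta", ]
```
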