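# coalsmc

Bayesian estimation of the scaled per-site mutation rate
**Θ = 4N<sub>e</sub>μ** (diploids) or **2N<sub>e</sub>μ** (haploids) from a
sample of aligned homologous DNA sequences, for population geneticists who
want full posteriors rather than moment estimates. The genealogy relating
the sample is unknown, so the package samples from the joint posterior

> p(Θ, λ, Υ | D) ∝ p(λ) p(Θ) p(Υ | Θ) Pr(D | Υ, λ)

over Θ, the substitution-model parameters λ (K80 or F84) and the latent
coalescent genealogy Υ, and marginalizes Θ out of the weighted sample.

The core engine is a **likelihood-tempered sequential Monte Carlo
sampler**: N particles traverse the bridge of distributions
π<sub>t</sub>(H) ∝ p(H) Pr(D|H)<sup>ε<sub>t</sub></sup> from the prior
(ε=0) to the posterior (ε=1), mutated at every temperature by
π<sub>t</sub>-invariant Metropolis–Hastings sweeps (Θ and κ random walks,
a Dirichlet proposal for π, node-time slides and ranked
nearest-neighbour interchanges on the genealogy), reweighted by
Pr(D|H)<sup>Δε</sup>, and systematically resampled when the effective
sample size 1/Σw² drops below N/2. A running product of the
normalizing sums estimates the model evidence. A move-matched
Metropolis–Hastings MCMC sampler (default budget: 50 000 burn-in +
20 000 retained sweeps) is included as the baseline, plus:

* Felsenstein pruning likelihoods over compressed site patterns (C++,
  per-node rescaling), K80/F84 transition probabilities in closed form;
* a coalescent/finite-sites simulator with known truth (`simulateDataset`);
* UPGMA initialization, Watterson's estimator, coalescent prior sampling;
* FASTA / sequential-PHYLIP / Newick input–output and a CLI.

## Worked example

Simulate one dataset of 20 sequences × 600 sites under K80 (κ = 2) at a
true Θ = 0.1, then estimate Θ with both samplers:

```r
library(coalsmc)

sim <- simulateDataset(simulationSpec(0.1, m = 20, l = 600,
                                      model = substitutionModel("K80", kappa = 2),
                                      seed = 42))
res <- runSMC(sim$alignment, smcConfig("K80", seed = 1))
round(posteriorSummary(res), 4)
#>         mean     sd   q2.5    q50  q97.5
#> theta 0.1092 0.0286 0.0655 0.1064 0.1836
#> kappa 1.7094 0.2557 1.2526 1.6856 2.2215
#> piA   0.2500 0.0000 0.2500 0.2500 0.2500
#> piC   0.2500 0.0000 0.2500 0.2500 0.2500
#> piG   0.2500 0.0000 0.2500 0.2500 0.2500
#> piT   0.2500 0.0000 0.2500 0.2500 0.2500
res@logEvidence
#> [1] -1951.72

base <- runMCMC(sim$alignment, "K80", mcfg = mcmcConfig(seed = 2))
round(posteriorSummary(base)["theta", ], 4)
#>         mean     sd   q2.5    q50  q97.5
#> theta 0.1129 0.0301 0.0661 0.1085 0.1833
```

The posterior mean of Θ (0.109 from SMC, 0.113 from MCMC) sits near the
truth 0.1 — the residual gap is the coalescent noise of the single
simulated genealogy, not sampler error — with κ estimated around its
generating value 2 and π fixed at ¼ under K80. The 95% credible interval
`[q2.5, q97.5]` spans roughly ±2 posterior standard deviations; the two
samplers agree within Monte-Carlo error, and the SMC cloud additionally
returns a log-evidence estimate (`res@logEvidence`).

The same analysis from the shell:

```sh
exec/coalsmc simulate --theta 0.1 --m 20 --l 600 --model K80 --seed 42 --out-prefix sim
exec/coalsmc infer --in sim.fasta --model K80 --particles 500 --temps 50 \
    --rmcmc 5 --ess-frac 0.5 --theta-max auto --seed 1 --out results.json
exec/coalsmc mcmc  --in sim.fasta --model K80 --burnin 50000 --chain 20000 --out mcmc.json
exec/coalsmc grid  --thetas 0.01,0.1,0.5 --lengths 200,400,600 --m 20 \
    --models K80,F84 --seed 1 --out grid.csv
```

`infer` writes posterior moments and quantiles of Θ, κ and π, the ESS
trace, the tempering schedule and the log evidence as JSON; `--trees`
additionally dumps the weighted Newick sample. Any option can also come
from a YAML file via `--config` (explicit flags win).

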