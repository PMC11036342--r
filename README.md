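# bkat — Bayesian kernel-based association testing for feature groups

Genome-wide association studies gain power by testing *groups* of
functionally related variants — the SNPs in a gene, a pathway, a
co-expression or protein-interaction module — jointly rather than one at a
time. The standard tool is kernel machine regression: with phenotype
`y`, covariates `X` and a group feature matrix `Z`,

    y = X beta + h(Z) + eps,    h ~ N(0, tau * K),    eps ~ N(0, sigma^2 I)

and "no group effect" is the variance-component null `tau = 0`. The
catch is that power depends heavily on the kernel `K`, and the functional
form linking features to phenotype is unknown; picking the kernel that
happens to give the smallest p-value inflates type-I error.

`bkat` resolves the kernel choice inside the test. It infers a
**composite kernel** `K_c = sum_i rho_i K_i` — a convex combination of
candidate kernels (Linear / Quadratic / Gaussian for continuous features,
IBS / Quadratic / Gaussian for 0/1/2 genotypes) — adaptively from the
data, while testing `H0: tau1 = 0` vs `H1: tau1 > 0`
(`tau1 = tau / sigma^2`) through the Bayes factor

    BF10 = P(Data | H1) / P(Data | H0)

reported as the posterior probability of association
`P(H1 | Data) = 1 / (1 + (P(H0)/P(H1)) / BF10)`, with 0.7 as the default
selection threshold and a Bayesian false-discovery-rate rule for
multiplicity across groups.

Two inference engines are provided:

* **MAP** (`bkat_map`) — derivative-free BOBYQA maximization of the
  posterior, Laplace-approximated marginal likelihoods with explicit
  boundary handling (kernel weights and `tau1` routinely sit on
  constraints). Fast; suitable for genome-wide sweeps.
* **MCMC** (`bkat_mcmc`) — adaptive Metropolis–Hastings (default 3
  chains × 50 000 iterations), Gelman–Rubin convergence checks, and
  Chib-style marginal likelihoods from the posterior output. Slower;
  gives full posteriors.

A synthetic-data module reproduces the benchmark designs (AR(1)
continuous features, LD-structured genotypes, scenario functions A–F), and
an evaluation harness computes empirical power / type-I error curves.

## Worked example

Simulate a cohort of 200 individuals with 50 AR(1)-correlated continuous
features whose effect on the phenotype is the product interaction
`h(Z) = 0.6 * Z1 * Z3` (a quadratic-kernel-type signal), then test the
group:

```r
library(bkat)

sim     <- simulate_dataset(simulation_config("A", n = 200, p = 50, seed = 1))
kernels <- default_kernels(sim$data$Z, type = "continuous")
res     <- bkat_map(sim$data, kernels)
res
#> bkat_result [MAP]
#>   log BF10        : 4.3191
#>   P(H1 | Data)    : 0.9869
#>   tau1_hat        : 0.7179
#>   kernel weights  : Linear=0.00, Quadratic=0.88, Gaussian=0.12
```

The test finds strong evidence of association (posterior probability
0.99, far above the 0.7 threshold), and the inferred composite kernel
puts 88% of its weight on the Quadratic kernel — matching the
product-form signal the data were generated with. On null data
(`scenario = "NULL"`) the `tau1` estimate collapses to its zero boundary
and the result is `BF10 = 0`, `P(H1 | Data) = 0`.

Many groups at once, with selection and Bayesian FDR:

```r
tab <- bkat_test(data, groups, engine = "map", threshold = 0.7, fdr_q = 0.05)
```

There is also a command-line interface (`inst/scripts/bkat`) with
`test`, `simulate` and `evaluate` subcommands over TSV / PLINK-.raw /
JSON files.

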