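# srmnet

Bayesian social relations models for multiplex household networks: how
material wealth patterns relational wealth in small communities.

## What it is for

Field studies of rural economies often collect, for one roster of
households, several directed binary networks (food sharing elicited by
name generators, gender-specific friendship and co-working), a wealth
inventory, a genealogy, GPS locations, and a couple of binary status
flags. The scientific questions are: do wealthy households send more
support ties? do ties concentrate among similarly wealthy households
(wealth homophily)? how much do kinship, distance, status groups and the
other network layers structure each layer? and how reciprocal are ties,
within dyads and across a household's sending/receiving propensities?

`srmnet` answers these with a generalized social relations model (SRM)
with stochastic block effects. For each ordered household pair, a tie is
Bernoulli with log-odds

    phi[i,j] = alpha + lambda[i] + pi[j] + delta[i,j]
             + B_S[S(i),S(j)] + B_M[M(i),M(j)]
             + gamma1*W[i] + gamma2*Wbar[i,j] + gamma3*Q[i,j]
             + gamma4*K[i,j] + gamma5*R[i,j] + gamma6*D[i,j]

with correlated sender/receiver effects (generalized reciprocity
`rho_gen`), correlated within-dyad effects (dyadic reciprocity
`rho_dyad`), 2x2 block matrices for the status (`S`) and development-group
(`M`) flags, standardized log wealth `W`, dyadic wealth distance `Wbar`,
cross-layer adjacencies `Q`, `K`, ..., relatedness `R` and spatial
distance `D`.

Double-sampled layers (food sharing asked from both the giver and the
receiver side) are fitted through a latent-network measurement model:
question-specific recall and false-positive rates are estimated jointly
with the structural parameters, with the binary latent tie marginalized
exactly per dyad. Posteriors are sampled by Hamiltonian Monte Carlo
(analytic gradients in compiled code, non-centered random effects).

The package also builds every covariate from raw tables — Wright's
relatedness from the pedigree (aggregated to household pairs), haversine
distances from GPS, standardized wealth terms, Gini coefficients,
polygynous wealth splitting — and ships a synthetic community generator
with known ground truth (44 households, 4 hamlets, wealth Gini calibrated
to 0.38, a patrilocal pedigree, five network layers) so the whole pipeline
is testable end to end.

## Worked example

Generate a synthetic community, inspect it, and fit the double-sampled
food-sharing layer with all other layers as predictors:

```r
library(srmnet)

com  <- generate_community(scenario_config(), seed = 2026)
data <- com$data

gini(data$households$wealth_total)
#> 0.441
descriptives(data)[, c("layer", "mode", "density", "reciprocated")]
#>          layer   mode density reciprocated
#> 1 friendship_f single    0.13         0.16
#> 2  coworking_f single    0.14         0.19
#> 3 friendship_m single    0.14         0.22
#> 4  coworking_m single    0.13         0.17
#> 5 food_sharing double    0.19         0.22

fit <- fit_srm(
  data, "food_sharing",
  srm_model_spec(sender = "log_wealth",
                 dyadic = c("wealth_distance", "relatedness", "distance",
                            "friendship_f", "coworking_f",
                            "friendship_m", "coworking_m"),
                 blocks = c("status", "dev_group")),
  mcmc_control(seed = 1))

summarize_draws(fit, pars = c("gamma_log_wealth", "gamma_wealth_distance",
  "gamma_relatedness", "gamma_distance", "rho_gen", "rho_dyad",
  "recall_give", "recall_receive", "fp_give", "fp_receive"))
#>              parameter  median ci_low ci_high reliable rhat  ess
#>       gamma_log_wealth  0.2454 -0.185   0.738    FALSE    1  665
#>  gamma_wealth_distance -0.1072 -0.456   0.202    FALSE    1 1002
#>      gamma_relatedness  1.0184  0.652   1.618     TRUE    1  107
#>         gamma_distance -0.5344 -0.977  -0.238     TRUE    1  263
#>                rho_gen  0.0053 -0.565   0.548    FALSE    1  602
#>               rho_dyad -0.0629 -0.720   0.430    FALSE    1  101
#>            recall_give  0.8713  0.801   0.933     TRUE    1  762
#>         recall_receive  0.8896  0.812   0.958     TRUE    1  650
#>                fp_give  0.0472  0.033   0.061     TRUE    1  860
#>             fp_receive  0.0204  0.010   0.033     TRUE    1  734
```

Reading the output: effects are per standard deviation of the covariate on
the log-odds scale. In this realization the relatedness and distance
effects are *reliable* (95% CI excludes zero) — households share food with
kin and with near neighbours — while wealth terms are not; the generating
truth for this seed had recall 0.9/0.85 and false-positive rates
0.05/0.03, and the measurement model recovers them (0.87/0.89 and
0.047/0.020). Block results come as probability-scale contrasts relative
to ties among flag-holding households:

```r
block_contrasts(fit, "dev_group")
#>  sender_group receiver_group delta_median delta_low delta_high delta_reliable
#>             1              1     -0.00678    -0.145      0.031          FALSE
#>             2              1      0.00416    -0.065      0.114          FALSE
#>             1              2      0.00053    -0.101      0.083          FALSE
#>             2              2      0.00000     0.000      0.000          FALSE
```

`run_analysis()` repeats one shared specification over all five layers and
writes summary/contrast CSVs and a JSON bundle; `export_digraph()` writes
GraphML digraphs with wealth-rank and degree attributes. A thin CLI over
these functions is installed at `inst/scripts/srmnet`
(`simulate | validate | covariates | fit | report | export-graph`).

## Layout

- `R/`, `src/` — covariate construction, model, HMC sampler, synthetic
  generator, pipeline
- `tests/testthat/` — unit, property and calibration tests
- `vignettes/wealth-and-relational-networks.Rmd` — the methods vignette:
  model, priors, measurement model, generator design, validation choices
- `inst/extdata/example_scenario.yaml` — example simulation scenario
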