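---
title: "Modelling how material wealth patterns relational wealth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling how material wealth patterns relational wealth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In many rural economies a household's security rests on two stocks of
wealth: material wealth (cash value of possessions, trees, equipment) and
relational wealth — the web of food-sharing, friendship and co-working ties
it can mobilize. `srmnet` implements a complete pipeline for asking how the
first patterns the second in a small community observed as a *multiplex
household network*: several directed binary layers (who gives food to whom,
who names whom a friend, who works with whom) over one roster of
households, together with household attributes (wealth, religious/secular
influence, development-group membership), a genealogy, and GPS locations.

The pipeline has three parts: covariate construction from raw field tables,
a Bayesian generative model for each network layer, and a synthetic
community generator that makes every stage testable against known ground
truth.

## The model

Each directed tie from household $i$ to household $j$ in a layer is
Bernoulli with log-odds

$$\phi_{ij} = \alpha + \lambda_i + \pi_j + \delta_{ij}
  + B^{(S)}_{S(i),S(j)} + B^{(M)}_{M(i),M(j)}
  + \gamma_1 W_i + \gamma_2 \bar W_{ij} + \gamma_3 Q_{ij}
  + \gamma_4 K_{ij} + \gamma_5 R_{ij} + \gamma_6 D_{ij},$$

the social relations model extended with stochastic block effects:

* $\lambda_i, \pi_j$ — sender and receiver random effects with scales
  $\sigma_\lambda, \sigma_\pi$ and correlation $\rho_{\mathrm{gen}}$
  (*generalized reciprocity*: do households that nominate many also receive
  many?);
* $\delta_{ij}$ — dyadic effects with scale $\sigma_\delta$ and within-dyad
  correlation $\rho_{\mathrm{dyad}}$ (*dyadic reciprocity*: does $i \to j$
  co-occur with $j \to i$?);
* $B^{(S)}, B^{(M)}$ — unpooled $2\times2$ block matrices indexed by
  (sender group, receiver group) for the status and development-group
  flags. With only two levels per factor, hierarchical pooling of block
  scales would be poorly informed, so the cells are plain coefficients
  under the common coefficient prior;
* $W_i$ — standardized log household wealth (sender term), $\bar W_{ij}$ —
  standardized $|\log W_i - \log W_j|$ (wealth distance; a negative
  $\gamma_2$ is wealth homophily), $R_{ij}$ — household relatedness,
  $D_{ij}$ — spatial distance, and $Q, K, \dots$ — the observed adjacency
  of the other layers (cross-layer overlap). The slope vector is
  variable-length with named entries, so any number of cross-layer
  predictors can enter; the pipeline default uses *all* other layers.

Only sender and dyadic-similarity versions of each covariate are included:
sender, receiver and similarity terms of the same household covariate are
collinear in this model, and the sender + similarity pair is the one that
answers "who gives support, and is support homophilous?".

### Measurement model for double-sampled layers

Food sharing is elicited twice per directed pair — the giver question
(answered by $i$) and the receiver question (answered by $j$). Reports are
noisy: a true tie is reported with question-specific recall $r_g, r_r$, a
non-tie with false-positive rate $f_g, f_r$. Writing $p_{ij} =
\mathrm{logit}^{-1}(\phi_{ij})$ and observed reports $(o, q)$,

$$P(o, q) = p_{ij}\, r_g^{o}(1-r_g)^{1-o} r_r^{q}(1-r_r)^{1-q}
 + (1-p_{ij})\, f_g^{o}(1-f_g)^{1-o} f_r^{q}(1-f_r)^{1-q}.$$

The binary latent tie is marginalized analytically per ordered pair
(summed in log space), rather than sampled: the sum has two terms, so exact
marginalization is both cheaper and removes 1892 discrete parameters from
the sampler. Question-specific rates absorb mean differences between how
the two questions behave; a per-respondent question-duplication term is out
of scope. `loglik_double()` is checked against exhaustive enumeration over
all $2^{n(n-1)}$ latent configurations for $n \le 4$.

### Priors

The sources this model class comes from leave priors to the software, so
the package documents its own weakly informative defaults (all overridable
through `hyper`):

| parameter | prior | rationale |
|---|---|---|
| $\alpha$, $\gamma$, block cells | Normal(0, 2.5) | weakly informative on the logistic scale |
| $\sigma_\lambda, \sigma_\pi, \sigma_\delta$ | half-Normal(1) | random-effect scales of order one on log-odds |
| $\rho_{\mathrm{gen}}, \rho_{\mathrm{dyad}}$ | uniform on $(-1, 1)$ | the two-dimensional correlation-matrix prior |
| recall $r_g, r_r$ | Beta(8, 2) | reports are mostly right |
| false positive $f_g, f_r$ | Beta(1, 10) | spurious nominations are rare |

The recall/false-positive priors also carry the identifiability guard:
complementing the latent network swaps the roles of recall and false
positives while leaving the likelihood unchanged, and the asymmetric priors
put essentially all posterior mass on the intended mode. For the same
reason the sampler initializes the reporting rates at their prior means
rather than at 0.5/0.5, which sits exactly on the symmetry ridge.

## Covariate construction

* **Relatedness.** Wright's $r$ from the pedigree by the tabular kinship
  recursion (founders unrelated and non-inbred, $r = 2\phi$); household
  relatedness is the mean of $r$ over cross-household member pairs.
  Self-relatedness never enters the aggregation — the model has no
  self-ties, so a household's relatedness to itself is unused and the
  diagonal is set to zero.
* **Distance.** Haversine great-circle distance on a 6,371 km sphere from
  the GPS coordinates.
* **Standardization.** Wealth terms are always standardized (effects are
  reported on the standardized scale). Whether relatedness and distance
  should also be standardized is a genuinely open choice; the default
  standardizes both so all slope coefficients are comparable
  per-standard-deviation effects, and `standardize_covariates = FALSE` in
  the generator (or supplying raw matrices) leaves them on their natural
  scales. For dyadic matrices the off-diagonal entries alone define the
  center and scale, since the diagonal is structural.
* **Polygyny.** Each wife heads her own household holding her own assets
  plus a share of the husband's male property. The share is split
  *equally* among wives — the source material says only "a share", and
  equal division is the one choice that needs no further elicitation.
* **Inequality.** `gini()` is the population Gini (mean absolute
  difference over $2n^2\bar x$); no small-sample correction is applied by
  default because none is applied to the published values, and
  `corrected = TRUE` provides the $n/(n-1)$ variant.
* **Missing data.** Missing GPS or pedigree fields are hard errors, not
  imputed: the analysis needs complete covariates for every household, and
  the loaders fail with the offending row named. Nominations to labels
  outside the roster (e.g. out-of-village alters) error by default and are
  dropped only under the explicit `drop_unknown` flag, since how such
  nominations were recorded upstream is unknown.

## Inference

`fit_srm()` samples the posterior with Hamiltonian Monte Carlo: all
parameters are transformed to an unconstrained space (log scales, atanh
correlations, logit rates), random effects are *non-centered*
($\lambda_i = \sigma_\lambda z_i$ etc., which removes the funnel between
scales and effects; the posterior is unchanged), and the log-posterior and
its analytic gradient are evaluated in compiled code. Warmup adapts the
step size by dual averaging (target acceptance 0.8) and estimates a
diagonal mass matrix from the first warmup half (shrunk toward unit
variance); trajectories use a jittered number of leapfrog steps. A
transition with an energy error above 1000 counts as divergent and is
reported in the fit's diagnostics.

Defaults are 4 chains of 1000 warmup + 1000 sampling iterations —
generous for 44 households (1892 ordered pairs), where chains converge in
seconds. Summaries report the posterior median and central 95% credible
interval by the standard quantile rule, split-chain $\widehat R$ and an
autocorrelation-based effective sample size; a fit warns (and records)
$\widehat R > 1.05$ on any top-level parameter. A coefficient is flagged
*reliable* when its 95% CI excludes zero — the usage behind statements
like "no reliable association" — and no multiple-testing adjustment is
applied, matching how such analyses are reported.

Block results are given as offsets and contrasts: per draw, the baseline
tie probability of cell $(g,h)$ is $\mathrm{logit}^{-1}(\alpha + B_{g,h})$
at zero covariates and zero random effects, and $\Delta(g,h)$ is its
difference from the reference cell. The probability scale is the default
because contrasts are naturally read as changes in tie probability; a
log-odds option is provided since the probability-vs-log-odds convention
for offsets is ambiguous in graphical presentations. Groups are coded
1 = flag absent, 2 = flag present, and the default reference cell (2,2)
is "both households hold the flag", so negative contrasts read as "less
likely than ties among flag-holders".

## The synthetic community generator

`generate_community()` emulates the study conditions: 44 households in 4
hamlets scattered within roughly a square kilometre (centroid spacing 700
m, within-hamlet jitter 60 m — enough spatial structure for the distance
covariate to matter); log-normal cash wealth calibrated so the *population*
Gini is 0.38 (clove-tree value 0.62) via
$\sigma = \sqrt2\,\Phi^{-1}((1+G)/2)$; a three-generation patrilocal
pedigree descending from five patrilines of related founder brothers, with
sons founding households in their father's hamlet (rate 0.85) and marrying
village daughters from other lineages (rate 0.6), which yields the nonzero
between-household relatedness the covariate needs; flag prevalences 0.2
(status) and 0.35 (development group), chosen so both block levels are
well populated at $n = 44$; and five layers simulated from known
parameters, food sharing double-sampled through the reporting-error model
(recall 0.9/0.85, false positives 0.05/0.03).

The default layer parameters are *illustrative*, not estimates: they
reproduce the qualitative sign structure the model family is meant to
detect (positive wealth-sender effects everywhere; wealth homophily only
in the women's layers; relatedness effects in food sharing and women's
layers; distance decay except men's co-working; dyadic reciprocity
concentrated in men's co-working; food sharing predicted by all four other
layers). Gender-specific parameter sets make gender contrasts reproducible
qualitatively. Because layers enter each other's models as observed
predictors, simulation proceeds in configuration order and each layer may
condition only on earlier ones.

What the generator does *not* emulate: individual-level nominations within
households, marriage/divorce dynamics or demographic change, interviewer
effects (a gender-matched design cannot separate interviewer from
respondent, so no such term exists in the model), and any dependence of
wealth on the networks (wealth is exogenous in the generator). Passing
recovery tests on this generator therefore shows the estimator is
calibrated *under the model*, not that the model is true of any real
community.

## Validation design and problem sizes

The test suite checks, among others: closed-form kinship values
(parent–offspring 0.5, half-sibs 0.25, first cousins 0.125, $0.5^k$ descent
chains), closed-form arcs for the distance matrix, Gini against a
pairwise-difference oracle, the marginalized likelihood against exhaustive
latent enumeration at $n \le 4$ (tolerance 1e-10), the noiseless limit in
which the double-sample likelihood collapses to the single-sample one and
conflicting reports get probability zero, and full parameter recovery: 20
replicate communities at $n = 44$ generated with wealth-sender effect
0.75, dyadic reciprocity 0.6, recall 0.9 and false positives 0.05, refit
with 2 chains of 400 + 400 iterations each. Coverage of the 95% intervals
is gated at 17/20 per parameter and the reliable flag for the two effects
generated at exactly zero (wealth distance, generalized reciprocity) at
3/20 — the exact-binomial bands around nominal 0.95 and 0.05. These
replicate counts and iteration budgets are the package's validation
choices: large enough for the binomial gates to be meaningful, small
enough to run routinely.

## Known limitations

* The measurement model treats the two questions' error rates as shared
  across respondents; respondent-level reporting heterogeneity (including
  question duplication) is not modelled.
* Static HMC with a diagonal mass matrix is tuned for this model's scale
  (a few thousand dimensions at $n \approx 44$); much larger rosters would
  warrant a dynamic-trajectory sampler.
* Ties are binary and cross-sectional; valued ties and dynamics are out of
  scope, as is any causal reading of the coefficients.
* With both block factors and an intercept the cell means are only weakly
  identified individually (the priors resolve the allocation); contrasts
  within a block are identified, which is why results are reported as
  contrasts.
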