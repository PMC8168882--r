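---
title: "Predicting host-parasitoid networks and apparent competition from traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting host-parasitoid networks and apparent competition from traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcnet)
```

## The problem

Parasitoids link host (caterpillar) populations indirectly: an increase in
one host species feeds a shared parasitoid population, which then attacks
other hosts harder — apparent competition. Quantifying that risk for a
community normally requires a fully resolved quantitative food web, which is
expensive to sample. `apcnet` implements a two-stage alternative:

1. **Direct effects.** Predict the quantitative host-parasitoid network of a
   site from species traits (body size, monthly phenology, normalised
   degree, biogeographic status) and phylogenetic position, using models
   trained on pooled "meta-networks" from separately sampled training sites.
   Two learners are provided: a random-forest classifier on pairwise
   trait/phylogeny features (predicting interaction *occurrence*
   probability) and a k-nearest-neighbour collaborative-filtering
   recommender (predicting interaction *frequency* from the host-use
   profiles of trait-similar parasitoids).
2. **Indirect effects.** Project a quantitative network into the potential
   for apparent competition between hosts, `d_ij` — the proportion of the
   parasitoids attacking host *i* expected to have recruited from host *j* —
   and combine it with time-*t* attack rates and observed host abundance
   changes to obtain an expected parasitism rate at time *t+1*, which is
   validated against observed parasitism.

All stages are testable without any field data through a synthetic
metacommunity generator that emulates the sampling design: two habitats
(native and plantation forest), training sites pooled into meta-networks,
and test sites sampled at two time steps with a host-reduction perturbation
at half of the plantation test sites.

## The projection model

For a weighted meta-network with attack counts $\alpha_{ik}$ (host $i$,
parasitoid $k$),

$$d_{ij} = \sum_k \frac{\alpha_{ik}}{\sum_l \alpha_{il}}
           \cdot \frac{\alpha_{jk}}{\sum_m \alpha_{mk}},$$

so each row of a parasitized host is a probability distribution over the
hosts its parasitoids recruited from (rows sum to one; hosts without
parasitoids carry flagged zero rows). The expected parasitism rate of host
$i$ at the second time step is

$$E_i(t{+}1) = \frac{1}{n_{i,t+1}} \Big(\sum_l \alpha_{ilt}\Big)
              \sum_j d_{ij}\, \frac{n_{j,t+1}}{n_{jt}},$$

with $n$ the number of host individuals collected. Two consequences are
used as exact tests: with unchanged abundances $E_i$ equals the time-*t*
parasitism rate (because valid $d$ rows sum to one), and raising a donor's
$t{+}1$ abundance can never lower $E_i$.

A host enters the validation only when it was collected at both time steps
and had a non-zero summed attack rate at time *t*; in addition a host
missing from the $d$ matrix (or with a flagged all-zero row) has no
apparent-competition estimate and is excluded with an explicit reason
rather than entered as a spurious $E = 0$.

## Feature construction and the learners

Pairwise features concatenate, in a fixed documented order: host body size,
exotic-status indicator, seven monthly phenology values and normalised
degree; host principal-coordinate phylogenetic axes; the parasitoid block
(no status indicator); and the pair's Schoener phenological overlap
$\sum_m \min(p_m, q_m)$ on month-proportion vectors. Phylogenetic position
is represented by classical multidimensional scaling (principal
coordinates) of the patristic distance matrix with negative-eigenvalue axes
dropped and no Cailliez correction — deterministic and metric-faithful for
small ultrametric trees; the number of retained axes is a tunable
(default 5).

The random forest is a probability forest (Gini impurity splits,
`ranger`), trained on the *binary* meta-network; its hyperparameters
(trees, depth, features per split, phylogenetic axes, trait mask) can be
tuned by stratified 5-fold cross-validation scored by ranking AUC, with
folds keyed to pair identity so row order cannot change the assignment.
Ranking AUC rather than accuracy is used because link prediction is heavily
class-imbalanced. No resampling or class weighting is applied: the raw
predicted probability is the quantity carried forward, mirroring its later
use as a quantitative predictor.

The KNN recommender predicts a frequency for host $h$ as the
similarity-weighted (default; uniform offered) mean of the weighted
meta-network rows of the focal parasitoid's $k$ most similar training
parasitoids. Similarity is Gower-style over mixed trait types: continuous
traits as range-normalised absolute differences (training ranges; test
values clipped), status as 0/1 mismatch, phenology as one minus Schoener
overlap, phylogeny as unit-scaled coordinate distance. Parasitoid
similarity defaults to body size + phenology + ND (phylogeny excluded by
default but available through the mask); host-side similarity for
cold-start insertion uses all host traits including phylogeny. A parasitoid
present in training is never its own neighbour (`exclude_self`), keeping
the evaluation honest for species whose interactions would be unknown in a
risk-assessment setting. Hosts unseen in training receive an imputed
meta-network row from their $k$ nearest training hosts before prediction;
imputed rows stay fractional. Ties among equal similarities are broken by a
seeded random order.

Attack rates for the projection come from a configurable source: RF
probabilities are converted to expected attack counts as
$\hat\alpha_{il} = \hat p_{il} \times n_{it}$ (a per-individual occurrence
risk times exposure; the raw-probability convention is available as a
switch), KNN frequencies pass through unchanged, and the data-based route
copies the observed time-*t* network. $d_{ij}$ defaults to the observed
combined training meta-network, with a switch to compute it from the pooled
predicted networks instead.

## Statistical evaluation

Validation regressions follow quantitative food-web practice. Direct
effects: observed pair frequency at the test sites (time *t*) regressed on
the scaled prediction, Poisson family, with parasitoid identity and site as
candidate random intercepts; the random structure is chosen first by AIC.
Indirect effects: observed parasitism as events-of-trials binomial on the
scaled expected rate with site as a candidate random intercept. Models with
grouping factors are random-intercept GLMMs (lme4); random slopes are
deliberately out of scope — the package's inferential contract is the sign
and significance of the focal slope and the information-criterion ranking,
not coefficient-level parity with any particular mixed-model fit. When a
mixed fit fails outright the model falls back to the fixed-effects GLM and
is flagged as non-converged rather than silently dropped.

Around the focal fits the package provides:

* **All-subsets selection** over marginality-respecting subsets of the
  fixed terms (an interaction never appears without its lower-order
  relatives), ranked by AIC or AICc ($\mathrm{AICc} = \mathrm{AIC} +
  2k(k{+}1)/(n{-}k{-}1)$), with the $\Delta < 2$ candidate set and
  per-term inclusion fractions reported as a collinearity audit. Ties go to
  the smaller model.
* **Overdispersion handling**: the ratio of the sum of squared Pearson
  residuals to the residual degrees of freedom plus a chi-squared tail
  test; a flagged model ($\ge 2$ or significant) is refitted with an
  observation-level random factor.
* **Variance-decomposition R²** (delta method): marginal = fixed-effect
  share, conditional = fixed + random share of the latent-scale variance;
  the observation-level variance is $1/\lambda$ for Poisson (log link,
  $\lambda$ at the intercept plus half the random variance — predictors are
  scaled and centred, so the intercept sits at the covariate mean) and
  $1/(p(1-p))$ for binomial (logit, $p$ at the intercept). For a Gaussian
  fit without grouping the marginal value reduces exactly to classical R².
* **Bernoulli multiple-test probability**: the exact binomial tail
  $P(X \ge k)$, $X \sim \mathrm{Bin}(N, \alpha)$, summarising how likely
  $k$ of $N$ significant slopes would be under a global null at per-test
  level $\alpha = 0.05$.
* **Leverage screening**: hat values from the final weighted
  least-squares step, flagging $h_i > 2p/n$ (a standard convention — the
  source analyses say only "high influence"); fits with and without the
  flagged points are both reported.

## The synthetic metacommunity

The generator is first-class, tested code, not a fixture. Its defaults
*are* the emulated study conditions: 40 hosts and 20 parasitoids on
pure-birth ultrametric phylogenies; 8 training sites per habitat, each with
an edge and an interior transect sampled on 7 occasions; 16 test sites per
habitat with a single edge transect sampled twice at time *t* and twice at
*t+1*; a 7-slot monthly phenology axis; and a host-reduction treatment
(abundance multiplier $\rho = 0.2$) at half of the plantation test sites.

Traits: log body size evolves by Brownian motion along the tree
(`bm_sigma = 0.6`); phenology is a Dirichlet draw (concentration 1.5)
scaled by species abundance; hosts are exotic with probability 0.25; host
normalised degree — generality on their *plant* hosts, an input trait, so
no circularity with the host-parasitoid network — is Beta(2, 5);
parasitoid ND is computed afterwards from the binary combined training
meta-network, exactly as a practitioner would measure it.

Interactions: at the training sites and test-site time *t*, attacks per
sampling unit are Poisson in (collected hosts) × (per-individual
propensity), with

$$\log B_{il} = \beta_0 + \beta_{size}\, e^{-\Delta^2 / 2\sigma^2}
             + \beta_{phen}\,\mathrm{overlap}_{il} + \beta_{phylo} K_{il},$$

$\Delta$ the log body-size difference, times the parasitoid's site-level
activity — trait matching plus a neutral abundance term. The default
regime ($\beta_{size} = 6$, $\sigma = 0.5$ log units, $\beta_{phen} = 1$,
$\beta_{phylo} = 0$, $\beta_0 = -8.5$) makes body-size matching the
dominant niche axis at realistic parasitism rates (roughly 10-20% of
collected individuals). Host abundances are log-normal with species-level
(sd 0.6) and site-level (sd 0.4) components and an opposite-signed habitat
preference shift (sd 0.3).

The $t \to t{+}1$ transition encodes the one-generation numerical response
that the projection model assumes: each pair's expected site-level attack
total is rescaled by the parasitoid's recruitment-share-weighted host
abundance change, with allocation frozen at its time-*t* structure, and
divided by the new host abundance. Under this dynamic a uniform host
decline leaves per-individual parasitism rates unchanged — exactly the
fixed point of the $E$ equation — while selective declines propagate
through shared parasitoids. Untreated sites fluctuate log-normally between
time steps (sd 0.5, mean-corrected), which is itself signal: the method is
meant to predict abundance-driven parasitism change whether the change is
experimental or natural. A simpler alternative — keeping per-individual
rates proportional to parasitoid activity at *t+1* without the budget
reallocation — is *not* Eq-consistent (a uniform decline would then scale
parasitism by $\rho$), and empirically buries the indirect signal; the
frozen-allocation response was chosen for that reason.

What passing tests on these communities do **not** show about real data:
traits here cause interactions by construction, the phenology vectors are
exchangeable across months (no seasonality), detection is perfect given
collection, parasitoid dispersal between sites is ignored, and the
treatment suppresses all hosts equally (the real biopesticide was
caterpillar-specific but species selectivity is unmodelled). Transect
labels are emitted but carry no generating effect, matching how they are
pooled in the analysis.

## Numerical choices and degenerate inputs

* Validation problem sizes: the shipped checks run the default community
  (one seed) for direct-effect recovery; 20 seeds for the neutral limit
  (all matching coefficients zero; discrimination should collapse towards
  chance); 50 seeds of a strong-sharing community
  ($\beta_{size} = 3$, $\sigma = 2$ — generalist kernels, hence heavy
  parasitoid sharing) for indirect recovery; and a 200-replicate
  within-site permutation null for the Type-I error of the indirect slope
  test, run with the same dispersion handling the real fit uses.
* Held-out discrimination is measured at the *test sites* (train on
  training-site meta-networks, rank predictions against observed test-site
  occurrence), matching the study design. Cross-validated AUC over
  meta-network pairs is used only inside the tuning grid: under a null it
  is biased below 0.5 in small samples, which would corrupt a
  neutral-limit check.
* `d_ij` is scale-free in total counts; rows of parasitized hosts sum to 1
  within 1e-10 and the worked three-host example is exact to 1e-12.
* Donor hosts with $n_{jt} = 0$ are skipped (undefined ratio) with a
  logged warning; focal-host eligibility is data, not an error.
* Degenerate learners error loudly: single-class labels, empty grids,
  folds without both classes, all-zero phenology vectors, constant
  predictors in `scale_center`.
* Zero-range continuous traits are dropped from Gower similarity with a
  warning; if nothing usable remains, that is an error.
* Determinism: every stochastic step (tree simulation, trait draws, fold
  assignment, tie-breaking, ranger training) consumes an explicit seed
  derived from the master seed; identical configurations reproduce every
  output hash.

## Known limitations

* Random slopes (predicted probability varying by parasitoid) are not
  fitted; where the emulated analyses selected them, this package's
  random-intercept structure is an approximation.
* The binomial/Poisson R² decomposition uses the delta method evaluated at
  the intercept; with strongly skewed covariates it is a first-order
  approximation only.
* `d_ij` from predicted networks (the supplementary configuration switch)
  pools predicted site networks by summation; alternative poolings are not
  explored.
* The generator conflates abundance with sampling effort (collected counts
  serve as both), as the emulated design does.

## A minimal run

```{r example, eval = FALSE}
cfg <- default_pipeline_config(
  seed = 1,
  community = community_config(seed = 1),
  engine = "both")
run <- run_pipeline(cfg)
run$report$direct$rf_combined$estimate   # slope of observed on predicted
run$report$indirect$rf$p                 # indirect-effect validation
write_report(run, "apcnet-report")
```
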