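# apcnet

Predicting quantitative host–parasitoid networks from species traits and
phylogenies, and projecting the predictions into indirect effects among
hosts (apparent competition) — with a synthetic metacommunity generator so
the whole analysis is verifiable end to end.

## Who this is for

Community ecologists and biocontrol risk assessors who want to know, for a
host assemblage and a pool of parasitoids, (a) which host–parasitoid
interactions are likely and how strong, given only traits, phylogenies and
training networks from other sites; and (b) how parasitism of each host
should respond to abundance changes in the *other* hosts that share its
parasitoids.

## The model at the core

**Direct effects.** Two learners are trained on meta-networks pooled from
training sites:

* a random-forest classifier on pairwise features (body size, monthly
  phenology, normalised degree ND, biogeographic status, principal-coordinate
  phylogenetic axes, and Schoener phenological overlap), predicting the
  probability p̂ of interaction occurrence;
* a k-nearest-neighbour collaborative-filtering recommender: the predicted
  frequency ŵ for a parasitoid is the similarity-weighted mean of the
  host-use rows of its k most trait-similar training parasitoids, with
  self-exclusion, and cold-start insertion of hosts unseen in training.

**Indirect effects.** For a quantitative web with attack counts α, the
potential for apparent competition is

    d_ij = Σ_k [α_ik / Σ_l α_il] · [α_jk / Σ_m α_mk]

(the share of host *i*'s parasitoids recruited from host *j*; rows of
parasitized hosts sum to 1), and the expected parasitism rate of host *i*
at the second time step is

    E_i(t+1) = (1 / n_i(t+1)) · (Σ_l α_ilt) · Σ_j d_ij · n_j(t+1) / n_jt

which is validated against observed parasitism with binomial mixed models,
AIC/AICc all-subsets selection, overdispersion handling, delta-method R²,
a Bernoulli multiple-testing summary and leverage-based outlier screening.

## Worked example

```r
library(apcnet)

cfg <- default_pipeline_config(seed = 99,
  community = community_config(
    n_hosts = 16, n_parasitoids = 8,
    n_training_sites = c(native = 3, plantation = 3),
    n_test_sites = c(native = 4, plantation = 4),
    seed = 99),
  engine = "both")
run <- run_pipeline(cfg)

run$report$direct$rf_combined[c("estimate", "z", "p")]
#> $estimate  1.085...
#> $z         5.24...
#> $p         1.57e-07
run$report$direct$knn_combined[c("estimate", "p")]
#> $estimate  0.417...   $p  0.088...
run$report$eligibility$rf
#> $eligible_records 46   $total_records 128   $eligible_species 7
```

Reading: on this small simulated metacommunity the random-forest predicted
probability is a significant positive predictor of observed interaction
frequency at the held-out test sites (slope on the scaled predictor 1.09,
z = 5.2), while the KNN frequency prediction is weaker (p = 0.09) — the
recommender needs more trait-similar neighbours than eight parasitoid
species provide. Of 128 site × host records, 46 were eligible for an
expected-parasitism value (collected at both time steps, non-zero attack
rate at time t, and covered by the d_ij matrix).

The main entry points are also usable piecewise: `pool_meta_network()`,
`build_pair_features()` / `train_rf()` / `predict_probabilities()`,
`gower_similarity()` / `knn_predict()` / `add_new_hosts()`,
`potential_apparent_competition()`, `expected_parasitism()`,
`validate_direct()` / `validate_indirect()`, and
`make_study_bundle()` to write a complete synthetic study to disk
(interactions.csv, traits.csv, host_samples.csv, Newick trees, config echo,
hash manifest).

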