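Package: apcnet
Title: Predicting Host-Parasitoid Networks and Apparent Competition from
    Traits and Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts quantitative host-parasitoid interaction networks from
    species traits and phylogenies using random-forest classification and a
    k-nearest-neighbour collaborative-filtering recommender (with cold-start
    insertion of hosts unseen in training), and projects the predicted
    networks into indirect effects among hosts: the potential for apparent
    competition (d_ij) and expected parasitism rates under observed host
    abundance change. Ships a synthetic metacommunity generator with
    phylogenetically structured traits, trait-matching and neutral-abundance
    interaction propensities, and a host-reduction perturbation, so every
    stage of the analysis can be validated end to end. Statistical
    evaluation follows quantitative food-web practice: Poisson and binomial
    mixed models, all-subsets AIC/AICc selection with marginality,
    overdispersion checks with observation-level random effects, delta-method
    marginal and conditional R-squared, Bernoulli multiple-test probability,
    and leverage-based outlier screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    ranger,
    lme4,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
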