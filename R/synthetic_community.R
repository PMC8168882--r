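# Synthetic host-parasitoid metacommunities with the statistical structure
# the analysis assumes: phylogenetically structured traits, trait-matching
# plus neutral-abundance interaction propensities, two habitats, pooled
# training sites, and test sites sampled at times t and t+1 with a
# host-reduction perturbation at half of the plantation test sites.
#
# Attack model. At the training sites and at test-site time t, each
# collected host individual of species i is attacked by parasitoid l at
# per-individual rate lambda_il = B_il x a_ls (trait-matching propensity
# times site-level parasitoid activity), so counts are Poisson in
# collected-hosts x lambda - trait matching plus a neutral abundance term.
# The t -> t+1 transition is a one-generation numerical response: each
# pair's expected site-level attack total is rescaled by the parasitoid's
# recruitment-share-weighted host abundance change, with allocation frozen
# at its time-t structure, and the new per-individual rate divides by the
# new host abundance. Under this dynamic a uniform host decline leaves
# per-individual parasitism rates unchanged and selective declines
# propagate to hosts sharing parasitoids - the semantics the d_ij /
# expected-parasitism projection assumes.

#' Configuration of a synthetic metacommunity
#'
#' Defaults mirror the emulated study design: 8 training sites per habitat
#' (two transects, seven sampling occasions), 16 test sites per habitat (one
#' edge transect; occasions 1-2 = time t, 3-4 = time t+1), a 7-month
#' phenology axis, and a host-reduction treatment (multiplier `rho`) at half
#' of the plantation test sites at t+1.
#'
#' @param n_hosts,n_parasitoids species counts.
#' @param n_training_sites,n_test_sites named counts per habitat.
#' @param birth_rate pure-birth rate of the simulated phylogenies.
#' @param bm_sigma Brownian-motion sd of log body size along the tree.
#' @param pheno_concentration Dirichlet concentration of monthly phenology.
#' @param exotic_fraction Bernoulli probability that a host is exotic.
#' @param host_nd_beta shape1/shape2 of the Beta draw for host (plant-based)
#'   normalised degree.
#' @param beta0 baseline log per-individual attack propensity.
#' @param beta_size,sigma_size weight and width (log body-size units) of the
#'   Gaussian size-matching kernel.
#' @param beta_phen weight of pairwise phenological overlap.
#' @param beta_phylo,phylo_bandwidth weight and bandwidth of the
#'   phylogenetic matching kernel (on leading principal-coordinate axes,
#'   unit-scaled).
#' @param abund_meanlog,abund_sdlog_species,abund_sdlog_site log-normal host
#'   abundance model: species-level mean and sd, plus independent site-level
#'   sd.
#' @param habitat_effect sd of the per-species habitat preference shift
#'   applied with opposite sign in the two habitats.
#' @param para_activity_sdlog site-level log-normal sd of parasitoid activity.
#' @param exposure sampling-effort multiplier on per-individual attack rates.
#' @param enemy_response fraction of each parasitoid's t+1 activity that
#'   tracks the abundance change of its time-t host pool (0 = no numerical
#'   response, 1 = fully proportional).
#' @param natural_fluctuation_sdlog log-normal sd of natural (untreated)
#'   host abundance change from t to t+1.
#' @param rho treatment multiplier in (0, 1] on host abundance at treated
#'   sites at t+1.
#' @param seed master seed; every stage derives its own stream from it.
#' @export
community_config <- function(n_hosts = 40L, n_parasitoids = 20L,
                             n_training_sites = c(native = 8L, plantation = 8L),
                             n_test_sites = c(native = 16L, plantation = 16L),
                             birth_rate = 1,
                             bm_sigma = 0.6,
                             pheno_concentration = 1.5,
                             exotic_fraction = 0.25,
                             host_nd_beta = c(2, 5),
                             beta0 = -8.5,
                             beta_size = 6,
                             sigma_size = 0.5,
                             beta_phen = 1,
                             beta_phylo = 0,
                             phylo_bandwidth = 1,
                             abund_meanlog = 2.3,
                             abund_sdlog_species = 0.6,
                             abund_sdlog_site = 0.4,
                             habitat_effect = 0.3,
                             para_activity_sdlog = 0.5,
                             exposure = 1,
                             enemy_response = 1,
                             natural_fluctuation_sdlog = 0.5,
                             rho = 0.2,
                             seed = 1L) {
  if (n_hosts < 2 || n_parasitoids < 2) stop("need at least 2 species per guild")
  if (any(n_training_sites < 1) || any(n_test_sites < 1)) stop("site counts must be >= 1")
  if (!setequal(names(n_training_sites), c("native", "plantation")) ||
      !setequal(names(n_test_sites), c("native", "plantation")))
    stop("site counts must be named native/plantation")
  if (rho <= 0 || rho > 1) stop("treatment multiplier rho must lie in (0, 1]")
  if (sigma_size <= 0) stop("sigma_size must be positive")
  structure(list(n_hosts = as.integer(n_hosts),
                 n_parasitoids = as.integer(n_parasitoids),
                 n_training_sites = n_training_sites,
                 n_test_sites = n_test_sites,
                 n_months = .n_months,
                 birth_rate = birth_rate, bm_sigma = bm_sigma,
                 pheno_concentration = pheno_concentration,
                 exotic_fraction = exotic_fraction,
                 host_nd_beta = host_nd_beta,
                 beta0 = beta0, beta_size = beta_size, sigma_size = sigma_size,
                 beta_phen = beta_phen, beta_phylo = beta_phylo,
                 phylo_bandwidth = phylo_bandwidth,
                 abund_meanlog = abund_meanlog,
                 abund_sdlog_species = abund_sdlog_species,
                 abund_sdlog_site = abund_sdlog_site,
                 habitat_effect = habitat_effect,
                 para_activity_sdlog = para_activity_sdlog,
                 exposure = exposure,
                 enemy_response = enemy_response,
                 natural_fluctuation_sdlog = natural_fluctuation_sdlog,
                 rho = rho, seed = as.integer(seed)),
            class = "community_config")
}

#' Simulate a pure-birth ultrametric phylogeny for one guild
#'
#' @param n_taxa number of tips (>= 2).
#' @param rate birth rate.
#' @param seed random seed.
#' @param guild "host" or "parasitoid"; sets the tip-label prefix.
#' @return an `ape::phylo` tree with guild-prefixed tip labels.
#' @export
simulate_tree <- function(n_taxa, rate = 1, seed = 1L,
                          guild = c("host", "parasitoid")) {
  guild <- match.arg(guild)
  if (n_taxa < 2) stop("need at least 2 taxa")
  set.seed(seed)
  phy <- ape::rphylo(n_taxa, birth = rate, death = 0)
  pre <- if (guild == "host") "H:h" else "P:p"
  phy$tip.label <- paste0(pre, sprintf("%03d", seq_len(n_taxa)))
  phy
}

#' Simulate a trait table for one guild along a phylogeny
#'
#' Log body size evolves by Brownian motion on the tree; species total
#' abundance is log-normal; monthly phenology is a Dirichlet draw scaled by
#' the species' abundance; biogeographic status is Bernoulli(exotic
#' fraction) for hosts; host normalised degree (generality on their plant
#' hosts, an input trait) is Beta-distributed; parasitoid ND is left NA and
#' filled later from the training meta-network.
#'
#' @param tree guild phylogeny from [simulate_tree()].
#' @param config a `community_config`.
#' @param guild "host" or "parasitoid".
#' @param seed random seed.
#' @return a trait table in the [read_traits()] schema.
#' @export
simulate_traits <- function(tree, config, guild = c("host", "parasitoid"),
                            seed = config$seed) {
  guild <- match.arg(guild)
  set.seed(seed)
  ids <- tree$tip.label
  n <- length(ids)
  root <- if (guild == "host") 1 else 0  # hosts (caterpillars) a size class above
  log_bs <- ape::rTraitCont(tree, model = "BM", sigma = config$bm_sigma,
                            root.value = root)
  abund <- stats::rlnorm(n, config$abund_meanlog, config$abund_sdlog_species)
  ph <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(config$n_months, shape = config$pheno_concentration)
    abund[i] * g / sum(g)
  }, numeric(config$n_months)))
  colnames(ph) <- paste0("pheno_m", seq_len(config$n_months))
  status <- if (guild == "host") {
    ifelse(stats::rbinom(n, 1, config$exotic_fraction) == 1, "exotic", "native")
  } else NA_character_
  nd <- if (guild == "host") {
    stats::rbeta(n, config$host_nd_beta[1], config$host_nd_beta[2])
  } else NA_real_
  out <- data.frame(species_id = ids, guild = guild,
                    body_size = exp(as.numeric(log_bs[ids])),
                    biogeographic_status = status,
                    stringsAsFactors = FALSE)
  out <- cbind(out, ph)
  out$nd <- nd
  out$total_abundance <- as.integer(pmax(1, round(abund)))
  validate_traits(out)
}

latent_propensity <- function(traits, host_coords, para_coords, config) {
  tr <- traits
  rownames(tr) <- tr$species_id
  hosts <- tr$species_id[tr$guild == "host"]
  paras <- tr$species_id[tr$guild == "parasitoid"]
  dlog <- outer(log(tr[hosts, "body_size"]), log(tr[paras, "body_size"]), "-")
  k_size <- exp(-dlog^2 / (2 * config$sigma_size^2))
  ph <- pheno_matrix(traits)
  ov <- matrix(0, length(hosts), length(paras), dimnames = list(hosts, paras))
  for (h in hosts)
    for (p in paras)
      ov[h, p] <- phenological_overlap(ph[h, ], ph[p, ])
  if (config$beta_phylo != 0) {
    u <- host_coords$coords[hosts, 1]
    v <- para_coords$coords[paras, 1]
    u <- u / max(stats::sd(u), 1e-12)
    v <- v / max(stats::sd(v), 1e-12)
    k_phy <- exp(-outer(u, v, "-")^2 / (2 * config$phylo_bandwidth^2))
  } else {
    k_phy <- matrix(0, length(hosts), length(paras))
  }
  b <- exp(config$beta0 + config$beta_size * k_size +
           config$beta_phen * ov + config$beta_phylo * k_phy)
  dimnames(b) <- list(hosts, paras)
  b
}

#' Simulate interaction records, host samples and test-site dynamics
#'
#' Latent trait-matching propensity for pair (i, l):
#'   log B_il = beta0 + beta_size * exp(-d^2/(2 sigma^2))
#'            + beta_phen * overlap_il + beta_phylo * K_phylo
#' At the training sites and at test-site time t, attack counts in a
#' sampling unit are Poisson(collected_i x B_il x a_ls x exposure) - trait
#' matching plus neutral abundance. Treated plantation test sites have host
#' abundance multiplied by `rho` at t+1; untreated test sites fluctuate
#' log-normally. At t+1 each pair's expected attack total is the time-t
#' total rescaled by the parasitoid's recruitment-share-weighted host
#' abundance change (`enemy_response`), with allocation frozen at time t,
#' divided by the new host abundance to give per-individual rates.
#'
#' @param traits combined trait table for both guilds.
#' @param host_coords,para_coords `phylo_coords` per guild.
#' @param config a `community_config`.
#' @param seed random seed.
#' @return list with `latent` (propensity matrix + per-site states),
#'   `records`, `host_samples`, `site_info`.
#' @export
simulate_interactions <- function(traits, host_coords, para_coords, config,
                                  seed = config$seed) {
  set.seed(seed)
  tr <- traits
  rownames(tr) <- tr$species_id
  hosts <- tr$species_id[tr$guild == "host"]
  paras <- tr$species_id[tr$guild == "parasitoid"]
  B <- latent_propensity(traits, host_coords, para_coords, config)

  # fixed per-species habitat preference (applied with opposite signs)
  pref_h <- stats::rnorm(length(hosts), 0, 1)
  names(pref_h) <- hosts
  host_mean <- tr[hosts, "total_abundance"]
  names(host_mean) <- hosts
  para_act <- tr[paras, "total_abundance"]
  para_act <- para_act / mean(para_act)  # relative activity scale
  names(para_act) <- paras

  site_info <- NULL
  rec <- list()
  hs <- list()
  latent_sites <- list()

  make_site <- function(site_id, habitat, role, treated) {
    rbind(site_info, data.frame(site_id = site_id, habitat = habitat,
                                role = role, treated = treated,
                                stringsAsFactors = FALSE))
  }

  hab_sign <- c(native = 1, plantation = -1)

  draw_unit <- function(site_id, habitat, transect, occasion, time_step,
                        n_vec, q_mat) {
    # n_vec: host individuals collected; q_mat: per-individual attack rates
    lam <- q_mat * n_vec                        # recycles n down rows
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam),
                     dimnames = dimnames(lam))
    counts[n_vec == 0, ] <- 0
    nz <- which(counts > 0, arr.ind = TRUE)
    out_rec <- if (nrow(nz) > 0) {
      data.frame(site_id = site_id, habitat = habitat, transect = transect,
                 occasion = occasion, time_step = time_step,
                 host_id = rownames(counts)[nz[, 1]],
                 parasitoid_id = colnames(counts)[nz[, 2]],
                 count = counts[nz], stringsAsFactors = FALSE)
    } else NULL
    pos <- which(n_vec > 0)
    out_hs <- if (length(pos) > 0) {
      data.frame(site_id = site_id, habitat = habitat, transect = transect,
                 occasion = occasion, time_step = time_step,
                 host_id = hosts[pos], n = as.integer(n_vec[pos]),
                 stringsAsFactors = FALSE)
    } else NULL
    list(rec = out_rec, hs = out_hs)
  }

  add_unit <- function(u) {
    if (!is.null(u$rec)) rec[[length(rec) + 1L]] <<- u$rec
    if (!is.null(u$hs))  hs[[length(hs) + 1L]]  <<- u$hs
  }

  site_abundances <- function(habitat) {
    shift <- hab_sign[habitat] * config$habitat_effect * pref_h
    n <- stats::rlnorm(length(hosts),
                       log(host_mean) + shift - config$abund_sdlog_site^2 / 2,
                       config$abund_sdlog_site)
    names(n) <- hosts
    n
  }
  site_activity <- function() {
    a <- para_act * stats::rlnorm(length(paras),
                                  -config$para_activity_sdlog^2 / 2,
                                  config$para_activity_sdlog)
    names(a) <- paras
    a
  }
  per_individual_rates <- function(a_vec) {
    # lambda_il = B_il a_ls exposure, per collected host individual
    sweep(B, 2, a_vec, "*") * config$exposure
  }

  # --- training sites: 2 transects x 7 occasions, time_step "training"
  for (habitat in c("native", "plantation")) {
    for (s in seq_len(config$n_training_sites[[habitat]])) {
      site_id <- sprintf("TRN-%s-%02d", toupper(substr(habitat, 1, 3)), s)
      site_info <- make_site(site_id, habitat, "training", FALSE)
      N <- site_abundances(habitat)
      q <- per_individual_rates(site_activity())
      per_unit <- N / (config$n_months * 2)  # collected over occasions x transects
      for (occ in seq_len(config$n_months)) {
        for (transect in c("edge", "interior")) {
          n_vec <- stats::rpois(length(hosts), per_unit)
          names(n_vec) <- hosts
          add_unit(draw_unit(site_id, habitat, transect, occ, "training",
                             n_vec, q))
        }
      }
    }
  }

  # --- test sites: 1 edge transect; occasions 1-2 at t, 3-4 at t+1
  treated_ids <- character(0)
  n_pl <- config$n_test_sites[["plantation"]]
  treated_idx <- sample(seq_len(n_pl), floor(n_pl / 2))
  for (habitat in c("native", "plantation")) {
    for (s in seq_len(config$n_test_sites[[habitat]])) {
      site_id <- sprintf("TST-%s-%02d", toupper(substr(habitat, 1, 3)), s)
      treated <- habitat == "plantation" && s %in% treated_idx
      if (treated) treated_ids <- c(treated_ids, site_id)
      site_info <- make_site(site_id, habitat, "test", treated)
      N_t <- site_abundances(habitat)
      q_t <- per_individual_rates(site_activity())
      for (occ in 1:2) {
        n_vec <- stats::rpois(length(hosts), N_t / 2)
        names(n_vec) <- hosts
        add_unit(draw_unit(site_id, habitat, "edge", occ, "t", n_vec, q_t))
      }
      # abundance change t -> t+1
      change <- if (treated) rep(config$rho, length(hosts)) else
        stats::rlnorm(length(hosts),
                      -config$natural_fluctuation_sdlog^2 / 2,
                      config$natural_fluctuation_sdlog)
      names(change) <- hosts
      N_t1 <- N_t * change
      # one-generation numerical response: expected site-level attack
      # totals T_il = q_il N_it are rescaled by the recruitment-share-
      # weighted host abundance change and re-expressed per individual
      T_t <- q_t * N_t                       # recycles N down rows
      colsum <- colSums(T_t)
      r_share <- sweep(T_t, 2, ifelse(colsum > 0, colsum, 1), "/")
      R <- as.numeric(t(r_share) %*% change)
      R[colsum == 0] <- 1
      resp <- (1 - config$enemy_response) + config$enemy_response * R
      T_t1 <- sweep(T_t, 2, resp, "*")
      q_t1 <- T_t1 / ifelse(N_t1 > 0, N_t1, 1)
      q_t1[N_t1 == 0, ] <- 0
      for (occ in 3:4) {
        n_vec <- stats::rpois(length(hosts), N_t1 / 2)
        names(n_vec) <- hosts
        add_unit(draw_unit(site_id, habitat, "edge", occ, "t_plus_1",
                           n_vec, q_t1))
      }
      latent_sites[[site_id]] <- list(N_t = N_t, N_t1 = N_t1, q_t = q_t,
                                      q_t1 = q_t1, treated = treated)
    }
  }

  records <- do.call(rbind, rec)
  if (is.null(records) || nrow(records) == 0)
    stop("simulation produced no interaction records; increase attack_budget or abundances")
  host_samples <- do.call(rbind, hs)
  rownames(records) <- rownames(host_samples) <- NULL
  list(latent = list(propensity = B, sites = latent_sites,
                     host_pref = pref_h, treated_sites = treated_ids),
       records = validate_interactions(records),
       host_samples = host_samples,
       site_info = site_info)
}

#' Simulate a complete study community in memory
#'
#' Runs the tree, trait and interaction generators with seeds derived from
#' the master seed, then fills the network-derived trait columns: parasitoid
#' ND from the binary combined training meta-network and realised total
#' abundances (hosts: individuals collected; parasitoids: rearing events).
#'
#' @param config a `community_config`.
#' @return list with config, traits, trees, coordinates, records,
#'   host_samples, site_info and the latent generator state.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  host_tree <- simulate_tree(config$n_hosts, config$birth_rate,
                             seed = config$seed + 101L, guild = "host")
  para_tree <- simulate_tree(config$n_parasitoids, config$birth_rate,
                             seed = config$seed + 202L, guild = "parasitoid")
  ht <- simulate_traits(host_tree, config, "host", seed = config$seed + 303L)
  pt <- simulate_traits(para_tree, config, "parasitoid", seed = config$seed + 404L)
  traits <- rbind(ht, pt)
  host_coords <- patristic_coordinates(host_tree, min(5L, config$n_hosts - 1L))
  para_coords <- patristic_coordinates(para_tree, min(5L, config$n_parasitoids - 1L))
  sim <- simulate_interactions(traits, host_coords, para_coords, config,
                               seed = config$seed + 505L)
  train <- sim$records[sim$records$time_step == "training", , drop = FALSE]
  meta_bin <- pool_meta_network(train, "combined", "binary")
  para_rows <- traits$guild == "parasitoid"
  traits$nd[para_rows] <- vapply(traits$species_id[para_rows], function(p) {
    if (p %in% colnames(meta_bin$matrix))
      normalised_degree(meta_bin, p, "parasitoid") else 0
  }, numeric(1))
  # realised total abundances across all sites and sampling dates
  traits$total_abundance <- vapply(traits$species_id, function(sp) {
    if (is_host_id(sp)) {
      if (sp %in% sim$host_samples$host_id)
        total_abundance(sp, host_samples = sim$host_samples) else 0L
    } else {
      if (sp %in% sim$records$parasitoid_id)
        total_abundance(sp, records = sim$records) else 0L
    }
  }, numeric(1))
  list(config = config, traits = validate_traits(traits),
       host_tree = host_tree, para_tree = para_tree,
       host_coords = host_coords, para_coords = para_coords,
       records = sim$records, host_samples = sim$host_samples,
       site_info = sim$site_info, latent = sim$latent)
}

#' Write a simulated study bundle to disk
#'
#' Emits interactions.csv, traits.csv, host_samples.csv, host.nwk,
#' parasitoid.nwk, a config echo (config.yaml with the resolved seed) and a
#' manifest.json listing every file with its MD5 content hash. Two bundles
#' from the same config are file-identical.
#'
#' @param config a `community_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, the in-memory community plus the manifest.
#' @export
make_study_bundle <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  comm <- simulate_community(config)
  paths <- c(interactions = file.path(dir, "interactions.csv"),
             traits = file.path(dir, "traits.csv"),
             host_samples = file.path(dir, "host_samples.csv"),
             host_tree = file.path(dir, "host.nwk"),
             para_tree = file.path(dir, "parasitoid.nwk"),
             config = file.path(dir, "config.yaml"))
  write_interactions(comm$records, paths[["interactions"]])
  write_traits(comm$traits, paths[["traits"]])
  utils::write.csv(comm$host_samples, paths[["host_samples"]], row.names = FALSE)
  ape::write.tree(comm$host_tree, paths[["host_tree"]])
  ape::write.tree(comm$para_tree, paths[["para_tree"]])
  yaml::write_yaml(unclass(config), paths[["config"]])
  manifest <- list(files = lapply(seq_along(paths), function(i)
    list(name = basename(paths[[i]]),
         md5 = unname(tools::md5sum(paths[[i]])))))
  names(manifest$files) <- names(paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(community = comm, manifest = manifest, dir = dir))
}
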