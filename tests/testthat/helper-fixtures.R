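# Shared fixtures built in code: tiny record tables, hand-made trait tables,
# a cached small simulated community, and small random generators for
# property-style tests.

tiny_records <- function() {
  data.frame(site_id = c("TRN-NAT-01", "TRN-NAT-01", "TRN-PLA-01"),
             habitat = c("native", "native", "plantation"),
             transect = c("edge", "interior", "edge"),
             occasion = c(1L, 2L, 1L),
             time_step = "training",
             host_id = c("H:h1", "H:h1", "H:h2"),
             parasitoid_id = c("P:p1", "P:p2", "P:p1"),
             count = c(2L, 1L, 3L),
             stringsAsFactors = FALSE)
}

make_traits <- function(ids, guild, seed = 1, body_size = NULL, nd = NULL,
                        pheno = NULL, status = NULL, abundance = NULL) {
  set.seed(seed)
  n <- length(ids)
  if (is.null(body_size)) body_size <- stats::rlnorm(n, 1, 0.5)
  if (is.null(nd)) nd <- stats::runif(n, 0.05, 0.95)
  if (is.null(pheno)) pheno <- matrix(stats::rgamma(n * 7, 2), n, 7)
  colnames(pheno) <- paste0("pheno_m", 1:7)
  if (is.null(status))
    status <- if (guild == "host") sample(c("native", "exotic"), n, TRUE)
              else NA_character_
  if (is.null(abundance)) abundance <- stats::rpois(n, 20) + 1L
  df <- data.frame(species_id = ids, guild = guild, body_size = body_size,
                   biogeographic_status = status, stringsAsFactors = FALSE)
  df <- cbind(df, pheno)
  df$nd <- nd
  df$total_abundance <- abundance
  validate_traits(df)
}

rand_records <- function(seed, n = 40, n_sites = 3) {
  set.seed(seed)
  sites <- sprintf("TRN-NAT-%02d", seq_len(n_sites))
  data.frame(site_id = sample(sites, n, TRUE),
             habitat = "native", transect = sample(c("edge", "interior"), n, TRUE),
             occasion = sample(1:7, n, TRUE), time_step = "training",
             host_id = paste0("H:h", sample(1:6, n, TRUE)),
             parasitoid_id = paste0("P:p", sample(1:4, n, TRUE)),
             count = sample(1:5, n, TRUE), stringsAsFactors = FALSE)
}

rand_meta <- function(seed, n_h = 6, n_p = 4, fill = 0.6) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_h * n_p, 3) * stats::rbinom(n_h * n_p, 1, fill),
              n_h, n_p,
              dimnames = list(paste0("H:h", seq_len(n_h)),
                              paste0("P:p", seq_len(n_p))))
  meta_network(m)
}

make_attacks <- function(mat, site = "s1", source = "observed") {
  structure(list(matrix = mat, site_id = site, source = source),
            class = "attack_rates")
}

# a toy community whose interactions follow a separable body-size rule
toy_rule_community <- function(n_h = 20, n_p = 10, seed = 1) {
  host_tree <- simulate_tree(n_h, seed = seed, guild = "host")
  para_tree <- simulate_tree(n_p, seed = seed + 1, guild = "parasitoid")
  traits <- rbind(make_traits(host_tree$tip.label, "host", seed = seed + 2),
                  make_traits(para_tree$tip.label, "parasitoid", seed = seed + 3))
  hc <- patristic_coordinates(host_tree, min(3, n_h - 1))
  pc <- patristic_coordinates(para_tree, min(3, n_p - 1))
  tr <- traits; rownames(tr) <- tr$species_id
  lab <- outer(tr[host_tree$tip.label, "body_size"],
               tr[para_tree$tip.label, "body_size"], ">") * 1
  dimnames(lab) <- list(host_tree$tip.label, para_tree$tip.label)
  meta_b <- meta_network(lab, "binary")
  feats <- build_pair_features(rownames(lab), colnames(lab), traits, hc, pc,
                               labels = meta_b)
  list(traits = traits, host_coords = hc, para_coords = pc,
       meta_binary = meta_b, features = feats,
       hosts = host_tree$tip.label, parasitoids = para_tree$tip.label)
}

small_config <- function(seed = 99, ...) {
  community_config(n_hosts = 16, n_parasitoids = 8,
                   n_training_sites = c(native = 3, plantation = 3),
                   n_test_sites = c(native = 4, plantation = 4),
                   seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

small_comm <- function() {
  if (is.null(.fixture_cache$comm))
    .fixture_cache$comm <- simulate_community(small_config())
  .fixture_cache$comm
}
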