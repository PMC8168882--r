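# Collaborative-filtering prediction of interaction frequencies.
#
# A focal parasitoid's host use is predicted from the host-use profiles (in
# the weighted training meta-network) of its k most trait-similar training
# parasitoids, excluding the focal species itself when it occurs in
# training. Hosts unseen in training ("new" hosts, the cold-start problem)
# first receive an imputed meta-network row from their k most similar
# training hosts.

.knn_trait_components <- c("body_size", "status", "phenology", "nd",
                           "abundance", "phylo")

#' KNN hyperparameters
#'
#' @param k number of neighbours (>= 1).
#' @param weighting "similarity" (similarity-weighted mean, the default) or
#'   "uniform".
#' @param trait_mask similarity components to include; any of
#'   body_size, status, phenology, nd, abundance, phylo.
#' @param seed seed for breaking ties among equal similarities.
#' @export
knn_hyperparams <- function(k = 3L, weighting = c("similarity", "uniform"),
                            trait_mask = c("body_size", "phenology", "nd"),
                            seed = 1L) {
  weighting <- match.arg(weighting)
  if (k < 1) stop("k must be >= 1")
  if (!all(trait_mask %in% .knn_trait_components))
    stop("unknown similarity component(s): ",
         paste(setdiff(trait_mask, .knn_trait_components), collapse = ", "))
  structure(list(k = as.integer(k), weighting = weighting,
                 trait_mask = trait_mask, seed = as.integer(seed)),
            class = "knn_hyperparams")
}

#' Gower similarity among the species of one guild
#'
#' Mixed-type Gower dissimilarity averaged over the included components:
#' continuous traits (body size, ND, abundance) as range-normalised absolute
#' differences (ranges taken from this table unless supplied, and
#' differences clipped to [0, 1] so test values outside the training range
#' stay bounded); biogeographic status as 0/1 mismatch (hosts only);
#' phenology as 1 - Schoener overlap; phylogeny as Euclidean distance over
#' principal-coordinate axes scaled by its maximum. Similarity is
#' 1 - dissimilarity.
#'
#' @param traits validated trait table.
#' @param guild "host" or "parasitoid".
#' @param mask components to include.
#' @param coords `phylo_coords` (required when "phylo" is in the mask).
#' @param ranges optional named list of c(min, max) training ranges for
#'   continuous components.
#' @return symmetric species x species similarity matrix in [0, 1] with unit
#'   diagonal (class `similarity_matrix`).
#' @export
gower_similarity <- function(traits, guild = c("host", "parasitoid"),
                             mask = c("body_size", "phenology", "nd"),
                             coords = NULL, ranges = NULL) {
  guild <- match.arg(guild)
  traits <- validate_traits(traits)
  if (!all(mask %in% .knn_trait_components))
    stop("unknown similarity component(s): ",
         paste(setdiff(mask, .knn_trait_components), collapse = ", "))
  tr <- traits[traits$guild == guild, , drop = FALSE]
  if (nrow(tr) < 2) stop("need at least two ", guild, " species")
  ids <- tr$species_id
  n <- length(ids)
  comp <- list()

  cont_component <- function(v, nm) {
    if (any(!is.finite(v))) stop("missing values in similarity component '", nm, "'")
    rg <- if (!is.null(ranges) && nm %in% names(ranges)) {
      diff(range(ranges[[nm]]))
    } else {
      diff(range(v))
    }
    if (rg <= 0) {
      warning("zero-range continuous trait '", nm, "' dropped from similarity")
      return(NULL)
    }
    pmin(abs(outer(v, v, "-")) / rg, 1)
  }

  if ("body_size" %in% mask)
    comp$body_size <- cont_component(tr$body_size, "body_size")
  if ("nd" %in% mask)
    comp$nd <- cont_component(tr$nd, "nd")
  if ("abundance" %in% mask)
    comp$abundance <- cont_component(tr$total_abundance, "abundance")
  if ("status" %in% mask) {
    if (guild != "host")
      warning("biogeographic status is a host trait; dropped for parasitoids")
    else {
      st <- tr$biogeographic_status
      comp$status <- (outer(st, st, "!=")) * 1
    }
  }
  if ("phenology" %in% mask) {
    ph <- pheno_matrix(tr)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1))
      for (j in seq(i + 1, n)) {
        d[i, j] <- 1 - phenological_overlap(ph[i, ], ph[j, ])
        d[j, i] <- d[i, j]
      }
    comp$phenology <- d
  }
  if ("phylo" %in% mask) {
    if (is.null(coords)) stop("'phylo' similarity component needs coordinates")
    miss <- setdiff(ids, rownames(coords$coords))
    if (length(miss) > 0)
      stop("species without phylogenetic coordinates: ", paste(miss, collapse = ", "))
    e <- as.matrix(stats::dist(coords$coords[ids, , drop = FALSE]))
    mx <- max(e)
    comp$phylo <- if (mx > 0) e / mx else e
  }
  comp <- Filter(Negate(is.null), comp)
  if (length(comp) == 0) stop("no usable traits for similarity")
  dis <- Reduce(`+`, comp) / length(comp)
  s <- 1 - dis
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  attr(s, "guild") <- guild
  class(s) <- c("similarity_matrix", class(s))
  s
}

knn_neighbours <- function(sim, focal, candidates, k, seed) {
  s <- sim[focal, candidates]
  set.seed(seed)
  tie <- sample.int(length(candidates))  # seeded tie-break among equal similarities
  ord <- order(-s, tie)
  k_eff <- min(k, length(candidates))
  if (k_eff < k)
    warning(sprintf("only %d eligible neighbour(s) for %s (k = %d); clamped",
                    length(candidates), focal, k))
  nb <- candidates[ord[seq_len(k_eff)]]
  list(ids = nb, sims = s[match(nb, candidates)])
}

knn_weights <- function(sims, weighting) {
  w <- if (weighting == "uniform") rep(1, length(sims)) else sims
  if (sum(w) <= 0) w <- rep(1, length(sims))
  w / sum(w)
}

#' KNN interaction-frequency prediction for one parasitoid
#'
#' Prediction for host h is the (uniform or similarity-weighted) mean of the
#' meta-network frequencies with h across the focal parasitoid's k most
#' similar training parasitoids. With `exclude_self` the focal species is
#' never its own neighbour.
#'
#' @param meta weighted `meta_network` (possibly host-augmented).
#' @param sim parasitoid `similarity_matrix` covering the focal species.
#' @param hp `knn_hyperparams`.
#' @param focal focal parasitoid id.
#' @param hosts hosts to predict for (default: all meta-network hosts).
#' @param exclude_self drop the focal species from the neighbour pool.
#' @param exclude additional parasitoids barred from the neighbour pool
#'   (used by leave-species-out tuning).
#' @return named numeric vector of predicted frequencies over `hosts`.
#' @export
knn_predict <- function(meta, sim, hp, focal, hosts = NULL,
                        exclude_self = TRUE, exclude = character(0)) {
  stopifnot(inherits(meta, "meta_network"), inherits(hp, "knn_hyperparams"))
  if (meta$mode != "weighted") stop("KNN needs a weighted meta-network")
  if (!focal %in% rownames(sim))
    stop("focal parasitoid has no similarity row: ", focal)
  if (is.null(hosts)) hosts <- rownames(meta$matrix)
  miss <- setdiff(hosts, rownames(meta$matrix))
  if (length(miss) > 0)
    stop("host(s) absent from the (augmented) meta-network: ",
         paste(miss, collapse = ", "))
  cand <- intersect(colnames(meta$matrix), rownames(sim))
  cand <- setdiff(cand, exclude)
  if (exclude_self) cand <- setdiff(cand, focal)
  if (length(cand) == 0) stop("no eligible neighbours for ", focal)
  nb <- knn_neighbours(sim, focal, cand, hp$k, hp$seed)
  w <- knn_weights(nb$sims, hp$weighting)
  pred <- as.numeric(meta$matrix[hosts, nb$ids, drop = FALSE] %*% w)
  names(pred) <- hosts
  pred
}

#' Insert 'new' hosts into a weighted training meta-network (cold start)
#'
#' Each host absent from training gains a meta-network row equal to the
#' (weighted) mean of the parasitoid profiles of its k most trait-similar
#' training hosts. Original rows are untouched.
#'
#' @param meta weighted `meta_network`.
#' @param new_hosts host ids absent from `meta`.
#' @param host_sim host `similarity_matrix` covering training and new hosts.
#' @param hp `knn_hyperparams` (k is reused from the parasitoid side unless
#'   a dedicated object is passed).
#' @return the augmented `meta_network`; attribute `new_hosts` lists the
#'   imputed rows.
#' @export
add_new_hosts <- function(meta, new_hosts, host_sim, hp) {
  stopifnot(inherits(meta, "meta_network"), inherits(hp, "knn_hyperparams"))
  if (meta$mode != "weighted") stop("cold-start insertion needs a weighted meta-network")
  if (length(new_hosts) == 0) return(meta)
  dup <- intersect(new_hosts, rownames(meta$matrix))
  if (length(dup) > 0)
    stop("host(s) already in the meta-network: ", paste(dup, collapse = ", "))
  train_hosts <- intersect(rownames(host_sim), rownames(meta$matrix))
  if (length(train_hosts) == 0)
    stop("host similarity matrix covers no training hosts")
  miss <- setdiff(new_hosts, rownames(host_sim))
  if (length(miss) > 0)
    stop("new host(s) without similarity rows: ", paste(miss, collapse = ", "))
  rows <- matrix(0, length(new_hosts), ncol(meta$matrix),
                 dimnames = list(new_hosts, colnames(meta$matrix)))
  for (h in new_hosts) {
    nb <- knn_neighbours(host_sim, h, train_hosts, hp$k, hp$seed)
    w <- knn_weights(nb$sims, hp$weighting)
    rows[h, ] <- as.numeric(w %*% meta$matrix[nb$ids, , drop = FALSE])
  }
  out <- meta
  out$matrix <- rbind(meta$matrix, rows)
  attr(out, "new_hosts") <- new_hosts
  out
}

#' Predict the full interaction-frequency matrix for a site
#'
#' @param meta weighted, host-augmented `meta_network` covering all site hosts.
#' @param sim parasitoid similarity matrix covering all site parasitoids.
#' @param hp `knn_hyperparams`.
#' @param hosts,parasitoids species present at the site.
#' @param site_id recorded on the result.
#' @param exclude_self passed to [knn_predict()].
#' @return hosts x parasitoids frequency matrix (entries >= 0) with
#'   attributes `site_id` and `source = "knn"`.
#' @export
predict_site_frequencies <- function(meta, sim, hp, hosts, parasitoids,
                                     site_id = NA_character_,
                                     exclude_self = TRUE) {
  miss <- setdiff(hosts, rownames(meta$matrix))
  if (length(miss) > 0)
    stop("host(s) not covered by the augmented meta-network: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(parasitoids, rownames(sim))
  if (length(miss) > 0)
    stop("parasitoid(s) without similarity rows: ", paste(miss, collapse = ", "))
  m <- vapply(parasitoids,
              function(p) knn_predict(meta, sim, hp, p, hosts, exclude_self),
              numeric(length(hosts)))
  m <- matrix(m, nrow = length(hosts), ncol = length(parasitoids),
              dimnames = list(hosts, parasitoids))
  attr(m, "site_id") <- site_id
  attr(m, "source") <- "knn"
  m
}

#' Tune KNN by leave-species-out cross-validation
#'
#' Folds group parasitoid species; every species of a held-out fold is
#' predicted from the remaining training parasitoids only, and a cell's
#' score is the mean root-mean-square error between predicted and observed
#' meta-network frequencies. Ties go to smaller k, then grid order.
#'
#' @param meta weighted `meta_network`.
#' @param traits trait table (similarities are rebuilt per trait mask).
#' @param grid list of `knn_hyperparams` cells.
#' @param folds number of species folds (2 <= folds <= number of parasitoids).
#' @param coords optional `phylo_coords` for masks containing "phylo".
#' @param seed fold-assignment seed.
#' @return list with `best`, `errors` (mean CV RMSE per cell), `fold_id`.
#' @export
tune_knn <- function(meta, traits, grid, folds = 5L, coords = NULL, seed = 1L) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  paras <- colnames(meta$matrix)
  if (folds > length(paras)) stop("more folds than parasitoid species")
  if (folds < 2) stop("need at least 2 folds")
  set.seed(seed)
  fold_id <- stats::setNames(sample(rep(seq_len(folds), length.out = length(paras))),
                             paras)
  errors <- vapply(grid, function(cell) {
    sim <- gower_similarity(traits, "parasitoid", cell$trait_mask, coords = coords)
    fold_err <- vapply(seq_len(folds), function(f) {
      held <- paras[fold_id == f]
      mean(vapply(held, function(p) {
        pred <- suppressWarnings(
          knn_predict(meta, sim, cell, p, exclude_self = TRUE,
                      exclude = setdiff(held, p)))
        sqrt(mean((pred - meta$matrix[, p])^2))
      }, numeric(1)))
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  ks <- vapply(grid, function(cell) as.numeric(cell$k), numeric(1))
  ord <- order(errors, ks, seq_along(grid))
  list(best = grid[[ord[1]]], errors = errors, fold_id = fold_id)
}
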