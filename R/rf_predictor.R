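# Pairwise trait/phylogeny feature construction and random-forest prediction
# of interaction occurrence probability for host x parasitoid pairs.
#
# The feature order is fixed and documented: host body size, host exotic
# indicator, host monthly phenology (7), host ND, host phylo axes; then the
# parasitoid block (no status indicator); then the pairwise phenological
# overlap. The trait-inclusion mask of the hyperparameters selects groups of
# these columns at training time.

.rf_trait_groups <- c("host_body_size", "host_status", "host_phenology",
                      "host_nd", "host_phylo",
                      "para_body_size", "para_phenology", "para_nd",
                      "para_phylo", "overlap")

#' Random-forest hyperparameters
#'
#' @param n_trees number of trees (>= 1).
#' @param max_depth maximum tree depth; `NULL` = unbounded.
#' @param features_per_split "sqrt" or "all" candidate features per split.
#' @param min_leaf minimum terminal-node size.
#' @param trait_mask character vector of trait groups to include (see
#'   `apcnet:::.rf_trait_groups`).
#' @param m_axes number of phylogenetic principal-coordinate axes to use
#'   (clamped to the axes available in the feature table).
#' @param seed mandatory random seed; makes training and prediction
#'   bit-reproducible.
#' @export
rf_hyperparams <- function(n_trees = 500L, max_depth = NULL,
                           features_per_split = c("sqrt", "all"),
                           min_leaf = 1L,
                           trait_mask = .rf_trait_groups,
                           m_axes = 5L, seed = 1L) {
  features_per_split <- match.arg(features_per_split)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (m_axes < 1) stop("m_axes must be >= 1")
  if (!all(trait_mask %in% .rf_trait_groups))
    stop("unknown trait group(s) in mask: ",
         paste(setdiff(trait_mask, .rf_trait_groups), collapse = ", "))
  if (is.null(seed)) stop("a random seed is mandatory")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 features_per_split = features_per_split,
                 min_leaf = as.integer(min_leaf),
                 trait_mask = trait_mask, m_axes = as.integer(m_axes),
                 seed = as.integer(seed)),
            class = "rf_hyperparams")
}

#' Default hyperparameter grid for the random forest
#'
#' Crossing n_trees {200, 500}, max_depth {unbounded, 10},
#' features_per_split {sqrt, all} and m_axes {3, 5} at the full trait mask.
#'
#' @param seed seed shared by every grid cell.
#' @export
default_rf_grid <- function(seed = 1L) {
  cells <- expand.grid(n_trees = c(200L, 500L), depth = c(NA, 10),
                       fps = c("sqrt", "all"), m = c(3L, 5L),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    rf_hyperparams(n_trees = cells$n_trees[i],
                   max_depth = if (is.na(cells$depth[i])) NULL else cells$depth[i],
                   features_per_split = cells$fps[i],
                   m_axes = cells$m[i], seed = seed))
}

#' Build the pairwise feature table for all host x parasitoid pairs
#'
#' One row per pair (hosts x parasitoids Cartesian product). When a binary
#' meta-network is supplied its entries become the 0/1 `label` column.
#'
#' @param hosts,parasitoids species id vectors.
#' @param traits validated trait table covering all listed species.
#' @param host_coords,para_coords `phylo_coords` covering the species.
#' @param labels optional binary `meta_network` whose axes cover the species.
#' @return data.frame with id columns, feature columns, and optionally `label`.
#' @export
build_pair_features <- function(hosts, parasitoids, traits,
                                host_coords, para_coords, labels = NULL) {
  traits <- validate_traits(traits)
  missing_tr <- setdiff(c(hosts, parasitoids), traits$species_id)
  if (length(missing_tr) > 0)
    stop("species without trait rows: ", paste(missing_tr, collapse = ", "))
  miss <- c(setdiff(hosts, rownames(host_coords$coords)),
            setdiff(parasitoids, rownames(para_coords$coords)))
  if (length(miss) > 0)
    stop("species without phylogenetic coordinates: ", paste(miss, collapse = ", "))
  tr <- traits
  rownames(tr) <- tr$species_id
  bad <- hosts[!is.finite(tr[hosts, "body_size"])]
  if (length(bad) > 0)
    stop("host(s) with missing body_size: ", paste(bad, collapse = ", "))
  bad <- parasitoids[!is.finite(tr[parasitoids, "body_size"])]
  if (length(bad) > 0)
    stop("parasitoid(s) with missing body_size: ", paste(bad, collapse = ", "))
  bad <- c(hosts[!is.finite(tr[hosts, "nd"])], parasitoids[!is.finite(tr[parasitoids, "nd"])])
  if (length(bad) > 0)
    stop("species with missing normalised degree: ", paste(bad, collapse = ", "))

  ph <- pheno_matrix(traits)
  grid <- expand.grid(parasitoid_id = parasitoids, host_id = hosts,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("host_id", "parasitoid_id")]
  X <- data.frame(host_id = grid$host_id, parasitoid_id = grid$parasitoid_id,
                  stringsAsFactors = FALSE)
  X$h_body_size <- tr[grid$host_id, "body_size"]
  X$h_exotic <- as.numeric(tr[grid$host_id, "biogeographic_status"] == "exotic")
  hp_m <- ph[grid$host_id, , drop = FALSE]
  colnames(hp_m) <- paste0("h_pheno_m", seq_len(.n_months))
  X <- cbind(X, hp_m)
  X$h_nd <- tr[grid$host_id, "nd"]
  hc <- host_coords$coords[grid$host_id, , drop = FALSE]
  colnames(hc) <- paste0("h_phylo", seq_len(ncol(hc)))
  X <- cbind(X, hc)
  X$p_body_size <- tr[grid$parasitoid_id, "body_size"]
  pp_m <- ph[grid$parasitoid_id, , drop = FALSE]
  colnames(pp_m) <- paste0("p_pheno_m", seq_len(.n_months))
  X <- cbind(X, pp_m)
  X$p_nd <- tr[grid$parasitoid_id, "nd"]
  pc <- para_coords$coords[grid$parasitoid_id, , drop = FALSE]
  colnames(pc) <- paste0("p_phylo", seq_len(ncol(pc)))
  X <- cbind(X, pc)
  ov <- matrix(NA_real_, length(hosts), length(parasitoids),
               dimnames = list(hosts, parasitoids))
  for (h in hosts)
    for (p in parasitoids)
      ov[h, p] <- phenological_overlap(ph[h, ], ph[p, ])
  X$pheno_overlap <- ov[cbind(grid$host_id, grid$parasitoid_id)]
  rownames(X) <- NULL
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "meta_network"))
    if (labels$mode != "binary") stop("labels must come from a binary meta-network")
    miss <- c(setdiff(hosts, rownames(labels$matrix)),
              setdiff(parasitoids, colnames(labels$matrix)))
    if (length(miss) > 0)
      stop("species absent from the label meta-network: ", paste(miss, collapse = ", "))
    X$label <- labels$matrix[cbind(grid$host_id, grid$parasitoid_id)]
  }
  X
}

rf_feature_columns <- function(mask, m_host, m_para) {
  cols <- character(0)
  if ("host_body_size" %in% mask) cols <- c(cols, "h_body_size")
  if ("host_status" %in% mask)    cols <- c(cols, "h_exotic")
  if ("host_phenology" %in% mask) cols <- c(cols, paste0("h_pheno_m", seq_len(.n_months)))
  if ("host_nd" %in% mask)        cols <- c(cols, "h_nd")
  if ("host_phylo" %in% mask && m_host > 0)
    cols <- c(cols, paste0("h_phylo", seq_len(m_host)))
  if ("para_body_size" %in% mask) cols <- c(cols, "p_body_size")
  if ("para_phenology" %in% mask) cols <- c(cols, paste0("p_pheno_m", seq_len(.n_months)))
  if ("para_nd" %in% mask)        cols <- c(cols, "p_nd")
  if ("para_phylo" %in% mask && m_para > 0)
    cols <- c(cols, paste0("p_phylo", seq_len(m_para)))
  if ("overlap" %in% mask)        cols <- c(cols, "pheno_overlap")
  cols
}

#' Train a random-forest interaction-occurrence classifier
#'
#' Fits a probability forest (Gini impurity splits) on the labelled pair
#' features. Training is deterministic for a fixed seed and input.
#'
#' @param features labelled output of [build_pair_features()].
#' @param hp an `rf_hyperparams` object.
#' @return An `rf_model` handle.
#' @export
train_rf <- function(features, hp) {
  stopifnot(inherits(hp, "rf_hyperparams"))
  if (is.null(features$label))
    stop("features carry no labels; supply a binary meta-network to build_pair_features")
  if (length(unique(features$label)) < 2)
    stop("degenerate training set: labels contain a single class")
  n_h <- sum(grepl("^h_phylo", names(features)))
  n_p <- sum(grepl("^p_phylo", names(features)))
  cols <- rf_feature_columns(hp$trait_mask, min(hp$m_axes, n_h), min(hp$m_axes, n_p))
  miss <- setdiff(cols, names(features))
  if (length(miss) > 0) stop("feature columns missing: ", paste(miss, collapse = ", "))
  # canonical row order: training is invariant to input row permutation
  ord <- if (all(c("host_id", "parasitoid_id") %in% names(features))) {
    order(features$host_id, features$parasitoid_id)
  } else seq_len(nrow(features))
  dat <- features[ord, cols, drop = FALSE]
  dat$.label <- factor(features$label[ord], levels = c(0, 1))
  mtry <- if (hp$features_per_split == "all") length(cols)
          else max(1L, floor(sqrt(length(cols))))
  fit <- ranger::ranger(dependent.variable.name = ".label", data = dat,
                        probability = TRUE, num.trees = hp$n_trees,
                        mtry = mtry,
                        max.depth = if (is.null(hp$max_depth)) 0 else hp$max_depth,
                        min.node.size = hp$min_leaf,
                        importance = "impurity", seed = hp$seed,
                        num.threads = 1L, verbose = FALSE)
  structure(list(forest = fit, hyperparams = hp, feature_cols = cols),
            class = "rf_model")
}

#' Predicted interaction probability for rows of a pair-feature table
#' @param model an `rf_model`.
#' @param features pair-feature table (labels ignored).
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_rf <- function(model, features) {
  stopifnot(inherits(model, "rf_model"))
  miss <- setdiff(model$feature_cols, names(features))
  if (length(miss) > 0) stop("feature columns missing: ", paste(miss, collapse = ", "))
  pr <- stats::predict(model$forest, data = features[model$feature_cols],
                       num.threads = 1L, seed = model$hyperparams$seed)$predictions
  as.numeric(pr[, "1"])
}

#' Predict the full interaction-probability matrix for a site
#'
#' @param model trained `rf_model`.
#' @param hosts,parasitoids species present at the site.
#' @param traits,host_coords,para_coords as in [build_pair_features()].
#' @param site_id recorded on the result.
#' @return hosts x parasitoids probability matrix with attributes `site_id`
#'   and `source = "rf"`.
#' @export
predict_probabilities <- function(model, hosts, parasitoids, traits,
                                  host_coords, para_coords,
                                  site_id = NA_character_) {
  feats <- build_pair_features(hosts, parasitoids, traits, host_coords, para_coords)
  p <- predict_rf(model, feats)
  m <- matrix(p, nrow = length(hosts), ncol = length(parasitoids),
              byrow = TRUE, dimnames = list(hosts, parasitoids))
  attr(m, "site_id") <- site_id
  attr(m, "source") <- "rf"
  m
}

#' Gini feature importances of a trained forest
#'
#' Impurity importances normalised to sum to one, keyed by feature name.
#' @param model trained `rf_model`.
#' @export
gini_importances <- function(model) {
  if (!inherits(model, "rf_model")) stop("not a trained rf_model")
  imp <- pmax(model$forest$variable.importance, 0)
  if (sum(imp) == 0) return(stats::setNames(rep(1 / length(imp), length(imp)), names(imp)))
  imp / sum(imp)
}

rank_auc <- function(labels, scores) {
  # internal cross-check helper; the CV path scores with pROC
  pos <- labels == 1
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

cv_auc <- function(labels, scores) {
  as.numeric(pROC::auc(response = factor(labels, levels = c(0, 1)),
                       predictor = scores, levels = c("0", "1"),
                       direction = "<", quiet = TRUE))
}

#' Grid search over random-forest hyperparameters by cross-validated AUC
#'
#' Stratified k-fold cross-validation over pairs, scored by ranking AUC.
#' Fold assignment is keyed to the (host, parasitoid) identity of each row,
#' so permuting training-row order cannot change the folds. Ties are broken
#' towards the smaller model (fewer trees, then shallower), then grid order.
#'
#' @param features labelled pair features.
#' @param grid list of `rf_hyperparams` cells.
#' @param folds number of CV folds (>= 2).
#' @param seed seed for the fold assignment.
#' @return list with `best` (the winning cell), `scores` (mean CV AUC per
#'   cell) and `fold_id`.
#' @export
grid_search <- function(features, grid, folds = 5L, seed = 1L) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  if (folds < 2) stop("cross-validation needs at least 2 folds")
  y <- features$label
  if (is.null(y)) stop("features carry no labels")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < folds)
    stop("too few members of the rarer class for ", folds, "-fold stratified CV")
  key <- order(features$host_id, features$parasitoid_id)
  fold_id <- integer(nrow(features))
  set.seed(seed)
  for (cl in c(0, 1)) {
    idx <- key[y[key] == cl]  # canonical order within class
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  scores <- vapply(grid, function(hp) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- features[fold_id != f, , drop = FALSE]
      te <- features[fold_id == f, , drop = FALSE]
      mod <- train_rf(tr, hp)
      cv_auc(te$label, predict_rf(mod, te))
    }, numeric(1)))
  }, numeric(1))
  trees <- vapply(grid, function(hp) as.numeric(hp$n_trees), numeric(1))
  depth <- vapply(grid, function(hp) if (is.null(hp$max_depth)) Inf
                  else as.numeric(hp$max_depth), numeric(1))
  ord <- order(-scores, trees, depth, seq_along(grid))
  list(best = grid[[ord[1]]], scores = scores, fold_id = fold_id)
}
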