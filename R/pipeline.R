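# Config-driven orchestration of the full analysis: simulate/load ->
# pool training meta-networks -> train -> predict per test site at time t ->
# d_ij -> attack rates -> expected parasitism -> validation fits -> report.

#' Default pipeline configuration
#'
#' @param seed master seed, propagated to the community generator and the
#'   learners.
#' @param ... overrides for any top-level entry.
#' @return a named list understood by [run_pipeline()]. Entries:
#'   `community` (a `community_config`, used when `data_dir` is NULL),
#'   `data_dir` (a study-bundle directory to load instead of simulating),
#'   `training_pool` ("native", "plantation", "combined" or "all" for the
#'   three-model family), `engine` ("rf", "knn" or "both"), `d_source`
#'   ("observed_meta" or "predicted"), `alpha_source` ("auto" = each
#'   engine's own predictions, or "observed" for the data-based approach),
#'   `rf`, `knn` (hyperparameters), `tune` (run the grid searches),
#'   `evaluation` (criterion, alpha), `out_dir`.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed),
              community = community_config(seed = seed),
              data_dir = NULL,
              training_pool = "combined",
              engine = "rf",
              d_source = "observed_meta",
              alpha_source = "auto",
              rf = rf_hyperparams(seed = seed),
              knn = knn_hyperparams(seed = seed),
              tune = FALSE,
              evaluation = list(criterion = "AIC", alpha = 0.05),
              out_dir = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  if (!config$training_pool %in% c("native", "plantation", "combined", "all"))
    stop("training_pool must be native/plantation/combined/all")
  if (!config$engine %in% c("rf", "knn", "both"))
    stop("engine must be rf/knn/both")
  if (!config$d_source %in% c("observed_meta", "predicted"))
    stop("d_source must be observed_meta/predicted")
  if (!config$alpha_source %in% c("auto", "rf", "knn", "observed"))
    stop("alpha_source must be auto/rf/knn/observed")
  if (config$alpha_source %in% c("rf", "knn")) {
    eng <- if (config$engine == "both") c("rf", "knn") else config$engine
    if (!config$alpha_source %in% eng)
      stop("alpha_source '", config$alpha_source,
           "' requires that engine to be enabled")
  }
  invisible(config)
}

#' Load a study bundle written by [make_study_bundle()]
#'
#' Reads the interaction, trait and host-sample tables and the two Newick
#' trees, recomputes phylogenetic coordinates, and reconstructs the site
#' table from the record prefixes.
#'
#' @param dir bundle directory.
#' @return a community list in the [simulate_community()] layout (without
#'   latent generator state).
#' @export
load_study_bundle <- function(dir) {
  records <- read_interactions(file.path(dir, "interactions.csv"))
  traits <- read_traits(file.path(dir, "traits.csv"))
  host_samples <- utils::read.csv(file.path(dir, "host_samples.csv"),
                                  stringsAsFactors = FALSE)
  host_tree <- ape::read.tree(file.path(dir, "host.nwk"))
  para_tree <- ape::read.tree(file.path(dir, "parasitoid.nwk"))
  n_h <- length(host_tree$tip.label)
  n_p <- length(para_tree$tip.label)
  site_cols <- unique(records[c("site_id", "habitat")])
  site_info <- data.frame(site_id = site_cols$site_id,
                          habitat = site_cols$habitat,
                          role = ifelse(startsWith(site_cols$site_id, "TRN"),
                                        "training", "test"),
                          treated = NA, stringsAsFactors = FALSE)
  list(traits = traits, records = records, host_samples = host_samples,
       host_tree = host_tree, para_tree = para_tree,
       host_coords = patristic_coordinates(host_tree, min(5L, n_h - 1L)),
       para_coords = patristic_coordinates(para_tree, min(5L, n_p - 1L)),
       site_info = site_info, config = NULL, latent = NULL)
}

hash_object <- function(x) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(x, tmp, ascii = TRUE, compress = FALSE)
  unname(tools::md5sum(tmp))
}

site_abundance_series <- function(host_samples, site) {
  hs <- host_samples[host_samples$site_id == site, , drop = FALSE]
  n_t  <- tapply(hs$n[hs$time_step == "t"], hs$host_id[hs$time_step == "t"], sum)
  n_t1 <- tapply(hs$n[hs$time_step == "t_plus_1"],
                 hs$host_id[hs$time_step == "t_plus_1"], sum)
  hosts <- sort(unique(c(names(n_t), names(n_t1))))
  data.frame(host_id = hosts,
             n_t = as.numeric(ifelse(hosts %in% names(n_t), n_t[hosts], 0)),
             n_t_plus_1 = as.numeric(ifelse(hosts %in% names(n_t1), n_t1[hosts], 0)),
             stringsAsFactors = FALSE)
}

pool_predicted_meta <- function(pred_list) {
  hosts <- sort(unique(unlist(lapply(pred_list, rownames))))
  paras <- sort(unique(unlist(lapply(pred_list, colnames))))
  m <- matrix(0, length(hosts), length(paras), dimnames = list(hosts, paras))
  for (pm in pred_list)
    m[rownames(pm), colnames(pm)] <- m[rownames(pm), colnames(pm)] + pm
  meta_network(m, "weighted", "combined")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or load the study data; pool the training
#' meta-network(s); train the engine(s); predict every test site at time t
#' (sites with no parasitoids at t are excluded); compute d_ij; convert
#' predictions to attack rates; compute expected and observed parasitism;
#' fit the direct and indirect validation models; assemble the report and a
#' run manifest with content hashes. Deterministic for a fixed config.
#'
#' @param config from [default_pipeline_config()].
#' @return list with `results`, `report`, `manifest` and the data used.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_pipeline_config(config)
  t0 <- Sys.time()
  timing <- list()
  tick <- function(stage) {
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  # -- stage: data
  data <- if (!is.null(config$data_dir)) load_study_bundle(config$data_dir)
          else simulate_community(config$community)
  tick("data")
  records <- data$records
  traits <- data$traits
  train_rec <- records[records$time_step == "training", , drop = FALSE]
  if (nrow(train_rec) == 0) stop("stage meta: no training interaction records")

  pools <- if (config$training_pool == "all")
    c("native", "plantation", "combined") else config$training_pool
  engines <- if (config$engine == "both") c("rf", "knn") else config$engine

  metas <- lapply(pools, function(p) list(
    weighted = pool_meta_network(train_rec, p, "weighted"),
    binary = pool_meta_network(train_rec, p, "binary")))
  names(metas) <- pools
  tick("meta")

  # -- stage: test-site composition at time t
  test_sites <- data$site_info$site_id[data$site_info$role == "test"]
  nets_t <- lapply(test_sites, function(s)
    build_site_network(records, data$host_samples, s, "t"))
  names(nets_t) <- test_sites
  has_para <- vapply(nets_t, function(n) ncol(n$count_matrix) > 0, logical(1))
  excluded_sites <- test_sites[!has_para]
  test_sites <- test_sites[has_para]
  if (length(test_sites) == 0) stop("stage predict: no test sites with parasitoids at time t")
  nets_t <- nets_t[test_sites]
  site_species <- lapply(nets_t, function(n)
    list(hosts = names(n$host_sample)[n$host_sample > 0],
         parasitoids = colnames(n$count_matrix)))
  site_habitat <- stats::setNames(data$site_info$habitat, data$site_info$site_id)

  # -- stage: train + predict per pool/engine
  models <- list()
  predictions <- list()   # predictions[[pool]][[engine]][[site]]
  tuning <- list()
  for (p in pools) {
    models[[p]] <- list()
    predictions[[p]] <- list()
    if ("rf" %in% engines) {
      meta_b <- metas[[p]]$binary
      feats <- build_pair_features(rownames(meta_b$matrix), colnames(meta_b$matrix),
                                   traits, data$host_coords, data$para_coords,
                                   labels = meta_b)
      hp <- config$rf
      if (isTRUE(config$tune)) {
        gs <- grid_search(feats, default_rf_grid(seed = config$seed),
                          seed = config$seed)
        hp <- gs$best
        tuning[[paste0("rf_", p)]] <- gs$scores
      }
      mod <- train_rf(feats, hp)
      models[[p]]$rf <- mod
      predictions[[p]]$rf <- lapply(test_sites, function(s) {
        sp <- site_species[[s]]
        predict_probabilities(mod, sp$hosts, sp$parasitoids, traits,
                              data$host_coords, data$para_coords, site_id = s)
      })
      names(predictions[[p]]$rf) <- test_sites
    }
    if ("knn" %in% engines) {
      meta_w <- metas[[p]]$weighted
      hp <- config$knn
      para_sim <- gower_similarity(traits, "parasitoid", hp$trait_mask,
                                   coords = data$para_coords)
      host_sim <- gower_similarity(traits, "host",
                                   c("body_size", "status", "phenology",
                                     "nd", "phylo"),
                                   coords = data$host_coords)
      if (isTRUE(config$tune)) {
        grid <- lapply(c(1L, 3L, 5L), function(k)
          knn_hyperparams(k = k, trait_mask = hp$trait_mask, seed = config$seed))
        tk <- tune_knn(meta_w, traits, grid,
                       folds = min(5L, ncol(meta_w$matrix)),
                       coords = data$para_coords, seed = config$seed)
        hp <- tk$best
        tuning[[paste0("knn_", p)]] <- tk$errors
      }
      all_hosts <- unique(unlist(lapply(site_species, `[[`, "hosts")))
      new_hosts <- setdiff(all_hosts, rownames(meta_w$matrix))
      meta_aug <- add_new_hosts(meta_w, new_hosts, host_sim, hp)
      models[[p]]$knn <- list(hp = hp, meta = meta_aug, para_sim = para_sim)
      predictions[[p]]$knn <- lapply(test_sites, function(s) {
        sp <- site_species[[s]]
        predict_site_frequencies(meta_aug, para_sim, hp, sp$hosts,
                                 sp$parasitoids, site_id = s)
      })
      names(predictions[[p]]$knn) <- test_sites
    }
  }
  tick("predict")

  # -- stage: d_ij (combined pool, per the main analysis)
  meta_combined <- pool_meta_network(train_rec, "combined", "weighted")
  d_by_engine <- list()
  for (e in engines) {
    d_by_engine[[e]] <- if (config$d_source == "observed_meta") {
      potential_apparent_competition(meta_combined)
    } else {
      pool_used <- if ("combined" %in% pools) "combined" else pools[1]
      potential_apparent_competition(
        pool_predicted_meta(predictions[[pool_used]][[e]]))
    }
  }
  tick("dij")

  # -- stage: expected + observed parasitism
  nets_t1 <- lapply(test_sites, function(s)
    build_site_network(records, data$host_samples, s, "t_plus_1"))
  names(nets_t1) <- test_sites
  observed_par <- do.call(rbind, lapply(nets_t1, observed_parasitism))

  pool_for_E <- if ("combined" %in% pools) "combined" else pools[1]
  alpha_sources <- if (config$alpha_source == "auto") engines
                   else config$alpha_source
  expected_par <- list()
  for (src in alpha_sources) {
    per_site <- lapply(test_sites, function(s) {
      ab <- site_abundance_series(data$host_samples, s)
      attacks <- if (src == "observed") {
        attack_rates_from_predictions(source = "observed",
                                      site_network = nets_t[[s]])
      } else if (src == "rf") {
        attack_rates_from_predictions(predictions[[pool_for_E]]$rf[[s]],
                                      source = "rf", abundances = ab)
      } else {
        attack_rates_from_predictions(predictions[[pool_for_E]]$knn[[s]],
                                      source = "knn")
      }
      d_use <- if (src == "observed") {
        potential_apparent_competition(meta_combined)
      } else d_by_engine[[src]]
      suppressWarnings(expected_parasitism(d_use, attacks, ab))
    })
    expected_par[[src]] <- do.call(rbind, per_site)
  }
  tick("indirect")

  # -- stage: validation fits
  crit <- config$evaluation$criterion %||% "AIC"
  direct_fits <- list()
  for (p in pools)
    for (e in engines)
      direct_fits[[paste(e, p, sep = "_")]] <-
        validate_direct(predictions[[p]][[e]], nets_t, criterion = crit)
  indirect_fits <- lapply(expected_par, function(ep)
    validate_indirect(ep, observed_par, criterion = crit))
  tick("evaluate")

  results <- list(config = config,
                  pools = pools, engines = engines,
                  excluded_sites = excluded_sites,
                  test_sites = test_sites,
                  metas = metas,
                  models = models, tuning = tuning,
                  predictions = predictions,
                  d = d_by_engine,
                  expected_parasitism = expected_par,
                  observed_parasitism = observed_par,
                  direct_fits = direct_fits,
                  indirect_fits = indirect_fits)
  report <- build_report(results, alpha = config$evaluation$alpha %||% 0.05)
  manifest <- list(config = config,
                   seed = config$seed,
                   input_hash = hash_object(list(records = records,
                                                 traits = traits,
                                                 host_samples = data$host_samples)),
                   prediction_hash = hash_object(predictions),
                   report_hash = hash_object(report),
                   timing_secs = timing,
                   outputs = character(0))
  out <- list(results = results, report = report, manifest = manifest,
              data = data)
  if (!is.null(config$out_dir)) {
    files <- write_report(out, config$out_dir)
    manifest$outputs <- vapply(files, function(f) unname(tools::md5sum(f)),
                               character(1))
    names(manifest$outputs) <- basename(unlist(files))
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  out
}

#' Train on the pooled training meta-network and predict the test sites
#'
#' Convenience wrapper for the direct-effect workflow: pools the training
#' records, trains the chosen engine, and predicts every test site with at
#' least one parasitoid at time t.
#'
#' @param comm a community from [simulate_community()] or [load_study_bundle].
#' @param engine "rf" or "knn".
#' @param hp engine hyperparameters (defaults per engine).
#' @param pool training pool: "native", "plantation" or "combined".
#' @return list with `predictions` (per site), `networks_t` (observed
#'   `site_network`s at t), and the trained `model`.
#' @export
direct_test_predictions <- function(comm, engine = c("rf", "knn"), hp = NULL,
                                    pool = "combined") {
  engine <- match.arg(engine)
  records <- comm$records
  train_rec <- records[records$time_step == "training", , drop = FALSE]
  if (nrow(train_rec) == 0) stop("no training interaction records")
  test_sites <- comm$site_info$site_id[comm$site_info$role == "test"]
  nets_t <- lapply(test_sites, function(s)
    build_site_network(records, comm$host_samples, s, "t"))
  names(nets_t) <- test_sites
  keep <- vapply(nets_t, function(n) ncol(n$count_matrix) > 0, logical(1))
  nets_t <- nets_t[keep]
  if (length(nets_t) == 0) stop("no test sites with parasitoids at time t")
  species <- lapply(nets_t, function(n)
    list(hosts = names(n$host_sample)[n$host_sample > 0],
         parasitoids = colnames(n$count_matrix)))
  if (engine == "rf") {
    hp <- hp %||% rf_hyperparams(seed = comm$config$seed %||% 1L)
    meta_b <- pool_meta_network(train_rec, pool, "binary")
    feats <- build_pair_features(rownames(meta_b$matrix), colnames(meta_b$matrix),
                                 comm$traits, comm$host_coords, comm$para_coords,
                                 labels = meta_b)
    mod <- train_rf(feats, hp)
    preds <- lapply(names(nets_t), function(s)
      predict_probabilities(mod, species[[s]]$hosts, species[[s]]$parasitoids,
                            comm$traits, comm$host_coords, comm$para_coords,
                            site_id = s))
  } else {
    hp <- hp %||% knn_hyperparams(seed = comm$config$seed %||% 1L)
    meta_w <- pool_meta_network(train_rec, pool, "weighted")
    para_sim <- gower_similarity(comm$traits, "parasitoid", hp$trait_mask,
                                 coords = comm$para_coords)
    host_sim <- gower_similarity(comm$traits, "host",
                                 c("body_size", "status", "phenology", "nd", "phylo"),
                                 coords = comm$host_coords)
    all_hosts <- unique(unlist(lapply(species, `[[`, "hosts")))
    meta_aug <- add_new_hosts(meta_w, setdiff(all_hosts, rownames(meta_w$matrix)),
                              host_sim, hp)
    mod <- list(hp = hp, meta = meta_aug, para_sim = para_sim)
    preds <- lapply(names(nets_t), function(s)
      predict_site_frequencies(meta_aug, para_sim, hp, species[[s]]$hosts,
                               species[[s]]$parasitoids, site_id = s))
  }
  names(preds) <- names(nets_t)
  list(predictions = preds, networks_t = nets_t, model = mod)
}

#' Expected and observed parasitism across the test sites
#'
#' The indirect-effect workflow: d_ij from the combined training
#' meta-network (or a supplied `apparent_competition` object), attack rates
#' per site from the chosen source, Eq-style expected parasitism per host,
#' and observed parasitism at t+1.
#'
#' @param comm a community from [simulate_community()] or [load_study_bundle].
#' @param source attack-rate source: "observed" (the data-based approach),
#'   "rf" or "knn".
#' @param predictions per-site prediction matrices (required for rf/knn).
#' @param d optionally override the `apparent_competition` matrix.
#' @return list with `expected` and `observed` record tables.
#' @export
expected_observed_parasitism <- function(comm,
                                         source = c("observed", "rf", "knn"),
                                         predictions = NULL, d = NULL) {
  source <- match.arg(source)
  records <- comm$records
  train_rec <- records[records$time_step == "training", , drop = FALSE]
  if (is.null(d))
    d <- potential_apparent_competition(
      pool_meta_network(train_rec, "combined", "weighted"))
  test_sites <- comm$site_info$site_id[comm$site_info$role == "test"]
  ep <- list(); op <- list()
  for (s in test_sites) {
    nt <- build_site_network(records, comm$host_samples, s, "t")
    if (ncol(nt$count_matrix) == 0) next  # no parasitoids emerged at t
    ab <- site_abundance_series(comm$host_samples, s)
    attacks <- switch(source,
      observed = attack_rates_from_predictions(source = "observed",
                                               site_network = nt),
      rf = attack_rates_from_predictions(predictions[[s]], source = "rf",
                                         abundances = ab),
      knn = attack_rates_from_predictions(predictions[[s]], source = "knn"))
    ep[[s]] <- suppressWarnings(expected_parasitism(d, attacks, ab))
    op[[s]] <- observed_parasitism(
      build_site_network(records, comm$host_samples, s, "t_plus_1"))
  }
  if (length(ep) == 0) stop("no test sites with parasitoids at time t")
  list(expected = do.call(rbind, ep), observed = do.call(rbind, op))
}

fit_summary <- function(fit, focal_term) {
  co <- fit$coefficients
  focal <- co[co$term == focal_term, , drop = FALSE]
  list(n = fit$n, aic = fit$aic, aicc = fit$aicc,
       converged = fit$converged,
       focal_term = focal_term,
       estimate = if (nrow(focal)) focal$estimate else NA_real_,
       z = if (nrow(focal)) focal$z else NA_real_,
       p = if (nrow(focal)) focal$p else NA_real_)
}

build_report <- function(results, alpha = 0.05) {
  direct <- lapply(results$direct_fits, function(v) {
    s <- fit_summary(v$fit, "predicted_s")
    s$retained <- "predicted_s" %in% v$selection$best_terms
    s$delta_aic_null <- {
      null_idx <- which(lengths(v$selection$subsets) == 0)
      v$selection$ics[null_idx] - min(v$selection$ics)
    }
    s$inclusion <- as.list(v$selection$inclusion)
    s$dispersion_ratio <- v$dispersion$ratio
    s$r2 <- if (is.null(v$r2)) "undefined" else v$r2
    s
  })
  n_tests <- length(direct)
  k_sig <- sum(vapply(direct, function(s)
    isTRUE(s$p < alpha) && isTRUE(s$estimate > 0), logical(1)))
  bern <- if (n_tests > 0)
    bernoulli_multiple_tests(n_tests, k_sig, alpha) else NA_real_
  indirect <- lapply(results$indirect_fits, function(v) {
    s <- fit_summary(v$fit, "E_s")
    s$retained <- "E_s" %in% v$selection$best_terms
    s$r2 <- if (is.null(v$r2)) "undefined" else v$r2
    s$dispersion_ratio <- v$dispersion$ratio
    s$n_outliers <- length(v$leverage$flagged)
    s$slope_without_outliers <- if (is.null(v$fit_no_outliers)) NA_real_ else
      fit_summary(v$fit_no_outliers, "E_s")$estimate
    s
  })
  eligible <- lapply(results$expected_parasitism, function(ep) {
    list(eligible_records = sum(ep$eligible),
         total_records = nrow(ep),
         eligible_species = length(unique(ep$host_id[ep$eligible])))
  })
  list(direct = direct,
       bernoulli = list(n_tests = n_tests, k_significant = k_sig,
                        alpha = alpha, tail_probability = bern),
       indirect = indirect,
       eligibility = eligible,
       excluded_sites = results$excluded_sites,
       n_test_sites = length(results$test_sites))
}

#' Write the consolidated report (JSON + text)
#'
#' Deterministic given the results: regenerating from the same results gives
#' byte-identical files.
#'
#' @param run output of [run_pipeline()] (or a list with `report`).
#' @param dir output directory.
#' @return character vector of the files written.
#' @export
write_report <- function(run, dir) {
  report <- run$report %||% run
  if (is.null(report) || length(report) == 0) stop("empty results: nothing to report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("== direct-effect validation ==")
  for (nm in names(report$direct)) {
    s <- report$direct[[nm]]
    r2m <- if (identical(s$r2, "undefined")) "undefined" else sprintf("%.3f", s$r2$marginal)
    r2c <- if (identical(s$r2, "undefined")) "undefined" else sprintf("%.3f", s$r2$conditional)
    w("%s: slope=%.4f z=%.2f p=%.3g retained=%s dAIC(null)=%.2f disp=%.2f R2m=%s R2c=%s n=%d",
      nm, s$estimate, s$z, s$p, s$retained, s$delta_aic_null,
      s$dispersion_ratio, r2m, r2c, s$n)
  }
  w("Bernoulli: P(>= %d of %d tests significant at %.2f) = %.3g",
    report$bernoulli$k_significant, report$bernoulli$n_tests,
    report$bernoulli$alpha, report$bernoulli$tail_probability)
  w("")
  w("== indirect-effect validation ==")
  for (nm in names(report$indirect)) {
    s <- report$indirect[[nm]]
    r2m <- if (identical(s$r2, "undefined")) "undefined" else sprintf("%.3f", s$r2$marginal)
    w("%s: slope=%.4f z=%.2f p=%.3g retained=%s R2m=%s outliers=%d n=%d",
      nm, s$estimate, s$z, s$p, s$retained, r2m, s$n_outliers, s$n)
  }
  for (nm in names(report$eligibility)) {
    e <- report$eligibility[[nm]]
    w("%s eligibility: %d of %d site x host records eligible (%d host species)",
      nm, e$eligible_records, e$total_records, e$eligible_species)
  }
  w("")
  w("test sites used: %d; excluded (no parasitoids at t): %s",
    report$n_test_sites,
    if (length(report$excluded_sites)) paste(report$excluded_sites, collapse = ", ")
    else "none")
  c(json_path, txt_path)
}
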