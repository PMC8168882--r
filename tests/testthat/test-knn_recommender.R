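test_that("Gower similarity matches hand computation and metric properties", {
  ids <- c("H:a", "H:b")
  tr <- make_traits(ids, "host", seed = 1,
                    body_size = c(2, 7), status = c("native", "native"))
  s <- gower_similarity(tr, "host", mask = c("body_size", "status"),
                        ranges = list(body_size = c(0, 10)))
  expect_equal(unname(s["H:a", "H:b"]), 0.75)  # (0.5 + 0)/2 dissimilarity

  ids3 <- c("P:a", "P:b", "P:c")
  ph <- matrix(rep(c(1, 2, 1, 0, 0, 0, 0), 3), 3, 7, byrow = TRUE)
  tr3 <- make_traits(ids3, "parasitoid", seed = 2,
                     body_size = c(1, 1, 4), nd = c(0.2, 0.2, 0.9),
                     pheno = ph)
  s3 <- gower_similarity(tr3, "parasitoid", mask = c("body_size", "phenology", "nd"))
  expect_equal(unname(s3["P:a", "P:b"]), 1.0)  # identical trait rows
  expect_equal(s3, t(s3))
  expect_true(all(diag(s3) == 1))
  expect_true(all(s3 >= 0 & s3 <= 1))

  tr_flat <- make_traits(ids3, "parasitoid", seed = 3, body_size = c(2, 2, 2))
  expect_warning(gower_similarity(tr_flat, "parasitoid",
                                  mask = c("body_size", "nd")),
                 "zero-range")
  expect_error(suppressWarnings(
    gower_similarity(tr_flat, "parasitoid", mask = "body_size")),
    "no usable traits")
})

test_that("knn predictions copy twins, average neighbours, and exclude self", {
  m <- matrix(c(4, 0,
                0, 8,
                2, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("H:h1", "H:h2", "H:h3"), c("P:n1", "P:n2")))
  meta <- meta_network(m)
  sim <- matrix(c(1.0, 0.3, 0.9, 0.8,
                  0.3, 1.0, 0.2, 0.1,
                  0.9, 0.2, 1.0, 0.5,
                  0.8, 0.1, 0.5, 1.0), 4, 4, byrow = TRUE,
                dimnames = list(c("P:n1", "P:n2", "P:f", "P:g"),
                                c("P:n1", "P:n2", "P:f", "P:g")))
  # twin copy: f's nearest neighbour is n1
  hp1 <- knn_hyperparams(k = 1, seed = 3)
  expect_equal(knn_predict(meta, sim, hp1, "P:f"),
               stats::setNames(m[, "P:n1"], rownames(m)))
  # uniform mean of neighbour frequencies 4 and 0 is 2
  hp2 <- knn_hyperparams(k = 2, weighting = "uniform", seed = 3)
  expect_equal(unname(knn_predict(meta, sim, hp2, "P:f")["H:h1"]), 2)
  # self-exclusion: n1 predicts from n2, not from its own row
  expect_equal(knn_predict(meta, sim, hp1, "P:n1"),
               stats::setNames(m[, "P:n2"], rownames(m)))
  expect_equal(knn_predict(meta, sim, hp1, "P:n1", exclude_self = FALSE),
               stats::setNames(m[, "P:n1"], rownames(m)))
  # clamped k warns; empty neighbour pool errors
  expect_warning(knn_predict(meta, sim, knn_hyperparams(k = 5, seed = 1), "P:f"),
                 "clamped")
  expect_error(knn_predict(meta, sim, hp1, "P:f",
                           exclude = c("P:n1", "P:n2")), "no eligible")
})

test_that("twin recovery holds exactly for every training parasitoid and seed", {
  meta <- rand_meta(11, n_h = 8, n_p = 5)
  paras <- colnames(meta$matrix)
  tr <- make_traits(paras, "parasitoid", seed = 12)
  for (p in paras) {
    twin <- tr[tr$species_id == p, ]
    twin$species_id <- "P:twin"
    sim <- gower_similarity(rbind(tr, twin), "parasitoid",
                            mask = c("body_size", "phenology", "nd"))
    for (seed in 1:3) {
      pred <- knn_predict(meta, sim, knn_hyperparams(k = 1, seed = seed), "P:twin")
      expect_equal(pred, stats::setNames(meta$matrix[, p], rownames(meta$matrix)))
    }
  }
})

test_that("knn predictions are convex combinations of neighbour rows", {
  for (seed in 1:10) {
    meta <- rand_meta(seed, n_h = 7, n_p = 6)
    set.seed(seed + 100)
    paras <- colnames(meta$matrix)
    sim <- matrix(stats::runif(36), 6, 6, dimnames = list(paras, paras))
    sim <- (sim + t(sim)) / 2; diag(sim) <- 1
    k <- sample(1:4, 1)
    w <- sample(c("uniform", "similarity"), 1)
    hp <- knn_hyperparams(k = k, weighting = w, seed = seed)
    pred <- knn_predict(meta, sim, hp, paras[1])
    rng <- apply(meta$matrix[, setdiff(paras, paras[1]), drop = FALSE], 1, range)
    expect_true(all(pred >= rng[1, ] - 1e-12))
    expect_true(all(pred <= rng[2, ] + 1e-12))
  }
})

test_that("an exhaustive neighbour search reproduces knn_predict exactly", {
  for (seed in 1:10) {
    meta <- rand_meta(seed + 30, n_h = 5, n_p = 6)
    paras <- colnames(meta$matrix)
    set.seed(seed)
    sim <- matrix(stats::runif(36), 6, 6, dimnames = list(paras, paras))
    sim <- (sim + t(sim)) / 2; diag(sim) <- 1   # distinct off-diagonal sims
    k <- sample(1:4, 1)
    w <- sample(c("uniform", "similarity"), 1)
    hp <- knn_hyperparams(k = k, weighting = w, seed = seed)
    focal <- paras[1]
    got <- knn_predict(meta, sim, hp, focal)
    # brute force: sort candidates by similarity, weighted mean of top k
    cand <- setdiff(paras, focal)
    s <- sim[focal, cand]
    nb <- cand[order(s, decreasing = TRUE)][seq_len(k)]
    wts <- if (w == "uniform") rep(1, k) else s[nb]
    wts <- wts / sum(wts)
    want <- drop(meta$matrix[, nb, drop = FALSE] %*% wts)
    expect_equal(got, want)
  }
})

test_that("cold-start host insertion copies twins and preserves training rows", {
  m <- matrix(c(2, 0,
                0, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("H:h1", "H:h2"), c("P:p1", "P:p2")))
  meta <- meta_network(m)
  hs <- matrix(c(1, 0.2, 0.9, 0.8,
                 0.2, 1, 0.3, 0.4,
                 0.9, 0.3, 1, 0.5,
                 0.8, 0.4, 0.5, 1), 4, 4, byrow = TRUE,
               dimnames = list(c("H:h1", "H:h2", "H:new1", "H:new2"),
                               c("H:h1", "H:h2", "H:new1", "H:new2")))
  aug1 <- add_new_hosts(meta, "H:new1", hs, knn_hyperparams(k = 1, seed = 1))
  expect_equal(unname(aug1$matrix["H:new1", ]), unname(m["H:h1", ]))

  aug2 <- add_new_hosts(meta, c("H:new1", "H:new2"), hs,
                        knn_hyperparams(k = 2, weighting = "uniform", seed = 1))
  expect_equal(nrow(aug2$matrix), 4)
  expect_identical(aug2$matrix[rownames(m), ], m)       # non-interference
  expect_equal(unname(aug2$matrix["H:new1", ]), c(1, 2))  # mean of (2,0) and (0,4)
  expect_error(add_new_hosts(meta, "H:h1", hs, knn_hyperparams(k = 1)),
               "already")
})

test_that("site frequency matrices propagate zeros and imputed rows", {
  m <- matrix(0, 2, 3, dimnames = list(c("H:h1", "H:h2"),
                                       c("P:p1", "P:p2", "P:p3")))
  meta <- meta_network(m)
  paras <- colnames(m)
  sim <- matrix(0.5, 3, 3, dimnames = list(paras, paras)); diag(sim) <- 1
  fm <- predict_site_frequencies(meta, sim, knn_hyperparams(k = 2, seed = 1),
                                 rownames(m), paras, site_id = "s")
  expect_true(all(fm == 0))
  expect_equal(dim(fm), c(2, 3))
  expect_error(predict_site_frequencies(meta, sim, knn_hyperparams(k = 1),
                                        c("H:h1", "H:missing"), paras),
               "H:missing", fixed = TRUE)
})

test_that("knn tuning prefers the trait that generates host use", {
  paras <- paste0("P:p", 1:8)
  hostids <- paste0("H:h", 1:10)
  set.seed(42)
  bs_p <- stats::runif(8, 1, 5)
  bs_h <- stats::runif(10, 1, 5)
  m <- round(20 * exp(-outer(bs_h, bs_p, "-")^2))
  dimnames(m) <- list(hostids, paras)
  meta <- meta_network(m)
  tr <- make_traits(paras, "parasitoid", seed = 43, body_size = bs_p)

  grid1 <- list(knn_hyperparams(k = 2, trait_mask = "body_size", seed = 1))
  expect_identical(tune_knn(meta, tr, grid1, folds = 4, seed = 2)$best,
                   grid1[[1]])

  grid <- list(knn_hyperparams(k = 2, trait_mask = "nd", seed = 1),
               knn_hyperparams(k = 2, trait_mask = "body_size", seed = 1))
  tk <- tune_knn(meta, tr, grid, folds = 4, seed = 2)
  expect_lt(tk$errors[2], tk$errors[1])
  expect_identical(tk$best$trait_mask, "body_size")

  expect_error(tune_knn(meta, tr, grid, folds = 20), "more folds")
  expect_error(tune_knn(meta, tr, list(), folds = 4), "empty")
})
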