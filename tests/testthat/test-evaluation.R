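test_that("scale_center standardises to mean zero, sd one", {
  expect_equal(scale_center(c(1, 2, 3)), c(-1, 0, 1))
  x <- scale_center(stats::rnorm(50, 5, 3))
  expect_equal(scale_center(x), x, tolerance = 1e-12)
  expect_error(scale_center(c(5, 5, 5)), "constant")
  expect_error(scale_center(3), "two values")
})

test_that("GLM fits recover known Poisson and binomial structure", {
  # intercept-only Poisson: MLE intercept is log of the mean
  set.seed(1)
  y <- stats::rpois(300, 7)
  f0 <- fit_glm(y ~ 1, data.frame(y = y), "poisson")
  expect_equal(f0$coefficients$estimate[1], log(mean(y)), tolerance = 1e-8)

  # slope recovery on a scaled predictor
  set.seed(2)
  x <- scale_center(stats::rnorm(500))
  y <- stats::rpois(500, exp(0.5 + 0.5 * x))
  f1 <- fit_glm(y ~ x, data.frame(y = y, x = x), "poisson")
  expect_lt(abs(slope_of(f1, "x")$estimate - 0.5), 0.15)
  expect_true(f1$converged)
  expect_gte(f1$aicc, f1$aic)

  # aggregated events-of-trials equals row-expanded 0/1 likelihood
  set.seed(3)
  agg <- data.frame(x = stats::rnorm(40), trials = stats::rpois(40, 12) + 3)
  agg$events <- stats::rbinom(40, agg$trials, stats::plogis(-0.4 + 0.8 * agg$x))
  fa <- fit_glm(cbind(events, trials - events) ~ x, agg, "binomial")
  long <- data.frame(
    x = rep(agg$x, agg$trials),
    y = unlist(mapply(function(e, t) c(rep(1, e), rep(0, t - e)),
                      agg$events, agg$trials, SIMPLIFY = FALSE)))
  fl <- fit_glm(y ~ x, long, "binomial")
  expect_equal(fa$coefficients$estimate, fl$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("random-intercept fits report grouping structure", {
  set.seed(4)
  g <- factor(rep(1:12, each = 25))
  u <- stats::rnorm(12, 0, 0.6)[g]
  x <- scale_center(stats::rnorm(300))
  y <- stats::rpois(300, exp(0.3 + 0.4 * x + u))
  fm <- fit_glm(y ~ x, data.frame(y = y, x = x, g = g), "poisson", groups = "g")
  expect_s4_class(fm$model, "glmerMod")
  expect_lt(abs(slope_of(fm, "x")$estimate - 0.4), 0.15)
  r2 <- nakagawa_r2(fm)
  expect_gte(r2$conditional, r2$marginal)
  expect_true(r2$marginal >= 0 && r2$conditional <= 1)
})

test_that("all-subsets selection respects marginality and finds the truth", {
  set.seed(5)
  n <- 500
  d <- data.frame(x = scale_center(stats::rnorm(n)),
                  z = scale_center(stats::rnorm(n)))
  d$y <- stats::rpois(n, exp(0.2 + 0.6 * d$x))
  full <- fit_glm(y ~ x * z, d, "poisson")
  sel <- all_subsets_selection(full)
  # no enumerated subset contains x:z without both main effects
  ix <- which(sel$terms == "x:z")
  for (s in sel$subsets)
    if (ix %in% s) expect_true(all(match(c("x", "z"), sel$terms) %in% s))
  expect_true("x" %in% sel$best_terms)          # strong true slope retained
  expect_false("x:z" %in% sel$best_terms)

  # a pure-noise predictor leads to the null model
  d2 <- data.frame(x = scale_center(stats::rnorm(n)))
  d2$y <- stats::rpois(n, exp(0.3))
  sel2 <- all_subsets_selection(fit_glm(y ~ x, d2, "poisson"))
  expect_length(sel2$best_terms, 0)
  expect_named(sel2$inclusion, "x")
})

test_that("overdispersion ratio separates equi- from overdispersed counts", {
  set.seed(6)
  x <- scale_center(stats::rnorm(2000))
  y <- stats::rpois(2000, exp(1 + 0.3 * x))
  f <- fit_glm(y ~ x, data.frame(y = y, x = x), "poisson")
  chk <- overdispersion_check(f)
  expect_gt(chk$ratio, 0.8); expect_lt(chk$ratio, 1.2)
  expect_false(chk$flag)

  y2 <- MASS::rnegbin(2000, exp(1 + 0.3 * x), theta = 0.8)
  f2 <- fit_glm(y2 ~ x, data.frame(y2 = y2, x = x), "poisson")
  chk2 <- overdispersion_check(f2)
  expect_gt(chk2$ratio, 2)
  expect_true(chk2$flag)
  f3 <- refit_with_olre(f2)
  expect_true(f3$olre)
  expect_s4_class(f3$model, "glmerMod")

  sat <- fit_glm(y ~ g, data.frame(y = stats::rpois(4, 5), g = factor(1:4)),
                 "poisson")
  expect_error(overdispersion_check(sat), "degrees of freedom")
})

test_that("variance-decomposition R2 matches classical R2 for Gaussian GLMs", {
  set.seed(7)
  x <- stats::rnorm(200)
  y <- 1 + 0.8 * x + stats::rnorm(200)
  f <- fit_glm(y ~ x, data.frame(y = y, x = x), "gaussian")
  r2 <- nakagawa_r2(f)
  classical <- summary(stats::lm(y ~ x))$r.squared
  expect_equal(r2$marginal, classical, tolerance = 1e-6)
  expect_equal(r2$marginal, r2$conditional)    # no grouping variance

  f0 <- fit_glm(y ~ 1, data.frame(y = stats::rpois(100, 4)), "poisson")
  expect_equal(nakagawa_r2(f0)$marginal, 0)
})

test_that("the Bernoulli tail equals exhaustive enumeration over outcomes", {
  for (n in 1:10) {
    for (alpha in c(0.01, 0.05, 0.2)) {
      outcomes <- expand.grid(rep(list(c(TRUE, FALSE)), n))
      k_each <- rowSums(outcomes)
      p_each <- alpha^k_each * (1 - alpha)^(n - k_each)
      for (k in 0:n) {
        brute <- sum(p_each[k_each >= k])
        expect_equal(bernoulli_multiple_tests(n, k, alpha), brute,
                     tolerance = 1e-12)
      }
    }
  }
  expect_lt(abs(bernoulli_multiple_tests(6, 3, 0.05) - 0.0022299), 1e-6)
  expect_equal(bernoulli_multiple_tests(2, 2, 0.05), 0.0025, tolerance = 1e-12)
  expect_equal(bernoulli_multiple_tests(6, 0, 0.05), 1)
  expect_error(bernoulli_multiple_tests(6, 7, 0.05), "0 <= k <= N")
  expect_error(bernoulli_multiple_tests(6, 3, 1.5), "alpha")
})

test_that("leverage screening flags high-influence points", {
  x <- c(0, 1, 2, 3, 100)
  set.seed(8)
  y <- stats::rpois(5, 3)
  f <- fit_glm(y ~ x, data.frame(y = y, x = x), "poisson")
  lev <- leverage_outliers(f)
  expect_equal(sum(lev$hat), lev$n_params, tolerance = 1e-8)
  expect_equal(unname(which.max(lev$hat)), 5)
  expect_true(5 %in% lev$flagged)

  # balanced one-factor design: uniform leverage, nothing flagged
  d <- data.frame(y = stats::rpois(20, 6), g = factor(rep(1:2, each = 10)))
  fb <- fit_glm(y ~ g, d, "poisson")
  levb <- leverage_outliers(fb)
  expect_length(levb$flagged, 0)
  expect_equal(sum(levb$hat), levb$n_params, tolerance = 1e-8)

  # rank deficiency is an error, and mixed fits are rejected
  d2 <- data.frame(y = stats::rpois(20, 4), x1 = stats::rnorm(20))
  d2$x2 <- d2$x1
  expect_error(leverage_outliers(fit_glm(y ~ x1 + x2, d2, "poisson")),
               "rank")
  dm <- data.frame(y = stats::rpois(40, 4), g = factor(rep(1:4, 10)))
  fmix <- fit_glm(y ~ 1, dm, "poisson", groups = "g")
  expect_error(leverage_outliers(fmix), "fixed-effects")
})

test_that("validate_direct builds the pair table and detects self-consistency", {
  comm <- small_comm()
  dtp <- direct_test_predictions(comm, "rf")
  nets <- dtp$networks_t
  # predictions equal to observations give a positive significant slope
  perfect <- lapply(names(nets), function(s) {
    n <- nets[[s]]
    hosts <- names(n$host_sample)[n$host_sample > 0]
    m <- n$count_matrix[hosts, , drop = FALSE]
    attr(m, "site_id") <- s
    m
  })
  names(perfect) <- names(nets)
  v <- suppressWarnings(validate_direct(perfect, nets))
  expect_equal(nrow(v$table),
               sum(vapply(perfect, function(m) nrow(m) * ncol(m), numeric(1))))
  sl <- slope_of(v$fit, "predicted_s")
  expect_gt(sl$estimate, 0)
  expect_lt(sl$p, 0.05)
  expect_true("predicted_s" %in% v$selection$best_terms)

  # a permuted predictor is dropped by selection
  permuted <- perfect
  set.seed(9)
  for (s in names(permuted)) {
    m <- permuted[[s]]
    m[] <- sample(as.numeric(m))
    permuted[[s]] <- m
  }
  v0 <- suppressWarnings(validate_direct(permuted, nets))
  expect_false("predicted_s" %in% v0$selection$best_terms)
})

test_that("validate_indirect joins eligible records only and screens leverage", {
  expected <- data.frame(site_id = rep(c("s1", "s2"), each = 3),
                         host_id = rep(c("H:a", "H:b", "H:c"), 2),
                         E = c(0.2, 0.5, NA, 0.1, 0.4, NA),
                         eligible = rep(c(TRUE, TRUE, FALSE), 2),
                         exclusion_reason = NA_character_,
                         stringsAsFactors = FALSE)
  observed <- data.frame(site_id = rep(c("s1", "s2"), each = 3),
                         host_id = rep(c("H:a", "H:b", "H:c"), 2),
                         events = c(1, 5, 2, 0, 4, 1),
                         sampled = c(10, 12, 8, 9, 11, 7),
                         rate = NA, stringsAsFactors = FALSE)
  v <- suppressWarnings(validate_indirect(expected, observed))
  expect_equal(nrow(v$table), 4)            # ineligible hosts never join
  expect_s3_class(v$leverage, "leverage_report")
  expect_true(all(c("fit", "selection", "dispersion", "r2") %in% names(v)))
  expect_error(validate_indirect(expected[expected$eligible == FALSE, ],
                                 observed), "no eligible")
})
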