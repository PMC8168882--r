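test_that("d_ij reproduces the hand-worked quantitative web", {
  m <- matrix(0, 3, 2, dimnames = list(c("H:h1", "H:h2", "H:h3"),
                                       c("P:pA", "P:pB")))
  m["H:h1", "P:pA"] <- 2; m["H:h2", "P:pA"] <- 2
  m["H:h2", "P:pB"] <- 1; m["H:h3", "P:pB"] <- 3
  d <- potential_apparent_competition(meta_network(m))
  expect_equal(unname(d$d["H:h2", "H:h1"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(d$d["H:h2", "H:h2"]), 5 / 12, tolerance = 1e-12)
  expect_equal(unname(d$d["H:h2", "H:h3"]), 1 / 4, tolerance = 1e-12)
  expect_equal(unname(rowSums(d$d)), rep(1, 3), tolerance = 1e-12)

  one <- potential_apparent_competition(
    meta_network(matrix(7, 1, 1, dimnames = list("H:h1", "P:p1"))))
  expect_equal(unname(one$d[1, 1]), 1)

  # hosts sharing no parasitoid species have zero mutual potential
  m2 <- matrix(c(3, 0, 0, 5), 2, 2,
               dimnames = list(c("H:h1", "H:h2"), c("P:pA", "P:pB")))
  d2 <- potential_apparent_competition(meta_network(m2))
  expect_equal(unname(d2$d["H:h1", "H:h2"]), 0)
  expect_equal(unname(d2$d["H:h2", "H:h1"]), 0)
})

test_that("valid d rows sum to one and d is scale-free", {
  for (seed in 1:100) {
    meta <- rand_meta(seed, n_h = sample(3:8, 1), n_p = sample(2:6, 1))
    d <- potential_apparent_competition(meta)
    rs <- rowSums(d$d)
    expect_true(all(abs(rs[d$valid] - 1) < 1e-10))
    expect_true(all(rs[!d$valid] == 0))
    expect_true(all(d$d >= 0 & d$d <= 1 + 1e-12))
  }
  meta <- rand_meta(7)
  scaled <- meta_network(meta$matrix * 13L)
  expect_equal(potential_apparent_competition(meta)$d,
               potential_apparent_competition(scaled)$d)
})

test_that("attack rates follow the source conventions", {
  pm <- matrix(c(0, 0.3), 2, 1,
               dimnames = list(c("H:h1", "H:h2"), "P:p1"))
  attr(pm, "site_id") <- "s1"
  ab <- data.frame(host_id = c("H:h1", "H:h2"), n_t = c(4, 10),
                   n_t_plus_1 = c(4, 10))
  a_rf <- attack_rates_from_predictions(pm, "rf", abundances = ab)
  expect_equal(unname(a_rf$matrix["H:h1", 1]), 0)     # zero probability propagates
  expect_equal(unname(a_rf$matrix["H:h2", 1]), 3.0)   # 0.3 x 10
  a_raw <- attack_rates_from_predictions(pm, "rf", abundances = ab,
                                         rf_convention = "p_raw")
  expect_equal(unname(a_raw$matrix["H:h2", 1]), 0.3)

  fm <- matrix(2.5, 1, 1, dimnames = list("H:h1", "P:p1"))
  expect_equal(unname(attack_rates_from_predictions(fm, "knn")$matrix[1, 1]), 2.5)

  ab_missing <- data.frame(host_id = "H:h1", n_t = 4, n_t_plus_1 = 4)
  expect_error(attack_rates_from_predictions(pm, "rf", abundances = ab_missing),
               "H:h2", fixed = TRUE)
})

test_that("expected parasitism reproduces the worked example and its limits", {
  # two hosts, one shared parasitoid, equal counts: d rows are (1/2, 1/2)
  m <- matrix(1, 2, 1, dimnames = list(c("H:h1", "H:h2"), "P:pA"))
  d <- potential_apparent_competition(meta_network(m))
  alpha <- matrix(c(4, 0), 2, 1, dimnames = list(c("H:h1", "H:h2"), "P:pA"))
  ab <- data.frame(host_id = c("H:h1", "H:h2"), n_t = c(10, 10),
                   n_t_plus_1 = c(5, 20))
  ep <- expected_parasitism(d, make_attacks(alpha), ab)
  expect_equal(ep$E[ep$host_id == "H:h1"], 1.0, tolerance = 1e-12)
  expect_false(ep$eligible[ep$host_id == "H:h2"])
  expect_equal(ep$exclusion_reason[ep$host_id == "H:h2"],
               "zero predicted attack rate at time t")

  # host absent at t+1 is filtered with the collection reason
  ab2 <- data.frame(host_id = c("H:h1", "H:h2"), n_t = c(10, 10),
                    n_t_plus_1 = c(0, 20))
  ep2 <- expected_parasitism(d, make_attacks(alpha), ab2)
  expect_false(ep2$eligible[ep2$host_id == "H:h1"])
  expect_equal(ep2$exclusion_reason[ep2$host_id == "H:h1"],
               "not collected at both time steps")
})

test_that("with constant abundances E collapses to the time-t parasitism rate", {
  for (seed in 1:100) {
    meta <- rand_meta(seed + 500, n_h = 6, n_p = 4)
    d <- potential_apparent_competition(meta)
    set.seed(seed)
    alpha <- matrix(stats::rpois(24, 2), 6, 4, dimnames = dimnames(meta$matrix))
    n <- stats::rpois(6, 20) + 1
    ab <- data.frame(host_id = rownames(meta$matrix), n_t = n, n_t_plus_1 = n)
    ep <- suppressWarnings(expected_parasitism(d, make_attacks(alpha), ab))
    el <- ep[ep$eligible, ]
    want <- rowSums(alpha)[el$host_id] / n[match(el$host_id, ab$host_id)]
    expect_equal(el$E, unname(want), tolerance = 1e-12)
  }
})

test_that("a naive triple loop reproduces the vectorised Eq evaluation", {
  for (seed in 1:20) {
    meta <- rand_meta(seed + 900, n_h = 7, n_p = 5)
    d <- potential_apparent_competition(meta)
    set.seed(seed)
    hosts <- rownames(meta$matrix)
    alpha <- matrix(stats::runif(35, 0, 4), 7, 5, dimnames = dimnames(meta$matrix))
    ab <- data.frame(host_id = hosts, n_t = stats::rpois(7, 15) + 1,
                     n_t_plus_1 = stats::rpois(7, 15) + 1)
    ep <- expected_parasitism(d, make_attacks(alpha), ab)
    for (i in seq_len(nrow(ep))) {
      if (!ep$eligible[i]) next
      h <- ep$host_id[i]
      n1 <- ab$n_t_plus_1[ab$host_id == h]
      acc <- 0
      for (j in hosts) {
        n_jt <- ab$n_t[ab$host_id == j]
        if (n_jt == 0) next
        n_jt1 <- ab$n_t_plus_1[ab$host_id == j]
        for (l in colnames(alpha))
          acc <- acc + d$d[h, j] * alpha[h, l] * (n_jt1 / n_jt)
      }
      expect_equal(ep$E[i], acc / n1, tolerance = 1e-12)
    }
  }
})

test_that("raising a donor's t+1 abundance never lowers expected parasitism", {
  meta <- rand_meta(77, n_h = 5, n_p = 4)
  d <- potential_apparent_competition(meta)
  set.seed(77)
  alpha <- matrix(stats::runif(20, 0, 3), 5, 4, dimnames = dimnames(meta$matrix))
  hosts <- rownames(meta$matrix)
  ab <- data.frame(host_id = hosts, n_t = rep(10, 5), n_t_plus_1 = rep(10, 5))
  base <- expected_parasitism(d, make_attacks(alpha), ab)
  for (j in hosts[-1]) {
    ab2 <- ab
    ab2$n_t_plus_1[ab2$host_id == j] <- 25
    bumped <- expected_parasitism(d, make_attacks(alpha), ab2)
    i <- hosts[1]
    if (base$eligible[base$host_id == i] && d$d[i, j] > 0)
      expect_gte(bumped$E[bumped$host_id == i], base$E[base$host_id == i])
  }
})

test_that("hosts without an apparent-competition estimate are flagged, not zeroed", {
  m <- matrix(1, 1, 1, dimnames = list("H:h1", "P:pA"))
  d <- potential_apparent_competition(meta_network(m))
  alpha <- matrix(c(2, 3), 2, 1, dimnames = list(c("H:h1", "H:h9"), "P:pA"))
  ab <- data.frame(host_id = c("H:h1", "H:h9"), n_t = c(5, 5),
                   n_t_plus_1 = c(5, 5))
  ep <- expected_parasitism(d, make_attacks(alpha), ab)
  expect_true(ep$eligible[ep$host_id == "H:h1"])
  expect_false(ep$eligible[ep$host_id == "H:h9"])
  expect_equal(ep$exclusion_reason[ep$host_id == "H:h9"],
               "no apparent-competition estimate")
})

test_that("observed parasitism caps events at hosts sampled", {
  cm <- matrix(c(3, 0, 15), 3, 1,
               dimnames = list(c("H:h1", "H:h2", "H:h3"), "P:p1"))
  sn <- structure(list(site_id = "s1", time_step = "t_plus_1",
                       count_matrix = cm,
                       host_sample = c("H:h1" = 12, "H:h2" = 5, "H:h3" = 10,
                                       "H:h4" = 0)),
                  class = "site_network")
  op <- observed_parasitism(sn)
  expect_equal(op$rate[op$host_id == "H:h1"], 0.25)
  expect_equal(op$rate[op$host_id == "H:h2"], 0)
  expect_equal(op$events[op$host_id == "H:h3"], 10)  # capped at sampled
  expect_equal(op$rate[op$host_id == "H:h3"], 1)
  expect_false("H:h4" %in% op$host_id)               # not collected at t+1
})
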