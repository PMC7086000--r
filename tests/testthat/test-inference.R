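test_that("seed-excluded correlation uses only non-seed regions", {
  p <- c(9, 1, 2, 3, 4)
  m <- c(0, 1, 2, 3, 4)
  expect_equal(correlation_excluding_seeds(p, m, 1L), 1.0)
  expect_equal(correlation_excluding_seeds(p, -m, 1L), -1.0)
  # seeds given as a 0/1 vector behave identically
  expect_equal(correlation_excluding_seeds(p, m, c(1, 0, 0, 0, 0)), 1.0)
  # hand computation over the 4 retained points
  set.seed(13)
  p2 <- stats::rnorm(5)
  m2 <- stats::rnorm(5)
  expect_equal(correlation_excluding_seeds(p2, m2, 2L),
               stats::cor(p2[-2], m2[-2]))

  expect_error(correlation_excluding_seeds(p, m, c(1L, 2L, 3L)),
               "at least 3 non-seed")
  expect_true(is.na(correlation_excluding_seeds(c(1, 5, 5, 5), 1:4, 1L)))
})

test_that("screening recovers a self-generated single seed", {
  set.seed(17)
  lap <- random_lap(20)
  profiles <- all_seed_profiles(lap)
  k <- 6L
  y <- profiles[[k]]$values[, 8]          # seeded at k, observed at t = 7
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  expect_equal(dim(screen$correlation_matrix), c(20L, 20L))
  expect_equal(unname(screen$t_best[k]), 7)
  expect_gt(screen$R[k], 1 - 1e-10)
  expect_true(all(screen$R[k] >= screen$R))
  # t = 0 predictions are degenerate indicators: undefined, recorded as 0
  expect_false(any(screen$defined[, 1]))
  expect_true(all(screen$correlation_matrix[, 1] == 0))
})

test_that("screening yields an 82 x 20 correlation matrix at full scale", {
  set.seed(19)
  lap <- random_lap(82, density = 0.15)
  profiles <- all_seed_profiles(lap)
  y <- profiles[[5]]$values[, 8] + stats::rnorm(82, 0, 0.01)
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  expect_equal(dim(screen$correlation_matrix), c(82L, 20L))
  expect_true(all(abs(screen$correlation_matrix) <= 1 + 1e-12))
  expect_equal(screen$R,
               apply(screen$correlation_matrix, 1, max))
})

test_that("screening respects graph automorphisms", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 3] <- w[3, 4] <- 1
  w <- w + t(w)
  lap <- graph_laplacian(toy_connectome(w))
  profiles <- all_seed_profiles(lap)
  y <- c(0.4, 0.1, 0.1, 0.4)              # symmetric under reversal
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  expect_equal(unname(screen$R[1]), unname(screen$R[4]), tolerance = 1e-10)
  expect_equal(unname(screen$R[2]), unname(screen$R[3]), tolerance = 1e-10)

  expect_error(screen_single_seeds(profiles, atrophy_from_y(rep(1, 4))),
               "constant")
})

test_that("initial configuration applies the three filtering rules in order", {
  sc <- fake_screen(R = c(0.5, 0.4, -0.2), t_best = c(5, 0, 10))
  # rule 1 zeroes region 2 (t = 0); median of [0.5, 0, -0.2] = 0;
  # rule 2 zeroes -0.2; rule 3 binarizes
  expect_equal(unname(initial_configuration(sc)), c(1L, 0L, 0L))

  sc <- fake_screen(R = c(0.5, 0.4, 0.3), t_best = c(0, 19, 19))
  expect_equal(unname(initial_configuration(sc)), c(0L, 0L, 0L))

  sc <- fake_screen(R = c(0.5, 0.4, 0.3), t_best = c(5, 7, 9))
  expect_equal(unname(initial_configuration(sc)), c(1L, 1L, 1L))

  # the R < 0 conjunct: negative R above the median survives rule 2
  sc <- fake_screen(R = c(-0.1, -0.4, -0.5), t_best = c(5, 7, 9))
  expect_equal(unname(initial_configuration(sc)), c(0L, 0L, 0L))
})

test_that("find_tmax recovers the generating time and excludes endpoints", {
  set.seed(23)
  lap <- random_lap(20)
  true_seed <- 4L
  y <- all_seed_profiles(lap)[[true_seed]]$values[, 8]
  fit <- find_tmax(lap, true_seed, atrophy_from_y(y))
  expect_equal(fit$t_max, 7)
  expect_gt(fit$r_best, 1 - 1e-10)
  expect_false(fit$t_max %in% c(0, 19))

  # an atrophy pattern orthogonalized against every interior prediction
  lap40 <- random_lap(40)
  seed40 <- 4L
  keep <- setdiff(seq_len(40), seed40)
  P <- vapply(1:18, function(t) {
    simulate_diffusion(lap40, replace(numeric(40), seed40, 1),
                       0.25, t)$values[keep, 1]
  }, numeric(39))
  basis <- cbind(1, P)
  resid <- stats::rnorm(39)
  resid <- resid - qr.fitted(qr(basis), resid)
  y0 <- numeric(40)
  y0[keep] <- resid
  fit0 <- find_tmax(lap40, seed40, atrophy_from_y(y0))
  expect_lt(abs(fit0$r_best), 1e-6)
})

test_that("greedy search returns the true seed set on noise-free patients", {
  set.seed(29)
  for (rep in 1:3) {
    lap <- random_lap(20)
    profiles <- all_seed_profiles(lap)
    true_seed <- sample(20, 1)
    y <- profiles[[true_seed]]$values[, 8]
    screen <- screen_single_seeds(profiles, atrophy_from_y(y))
    res <- optimize_seed_combination(lap, screen, atrophy_from_y(y))
    expect_equal(res$seed_idx, true_seed)
    expect_gt(res$r_best, 1 - 1e-8)
    expect_equal(res$t_max, 7)
  }
})

test_that("two-seed noise-free patients are covered by the inferred set", {
  set.seed(31)
  lap <- random_lap(20)
  profiles <- all_seed_profiles(lap)
  pair <- c(3L, 14L)
  f0 <- replace(numeric(20), pair, 1)
  y <- simulate_diffusion(lap, f0, 0.25, 0:19)$values[, 8]
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  res <- optimize_seed_combination(lap, screen, atrophy_from_y(y))
  expect_true(all(pair %in% res$seed_idx))
  single <- find_tmax(lap, pair[1], atrophy_from_y(y))
  expect_gte(res$r_best, single$r_best)
})

test_that("the search trace is monotone and r_best re-evaluates exactly", {
  set.seed(37)
  lap <- random_lap(20)
  profiles <- all_seed_profiles(lap)
  y <- profiles[[9]]$values[, 8] + stats::rnorm(20, 0, 0.2)
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  res <- optimize_seed_combination(lap, screen, atrophy_from_y(y))
  adds <- res$search_trace[res$search_trace$action != "drop", ]
  expect_true(all(diff(adds$r) > 0))
  expect_true(all(diff(res$search_trace$r) >= 0))
  refit <- find_tmax(lap, res$seed_idx, atrophy_from_y(y))
  expect_identical(refit$r_best, res$r_best)
  expect_identical(refit$t_max, res$t_max)
})

test_that("a singleton pool reduces the search to find_tmax", {
  set.seed(41)
  lap <- random_lap(15)
  profiles <- all_seed_profiles(lap)
  y <- profiles[[2]]$values[, 6] + stats::rnorm(15, 0, 0.1)
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  res <- optimize_seed_combination(lap, screen, atrophy_from_y(y), pool = 7L)
  fit <- find_tmax(lap, 7L, atrophy_from_y(y))
  expect_equal(res$seed_idx, 7L)
  expect_equal(res$r_best, fit$r_best)
  expect_equal(res$t_max, fit$t_max)
})

test_that("greedy search matches the exhaustive-subset oracle on small pools", {
  set.seed(43)
  for (rep in 1:3) {
    lap <- random_lap(20)
    profiles <- all_seed_profiles(lap)
    true_seed <- sample(20, 1)
    y <- profiles[[true_seed]]$values[, 8]
    screen <- screen_single_seeds(profiles, atrophy_from_y(y))
    pool <- order(screen$R, decreasing = TRUE)[1:4]
    res <- optimize_seed_combination(lap, screen, atrophy_from_y(y),
                                     pool = pool)
    best <- exhaustive_best_r(lap, pool, atrophy_from_y(y))
    expect_equal(res$r_best, best, tolerance = 1e-12)
  }
})

test_that("extreme atrophy at the seed regions cannot change the fit", {
  set.seed(47)
  lap <- random_lap(20)
  profiles <- all_seed_profiles(lap)
  y <- profiles[[11]]$values[, 8] + stats::rnorm(20, 0, 0.1)
  screen <- screen_single_seeds(profiles, atrophy_from_y(y))
  res <- optimize_seed_combination(lap, screen, atrophy_from_y(y))
  y2 <- y
  y2[res$seed_idx] <- y2[res$seed_idx] + 50
  refit <- find_tmax(lap, res$seed_idx, atrophy_from_y(y2))
  expect_identical(refit$r_best, res$r_best)
  expect_identical(refit$t_max, res$t_max)
})
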