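test_that("maxmean follows its hand-computable definition", {
  mm <- maxmean(c(a = 1, b = 2, c = -1), c("a", "b", "c"))
  expect_equal(mm$S, 1)
  expect_equal(mm$s_minus, 1 / 3)
  expect_equal(mm$direction, "up")
  z0 <- maxmean(setNames(rep(0, 4), letters[1:4]), letters[1:4])
  expect_equal(z0$S, 0)
  expect_equal(z0$direction, "up")              # tie resolves to up
  expect_error(maxmean(c(a = 1), "zz"), "empty intersection")
})

test_that("maxmean negates and flips direction under sign flip", {
  set.seed(30)
  for (i in 1:200) {
    z <- setNames(rnorm(30), paste0("g", 1:30))
    members <- sample(names(z), 7)
    a <- maxmean(z, members)
    b <- maxmean(-z, members)
    if (a$s_plus != a$s_minus) {
      expect_equal(b$S, -a$S)
      expect_true(a$direction != b$direction)
    }
  }
})

test_that("Monte-Carlo restandardization matches exhaustive enumeration on a size-8 catalogue", {
  set.seed(31)
  z <- rnorm(8)
  # independent oracle: enumerate the positive-part set means of all C(8,3)
  # subsets by hand (the moments behind an up-directed statistic)
  combs <- combn(8, 3)
  s_all <- apply(combs, 2, function(ii) mean(pmax(z[ii], 0)))
  mu_oracle <- mean(s_all)
  sd_oracle <- sqrt(mean((s_all - mu_oracle)^2))   # population: all subsets
  ex <- restandardize(0.5, z, 3, mode = "exact")
  expect_equal(ex$mu_rand, mu_oracle, tolerance = 1e-12)
  expect_equal(ex$sigma_rand, sd_oracle, tolerance = 1e-12)
  R <- 1e5
  mc <- restandardize(0.5, z, 3, mode = "montecarlo", R = R, seed = 9)
  se_mu <- sd_oracle / sqrt(R)
  m4 <- mean((s_all - mu_oracle)^4)
  se_sd <- sqrt(max(m4 - sd_oracle^4, 0) / (4 * sd_oracle^2 * R))
  expect_lt(abs(mc$mu_rand - mu_oracle), 3 * se_mu)
  expect_lt(abs(mc$sigma_rand - sd_oracle), 3 * se_sd + 1e-4)
  expect_equal(ex$S_star, (0.5 - mu_oracle) / sd_oracle)
  # a down-directed statistic uses the negative-part moments, mirrored
  s_neg <- apply(combs, 2, function(ii) mean(pmax(-z[ii], 0)))
  exd <- restandardize(-0.5, z, 3, mode = "exact")
  expect_equal(exd$S_star,
               (-0.5 + mean(s_neg)) / sqrt(mean((s_neg - mean(s_neg))^2)))
})

test_that("restandardization mean approaches the positive-part normal limit", {
  set.seed(32)
  z <- rnorm(20000)
  mc <- restandardize(1, z, 200, mode = "montecarlo", R = 5000, seed = 5)
  expect_lt(abs(mc$mu_rand - 1 / sqrt(2 * pi)), 0.01)
})

test_that("a degenerate all-identical catalogue raises the sigma error", {
  expect_error(restandardize(1, rep(0.7, 50), 5, mode = "montecarlo",
                             R = 200, seed = 1),
               "degenerate catalogue")
})

test_that("the identity rotation reproduces the observed statistics", {
  set.seed(33)
  groups <- factor(three_groups(3), c("young", "old", "old_OSKM"))
  m <- matrix(rnorm(120 * 9), 120, 9,
              dimnames = list(paste0("g", 1:120), NULL))
  sets <- list(s1 = paste0("g", 1:10), s2 = paste0("g", 11:25))
  d <- 9 - 3                                     # residual df
  ident <- matrix(c(1, rep(0, d)), 1)
  res <- suppressWarnings(rotation_test(
    m, groups, c(young = -1, old = 1), sets, B = 99, R = 300, seed = 2,
    rotations = ident))
  # with S*_rot == S*_obs exactly, every p equals (1 + 1) / (1 + 1) = 1
  expect_true(all(res$p_two_sided == 1))
  expect_true(all(res$p_up == 1))
  expect_true(all(res$p_down == 1))
})

test_that("rotation p-values respect the permutation-style lower bound and determinism", {
  set.seed(34)
  groups <- factor(rep(c("young", "old"), each = 5), c("young", "old"))
  m <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(paste0("g", 1:150), NULL))
  m[1:10, 6:10] <- m[1:10, 6:10] + 3
  sets <- list(hot = paste0("g", 1:10), cold = paste0("g", 101:115))
  r1 <- suppressWarnings(rotation_test(m, groups, c(young = -1, old = 1),
                                       sets, B = 199, R = 300, seed = 7))
  r2 <- suppressWarnings(rotation_test(m, groups, c(young = -1, old = 1),
                                       sets, B = 199, R = 300, seed = 7))
  expect_identical(r1, r2)
  expect_true(all(r1$p_two_sided >= 1 / 200))
  expect_equal(r1$p_two_sided[1], 1 / 200)       # planted set at the floor
  expect_equal(r1$direction[1], "up")
  expect_error(rotation_test(m, groups, c(young = -1, old = 1), sets, B = 50,
                             seed = 1), "B must be")
  expect_error(suppressWarnings(rotation_test(m, groups, c(young = -1, old = 1),
                                              sets, B = 99)),
               "seed is required")
})

test_that("adding a constant to all scores leaves the competitive statistic nearly unchanged", {
  set.seed(35)
  z <- setNames(rnorm(400) + 0.8, paste0("g", 1:400))  # up-shifted catalogue
  members <- paste0("g", 1:12)
  shift <- 1.3
  a <- restandardize(maxmean(z, members)$S, z, 12, R = 30000, seed = 11)
  b <- restandardize(maxmean(z + shift, members)$S, z + shift, 12,
                     R = 30000, seed = 12)
  # the shift moves S and the random-set moments together; the standardized
  # statistic moves by far less than the raw one (3 MC SEs + nonlinearity of
  # the positive part near zero)
  raw_move <- abs(maxmean(z + shift, members)$S - maxmean(z, members)$S) /
    a$sigma_rand
  expect_lt(abs(a$S_star - b$S_star), 0.1 * raw_move)
})

test_that("the running enrichment score matches its exhaustive small-case oracle", {
  # perfect enrichment: members occupy the top of the ranking
  z <- setNames(c(5, 4, 3, 2, 1, 0.5), paste0("g", 1:6))
  ks <- ks_running_score(z, c("g1", "g2"))
  expect_equal(ks$statistic, 1)
  # exhaustive check at N = 6, |set| = 2: all 15 member placements
  for (pair in utils::combn(6, 2, simplify = FALSE)) {
    members <- paste0("g", pair)
    got <- ks_running_score(z, members)$statistic
    steps <- ifelse(seq_len(6) %in% pair, 1 / 2, -1 / 4)
    run <- cumsum(steps)
    expect_equal(got, run[which.max(abs(run))])
  }
  # evenly spread members stay near zero
  z12 <- setNames(12:1, paste0("g", 1:12))
  even <- ks_running_score(z12, paste0("g", c(2, 4, 6, 8, 10, 12)))
  expect_lte(abs(even$statistic), 1 / 6 + 1e-12)
  expect_error(ks_running_score(z, names(z)), "full catalogue")
})
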