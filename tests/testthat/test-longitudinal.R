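test_that("delta_change pairs rows, excludes incomplete subjects and is order-invariant", {
  d <- tibble::tibble(
    subject_id = c("s1", "s1", "s2", "s2", "s3"),
    group = c("a", "a", "a", "a", "b"),
    timepoint = c("pre", "post", "post", "pre", "pre"),
    value = c(50, 46, 60, 58, 40))
  dc <- delta_change(d)
  expect_equal(dc$delta[dc$subject_id == "s1"], -4)
  expect_equal(dc$delta[dc$subject_id == "s2"], 2)
  expect_identical(attr(dc, "incomplete"), "s3")
  # brute-force row-matching oracle over shuffled inputs
  set.seed(50)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    tbl <- tibble::tibble(
      subject_id = rep(paste0("x", 1:n), each = 2),
      timepoint = rep(c("pre", "post"), n),
      value = rnorm(2 * n, 50, 5))
    shuffled <- tbl[sample(nrow(tbl)), ]
    got <- delta_change(shuffled)
    oracle <- vapply(paste0("x", 1:n), function(s)
      tbl$value[tbl$subject_id == s & tbl$timepoint == "post"] -
        tbl$value[tbl$subject_id == s & tbl$timepoint == "pre"], numeric(1))
    expect_equal(got$delta[match(names(oracle), got$subject_id)],
                 unname(oracle))
  }
  # swapped timepoints negate delta
  sw <- d
  sw$timepoint <- ifelse(sw$timepoint == "pre", "post", "pre")
  expect_equal(delta_change(sw)$delta[1:2], -dc$delta[1:2])
  expect_error(delta_change(d[c(1, 5), ]), "both timepoints")
})

test_that("Mann-Whitney p equals exact enumeration for the extreme 4-vs-3 configuration", {
  deltas <- tibble::tibble(
    subject_id = paste0("s", 1:7),
    group = rep(c("control", "treated"), c(4, 3)),
    delta = c(4, 4, 4, 4, -4, -4, -4))
  res <- compare_groups(deltas, method = "mann_whitney")
  expect_equal(res$p_value, 2 / choose(7, 3), tolerance = 1e-12)
  # agreement with the independent exact implementation (no ties, n <= 8)
  set.seed(51)
  for (i in 1:20) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    d2 <- tibble::tibble(subject_id = paste0("s", 1:(nx + ny)),
                         group = rep(c("g1", "g2"), c(nx, ny)),
                         delta = c(x, y))
    got <- compare_groups(d2, method = "mann_whitney")
    oracle <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_value, oracle$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(oracle$statistic))
  }
})

test_that("the paired path gates on Shapiro-Wilk and handles degenerate deltas", {
  all_zero <- tibble::tibble(subject_id = paste0("s", 1:5),
                             delta = rep(0, 5))
  res <- compare_groups(all_zero, method = "auto_paired_t")
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  set.seed(52)
  gauss <- tibble::tibble(subject_id = paste0("s", 1:20),
                          delta = rnorm(20, 1))
  rg <- compare_groups(gauss, method = "auto_paired_t")
  expect_false(rg$fallback)
  expect_equal(rg$p_value, t.test(gauss$delta)$p.value)
  # grossly non-normal deltas trigger the signed-rank fallback
  skewed <- tibble::tibble(subject_id = paste0("s", 1:30),
                           delta = c(rexp(29, 1 / 10)^2, 4000))
  rs <- compare_groups(skewed, method = "auto_paired_t")
  expect_true(rs$fallback)
})

test_that("both longitudinal tests are calibrated under a Gaussian null", {
  set.seed(53)
  p_t <- replicate(800, {
    d <- tibble::tibble(subject_id = paste0("s", 1:10), delta = rnorm(10))
    compare_groups(d, method = "auto_paired_t")$p_value
  })
  expect_gt(suppressWarnings(
    ks.test(p_t, "punif"))$p.value, 0.001)
  p_mw <- replicate(800, {
    d <- tibble::tibble(subject_id = paste0("s", 1:12),
                        group = rep(c("a", "b"), each = 6),
                        delta = rnorm(12))
    compare_groups(d, method = "mann_whitney")$p_value
  })
  expect_lt(abs(mean(p_mw < 0.05) - 0.05), 0.025)
})

test_that("clock_fit reproduces the closed-form OLS line and averages CpG panels", {
  fit <- clock_fit(data.frame(age = c(10, 55, 100), value = c(20, 37.5, 55)))
  expect_equal(fit$slope, 35 / 90, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  # closed-form normal equations on noisy data
  set.seed(54)
  age <- runif(40, 10, 100)
  val <- 20 + 0.35 * age + rnorm(40, 0, 2)
  f2 <- clock_fit(data.frame(age = age, value = val))
  sxx <- sum((age - mean(age))^2)
  beta <- sum((age - mean(age)) * (val - mean(val))) / sxx
  expect_equal(f2$slope, beta, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(val) - beta * mean(age), tolerance = 1e-10)
  se_slope <- sqrt(sum(residuals(f2$lm)^2) / 38 / sxx)
  expect_lt(abs(f2$slope - 0.35), 3 * se_slope)
  # three CpGs per animal are averaged before fitting
  panel <- data.frame(animal_id = rep(1:6, each = 3),
                      age = rep(c(10, 20, 40, 60, 80, 100), each = 3),
                      cpg = rep(1:3, 6),
                      value = rep(c(20, 24, 32, 40, 48, 55), each = 3) +
                        rep(c(-1, 0, 1), 6))
  f3 <- clock_fit(panel)
  expect_equal(f3$n, 6)
  expect_equal(f3$points$value,
               as.numeric(tapply(panel$value, panel$animal_id, mean)))
  # degenerate inputs
  expect_error(clock_fit(data.frame(age = c(10, 10, 10), value = 1:3)),
               "constant")
  flat <- clock_fit(data.frame(age = c(10, 50, 90), value = c(30, 30, 30)))
  expect_equal(flat$slope, 0)
  expect_true(flat$zero_residual)
  expect_true(is.na(flat$r))
})

test_that("the mixed model matches the paired-t oracle without between-subject variance", {
  sim <- simulate_longitudinal(n_subjects = 20, delta = c(g = 1.2),
                               between_sd = 0, within_sd = 1,
                               baseline_mean = 10, seed = 1)
  tab <- sim$data
  tab$metabolite <- "m1"
  tab$specimen_id <- tab$subject_id
  res <- metabolite_mixed_model(tab, log_scale = FALSE)
  d <- delta_change(sim$data)
  tt <- t.test(d$delta)
  expect_lt(abs(abs(res$statistic) - abs(tt$statistic)) / abs(tt$statistic),
            0.1)
  expect_equal(res$estimate, mean(d$delta), tolerance = 0.15)
})

test_that("mixed-model p-values are calibrated and single measurements fall back", {
  set.seed(56)
  n_met <- 150; n_spec <- 12
  tab <- tidyr::expand_grid(metabolite = paste0("m", 1:n_met),
                            specimen_id = paste0("sp", 1:n_spec),
                            timepoint = c("pre", "post"))
  tab$value <- exp(rnorm(nrow(tab), 2, 0.4) +
                     rep(rnorm(n_met * n_spec, 0, 0.5), each = 2))
  res <- metabolite_mixed_model(tab)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.05)
  expect_gt(suppressWarnings(ks.test(res$p_value, "punif"))$p.value, 0.001)
  # one measurement per specimen: fixed-effects path, flagged
  single <- tibble::tibble(metabolite = "m",
                           specimen_id = paste0("sp", 1:10),
                           timepoint = rep(c("pre", "post"), 5),
                           value = exp(rnorm(10)))
  rs <- metabolite_mixed_model(single)
  expect_true(rs$singular_fallback)
})
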