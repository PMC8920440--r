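test_that("pattern enumeration yields the Bell-number spaces with rejuvenation first", {
  p3 <- enumerate_patterns(c("young", "old", "old_OSKM"))
  expect_equal(nrow(p3), 5)
  expect_equal(p3$label[1], "young,old_OSKM|old")
  expect_equal(p3$label[2], "young,old,old_OSKM")
  expect_equal(nrow(enumerate_patterns(c("a", "b"))), 2)
  expect_equal(nrow(enumerate_patterns(letters[1:4])), 15)
  cl <- p3$cluster[[1]]
  expect_equal(cl[["young"]], cl[["old_OSKM"]])
  expect_true(cl[["old"]] != cl[["young"]])
})

test_that("the closed-form cluster marginal equals numerical integration", {
  clm <- rejuvenomics:::cluster_log_marginal
  set.seed(40)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    x <- rnorm(n, runif(1, -3, 3), runif(1, 0.3, 2))
    sigma2 <- runif(1, 0.1, 4)
    mu0 <- runif(1, -2, 2)
    tau2 <- runif(1, 0.05, 8)
    num <- integrate(function(mu) vapply(mu, function(m)
      exp(sum(dnorm(x, m, sqrt(sigma2), log = TRUE)) +
            dnorm(m, mu0, sqrt(tau2), log = TRUE)), numeric(1)),
      mu0 - 40 * sqrt(tau2), mu0 + 40 * sqrt(tau2),
      rel.tol = 1e-12, abs.tol = 0)$value
    ana <- clm(mean(x), sum((x - mean(x))^2), n, sigma2, mu0, tau2)
    expect_equal(ana, log(num), tolerance = 1e-8)
  }
})

test_that("forcing tau2 to zero returns the prior for every feature", {
  set.seed(41)
  groups <- three_groups(4)
  m <- plant_pattern_matrix(sample(1:5, 40, replace = TRUE), groups, seed = 41)
  pri <- c(0.4, 0.1, 0.2, 0.2, 0.1)
  fit <- fit_nn_model(m, groups, tau2 = 0, mu0 = 0, pi = pri)
  post <- as.matrix(fit$posterior[, -1])
  expect_lt(max(abs(sweep(post, 2, pri))), 1e-10)
})

test_that("posteriors are proper and the EM objective is monotone", {
  set.seed(42)
  groups <- three_groups(5)
  m <- plant_pattern_matrix(sample(1:5, 150, replace = TRUE), groups,
                            effect = 3, baseline_sd = 2, seed = 42)
  for (method in c("em", "cem")) {
    fit <- fit_nn_model(m, groups, pi_method = method)
    post <- as.matrix(fit$posterior[, -1])
    expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
    if (method == "em") {
      expect_true(all(diff(fit$log_lik_trace) >=
                        -1e-8 * abs(fit$log_lik_trace[-1])))
    }
    expect_gt(fit$tau2, 0)
  }
})

test_that("restricting the space to the all-distinct pattern reduces to independent group means", {
  clm <- rejuvenomics:::cluster_log_marginal
  set.seed(43)
  groups <- three_groups(4)
  pats <- enumerate_patterns(unique(groups))
  # strongly separated group means: the full fit must agree with a fit on the
  # all-distinct pattern alone for those features (posterior ~ 1 there)
  m <- plant_pattern_matrix(rep(5, 30), groups, effect = 8, sigma = 0.5,
                            baseline_sd = 1, seed = 43)
  fit <- fit_nn_model(m, groups, pi_method = "uniform")
  expect_gt(min(fit$posterior$pattern_5), 0.95)
  # the pattern-5 marginal is the product of independent per-group marginals
  x <- m[1, ]
  per_group <- sum(vapply(unique(groups), function(g) {
    xi <- x[groups == g]
    clm(mean(xi), sum((xi - mean(xi))^2), length(xi),
        fit$sigma2[1], fit$mu0, fit$tau2)
  }, numeric(1)))
  merged <- clm(mean(x), sum((x - mean(x))^2), length(x),
                fit$sigma2[1], fit$mu0, fit$tau2)
  expect_gt(per_group, merged)   # the split model wins on separated data
})

test_that("Bayesian FDR selection follows the posterior-prefix rule and is monotone", {
  post <- tibble::tibble(feature_id = c("a", "b", "c"),
                         pattern_1 = c(0.99, 0.97, 0.60))
  sel <- select_by_bayes_fdr(post, pattern = 1, fdr = 0.05)
  expect_identical(sel$feature_id, c("a", "b"))
  expect_equal(sel$expected_fdr, c(0.01, 0.02))
  # adding the third feature would push the expected FDR to 0.44/3 > 0.05
  expect_equal(nrow(select_by_bayes_fdr(post, fdr = 0.15)), 3)
  # all-0.5 posteriors: empty selection
  flat <- tibble::tibble(feature_id = letters[1:4], pattern_1 = rep(0.5, 4))
  expect_equal(nrow(select_by_bayes_fdr(flat)), 0)
  # monotone in fdr
  set.seed(44)
  rnd <- tibble::tibble(feature_id = paste0("f", 1:50),
                        pattern_1 = runif(50))
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5), function(q)
    nrow(select_by_bayes_fdr(rnd, fdr = q)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the identity permutation reproduces the unpermuted selection count", {
  set.seed(45)
  groups <- three_groups(4)
  m <- plant_pattern_matrix(rep(c(1, 2), c(30, 30)), groups, effect = 5,
                            baseline_sd = 2, seed = 45)
  fit <- fit_nn_model(m, groups)
  n_obs <- nrow(select_by_bayes_fdr(fit, 1, 0.05))
  rc <- randomization_control(m, groups, n_permutations = 2, seed = 46)
  expect_identical(rc$observed_count, n_obs)
})

test_that("exchangeable null data give permuted counts like the observed one", {
  set.seed(47)
  groups <- three_groups(4)
  m <- matrix(rnorm(80 * 12, 0, 1), 80, 12,
              dimnames = list(paste0("f", 1:80), NULL)) + rnorm(80, 0, 2)
  rc <- randomization_control(m, groups, n_permutations = 6, seed = 48)
  expect_lte(abs(rc$observed_count - median(rc$perm_counts$n_selected)), 3)
})
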