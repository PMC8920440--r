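#' Enumerate group-mean patterns (set partitions of the groups)
#'
#' A "pattern" assigns the experimental groups to equal-mean clusters; the
#' pattern space of k groups is the set of all partitions (Bell number B_k:
#' 5 patterns for 3 groups). For the canonical young / old / old_OSKM design
#' the rejuvenation pattern - young and old_OSKM share a mean, old differs
#' ("Young != Old & Young = Old OSKM") - is placed first, as pattern 1.
#'
#' @param groups Character vector of group labels (>= 2).
#' @return A tibble: pattern_id, label (clusters separated by "|"),
#'   n_clusters, and `cluster` (list column: named integer vector mapping
#'   each group to its cluster index).
#' @examples
#' enumerate_patterns(c("young", "old", "old_OSKM"))$label
#' @export
enumerate_patterns <- function(groups) {
  k <- length(groups)
  if (k < 2) abort("need >= 2 groups.")
  # all restricted-growth strings of length k
  parts <- list(c(1L))
  for (i in 2:k) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(c) c(p, c))
    }), recursive = FALSE)
  }
  labels <- vapply(parts, function(p) {
    paste(vapply(seq_len(max(p)), function(c)
      paste(groups[p == c], collapse = ","), character(1)), collapse = "|")
  }, character(1))
  out <- tibble::tibble(
    pattern_id = seq_along(parts),
    label = labels,
    n_clusters = vapply(parts, max, integer(1)),
    cluster = lapply(parts, function(p) setNames(p, groups)))
  if (setequal(groups, c("young", "old", "old_OSKM"))) {
    rejuv <- which(vapply(out$cluster, function(p)
      p[["young"]] == p[["old_OSKM"]] && p[["young"]] != p[["old"]],
      logical(1)))
    out <- out[c(rejuv, setdiff(seq_len(nrow(out)), rejuv)), ]
    out$pattern_id <- seq_len(nrow(out))
  }
  out
}

# Hard (modal) pattern assignment for the classification-EM weight update.
# Features whose log marginal likelihoods are (nearly) constant across
# patterns carry no pattern evidence -- their posterior equals the prior, and
# counting them toward the currently-largest weight would create an absorbing
# state (e.g. when tau2 collapses under permuted labels). Such features are
# assigned to the most parsimonious pattern (fewest clusters) instead.
modal_parsimonious <- function(w, lm_mat, n_clusters, eps = 1e-6) {
  modal <- max.col(w, ties.method = "first")
  spread <- apply(lm_mat, 1, max) - apply(lm_mat, 1, min)
  no_evidence <- spread < eps
  if (any(no_evidence)) {
    pars <- order(n_clusters, seq_len(ncol(w)))[1]
    modal[no_evidence] <- pars
  }
  modal
}

# Closed-form log marginal likelihood of one cluster of observations under
# the Normal-Normal model: x_i | mu ~ N(mu, sigma2), mu ~ N(mu0, tau2).
# log m = -(n/2) log(2 pi sigma2) - SS/(2 sigma2) + (1/2) log(2 pi sigma2/n)
#         + log N(xbar; mu0, sigma2/n + tau2)
cluster_log_marginal <- function(xbar, ss, n, sigma2, mu0, tau2) {
  -(n / 2) * log(2 * pi * sigma2) - ss / (2 * sigma2) +
    0.5 * log(2 * pi * sigma2 / n) +
    dnorm(xbar, mu0, sqrt(sigma2 / n + tau2), log = TRUE)
}

#' Fit the Normal-Normal hierarchical pattern model
#'
#' Each feature (gene or gene-set score) follows one of the group-mean
#' patterns: within a pattern, every cluster of groups shares a latent mean
#' drawn from N(mu0, tau2), and observations are Normal around it with
#' feature-specific variance sigma_g^2 (plugged in as the pooled
#' within-group variance shrunk toward the cross-feature median). The
#' cluster marginal likelihood is evaluated in closed form; hyperparameters
#' (mu0, tau2) and pattern priors pi are fitted by EM.
#'
#' Pattern weights pi are updated from modal (hard) assignments by default
#' (`pi_method = "cem"`, classification EM): because the all-distinct pattern
#' nests every other pattern, the textbook soft update (`pi_method = "em"`)
#' is driven toward an absorbing state in which that pattern soaks up all
#' weight, destroying pattern recovery; hard assignment stops the leakage
#' while remaining adaptive. `pi_method = "uniform"` keeps equal weights.
#'
#' @param mat Features x samples matrix (e.g. from [scores_matrix()]).
#' @param groups Per-sample group labels (>= 2 samples per group).
#' @param patterns Optional [enumerate_patterns()] tibble (default: all
#'   patterns of the observed groups, rejuvenation first when applicable).
#' @param shrink_weight Weight of the cross-feature median in the sigma_g^2
#'   plug-in (default 0.3).
#' @param pi_method Pattern-weight update: "cem" (default), "em" or
#'   "uniform".
#' @param pi_init Optional starting value for the pattern weights (default
#'   uniform). With adaptive weights the likelihood surface is multimodal;
#'   [fit_nn_model()] with `pi_method = "cem"` therefore runs a second start
#'   from the evidence-only (uniform-weight) modal proportions and keeps the
#'   solution with the higher marginal log-likelihood.
#' @param mu0,tau2,pi Optional fixed values; supplying one skips its
#'   estimation (e.g. `tau2 = 0` forces the limit where all patterns share
#'   one marginal and posteriors equal the priors).
#' @param max_iter,tol Stopping rule: relative change of the observed-data
#'   marginal log-likelihood below `tol` (default 1e-8) or `max_iter`
#'   iterations (default 500; non-convergence returns the best iterate with
#'   a flag).
#' @return An object of class `nn_fit`: list with `posterior` (tibble
#'   feature_id x pattern probabilities), `patterns`, `mu0`, `tau2`, `pi`,
#'   `sigma2` (per feature), `log_lik_trace`, `converged`.
#' @examples
#' sim <- simulate_expression(expr_sim_config(n_genes = 300, n_sets = 6,
#'   set_size = 10, pattern_counts = c(`1` = 3, `2` = 3), seed = 11,
#'   samples_per_group = 4))
#' sc <- signature_scores(log2(sim$expr + 1), sim$gene_sets,
#'                        sim$samples$group, adjust = FALSE)
#' fit <- fit_nn_model(scores_matrix(sc, "score"), sim$samples$group)
#' glance(fit)
#' @export
fit_nn_model <- function(mat, groups, patterns = NULL, shrink_weight = 0.3,
                         pi_method = c("cem", "em", "uniform"),
                         mu0 = NULL, tau2 = NULL, pi = NULL, pi_init = NULL,
                         max_iter = 500, tol = 1e-8) {
  pi_method <- match.arg(pi_method)
  m <- as_feature_matrix(mat)
  glev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  tab <- table(factor(groups, levels = glev))
  if (any(tab < 2)) abort("need >= 2 samples per group.")
  if (is.null(patterns)) patterns <- enumerate_patterns(glev)
  G <- nrow(m)
  K <- nrow(patterns)
  ss_within <- rowSums(vapply(glev, function(g) {
    sub <- m[, groups == g, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }, numeric(G)))
  df_within <- sum(tab - 1)
  s2 <- ss_within / df_within
  med <- median(s2)
  if (med == 0 && all(s2 == 0)) abort("degenerate variances: all features have zero within-group variance.")
  sigma2 <- (1 - shrink_weight) * s2 + shrink_weight * med
  if (any(sigma2 == 0)) sigma2[sigma2 == 0] <- med

  # per-pattern cluster summaries: for each pattern k and cluster c, the
  # member samples' mean, within-cluster SS and size, per feature
  summaries <- lapply(seq_len(K), function(k) {
    cl <- patterns$cluster[[k]]
    lapply(seq_len(max(cl)), function(c) {
      sel <- groups %in% names(cl)[cl == c]
      sub <- m[, sel, drop = FALSE]
      xbar <- rowMeans(sub)
      list(xbar = xbar, ss = rowSums((sub - xbar)^2), n = sum(sel))
    })
  })

  log_marg <- function(mu0, tau2) {
    # G x K matrix of log marginal likelihoods
    vapply(seq_len(K), function(k) {
      Reduce(`+`, lapply(summaries[[k]], function(s)
        cluster_log_marginal(s$xbar, s$ss, s$n, sigma2, mu0, tau2)))
    }, numeric(G))
  }
  # only the N(xbar; mu0, sigma2/n + tau2) factors vary in (mu0, tau2); the
  # M-step objective drops the constant terms for speed
  mstep_neg <- function(par, w) {
    mu0 <- par[1]; tau2 <- exp(par[2])
    -sum(vapply(seq_len(K), function(k) {
      sum(w[, k] * Reduce(`+`, lapply(summaries[[k]], function(s)
        dnorm(s$xbar, mu0, sqrt(sigma2 / s$n + tau2), log = TRUE))))
    }, numeric(1)))
  }

  fix_mu0 <- mu0; fix_tau2 <- tau2; fix_pi <- pi
  fit_hyper <- is.null(fix_mu0) || is.null(fix_tau2)
  update_pi <- is.null(fix_pi) && pi_method != "uniform"
  gm <- vapply(glev, function(g) rowMeans(m[, groups == g, drop = FALSE]),
               numeric(G))
  tau2_start <- max(mean(apply(gm, 1, var)), 1e-6)

  run_em <- function(pi_start) {
    mu0 <- fix_mu0 %||% mean(m)
    tau2 <- fix_tau2 %||% tau2_start
    pi_k <- pi_start
    trace <- numeric(0)
    converged <- FALSE
    lm_mat <- log_marg(mu0, tau2)
    for (it in seq_len(max_iter)) {
      lw <- sweep(lm_mat, 2, log(pi_k), `+`)
      mx <- apply(lw, 1, max)
      w <- exp(lw - mx)
      w <- w / rowSums(w)
      obj <- sum(mx + log(rowSums(exp(lw - mx))))   # observed-data log-lik
      trace <- c(trace, obj)
      pi_prev <- pi_k
      if (update_pi) {
        pi_k <- if (pi_method == "cem") {
          (tabulate(modal_parsimonious(w, lm_mat, patterns$n_clusters), K) +
             1) / (G + K)
        } else {
          p <- pmax(colMeans(w), 1e-12)
          p / sum(p)
        }
      }
      # the log-likelihood is nearly flat along the pattern-weight ridge, so
      # convergence additionally requires the weights themselves to settle
      if (it > 1 &&
          abs(obj - trace[it - 1]) <= tol * (abs(trace[it - 1]) + tol) &&
          max(abs(pi_k - pi_prev)) < 1e-5) {
        converged <- TRUE
        break
      }
      if (!fit_hyper && !update_pi) { converged <- TRUE; break }
      if (fit_hyper) {
        opt <- optim(c(mu0, log(max(tau2, 1e-12))), mstep_neg, w = w,
                     method = "Nelder-Mead",
                     control = list(maxit = 200, reltol = 1e-10))
        if (is.null(fix_mu0)) mu0 <- opt$par[1]
        if (is.null(fix_tau2)) tau2 <- exp(opt$par[2])
        lm_mat <- log_marg(mu0, tau2)
      }
    }
    lw <- sweep(lm_mat, 2, log(pi_k), `+`)
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx); w <- w / rowSums(w)
    obj <- sum(mx + log(rowSums(exp(lw - mx))))
    list(mu0 = mu0, tau2 = tau2, pi = pi_k, w = w, lm_mat = lm_mat,
         trace = trace, converged = converged, log_lik = obj)
  }

  pi_start <- if (!is.null(fix_pi)) fix_pi / sum(fix_pi) else
    pi_init %||% rep(1 / K, K)
  fit <- run_em(pi_start)

  # adaptive weights make the likelihood multimodal (nested patterns can
  # absorb one another): try a second start at the evidence-only modal
  # proportions and keep the better optimum
  if (update_pi && pi_method == "cem" && is.null(pi_init)) {
    lw_u <- fit$lm_mat
    mx <- apply(lw_u, 1, max)
    w_u <- exp(lw_u - mx); w_u <- w_u / rowSums(w_u)
    pi2 <- (tabulate(modal_parsimonious(w_u, lw_u, patterns$n_clusters), K) +
              1) / (G + K)
    fit2 <- run_em(pi2)
    if (fit2$log_lik > fit$log_lik + 1e-9 * abs(fit$log_lik)) fit <- fit2
  }
  if (!fit$converged) warn("EM did not converge; returning the best iterate.")

  post <- tibble::as_tibble(fit$w,
                            .name_repair = ~ paste0("pattern_", seq_len(K)))
  post <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)), post)
  structure(list(posterior = post, patterns = patterns, mu0 = fit$mu0,
                 tau2 = fit$tau2, pi = fit$pi, sigma2 = sigma2,
                 log_lik_trace = fit$trace, converged = fit$converged,
                 groups = groups),
            class = "nn_fit")
}

#' Select features by Bayesian expected FDR
#'
#' Sorts features by decreasing posterior probability of the target pattern
#' and keeps the largest prefix whose mean posterior probability of NOT
#' following the pattern is at most `fdr`.
#'
#' @param fit An [fit_nn_model()] object, or a posterior tibble with a
#'   `feature_id` column and `pattern_*` probability columns.
#' @param pattern Target pattern id (default 1, the rejuvenation pattern).
#' @param fdr Nominal Bayesian FDR (default 0.05).
#' @return A tibble of selected features: feature_id, posterior, cumulative
#'   expected FDR. Zero rows when nothing passes.
#' @examples
#' post <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                        pattern_1 = c(0.99, 0.97, 0.60))
#' select_by_bayes_fdr(post)$feature_id  # a, b
#' @export
select_by_bayes_fdr <- function(fit, pattern = 1, fdr = 0.05) {
  post <- if (inherits(fit, "nn_fit")) fit$posterior else tibble::as_tibble(fit)
  col <- paste0("pattern_", pattern)
  if (!col %in% names(post)) abort(sprintf("no column `%s` in posterior.", col))
  ord <- order(post[[col]], decreasing = TRUE)
  p <- post[[col]][ord]
  efdr <- cumsum(1 - p) / seq_along(p)
  keep <- which(efdr <= fdr)
  n_keep <- if (length(keep)) max(keep) else 0
  tibble::tibble(
    feature_id = post$feature_id[ord][seq_len(n_keep)],
    posterior = p[seq_len(n_keep)],
    expected_fdr = efdr[seq_len(n_keep)])
}

#' Sample-randomization control for pattern selection
#'
#' Re-runs the fit + Bayesian-FDR selection after randomly re-assigning
#' samples to groups (preserving group sizes) and reports the number of
#' selected features per permutation next to the unpermuted count -- the
#' control used to show that far fewer rejuvenation-pattern features are
#' found once the group structure is destroyed.
#'
#' @inheritParams fit_nn_model
#' @param pattern,fdr Selection parameters (see [select_by_bayes_fdr()]).
#' @param n_permutations Number of random group assignments.
#' @param seed Integer seed.
#' @return A list: `observed_count`, `perm_counts` (tibble permutation,
#'   n_selected), `ratio` (observed / median permuted; Inf when the median
#'   is 0).
#' @export
randomization_control <- function(mat, groups, pattern = 1, fdr = 0.05,
                                  n_permutations = 20, seed = 1,
                                  patterns = NULL, shrink_weight = 0.3,
                                  pi_method = "cem",
                                  max_iter = 500, tol = 1e-8) {
  m <- as_feature_matrix(mat)
  groups <- as.character(groups)
  # fix the pattern enumeration once so permuted refits share pattern ids
  patterns <- patterns %||% enumerate_patterns(unique(groups))
  run <- function(g) {
    fit <- fit_nn_model(m, g, patterns = patterns,
                        shrink_weight = shrink_weight,
                        pi_method = pi_method,
                        max_iter = max_iter, tol = tol)
    nrow(select_by_bayes_fdr(fit, pattern = pattern, fdr = fdr))
  }
  observed <- run(groups)
  perms <- with_seed(seed, {
    lapply(seq_len(n_permutations), function(i) sample(groups))
  })
  counts <- vapply(perms, function(g) suppressWarnings(run(g)), numeric(1))
  med <- median(counts)
  list(observed_count = observed,
       perm_counts = tibble::tibble(permutation = seq_len(n_permutations),
                                    n_selected = counts),
       ratio = if (med == 0) Inf else observed / med)
}
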