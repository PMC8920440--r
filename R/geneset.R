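#' The maxmean gene-set statistic
#'
#' For member-gene scores z, s_plus is the set mean of `max(z, 0)` and
#' s_minus the set mean of `max(-z, 0)`; the statistic is the larger of the
#' two, signed by direction: `S = s_plus` (direction "up") when
#' `s_plus >= s_minus`, else `S = -s_minus` (direction "down").
#'
#' @param scores Named numeric vector of gene scores (the catalogue).
#' @param members Character vector of member gene ids (or integer indices).
#' @return A list: `S`, `direction`, `s_plus`, `s_minus`, `n_genes`.
#' @examples
#' maxmean(c(a = 1, b = 2, c = -1), c("a", "b", "c"))$S  # 1.0, up
#' @export
maxmean <- function(scores, members) {
  if (is.character(members)) {
    members <- intersect(members, names(scores))
    if (length(members) == 0) abort("empty intersection of set with catalogue.")
  }
  z <- scores[members]
  s_plus <- mean(pmax(z, 0))
  s_minus <- mean(pmax(-z, 0))
  if (s_plus >= s_minus) {
    list(S = s_plus, direction = "up", s_plus = s_plus, s_minus = s_minus,
         n_genes = length(z))
  } else {
    list(S = -s_minus, direction = "down", s_plus = s_plus, s_minus = s_minus,
         n_genes = length(z))
  }
}

#' Restandardize a maxmean statistic against the gene catalogue
#'
#' Converts the self-contained maxmean statistic into a competitive one.
#' Following the Efron-Tibshirani construction, the restandardization moments
#' are those of the one-sided set mean that produced `S`: for an up-directed
#' statistic, `mu_rand` and `sigma_rand` are the mean and SD of the
#' positive-part set mean `s_plus` over random gene sets of the same size
#' drawn from the catalogue (for a standard-normal catalogue,
#' `mu_rand -> E[max(z, 0)] = 1/sqrt(2*pi)`); for a down-directed statistic
#' the negative-part moments are used. The restandardized statistic keeps the
#' observed sign: `S* = (|S| - mu_rand) / sigma_rand`, negated for
#' down-directed sets. Monte Carlo (`mode = "montecarlo"`, `R` seeded draws
#' without replacement) is the default; `mode = "exact"` enumerates every
#' subset of a small catalogue.
#'
#' @param S Observed maxmean statistic (signed; direction = sign).
#' @param scores Numeric score catalogue.
#' @param set_size Size of the set that produced `S`.
#' @param mode "montecarlo" or "exact".
#' @param R Number of Monte Carlo draws (default 2000).
#' @param seed Seed for the Monte Carlo draws.
#' @param max_exact Enumeration guard for exact mode (default 2e5 subsets).
#' @return A list: `S_star`, `mu_rand`, `sigma_rand`, `R_used`.
#' @export
restandardize <- function(S, scores, set_size, mode = c("montecarlo", "exact"),
                          R = 2000, seed = 1, max_exact = 2e5) {
  mode <- match.arg(mode)
  n <- length(scores)
  if (set_size > n) abort("set_size exceeds catalogue size.")
  part <- if (S >= 0) pmax(scores, 0) else pmax(-scores, 0)
  if (mode == "exact") {
    if (choose(n, set_size) > max_exact) {
      abort("catalogue too large for exact enumeration; use montecarlo.")
    }
    idx <- combn(n, set_size)
    s_rand <- colMeans(matrix(part[idx], nrow = set_size))
  } else {
    s_rand <- with_seed(seed, {
      draws <- replicate(R, sample.int(n, set_size))
      colMeans(matrix(part[draws], nrow = set_size))
    })
  }
  mu <- mean(s_rand)
  # exact mode enumerates the full population of subsets: population SD
  sigma <- if (mode == "exact") {
    sqrt(mean((s_rand - mu)^2))
  } else sd(s_rand)
  if (!is.finite(sigma) || sigma == 0) {
    abort("degenerate catalogue: sigma_rand is zero.")
  }
  s_star <- if (S >= 0) (S - mu) / sigma else (S + mu) / sigma
  list(S_star = s_star, mu_rand = mu, sigma_rand = sigma,
       R_used = length(s_rand))
}

#' Competitive rotation test with the restandardized maxmean statistic
#'
#' Gene-wise data are whitened against the design via QR so that the contrast
#' corresponds to one coordinate of a (residual df + 1)-dimensional space;
#' each rotation replaces that coordinate's unit vector by a random unit
#' vector shared across genes (preserving inter-gene correlation), moderated
#' z-scores are recomputed, and each set's maxmean statistic is
#' restandardized against the rotated catalogue. The variance-prior
#' hyperparameters (d0, s0^2) are estimated once from the observed fit and
#' held fixed across rotations. p-values satisfy
#' `p = (1 + #\{|S*_rot| >= |S*_obs|\}) / (B + 1)`.
#'
#' @param expr Genes x samples matrix of preprocessed expression.
#' @param groups Factor of group labels (or a design matrix).
#' @param contrast Named contrast over group levels, e.g.
#'   `c(young = -1, old = 1)`.
#' @param gene_sets Named list or long tibble (set_id, gene_id).
#' @param B Number of rotations (default 999; >= 99 required).
#' @param R Random sets per restandardization (shared across rotations).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param restandardize Use the competitive restandardized statistic
#'   (default TRUE); FALSE tests the raw maxmean (self-contained behaviour,
#'   kept for contrast experiments).
#' @param per_rotation Restandardize each rotated statistic against its own
#'   rotated catalogue (default TRUE); FALSE reuses the observed moments.
#' @param min_set_size Minimum set size after intersection (default 5).
#' @param rotations Optional pre-specified rotation matrix
#'   (B x (residual df + 1) rows of unit norm), mainly for validation.
#' @return A tibble of class `rejuv_settest`: set_id, n_genes, S, S_star,
#'   direction, p_two_sided, p_up, p_down, B, seed. Gene scores in
#'   `attr(, "gene_scores")`, (d0, s0^2) in `attr(, "prior")`.
#' @examples
#' sim <- simulate_expression(expr_sim_config(n_genes = 150, n_sets = 3,
#'   set_size = 10, pattern_counts = c(`1` = 1, `2` = 2), seed = 8))
#' res <- rotation_test(log2(sim$expr + 1), factor(sim$samples$group),
#'   c(young = -1, old = 1), sim$gene_sets, B = 199, R = 200, seed = 9)
#' res[, c("set_id", "S_star", "p_two_sided")]
#' @export
rotation_test <- function(expr, groups, contrast, gene_sets, B = 999,
                          R = 2000, seed, restandardize = TRUE,
                          per_rotation = TRUE, min_set_size = 5,
                          rotations = NULL) {
  if (missing(seed)) abort("a seed is required for reproducibility.")
  if (B < 99) abort("B must be >= 99.")
  if (B < 999) {
    warn("B < 999 limits the attainable significance granularity.")
  }
  m <- as_feature_matrix(expr)
  dec <- rotation_decompose(m, groups, contrast)
  d <- dec$df_resid
  A <- dec$A
  G <- ncol(A)

  sets <- lapply(as_gene_set_list(gene_sets), function(g)
    intersect(unique(g), colnames(A)))
  sets <- sets[lengths(sets) >= min_set_size]
  if (length(sets) == 0) abort("no gene set passes min_set_size.")
  set_idx <- lapply(sets, function(g) match(g, colnames(A)))
  sizes <- lengths(set_idx)

  # observed moderated z-scores; prior fixed from the observed fit
  s2_obs <- colSums(A[-1, , drop = FALSE]^2) / d
  sq <- squeeze_var(s2_obs, d)
  d0 <- sq$d0; s0_2 <- sq$s0_2
  df_total <- d + d0
  z_obs <- zscore_t(A[1, ] / sqrt(sq$s2_post), df_total)

  # shared random-set membership per unique size (reused across rotations),
  # encoded as sparse G x R averaging matrices
  uniq_sizes <- sort(unique(sizes))
  W <- with_seed(seed, {
    setNames(lapply(uniq_sizes, function(msize) {
      draws <- replicate(R, sample.int(G, msize))   # msize x R
      Matrix::sparseMatrix(i = as.vector(draws),
                           j = rep(seq_len(R), each = msize),
                           x = 1 / msize, dims = c(G, R))
    }), as.character(uniq_sizes))
  })

  stat_all <- function(z) {
    zp <- pmax(z, 0); zn <- pmax(-z, 0)
    S <- vapply(set_idx, function(ii) {
      sp <- mean(zp[ii]); sn <- mean(zn[ii])
      if (sp >= sn) sp else -sn
    }, numeric(1))
    if (!restandardize) return(S)
    mu_p <- sig_p <- mu_n <- sig_n <- numeric(length(S))
    for (ms in uniq_sizes) {
      sp <- as.vector(zp %*% W[[as.character(ms)]])
      sn <- as.vector(zn %*% W[[as.character(ms)]])
      sel <- sizes == ms
      mu_p[sel] <- mean(sp); sig_p[sel] <- sd(sp)
      mu_n[sel] <- mean(sn); sig_n[sel] <- sd(sn)
    }
    if (any(c(sig_p, sig_n) == 0)) {
      abort("degenerate catalogue: sigma_rand is zero.")
    }
    s_star <- ifelse(S >= 0, (S - mu_p) / sig_p, (S + mu_n) / sig_n)
    list(S = S, S_star = s_star,
         mu_p = mu_p, sig_p = sig_p, mu_n = mu_n, sig_n = sig_n)
  }

  obs <- stat_all(z_obs)
  if (!restandardize) {
    obs <- list(S = obs, S_star = obs)
  }

  # rotations: random unit vectors in dimension d + 1, one per iteration
  if (is.null(rotations)) {
    rotations <- with_seed(seed + 1L, {
      Rm <- matrix(rnorm(B * (d + 1)), B, d + 1)
      Rm / sqrt(rowSums(Rm^2))
    })
  } else {
    B <- nrow(rotations)
  }
  tot_ss <- colSums(A^2)
  U <- rotations %*% A                            # B x G rotated effects
  S2 <- sweep(-(U^2), 2, tot_ss, `+`) / d
  S2[S2 < 0] <- 0
  S2post <- if (is.infinite(d0)) matrix(s0_2, B, G) else
    (d0 * s0_2 + d * S2) / (d0 + d)
  Zrot <- zscore_t_mat(U / sqrt(S2post), df_total)

  n_sets <- length(set_idx)
  ge_abs <- ge_up <- le_down <- integer(n_sets)
  Zp <- pmax(Zrot, 0); Zn <- pmax(-Zrot, 0)
  # per-set rotated maxmean
  S_rot <- matrix(NA_real_, B, n_sets)
  for (j in seq_len(n_sets)) {
    ii <- set_idx[[j]]
    sp <- rowMeans(Zp[, ii, drop = FALSE])
    sn <- rowMeans(Zn[, ii, drop = FALSE])
    S_rot[, j] <- ifelse(sp >= sn, sp, -sn)
  }
  if (restandardize) {
    Sstar_rot <- matrix(NA_real_, B, n_sets)
    for (ms in uniq_sizes) {
      sel <- which(sizes == ms)
      if (per_rotation) {
        Mp <- as.matrix(Zp %*% W[[as.character(ms)]])   # B x R
        Mn <- as.matrix(Zn %*% W[[as.character(ms)]])
        mu_p <- rowMeans(Mp)
        sig_p <- sqrt(pmax(rowSums((Mp - mu_p)^2) / (R - 1), 0))
        mu_n <- rowMeans(Mn)
        sig_n <- sqrt(pmax(rowSums((Mn - mu_n)^2) / (R - 1), 0))
        sig_p[sig_p == 0] <- NA_real_
        sig_n[sig_n == 0] <- NA_real_
        sr <- S_rot[, sel, drop = FALSE]
        Sstar_rot[, sel] <- ifelse(sr >= 0, (sr - mu_p) / sig_p,
                                   (sr + mu_n) / sig_n)
      } else {
        j1 <- sel[1]
        sr <- S_rot[, sel, drop = FALSE]
        Sstar_rot[, sel] <- ifelse(sr >= 0,
                                   (sr - obs$mu_p[j1]) / obs$sig_p[j1],
                                   (sr + obs$mu_n[j1]) / obs$sig_n[j1])
      }
    }
  } else {
    Sstar_rot <- S_rot
  }
  for (j in seq_len(n_sets)) {
    sj <- Sstar_rot[, j]
    sj <- sj[is.finite(sj)]
    ge_abs[j] <- sum(abs(sj) >= abs(obs$S_star[j]))
    ge_up[j] <- sum(sj >= obs$S_star[j])
    le_down[j] <- sum(sj <= obs$S_star[j])
  }

  out <- tibble::tibble(
    set_id = names(set_idx),
    n_genes = unname(sizes),
    S = unname(obs$S),
    S_star = unname(obs$S_star),
    direction = unname(ifelse(obs$S >= 0, "up", "down")),
    p_two_sided = (1 + ge_abs) / (B + 1),
    p_up = (1 + ge_up) / (B + 1),
    p_down = (1 + le_down) / (B + 1),
    B = B,
    seed = seed)
  structure(out,
            gene_scores = setNames(z_obs, colnames(A)),
            prior = c(d0 = d0, s0_2 = s0_2, df_resid = d),
            class = c("rejuv_settest", class(out)))
}

# Vectorized t -> z mapping for a matrix (finite df).
zscore_t_mat <- function(tm, df) {
  if (is.infinite(df)) return(tm)
  z <- tm
  lp <- pt(abs(tm), df = df, lower.tail = FALSE, log.p = TRUE)
  z[] <- sign(tm) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z
}

#' GSEA-style running enrichment score
#'
#' Genes are ranked by decreasing score; a running sum gains `1/|set|` at
#' member positions and loses `1/(N - |set|)` elsewhere. The statistic is the
#' signed extremum of the curve (Kolmogorov-Smirnov-style), the usual
#' visualization of competitive enrichment results.
#'
#' @param scores Named numeric vector of gene scores.
#' @param members Character vector of member gene ids.
#' @return A list with `statistic` (signed extremum) and `curve` (tibble:
#'   rank, gene_id, score, member, running).
#' @export
ks_running_score <- function(scores, members) {
  if (is.null(names(scores))) abort("scores must be a named vector.")
  members <- intersect(members, names(scores))
  N <- length(scores)
  mlen <- length(members)
  if (mlen == 0) abort("empty intersection of set with catalogue.")
  if (mlen == N) abort("set equals the full catalogue; decrement undefined.")
  ord <- order(scores, decreasing = TRUE)
  is_mem <- names(scores)[ord] %in% members
  step <- ifelse(is_mem, 1 / mlen, -1 / (N - mlen))
  running <- cumsum(step)
  ext <- running[which.max(abs(running))]
  list(statistic = ext,
       curve = tibble::tibble(rank = seq_len(N),
                              gene_id = names(scores)[ord],
                              score = scores[ord],
                              member = is_mem,
                              running = running))
}
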