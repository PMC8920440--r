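#' Empirical-Bayes moderated gene statistics for a contrast
#'
#' Fits a gene-wise linear model, shrinks residual variances toward a common
#' prior fitted by moment-matching on the log sample variances (the scaled
#' F-distribution construction used by moderated-t pipelines), and maps the
#' moderated t (df = residual df + prior df) to a z-score by matching tail
#' probabilities. These z-scores are the gene-level input of the competitive
#' gene-set machinery.
#'
#' @param expr Genes x samples matrix of (preprocessed) expression values.
#' @param groups Factor of group labels per sample, or a full design matrix.
#' @param contrast Named numeric vector over group levels (e.g.
#'   `c(young = -1, old = 1)`), or a numeric vector over design columns when
#'   `groups` is a design matrix.
#' @param d0 Override the prior degrees of freedom: `0` disables shrinkage
#'   (plain t), `Inf` forces complete shrinkage to the common variance,
#'   `NULL` (default) estimates d0 by moment matching.
#' @return A tibble: gene_id, estimate (contrast units), s2 (residual
#'   variance), s2_post, t, df_total, p_value (two-sided), z,
#'   zero_variance flag. Attributes: `d0`, `s0_2`, `df_resid`, and
#'   `catalogue` (mean/SD of z and of its positive and negative parts).
#' @examples
#' sim <- simulate_expression(expr_sim_config(n_genes = 100, n_sets = 2,
#'   pattern_counts = c(`1` = 1, `2` = 1), seed = 4))
#' gs <- moderated_gene_stats(log2(sim$expr + 1), factor(sim$samples$group),
#'                            contrast = c(young = -1, old = 1, old_OSKM = 0))
#' attr(gs, "d0")
#' @export
moderated_gene_stats <- function(expr, groups, contrast, d0 = NULL) {
  m <- as_feature_matrix(expr)
  dec <- rotation_decompose(m, groups, contrast)
  d <- dec$df_resid
  if (d < 1) abort("residual degrees of freedom must be >= 1.")
  u <- unname(dec$A[1, ])
  s2 <- unname(colSums(dec$A[-1, , drop = FALSE]^2)) / d
  # constant genes: the whitened effects vanish up to rounding error
  tot <- unname(colSums(dec$A^2))
  const <- tot <= 1e-16 * max(tot, 1)
  s2[s2 <= 1e-14 * max(s2)] <- 0
  sq <- squeeze_var(s2, d, d0 = d0)
  t_mod <- u / sqrt(sq$s2_post)
  t_mod[sq$s2_post == 0 | const] <- 0
  df_total <- d + sq$d0
  z <- zscore_t(t_mod, df_total)
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  out <- tibble::tibble(
    gene_id = colnames(dec$A) %||% paste0("g", seq_along(z)),
    estimate = u / dec$scale,
    s2 = s2,
    s2_post = sq$s2_post,
    t = t_mod,
    df_total = df_total,
    p_value = p,
    z = z,
    zero_variance = s2 == 0)
  structure(out, d0 = sq$d0, s0_2 = sq$s0_2, df_resid = d,
            catalogue = catalogue_moments(z))
}

# Whiten a genes x samples matrix against a design, with the requested
# contrast isolated as the first coordinate. Returns A ((d+1) x G): row 1 is
# the normalized contrast effect u, rows 2..d+1 the residual effects -- the
# coordinates rotated by the rotation test. `scale` converts u back to
# contrast units (u / scale = contrast estimate).
rotation_decompose <- function(m, groups, contrast) {
  if (is.matrix(groups)) {
    X <- groups
    cvec <- contrast
  } else {
    g <- factor(groups)
    X <- model.matrix(~ 0 + g)
    colnames(X) <- levels(g)
    if (is.null(names(contrast))) {
      if (length(contrast) != ncol(X)) abort("contrast length != groups.")
      cvec <- contrast
    } else {
      cvec <- setNames(rep(0, ncol(X)), colnames(X))
      bad <- setdiff(names(contrast), colnames(X))
      if (length(bad)) abort(sprintf("unknown contrast level(s): %s",
                                     paste(bad, collapse = ", ")))
      cvec[names(contrast)] <- contrast
    }
  }
  p <- ncol(X)
  n <- nrow(X)
  if (n - p < 1) abort("residual degrees of freedom must be >= 1.")
  # reparametrize so the (unit-norm) contrast is the LAST coefficient
  Q <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)
  sgn <- sign(sum(Q[, 1] * cvec))               # qr may flip the sign
  Q[, 1] <- Q[, 1] * sgn
  Xt <- X %*% Q[, c(seq_len(p)[-1], 1), drop = FALSE]
  qx <- qr(Xt)
  if (qx$rank < p) abort("design matrix is rank deficient.")
  if (!identical(qx$pivot[seq_len(p)], seq_len(p))) {
    abort("unexpected pivoting in design QR decomposition.")
  }
  E <- qr.qty(qx, t(m))                          # n x G effects
  A <- E[c(p, (p + 1):n), , drop = FALSE]        # contrast effect + residuals
  colnames(A) <- rownames(m)
  # u = R[p,p] * gamma_p with gamma_p = c'beta / ||c||
  scale_ <- qr.R(qx)[p, p] / sqrt(sum(cvec^2))
  list(A = A, df_resid = n - p, scale = scale_)
}

# Moment-matching fit of the variance prior: log s^2 follows (up to a
# constant) log s0^2 + log F(d, d0); solve for (d0, s0^2) from the mean and
# variance of e = log s^2 - digamma(d/2) + log(d/2). Zero variances are
# excluded from the fit and get the shrunken floor.
squeeze_var <- function(s2, d, d0 = NULL) {
  pos <- s2 > 0
  if (!any(pos)) {
    # fully degenerate input: no variance information at all
    return(list(d0 = Inf, s0_2 = 0, s2_post = rep(0, length(s2))))
  }
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  if (is.null(d0)) {
    ev <- var(e) - trigamma(d / 2)
    d0 <- if (is.na(ev) || ev <= 0) Inf else 2 * trigamma_inverse(ev)
  }
  if (is.infinite(d0)) {
    s0_2 <- exp(mean(e))
    s2_post <- rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s0_2 <- NA_real_
    s2_post <- s2
  } else {
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

# Newton solve trigamma(x) = y, y > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Map t with df degrees of freedom to a standard normal z by matching tail
# probabilities (stable in the tails via log probabilities).
zscore_t <- function(t, df) {
  if (is.infinite(df)) return(t)
  lp <- pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

# Mean/SD of a score catalogue and of its positive/negative parts.
catalogue_moments <- function(z) {
  tibble::tibble(
    mean = mean(z), sd = sd(z),
    mean_pos = mean(pmax(z, 0)), sd_pos = sd(pmax(z, 0)),
    mean_neg = mean(pmax(-z, 0)), sd_neg = sd(pmax(-z, 0)))
}
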