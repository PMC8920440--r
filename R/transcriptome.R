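#' Preprocess a raw expression matrix
#'
#' Applies `log2(x + pseudocount)`, quantile normalization to the mean
#' empirical distribution (ties share averaged values), and an a-priori
#' removal of the library-size covariate: a gene-wise linear model
#' `value ~ group + total_reads` is fitted and the centered `total_reads`
#' component subtracted, so group effects are retained while the technical
#' covariate is regressed out.
#'
#' @param raw Genes x samples matrix (or data frame with a gene id column) of
#'   non-negative RPKM-like values.
#' @param samples Sample sheet with `sample_id`, `group` and `total_reads`
#'   (rows matching the matrix columns by name or order).
#' @param pseudocount Added before log2 (default 1).
#' @param correct_total_reads Remove the total-reads component (default TRUE).
#' @return A genes x samples matrix of preprocessed log2 values, with the
#'   sample sheet in `attr(, "samples")`.
#' @examples
#' sim <- simulate_expression(expr_sim_config(n_genes = 200, n_sets = 4,
#'   pattern_counts = c(`1` = 1, `2` = 3), seed = 1))
#' expr <- preprocess_expression(sim$expr, sim$samples)
#' @export
preprocess_expression <- function(raw, samples, pseudocount = 1,
                                  correct_total_reads = TRUE) {
  m <- as_feature_matrix(raw)
  if (any(m < 0)) abort("raw expression values must be >= 0.")
  samples <- tibble::as_tibble(samples)
  if (!is.null(colnames(m)) && all(colnames(m) %in% samples$sample_id)) {
    samples <- samples[match(colnames(m), samples$sample_id), ]
  }
  if (nrow(samples) != ncol(m)) abort("sample sheet does not match matrix columns.")
  if (any(samples$total_reads <= 0)) abort("total_reads must be > 0.")

  lg <- log2(m + pseudocount)
  qn <- limma::normalizeQuantiles(lg, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (correct_total_reads) {
    qn <- remove_covariate(qn, groups = samples$group,
                           covariate = samples$total_reads)
  }
  attr(qn, "samples") <- samples
  qn
}

# Gene-wise fit value ~ group + covariate; subtract the centered covariate
# component, keeping group effects. One mechanism reused for total-reads and
# for global-signature correction.
remove_covariate <- function(mat, groups, covariate) {
  g <- factor(groups)
  x_c <- covariate - mean(covariate)
  X <- model.matrix(~ g + x_c)
  fit <- lm.fit(X, t(mat))
  beta <- if (is.matrix(fit$coefficients)) {
    fit$coefficients["x_c", ]
  } else fit$coefficients["x_c"]
  beta[is.na(beta)] <- 0                         # constant rows pass through
  out <- mat - outer(beta, x_c)
  dimnames(out) <- dimnames(mat)
  out
}

#' Select aging differentially-expressed genes
#'
#' Per gene, a two-sample test on preprocessed log2 values yields a raw p;
#' the fold change is `2^(mean_old - mean_young)`. A gene is a DEG when
#' `|FC| > fc_threshold` on the linear scale (i.e. |log2 FC| > log2 1.5 by
#' default, two-sided) AND raw p < `p_threshold`. The default test is the
#' empirical-Bayes moderated t (see [moderated_gene_stats()]); a plain Welch
#' t is available via `method = "welch"`.
#'
#' @param expr Preprocessed genes x samples matrix.
#' @param young_ids,old_ids Column names (or indices) of the two groups.
#' @param fc_threshold Linear-scale fold-change threshold (default 1.5).
#' @param p_threshold Raw p threshold (default 0.01).
#' @param method "moderated" (default) or "welch".
#' @return A tibble: gene_id, log2_fc, fc, p_raw, direction ("up" = higher in
#'   old), deg flag.
#' @export
select_degs <- function(expr, young_ids, old_ids, fc_threshold = 1.5,
                        p_threshold = 0.01, method = c("moderated", "welch")) {
  method <- match.arg(method)
  m <- as_feature_matrix(expr)
  y <- m[, young_ids, drop = FALSE]
  o <- m[, old_ids, drop = FALSE]
  if (ncol(y) < 2 || ncol(o) < 2) abort("need >= 2 samples per group.")
  lfc <- rowMeans(o) - rowMeans(y)
  if (method == "welch") {
    p <- vapply(seq_len(nrow(m)), function(i) {
      if (var(y[i, ]) == 0 && var(o[i, ]) == 0) {
        if (mean(y[i, ]) == mean(o[i, ])) return(1)
        return(0)
      }
      t.test(o[i, ], y[i, ])$p.value
    }, numeric(1))
  } else {
    sub <- cbind(y, o)
    groups <- factor(rep(c("young", "old"), c(ncol(y), ncol(o))),
                     levels = c("young", "old"))
    ms <- moderated_gene_stats(sub, groups, contrast = c(young = -1, old = 1))
    p <- ms$p_value
    zero_var <- ms$zero_variance & lfc == 0
    p[zero_var] <- 1
  }
  tibble::tibble(
    gene_id = rownames(m),
    log2_fc = lfc,
    fc = 2^lfc,
    p_raw = p,
    direction = ifelse(lfc >= 0, "up", "down"),
    deg = abs(lfc) > log2(fc_threshold) & p < p_threshold)
}

#' Gene-set signature scores with global-signature correction
#'
#' Expression values are z-scored gene-wise (mean 0, SD 1 across samples);
#' the unadjusted score of a set is the per-sample mean z over member genes,
#' and the global signature is the same mean over all genes in the matrix.
#' Adjusted scores remove the global-signature component with the same
#' group-preserving linear-model construction used for library-size
#' correction, which adjusts each set for the association expected of a
#' random gene signature.
#'
#' @param expr Preprocessed genes x samples matrix.
#' @param gene_sets Named list of gene id vectors, or long tibble
#'   (set_id, gene_id).
#' @param groups Per-sample group labels (needed for adjustment).
#' @param min_set_size Sets with fewer members present in the matrix are
#'   skipped and logged (default 5).
#' @param adjust Compute globally-adjusted scores (default TRUE).
#' @return A tibble of class `signature_scores` (long): set_id, sample_id,
#'   group, score, adjusted_score, n_genes. The global signature per sample
#'   is in `attr(, "global")`; skipped sets in `attr(, "skipped")`.
#' @export
signature_scores <- function(expr, gene_sets, groups, min_set_size = 5,
                             adjust = TRUE) {
  m <- as_feature_matrix(expr)
  sets <- as_gene_set_list(gene_sets)
  z <- gene_zscores(m)
  global <- colMeans(z)

  sets_in <- lapply(sets, function(g) intersect(unique(g), rownames(m)))
  sizes <- lengths(sets_in)
  skipped <- names(sets_in)[sizes < min_set_size]
  if (length(skipped)) {
    inform(sprintf("skipping %d set(s) below min_set_size.", length(skipped)))
  }
  sets_in <- sets_in[sizes >= min_set_size]
  if (length(sets_in) == 0) abort("no gene set passes min_set_size.")

  score_mat <- t(vapply(sets_in, function(g)
    colMeans(z[g, , drop = FALSE]), numeric(ncol(m))))
  rownames(score_mat) <- names(sets_in)
  adj_mat <- if (adjust) {
    remove_covariate(score_mat, groups = groups, covariate = global)
  } else score_mat

  out <- tibble::tibble(
    set_id = rep(rownames(score_mat), ncol(m)),
    sample_id = rep(colnames(m) %||% paste0("s", seq_len(ncol(m))),
                    each = nrow(score_mat)),
    group = rep(as.character(groups), each = nrow(score_mat)),
    score = as.vector(score_mat),
    adjusted_score = as.vector(adj_mat),
    n_genes = rep(lengths(sets_in), ncol(m)))
  structure(out, global = global, skipped = skipped,
            class = c("signature_scores", class(out)))
}

# Gene-wise z-scores across samples; zero-variance genes map to all-zero.
gene_zscores <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0] <- Inf
  (m - mu) / s
}

#' Convert long signature scores to a sets x samples matrix
#'
#' @param scores A [signature_scores()] tibble.
#' @param value `"adjusted_score"` (default) or `"score"`.
#' @return Numeric matrix sets x samples.
#' @export
scores_matrix <- function(scores, value = "adjusted_score") {
  wide <- tidyr::pivot_wider(scores[, c("set_id", "sample_id", value)],
                             names_from = "sample_id",
                             values_from = tidyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$set_id
  m
}
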