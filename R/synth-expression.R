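#' Configuration for the synthetic expression generator
#'
#' Builds a three-group gene-expression simulation where each gene set is
#' assigned one of the five three-group mean patterns (see
#' [enumerate_patterns()]); member genes share the pattern's group shift plus
#' a rho-weighted within-set latent factor, which makes the competitive
#' gene-set null non-trivial. A multiplicative library-size effect is added on
#' the raw scale so preprocessing has something to remove.
#'
#' @param n_genes Total genes (set members first, then background genes).
#' @param n_sets Number of disjoint gene sets.
#' @param set_size Genes per set (>= 2).
#' @param samples_per_group Samples per group (young, old, old_OSKM).
#' @param pattern_counts Named integer vector giving how many sets follow each
#'   pattern id 1..5 (pattern 1 = rejuvenation: young == old_OSKM != old;
#'   pattern 2 = complete null). Must sum to `n_sets`.
#' @param effect_log2 Between-cluster shift in log2 units.
#' @param rho Within-set latent-factor correlation in [0, 1).
#' @param noise_sd Residual SD in log2 units.
#' @param baseline_mean,baseline_sd Gene baseline abundance (log2 units).
#' @param lib_multipliers Per-sample multiplicative library-size factors
#'   (recycled/length `3 * samples_per_group`), or `NULL` for log-normal
#'   factors with sdlog 0.3.
#' @param balance_directions Alternate the sign of the shift across the sets
#'   of each pattern (default TRUE), mirroring real aging signatures where
#'   up- and down-regulated programs coexist; a strongly one-sided planted
#'   signal would additionally distort quantile normalization.
#' @param seed Integer seed.
#' @return A list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 2000,
                            n_sets = 40,
                            set_size = 20,
                            samples_per_group = 5,
                            pattern_counts = c(`1` = 10, `2` = 18, `3` = 4,
                                               `4` = 4, `5` = 4),
                            effect_log2 = 1,
                            rho = 0.2,
                            noise_sd = 0.5,
                            baseline_mean = 5,
                            baseline_sd = 1.5,
                            lib_multipliers = NULL,
                            balance_directions = TRUE,
                            seed = 1) {
  if (set_size < 2) abort("set_size must be >= 2.")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1).")
  if (sum(pattern_counts) != n_sets) {
    abort("pattern_counts must sum to n_sets.")
  }
  if (n_sets * set_size > n_genes) {
    abort("n_genes too small for the requested disjoint sets.")
  }
  structure(
    list(n_genes = n_genes, n_sets = n_sets, set_size = set_size,
         samples_per_group = samples_per_group,
         pattern_counts = pattern_counts, effect_log2 = effect_log2,
         rho = rho, noise_sd = noise_sd, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, lib_multipliers = lib_multipliers,
         balance_directions = balance_directions,
         seed = seed),
    class = "expr_sim_config")
}

#' Simulate three-group expression with pattern-coordinated gene sets
#'
#' @param config An [expr_sim_config()].
#' @return A list with `expr` (raw-scale genes x samples matrix, RPKM-like),
#'   `gene_sets` (long tibble set_id/gene_id), `samples` (sample_id, group,
#'   total_reads, lib_multiplier) and `truth` (set_id, pattern_id,
#'   pattern label, effect_log2, seed), plus the echoed `config`.
#' @details Group shifts for a pattern assign offset 0 to the cluster holding
#'   the young group and `effect_log2 * (1, -1, ...)` to the remaining
#'   clusters, so any two clusters differ whenever `effect_log2 != 0`.
#' @examples
#' sim <- simulate_expression(expr_sim_config(n_genes = 300, n_sets = 5,
#'   pattern_counts = c(`1` = 2, `2` = 3), seed = 2))
#' dim(sim$expr)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  groups <- c("young", "old", "old_OSKM")
  n_s <- config$samples_per_group
  group_vec <- rep(groups, each = n_s)
  n_samp <- length(group_vec)
  patterns <- enumerate_patterns(groups)

  with_seed(config$seed, {
    lib <- config$lib_multipliers
    if (is.null(lib)) lib <- exp(rnorm(n_samp, 0, 0.3))
    lib <- rep_len(lib, n_samp)

    set_pattern <- rep(as.integer(names(config$pattern_counts)),
                       config$pattern_counts)
    gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
    baseline <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    logx <- matrix(baseline, config$n_genes, n_samp)

    gene_sets <- vector("list", config$n_sets)
    rank_in_pattern <- stats::ave(seq_along(set_pattern), set_pattern,
                                  FUN = seq_along)
    set_sign <- if (config$balance_directions) {
      ifelse(rank_in_pattern %% 2 == 1, 1, -1)
    } else rep(1, config$n_sets)
    for (s in seq_len(config$n_sets)) {
      idx <- ((s - 1) * config$set_size + 1):(s * config$set_size)
      gene_sets[[s]] <- tibble::tibble(
        set_id = sprintf("set_%03d", s), gene_id = gene_ids[idx])
      pat <- patterns$cluster[[set_pattern[s]]]   # named cluster index per group
      # cluster containing young -> 0; others +/- effect
      offs <- rep(0, max(pat))
      other <- setdiff(seq_len(max(pat)), pat[["young"]])
      if (length(other)) {
        offs[other] <- set_sign[s] * config$effect_log2 *
          c(1, -1, 1)[seq_along(other)]
      }
      shift <- offs[pat[group_vec]]
      latent <- rnorm(n_samp)
      eps <- matrix(rnorm(config$set_size * n_samp), config$set_size, n_samp)
      logx[idx, ] <- logx[idx, ] +
        matrix(shift, config$set_size, n_samp, byrow = TRUE) +
        config$noise_sd * (sqrt(config$rho) *
                             matrix(latent, config$set_size, n_samp, byrow = TRUE) +
                           sqrt(1 - config$rho) * eps)
    }
    bg <- (config$n_sets * config$set_size + 1):config$n_genes
    if (length(bg) && bg[1] <= config$n_genes) {
      logx[bg, ] <- logx[bg, ] +
        config$noise_sd * matrix(rnorm(length(bg) * n_samp), length(bg), n_samp)
    }

    expr <- 2^logx * matrix(lib, config$n_genes, n_samp, byrow = TRUE)
    dimnames(expr) <- list(gene_ids,
                           paste0(group_vec, "_", rep(seq_len(n_s), length(groups))))
    samples <- tibble::tibble(
      sample_id = colnames(expr), group = group_vec,
      lib_multiplier = lib, total_reads = colSums(expr))
    null_id <- which(patterns$label == "young,old,old_OSKM")
    truth <- tibble::tibble(
      set_id = sprintf("set_%03d", seq_len(config$n_sets)),
      pattern_id = set_pattern,
      pattern = patterns$label[set_pattern],
      effect_log2 = ifelse(set_pattern == null_id, 0,
                           set_sign * config$effect_log2),
      seed = config$seed)
    list(expr = expr, gene_sets = dplyr::bind_rows(gene_sets),
         samples = samples, truth = truth, config = config)
  })
}
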