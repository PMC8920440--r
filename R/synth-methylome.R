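#' Configuration for the synthetic methylome generator
#'
#' Defines a three-group (young / old / old_OSKM, optionally a fourth
#' old_OSKM_d7 group) RRBS-like simulation with planted aging and
#' rejuvenation structure. Defaults mirror a typical transient-reprogramming
#' cohort: 5 animals per group, ~5 CpGs per regulatory region, mean coverage
#' 30x, aging effects of 20-40 percentage points (comfortably above the
#' 10-point differential-methylation rule), 30% of regions aging-affected,
#' 55% of those hypermethylated with age, and 40% of aging regions reverted
#' toward the young mean with strength 0.8-1.
#'
#' @param n_regions Number of regulatory regions to simulate.
#' @param cpgs_per_region_mean Mean CpGs per region (>= 1; Poisson-distributed).
#' @param samples_per_group Samples in each group.
#' @param baseline_beta_params Beta(a, b) parameters for the young-group
#'   baseline methylation proportion.
#' @param frac_aging Proportion of regions with a planted aging effect.
#' @param frac_hyper Among aging regions, proportion hypermethylated with age.
#' @param aging_effect_range Aging effect interval in percentage points
#'   (lower bound must be >= 10 so planted effects are detectable).
#' @param frac_rejuvenated Among aging regions, proportion reverted by OSKM.
#' @param rejuvenation_strength_range Interval in (0, 1]: fraction of the
#'   aging effect undone in the old_OSKM group.
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage
#'   per CpG per sample (mean and size).
#' @param meth_error_floor Methylation proportions are kept inside
#'   `[floor, 1 - floor]`, modelling bisulfite non-conversion/sequencing error.
#' @param cpg_jitter_sd SD of the per-CpG jitter around the region mean
#'   (drawn once per CpG, shared across samples and groups).
#' @param include_d7 Also simulate an "old_OSKM_d7" group (end of induction).
#' @param d7_retain_prob For rejuvenated regions, probability the reversion is
#'   already present at d7 (otherwise acquired during recovery).
#' @param d7_transient_prob For non-rejuvenated aging regions, probability of
#'   a transient d7-only reversion (lost by d21).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `methyl_sim_config`.
#' @seealso [simulate_methylome()]
#' @export
methyl_sim_config <- function(n_regions = 500,
                              cpgs_per_region_mean = 5,
                              samples_per_group = 5,
                              baseline_beta_params = c(2, 2),
                              frac_aging = 0.3,
                              frac_hyper = 0.55,
                              aging_effect_range = c(20, 40),
                              frac_rejuvenated = 0.4,
                              rejuvenation_strength_range = c(0.8, 1),
                              coverage_mean = 30,
                              coverage_dispersion = 5,
                              meth_error_floor = 0.02,
                              cpg_jitter_sd = 0.03,
                              include_d7 = FALSE,
                              d7_retain_prob = 0.5,
                              d7_transient_prob = 0.1,
                              seed = 1) {
  check_proportion(frac_aging, "frac_aging")
  check_proportion(frac_hyper, "frac_hyper")
  check_proportion(frac_rejuvenated, "frac_rejuvenated")
  check_proportion(meth_error_floor, "meth_error_floor")
  if (frac_aging > 0 && aging_effect_range[1] < 10) {
    abort("aging_effect_range lower bound must be >= 10 percentage points.")
  }
  if (coverage_mean < 1) abort("coverage_mean must be >= 1.")
  if (aging_effect_range[2] > aging_effect_range[1] * 10) {
    abort("aging_effect_range looks malformed (upper >> lower).")
  }
  if (any(rejuvenation_strength_range <= 0) ||
      any(rejuvenation_strength_range > 1)) {
    abort("rejuvenation_strength_range must lie in (0, 1].")
  }
  # Degenerate-effect guard: the largest requested effect must fit between
  # the error floors for at least some baseline value.
  if (frac_aging > 0 &&
      aging_effect_range[2] / 100 > 1 - 2 * meth_error_floor) {
    abort(paste0("degenerate effect: aging_effect_range exceeds the headroom",
                 " left by meth_error_floor; no baseline can host it."))
  }
  structure(
    list(n_regions = n_regions,
         cpgs_per_region_mean = cpgs_per_region_mean,
         samples_per_group = samples_per_group,
         baseline_beta_params = baseline_beta_params,
         frac_aging = frac_aging,
         frac_hyper = frac_hyper,
         aging_effect_range = aging_effect_range,
         frac_rejuvenated = frac_rejuvenated,
         rejuvenation_strength_range = rejuvenation_strength_range,
         coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         meth_error_floor = meth_error_floor,
         cpg_jitter_sd = cpg_jitter_sd,
         include_d7 = include_d7,
         d7_retain_prob = d7_retain_prob,
         d7_transient_prob = d7_transient_prob,
         seed = seed),
    class = "methyl_sim_config")
}

#' Simulate a three-group methylome with planted aging/rejuvenation structure
#'
#' Per region, a true young-group methylation level p0 is drawn from the
#' configured Beta distribution (resampled deterministically until the
#' planted aging effect fits inside `[floor, 1 - floor]`); aging regions get
#' old = p0 +/- delta, and rejuvenated regions get
#' old_OSKM = old -/+ r * delta (r = 1 restores the young mean exactly).
#' Per-CpG true levels are the region's group mean plus a per-CpG jitter
#' shared across samples; observed counts are
#' coverage ~ NegBin(coverage_mean, coverage_dispersion) and
#' methylated ~ Binomial(coverage, level). Deterministic given the seed, with
#' per-region sub-streams so enlarging `n_regions` never perturbs earlier
#' regions.
#'
#' @param config A [methyl_sim_config()].
#' @return A list with tibbles `cpgs` (long: chrom, pos, region_id, sample_id,
#'   meth_reads, unmeth_reads), `regions` (region_id, chrom, start, end, kind,
#'   strand, linked_gene), `samples` (sample_id, group, total_reads) and
#'   `truth` (region_id, aging_label, rejuvenated, planted_effect_pp,
#'   rejuvenation_strength, true young/old/oskm means, seed), plus the echoed
#'   `config`.
#' @examples
#' sim <- simulate_methylome(methyl_sim_config(n_regions = 20, seed = 3))
#' table(sim$truth$aging_label)
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "methyl_sim_config"))
  groups <- c("young", "old", "old_OSKM")
  if (config$include_d7) groups <- c(groups, "old_OSKM_d7")
  n_s <- config$samples_per_group
  samples <- tibble::tibble(
    sample_id = paste0(rep(groups, each = n_s), "_", rep(seq_len(n_s), length(groups))),
    group = rep(groups, each = n_s)
  )
  floor_ <- config$meth_error_floor

  one_region <- function(i) {
    with_seed(feature_seed(config$seed, i), {
      n_cpg <- 1L + rpois(1, max(config$cpgs_per_region_mean - 1, 0))
      aging <- runif(1) < config$frac_aging
      hyper <- runif(1) < config$frac_hyper
      delta <- runif(1, config$aging_effect_range[1],
                     config$aging_effect_range[2]) / 100
      sgn <- if (hyper) 1 else -1
      # rejection-sample p0 until the planted effect has clipping headroom
      p0 <- NA_real_
      for (try in seq_len(1000L)) {
        cand <- rbeta(1, config$baseline_beta_params[1],
                      config$baseline_beta_params[2])
        cand <- clip(cand, floor_, 1 - floor_)
        if (!aging) { p0 <- cand; break }
        if (cand + sgn * delta >= floor_ && cand + sgn * delta <= 1 - floor_) {
          p0 <- cand; break
        }
      }
      if (is.na(p0)) {
        abort(sprintf("degenerate effect: no baseline headroom for region %d", i))
      }
      old <- if (aging) clip(p0 + sgn * delta, floor_, 1 - floor_) else p0
      rejuv <- aging && runif(1) < config$frac_rejuvenated
      strength <- if (rejuv) {
        runif(1, config$rejuvenation_strength_range[1],
              config$rejuvenation_strength_range[2])
      } else NA_real_
      oskm <- if (rejuv) old - strength * (old - p0) else old
      d7 <- old
      if (config$include_d7) {
        if (rejuv && runif(1) < config$d7_retain_prob) {
          d7 <- oskm                             # established at d7, retained
        } else if (!rejuv && aging &&
                   runif(1) < config$d7_transient_prob) {
          d7 <- p0                               # transient: present d7, lost d21
        }
      }
      group_means <- c(young = p0, old = old, old_OSKM = oskm)
      if (config$include_d7) group_means <- c(group_means, old_OSKM_d7 = d7)

      jitter <- rnorm(n_cpg, 0, config$cpg_jitter_sd)   # once per CpG
      start <- i * 10000L
      pos <- start + sort(sample.int(2400L, n_cpg))
      n_samp <- nrow(samples)
      cov <- matrix(rnbinom(n_cpg * n_samp, mu = config$coverage_mean,
                            size = config$coverage_dispersion),
                    n_cpg, n_samp)
      lev <- clip(outer(jitter, group_means[samples$group], `+`), floor_, 1 - floor_)
      meth <- matrix(rbinom(n_cpg * n_samp, as.vector(cov), as.vector(lev)),
                     n_cpg, n_samp)
      list(
        cpgs = tibble::tibble(
          chrom = "chr1",
          pos = rep(pos, n_samp),
          region_id = sprintf("region_%04d", i),
          sample_id = rep(samples$sample_id, each = n_cpg),
          meth_reads = as.vector(meth),
          unmeth_reads = as.vector(cov - meth)),
        region = tibble::tibble(
          region_id = sprintf("region_%04d", i), chrom = "chr1",
          start = start, end = start + 2500L,
          kind = if (i %% 2 == 0) "enhancer" else "promoter",
          strand = "+", linked_gene = sprintf("gene_%04d", i)),
        truth = tibble::tibble(
          region_id = sprintf("region_%04d", i),
          aging_label = if (!aging) "none" else if (hyper) "hyper" else "hypo",
          rejuvenated = rejuv,
          planted_effect_pp = if (aging) 100 * (old - p0) else 0,
          rejuvenation_strength = strength,
          true_young = 100 * p0, true_old = 100 * old,
          true_oskm = 100 * oskm,
          true_d7 = if (config$include_d7) 100 * d7 else NA_real_,
          seed = config$seed))
    })
  }

  parts <- lapply(seq_len(config$n_regions), one_region)
  cpgs <- dplyr::bind_rows(lapply(parts, `[[`, "cpgs"))
  regions <- dplyr::bind_rows(lapply(parts, `[[`, "region"))
  truth <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  totals <- cpgs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total_reads = sum(.data$meth_reads + .data$unmeth_reads),
                     .groups = "drop")
  samples <- dplyr::left_join(samples, totals, by = "sample_id")
  list(cpgs = cpgs, regions = regions, samples = samples, truth = truth,
       config = config)
}
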