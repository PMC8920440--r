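#' Define promoter regions around transcription start sites
#'
#' Promoters span -2000 bp to +500 bp of the TSS, reflected for minus-strand
#' genes. Coordinates are 0-based, half-open throughout the package.
#'
#' @param tss A data frame with columns `chrom`, `pos` (0-based TSS
#'   coordinate), `strand` ("+" or "-") and `gene_id`.
#' @param upstream,downstream Window extents in bp (defaults 2000 and 500).
#' @return A tibble RegionSet: region_id, chrom, start, end (half-open),
#'   kind = "promoter", strand, linked_gene, truncated flag.
#' @details A plus-strand TSS t yields `[t - upstream, t + downstream)`;
#'   a minus-strand TSS t yields the strand-reflected window
#'   `[t - downstream + 1, t + upstream + 1)`. Windows running past the
#'   contig start are truncated at 0 with a warning.
#' @examples
#' define_promoters(data.frame(chrom = "chr1", pos = 10000,
#'                             strand = "+", gene_id = "g1"))
#' @export
define_promoters <- function(tss, upstream = 2000, downstream = 500) {
  tss <- tibble::as_tibble(tss)
  stopifnot(all(c("chrom", "pos", "strand", "gene_id") %in% names(tss)))
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$pos - upstream, tss$pos - downstream + 1)
  end <- ifelse(plus, tss$pos + downstream, tss$pos + upstream + 1)
  truncated <- start < 0
  if (any(truncated)) {
    warn(sprintf("%d promoter window(s) truncated at contig start.",
                 sum(truncated)))
    start[truncated] <- 0
  }
  tibble::tibble(
    region_id = paste0("prom_", tss$gene_id),
    chrom = tss$chrom,
    start = as.integer(start),
    end = as.integer(end),
    kind = "promoter",
    strand = tss$strand,
    linked_gene = tss$gene_id,
    truncated = truncated)
}

#' Classify H3K27ac peaks as enhancers and link them to nearby genes
#'
#' Peaks overlapping any promoter by >= 1 bp are removed; remaining peaks are
#' enhancers, linked to the nearest gene TSS within `max_link_dist`
#' (distance = minimal gap between the peak interval and the TSS; 0 if the
#' TSS lies inside the peak). Equidistant ties are broken toward the smaller
#' TSS coordinate and flagged.
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param promoters A promoter RegionSet from [define_promoters()].
#' @param genes Data frame with `chrom`, `pos` (TSS), `gene_id`.
#' @param max_link_dist Maximum linking distance in bp (default 1e6).
#' @return A tibble RegionSet: region_id, chrom, start, end,
#'   kind = "enhancer", strand = "*", linked_gene (NA when nothing within
#'   range), link_distance, link_tie flag.
#' @export
call_enhancers <- function(peaks, promoters, genes, max_link_dist = 1e6) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          kind = character(), strand = character(),
                          linked_gene = character(),
                          link_distance = numeric(), link_tie = logical()))
  }
  stopifnot(all(peaks$start < peaks$end))
  # drop peaks overlapping a promoter on the same chrom (half-open overlap)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    p <- promoters[promoters$chrom == peaks$chrom[i], , drop = FALSE]
    !any(p$start < peaks$end[i] & peaks$start[i] < p$end)
  }, logical(1))
  enh <- peaks[keep, , drop = FALSE]
  if (nrow(enh) == 0) {
    return(call_enhancers(enh, promoters, genes, max_link_dist))
  }
  genes <- tibble::as_tibble(genes)
  link <- purrr::map(seq_len(nrow(enh)), function(i) {
    g <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      return(list(gene = NA_character_, dist = NA_real_, tie = FALSE))
    }
    d <- pmax(0, pmax(enh$start[i] - g$pos, g$pos - (enh$end[i] - 1)))
    dmin <- min(d)
    cand <- which(d == dmin)
    tie <- length(cand) > 1
    pick <- cand[which.min(g$pos[cand])]
    if (dmin <= max_link_dist) {
      list(gene = g$gene_id[pick], dist = dmin, tie = tie)
    } else {
      list(gene = NA_character_, dist = dmin, tie = FALSE)
    }
  })
  tibble::tibble(
    region_id = sprintf("enh_%s_%d", enh$chrom, enh$start),
    chrom = enh$chrom,
    start = as.integer(enh$start),
    end = as.integer(enh$end),
    kind = "enhancer",
    strand = "*",
    linked_gene = purrr::map_chr(link, "gene"),
    link_distance = purrr::map_dbl(link, "dist"),
    link_tie = purrr::map_lgl(link, "tie"))
}

#' Aggregate per-CpG methylation counts to region-level methylation
#'
#' A CpG enters the analysis only if its coverage (meth + unmeth reads) is at
#' least `min_reads` in EVERY sample. The region value per sample is the
#' unweighted mean of the retained CpGs' percent methylation; per-sample
#' methylated/total counts summed over retained CpGs are carried along for
#' count-based differential testing. Regions with zero retained CpGs are
#' dropped and reported.
#'
#' @param cpgs Long tibble of per-CpG counts: `chrom`, `pos`, `sample_id`,
#'   `meth_reads`, `unmeth_reads` (as produced by [simulate_methylome()] or
#'   [read_bismark_cov()]).
#' @param regions RegionSet tibble (`region_id`, `chrom`, `start`, `end`);
#'   a CpG belongs to a region when `start <= pos < end` on the same chrom.
#' @param min_reads Minimum coverage in every sample (default 5).
#' @return A tibble of class `region_meth` (long): region_id, kind (if
#'   present), sample_id, mean_pct, meth_reads, total_reads, n_cpgs. Dropped
#'   regions are listed in `attr(, "dropped")`.
#' @export
aggregate_regions <- function(cpgs, regions, min_reads = 5) {
  cpgs <- tibble::as_tibble(cpgs)
  regions <- tibble::as_tibble(regions)
  samples <- unique(cpgs$sample_id)
  if (length(samples) == 0) abort("cpgs contains no samples.")

  cpgs <- cpgs |>
    dplyr::mutate(coverage = .data$meth_reads + .data$unmeth_reads)

  # coverage filter: >= min_reads in all samples at that site
  site_ok <- cpgs |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      ok = dplyr::n() == length(samples) && all(.data$coverage >= min_reads),
      .groups = "drop")
  kept <- cpgs |>
    dplyr::inner_join(dplyr::filter(site_ok, .data$ok),
                      by = c("chrom", "pos")) |>
    dplyr::mutate(pct = 100 * .data$meth_reads / .data$coverage)

  # assign CpGs to regions (interval join; half-open)
  if (!"region_id" %in% names(kept) ||
      !all(kept$region_id %in% regions$region_id)) {
    kept$region_id <- NULL
    assign_one <- function(chr, p) {
      hit <- which(regions$chrom == chr & regions$start <= p & p < regions$end)
      if (length(hit)) regions$region_id[hit[1]] else NA_character_
    }
    sites <- dplyr::distinct(kept, .data$chrom, .data$pos)
    sites$region_id <- purrr::map2_chr(sites$chrom, sites$pos, assign_one)
    kept <- dplyr::inner_join(kept, sites, by = c("chrom", "pos"))
  }
  kept <- dplyr::filter(kept, !is.na(.data$region_id))

  out <- kept |>
    dplyr::group_by(.data$region_id, .data$sample_id) |>
    dplyr::summarise(mean_pct = mean(.data$pct),
                     meth_reads = sum(.data$meth_reads),
                     total_reads = sum(.data$coverage),
                     n_cpgs = dplyr::n(),
                     .groups = "drop")
  dropped <- setdiff(regions$region_id, out$region_id)
  if ("kind" %in% names(regions)) {
    out <- dplyr::left_join(out, regions[, c("region_id", "kind")],
                            by = "region_id")
  }
  out <- structure(out, dropped = dropped, class = c("region_meth", class(out)))
  out
}

#' Region-level differential-methylation test between two groups
#'
#' Per region, a binomial GLM with logit link regresses the methylated
#' proportion on the group indicator using per-sample counts aggregated over
#' the region's retained CpGs; the raw p-value is a likelihood-ratio test.
#' The effect size `delta_pp` is the difference of group means of the region
#' percentage (group_b minus group_a, percentage points). A region is
#' significant when `p < p_threshold` and `|delta_pp| >= min_delta`
#' (defaults 0.05 and 10). A BH-adjusted column is emitted for information
#' only; significance uses the raw p.
#'
#' @param region_meth Output of [aggregate_regions()].
#' @param samples Sample sheet tibble with `sample_id` and `group`.
#' @param group_a,group_b Group labels to contrast (direction: b minus a;
#'   with `group_a = "young"`, `group_b = "old"`, "hyper" means
#'   hypermethylated with aging).
#' @param p_threshold,min_delta Significance thresholds.
#' @param quasi Use a quasi-binomial (overdispersion-robust) GLM with an
#'   F-based likelihood-ratio test instead of the plain binomial (default
#'   FALSE).
#' @return A tibble of class `rejuv_dm`: region_id, kind, delta_pp, p_raw,
#'   p_bh, direction ("hyper"/"hypo"), significant, degenerate flag,
#'   per-group means.
#' @examples
#' sim <- simulate_methylome(methyl_sim_config(n_regions = 30, seed = 5))
#' rm <- aggregate_regions(sim$cpgs, sim$regions)
#' dm <- dm_test(rm, sim$samples)
#' head(dm)
#' @export
dm_test <- function(region_meth, samples, group_a = "young", group_b = "old",
                    p_threshold = 0.05, min_delta = 10, quasi = FALSE) {
  samples <- tibble::as_tibble(samples)
  dat <- region_meth |>
    dplyr::inner_join(samples[, c("sample_id", "group")], by = "sample_id") |>
    dplyr::filter(.data$group %in% c(group_a, group_b))
  if (nrow(dat) == 0) abort("no samples in the requested groups.")
  ns <- dat |> dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(ns) < 2 || any(ns$n < 2)) {
    abort("need >= 2 samples in each of the two groups.")
  }

  fam <- if (quasi) stats::quasibinomial() else binomial()
  one <- function(d) {
    grp <- factor(d$group, levels = c(group_a, group_b))
    delta <- mean(d$mean_pct[grp == group_b]) - mean(d$mean_pct[grp == group_a])
    y <- cbind(d$meth_reads, d$total_reads - d$meth_reads)
    degenerate <- all(d$meth_reads == 0) || all(d$meth_reads == d$total_reads)
    if (degenerate) {
      p <- 1
    } else {
      fit <- suppressWarnings(glm(y ~ grp, family = fam))
      if (quasi) {
        fit0 <- suppressWarnings(glm(y ~ 1, family = fam))
        a <- anova(fit0, fit, test = "F")
        p <- a$`Pr(>F)`[2]
        if (is.na(p)) p <- 1
      } else {
        p <- pchisq(fit$null.deviance - fit$deviance, df = 1,
                    lower.tail = FALSE)
      }
    }
    tibble::tibble(
      delta_pp = delta,
      p_raw = p,
      direction = if (delta >= 0) "hyper" else "hypo",
      degenerate = degenerate,
      mean_a = mean(d$mean_pct[grp == group_a]),
      mean_b = mean(d$mean_pct[grp == group_b]))
  }
  res <- dat |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  if ("kind" %in% names(region_meth)) {
    res <- dplyr::left_join(
      res, dplyr::distinct(region_meth, .data$region_id, .data$kind),
      by = "region_id")
  }
  res <- res |>
    dplyr::mutate(
      p_bh = p.adjust(.data$p_raw, "BH"),
      significant = .data$p_raw < p_threshold &
        abs(.data$delta_pp) >= min_delta)
  names(res)[names(res) == "mean_a"] <- paste0("mean_", group_a)
  names(res)[names(res) == "mean_b"] <- paste0("mean_", group_b)
  structure(res, class = c("rejuv_dm", class(res)),
            group_a = group_a, group_b = group_b,
            p_threshold = p_threshold, min_delta = min_delta)
}
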