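test_that("promoter windows follow the strand-reflected TSS convention", {
  tss <- tibble::tibble(chrom = "chr1", pos = c(10000, 10000, 1500),
                        strand = c("+", "-", "+"),
                        gene_id = c("gA", "gB", "gC"))
  pr <- suppressWarnings(define_promoters(tss))
  expect_equal(pr$start, c(8000L, 9501L, 0L))
  expect_equal(pr$end, c(10500L, 12001L, 2000L))
  expect_true(all(pr$end - pr$start == 2500L | pr$truncated))
  expect_equal(pr$truncated, c(FALSE, FALSE, TRUE))
  expect_warning(define_promoters(tss), "truncated")
})

test_that("enhancer calling removes promoter overlaps and links by distance", {
  pr <- define_promoters(tibble::tibble(chrom = "chr1", pos = 10000,
                                        strand = "+", gene_id = "gA"))
  genes <- tibble::tibble(chrom = "chr1",
                          pos = c(10000, 950000, 2200000),
                          gene_id = c("gA", "gB", "gC"))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(8100, 50000, 1e6 + 50000, 3.4e6),
                          end = c(8300, 50200, 1e6 + 50200, 3.4e6 + 200))
  enh <- call_enhancers(peaks, pr, genes)
  # first peak overlaps the promoter [8000, 10500) -> excluded
  expect_equal(nrow(enh), 3)
  expect_equal(enh$linked_gene[1], "gA")        # 50000 is ~40 kb from gA TSS
  expect_equal(enh$linked_gene[2], "gB")
  expect_true(is.na(enh$linked_gene[3]))        # > 1 Mb from every TSS
  expect_true(all(enh$kind == "enhancer"))
  expect_equal(nrow(call_enhancers(peaks[0, ], pr, genes)), 0)
})

test_that("equidistant gene ties break to the smaller coordinate, flagged, and match brute force", {
  pr <- suppressWarnings(
    define_promoters(tibble::tibble(chrom = "chr1", pos = 1,
                                    strand = "+", gene_id = "far")))[0, ]
  set.seed(5)
  genes <- tibble::tibble(chrom = "chr1",
                          pos = sort(sample.int(5e5, 40)),
                          gene_id = paste0("g", 1:40))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = sort(sample.int(5e5, 25)))
  peaks$end <- peaks$start + 200
  enh <- call_enhancers(peaks, pr, genes)
  brute <- vapply(seq_len(nrow(peaks)), function(i) {
    d <- pmax(0, pmax(peaks$start[i] - genes$pos,
                      genes$pos - (peaks$end[i] - 1)))
    cand <- which(d == min(d))
    genes$gene_id[cand[which.min(genes$pos[cand])]]
  }, character(1))
  expect_equal(enh$linked_gene, brute)
  # constructed exact tie: gene TSS 100 bp left and right of the peak
  tie <- call_enhancers(
    tibble::tibble(chrom = "chr2", start = 1000, end = 1200),
    pr, tibble::tibble(chrom = "chr2", pos = c(900, 1299),
                       gene_id = c("left", "right")))
  expect_true(tie$link_tie)
  expect_equal(tie$linked_gene, "left")
})

test_that("the coverage filter requires min_reads in every sample", {
  cov <- rbind(c(5, 5, 5), c(5, 4, 5), c(9, 9, 9))
  meth <- rbind(c(5, 0, 5), c(5, 4, 0), c(0, 9, 9))
  cpgs <- cpg_table(meth, cov)
  regions <- tibble::tibble(region_id = "r1", chrom = "chr1",
                            start = 0L, end = 100L)
  rm <- aggregate_regions(cpgs, regions, min_reads = 5)
  expect_equal(unique(rm$n_cpgs), 2L)            # site 2 dropped (coverage 4)
  # region value = unweighted mean of retained CpG percentages
  expect_equal(rm$mean_pct[rm$sample_id == "s1"], mean(c(100, 0)))
  expect_equal(rm$mean_pct[rm$sample_id == "s2"], mean(c(0, 100)))
})

test_that("region aggregation equals a brute-force oracle on random tables", {
  set.seed(11)
  n_site <- 60; n_samp <- 4
  cov <- matrix(rpois(n_site * n_samp, 12), n_site, n_samp)
  meth <- matrix(rbinom(n_site * n_samp, as.vector(cov), 0.4), n_site, n_samp)
  pos <- sort(sample.int(3000, n_site))
  cpgs <- cpg_table(meth, cov, pos = pos)
  regions <- tibble::tibble(region_id = paste0("r", 1:6), chrom = "chr1",
                            start = seq(0, 2500, by = 500),
                            end = seq(500, 3000, by = 500))
  rm <- aggregate_regions(cpgs, regions, min_reads = 5)
  keep <- apply(cov >= 5, 1, all)
  for (r in seq_len(6)) {
    inside <- keep & pos >= regions$start[r] & pos < regions$end[r]
    if (!any(inside)) {
      expect_false(regions$region_id[r] %in% rm$region_id)
      next
    }
    for (s in seq_len(n_samp)) {
      got <- rm$mean_pct[rm$region_id == regions$region_id[r] &
                           rm$sample_id == paste0("s", s)]
      expect_equal(got, mean(100 * meth[inside, s] / cov[inside, s]))
    }
  }
  # permutation invariance in row order
  rm2 <- aggregate_regions(cpgs[sample(nrow(cpgs)), ], regions, min_reads = 5)
  expect_equal(dplyr::arrange(as.data.frame(rm), region_id, sample_id),
               dplyr::arrange(as.data.frame(rm2), region_id, sample_id))
})

test_that("dm_test applies the p and 10-point rules and flags degenerate regions", {
  mk <- function(meth, tot, pct) tibble::tibble(
    region_id = "r", sample_id = paste0("s", seq_along(meth)),
    mean_pct = pct, meth_reads = meth, total_reads = tot)
  samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                            group = rep(c("young", "old"), each = 3))
  # maximal separation: young all methylated, old none
  dm <- dm_test(mk(c(20, 20, 20, 0, 0, 0), rep(20, 6),
                   c(100, 100, 100, 0, 0, 0)), samples)
  expect_equal(dm$delta_pp, -100)
  expect_lt(dm$p_raw, 0.05)
  expect_true(dm$significant)
  expect_equal(dm$direction, "hypo")
  # identical groups: null
  dm0 <- dm_test(mk(rep(10, 6), rep(20, 6), rep(50, 6)), samples)
  expect_equal(dm0$delta_pp, 0)
  expect_false(dm0$significant)
  # all-zero in both groups: degenerate, p = 1
  dmz <- dm_test(mk(rep(0, 6), rep(20, 6), rep(0, 6)), samples)
  expect_true(dmz$degenerate)
  expect_equal(dmz$p_raw, 1)
  # significant requires BOTH small p and >= 10 pp
  near <- mk(c(52, 53, 54, 40, 41, 42), rep(100, 6),
             c(52, 53, 54, 40, 41, 42))
  dm_n <- dm_test(near, samples, min_delta = 10)
  expect_equal(dm_n$significant,
               dm_n$p_raw < 0.05 && abs(dm_n$delta_pp) >= 10)
  expect_true(dm_n$significant)
  dm_h <- dm_test(near, samples, min_delta = 15)
  expect_false(dm_h$significant)                # same p, stricter delta rule
})

test_that("delta flips sign and p is unchanged under group swap", {
  sim <- simulate_methylome(methyl_sim_config(n_regions = 15, seed = 9))
  rm <- aggregate_regions(sim$cpgs, sim$regions)
  a <- dm_test(rm, sim$samples, group_a = "young", group_b = "old")
  b <- dm_test(rm, sim$samples, group_a = "old", group_b = "young")
  expect_equal(a$delta_pp, -b$delta_pp)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-10)
})
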