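# Shared fixtures built in code.

three_groups <- function(n = 5) rep(c("young", "old", "old_OSKM"), each = n)

# Features x samples matrix with one planted pattern per feature (offsets
# `effect * c(0, 1, -1)` by cluster, cluster 1 holding the young group).
plant_pattern_matrix <- function(labels, groups, effect = 3, sigma = 1,
                                 baseline_sd = 0, seed = 1) {
  pats <- enumerate_patterns(unique(groups))
  set.seed(seed)
  m <- t(vapply(labels, function(k) {
    cl <- pats$cluster[[k]]
    offs <- effect * c(0, 1, -1)[seq_len(max(cl))]
    rnorm(1, 0, baseline_sd) + offs[cl[groups]] +
      rnorm(length(groups), 0, sigma)
  }, numeric(length(groups))))
  rownames(m) <- paste0("f", seq_along(labels))
  m
}

# Long per-CpG count table from explicit count matrices (sites x samples).
cpg_table <- function(meth, cov, chrom = "chr1", pos = NULL) {
  n_site <- nrow(meth); n_samp <- ncol(meth)
  pos <- pos %||% (seq_len(n_site) * 10L)
  tibble::tibble(
    chrom = chrom,
    pos = rep(pos, n_samp),
    sample_id = rep(paste0("s", seq_len(n_samp)), each = n_site),
    meth_reads = as.vector(meth),
    unmeth_reads = as.vector(cov - meth))
}

`%||%` <- rlang::`%||%`
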