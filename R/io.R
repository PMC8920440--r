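# Readers/writers for the small text formats the pipeline consumes and
# emits. Internal coordinates are 0-based half-open; the bisulfite coverage
# format is 1-based inclusive and is converted on read/write.

#' Read bisulfite coverage files
#'
#' Reads one 6-column coverage file per sample (chrom, start, end,
#' percent_methylation, count_methylated, count_unmethylated; 1-based
#' inclusive positions, as written by bisulfite methylation extractors) into
#' the package's long per-CpG table (0-based `pos`).
#'
#' @param files Character vector of file paths.
#' @param sample_ids Sample names (default: file base names).
#' @return Long tibble: chrom, pos, sample_id, meth_reads, unmeth_reads.
#' @export
read_bismark_cov <- function(files, sample_ids = NULL) {
  sample_ids <- sample_ids %||% sub("\\.(cov|txt|tsv)(\\.gz)?$", "",
                                    basename(files))
  purrr::map2(files, sample_ids, function(f, s) {
    x <- readr::read_tsv(f, col_names = c("chrom", "start", "end", "percent",
                                          "meth_reads", "unmeth_reads"),
                         col_types = "ciinii", progress = FALSE)
    tibble::tibble(chrom = x$chrom, pos = x$start - 1L, sample_id = s,
                   meth_reads = x$meth_reads, unmeth_reads = x$unmeth_reads)
  }) |> dplyr::bind_rows()
}

#' Write bisulfite coverage files (one per sample)
#'
#' @param cpgs Long per-CpG tibble (chrom, pos, sample_id, meth_reads,
#'   unmeth_reads).
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_bismark_cov <- function(cpgs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(cpgs, cpgs$sample_id), function(d) {
    cov <- d$meth_reads + d$unmeth_reads
    out <- tibble::tibble(
      chrom = d$chrom, start = d$pos + 1L, end = d$pos + 1L,
      percent = ifelse(cov > 0, 100 * d$meth_reads / cov, NA_real_),
      meth = d$meth_reads, unmeth = d$unmeth_reads)
    p <- file.path(dir, paste0(d$sample_id[1], ".cov"))
    readr::write_tsv(out, p, col_names = FALSE, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a BED file of intervals
#'
#' @param file Path to a 3+ column BED file (0-based half-open, headerless).
#' @return Tibble: chrom, start, end, and name/score/strand when present.
#' @export
read_bed <- function(file) {
  x <- readr::read_tsv(file, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"),
                       comment = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(min(ncol(x), 6))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  tibble::as_tibble(x)
}

#' Write a RegionSet (or any interval tibble) as BED
#'
#' @param regions Tibble with chrom, start, end; `region_id`/`name`, `kind`
#'   and `linked_gene` are packed into the BED name column when present.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_bed <- function(regions, file) {
  name <- regions$region_id %||% regions$name %||% "."
  extra <- c()
  if (!is.null(regions$kind)) extra <- paste0(extra, regions$kind)
  if (!is.null(regions$linked_gene)) {
    extra <- paste0(extra, ifelse(nzchar(extra), ";", ""),
                    ifelse(is.na(regions$linked_gene), "NA",
                           regions$linked_gene))
  }
  if (length(extra)) name <- paste0(name, "|", extra)
  out <- tibble::tibble(chrom = regions$chrom, start = regions$start,
                        end = regions$end, name = name)
  readr::write_tsv(out, file, col_names = FALSE, progress = FALSE)
  invisible(file)
}

#' Read a GMT gene-set collection
#'
#' @param file Path to a GMT file (set name, description, member genes,
#'   tab-separated).
#' @return Long tibble: set_id, gene_id.
#' @export
read_gmt <- function(file) {
  sets <- fgsea::gmtPathways(file)
  tibble::tibble(set_id = rep(names(sets), lengths(sets)),
                 gene_id = unlist(sets, use.names = FALSE))
}

#' Write gene sets as GMT
#'
#' @param gene_sets Named list or long tibble (set_id, gene_id).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_gmt <- function(gene_sets, file) {
  sets <- as_gene_set_list(gene_sets)
  lines <- vapply(names(sets), function(s)
    paste(c(s, s, sets[[s]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}
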