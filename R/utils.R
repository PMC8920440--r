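# Internal helpers shared across modules.

# Clip numeric vector into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-feature sub-seed: adding features must not perturb the
# streams of earlier ones, so each feature gets its own arithmetic seed
# derived from the master seed (kept below .Machine$integer.max).
feature_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Run code with a locally-set RNG seed, restoring the global state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Coerce a genes-x-samples input (matrix or data frame with an id column)
# to a numeric matrix with rownames; returns list(mat, ids).
as_feature_matrix <- function(x, id_col = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
    return(x)
  }
  x <- as.data.frame(x)
  if (is.null(id_col)) {
    chr <- vapply(x, is.character, logical(1)) | vapply(x, is.factor, logical(1))
    id_col <- if (any(chr)) names(x)[which(chr)[1]] else NULL
  }
  if (!is.null(id_col)) {
    ids <- as.character(x[[id_col]])
    x[[id_col]] <- NULL
  } else {
    ids <- paste0("f", seq_len(nrow(x)))
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Standardise a gene-set input (named list of character vectors, or a long
# tibble with set/gene columns) to a named list.
as_gene_set_list <- function(gene_sets) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    if (is.null(names(gene_sets))) {
      names(gene_sets) <- paste0("set", seq_along(gene_sets))
    }
    return(lapply(gene_sets, as.character))
  }
  df <- as.data.frame(gene_sets)
  set_col <- intersect(c("set_id", "set", "pathway"), names(df))[1]
  gene_col <- intersect(c("gene_id", "gene"), names(df))[1]
  if (is.na(set_col) || is.na(gene_col)) {
    abort("gene_sets must be a named list or a data frame with set_id/gene_id columns.")
  }
  split(as.character(df[[gene_col]]), df[[set_col]])
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a proportion in [0, 1].", name))
  }
  invisible(x)
}
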