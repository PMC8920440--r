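#' Nearest-mean rejuvenation classification
#'
#' A feature (region, gene, score...) counts as rejuvenated when the treated
#' old group's mean is strictly closer to the young mean than to the old
#' mean: `|oskm - young| < |oskm - old|`. Exact ties are not rejuvenated and
#' flagged; features with no aging gap (young == old) are flagged
#' `no_aging_gap` and not rejuvenated. The rule is purely metric, so
#' overshoot beyond the young mean still counts as rejuvenated; such features
#' are flagged `overshoot` for inspection.
#'
#' @param data A data frame with one row per feature, or `NULL` to use the
#'   bare numeric vectors below.
#' @param young,old,oskm Column names (tidy usage) or numeric vectors (when
#'   `data` is NULL) holding the three group means on a common scale.
#' @param feature_id Optional column name / vector of feature ids.
#' @return A tibble: feature_id, young_mean, old_mean, oskm_mean,
#'   aging_direction, distance_to_young, distance_to_old, rejuvenated, tie,
#'   no_aging_gap, overshoot.
#' @examples
#' classify_rejuvenated(young = 30, old = 60, oskm = 40)$rejuvenated
#' @export
classify_rejuvenated <- function(data = NULL, young = "young", old = "old",
                                 oskm = "oskm", feature_id = NULL) {
  if (is.null(data)) {
    y <- young; o <- old; k <- oskm
    ids <- feature_id %||% paste0("f", seq_along(y))
  } else {
    y <- data[[young]]; o <- data[[old]]; k <- data[[oskm]]
    ids <- if (!is.null(feature_id)) data[[feature_id]] else
      paste0("f", seq_len(nrow(data)))
  }
  dy <- abs(k - y)
  do <- abs(k - o)
  no_gap <- y == o
  tie <- !no_gap & dy == do
  tibble::tibble(
    feature_id = as.character(ids),
    young_mean = y, old_mean = o, oskm_mean = k,
    aging_direction = dplyr::case_when(no_gap ~ NA_character_,
                                       o > y ~ "hyper", TRUE ~ "hypo"),
    distance_to_young = dy,
    distance_to_old = do,
    rejuvenated = !no_gap & dy < do,
    tie = tie,
    no_aging_gap = no_gap,
    overshoot = !no_gap & dy < do & ((o > y & k < y) | (o < y & k > y)))
}

#' Temporal classification of treatment-induced methylation changes
#'
#' Applies the nearest-mean rejuvenation predicate at the end of induction
#' (d7) and after recovery (d21) and combines the two outcomes:
#' (TRUE, TRUE) -> `established_d7_retained`; (TRUE, FALSE) ->
#' `established_d7_lost`; (FALSE, TRUE) -> `acquired_in_recovery`;
#' (FALSE, FALSE) -> `never`.
#'
#' @inheritParams classify_rejuvenated
#' @param d7,d21 Column names / numeric vectors of the treated-group means at
#'   day 7 and day 21.
#' @return A tibble: feature_id, class, the four means, flags from both calls.
#' @examples
#' classify_temporal(young = 30, old = 60, d7 = 58, d21 = 38)$class
#' @export
classify_temporal <- function(data = NULL, young = "young", old = "old",
                              d7 = "d7", d21 = "d21", feature_id = NULL) {
  if (is.null(data)) {
    y <- young; o <- old; m7 <- d7; m21 <- d21
    ids <- feature_id %||% paste0("f", seq_along(y))
  } else {
    y <- data[[young]]; o <- data[[old]]
    m7 <- data[[d7]]; m21 <- data[[d21]]
    ids <- if (!is.null(feature_id)) data[[feature_id]] else
      paste0("f", seq_len(nrow(data)))
  }
  at7 <- classify_rejuvenated(young = y, old = o, oskm = m7)
  at21 <- classify_rejuvenated(young = y, old = o, oskm = m21)
  cls <- dplyr::case_when(
    at7$rejuvenated & at21$rejuvenated ~ "established_d7_retained",
    at7$rejuvenated & !at21$rejuvenated ~ "established_d7_lost",
    !at7$rejuvenated & at21$rejuvenated ~ "acquired_in_recovery",
    TRUE ~ "never")
  tibble::tibble(
    feature_id = as.character(ids),
    class = factor(cls, levels = c("established_d7_retained",
                                   "established_d7_lost",
                                   "acquired_in_recovery", "never")),
    young_mean = y, old_mean = o, d7_mean = m7, d21_mean = m21,
    no_aging_gap = at7$no_aging_gap,
    tie_d7 = at7$tie, tie_d21 = at21$tie)
}

#' PCA of samples on aging-affected features
#'
#' Centers features (optionally unit-scales them), drops zero-variance
#' features with a warning, and projects samples onto the principal
#' components of the feature covariance.
#'
#' @param mat Features x samples numeric matrix (or data frame with a feature
#'   id column).
#' @param groups Optional per-sample group labels carried into the scores.
#' @param scale. Unit-scale features before decomposition (default FALSE).
#' @return A tibble of class `rejuv_pca` with sample_id, group and PC score
#'   columns; explained-variance fractions in `attr(, "explained")`.
#' @export
pca_aging_features <- function(mat, groups = NULL, scale. = FALSE) {
  m <- as_feature_matrix(mat)
  if (nrow(m) < 2 || ncol(m) < 3) abort("need >= 2 features and >= 3 samples.")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(sprintf("dropping %d zero-variance feature(s).", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) == 0) {
    sc <- matrix(0, ncol(mat), 1, dimnames = list(NULL, "PC1"))
    ev <- 0
  } else {
    pc <- prcomp(t(m), center = TRUE, scale. = scale.)
    sc <- pc$x
    tot <- sum(pc$sdev^2)
    ev <- if (tot > 0) pc$sdev^2 / max(tot, .Machine$double.eps) else
      rep(0, length(pc$sdev))
    if (tot == 0) sc[] <- 0
  }
  out <- tibble::as_tibble(sc)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(m) %||% paste0("s", seq_len(nrow(out)))),
    out)
  if (!is.null(groups)) out$group <- groups
  structure(out, explained = ev, class = c("rejuv_pca", class(out)))
}

#' Summarize rejuvenation calls over significant differentially-methylated regions
#'
#' Counts and fractions of rejuvenated regions by kind (promoter/enhancer)
#' and aging direction - e.g. hypermethylated-with-aging regions demethylated
#' by treatment - plus the overall fraction and tie/no-gap tallies, in the
#' shape of the headline "x out of n reversed toward a younger state"
#' summaries.
#'
#' @param dm A [dm_test()] result (only `significant` rows are summarized).
#' @param calls A [classify_rejuvenated()] tibble whose `feature_id` matches
#'   `dm$region_id`.
#' @return A list with `by_class` (tibble kind x direction: n, n_rejuvenated,
#'   fraction), `overall` (one-row tibble) and `flags` (ties, no-gap counts).
#' @export
summarize_rejuvenation <- function(dm, calls) {
  sig <- dm[dm$significant, , drop = FALSE]
  if (!"kind" %in% names(sig)) sig$kind <- "region"
  merged <- dplyr::inner_join(
    tibble::as_tibble(sig)[, c("region_id", "kind", "direction")],
    calls, by = c(region_id = "feature_id"))
  by_class <- merged |>
    dplyr::group_by(.data$kind, .data$direction) |>
    dplyr::summarise(n = dplyr::n(),
                     n_rejuvenated = sum(.data$rejuvenated),
                     fraction = ifelse(dplyr::n() > 0,
                                       sum(.data$rejuvenated) / dplyr::n(), NA),
                     .groups = "drop")
  overall <- tibble::tibble(
    n = nrow(merged),
    n_rejuvenated = sum(merged$rejuvenated),
    fraction = if (nrow(merged) > 0) sum(merged$rejuvenated) / nrow(merged)
               else NA_real_)
  flags <- tibble::tibble(
    n_tie = sum(merged$tie),
    n_no_aging_gap = sum(merged$no_aging_gap),
    n_overshoot = sum(merged$overshoot))
  list(by_class = by_class, overall = overall, flags = flags)
}
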