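# ggplot2 surfaces for the main result types.

#' Plot sample scores from a PCA of aging features
#'
#' @param object A [pca_aging_features()] result.
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2 (or PC1 vs sample index when only one
#'   component exists), colored by group when available.
#' @export
autoplot.rejuv_pca <- function(object, ...) {
  ev <- attr(object, "explained")
  lab <- function(i) sprintf("PC%d (%.0f%%)", i, 100 * ev[i])
  has_pc2 <- "PC2" %in% names(object)
  p <- if (has_pc2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = seq_len(nrow(object)),
                                         y = .data$PC1))
  }
  if ("group" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::labs(x = lab(1), y = if (has_pc2) lab(2) else "PC1") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of region differential methylation
#'
#' @param object A [dm_test()] result.
#' @param ... Unused.
#' @return A ggplot of delta (percentage points) vs -log10 raw p, with the
#'   significance thresholds drawn and significant regions highlighted.
#' @export
autoplot.rejuv_dm <- function(object, ...) {
  thr_p <- attr(object, "p_threshold") %||% 0.05
  thr_d <- attr(object, "min_delta") %||% 10
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_pp,
                                       y = -log10(pmax(.data$p_raw, 1e-300)),
                                       color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-thr_d, thr_d), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(thr_p), linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "methylation difference (percentage points)",
                  y = "-log10 raw p") +
    ggplot2::theme_minimal()
}

#' Plot a GSEA-style running enrichment curve
#'
#' @param ks A [ks_running_score()] result.
#' @param title Optional plot title (e.g. the set name).
#' @return A ggplot of the running score with member positions marked.
#' @export
plot_enrichment_curve <- function(ks, title = NULL) {
  ggplot2::ggplot(ks$curve, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = ks$curve[ks$curve$member, ], sides = "b",
                      alpha = 0.5) +
    ggplot2::labs(x = "gene rank", y = "running enrichment score",
                  title = title,
                  subtitle = sprintf("extremum = %.3f", ks$statistic)) +
    ggplot2::theme_minimal()
}

#' Plot per-group signature scores for selected gene sets
#'
#' @param scores A [signature_scores()] tibble.
#' @param sets Set ids to display (default: first 6).
#' @param adjusted Plot globally-adjusted scores (default TRUE).
#' @return A ggplot: per-sample scores by group, faceted by set.
#' @export
plot_signature_scores <- function(scores, sets = NULL, adjusted = TRUE) {
  sets <- sets %||% head(unique(scores$set_id), 6)
  d <- scores[scores$set_id %in% sets, , drop = FALSE]
  val <- if (adjusted) "adjusted_score" else "score"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[val]],
                                  color = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::facet_wrap(~ set_id, scales = "free_y") +
    ggplot2::labs(y = if (adjusted) "adjusted signature score (z-units)"
                  else "signature score (z-units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a methylation-clock fit
#'
#' @param x A [clock_fit()] object.
#' @param ... Unused.
#' @return A ggplot of methylation vs age with the OLS line.
#' @export
plot.clock_fit <- function(x, ...) {
  ggplot2::ggplot(x$points, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         color = "firebrick") +
    ggplot2::labs(x = "age (weeks)", y = "methylation (%)",
                  subtitle = sprintf("slope %.3f pp/week, r = %.3f",
                                     x$slope, x$r)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
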