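# broom-style tidiers for the package's fitted objects.

#' Tidy a Normal-Normal pattern-model fit
#'
#' @param x An [fit_nn_model()] object.
#' @param ... Unused.
#' @return Long tibble: feature_id, pattern_id, pattern (label), posterior.
#' @export
tidy.nn_fit <- function(x, ...) {
  x$posterior |>
    tidyr::pivot_longer(dplyr::starts_with("pattern_"),
                        names_to = "pattern_id", values_to = "posterior",
                        names_prefix = "pattern_") |>
    dplyr::mutate(pattern_id = as.integer(.data$pattern_id)) |>
    dplyr::left_join(x$patterns[, c("pattern_id", "label")],
                     by = "pattern_id") |>
    dplyr::rename(pattern = "label")
}

#' Glance at a Normal-Normal pattern-model fit
#'
#' @param x An [fit_nn_model()] object.
#' @param ... Unused.
#' @return One-row tibble: mu0, tau2, the pattern prior probabilities,
#'   n_features, n_iter, log_lik, converged.
#' @export
glance.nn_fit <- function(x, ...) {
  pri <- setNames(as.list(x$pi), paste0("pi_", seq_along(x$pi)))
  dplyr::bind_cols(
    tibble::tibble(mu0 = x$mu0, tau2 = x$tau2),
    tibble::as_tibble(pri),
    tibble::tibble(n_features = nrow(x$posterior),
                   n_iter = length(x$log_lik_trace),
                   log_lik = x$log_lik_trace[length(x$log_lik_trace)],
                   converged = x$converged))
}

#' Tidy a methylation-clock fit
#'
#' @param x A [clock_fit()] object.
#' @param ... Unused.
#' @return Tibble with term/estimate rows (intercept and slope).
#' @export
tidy.clock_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "age"),
                 estimate = c(x$intercept, x$slope))
}

#' Glance at a methylation-clock fit
#'
#' @param x A [clock_fit()] object.
#' @param ... Unused.
#' @return One-row tibble: slope, intercept, r, r_squared, n, zero_residual.
#' @export
glance.clock_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r_squared = x$r_squared, n = x$n,
                 zero_residual = x$zero_residual)
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf(
    "Methylation clock fit: %d animals\n  slope: %.4f pp/week  intercept: %.2f  r: %s\n",
    x$n, x$slope, x$intercept,
    if (is.na(x$r)) "undefined (zero residuals)" else sprintf("%.3f", x$r)))
  invisible(x)
}

#' @export
print.nn_fit <- function(x, ...) {
  cat(sprintf(
    "Normal-Normal pattern model: %d features, %d patterns\n  mu0 = %.3f, tau2 = %.4f, %s after %d EM iterations\n  pattern priors: %s\n",
    nrow(x$posterior), nrow(x$patterns), x$mu0, x$tau2,
    if (x$converged) "converged" else "NOT converged",
    length(x$log_lik_trace),
    paste(sprintf("%.3f", x$pi), collapse = " ")))
  invisible(x)
}
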