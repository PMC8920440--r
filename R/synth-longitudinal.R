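#' Simulate a paired pre/post longitudinal dataset
#'
#' Two rows (pre, post) per subject; given the subject's random intercept the
#' post-minus-pre change is Normal(group delta, within_sd * sqrt(2)). The
#' default scenario mirrors a paired blood-methylation design: control
#' subjects drift by +4 units over the interval while treated subjects move
#' by -4 units, a total between-group difference of 8.
#'
#' @param n_subjects Subjects per group (>= 2); recycled over `groups`.
#' @param delta Named numeric vector of true post-minus-pre changes per group.
#' @param between_sd Between-subject SD of the baseline.
#' @param within_sd Within-subject (measurement) SD; 0 gives exact deltas.
#' @param baseline_mean Mean baseline value.
#' @param groups Group labels (defaults to the names of `delta`).
#' @param seed Integer seed.
#' @return A list with `data` (tibble subject_id, group, timepoint, value) and
#'   `truth` (group, true_delta, seed).
#' @examples
#' sim <- simulate_longitudinal(n_subjects = 4, within_sd = 0, seed = 1)
#' delta_change(sim$data)
#' @export
simulate_longitudinal <- function(n_subjects = 6,
                                  delta = c(control = 4, treated = -4),
                                  between_sd = 3,
                                  within_sd = 1,
                                  baseline_mean = 50,
                                  groups = names(delta),
                                  seed = 1) {
  if (any(rep_len(n_subjects, length(groups)) < 2)) {
    abort("n_subjects must be >= 2 per group (no test possible otherwise).")
  }
  n_subjects <- rep_len(n_subjects, length(groups))
  with_seed(seed, {
    rows <- purrr::map2(groups, n_subjects, function(g, n) {
      b <- rnorm(n, 0, between_sd)
      pre <- baseline_mean + b + rnorm(n, 0, within_sd)
      post <- baseline_mean + b + delta[[g]] + rnorm(n, 0, within_sd)
      tibble::tibble(
        subject_id = paste0(g, "_s", seq_len(n)),
        group = g,
        pre = pre, post = post)
    })
    data <- dplyr::bind_rows(rows) |>
      tidyr::pivot_longer(c("pre", "post"), names_to = "timepoint",
                          values_to = "value") |>
      dplyr::mutate(timepoint = factor(.data$timepoint, c("pre", "post")))
    truth <- tibble::tibble(group = groups,
                            true_delta = unname(delta[groups]),
                            seed = seed)
    list(data = data, truth = truth)
  })
}
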