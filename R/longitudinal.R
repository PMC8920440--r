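#' Per-subject post-minus-pre change
#'
#' @param data Long tibble with `subject_id`, `timepoint` ("pre"/"post"),
#'   `value`, and optionally `group` (carried through). Each
#'   (subject, timepoint) may appear at most once.
#' @return A tibble: subject_id, group (if present), pre, post,
#'   delta = post - pre. Subjects missing a timepoint are listed in
#'   `attr(, "incomplete")` and excluded.
#' @examples
#' d <- data.frame(subject_id = c("s1", "s1"), timepoint = c("pre", "post"),
#'                 value = c(50, 46))
#' delta_change(d)$delta  # -4
#' @export
delta_change <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("subject_id", "timepoint", "value") %in% names(data)))
  data$timepoint <- as.character(data$timepoint)
  if (!all(data$timepoint %in% c("pre", "post"))) {
    abort("timepoint must be 'pre' or 'post'.")
  }
  if (any(duplicated(data[, c("subject_id", "timepoint")]))) {
    abort("duplicate (subject, timepoint) rows.")
  }
  keep <- intersect(c("subject_id", "group"), names(data))
  wide <- tidyr::pivot_wider(data[, c(keep, "timepoint", "value")],
                             names_from = "timepoint", values_from = "value")
  if (!"pre" %in% names(wide)) wide$pre <- NA_real_
  if (!"post" %in% names(wide)) wide$post <- NA_real_
  incomplete <- wide$subject_id[is.na(wide$pre) | is.na(wide$post)]
  out <- wide[!wide$subject_id %in% incomplete, , drop = FALSE]
  if (nrow(out) == 0) abort("no subject has both timepoints.")
  out$delta <- out$post - out$pre
  structure(out, incomplete = incomplete)
}

#' Compare longitudinal changes between or within groups
#'
#' `method = "mann_whitney"` compares delta between two groups with the
#' Mann-Whitney / Wilcoxon rank-sum test. For small samples (combined n <=
#' 18) the p-value is exact by full enumeration of the rank-sum permutation
#' distribution, with ties handled by mid-ranks and the two-sided p obtained
#' by doubling the smaller tail; larger samples use the standard normal
#' approximation. `method = "auto_paired_t"`
#' tests mean delta = 0 within one group with a paired t, gated on normality:
#' if Shapiro-Wilk rejects at `shapiro_alpha` the Wilcoxon signed-rank test
#' is used instead and flagged.
#'
#' @param deltas A [delta_change()] tibble (needs `group` for the
#'   between-group method).
#' @param method "mann_whitney" or "auto_paired_t".
#' @param groups For "mann_whitney": the two group labels to compare
#'   (default: the two groups present).
#' @param shapiro_alpha Normality-gate level (default 0.05).
#' @return A one-row tibble: method, statistic, p_value, n (per group),
#'   fallback flag (signed-rank used), degenerate flag (all values tied).
#' @export
compare_groups <- function(deltas, method = c("mann_whitney", "auto_paired_t"),
                           groups = NULL, shapiro_alpha = 0.05) {
  method <- match.arg(method)
  d <- tibble::as_tibble(deltas)
  if (method == "mann_whitney") {
    if (!"group" %in% names(d)) abort("mann_whitney needs a `group` column.")
    groups <- groups %||% unique(d$group)
    if (length(groups) != 2) abort("mann_whitney compares exactly two groups.")
    x <- d$delta[d$group == groups[1]]
    y <- d$delta[d$group == groups[2]]
    if (length(x) < 2 || length(y) < 2) abort("need >= 2 deltas per group.")
    if (length(unique(c(x, y))) == 1) {
      return(tibble::tibble(method = method, statistic = NA_real_,
                            p_value = 1, n = length(x) + length(y),
                            fallback = FALSE, degenerate = TRUE))
    }
    n <- length(x) + length(y)
    nx <- length(x)
    if (n <= 18) {
      # exact enumeration of the rank-sum permutation distribution
      r <- rank(c(x, y))
      t_obs <- sum(r[seq_len(nx)])
      sums <- colSums(matrix(r[combn(n, nx)], nrow = nx))
      p <- min(1, 2 * min(mean(sums <= t_obs + 1e-9),
                          mean(sums >= t_obs - 1e-9)))
      u <- t_obs - nx * (nx + 1) / 2
    } else {
      wt <- suppressWarnings(wilcox.test(x, y))
      p <- wt$p.value
      u <- unname(wt$statistic)
    }
    tibble::tibble(method = method, statistic = u,
                   p_value = p, n = n,
                   fallback = FALSE, degenerate = FALSE)
  } else {
    dd <- d$delta
    if (length(dd) < 3) abort("paired mode needs >= 3 deltas.")
    if (length(unique(dd)) == 1) {
      if (dd[1] == 0) {
        return(tibble::tibble(method = method, statistic = NA_real_,
                              p_value = 1, n = length(dd),
                              fallback = FALSE, degenerate = TRUE))
      }
      # constant non-zero deltas: t undefined; signed-rank fallback
      wt <- suppressWarnings(wilcox.test(dd, mu = 0))
      return(tibble::tibble(method = method, statistic = unname(wt$statistic),
                            p_value = wt$p.value, n = length(dd),
                            fallback = TRUE, degenerate = TRUE))
    }
    sw <- shapiro.test(dd)
    if (sw$p.value < shapiro_alpha) {
      wt <- suppressWarnings(wilcox.test(dd, mu = 0))
      tibble::tibble(method = method, statistic = unname(wt$statistic),
                     p_value = wt$p.value, n = length(dd),
                     fallback = TRUE, degenerate = FALSE)
    } else {
      tt <- t.test(dd, mu = 0)
      tibble::tibble(method = method, statistic = unname(tt$statistic),
                     p_value = tt$p.value, n = length(dd),
                     fallback = FALSE, degenerate = FALSE)
    }
  }
}

#' Methylation-clock regression of a CpG panel on age
#'
#' Averages the CpG panel per animal (when `cpg` is present), then fits
#' ordinary least squares of percent methylation on chronological age and
#' reports slope, intercept and Pearson correlation - the construction behind
#' single-locus aging clocks such as the Hsf4 blood panel.
#'
#' @param data Tibble with `age` (weeks), `value` (percent methylation), and
#'   optionally `animal_id` and `cpg` (multiple CpGs per animal are averaged
#'   before fitting).
#' @return An object of class `clock_fit`: list with `slope` (percentage
#'   points per week), `intercept`, `r` (Pearson), `r_squared`, `n`,
#'   `zero_residual` flag (r undefined-with-flag when all residuals vanish
#'   on zero-slope data), and the per-animal `points` tibble.
#' @examples
#' fit <- clock_fit(data.frame(age = c(10, 55, 100),
#'                             value = c(20, 37.5, 55)))
#' fit$slope  # 35/90
#' @export
clock_fit <- function(data) {
  d <- tibble::as_tibble(data)
  stopifnot(all(c("age", "value") %in% names(d)))
  if ("animal_id" %in% names(d)) {
    d <- d |>
      dplyr::group_by(.data$animal_id, .data$age) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  if (nrow(d) < 3) abort("need >= 3 points.")
  if (length(unique(d$age)) < 2) abort("ages are constant; slope undefined.")
  fit <- lm(value ~ age, data = d)
  res <- residuals(fit)
  zero_resid <- all(abs(res) < 1e-12)
  r <- if (sd(d$value) == 0) {
    NA_real_                      # zero-slope, zero-noise: r undefined
  } else cor(d$age, d$value)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r,
                 r_squared = if (is.na(r)) NA_real_ else r^2,
                 n = nrow(d),
                 zero_residual = zero_resid,
                 points = d,
                 lm = fit),
            class = "clock_fit")
}

#' Mixed-effect models for longitudinal metabolite levels
#'
#' Per metabolite, fits `value ~ timepoint (+ batch) + (1 | specimen)` by
#' REML and reports the Wald test of the timepoint effect (Satterthwaite
#' degrees of freedom). Values are analyzed on the log scale by default.
#' Singular random-effect fits (or metabolites measured once per specimen)
#' fall back to a fixed-effects model, flagged.
#'
#' @param data Long tibble: `metabolite`, `specimen_id`, `timepoint`
#'   ("pre"/"post" or any 2+ level factor), `value`, optional `batch`.
#' @param log_scale Analyze log(value) (default TRUE; requires positive
#'   values).
#' @param batch Include a fixed batch effect when a `batch` column exists
#'   (default TRUE).
#' @return A tibble: metabolite, estimate (timepoint effect), statistic
#'   (Wald t/z), df, p_value, singular_fallback flag.
#' @export
metabolite_mixed_model <- function(data, log_scale = TRUE, batch = TRUE) {
  d <- tibble::as_tibble(data)
  stopifnot(all(c("metabolite", "specimen_id", "timepoint", "value") %in% names(d)))
  d$timepoint <- factor(d$timepoint)
  if (nlevels(d$timepoint) < 2) abort("need >= 2 timepoints.")
  if (log_scale) {
    if (any(d$value <= 0)) abort("log scale requires positive values.")
    d$value <- log(d$value)
  }
  use_batch <- batch && "batch" %in% names(d) && length(unique(d$batch)) > 1
  fixed <- if (use_batch) value ~ timepoint + batch else value ~ timepoint

  one <- function(sub) {
    term <- paste0("timepoint", levels(d$timepoint)[2])
    repeated <- any(duplicated(sub$specimen_id))
    if (repeated) {
      form <- stats::update(fixed, . ~ . + (1 | specimen_id))
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = sub, REML = TRUE)))
      singular <- lme4::isSingular(fit, tol = 1e-6)
      if (!singular) {
        cf <- coef(summary(fit))
        return(tibble::tibble(estimate = cf[term, "Estimate"],
                              statistic = cf[term, "t value"],
                              df = cf[term, "df"],
                              p_value = cf[term, "Pr(>|t|)"],
                              singular_fallback = FALSE))
      }
    }
    # fixed-effects fallback; the specimen enters as a fixed effect when
    # repeated measures exist, preserving the pairing (paired-t equivalent)
    form_fix <- if (repeated) {
      stats::update(fixed, . ~ . + specimen_id)
    } else fixed
    fit <- lm(form_fix, data = sub)
    cf <- coef(summary(fit))
    tibble::tibble(estimate = cf[term, "Estimate"],
                   statistic = cf[term, "t value"],
                   df = fit$df.residual,
                   p_value = cf[term, "Pr(>|t|)"],
                   singular_fallback = TRUE)
  }
  d |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}
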