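# Replicate-level aggregation and the treated-vs-vehicle hypothesis test.

#' Mean per-type error rates across replicates
#'
#' Arithmetic mean of each substitution type's rate across the replicate
#' spectra of a group ("average error rate"). Undefined (NA) replicate
#' rates are excluded from the mean with a warning.
#'
#' @param spectra One or more stacked [error_spectrum()] tibbles (rows bind
#'   cleanly); an optional grouping column keeps conditions apart.
#' @param group Name of a grouping column in `spectra`, or `NULL`.
#' @return A tibble with one row per (group,) substitution type:
#'   `n_replicates` (non-NA) and `mean_rate`.
#' @export
group_mean_rates <- function(spectra, group = NULL) {
  if (!is.null(group) && !group %in% names(spectra)) {
    abort(sprintf("Column `%s` not found in `spectra`.", group))
  }
  if (nrow(spectra) == 0L) abort("`spectra` is empty.")
  if (anyNA(spectra$rate)) {
    warn("group_mean_rates: undefined (NA) replicate rates excluded.")
  }
  spectra |>
    dplyr::group_by(dplyr::across(dplyr::any_of(group)),
                    .data$ref_base, .data$alt_base, .data$substitution) |>
    dplyr::summarise(n_replicates = sum(!is.na(.data$rate)),
                     mean_rate = mean(.data$rate, na.rm = TRUE),
                     .groups = "drop")
}

#' Compare one substitution type's error rate between two groups
#'
#' Unpaired two-tailed t-test on per-replicate rates, pooled-variance
#' Student's t by default (`var_equal = FALSE` gives Welch). With two-tailed
#' testing the result is symmetric in group order: the t statistic flips
#' sign, the p-value is identical. An optional Bonferroni correction over
#' the 12 substitution types is available but off by default (a single
#' pre-specified type is the primary comparison).
#'
#' @param spectra Stacked replicate spectra with a grouping column.
#' @param substitution RNA-space substitution label, e.g. `"C>U"`.
#' @param group Name of the grouping column (exactly two levels).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @param bonferroni Multiply the p-value by 12 (capped at 1).
#' @return An object of class `tm_rate_test`; see [tidy()] / [glance()].
#' @examples
#' s <- tidyr::crossing(group = c("a", "b"), sample_id = 1:3) |>
#'   dplyr::mutate(ref_base = "C", alt_base = "T", substitution = "C>U",
#'                 rate = c(1, 2, 3, 1, 2, 3) * 1e-5)
#' compare_groups(s)   # identical groups: t = 0, p = 1
#' @export
compare_groups <- function(spectra, substitution = "C>U", group = "group",
                           var_equal = TRUE, bonferroni = FALSE) {
  if (!group %in% names(spectra)) {
    abort(sprintf("Column `%s` not found in `spectra`.", group))
  }
  sub <- spectra[spectra$substitution == substitution, ]
  if (nrow(sub) == 0L) {
    abort(sprintf("No rows with substitution `%s`.", substitution))
  }
  levels <- sort(unique(sub[[group]]))
  if (length(levels) != 2L) {
    abort("`compare_groups()` needs exactly two groups.")
  }
  x <- sub$rate[sub[[group]] == levels[1]]
  y <- sub$rate[sub[[group]] == levels[2]]
  if (anyNA(c(x, y))) {
    warn("compare_groups: undefined (NA) replicate rates excluded.")
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
  }
  if (length(x) < 2L || length(y) < 2L) {
    abort("The unpaired t-test is undefined with fewer than 2 replicates per group.")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  p <- unname(ht$p.value)
  if (bonferroni) p <- min(1, p * 12)
  structure(
    list(substitution = substitution,
         groups = levels, n = c(length(x), length(y)),
         means = c(mean(x), mean(y)),
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = p,
         method = if (var_equal) "Student (pooled variance)" else "Welch",
         bonferroni = bonferroni,
         rates = list(x, y)),
    class = "tm_rate_test"
  )
}

#' @export
print.tm_rate_test <- function(x, ...) {
  cat(sprintf(
    "Unpaired two-tailed t-test (%s), %s rate\n  %s (n=%d): %.3g   %s (n=%d): %.3g\n  t = %.4g, df = %.4g, p = %.4g%s\n",
    x$method, x$substitution,
    x$groups[1], x$n[1], x$means[1], x$groups[2], x$n[2], x$means[2],
    x$statistic, x$df, x$p_value,
    if (x$bonferroni) " (Bonferroni x12)" else ""))
  invisible(x)
}

#' @export
tidy.tm_rate_test <- function(x, ...) {
  tibble::tibble(
    substitution = x$substitution,
    group1 = x$groups[1], group2 = x$groups[2],
    estimate1 = x$means[1], estimate2 = x$means[2],
    estimate = x$means[1] - x$means[2],
    statistic = x$statistic, parameter = x$df, p.value = x$p_value,
    method = x$method
  )
}

#' @export
glance.tm_rate_test <- function(x, ...) {
  tidy(x)[c("statistic", "parameter", "p.value", "method")]
}
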