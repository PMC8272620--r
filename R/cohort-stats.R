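# Nonparametric cohort statistics: Kruskal-Wallis group comparisons of the
# anthropometrics, the chi-square sex association and boxplot summaries.

#' Kruskal-Wallis comparison of labelled samples
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation for the p-value (delegated to \code{stats::kruskal.test}).
#' With two samples this is the two-sample rank test used for the pairwise
#' cells of the cohort comparison table.
#'
#' @param data Data frame in long form.
#' @param variable Column with the numeric values (tidy-eval).
#' @param group Column with the group labels (tidy-eval).
#' @return One-row tibble: \code{variable}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{n}.
#' @export
kruskal_wallis <- function(data, variable, group) {
  v <- rlang::eval_tidy(rlang::enquo(variable), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  abort_if(anyNA(v) || anyNA(g), "missing values in variable or group")
  counts <- table(g)
  abort_if(length(counts) < 2, "need at least 2 groups")
  abort_if(any(counts == 0), "every group must be non-empty")
  kt <- stats::kruskal.test(v, factor(g))
  tibble::tibble(
    variable = rlang::as_label(rlang::enquo(variable)),
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n = length(v))
}

#' Pairwise group comparisons of cohort anthropometrics
#'
#' For each variable, compares every pair of expert-label groups with the
#' two-sample Kruskal-Wallis test (equivalent to a Wilcoxon rank-sum test
#' up to the chi-square approximation), mirroring the standard cohort
#' comparison table. P-values are uncorrected by default; set
#' \code{adjust = "holm"} to apply a Holm correction across variables
#' within each comparison.
#'
#' @param cohort Cohort tibble with \code{expert_label} (1 normal,
#'   2 intermediate, 3 periodic-like).
#' @param variables Numeric columns to compare.
#' @param adjust \code{"none"} (default) or a \code{stats::p.adjust} method.
#' @return Long tibble: \code{comparison}, \code{variable}, \code{p_value}.
#' @export
compare_groups <- function(cohort,
                           variables = c("age", "weight_kg", "height_cm",
                                         "waist_cm", "hip_cm", "bmi", "whr"),
                           adjust = "none") {
  abort_if(!"expert_label" %in% names(cohort), "cohort lacks expert_label")
  grp_names <- c(`1` = "normal", `2` = "intermediate", `3` = "periodic-like")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- purrr::map(pairs, function(pr) {
    sub <- cohort[cohort$expert_label %in% pr, ]
    purrr::map(variables, function(v) {
      kw <- kruskal_wallis(sub, .data[[v]], .data$expert_label)
      tibble::tibble(
        comparison = paste(grp_names[as.character(pr)], collapse = " vs "),
        variable = v, p_value = kw$p_value)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (adjust != "none") {
    out <- out |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, method = adjust),
                    .by = "comparison")
  }
  out
}

#' Chi-square test of association in a contingency table
#'
#' Pearson chi-square with (r - 1)(c - 1) degrees of freedom and no
#' continuity correction, as used for the sex-by-pattern association.
#'
#' @param contingency Matrix (or table) of nonnegative integer counts,
#'   e.g. 2 x 3 for sex by breathing-pattern group.
#' @return One-row tibble: \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_square_association <- function(contingency) {
  m <- as.matrix(contingency)
  abort_if(any(m < 0) || any(m != round(m)), "counts must be nonnegative integers")
  abort_if(any(rowSums(m) == 0) || any(colSums(m) == 0),
           "contingency table has an all-zero margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Five-number boxplot summary with 1.5 IQR whiskers
#'
#' Median and quartiles (linear-interpolation convention) with whiskers at
#' the most extreme observations within 1.5 IQR of the box; points beyond
#' are listed as outliers.
#'
#' @param x Numeric sample (length >= 1).
#' @return One-row tibble: \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_lo}, \code{whisker_hi}, \code{outliers} (list-column).
#' @export
boxplot_summary <- function(x) {
  abort_if(length(x) < 1L, "sample must be non-empty")
  q <- quartiles(x)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inside <- x >= lo_lim & x <= hi_lim
  tibble::tibble(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
    outliers = list(sort(x[!inside])))
}
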