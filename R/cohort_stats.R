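#' Paired NC-vs-CAP comparison
#'
#' Compares paired per-sample values between non-capacitating and
#' capacitating conditions. The paired differences are first screened with a
#' Shapiro-Wilk normality test at `alpha`; normal-looking differences get a
#' paired t-test, otherwise a Wilcoxon signed-rank test. Identical
#' differences (zero variance) are reported as a flagged degenerate case
#' with p = 1 by convention.
#'
#' @param nc_values,cap_values equal-length numeric vectors (>= 3 pairs),
#'   paired by sample.
#' @param alpha significance level for the normality screen.
#' @return List with `test` (name of the branch taken), `statistic`,
#'   `p_value`, `shapiro_p`, `mean_nc`, `mean_cap`, `mean_diff`, `sem_diff`,
#'   `n`, `degenerate`.
#' @export
paired_compare <- function(nc_values, cap_values, alpha = 0.05) {
  stopifnot(length(nc_values) == length(cap_values))
  n <- length(nc_values)
  if (n < 3) stop("paired comparison needs at least 3 pairs")
  d <- cap_values - nc_values
  base <- list(mean_nc = mean(nc_values), mean_cap = mean(cap_values),
               mean_diff = mean(d), n = n)
  if (stats::sd(d) == 0) {
    return(c(base, list(test = "degenerate", statistic = NA_real_,
                        p_value = 1, shapiro_p = NA_real_,
                        sem_diff = 0, degenerate = TRUE)))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(cap_values, nc_values, paired = TRUE)
    res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(cap_values, nc_values,
                                              paired = TRUE))
    res <- list(test = "wilcoxon signed-rank",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  c(base, res, list(shapiro_p = sw$p.value,
                    sem_diff = stats::sd(d) / sqrt(n), degenerate = FALSE))
}

#' One-sample test of per-sample deltas against zero
#'
#' Tests whether the capacitation-induced changes (dEm, dpHi or dF_Peak)
#' depart from a theoretical mean of zero with a one-sample t-test.
#'
#' @param deltas numeric vector of per-sample changes (n >= 3).
#' @return List with `mean`, `sem`, `statistic`, `p_value`, `n`,
#'   `degenerate`.
#' @export
delta_vs_zero <- function(deltas) {
  n <- length(deltas)
  if (n < 3) stop("needs at least 3 deltas")
  if (stats::sd(deltas) == 0)
    return(list(mean = mean(deltas), sem = 0, statistic = NA_real_,
                p_value = 1, n = n, degenerate = TRUE))
  tt <- stats::t.test(deltas, mu = 0)
  list(mean = mean(deltas), sem = stats::sd(deltas) / sqrt(n),
       statistic = unname(tt$statistic), p_value = tt$p.value, n = n,
       degenerate = FALSE)
}

# round half away from zero, the convention behind the printed percentages
round_half_up <- function(x) floor(x + 0.5)

#' Cohort category summary
#'
#' Counts and integer-rounded percentages of classification categories over
#' one donor class and one parameter — the numbers behind the donut charts
#' (e.g. 8/8 alkalinized -> 100%, 1/6 -> 17%).
#'
#' @param categories character vector of per-sample categories from one
#'   classifier.
#' @param donor_class label for the donor class summarized.
#' @param levels optional category ordering; defaults to the categories seen.
#' @return A data frame of class `cohort_summary` with columns `donor_class`,
#'   `category`, `count`, `percent`; attribute `n`.
#' @export
summarize_cohort <- function(categories, donor_class = "unspecified",
                             levels = NULL) {
  if (!length(categories)) stop("no categories to summarize")
  categories <- as.character(categories)
  if (is.null(levels)) levels <- unique(categories)
  counts <- table(factor(categories, levels = levels))
  n <- length(categories)
  structure(data.frame(donor_class = donor_class,
                       category = names(counts),
                       count = as.integer(counts),
                       percent = round_half_up(100 * as.integer(counts) / n),
                       stringsAsFactors = FALSE),
            n = n,
            class = c("cohort_summary", "data.frame"))
}
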