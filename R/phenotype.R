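#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from group means, standard deviations
#' (sample SD, divisor n - 1) and sizes:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value from the t distribution.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("degenerate input: both standard deviations are zero")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch two-sample t-test from raw values
#'
#' Identical to [welch_t_from_summary()] applied to the computed group means
#' and sample standard deviations.
#'
#' @param values1,values2 Numeric vectors, at least two values each.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_from_values <- function(values1, values2) {
  if (length(values1) < 2 || length(values2) < 2)
    stop("each group needs at least two values")
  welch_t_from_summary(mean(values1), stats::sd(values1), length(values1),
                       mean(values2), stats::sd(values2), length(values2))
}

#' Welch tests over a trait summary table
#'
#' Applies [welch_t_from_summary()] row-wise to a two-group trait table, the
#' shape of the study's phenotype table (two groups of n plants per trait).
#'
#' @param traits data.frame with columns `trait`, `mean1`, `sd1`, `n1`,
#'   `mean2`, `sd2`, `n2`.
#' @return data.frame `trait`, `t`, `df`, `p`.
#' @export
welch_table <- function(traits) {
  need <- c("trait", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
  stopifnot(all(need %in% names(traits)))
  res <- lapply(seq_len(nrow(traits)), function(i)
    welch_t_from_summary(traits$mean1[i], traits$sd1[i], traits$n1[i],
                         traits$mean2[i], traits$sd2[i], traits$n2[i]))
  data.frame(trait = traits$trait,
             t = vapply(res, `[[`, 0, "t"),
             df = vapply(res, `[[`, 0, "df"),
             p = vapply(res, `[[`, 0, "p"))
}
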