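#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t statistic
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_t(5.22, 5.45, 7527, 12.21, 7.42, 490)$t
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Group-difference table with Bonferroni correction
#'
#' Per-variable Welch t-tests between the two levels of a binary group
#' column, Bonferroni-corrected over `m` comparisons. The sign convention
#' subtracts the group-1 (minority) mean from the group-0 mean, so t is
#' negative when the minority group scores higher.
#'
#' @param table cohort data frame.
#' @param group name of the 0/1 group column.
#' @param variables outcome columns to test (default: all other numeric
#'   columns).
#' @param m number of comparisons for the Bonferroni correction (default:
#'   the number of variables tested).
#' @param alpha family-wise significance level.
#' @return data frame with per-variable group means/SDs, `t`, `df`,
#'   `p_raw`, `p_adjusted = min(1, m * p_raw)` and `significant`
#'   (`p_adjusted < alpha`).
#' @export
group_difference_table <- function(table, group = "MS", variables = NULL,
                                   m = NULL, alpha = 0.05) {
  stopifnot(group %in% names(table))
  g <- table[[group]]
  if (!all(g %in% c(0, 1))) stop("group column must be 0/1")
  if (sum(g == 1) < 2 || sum(g == 0) < 2)
    stop("each group needs at least 2 rows")
  if (is.null(variables)) variables <- setdiff(names(table), group)
  if (is.null(m)) m <- length(variables)
  stopifnot(m >= 1)
  rows <- lapply(variables, function(v) {
    x1 <- table[[v]][g == 1]
    x0 <- table[[v]][g == 0]
    wt <- welch_t(mean(x0), stats::sd(x0), length(x0),
                  mean(x1), stats::sd(x1), length(x1))
    p_adj <- min(1, m * wt$p)
    data.frame(variable = v,
               mean_minority = mean(x1), sd_minority = stats::sd(x1),
               mean_heterosexual = mean(x0), sd_heterosexual = stats::sd(x0),
               t = wt$t, df = wt$df, p_raw = wt$p, p_adjusted = p_adj,
               significant = p_adj < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardized profile means by group
#'
#' z-scores every variable against the full sample and returns the mean
#' z-score per group (optionally within strata of another column) — the
#' plot-ready data behind a group profile plot.
#'
#' @param table cohort data frame.
#' @param group name of the grouping column.
#' @param variables columns to profile (default: all other numeric
#'   columns).
#' @param stratifier optional second grouping column (e.g. sex).
#' @return long data frame with columns `group`, (`stratum`,) `variable`,
#'   `mean_z`.
#' @export
z_profiles <- function(table, group = "MS", variables = NULL,
                       stratifier = NULL) {
  stopifnot(group %in% names(table))
  if (is.null(variables)) {
    variables <- setdiff(names(table), c(group, stratifier))
  }
  Z <- scale(as.matrix(table[variables]))
  key <- if (is.null(stratifier)) list(group = table[[group]])
  else list(group = table[[group]], stratum = table[[stratifier]])
  agg <- stats::aggregate(Z, by = key, FUN = mean)
  idcols <- if (is.null(stratifier)) "group" else c("group", "stratum")
  long <- stats::reshape(agg, direction = "long",
                         varying = variables, v.names = "mean_z",
                         times = variables, timevar = "variable",
                         idvar = idcols)
  rownames(long) <- NULL
  long[c(idcols, "variable", "mean_z")]
}
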