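#' Nonparametric bootstrap of the MGM edge weights
#'
#' Resamples rows with replacement `B` times, refits the full mixed
#' graphical model on each replicate, and records the signed weight of
#' every node pair (0 when the edge is absent in that replicate;
#' sign-undefined edges contribute their magnitude). Percentile 95%
#' confidence intervals are computed per edge. Replicates whose refit
#' fails are dropped and counted; more than 1% dropped is an error.
#'
#' @param table cohort data frame.
#' @param B number of bootstrap replicates (>= 2).
#' @param gamma EBIC hyperparameter passed to [fit_mgm()].
#' @param seed integer seed; identical seeds give identical results.
#' @param level confidence level for the percentile intervals.
#' @param ... further arguments for [fit_mgm()].
#' @return An object of class `mgm_boot`: `B`, `edges` (pair labels),
#'   `draws` (B-by-edges matrix), `point` (full-sample signed weights),
#'   `ci_lower`, `ci_upper`, `dropped`, `seed`.
#' @export
bootstrap_edges <- function(table, B, gamma = 0.3, seed = NULL,
                            level = 0.95, ...) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  kinds <- resolve_kinds(table, NULL)
  point_fit <- fit_mgm(table, kinds = kinds, gamma = gamma, ...)
  nodes <- colnames(point_fit$weights)
  pairs <- which(upper.tri(point_fit$weights), arr.ind = TRUE)
  edge_names <- paste(nodes[pairs[, 1]], nodes[pairs[, 2]], sep = "--")
  signed <- function(fit) {
    M <- fit$weights * ifelse(fit$signs == 0, 1, fit$signs)
    M[pairs]
  }
  n <- nrow(table)
  draws <- matrix(NA_real_, B, length(edge_names),
                  dimnames = list(NULL, edge_names))
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      fit_mgm(table[idx, , drop = FALSE], kinds = kinds, gamma = gamma, ...),
      error = function(e) NULL)
    if (is.null(rep_fit)) dropped <- dropped + 1L
    else draws[b, ] <- signed(rep_fit)
  }
  if (dropped > 0.01 * B)
    stop(sprintf("%d of %d bootstrap replicates failed to refit", dropped, B))
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  alpha <- 1 - level
  ci <- apply(draws, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  structure(
    list(B = B, edges = edge_names, draws = draws, point = signed(point_fit),
         ci_lower = ci[1, ], ci_upper = ci[2, ], level = level,
         dropped = dropped, seed = seed, fit = point_fit),
    class = "mgm_boot"
  )
}

#' @export
print.mgm_boot <- function(x, ...) {
  cat(sprintf("Edge bootstrap: %d replicates (%d dropped), %d edges, %g%% percentile CIs\n",
              x$B, x$dropped, length(x$edges), 100 * x$level))
  invisible(x)
}

boot_edge_name <- function(boot, edge) {
  if (length(edge) == 2) {
    cand <- c(paste(edge, collapse = "--"), paste(rev(edge), collapse = "--"))
    hit <- cand[cand %in% boot$edges]
    if (!length(hit)) stop("edge not tracked: ", paste(edge, collapse = "--"))
    hit[1]
  } else {
    stopifnot(edge %in% boot$edges)
    edge
  }
}

#' Bootstrap difference test between two edge weights
#'
#' The bootstrap distribution of `w_a - w_b`; the difference is declared
#' significant when the `(1 - alpha)` percentile interval excludes zero.
#'
#' @param boot an [bootstrap_edges()] result.
#' @param edge_a,edge_b edges as `c(node1, node2)` pairs or `"a--b"`
#'   labels.
#' @param alpha significance level (default 0.05).
#' @return list with `significant`, `diff_ci`, `diff_mean`.
#' @export
edge_difference_test <- function(boot, edge_a, edge_b, alpha = 0.05) {
  na <- boot_edge_name(boot, edge_a)
  nb <- boot_edge_name(boot, edge_b)
  d <- boot$draws[, na] - boot$draws[, nb]
  ci <- unname(stats::quantile(d, probs = c(alpha / 2, 1 - alpha / 2)))
  list(significant = ci[1] > 0 || ci[2] < 0, diff_ci = ci,
       diff_mean = mean(d))
}

#' Case-dropping bootstrap stability of centrality indices
#'
#' For each drop proportion, repeatedly refits the model on a random
#' subsample retaining `(1 - proportion)` of the rows and correlates the
#' subsample centralities with the full-sample centralities. The
#' CS-coefficient of an index is the largest proportion at which the
#' correlation stays at or above 0.7 in at least 95% of replicates.
#'
#' @param table cohort data frame.
#' @param proportions drop proportions, all in (0, 0.95).
#' @param B replicates per proportion.
#' @param seed integer seed.
#' @param gamma EBIC hyperparameter.
#' @param measures centrality columns to track.
#' @param cor_threshold,coverage CS-coefficient definition parameters.
#' @return list with `cs_coefficient` (per measure), `correlations`
#'   (B-by-proportions-by-measures array) and `mean_correlation` (matrix,
#'   proportions by measures).
#' @export
centrality_stability <- function(table, proportions = seq(0.1, 0.7, 0.1),
                                 B = 25, seed = NULL, gamma = 0.3,
                                 measures = c("strength",
                                              "expected_influence",
                                              "betweenness", "closeness"),
                                 cor_threshold = 0.7, coverage = 0.95) {
  stopifnot(all(proportions > 0), all(proportions < 0.95))
  if (!is.null(seed)) set.seed(seed)
  full <- centrality_table(as_weighted_network(fit_mgm(table, gamma = gamma)))
  n <- nrow(table)
  corr <- array(NA_real_, c(B, length(proportions), length(measures)),
                dimnames = list(NULL, paste0("drop_", proportions), measures))
  for (j in seq_along(proportions)) {
    keep <- n - round(proportions[j] * n)
    for (b in seq_len(B)) {
      idx <- sample.int(n, keep)
      sub <- tryCatch(
        centrality_table(as_weighted_network(
          fit_mgm(table[idx, , drop = FALSE], gamma = gamma))),
        error = function(e) NULL)
      if (is.null(sub)) next
      for (k in seq_along(measures)) {
        x <- full[[measures[k]]]
        y <- sub[[measures[k]]]
        corr[b, j, k] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
        else stats::cor(x, y)
      }
    }
  }
  cs <- vapply(seq_along(measures), function(k) {
    ok <- vapply(seq_along(proportions), function(j) {
      v <- corr[, j, k]
      v <- v[!is.na(v)]
      length(v) > 0 && mean(v >= cor_threshold) >= coverage
    }, logical(1))
    if (!any(ok)) 0 else max(proportions[ok])
  }, numeric(1))
  names(cs) <- measures
  list(cs_coefficient = cs, correlations = corr,
       mean_correlation = apply(corr, c(2, 3), mean, na.rm = TRUE),
       proportions = proportions)
}
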