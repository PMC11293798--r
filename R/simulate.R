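#' Draw a cohort from a mixed graphical model by Gibbs sampling
#'
#' Samples `nsim` rows from the pairwise mixed graphical model in `object`.
#' The sampler runs `nsim` independent chains in parallel (one per row) with
#' a systematic scan over nodes, so rows are independent draws: each chain
#' is advanced `burn_in + thin` full scans from an overdispersed start and
#' the final state is recorded. Full conditionals are, on the internal
#' standardized scale, Gaussian with unit residual variance for continuous
#' nodes and Bernoulli-logistic for binary nodes; continuous columns are
#' then mapped to `intercept + residual_sd * z`. With unit residual scales
#' and zero intercepts the conditionals are exactly
#' `N(sum_t theta_st x_t, 1)` and `Bernoulli(plogis(intercept + sum_t
#' theta_st x_t))`.
#'
#' The interaction matrix must be symmetric and the continuous-subblock
#' conditional system `I - Theta_cc` positive definite; otherwise the
#' sampler refuses to run.
#'
#' @param object an [mgm_spec()].
#' @param nsim number of rows (independent chains) to draw.
#' @param seed integer seed; identical `(spec, nsim, seed)` give a
#'   bitwise-identical table.
#' @param burn_in,thin non-negative scan counts; the chains are advanced
#'   `burn_in + thin` scans in total (thinning between records is vacuous
#'   for independent chains and is retained for interface compatibility).
#' @param ... unused.
#' @return A data frame with one column per variable, binary columns coded
#'   0/1. The generating spec is attached as attribute `"spec"` and the
#'   kind of each column as attribute `"kinds"`.
#' @examples
#' spec <- mcs_like_spec()
#' cohort <- simulate(spec, nsim = 500, seed = 1)
#' mean(cohort$MS)
#' @export
simulate.mgm_spec <- function(object, nsim = 1, seed = NULL, burn_in = 1000,
                              thin = 10, ...) {
  stopifnot(nsim >= 1, burn_in >= 0, thin >= 1)
  check_spec_stability(object)
  if (!is.null(seed)) set.seed(seed)
  vars <- object$variables$name
  kind <- object$variables$kind
  icpt <- object$variables$intercept
  rsd <- object$variables$residual_sd
  th <- object$interactions
  p <- length(vars)
  n <- as.integer(nsim)
  is_bin <- kind == "binary"

  # state on the internal scale: z for continuous, 0/1 for binary
  U <- matrix(0, n, p, dimnames = list(NULL, vars))
  for (s in seq_len(p)) {
    U[, s] <- if (is_bin[s]) stats::rbinom(n, 1L, stats::plogis(icpt[s]))
    else stats::rnorm(n)
  }
  sweeps <- burn_in + thin
  for (it in seq_len(sweeps)) {
    for (s in seq_len(p)) {
      eta <- drop(U[, -s, drop = FALSE] %*% th[-s, s])
      U[, s] <- if (is_bin[s]) {
        stats::rbinom(n, 1L, stats::plogis(icpt[s] + eta))
      } else {
        stats::rnorm(n, eta, 1)
      }
    }
  }
  out <- as.data.frame(U)
  for (s in seq_len(p)) if (!is_bin[s]) out[[s]] <- icpt[s] + rsd[s] * out[[s]]
  attr(out, "spec") <- object
  attr(out, "kinds") <- stats::setNames(kind, vars)
  out
}

#' @rdname simulate.mgm_spec
#' @param spec an [mgm_spec()].
#' @param n number of rows to draw.
#' @export
sample_mgm_gibbs <- function(spec, n, burn_in = 1000, thin = 10,
                             seed = NULL) {
  simulate.mgm_spec(spec, nsim = n, seed = seed, burn_in = burn_in,
                    thin = thin)
}

#' Plant subgroup profiles into the minority rows of a cohort
#'
#' Randomly partitions the rows with `group_col == 1` into `k` subgroups of
#' the exact sizes in `n_per_group` and adds each subgroup's row of
#' `mean_shift` to its members' outcome columns. The ground-truth
#' assignment is recorded (attribute `"subgroup"`, `NA` for non-minority
#' rows) so recovery can be scored.
#'
#' @param table cohort data frame.
#' @param n_per_group integer vector of positive subgroup sizes; must sum to
#'   the number of minority rows.
#' @param mean_shift k-by-q numeric matrix of additive shifts whose column
#'   names select the (continuous) outcome columns to shift.
#' @param seed integer seed for the random assignment.
#' @param group_col name of the 0/1 group column.
#' @return `table` with shifted minority rows and attribute `"subgroup"`.
#' @examples
#' spec <- mcs_like_spec()
#' cohort <- simulate(spec, nsim = 2000, seed = 1)
#' k <- sum(cohort$MS)
#' sizes <- c(k %/% 2, k - k %/% 2)
#' shifts <- mcs_subgroup_shifts(cohort)[c(1, 3), ]
#' planted <- plant_subgroups(cohort, sizes, shifts, seed = 2)
#' table(attr(planted, "subgroup"))
#' @export
plant_subgroups <- function(table, n_per_group, mean_shift, seed = NULL,
                            group_col = "MS") {
  stopifnot(group_col %in% names(table))
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group <= 0)) stop("subgroup counts must be positive")
  mean_shift <- as.matrix(mean_shift)
  k <- length(n_per_group)
  if (nrow(mean_shift) != k)
    stop("`mean_shift` must have one row per subgroup")
  cols <- colnames(mean_shift)
  if (is.null(cols) || !all(cols %in% names(table)))
    stop("`mean_shift` column names must name columns of `table`")
  idx <- which(table[[group_col]] == 1)
  if (sum(n_per_group) != length(idx))
    stop(sprintf("subgroup counts sum to %d but there are %d minority rows",
                 sum(n_per_group), length(idx)))
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(idx)
  labels <- rep(seq_len(k), times = n_per_group)
  assign <- rep(NA_integer_, nrow(table))
  assign[perm] <- labels
  for (g in seq_len(k)) {
    rows <- perm[labels == g]
    for (j in seq_along(cols))
      table[rows, cols[j]] <- table[rows, cols[j]] + mean_shift[g, j]
  }
  attr(table, "subgroup") <- assign
  table
}
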