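#' Construct a pairwise mixed graphical model specification
#'
#' An `mgm_spec` holds the generative parameters of a pairwise Markov random
#' field over binary (Bernoulli) and continuous (conditional-Gaussian) nodes:
#' per-variable intercepts and residual scales together with a symmetric
#' matrix of pairwise interaction parameters. Interactions are parameterized
#' on the standardized scale of the continuous variables (binary variables
#' enter as 0/1), so that a nodewise regression of any standardized
#' continuous node on all others recovers the corresponding row of
#' `interactions`. With unit residual scales and zero means this reduces to
#' the textbook form in which the conditional mean of node s is
#' `intercept_s + sum_t theta_st x_t`.
#'
#' @param variables data frame with columns `name` (unique labels), `kind`
#'   (`"binary"` or `"continuous"`), `intercept` (log-odds of the binary
#'   conditional for binary nodes; marginal location for continuous nodes)
#'   and `residual_sd` (conditional residual standard deviation; required
#'   positive for continuous nodes, must be `NA` for binary nodes).
#' @param interactions numeric p-by-p symmetric matrix of pairwise
#'   parameters with exactly zero diagonal. Row/column order follows
#'   `variables$name`.
#' @return An object of class `mgm_spec`.
#' @seealso [simulate.mgm_spec()], [mcs_like_spec()]
#' @examples
#' vars <- data.frame(
#'   name = c("G", "Y1", "Y2"),
#'   kind = c("binary", "continuous", "continuous"),
#'   intercept = c(-2.5, 0, 0),
#'   residual_sd = c(NA, 1, 1)
#' )
#' th <- matrix(0, 3, 3)
#' th[2, 3] <- th[3, 2] <- 0.4
#' spec <- mgm_spec(vars, th)
#' @export
mgm_spec <- function(variables, interactions) {
  stopifnot(is.data.frame(variables))
  required <- c("name", "kind", "intercept")
  if (!all(required %in% names(variables)))
    stop("`variables` must have columns name, kind, intercept")
  if (!"residual_sd" %in% names(variables)) variables$residual_sd <- NA_real_
  p <- nrow(variables)
  nm <- as.character(variables$name)
  if (anyDuplicated(nm)) stop("variable names must be unique")
  kind <- as.character(variables$kind)
  if (!all(kind %in% c("binary", "continuous")))
    stop("kind must be 'binary' or 'continuous'")
  rs <- as.numeric(variables$residual_sd)
  cont <- kind == "continuous"
  if (any(cont & (is.na(rs) | rs <= 0)))
    stop("continuous variables need residual_sd > 0")
  if (any(!cont & !is.na(rs)))
    stop("residual_sd must be NA for binary variables")
  interactions <- as.matrix(interactions)
  if (!is.numeric(interactions) || nrow(interactions) != p ||
      ncol(interactions) != p)
    stop("`interactions` must be a numeric ", p, "-by-", p, " matrix")
  if (max(abs(interactions - t(interactions))) > 1e-12)
    stop("`interactions` must be symmetric (tolerance 1e-12)")
  if (any(diag(interactions) != 0))
    stop("`interactions` must have an exactly zero diagonal")
  dimnames(interactions) <- list(nm, nm)
  structure(
    list(
      variables = data.frame(name = nm, kind = kind,
                             intercept = as.numeric(variables$intercept),
                             residual_sd = rs, stringsAsFactors = FALSE),
      interactions = interactions
    ),
    class = "mgm_spec"
  )
}

#' @export
print.mgm_spec <- function(x, ...) {
  p <- nrow(x$variables)
  ne <- sum(x$interactions[upper.tri(x$interactions)] != 0)
  cat("Pairwise mixed graphical model specification\n")
  cat(sprintf("  %d variables (%d binary, %d continuous), %d nonzero interactions\n",
              p, sum(x$variables$kind == "binary"),
              sum(x$variables$kind == "continuous"), ne))
  invisible(x)
}

# Continuous-subblock conditional system; must be positive definite for the
# Gibbs sampler to have a proper stationary distribution.
spec_continuous_precision <- function(spec) {
  cont <- spec$variables$kind == "continuous"
  diag(sum(cont)) - spec$interactions[cont, cont, drop = FALSE]
}

check_spec_stability <- function(spec) {
  K <- spec_continuous_precision(spec)
  if (nrow(K) == 0L) return(invisible(TRUE))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop(sprintf(paste0("interaction matrix is spectrally unstable: the ",
                        "continuous-subblock conditional system has minimum ",
                        "eigenvalue %.4g (must be > 0)"), min(ev)))
  invisible(TRUE)
}

#' Calibrated 10-variable cohort specification
#'
#' Returns an [mgm_spec()] with one rare binary variable (`MS`, minority
#' status, marginal prevalence 490/8017) and nine continuous outcome scores
#' (depression `DEP`, conduct problems `CP`, peer problems `PP`, social
#' support `SS`, victimization `VIC`, closeness to parents `PAR`, smoking
#' `SMO`, drinking `DRI`, drug use `DRU`; higher scores always indicate
#' poorer outcomes). The sparse interaction structure carries 12 edges: the
#' binary node is directly tied to depression (much the strongest edge),
#' peer problems, conduct problems, smoking and victimization, and the
#' continuous block links depression to victimization, closeness to parents
#' and drinking, closeness to parents to social support, peer to conduct
#' problems, conduct problems to smoking, and smoking to drug use. Under
#' this structure the geodesic from `MS` to smoking and drug use runs
#' through conduct problems while the geodesics to social support,
#' closeness to parents, victimization and drinking run through
#' depression.
#'
#' Calibration is by moment matching of marginal group means and standard
#' deviations and is exact for the binary prevalence, for every
#' heterosexual-group mean and standard deviation, and for the
#' minority-group depression mean; the remaining minority-group means are
#' approximate (the edge-magnitude floor of 0.15 and the mediated-path
#' structure are prioritized over exact moment matching; conduct problems
#' shows the largest deviation). The closed-form marginal moments implied by
#' the spec are attached as attribute `"calibration"`.
#'
#' @return An `mgm_spec` for 10 variables.
#' @examples
#' spec <- mcs_like_spec()
#' attr(spec, "calibration")$implied_minority_mean
#' @export
mcs_like_spec <- function() {
  vars <- c("MS", "DEP", "CP", "PP", "SS", "VIC", "PAR", "SMO", "DRI", "DRU")
  cc <- vars[-1]
  th <- matrix(0, 10, 10, dimnames = list(vars, vars))
  edge <- function(a, b, v) {
    th[a, b] <<- v
    th[b, a] <<- v
  }
  edge("DEP", "VIC", 0.45); edge("DEP", "PAR", 0.35); edge("SS", "PAR", 0.40)
  edge("DEP", "DRI", 0.25); edge("PP", "CP", 0.30); edge("CP", "SMO", 0.60)
  edge("SMO", "DRU", 0.40)
  edge("MS", "PP", 0.35); edge("MS", "CP", 0.55)
  edge("MS", "SMO", 0.22); edge("MS", "VIC", 0.25)

  het_mean <- c(DEP = 5.22, CP = 1.30, PP = 1.50, SS = 0.47, VIC = 6.14,
                PAR = 3.85, SMO = 1.25, DRI = 1.31, DRU = 0.05)
  het_sd <- c(DEP = 5.45, CP = 1.52, PP = 1.68, SS = 0.87, VIC = 2.97,
              PAR = 1.48, SMO = 0.78, DRI = 0.76, DRU = 0.23)
  min_mean <- c(DEP = 12.21, CP = 1.50, PP = 2.24, SS = 0.88, VIC = 7.98,
                PAR = 4.56, SMO = 1.60, DRI = 1.46, DRU = 0.13)
  prevalence <- 490 / 8017

  K <- diag(9) - th[cc, cc]
  Kinv <- solve(K)
  # latent z-scale: inner scale chosen so the heterosexual-group marginal SD
  # of each continuous variable matches its target exactly
  scale_s <- het_sd / sqrt(diag(Kinv))
  theta_ms <- th[cc, "MS"]
  # pin the minority-group depression mean exactly by solving the one free
  # coupling: (Kinv %*% theta_ms)[DEP] = (12.21 - 5.22) / scale_DEP
  dz_dep <- (min_mean["DEP"] - het_mean["DEP"]) / scale_s["DEP"]
  a <- Kinv["DEP", "DEP"]
  b <- sum(Kinv["DEP", ] * theta_ms) - a * theta_ms["DEP"]
  theta_ms["DEP"] <- (dz_dep - b) / a
  th["MS", cc] <- theta_ms
  th[cc, "MS"] <- theta_ms
  # binary marginal prevalence after integrating out the continuous block
  a0 <- stats::qlogis(prevalence) -
    0.5 * drop(t(theta_ms) %*% Kinv %*% theta_ms)

  variables <- data.frame(
    name = vars,
    kind = c("binary", rep("continuous", 9)),
    intercept = c(a0, unname(het_mean[cc])),
    residual_sd = c(NA, unname(scale_s[cc])),
    stringsAsFactors = FALSE
  )
  spec <- mgm_spec(variables, th)
  dz <- drop(Kinv %*% theta_ms)
  attr(spec, "calibration") <- list(
    target_prevalence = prevalence,
    target_minority_mean = min_mean,
    target_heterosexual_mean = het_mean,
    target_heterosexual_sd = het_sd,
    implied_minority_mean = het_mean + scale_s * dz,
    implied_latent_shift = stats::setNames(dz, cc)
  )
  spec
}

#' Default planted subgroup profiles for the calibrated cohort
#'
#' Three subgroup mean-shift profiles for the minority rows of a cohort,
#' mirroring the structure in which one subgroup is elevated on peer and
#' conduct problems, one on smoking, drinking and drug use, and one on
#' depression and victimization together with poor social support and poor
#' closeness to parents (support/closeness are coded so that higher is
#' worse, so all shifts are positive). Shifts are `magnitude` multiplied by
#' each column's full-sample standard deviation in `table`, expressed in raw
#' column units.
#'
#' @param table cohort data frame used to scale the shifts.
#' @param magnitude shift size in full-sample standard deviation units.
#' @return 3-by-9 numeric matrix of additive raw-scale shifts with outcome
#'   column names.
#' @export
mcs_subgroup_shifts <- function(table, magnitude = 2.5) {
  outcomes <- c("DEP", "CP", "PP", "SS", "VIC", "PAR", "SMO", "DRI", "DRU")
  stopifnot(all(outcomes %in% names(table)))
  sds <- vapply(table[outcomes], stats::sd, numeric(1))
  shifts <- matrix(0, 3, 9, dimnames = list(c("C1", "C2", "C3"), outcomes))
  shifts["C1", c("PP", "CP")] <- magnitude
  shifts["C2", c("SMO", "DRI", "DRU")] <- magnitude
  shifts["C3", c("DEP", "VIC", "SS", "PAR")] <- magnitude
  sweep(shifts, 2, sds, "*")
}
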