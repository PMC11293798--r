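#' Standardize the continuous columns of a cohort table
#'
#' Continuous columns are centred to mean zero and scaled to unit standard
#' deviation; binary columns are left on their 0/1 coding. The transform
#' parameters are retained as attributes `"center"` and `"scale"` for
#' back-mapping.
#'
#' @param table cohort data frame.
#' @param kinds named character vector (`"binary"`/`"continuous"`) per
#'   column; if `NULL`, taken from `attr(table, "kinds")` or inferred
#'   (columns whose values are all in \{0, 1\} are binary).
#' @return Standardized data frame with attributes `center`, `scale` and
#'   `kinds`.
#' @export
standardize_cohort <- function(table, kinds = NULL) {
  kinds <- resolve_kinds(table, kinds)
  center <- stats::setNames(numeric(ncol(table)), names(table))
  scl <- stats::setNames(rep(1, ncol(table)), names(table))
  for (v in names(table)) {
    if (kinds[[v]] == "continuous") {
      s <- stats::sd(table[[v]])
      if (!is.finite(s) || s == 0)
        stop("zero-variance continuous column: ", v)
      center[v] <- mean(table[[v]])
      scl[v] <- s
      table[[v]] <- (table[[v]] - center[v]) / s
    }
  }
  attr(table, "center") <- center
  attr(table, "scale") <- scl
  attr(table, "kinds") <- kinds
  table
}

resolve_kinds <- function(table, kinds = NULL) {
  if (is.null(kinds)) kinds <- attr(table, "kinds")
  if (is.null(kinds)) {
    kinds <- vapply(table, function(x) {
      if (all(x %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  if (is.null(names(kinds)) && length(kinds) == ncol(table))
    names(kinds) <- names(table)
  if (!all(names(table) %in% names(kinds)))
    stop("`kinds` must name every column of the table")
  kinds[names(table)]
}

#' Extended Bayesian information criterion
#'
#' `ebic_score = neg2_loglik + k * log(n) + 2 * gamma * k * log(p - 1)`,
#' where `k` is the number of nonzero coefficients, `n` the sample size and
#' `p - 1` the number of candidate predictors in a nodewise regression. At
#' `gamma = 0` this is the ordinary BIC.
#'
#' @param neg2_loglik minus twice the maximized log-likelihood.
#' @param k number of nonzero coefficients.
#' @param n sample size (>= 2).
#' @param p number of variables in the network (candidate predictors per
#'   node are `p - 1`).
#' @param gamma EBIC hyperparameter in `[0, 0.5]`.
#' @return numeric score (lower is better).
#' @export
ebic_score <- function(neg2_loglik, k, n, p, gamma) {
  stopifnot(n >= 2, gamma >= 0, gamma <= 0.5)
  neg2_loglik + k * log(n) + 2 * gamma * k * log(p - 1)
}

#' Nodewise L1-penalized regression with EBIC selection
#'
#' Fits the lasso path for one node regressed on all remaining variables
#' (squared-error loss for continuous nodes, logistic loss for binary
#' nodes) over a log-spaced grid of `grid_size` penalties running from
#' `lambda_max` (the smallest penalty giving an all-zero model) down to
#' `lambda_min_ratio * lambda_max`, and selects the penalty minimizing
#' [ebic_score()] with `k` the number of nonzero coefficients. The Gaussian
#' deviance is computed as `n * log(RSS / n)`. Predictors are internally
#' standardized for the penalty; reported coefficients are on the scale of
#' the supplied (already standardized) table, so binary predictors keep a
#' per-category interpretation.
#'
#' When `threshold = TRUE`, selected coefficients smaller in magnitude than
#' `sqrt(k) * sqrt(log(p) / n)` are set to zero (the high-dimensional
#' consistency threshold conventionally applied by MGM estimators), which
#' suppresses near-zero spurious coefficients that survive EBIC selection.
#'
#' @param table standardized cohort table (see [standardize_cohort()]).
#' @param node column name or index of the response node.
#' @param gamma EBIC hyperparameter (default 0.3).
#' @param grid_size number of penalties on the path.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty.
#' @param threshold apply the post-selection magnitude threshold.
#' @param maxit,tol coordinate-descent iteration cap and tolerance.
#' @return An object of class `nodewise_fit`: node, family, lambda grid,
#'   selected lambda, EBIC path, per-lambda model sizes, the full
#'   coefficient path and the selected (possibly thresholded) coefficient
#'   vector.
#' @export
fit_nodewise <- function(table, node, gamma = 0.3, grid_size = 100,
                         lambda_min_ratio = 0.01, threshold = TRUE,
                         maxit = 1e5, tol = 1e-6) {
  if (is.numeric(node)) node <- names(table)[node]
  stopifnot(node %in% names(table))
  kinds <- resolve_kinds(table, NULL)
  y <- table[[node]]
  x <- as.matrix(table[setdiff(names(table), node)])
  n <- length(y)
  p <- ncol(table)
  family <- if (kinds[[node]] == "binary") "binomial" else "gaussian"
  # explicit log-spaced grid from lambda_max (all-zero model) downwards;
  # lambda_max is the largest absolute gradient of the null model over the
  # penalty-standardized predictors
  xsd <- sqrt(colMeans(scale(x, scale = FALSE)^2))
  xsd[xsd == 0] <- 1
  x_std <- scale(x, scale = xsd)
  lambda_max <- max(abs(crossprod(x_std, y - mean(y)))) / n
  if (!is.finite(lambda_max) || lambda_max <= 0) lambda_max <- 1e-3
  lambda_max <- lambda_max * (1 + 1e-6)
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = grid_size))
  fit <- glmnet::glmnet(x, y, family = family, lambda = grid,
                        standardize = TRUE, maxit = maxit, thresh = tol)
  if (!all(fit$jerr == 0) && fit$jerr > 0)
    stop("nodewise lasso did not converge for node ", node,
         " (glmnet error ", fit$jerr, ")")
  k_path <- unname(fit$df)
  if (family == "gaussian") {
    pred <- stats::predict(fit, x)
    rss <- unname(colSums((y - pred)^2))
    n2ll <- n * log(rss / n)
  } else {
    n2ll <- unname((1 - fit$dev.ratio) * fit$nulldev)
  }
  ebic <- ebic_score(n2ll, k_path, n, p, gamma)
  sel <- which.min(ebic)
  beta <- as.matrix(fit$beta)
  coefs <- beta[, sel]
  if (threshold && k_path[sel] > 0) {
    tau <- sqrt(k_path[sel]) * sqrt(log(p) / n)
    coefs[abs(coefs) < tau] <- 0
  }
  structure(
    list(node = node, family = family, lambda_grid = fit$lambda,
         selected_lambda = fit$lambda[sel], selected_index = sel,
         ebic_path = ebic, k_path = k_path, neg2_loglik_path = n2ll,
         coefficients = coefs, beta_path = beta,
         intercept = unname(fit$a0[sel]), gamma = gamma, n = n),
    class = "nodewise_fit"
  )
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat(sprintf("Nodewise %s fit for '%s': %d of %d candidate predictors kept (lambda = %.4g)\n",
              x$family, x$node, sum(x$coefficients != 0),
              length(x$coefficients), x$selected_lambda))
  invisible(x)
}

#' Combine nodewise fits into a signed weighted network (AND rule)
#'
#' An edge (s, t) is present only when the coefficient of t in the fit for
#' s and the coefficient of s in the fit for t are both nonzero. Its
#' magnitude is the mean of the two absolute coefficients; its sign is the
#' shared sign when the two agree and 0 (sign-undefined) otherwise.
#'
#' @param nodewise list of [fit_nodewise()] objects, one per node, in node
#'   order.
#' @return list with `weights` (symmetric non-negative magnitude matrix,
#'   zero diagonal) and `signs` (matrix in \{-1, 0, 1\}).
#' @export
combine_edges <- function(nodewise) {
  nodes <- vapply(nodewise, function(f) f$node, character(1))
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  S <- W
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      bij <- nodewise[[i]]$coefficients[nodes[j]]
      bji <- nodewise[[j]]$coefficients[nodes[i]]
      if (bij != 0 && bji != 0) {
        W[i, j] <- W[j, i] <- mean(abs(c(bij, bji)))
        S[i, j] <- S[j, i] <- if (sign(bij) == sign(bji)) sign(bij) else 0
      }
    }
  }
  list(weights = W, signs = S)
}

#' Fit a pairwise mixed graphical model
#'
#' Estimates the MGM by nodewise L1-penalized regression with EBIC model
#' selection ([fit_nodewise()]), aggregated into a single signed weighted
#' network by the AND rule ([combine_edges()]). Continuous variables are
#' standardized first; binary variables stay on their 0/1 coding.
#'
#' @param data cohort data frame.
#' @param kinds optional named kind vector; inferred when `NULL`.
#' @param gamma EBIC hyperparameter (default 0.3).
#' @inheritParams fit_nodewise
#' @return An object of class `mgm_fit` with components `weights`, `signs`,
#'   `nodewise`, `gamma`, `kinds`, `predictability` and the standardized
#'   data used for fitting. Methods: [print.mgm_fit()], [summary.mgm_fit()],
#'   [coef.mgm_fit()], [predict.mgm_fit()], [plot.mgm_fit()].
#' @examples
#' spec <- mcs_like_spec()
#' cohort <- simulate(spec, nsim = 800, seed = 7, burn_in = 200)
#' fit <- fit_mgm(cohort)
#' fit
#' coef(fit)["MS", "DEP"]
#' @export
fit_mgm <- function(data, kinds = NULL, gamma = 0.3, grid_size = 100,
                    lambda_min_ratio = 0.01, threshold = TRUE) {
  kinds <- resolve_kinds(data, kinds)
  std <- standardize_cohort(data, kinds)
  nodewise <- lapply(names(std), function(v)
    fit_nodewise(std, v, gamma = gamma, grid_size = grid_size,
                 lambda_min_ratio = lambda_min_ratio,
                 threshold = threshold))
  net <- combine_edges(nodewise)
  stopifnot(max(abs(net$weights - t(net$weights))) == 0,
            all(diag(net$weights) == 0))
  fit <- structure(
    list(weights = net$weights, signs = net$signs, nodewise = nodewise,
         gamma = gamma, kinds = kinds, data = std, n = nrow(data),
         call = match.call()),
    class = "mgm_fit"
  )
  fit$predictability <- predictability(fit)
  fit
}

#' @export
print.mgm_fit <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Mixed graphical model fit: %d nodes, %d edges (EBIC gamma = %g, n = %d)\n",
              ncol(x$weights), ne, x$gamma, x$n))
  invisible(x)
}

#' @describeIn fit_mgm edge list and node predictability summary.
#' @param object,x an `mgm_fit`.
#' @param ... unused.
#' @export
summary.mgm_fit <- function(object, ...) {
  el <- edge_list(object)
  out <- list(edges = el, predictability = object$predictability,
              gamma = object$gamma, n = object$n)
  class(out) <- "summary.mgm_fit"
  out
}

#' @export
print.summary.mgm_fit <- function(x, ...) {
  cat(sprintf("MGM fit (EBIC gamma = %g, n = %d)\n\nEdges:\n", x$gamma, x$n))
  print(x$edges, row.names = FALSE, digits = 3)
  cat("\nNode predictability:\n")
  print(x$predictability, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @describeIn fit_mgm signed weight matrix (sign-undefined edges carry
#'   their magnitude and are listed in attribute `"sign_undefined"`).
#' @export
coef.mgm_fit <- function(object, ...) {
  signed <- object$weights * ifelse(object$signs == 0, 1, object$signs)
  attr(signed, "sign_undefined") <- object$weights != 0 & object$signs == 0
  signed
}

#' @describeIn fit_mgm fitted values for one node from its selected
#'   nodewise model (`type = "response"` gives probabilities for binary
#'   nodes).
#' @param node node to predict.
#' @param newdata optional standardized table; defaults to the fitting
#'   data.
#' @param type `"response"` or `"link"`.
#' @export
predict.mgm_fit <- function(object, node, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.numeric(node)) node <- colnames(object$weights)[node]
  nw <- object$nodewise[[match(node, colnames(object$weights))]]
  dat <- if (is.null(newdata)) object$data else newdata
  x <- as.matrix(dat[setdiff(colnames(object$weights), node)])
  eta <- drop(x %*% nw$coefficients[colnames(x)]) + nw$intercept
  if (nw$family == "binomial" && type == "response") stats::plogis(eta)
  else eta
}

#' Node predictability of a fitted mixed graphical model
#'
#' For continuous nodes, the in-sample proportion of variance explained
#' (`r_squared = 1 - SS_res / SS_tot`) by the selected nodewise model; for
#' binary nodes, the correct-classification rate (`cc`, fitted probability
#' thresholded at 0.5 against the observed value). A binary node with an
#' empty neighbourhood reduces to the majority-class rate and a continuous
#' node with an empty neighbourhood to `r_squared = 0`.
#'
#' @param fit an [fit_mgm()] object.
#' @return data frame with columns `node`, `kind`, `measure`
#'   (`"r_squared"`/`"cc"`) and `value` in `[0, 1]`.
#' @export
predictability <- function(fit) {
  nodes <- colnames(fit$weights)
  out <- data.frame(node = nodes, kind = unname(fit$kinds[nodes]),
                    measure = NA_character_, value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(nodes)) {
    y <- fit$data[[nodes[i]]]
    if (fit$kinds[[nodes[i]]] == "binary") {
      phat <- predict.mgm_fit(fit, nodes[i], type = "response")
      out$measure[i] <- "cc"
      out$value[i] <- mean((phat > 0.5) == y)
    } else {
      yhat <- predict.mgm_fit(fit, nodes[i])
      out$measure[i] <- "r_squared"
      out$value[i] <- max(0, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
    }
  }
  out
}

#' Edge list of a fitted network
#'
#' @param fit an `mgm_fit` or `weighted_network`.
#' @return data frame with columns `node_a`, `node_b`, `weight` (magnitude)
#'   and `sign` (+1, -1, or 0 for sign-undefined).
#' @export
edge_list <- function(fit) {
  W <- fit$weights
  S <- if (!is.null(fit$signs)) fit$signs else sign(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(
    node_a = colnames(W)[idx[, 1]],
    node_b = colnames(W)[idx[, 2]],
    weight = W[idx],
    sign = S[idx],
    stringsAsFactors = FALSE
  )
}

#' @describeIn fit_mgm dot chart of standardized centrality indices of the
#'   fitted network.
#' @export
plot.mgm_fit <- function(x, ...) {
  ct <- centrality_table(as_weighted_network(x))
  z <- as.matrix(ct[, c("z_strength", "z_expected_influence",
                        "z_betweenness", "z_closeness")])
  rownames(z) <- ct$node
  graphics::dotchart(z, xlab = "standardized centrality", ...)
  invisible(x)
}
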