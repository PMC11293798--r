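test_that("standardize_cohort centres and scales continuous columns only", {
  set.seed(1)
  tab <- data.frame(G = rbinom(200, 1, 0.3),
                    Y = rnorm(200, mean = 5.22, sd = 5.45))
  std <- standardize_cohort(tab, c(G = "binary", Y = "continuous"))
  expect_lt(abs(mean(std$Y)), 1e-12)
  expect_equal(sd(std$Y), 1, tolerance = 1e-12)
  expect_identical(std$G, tab$G)
  # idempotence
  std2 <- standardize_cohort(std)
  expect_equal(std2$Y, std$Y, tolerance = 1e-12)
  # zero-variance rejection names the column (constant non-binary column)
  tab$Z <- 2
  expect_error(standardize_cohort(tab), "Z")
})

test_that("ebic_score implements the stated formula", {
  expect_equal(ebic_score(57.3, 0, 100, 10, 0.3), 57.3)  # null model
  expect_equal(ebic_score(57.3, 4, 100, 10, 0),
               57.3 + 4 * log(100))                       # BIC limit
  # independently hand-computed: 100 + 3*log(8017) + 0.6*3*log(9)
  expect_equal(ebic_score(100, 3, 8017, 10, 0.3), 130.922962937,
               tolerance = 1e-9)
  expect_error(ebic_score(1, 1, 1, 10, 0.3))
  expect_error(ebic_score(1, 1, 100, 10, 0.7))
})

test_that("the penalty path starts at an all-zero model", {
  tab <- standardize_cohort(simulate(chain_spec(4, 0.3), nsim = 300,
                                     seed = 2, burn_in = 50))
  f <- fit_nodewise(tab, "Y2")
  expect_true(all(f$beta_path[, 1] == 0))
  expect_true(f$selected_lambda %in% f$lambda_grid)
  expect_equal(f$ebic_path[f$selected_index], min(f$ebic_path))
})

test_that("independent data select the empty model at every node", {
  spec <- independent_spec(p_cont = 4, prevalence = 0.2)
  tab <- standardize_cohort(simulate(spec, nsim = 5000, seed = 3,
                                     burn_in = 50))
  for (v in names(tab)) {
    f <- fit_nodewise(tab, v)
    expect_equal(sum(f$coefficients != 0), 0)
  }
})

test_that("chain-graph structure is recovered exactly", {
  spec <- chain_spec(5, 0.35)
  tab <- standardize_cohort(simulate(spec, nsim = 5000, seed = 4,
                                     burn_in = 100))
  for (s in 1:5) {
    f <- fit_nodewise(tab, s)
    nonzero <- names(f$coefficients)[f$coefficients != 0]
    truth <- paste0("Y", setdiff(c(s - 1, s + 1), c(0, 6)))
    expect_setequal(nonzero, truth)
  }
})

test_that("unpenalized limit agrees with ordinary least squares", {
  spec <- chain_spec(4, 0.3)
  tab <- standardize_cohort(simulate(spec, nsim = 500, seed = 5,
                                     burn_in = 50))
  f <- fit_nodewise(tab, "Y2", lambda_min_ratio = 1e-7, threshold = FALSE,
                    tol = 1e-12)
  lasso_at_zero <- f$beta_path[, ncol(f$beta_path)]
  ols <- coef(lm(Y2 ~ ., data = tab))[-1]
  expect_equal(unname(lasso_at_zero[names(ols)]), unname(ols),
               tolerance = 1e-4)
})

test_that("AND rule, magnitude and sign conventions of edge aggregation", {
  fake <- function(node, coefs) {
    structure(list(node = node, coefficients = coefs),
              class = "nodewise_fit")
  }
  nw <- list(fake("A", c(B = 0.5, C = 0)),
             fake("B", c(A = 0.3, C = 0.2)),
             fake("C", c(A = 0, B = -0.2)))
  net <- combine_edges(nw)
  expect_equal(net$weights["A", "B"], 0.4)       # mean of |0.5|, |0.3|
  expect_equal(net$signs["A", "B"], 1)
  expect_equal(net$weights["A", "C"], 0)         # AND rule: one side zero
  expect_equal(net$weights["B", "C"], 0.2)       # sign disagreement kept
  expect_equal(net$signs["B", "C"], 0)           # ... but sign-undefined
  expect_identical(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
})

test_that("predictability reduces to the majority rule and zero R2 for empty models", {
  set.seed(6)
  n <- 3000
  tab <- data.frame(G = rbinom(n, 1, 0.061), Y1 = rnorm(n), Y2 = rnorm(n))
  fit <- fit_mgm(tab)
  pr <- fit$predictability
  expect_equal(sum(fit$weights), 0)  # nothing to find
  expect_equal(pr$value[pr$node == "G"], mean(tab$G == 0))
  expect_equal(pr$value[pr$node == "Y1"], 0)
  expect_true(all(pr$value >= 0 & pr$value <= 1))
  expect_identical(pr$measure, c("cc", "r_squared", "r_squared"))
})

test_that("a near-noiseless child node is almost perfectly predictable", {
  set.seed(7)
  x <- rnorm(1000)
  tab <- data.frame(X = x, Y = 0.9 * x + 0.01 * rnorm(1000),
                    Z = rnorm(1000))
  fit <- fit_mgm(tab)
  pr <- fit$predictability
  expect_gt(pr$value[pr$node == "Y"], 0.99)
})

test_that("selected model size is non-increasing in the EBIC gamma", {
  spec <- chain_spec(6, 0.3)
  tab <- standardize_cohort(simulate(spec, nsim = 1000, seed = 8,
                                     burn_in = 50))
  for (v in names(tab)) {
    sizes <- vapply(seq(0, 0.5, 0.1), function(g)
      sum(fit_nodewise(tab, v, gamma = g)$coefficients != 0), numeric(1))
    expect_true(all(diff(sizes) <= 0 | diff(sizes) == 0))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("fitted weight matrices are symmetric with zero diagonal", {
  tab <- simulate(two_edge_spec(), nsim = 800, seed = 9, burn_in = 50)
  fit <- fit_mgm(tab)
  expect_identical(fit$weights, t(fit$weights))
  expect_true(all(diag(fit$weights) == 0))
  expect_true(all(fit$weights >= 0))
  expect_true(all(fit$signs[fit$weights == 0] == 0))
})
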