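test_that("spinglass splits two weakly-joined cliques (exhaustive oracle)", {
  p <- 8
  W <- matrix(0, p, p)
  W[1:4, 1:4] <- 0.8
  W[5:8, 5:8] <- 0.8
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.1
  net <- weighted_network(W)
  part <- spinglass_communities(net, seed = 1)
  # independent oracle: exhaustive search over all partitions of 8 nodes
  oracle <- best_partition_exhaustive(p, function(lab)
    -spinglass_hamiltonian(W, lab))
  expect_equal(part$n_communities, 2)
  expect_equal(adjusted_rand_index(part$labels, oracle$labels), 1)
  expect_equal(part$score, -oracle$score, tolerance = 1e-9)
  expect_equal(adjusted_rand_index(part$labels, rep(1:2, each = 4)), 1)
})

test_that("a positive clique stays one community and a zero network degenerates", {
  W <- matrix(0.5, 5, 5)
  diag(W) <- 0
  part <- spinglass_communities(weighted_network(W), seed = 2)
  expect_equal(part$n_communities, 1)
  zero <- spinglass_communities(weighted_network(matrix(0, 4, 4)), seed = 3)
  expect_equal(zero$n_communities, 4)
  expect_true(isTRUE(attr(zero, "degenerate")))
})

test_that("spinglass solutions are single-move local optima (zero-temperature limit)", {
  set.seed(4)
  net <- random_network(7, signed = TRUE)
  W <- net$weights * ifelse(net$signs == 0, 1, net$signs)
  part <- spinglass_communities(net, seed = 5)
  lab <- part$labels
  H0 <- spinglass_hamiltonian(W, lab)
  expect_equal(part$score, H0, tolerance = 1e-9)
  for (i in seq_along(lab)) {
    for (c in unique(c(lab, max(lab) + 1L))) {
      lab2 <- lab
      lab2[i] <- c
      expect_gte(spinglass_hamiltonian(W, lab2), H0 - 1e-9)
    }
  }
})

test_that("the calibrated synthetic network yields 3-5 stable node communities", {
  fit <- cached("mcs_fit_1", fit_mgm(mcs_cohort(n = 8017, seed = 1)))
  net <- as_weighted_network(fit)
  parts <- lapply(1:10, function(s) spinglass_communities(net, seed = s))
  ks <- vapply(parts, function(p) p$n_communities, numeric(1))
  expect_true(all(ks >= 3 & ks <= 5))
  for (a in 1:9) for (b in (a + 1):10)
    expect_gte(adjusted_rand_index(parts[[a]]$labels, parts[[b]]$labels),
               0.8)
})

test_that("person similarity is a correlation of cohort-referenced z-profiles", {
  # rows placed symmetrically around the column means give exactly
  # opposite z-profiles; duplicated rows give identical ones
  base <- data.frame(A = c(2, -2, 1, -1, 0.5, -0.5),
                     B = c(-4, 4, 3, -3, 1, -1),
                     C = c(1, -1, 2, -2, -1.5, 1.5))
  S <- person_similarity(base, measures = c("A", "B", "C"))
  expect_equal(diag(S), rep(1, 6), ignore_attr = TRUE)
  expect_equal(max(abs(S - t(S))), 0)
  expect_equal(S[1, 2], -1)   # mirrored profiles
  dup <- rbind(base, base[1, ])
  S2 <- person_similarity(dup, measures = c("A", "B", "C"))
  expect_equal(S2[1, 7], 1)   # identical profiles
  # constant profile (a row exactly at the column means) is rejected
  cst <- rbind(base, data.frame(A = 0, B = 0, C = 0))
  expect_error(person_similarity(cst, measures = c("A", "B", "C")), "7")
})

test_that("planted profiles are more similar within than between groups", {
  set.seed(6)
  n <- 90
  tab <- data.frame(MS = rep(1, n), DEP = rnorm(n), SMO = rnorm(n),
                    PP = rnorm(n), VIC = rnorm(n))
  shifts <- rbind(c(2.5, 0, 0, 2.5), c(0, 2.5, 0, 0), c(0, 0, 2.5, 0))
  colnames(shifts) <- c("DEP", "SMO", "PP", "VIC")
  planted <- plant_subgroups(tab, c(30, 30, 30), shifts, seed = 7)
  lab <- attr(planted, "subgroup")
  S <- person_similarity(planted, measures = colnames(shifts))
  same <- outer(lab, lab, "==") & upper.tri(S)
  diff_ <- outer(lab, lab, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff_]))
})

test_that("signed Louvain recovers planted blocks (exhaustive oracle)", {
  S <- block_similarity(c(4, 4), within = 0.9, between = -0.5)
  part <- louvain_signed(S, seed = 8)
  oracle <- best_partition_exhaustive(8, function(lab)
    modularity_signed(S, lab))
  expect_equal(part$n_communities, 2)
  expect_equal(adjusted_rand_index(part$labels, attr(S, "blocks")), 1)
  expect_equal(adjusted_rand_index(part$labels, oracle$labels), 1)
  expect_equal(part$score, oracle$score, tolerance = 1e-9)
})

test_that("Louvain is invariant to row permutation and self-consistent in Q", {
  set.seed(9)
  S <- block_similarity(c(5, 4, 3), within = 0.8, between = -0.3)
  m <- nrow(S)
  noise <- matrix(rnorm(m * m, sd = 0.05), m, m)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  S <- S + noise
  part <- louvain_signed(S, seed = 10)
  expect_equal(part$score, modularity_signed(S, part$labels),
               tolerance = 1e-12)
  perm <- sample(m)
  part2 <- louvain_signed(S[perm, perm], seed = 11)
  expect_equal(adjusted_rand_index(part2$labels, part$labels[perm]), 1)
})

test_that("ARI agrees with the reference implementation", {
  library(mclust)
  set.seed(12)
  for (rep in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("consensus on a noiseless block similarity converges in one round", {
  S <- block_similarity(c(6, 5, 4), within = 0.9, between = -0.4)
  part <- consensus_cluster(S, iterations = 10, tau = 0.5, seed = 13)
  expect_equal(attr(part, "rounds"), 1)
  expect_equal(adjusted_rand_index(part$labels, attr(S, "blocks")), 1)
  A <- attr(part, "agreement")
  expect_true(all(A %in% c(0, 1)))
  # agreement of a converged consensus is block diagonal in the labels
  expect_equal(A, outer(part$labels, part$labels, function(a, b)
    as.numeric(a == b)), ignore_attr = TRUE)
})

test_that("consensus Q and reproducibility on a noisy planted fixture", {
  set.seed(14)
  S <- block_similarity(c(20, 20, 20), within = 0.6, between = -0.2)
  m <- nrow(S)
  noise <- matrix(rnorm(m * m, sd = 0.15), m, m)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  S <- pmin(pmax(S + noise, -1), 1)
  diag(S) <- 1
  runs_q <- vapply(1:10, function(s) louvain_signed(S, seed = s)$score,
                   numeric(1))
  pa <- consensus_cluster(S, iterations = 20, tau = 0.5, seed = 100)
  pb <- consensus_cluster(S, iterations = 20, tau = 0.5, seed = 200)
  # consensus Q does not fall below the mean single-run Q by more than 0.02
  expect_gte(pa$score, mean(runs_q) - 0.02)
  # disjoint seed sets agree: consensus removes run-to-run variance
  expect_gte(adjusted_rand_index(pa$labels, pb$labels), 0.95)
})
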