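make_net <- function(edges, nodes) {
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  weighted_network(W)
}

test_that("edge lengths are reciprocal absolute weights", {
  net <- make_net(list(list("A", "B", 0.5), list("B", "C", -0.25)),
                  c("A", "B", "C"))
  L <- edge_lengths(net)
  expect_equal(L["A", "B"], 2)
  expect_equal(L["B", "C"], 4)    # magnitude of a negative edge
  expect_equal(L["A", "C"], Inf)  # absent edge
  expect_equal(diag(L), c(A = 0, B = 0, C = 0))
})

test_that("shortest paths on a line and a triangle", {
  line <- make_net(list(list("A", "B", 0.5), list("B", "C", 0.5)),
                   c("A", "B", "C"))
  pr <- shortest_paths_from(line, "A")
  pc <- pr[[which(vapply(pr, `[[`, "", "target") == "C")]]
  expect_equal(pc$node_sequence, c("A", "B", "C"))
  expect_equal(pc$length, 4)
  # a weak direct edge loses to a two-hop strong route: 4 < 1/0.2 = 5
  tri <- make_net(list(list("A", "B", 0.5), list("B", "C", 0.5),
                       list("A", "C", 0.2)), c("A", "B", "C"))
  pc <- shortest_paths_from(tri, "A")[[2]]
  expect_equal(pc$target, "C")
  expect_equal(pc$node_sequence, c("A", "B", "C"))
  expect_equal(pc$length, 4)
})

test_that("Dijkstra distances match the Floyd-Warshall oracle on random graphs", {
  set.seed(11)
  for (rep in 1:50) {
    net <- random_network(sample(4:8, 1), signed = TRUE)
    D <- distance_matrix(net)
    expect_equal(D, fw_distances(edge_lengths(net)), tolerance = 1e-9)
  }
})

test_that("betweenness matches the exhaustive path-enumeration oracle", {
  set.seed(12)
  for (rep in 1:50) {
    net <- random_network(sample(4:7, 1), signed = TRUE)
    ct <- centrality_table(net)
    expect_equal(ct$betweenness, enum_betweenness(edge_lengths(net)),
                 tolerance = 1e-8)
  }
})

test_that("star-graph centralities have their closed-form values", {
  nodes <- c("H", "L1", "L2", "L3", "L4")
  net <- make_net(lapply(1:4, function(i) list("H", paste0("L", i), 0.5)),
                  nodes)
  ct <- centrality_table(net)
  expect_equal(ct$strength[ct$node == "H"], 2)
  expect_equal(ct$strength[ct$node == "L1"], 0.5)
  expect_equal(ct$betweenness[ct$node == "L1"], 0)
  expect_equal(ct$betweenness[ct$node == "H"], choose(4, 2))
  # all-positive network: expected influence equals strength
  expect_equal(ct$expected_influence, ct$strength)
  # z columns standardized
  expect_lt(abs(mean(ct$z_strength)), 1e-12)
  expect_equal(sd(ct$z_strength), 1, tolerance = 1e-12)
})

test_that("sign-undefined edges count for strength but not expected influence", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["B", "C"] <- W["C", "B"] <- 0.3
  S <- sign(W)
  S["B", "C"] <- S["C", "B"] <- 0  # sign-undefined
  net <- weighted_network(W, S)
  ct <- centrality_table(net)
  expect_equal(ct$strength[ct$node == "B"], 0.8)
  expect_equal(ct$expected_influence[ct$node == "B"], 0.5)
  # strength dominates the magnitude of expected influence everywhere
  expect_true(all(ct$strength >= abs(ct$expected_influence) - 1e-12))
})

test_that("centralities are invariant under node permutation", {
  set.seed(13)
  net <- random_network(7, signed = TRUE)
  ct <- centrality_table(net)
  perm <- sample(7)
  W2 <- net$weights[perm, perm]
  S2 <- net$signs[perm, perm]
  ct2 <- centrality_table(weighted_network(W2, S2))
  reord <- match(ct$node, ct2$node)
  for (col in c("strength", "expected_influence", "betweenness",
                "closeness"))
    expect_equal(ct2[[col]][reord], ct[[col]], tolerance = 1e-9)
})

test_that("adding an edge never increases any geodesic distance", {
  set.seed(14)
  for (rep in 1:20) {
    net <- random_network(6)
    D <- distance_matrix(net)
    absent <- which(net$weights == 0 & upper.tri(net$weights), arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample(nrow(absent), 1), ]
    W2 <- net$weights
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- runif(1, 0.1, 1)
    D2 <- distance_matrix(weighted_network(W2))
    expect_true(all(D2 <= D + 1e-12))
  }
})

test_that("mediation report distinguishes direct and mediated routes", {
  # direct edge that is also the geodesic
  net <- make_net(list(list("A", "B", 0.5), list("B", "C", 0.5)),
                  c("A", "B", "C"))
  rep_ <- mediation_report(net, "A")
  expect_equal(rep_$relation[rep_$target == "B"], "direct")
  expect_equal(rep_$relation[rep_$target == "C"], "mediated")
  expect_equal(rep_$intermediaries[rep_$target == "C"], "B")
  expect_false(rep_$has_direct_edge[rep_$target == "C"])
  # disconnected target flagged
  W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  W["A", "B"] <- W["B", "A"] <- 1
  rep2 <- mediation_report(weighted_network(W), "A")
  expect_equal(rep2$relation[rep2$target == "C"], "unreachable")
})

test_that("the calibrated synthetic fit reproduces the mediated path structure", {
  fit <- cached("mcs_fit_1", fit_mgm(mcs_cohort(n = 8017, seed = 1)))
  med <- mediation_report(as_weighted_network(fit), "MS")
  direct <- med$target[med$relation == "direct"]
  expect_setequal(direct, c("DEP", "CP", "PP"))
  via <- function(v) strsplit(med$intermediaries[med$target == v], ",")[[1]]
  expect_true("CP" %in% via("SMO"))
  expect_true("CP" %in% via("DRU"))
  for (v in c("SS", "VIC", "PAR", "DRI"))
    expect_true("DEP" %in% via(v))
})
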