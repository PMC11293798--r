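#' @noRd
new_partition <- function(labels, score, method, nodes = NULL, ...) {
  labels <- as.integer(labels)
  # contiguous 0-based labels in order of first appearance
  labels <- match(labels, unique(labels)) - 1L
  if (!is.null(nodes)) names(labels) <- nodes
  structure(list(labels = labels, score = score,
                 n_communities = length(unique(labels)), method = method,
                 ...),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d communities over %d items, score = %.4f\n",
              x$method, x$n_communities, length(x$labels), x$score))
  invisible(x)
}

split_signs <- function(W) {
  list(pos = pmax(W, 0), neg = pmax(-W, 0))
}

#' Signed-network modularity (asymmetric normalization)
#'
#' Modularity of a labelled signed matrix under the asymmetric signed
#' convention: the positive part is normalized by the total positive
#' weight, the negative part by the total (positive plus negative) weight,
#' each against its own configuration null model:
#' `Q = (1/v+) * sum_in(w+ - g*e+) - (1/(v+ + v-)) * sum_in(w- - g*e-)`.
#' The diagonal is ignored.
#'
#' @param W symmetric signed matrix.
#' @param labels community assignment vector.
#' @param gamma resolution parameter.
#' @return numeric modularity Q.
#' @export
modularity_signed <- function(W, labels, gamma = 1) {
  W <- as.matrix(W)
  diag(W) <- 0
  sp <- split_signs(W)
  comm <- match(labels, unique(labels))
  part <- function(M) {
    v <- sum(M)
    if (v == 0) return(c(0, 0))
    s <- rowSums(M)
    within <- sum(M * outer(comm, comm, "=="))
    null <- sum(tapply(s, comm, sum)^2) / v
    c(within - gamma * null, v)
  }
  pp <- part(sp$pos)
  nn <- part(sp$neg)
  vp <- pp[2]; vn <- nn[2]
  qpos <- if (vp > 0) pp[1] / vp else 0
  qneg <- if (vp + vn > 0) nn[1] / (vp + vn) else 0
  qpos - qneg
}

# One Louvain level: local moves on (pos, neg) matrices with self-loop
# diagonals held constant. Returns labels (1-based, contiguous).
louvain_level <- function(Wp, Wn, vp, vn, gamma) {
  m <- nrow(Wp)
  # self-loops (aggregated within-community weight) count toward strengths
  # for the null model but move with the node, so they are excluded from
  # the community-link sums
  dp <- diag(Wp)
  dn <- diag(Wn)
  diag(Wp) <- 0
  diag(Wn) <- 0
  sp <- rowSums(Wp) + dp
  sn <- rowSums(Wn) + dn
  labels <- seq_len(m)
  Sp <- sp
  Sn <- sn
  cp <- if (vp > 0) 2 / vp else 0
  cn <- if (vp + vn > 0) 2 / (vp + vn) else 0
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(m)) {
      a <- labels[i]
      # strengths to each community with i removed from its own
      kp <- rowsum_by(Wp[i, ], labels, m)
      kn <- rowsum_by(Wn[i, ], labels, m)
      Sp_i <- Sp; Sn_i <- Sn
      Sp_i[a] <- Sp_i[a] - sp[i]
      Sn_i[a] <- Sn_i[a] - sn[i]
      # each part's null model is normalized by that part's own total weight
      gain <- cp * (kp - gamma * sp[i] * Sp_i / max(vp, .Machine$double.eps)) -
        cn * (kn - gamma * sn[i] * Sn_i / max(vn, .Machine$double.eps))
      cand <- unique(labels)
      best <- cand[which.max(gain[cand])]
      if (gain[best] > gain[a] + 1e-12 && best != a) {
        labels[i] <- best
        Sp[a] <- Sp[a] - sp[i]; Sp[best] <- Sp[best] + sp[i]
        Sn[a] <- Sn[a] - sn[i]; Sn[best] <- Sn[best] + sn[i]
        moved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(labels = match(labels, unique(labels)), improved = improved_any)
}

rowsum_by <- function(x, groups, ngroups) {
  out <- numeric(ngroups)
  agg <- rowsum(x, groups)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Louvain community detection on a signed similarity matrix
#'
#' Greedy two-phase Louvain maximizing the asymmetric signed modularity
#' ([modularity_signed()]): repeated local node moves followed by community
#' aggregation, until no move improves Q. The diagonal of `sim` is ignored.
#' Node visiting order is randomized, so results are deterministic only
#' given `seed`.
#'
#' @param sim symmetric signed matrix (e.g. a person-by-person Pearson
#'   similarity matrix).
#' @param seed integer seed.
#' @param gamma resolution parameter (default 1).
#' @return A `partition` with labels, Q (`score`) and community count.
#' @export
louvain_signed <- function(sim, seed = NULL, gamma = 1) {
  sim <- as.matrix(sim)
  m <- nrow(sim)
  stopifnot(m >= 2, max(abs(sim - t(sim))) <= 1e-12)
  if (!is.null(seed)) set.seed(seed)
  W <- sim
  diag(W) <- 0
  sp <- split_signs(W)
  vp <- sum(sp$pos)
  vn <- sum(sp$neg)
  Wp <- sp$pos
  Wn <- sp$neg
  assign <- seq_len(m)  # original item -> current community
  repeat {
    lev <- louvain_level(Wp, Wn, vp, vn, gamma)
    if (!lev$improved || length(unique(lev$labels)) == nrow(Wp)) break
    assign <- lev$labels[assign]
    Wp <- aggregate_matrix(Wp, lev$labels)
    Wn <- aggregate_matrix(Wn, lev$labels)
    if (nrow(Wp) == 1L) break
  }
  q <- modularity_signed(sim, assign, gamma)
  new_partition(assign, q, "louvain_signed", nodes = rownames(sim))
}

aggregate_matrix <- function(M, labels) {
  k <- length(unique(labels))
  G <- matrix(0, nrow(M), k)
  G[cbind(seq_len(nrow(M)), labels)] <- 1
  t(G) %*% M %*% G
}

#' Person-by-person profile similarity
#'
#' Each variable in `measures` is z-scored against the full cohort; the
#' similarity of two individuals is the Pearson correlation of their
#' z-score vectors over those measures.
#'
#' @param table cohort data frame (the z-scoring reference).
#' @param rows integer indices of the individuals to compare (default: all
#'   rows).
#' @param measures character vector of at least 3 column names.
#' @return m-by-m symmetric correlation matrix with unit diagonal;
#'   rownames are the row indices into `table`.
#' @export
person_similarity <- function(table, rows = NULL, measures) {
  stopifnot(length(measures) >= 3, all(measures %in% names(table)))
  if (is.null(rows)) rows <- seq_len(nrow(table))
  stopifnot(length(rows) >= 2)
  Z <- scale(as.matrix(table[measures]))
  Z <- Z[rows, , drop = FALSE]
  sds <- apply(Z, 1, stats::sd)
  if (any(sds == 0))
    stop("constant profile for row(s): ",
         paste(rows[sds == 0], collapse = ", "))
  S <- stats::cor(t(Z))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rows, rows)
  S
}

#' Spinglass community detection on a signed network
#'
#' Minimizes the signed-network spinglass Hamiltonian — positive edges
#' reward co-assignment relative to a configuration null model, negative
#' edges penalize it — by simulated annealing with geometric cooling,
#' followed by greedy zero-temperature sweeps to a local optimum (so the
#' Hamiltonian never increases once the temperature is zero).
#'
#' @param net a [weighted_network()] (or coercible) with at least 2 nodes.
#' @param gamma_pos,gamma_neg resolution parameters of the positive and
#'   negative null terms.
#' @param seed integer seed (annealing is stochastic).
#' @param t_start,t_end,cooling annealing schedule: temperature runs from
#'   `t_start` down to `t_end` by factor `cooling`.
#' @param moves_per_temp proposed single-node moves per temperature
#'   (default `10 * p`).
#' @param max_communities cap on the number of spin states.
#' @return A `partition` with the final Hamiltonian as `score` (lower is
#'   better). An all-zero network yields the singleton partition, flagged
#'   with attribute `degenerate = TRUE`.
#' @export
spinglass_communities <- function(net, gamma_pos = 1, gamma_neg = 1,
                                  seed = NULL, t_start = 1, t_end = 0.01,
                                  cooling = 0.99, moves_per_temp = NULL,
                                  max_communities = 25) {
  net <- as_weighted_network(net)
  p <- length(net$nodes)
  stopifnot(p >= 2)
  if (!is.null(seed)) set.seed(seed)
  W <- net$weights * ifelse(net$signs == 0, 1, net$signs)
  diag(W) <- 0
  sp <- split_signs(W)
  Wp <- sp$pos; Wn <- sp$neg
  vp <- sum(Wp); vn <- sum(Wn)
  if (vp == 0 && vn == 0) {
    part <- new_partition(seq_len(p), 0, "spinglass", nodes = net$nodes)
    attr(part, "degenerate") <- TRUE
    return(part)
  }
  spos <- rowSums(Wp); sneg <- rowSums(Wn)
  q <- min(p, max_communities)
  if (is.null(moves_per_temp)) moves_per_temp <- 10L * p
  labels <- sample.int(q, p, replace = TRUE)
  Sp <- rowsum_by(spos, labels, q)
  Sn <- rowsum_by(sneg, labels, q)
  # energy of node i in community c (excluding i itself)
  node_energy <- function(i, c, inc) {
    members <- labels == c
    members[i] <- FALSE
    sp_c <- Sp[c] - if (inc) spos[i] else 0
    sn_c <- Sn[c] - if (inc) sneg[i] else 0
    epos <- sum(Wp[i, members]) -
      if (vp > 0) gamma_pos * spos[i] * sp_c / vp else 0
    eneg <- sum(Wn[i, members]) -
      if (vn > 0) gamma_neg * sneg[i] * sn_c / vn else 0
    -epos + eneg
  }
  do_pass <- function(temp, nmoves) {
    for (mv in seq_len(nmoves)) {
      i <- sample.int(p, 1)
      cnew <- sample.int(q, 1)
      cold <- labels[i]
      if (cnew == cold) next
      dH <- node_energy(i, cnew, FALSE) - node_energy(i, cold, TRUE)
      if (dH < 0 || (temp > 0 && stats::runif(1) < exp(-dH / temp))) {
        labels[i] <<- cnew
        Sp[cold] <<- Sp[cold] - spos[i]; Sp[cnew] <<- Sp[cnew] + spos[i]
        Sn[cold] <<- Sn[cold] - sneg[i]; Sn[cnew] <<- Sn[cnew] + sneg[i]
      }
    }
  }
  temp <- t_start
  while (temp > t_end) {
    do_pass(temp, moves_per_temp)
    temp <- temp * cooling
  }
  # greedy zero-temperature sweeps to a single-move local optimum
  repeat {
    moved <- FALSE
    for (i in seq_len(p)) {
      cold <- labels[i]
      energies <- vapply(seq_len(q), function(c)
        node_energy(i, c, c == cold), numeric(1))
      best <- which.min(energies)
      if (energies[best] < energies[cold] - 1e-12) {
        labels[i] <- best
        Sp[cold] <- Sp[cold] - spos[i]; Sp[best] <- Sp[best] + spos[i]
        Sn[cold] <- Sn[cold] - sneg[i]; Sn[best] <- Sn[best] + sneg[i]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  H <- spinglass_hamiltonian(W, labels, gamma_pos, gamma_neg)
  new_partition(labels, H, "spinglass", nodes = net$nodes)
}

#' Signed spinglass Hamiltonian of a labelled network
#'
#' @param W symmetric signed weight matrix (zero diagonal).
#' @param labels community assignment.
#' @param gamma_pos,gamma_neg resolution parameters.
#' @return numeric Hamiltonian (lower indicates better community
#'   structure).
#' @export
spinglass_hamiltonian <- function(W, labels, gamma_pos = 1, gamma_neg = 1) {
  W <- as.matrix(W)
  diag(W) <- 0
  sp <- split_signs(W)
  same <- outer(labels, labels, "==")
  ham_part <- function(M, gamma) {
    v <- sum(M)
    if (v == 0) return(0)
    s <- rowSums(M)
    null <- outer(s, s) / v
    sum((M - gamma * null)[same & upper.tri(M)])
  }
  -ham_part(sp$pos, gamma_pos) + ham_part(sp$neg, gamma_neg)
}

#' Consensus clustering of a similarity matrix
#'
#' Runs [louvain_signed()] `iterations` times with distinct seeds, builds
#' the co-assignment agreement matrix, zeroes entries below `tau`, and
#' re-clusters the agreement matrix the same way, repeating until all runs
#' agree (the agreement matrix is exactly 0/1 block-diagonal). The final Q
#' is reported on the original similarity matrix.
#'
#' @param sim symmetric signed similarity matrix.
#' @param iterations number of community-detection runs per round (>= 2).
#' @param tau agreement threshold in `[0, 1)`.
#' @param seed integer seed controlling all runs.
#' @param max_rounds cap on consensus rounds.
#' @return A `partition` with attributes `agreement` (final matrix) and
#'   `rounds`.
#' @export
consensus_cluster <- function(sim, iterations = 1000, tau = 0.5,
                              seed = NULL, max_rounds = 100) {
  stopifnot(iterations >= 2, tau >= 0, tau < 1)
  sim <- as.matrix(sim)
  m <- nrow(sim)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- function(k) sample.int(.Machine$integer.max - 1L, k)
  current <- sim
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("consensus clustering did not converge within ", max_rounds,
           " rounds (last agreement matrix is not 0/1 block diagonal)")
    seeds <- run_seeds(iterations)
    runs <- lapply(seeds, function(s) louvain_signed(current, seed = s))
    A <- matrix(0, m, m)
    for (r in runs) {
      lab <- r$labels
      A <- A + outer(lab, lab, "==")
    }
    A <- A / iterations
    if (all(A %in% c(0, 1))) {
      labels <- runs[[1]]$labels
      q <- modularity_signed(sim, labels)
      part <- new_partition(labels, q, "consensus", nodes = rownames(sim))
      attr(part, "agreement") <- A
      attr(part, "rounds") <- rounds
      return(part)
    }
    A[A < tau] <- 0
    diag(A) <- 0
    current <- A
  }
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two assignment vectors; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b assignment vectors of equal length (any label coding).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
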