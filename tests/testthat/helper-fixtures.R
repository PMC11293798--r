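# Shared fixtures and independent oracles for the test suite.
# Cohorts are cached per (tag) within a test run so expensive Gibbs draws
# happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(tag, expr) {
  if (!exists(tag, envir = .fixture_cache))
    assign(tag, force(expr), envir = .fixture_cache)
  get(tag, envir = .fixture_cache)
}

# p continuous unit-SD variables with no interactions, plus optionally one
# binary variable with the given prevalence as the first column
independent_spec <- function(p_cont = 3, prevalence = NULL) {
  nm <- paste0("Y", seq_len(p_cont))
  vars <- data.frame(name = nm, kind = "continuous", intercept = 0,
                     residual_sd = 1)
  if (!is.null(prevalence)) {
    vars <- rbind(data.frame(name = "G", kind = "binary",
                             intercept = qlogis(prevalence),
                             residual_sd = NA), vars)
  }
  mgm_spec(vars, matrix(0, nrow(vars), nrow(vars)))
}

# chain graph Y1 - Y2 - ... - Yp with constant coupling
chain_spec <- function(p = 5, theta = 0.35) {
  nm <- paste0("Y", seq_len(p))
  vars <- data.frame(name = nm, kind = "continuous", intercept = 0,
                     residual_sd = 1)
  th <- matrix(0, p, p)
  for (i in seq_len(p - 1)) th[i, i + 1] <- th[i + 1, i] <- theta
  mgm_spec(vars, th)
}

# two planted continuous edges (A-B, C-D) for bootstrap harnesses
two_edge_spec <- function(w_ab = 0.4, w_cd = 0.3) {
  vars <- data.frame(name = c("A", "B", "C", "D"), kind = "continuous",
                     intercept = 0, residual_sd = 1)
  th <- matrix(0, 4, 4)
  th[1, 2] <- th[2, 1] <- w_ab
  th[3, 4] <- th[4, 3] <- w_cd
  mgm_spec(vars, th)
}

mcs_cohort <- function(n = 8017, seed = 1, burn_in = 300) {
  cached(sprintf("mcs_%d_%d_%d", n, seed, burn_in),
         simulate(mcs_like_spec(), nsim = n, seed = seed,
                  burn_in = burn_in, thin = 1))
}

# random connected-ish weighted graph for oracle comparisons
random_network <- function(p, edge_prob = 0.45, signed = FALSE) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (runif(1) < edge_prob) {
      w <- runif(1, 0.1, 1)
      if (signed && runif(1) < 0.3) w <- -w
      W[i, j] <- W[j, i] <- w
    }
  }
  dimnames(W) <- list(LETTERS[seq_len(p)], LETTERS[seq_len(p)])
  weighted_network(W)
}

# Floyd-Warshall all-pairs shortest distances: independent oracle
fw_distances <- function(L) {
  p <- nrow(L)
  D <- L
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# exhaustive-path-enumeration betweenness: enumerate every simple path
# between every pair, find the geodesics, give each intermediate node
# fractional credit 1/(number of geodesics)
enum_betweenness <- function(L, tol = 1e-9) {
  p <- nrow(L)
  bc <- numeric(p)
  adj <- lapply(seq_len(p), function(i) which(is.finite(L[i, ]) & L[i, ] > 0))
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      u <- path[length(path)]
      if (u == t) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return(invisible())
      }
      for (v in adj[[u]]) if (!(v %in% path))
        walk(c(path, v), len + L[u, v])
    }
    walk(s, 0)
    out
  }
  for (s in seq_len(p - 1)) for (t in seq(s + 1, p)) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    geo <- which(lens <= min(lens) + tol)
    for (g in geo) {
      inter <- paths[[g]]$path
      inter <- inter[-c(1, length(inter))]
      bc[inter] <- bc[inter] + 1 / length(geo)
    }
  }
  bc
}

# exhaustive search over all set partitions of n items (Bell number sized);
# score_fn(labels) is maximized
best_partition_exhaustive <- function(n, score_fn) {
  best <- NULL
  best_score <- -Inf
  rec <- function(i, labels, maxl) {
    if (i > n) {
      s <- score_fn(labels)
      if (s > best_score) {
        best_score <<- s
        best <<- labels
      }
      return(invisible())
    }
    for (l in seq_len(maxl + 1)) {
      labels[i] <- l
      rec(i + 1, labels, max(maxl, l))
    }
  }
  rec(2, rep(1L, n), 1L)
  list(labels = best, score = best_score)
}

# noiseless block similarity matrix
block_similarity <- function(sizes, within = 0.9, between = -0.5) {
  m <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- matrix(between, m, m)
  S[outer(lab, lab, "==")] <- within
  diag(S) <- 1
  attr(S, "blocks") <- lab
  S
}
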