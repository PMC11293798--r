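#' Signed weighted network container
#'
#' A `weighted_network` is a symmetric zero-diagonal magnitude matrix plus a
#' sign matrix in \{-1, 0, +1\}; sign 0 on a present edge marks a
#' sign-undefined association (as arises between categorical variables).
#'
#' @param weights symmetric non-negative matrix of edge magnitudes with
#'   zero diagonal; a signed matrix may be supplied, in which case signs
#'   are split off automatically.
#' @param signs optional sign matrix; defaults to `sign(weights)` before
#'   the magnitude split.
#' @param nodes optional node labels (defaults to the matrix dimnames).
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, signs = NULL, nodes = NULL) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  stopifnot(ncol(weights) == p)
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("`weights` must be symmetric")
  if (any(diag(weights) != 0)) stop("`weights` must have a zero diagonal")
  if (is.null(signs)) signs <- sign(weights)
  signs <- as.matrix(signs)
  weights <- abs(weights)
  if (is.null(nodes)) nodes <- colnames(weights)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  dimnames(weights) <- dimnames(signs) <- list(nodes, nodes)
  signs[weights == 0] <- 0
  structure(list(nodes = nodes, weights = weights, signs = signs),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("Signed weighted network: %d nodes, %d edges\n",
              length(x$nodes), sum(x$weights[upper.tri(x$weights)] != 0)))
  invisible(x)
}

#' Coerce a fitted MGM to a weighted network
#'
#' @param x object to coerce.
#' @param ... unused.
#' @export
as_weighted_network <- function(x, ...) UseMethod("as_weighted_network")

#' @export
as_weighted_network.mgm_fit <- function(x, ...)
  weighted_network(x$weights, x$signs)

#' @export
as_weighted_network.weighted_network <- function(x, ...) x

#' Edge length matrix of a weighted network
#'
#' Lengths are `1 / |w|` for present edges (magnitude, so negative and
#' sign-undefined edges count by their absolute weight), `Inf` for absent
#' edges and 0 on the diagonal.
#'
#' @param net a [weighted_network()] (or coercible object).
#' @return numeric length matrix.
#' @export
edge_lengths <- function(net) {
  net <- as_weighted_network(net)
  L <- 1 / net$weights
  L[net$weights == 0] <- Inf
  diag(L) <- 0
  L
}

# Dijkstra from one source over a length matrix with deterministic
# lexicographic tie-breaking on the node sequence of equal-length paths.
dijkstra_lex <- function(L, src, tol = 1e-9) {
  p <- nrow(L)
  dist <- rep(Inf, p)
  paths <- vector("list", p)
  dist[src] <- 0
  paths[[src]] <- src
  settled <- rep(FALSE, p)
  repeat {
    cand <- which(!settled & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    settled[u] <- TRUE
    for (v in which(is.finite(L[u, ]) & L[u, ] > 0)) {
      if (settled[v]) next
      alt <- dist[u] + L[u, v]
      newpath <- c(paths[[u]], v)
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        paths[[v]] <- newpath
      } else if (abs(alt - dist[v]) <= tol &&
                 lex_less(newpath, paths[[v]])) {
        paths[[v]] <- newpath
      }
    }
  }
  list(dist = dist, paths = paths)
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Shortest paths from a source node
#'
#' Dijkstra's algorithm over the [edge_lengths()] of the network (lengths
#' `1/|w|`), with deterministic lexicographic tie-breaking among
#' equal-length geodesics. Unreachable targets are flagged with infinite
#' length and an empty node sequence.
#'
#' @param net a [weighted_network()] (or coercible).
#' @param source source node label.
#' @return list of path records, one per other node, each with `source`,
#'   `target`, `node_sequence` and `length`.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' W["A", "B"] <- W["B", "A"] <- 0.5
#' W["B", "C"] <- W["C", "B"] <- 0.5
#' shortest_paths_from(weighted_network(W), "A")
#' @export
shortest_paths_from <- function(net, source) {
  net <- as_weighted_network(net)
  stopifnot(source %in% net$nodes)
  L <- edge_lengths(net)
  src <- match(source, net$nodes)
  res <- dijkstra_lex(L, src)
  targets <- setdiff(seq_along(net$nodes), src)
  lapply(targets, function(t) {
    reachable <- is.finite(res$dist[t])
    list(source = source, target = net$nodes[t],
         node_sequence = if (reachable) net$nodes[res$paths[[t]]]
         else character(0),
         length = res$dist[t], reachable = reachable)
  })
}

#' All-pairs geodesic distances
#'
#' @param net a [weighted_network()] (or coercible).
#' @return symmetric matrix of geodesic lengths over edge lengths `1/|w|`.
#' @export
distance_matrix <- function(net) {
  net <- as_weighted_network(net)
  L <- edge_lengths(net)
  p <- nrow(L)
  D <- matrix(Inf, p, p, dimnames = dimnames(L))
  for (s in seq_len(p)) {
    D[s, ] <- dijkstra_lex(L, s)$dist
  }
  D
}

# Brandes betweenness with fractional credit over tied geodesics,
# endpoints excluded; tolerance-based tie detection on path lengths.
brandes_betweenness <- function(L, tol = 1e-9) {
  p <- nrow(L)
  bc <- numeric(p)
  for (s in seq_len(p)) {
    dist <- rep(Inf, p)
    sigma <- numeric(p)
    preds <- vector("list", p)
    dist[s] <- 0
    sigma[s] <- 1
    settled <- rep(FALSE, p)
    order_settled <- integer(0)
    repeat {
      cand <- which(!settled & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      settled[u] <- TRUE
      order_settled <- c(order_settled, u)
      for (v in which(is.finite(L[u, ]) & L[u, ] > 0)) {
        if (settled[v]) next
        alt <- dist[u] + L[u, v]
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(p)
    for (w in rev(order_settled)) {
      for (u in preds[[w]])
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # undirected: each pair counted from both endpoints
}

#' Centrality indices of a signed weighted network
#'
#' Four node-level indices: strength (sum of absolute edge weights),
#' expected influence (sum of signed edge weights; sign-undefined edges are
#' excluded because their contribution has no sign), betweenness (Brandes
#' accumulation over geodesics on edge lengths `1/|w|`, fractional credit
#' for ties, endpoints excluded) and closeness (inverse of the summed
#' geodesic distance to all reachable nodes). Each index is also
#' z-standardized across nodes.
#'
#' @param net a [weighted_network()] (or coercible).
#' @return data frame with raw and `z_`-prefixed columns per index. If the
#'   network is disconnected, closeness is computed on each node's
#'   reachable set and the result carries attribute `disconnected = TRUE`.
#' @export
centrality_table <- function(net) {
  net <- as_weighted_network(net)
  W <- net$weights
  S <- net$signs
  p <- nrow(W)
  strength <- rowSums(W)
  ei <- rowSums(W * S)  # sign 0 contributes nothing
  L <- edge_lengths(net)
  bc <- brandes_betweenness(L)
  D <- distance_matrix(net)
  diag(D) <- NA
  disconnected <- any(is.infinite(D[!is.na(D)]))
  closeness <- apply(D, 1, function(d) {
    d <- d[!is.na(d) & is.finite(d)]
    if (!length(d)) return(0)
    1 / sum(d)
  })
  zs <- function(v) if (stats::sd(v) == 0) rep(0, length(v))
  else (v - mean(v)) / stats::sd(v)
  out <- data.frame(
    node = net$nodes, strength = strength, expected_influence = ei,
    betweenness = bc, closeness = closeness,
    z_strength = zs(strength), z_expected_influence = zs(ei),
    z_betweenness = zs(bc), z_closeness = zs(closeness),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "disconnected") <- disconnected
  out
}

#' Shortest-path mediation report from a source node
#'
#' Classifies the relation between `source` and every other node as
#' `"direct"` (the geodesic is the single connecting edge), `"mediated"`
#' (the geodesic passes through intermediary nodes, listed in order) or
#' `"unreachable"`.
#'
#' @inheritParams shortest_paths_from
#' @return data frame with columns `target`, `relation`, `intermediaries`
#'   (comma-separated, `""` when none), `path_length` and `has_direct_edge`.
#' @examples
#' spec <- mcs_like_spec()
#' net <- weighted_network(spec$interactions)
#' mediation_report(net, "MS")
#' @export
mediation_report <- function(net, source) {
  net <- as_weighted_network(net)
  paths <- shortest_paths_from(net, source)
  W <- net$weights
  do.call(rbind, lapply(paths, function(pr) {
    direct_edge <- W[source, pr$target] != 0
    if (!pr$reachable) {
      rel <- "unreachable"; inter <- ""
    } else if (length(pr$node_sequence) == 2) {
      rel <- "direct"; inter <- ""
    } else {
      rel <- "mediated"
      inter <- paste(pr$node_sequence[-c(1, length(pr$node_sequence))],
                     collapse = ",")
    }
    data.frame(target = pr$target, relation = rel, intermediaries = inter,
               path_length = pr$length, has_direct_edge = direct_edge,
               stringsAsFactors = FALSE)
  }))
}
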