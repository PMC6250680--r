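# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the library routines) used by the implementation.

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, probabilities from binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p0 <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Literal step-up definition: q_(i) = min_{j >= i} p_(j) * n / j, clipped.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q
}

bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in which(adj[u, ] > 0)) {
        if (is.infinite(d[w])) { d[w] <- d[u] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- nxt
  }
  d
}

# Unnormalized betweenness by exhaustive enumeration of all shortest paths
# (distance-guided depth-first search), fractional credit per path.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  B <- numeric(n)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      dv <- bfs_dist(adj, v)
      if (is.infinite(dv[u])) next
      paths <- list()
      rec <- function(node, path) {
        if (node == v) {
          paths[[length(paths) + 1]] <<- path
          return(invisible())
        }
        for (w in which(adj[node, ] > 0)) {
          if (dv[w] == dv[node] - 1) rec(w, c(path, w))
        }
      }
      rec(u, u)
      k <- length(paths)
      for (pth in paths) {
        inner <- setdiff(pth, c(u, v))
        B[inner] <- B[inner] + 1 / k
      }
    }
  }
  B
}

# Hypergeometric upper tail P(X >= k) from binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Ward linkage (ward.D2 convention) by the Lance-Williams update applied
# by hand; returns merge heights and the partition after each merge.
oracle_ward2 <- function(D) {
  n <- nrow(D)
  Dm <- D; diag(Dm) <- Inf
  size <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- Dm[idx, idx, drop = FALSE]
    hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(hit)]; j <- idx[max(hit)]
    heights[step] <- Dm[i, j]
    for (k in idx) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <- sqrt(
        ((size[i] + size[k]) * Dm[i, k]^2 +
           (size[j] + size[k]) * Dm[j, k]^2 -
           size[k] * Dm[i, j]^2) / (size[i] + size[j] + size[k]))
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    active[j] <- FALSE
    Dm[j, ] <- Dm[, j] <- Inf
    partitions[[step]] <- members[active]
  }
  list(heights = heights, partitions = partitions)
}

# Node set within k steps of seeds, via powers of the adjacency matrix.
oracle_reachable <- function(adj, seeds, k) {
  n <- nrow(adj)
  M <- adj + diag(n)
  R <- diag(n)
  for (i in seq_len(k)) R <- (R %*% M > 0) * 1
  which(colSums(R[seeds, , drop = FALSE] > 0) > 0)
}

# Random undirected simple graph as igraph + adjacency matrix.
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  list(g = g, adj = adj)
}

partition_equal <- function(a, b) {
  norm <- function(p) {
    s <- lapply(unname(p), function(x) unname(sort(as.integer(x))))
    s[order(vapply(s, `[`, integer(1), 1))]
  }
  identical(norm(a), norm(b))
}
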