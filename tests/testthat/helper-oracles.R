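# Brute-force oracles, kept deliberately independent of the package's
# implementations: explicit loops and exhaustive enumeration only.

oracle_gfp <- function(mat) {
  vapply(seq_len(ncol(mat)), function(j) {
    u <- mat[, j]
    sqrt(sum((u - mean(u))^2) / length(u))
  }, numeric(1))
}

# all simple paths between s and t on an adjacency/length structure
enum_paths <- function(adj, s, t) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# exhaustive shortest weighted distance (lengths = 1/w) between all pairs
oracle_distances <- function(W) {
  n <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- enum_paths(W, s, t)
    if (length(paths) > 0) {
      best <- min(vapply(paths, function(p) {
        sum(len[cbind(p[-length(p)], p[-1])])
      }, numeric(1)))
      d[s, t] <- d[t, s] <- best
    }
  }
  d
}

oracle_char_path_length <- function(W) {
  d <- oracle_distances(W)
  n <- nrow(d)
  sum(d[row(d) != col(d)]) / (n * (n - 1))
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  Wh <- W / max(W)
  k <- rowSums(W > 0)
  ci <- numeric(n)
  for (i in 1:n) {
    if (k[i] < 2) next
    ti <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h)
        ti <- ti + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    }
    ti <- ti / 2
    ci[i] <- 2 * ti / (k[i] * (k[i] - 1))
  }
  mean(ci)
}

# betweenness by exhaustive shortest-path counting (weighted lengths 1/w)
oracle_betweenness <- function(W) {
  n <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- enum_paths(W, s, t)
    if (length(paths) == 0) next
    plens <- vapply(paths, function(p)
      sum(len[cbind(p[-length(p)], p[-1])]), numeric(1))
    best <- min(plens)
    shortest <- paths[abs(plens - best) < 1e-9]
    for (v in setdiff(1:n, c(s, t))) {
      thru <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + thru / length(shortest)
    }
  }
  bc
}

oracle_bfs_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in 1:n) {
    frontier <- s; lvl <- 0
    while (length(frontier) > 0) {
      lvl <- lvl + 1
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0))
        if (d[s, w] > lvl || (d[s, w] == Inf)) {
          if (is.infinite(d[s, w])) { d[s, w] <- lvl; nxt <- c(nxt, w) }
        }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_h_index <- function(adj) {
  k <- rowSums(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ] > 0)
    if (!length(nb)) return(0)
    h <- 0
    for (cand in seq_len(length(nb)))
      if (sum(k[nb] >= cand) >= cand) h <- cand
    h
  }, numeric(1))
}

oracle_centralities <- function(W, ci_radius = 2) {
  A <- (W > 0) * 1; diag(A) <- 0
  n <- nrow(A)
  k <- rowSums(A)
  NC <- vapply(1:n, function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) 0 else mean(k[nb])
  }, numeric(1))
  # local clustering as closed-triplet fraction
  cl <- vapply(1:n, function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    tri <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] > 0) tri <- tri + 1
    2 * tri / (k[i] * (k[i] - 1))
  }, numeric(1))
  CR <- vapply(1:n, function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) 0 else 10^(-cl[i]) * sum(k[nb] + 1)
  }, numeric(1))
  h <- oracle_h_index(A)
  LH <- vapply(1:n, function(i) h[i] + sum(h[which(A[i, ] > 0)]), numeric(1))
  d <- oracle_bfs_dist(A)
  CI <- vapply(1:n, function(i) {
    if (k[i] == 0) return(0)
    (k[i] - 1) * sum(k[which(d[i, ] == ci_radius)] - 1)
  }, numeric(1))
  list(DC = k, NC = NC, CR = CR, LH = LH,
       BC = oracle_betweenness(W), CI = CI)
}

# random connected weighted graph for metric oracles (connectivity checked
# by cheap reachability, not by the expensive path-enumeration oracle)
is_connected_adj <- function(W) {
  n <- nrow(W)
  seen <- rep(FALSE, n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

random_connected_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < density) W[i, j] <- W[j, i] <- runif(1, 0.5, 2)
    if (is_connected_adj(W)) return(W)
  }
}

adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  A
}

# small fixture graphs (<= 6 nodes) for the centrality oracle sweep
fixture_graphs <- function() {
  gs <- list(
    path3 = adj_from_edges(3, list(c(1, 2), c(2, 3))),
    star5 = adj_from_edges(6, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6))),
    cycle6 = adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1))),
    complete4 = adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))),
    tri_plus_edge = adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5)))
  )
  set.seed(99)
  for (r in 1:3) {
    n <- sample(4:6, 1)
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.6) A[i, j] <- A[j, i] <- 1
    gs[[paste0("rand", r)]] <- A
  }
  gs
}
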