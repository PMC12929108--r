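# Independent brute-force oracles for the graph-metric suite. These are
# deliberately naive (enumeration, matrix powers) and share no code with
# the package implementations.

# shortest-path distances by matrix-power reachability
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n)
  step <- diag(n)
  for (h in seq_len(n)) {
    step <- (step %*% adj) > 0
    newly <- step & (!reach)
    d[newly & d > h] <- h
    reach <- reach | step
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  s <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracle_degree <- function(adj) rowSums(adj)

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(1:n, function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b] == 1) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  sapply(1:n, function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  })
}

# betweenness by explicit enumeration of all shortest paths (DFS over the
# shortest-path DAG), each unordered pair counted once, endpoints excluded
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bc <- numeric(n)
  count_paths_through <- function(s, t) {
    # enumerate all shortest s-t paths, return (n_paths, via-counts)
    via <- numeric(n)
    total <- 0
    walk <- function(v, path) {
      if (v == t) {
        total <<- total + 1
        inner <- setdiff(path, c(s, t))
        via[inner] <<- via[inner] + 1
        return(invisible())
      }
      for (w in which(adj[v, ] == 1)) {
        if (d[s, w] == d[s, v] + 1 && d[w, t] == d[v, t] - 1) {
          walk(w, c(path, w))
        }
      }
    }
    walk(s, s)
    list(total = total, via = via)
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (is.finite(d[s, t]) && d[s, t] >= 2) {
      r <- count_paths_through(s, t)
      bc <- bc + r$via / r$total
    }
  }
  bc
}

# random undirected graph as adjacency matrix, optionally forced connected
random_adj <- function(n, p = 0.4, connected = FALSE) {
  repeat {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    a[up] <- rbinom(length(up), 1, p)
    a <- a + t(a)
    if (!connected) return(a)
    if (all(is.finite(oracle_distances(a)))) return(a)
  }
}

# all labeled graphs on n nodes as adjacency matrices (n small)
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[1:m]
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

star_graph <- function(leaves) {
  a <- matrix(0, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1
  a
}

complete_graph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

# random labeled tree via Prufer sequence
random_tree <- function(n) {
  if (n == 2) return(path_graph(2))
  pruf <- sample.int(n, n - 2, replace = TRUE)
  degree <- rep(1, n) + tabulate(pruf, n)
  a <- matrix(0, n, n)
  for (v in pruf) {
    leaf <- min(which(degree == 1))
    a[v, leaf] <- a[leaf, v] <- 1
    degree[leaf] <- degree[leaf] - 1
    degree[v] <- degree[v] - 1
  }
  ends <- which(degree == 1)
  a[ends[1], ends[2]] <- a[ends[2], ends[1]] <- 1
  a
}
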