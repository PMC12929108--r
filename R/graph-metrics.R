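#' Subject-level state network
#'
#' Entrywise mean of a subject's Fisher-z connectivity matrices over the
#' windows assigned to one state. Returns NULL (with a message) when the
#' subject never visits the state; such subjects are excluded from that
#' state's group comparisons.
#'
#' @param z_series A `dfc_zseries` for one subject.
#' @param labels That subject's window state labels (same length/order as
#'   `z_series$z`).
#' @param state State index.
#' @return N x N mean z matrix with zero diagonal, or NULL.
#' @export
state_network <- function(z_series, labels, state) {
  z <- if (inherits(z_series, "dfc_zseries")) z_series$z else z_series
  stopifnot(length(labels) == length(z))
  sel <- which(labels == state)
  if (length(sel) == 0) {
    message("state ", state, " never visited; no network")
    return(NULL)
  }
  m <- Reduce(`+`, z[sel]) / length(sel)
  diag(m) <- 0
  m
}

#' Binarize a weighted network at a sparsity threshold
#'
#' Retains the `floor(sparsity * N(N-1)/2)` largest-valued edges (signed
#' values ranked descending; set `absolute = TRUE` to rank |w|). Ties at
#' the cutoff are broken deterministically by value descending then
#' row-major edge index ascending.
#'
#' @param weighted N x N symmetric weight matrix.
#' @param sparsity Proportion of possible edges to retain, in (0, 1).
#' @param absolute Rank by absolute weight instead of signed weight.
#' @return N x N symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
threshold_by_sparsity <- function(weighted, sparsity, absolute = FALSE) {
  stopifnot(is.matrix(weighted), sparsity > 0, sparsity < 1)
  n <- nrow(weighted)
  w <- vectorize_fc((weighted + t(weighted)) / 2)
  if (absolute) w <- abs(w)
  m <- length(w)
  k <- floor(sparsity * m)
  keep <- order(-w, seq_len(m))[seq_len(k)]
  v <- numeric(m)
  v[keep] <- 1
  devectorize_fc(v, n)
}

as_igraph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Hop distances between all node pairs
#'
#' Unweighted shortest-path (breadth-first) distances; disconnected pairs
#' are Inf.
#'
#' @param adjacency Symmetric 0/1 matrix.
#' @return N x N distance matrix, zero diagonal.
#' @export
all_pairs_distances <- function(adjacency) {
  unname(igraph::distances(as_igraph(adjacency)))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over ordered node pairs, with
#' 1/Inf = 0 for disconnected pairs. 1 for a complete graph, 0 for an
#' empty one.
#'
#' @inheritParams all_pairs_distances
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(adjacency) {
  n <- nrow(adjacency)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  d <- all_pairs_distances(adjacency)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal degree centrality
#'
#' @inheritParams all_pairs_distances
#' @return Integer vector: each node's edge count.
#' @export
nodal_degree <- function(adjacency) {
  as.integer(igraph::degree(as_igraph(adjacency)))
}

#' Nodal clustering coefficient
#'
#' `2 * triangles / (k (k - 1))` for node degree k, 0 when k < 2.
#'
#' @inheritParams all_pairs_distances
#' @return Numeric vector in \[0, 1\].
#' @export
nodal_clustering <- function(adjacency) {
  igraph::transitivity(as_igraph(adjacency), type = "localundirected",
                       isolates = "zero")
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbors
#' (0 with fewer than 2 neighbors). `local_efficiency()` is the mean over
#' all nodes.
#'
#' @inheritParams all_pairs_distances
#' @return Numeric vector (or scalar for [local_efficiency()]) in
#'   \[0, 1\].
#' @export
nodal_local_efficiency <- function(adjacency) {
  n <- nrow(adjacency)
  vapply(seq_len(n), function(v) {
    nb <- which(adjacency[v, ] != 0)
    if (length(nb) < 2) return(0)
    global_efficiency(adjacency[nb, nb, drop = FALSE])
  }, numeric(1))
}

#' @rdname nodal_local_efficiency
#' @export
local_efficiency <- function(adjacency) {
  mean(nodal_local_efficiency(adjacency))
}

#' Nodal betweenness centrality
#'
#' Unnormalized shortest-path betweenness on the undirected graph (each
#' unordered pair counted once, endpoints excluded), computed by Brandes
#' dependency accumulation.
#'
#' @inheritParams all_pairs_distances
#' @param normalized Divide by (N-1)(N-2)/2.
#' @return Numeric vector of betweenness values (>= 0).
#' @export
betweenness_centrality <- function(adjacency, normalized = FALSE) {
  b <- igraph::betweenness(as_igraph(adjacency), directed = FALSE,
                           normalized = FALSE)
  if (normalized) {
    n <- nrow(adjacency)
    b <- b / ((n - 1) * (n - 2) / 2)
  }
  unname(b)
}

# Characteristic path length: mean finite distance over ordered pairs of
# the largest connected component.
char_path_length <- function(adjacency) {
  g <- as_igraph(adjacency)
  comp <- igraph::components(g)
  giant <- which(comp$membership == which.max(comp$csize))
  if (length(giant) < 2) return(0)
  d <- igraph::distances(g, v = giant, to = giant)
  mean(d[row(d) != col(d)])
}

#' Small-world coefficients
#'
#' Compares the graph's mean nodal clustering (C) and characteristic path
#' length (L, mean finite distance on the largest component) against an
#' ensemble of degree-preserving rewired null graphs:
#' gamma = C/C_null, lambda = L/L_null, sigma = gamma/lambda. A
#' small-world graph has sigma > 1. Each null applies 10 x |E| rewiring
#' swaps; when a graph cannot be rewired (e.g., complete), the nulls
#' equal the graph itself and sigma = 1.
#'
#' @inheritParams all_pairs_distances
#' @param n_null Number of null graphs (default 100).
#' @param seed Integer seed for the rewiring.
#' @return Tibble: gamma, lambda, sigma, clustering, char_path,
#'   largest_component_frac.
#' @export
small_worldness <- function(adjacency, n_null = 100, seed = NULL) {
  g <- as_igraph(adjacency)
  n_edges <- igraph::ecount(g)
  if (n_edges < 1) stop("graph has no edges", call. = FALSE)
  c_obs <- mean(nodal_clustering(adjacency))
  l_obs <- char_path_length(adjacency)
  comp <- igraph::components(g)
  nulls <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) {
      gn <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * n_edges))
      a <- unname(igraph::as_adjacency_matrix(gn, sparse = FALSE))
      c(mean(nodal_clustering(a)), char_path_length(a))
    })
  })
  c_null <- mean(vapply(nulls, `[`, numeric(1), 1))
  l_null <- mean(vapply(nulls, `[`, numeric(1), 2))
  gamma <- if (c_null == 0 && c_obs == 0) 1 else c_obs / c_null
  lambda <- if (l_null == 0 && l_obs == 0) 1 else l_obs / l_null
  tibble::tibble(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 clustering = c_obs, char_path = l_obs,
                 largest_component_frac = max(comp$csize) / igraph::vcount(g))
}

#' Area under a metric-vs-sparsity curve
#'
#' Trapezoidal integral of a graph metric over the sparsity sweep; the
#' standard way to aggregate thresholded-graph metrics into a single
#' per-subject value. A constant metric of 1 over the default 0.10-0.40
#' sweep has AUC 0.30 (the range width).
#'
#' @param sparsities Increasing sparsity levels.
#' @param values Metric values at those levels (same length).
#' @return Scalar AUC.
#' @export
metric_auc <- function(sparsities, values) {
  stopifnot(length(sparsities) == length(values), length(sparsities) >= 2,
            all(diff(sparsities) > 0))
  if (any(!is.finite(values))) stop("non-finite metric values",
                                    call. = FALSE)
  sum(diff(sparsities) * (head(values, -1) + values[-1]) / 2)
}

#' Graph metrics over a sparsity sweep
#'
#' Thresholds one weighted network at every sparsity level and computes
#' global metrics (GE, LE, and small-world gamma/lambda/sigma when
#' `small_world = TRUE`) and nodal metrics (Ne, Ncc, Dc, Bc), returned as
#' a long tidy table.
#'
#' @param weighted N x N symmetric weight matrix (e.g., a state network).
#' @param sparsities Sweep levels, default `seq(0.10, 0.40, by = 0.01)`.
#' @param small_world Compute small-world coefficients (slower; default
#'   FALSE).
#' @param n_null,seed Passed to [small_worldness()].
#' @return Tibble: sparsity, metric, node (NA for global metrics), value.
#' @export
graph_metric_sweep <- function(weighted,
                               sparsities = seq(0.10, 0.40, by = 0.01),
                               small_world = FALSE, n_null = 100,
                               seed = NULL) {
  node_names <- colnames(weighted) %||% paste0("ROI_", seq_len(ncol(weighted)))
  purrr::map_dfr(sparsities, function(sp) {
    a <- threshold_by_sparsity(weighted, sp)
    glob <- tibble::tibble(
      sparsity = sp,
      metric = c("ge", "le"),
      node = NA_character_,
      value = c(global_efficiency(a), local_efficiency(a)))
    if (small_world) {
      sw <- small_worldness(a, n_null = n_null, seed = seed)
      glob <- dplyr::bind_rows(glob, tibble::tibble(
        sparsity = sp, metric = c("gamma", "lambda", "sigma"),
        node = NA_character_,
        value = c(sw$gamma, sw$lambda, sw$sigma)))
    }
    nodal <- tibble::tibble(
      sparsity = sp,
      metric = rep(c("ne", "ncc", "dc", "bc"), each = length(node_names)),
      node = rep(node_names, 4),
      value = c(nodal_local_efficiency(a), nodal_clustering(a),
                as.numeric(nodal_degree(a)), betweenness_centrality(a)))
    dplyr::bind_rows(glob, nodal)
  })
}

#' AUC summary of a sweep table
#'
#' Collapses a [graph_metric_sweep()] table (optionally stacked over
#' subjects/states) to one AUC per metric/node combination within each
#' extra grouping column present.
#'
#' @param sweep_tbl Long table with columns sparsity, metric, node, value
#'   plus any identifier columns.
#' @return Tibble with one `auc` per group.
#' @export
sweep_auc <- function(sweep_tbl) {
  extra <- setdiff(names(sweep_tbl), c("sparsity", "value"))
  sweep_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(extra))) |>
    dplyr::arrange(.data$sparsity, .by_group = TRUE) |>
    dplyr::summarise(auc = metric_auc(.data$sparsity, .data$value),
                     .groups = "drop")
}
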