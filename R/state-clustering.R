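#' Vectorize a symmetric connectivity matrix
#'
#' Row-major strict upper triangle: for N ROIs the feature vector has
#' N(N-1)/2 entries ordered (1,2), (1,3), ..., (1,N), (2,3), ...
#' `devectorize_fc()` inverts the operation (zero diagonal).
#'
#' @param z_matrix N x N symmetric matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @export
vectorize_fc <- function(z_matrix) {
  stopifnot(is.matrix(z_matrix), nrow(z_matrix) == ncol(z_matrix))
  if (max(abs(z_matrix - t(z_matrix))) > 1e-10) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  t(z_matrix)[lower.tri(z_matrix)]
}

#' @rdname vectorize_fc
#' @param v Feature vector of length N(N-1)/2.
#' @param n Matrix dimension N.
#' @export
devectorize_fc <- function(v, n) {
  stopifnot(length(v) == n * (n - 1) / 2)
  mt <- matrix(0, n, n)
  mt[lower.tri(mt)] <- v   # column-major lower of t(m) = row-major upper of m
  m <- t(mt)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Pool windowed connectivity into a feature matrix
#'
#' Stacks every subject's vectorized upper-triangle z values into the
#' (subject, window) x feature matrix that state clustering operates on.
#'
#' @param z_by_subject Named list of `dfc_zseries` (one per subject).
#' @return A list of class `dfc_features`: `features` (rows = windows
#'   pooled over subjects), `index` (tibble: subject_id, window, start).
#' @export
build_window_features <- function(z_by_subject) {
  stopifnot(length(z_by_subject) >= 1, !is.null(names(z_by_subject)))
  rows <- purrr::map(z_by_subject, function(zs) {
    t(vapply(zs$z, vectorize_fc,
             numeric(nrow(zs$z[[1]]) * (nrow(zs$z[[1]]) - 1) / 2)))
  })
  index <- purrr::map_dfr(names(z_by_subject), function(id) {
    zs <- z_by_subject[[id]]
    tibble::tibble(subject_id = id, window = seq_along(zs$z),
                   start = zs$starts)
  })
  features <- do.call(rbind, rows)
  if (any(!is.finite(features))) {
    stop("non-finite values in pooled window features", call. = FALSE)
  }
  structure(list(features = features, index = index),
            class = "dfc_features")
}

#' Manhattan-distance K-means over pooled connectivity windows
#'
#' True L1 K-means: windows are assigned to the centroid at minimum
#' Manhattan distance and centroids are updated as coordinate-wise medians
#' of their members (the L1-optimal center), iterated to label
#' convergence. The best of `n_init` random restarts by total cost is
#' returned. Empty clusters are reseeded from the point farthest from its
#' assigned centroid.
#'
#' @param features A `dfc_features` object or plain numeric matrix
#'   (rows = observations).
#' @param k Number of states (1 <= k <= rows).
#' @param n_init Number of restarts (default 20).
#' @param max_iter Iteration cap per restart (default 300).
#' @param init `"++"` (default) seeds each restart k-means++ style —
#'   centroids drawn with probability proportional to L1 distance from
#'   the nearest centroid chosen so far — which finds good optima far
#'   more reliably than `"random"` uniform seeding.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `dfc_partition`: `k`, `centroids` (k x d),
#'   `labels` (1..k per pooled window), `cost` (total L1 distance),
#'   `sizes`, `cost_trace` (per-iteration cost of the winning restart,
#'   nonincreasing), `index` (if `features` carried one), `seed`.
#' @export
kmeans_manhattan <- function(features, k, n_init = 20, max_iter = 300,
                             init = c("++", "random"), seed = NULL) {
  x <- if (inherits(features, "dfc_features")) features$features else features
  index <- if (inherits(features, "dfc_features")) features$index else NULL
  init <- match.arg(init)
  stopifnot(is.matrix(x), k >= 1, k <= nrow(x))
  init_idx <- with_seed(seed, {
    if (init == "random") {
      t(vapply(seq_len(n_init), function(i) sample.int(nrow(x), k),
               integer(k)))
    } else {
      t(vapply(seq_len(n_init), function(i) kpp_init(x, k), integer(k)))
    }
  })
  fit <- kmeans_l1_cpp(x, as.integer(k), init_idx, as.integer(max_iter))
  structure(
    list(k = as.integer(k), centroids = fit$centroids,
         labels = as.integer(fit$labels), cost = fit$cost,
         sizes = tabulate(fit$labels, k), iterations = fit$iterations,
         n_reseeds = fit$n_reseeds, cost_trace = fit$cost_trace,
         index = index, seed = seed),
    class = "dfc_partition")
}

# k-means++ seeding under the L1 metric: first centroid uniform, each
# subsequent one drawn with probability proportional to the Manhattan
# distance to the nearest already-chosen centroid.
kpp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k == 1) return(idx)
  d <- rowSums(abs(x - x[rep(idx[1], n), , drop = FALSE]))
  for (c in 2:k) {
    if (all(d == 0)) {
      idx[c] <- sample.int(n, 1)
    } else {
      idx[c] <- sample.int(n, 1, prob = d)
    }
    dn <- rowSums(abs(x - x[rep(idx[c], n), , drop = FALSE]))
    d <- pmin(d, dn)
  }
  idx
}

#' @export
print.dfc_partition <- function(x, ...) {
  cat("<dfc_partition> k = ", x$k, ", ", length(x$labels),
      " windows, total L1 cost = ", format(x$cost, digits = 6),
      "\nstate sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn kmeans_manhattan One row per pooled window with its state
#'   label (joined to the subject/window index when available).
#' @param x A `dfc_partition`.
#' @param ... Unused.
#' @export
tidy.dfc_partition <- function(x, ...) {
  base <- if (!is.null(x$index)) x$index else
    tibble::tibble(window = seq_along(x$labels))
  dplyr::mutate(base, state = x$labels)
}

#' @describeIn kmeans_manhattan One-row fit summary.
#' @export
glance.dfc_partition <- function(x, ...) {
  tibble::tibble(k = x$k, n_windows = length(x$labels),
                 total_cost = x$cost, iterations = x$iterations,
                 n_reseeds = x$n_reseeds,
                 min_state_size = min(x$sizes))
}

#' Elbow-based selection of the number of states
#'
#' Fits [kmeans_manhattan()] for each candidate K and selects the elbow as
#' the interior K maximising the discrete second difference of the cost
#' curve, `cost(k-1) - 2 cost(k) + cost(k+1)` — the point of largest
#' curvature. Ties go to the smallest K.
#'
#' @inheritParams kmeans_manhattan
#' @param k_range Increasing candidate counts (default 2:8); at least 3
#'   values are needed to form a second difference.
#' @return An object of class `dfc_elbow`: `curve` (tibble k, cost),
#'   `selected_k`, and the fitted `dfc_partition` for each K in `fits`.
#' @export
select_k_elbow <- function(features, k_range = 2:8, n_init = 20,
                           max_iter = 300, init = c("++", "random"),
                           seed = NULL) {
  init <- match.arg(init)
  k_range <- as.integer(k_range)
  if (length(k_range) < 3) {
    stop("need at least 3 candidate values of k for the elbow criterion",
         call. = FALSE)
  }
  stopifnot(all(diff(k_range) > 0))
  seeds <- derive_seeds(seed, length(k_range))
  fits <- purrr::map2(k_range, seeds, function(k, s) {
    kmeans_manhattan(features, k, n_init = n_init, max_iter = max_iter,
                     init = init, seed = s)
  })
  costs <- vapply(fits, function(f) f$cost, numeric(1))
  interior <- 2:(length(k_range) - 1)
  curvature <- costs[interior - 1] - 2 * costs[interior] + costs[interior + 1]
  sel <- k_range[interior[which.max(curvature)]]  # which.max: lowest tie wins
  structure(
    list(curve = tibble::tibble(k = k_range, cost = costs),
         selected_k = sel, fits = setNames(fits, paste0("k", k_range)),
         seed = seed),
    class = "dfc_elbow")
}

#' @export
print.dfc_elbow <- function(x, ...) {
  cat("<dfc_elbow> selected k =", x$selected_k, "\n")
  print(x$curve)
  invisible(x)
}

#' @describeIn select_k_elbow The elbow curve as a tibble with the
#'   second-difference curvature and selection flag.
#' @param x A `dfc_elbow`.
#' @param ... Unused.
#' @export
tidy.dfc_elbow <- function(x, ...) {
  n <- nrow(x$curve)
  curv <- c(NA, x$curve$cost[1:(n - 2)] - 2 * x$curve$cost[2:(n - 1)] +
              x$curve$cost[3:n], NA)
  dplyr::mutate(x$curve, curvature = curv,
                selected = .data$k == x$selected_k)
}

#' @describeIn select_k_elbow Cost-vs-K curve with the selected elbow
#'   marked.
#' @param object A `dfc_elbow`.
#' @export
autoplot.dfc_elbow <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::labs(x = "number of states K", y = "total L1 cost",
                  title = paste0("Elbow selection: K = ",
                                 object$selected_k)) +
    ggplot2::theme_minimal()
}

#' State-validity check
#'
#' A clustered state is considered valid when it holds at least
#' `min_windows` pooled windows; the analysis should not be interpreted
#' (and the pipeline aborts) when any state fails.
#'
#' @param partition A `dfc_partition`.
#' @param min_windows Minimum pooled window count per state (default 10).
#' @return Tibble: state, n_windows, valid.
#' @export
validate_states <- function(partition, min_windows = 10) {
  tibble::tibble(state = seq_len(partition$k),
                 n_windows = partition$sizes,
                 valid = partition$sizes >= min_windows)
}

#' Rank states by connectivity strength
#'
#' Renumbers states by descending mean absolute centroid connectivity, so
#' state 1 ("state I") is always the most strongly connected pattern.
#' Exact ties keep the original order.
#'
#' @param partition A `dfc_partition`.
#' @return The partition with centroids, labels and sizes relabeled; the
#'   applied permutation is stored as `state_order` (old index per new
#'   state).
#' @export
rank_states_by_strength <- function(partition) {
  strength <- rowMeans(abs(partition$centroids))
  ord <- order(-strength, seq_along(strength))
  remap <- match(seq_len(partition$k), ord)
  partition$centroids <- partition$centroids[ord, , drop = FALSE]
  partition$labels <- remap[partition$labels]
  partition$sizes <- partition$sizes[ord]
  partition$state_order <- ord
  partition
}

#' Optimal state matching against a reference labeling
#'
#' Finds the permutation of estimated state labels maximising agreement
#' with a reference (e.g., planted ground truth), by exhaustive search
#' over the K! permutations (intended for small K).
#'
#' @param truth,estimate Integer label vectors of equal length, values in
#'   1..k.
#' @param k Number of states.
#' @return List: `accuracy` (best agreement proportion), `permutation`
#'   (new label for each estimated label).
#' @export
match_states <- function(truth, estimate, k) {
  stopifnot(length(truth) == length(estimate), k <= 7)
  perms <- permutations_of(k)
  acc <- apply(perms, 1, function(p) mean(p[estimate] == truth))
  best <- which.max(acc)
  list(accuracy = acc[best], permutation = perms[best, ])
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], k, after = pos - 1)
    }
  }
  out
}

#' Majority-vote window ground truth
#'
#' Converts a time-point-level ground-truth state sequence into
#' window-level labels by majority vote within each window (ties go to
#' the lowest state index), for comparing clustering output against the
#' generative truth.
#'
#' @param states Length-T integer state sequence.
#' @param spec A [window_spec()].
#' @return Integer vector of window labels.
#' @export
window_truth <- function(states, spec = window_spec()) {
  w <- extract_windows(matrix(states, ncol = 1), spec)
  vapply(w$segments, function(s) {
    tab <- tabulate(s[, 1])
    which.max(tab)
  }, integer(1))
}
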