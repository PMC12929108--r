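#' Residualize an outcome on nuisance covariates
#'
#' Least-squares residuals of the outcome on an intercept plus the
#' covariate columns; the adjustment step shared by the permutation tests
#' and partial correlations.
#'
#' @param values Numeric outcome, one value per subject.
#' @param covariates Data frame (or matrix) of numeric covariates; NULL
#'   or zero columns reduces to centering.
#' @return Numeric residual vector.
#' @export
covariate_adjust <- function(values, covariates = NULL) {
  n <- length(values)
  x <- cbind(intercept = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    if (any(!is.finite(cm))) stop("missing/non-finite covariate values",
                                  call. = FALSE)
    x <- cbind(x, cm)
  }
  q <- qr(x)
  if (q$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), q$pivot[seq_len(q$rank)])]
    stop("collinear design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(qr.resid(q, values))
}

#' Covariate-adjusted two-group permutation test
#'
#' Freedman-Lane style inference: the outcome is residualized on the
#' covariates, the observed statistic is the difference of group means of
#' the residuals, and the null is built by permuting the residuals'
#' group assignment. Two-sided p with add-one correction, so
#' p >= 1/(n_perm + 1).
#'
#' @param values Numeric outcome per subject.
#' @param groups Group labels (exactly 2 levels, each >= 2 subjects).
#' @param covariates Optional covariate data frame (e.g., age, gender).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return Tibble of class `dfc_permtest`: statistic (mean of group 1
#'   minus mean of group 2, groups in factor-level order), p_value,
#'   n_perm, plus the null statistics in `attr(, "null_stats")`.
#' @export
permutation_test <- function(values, groups, covariates = NULL,
                             n_perm = 5000, seed = NULL) {
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs >= 2 subjects",
                                   call. = FALSE)
  r <- covariate_adjust(values, covariates)
  g1 <- groups == lev[1]
  obs <- mean(r[g1]) - mean(r[!g1])
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rp <- sample(r)
      mean(rp[g1]) - mean(rp[!g1])
    }, numeric(1))
  })
  if (sd(r) == 0) {
    p <- 1
  } else {
    p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_perm + 1)
  }
  out <- tibble::tibble(group_1 = lev[1], group_2 = lev[2],
                        statistic = obs, p_value = p, n_perm = n_perm)
  attr(out, "null_stats") <- null_stats
  class(out) <- c("dfc_permtest", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR adjustment: adjusted p_i = min over j >= i of m p_(j) / j,
#' capped at 1; rejections at the target q.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @param family Optional label recording which comparisons form the
#'   correction family.
#' @return Tibble: p_raw, p_adj, reject, family.
#' @export
fdr_bh <- function(p_values, q = 0.05, family = NA_character_) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_adj = adj, reject = adj < q,
                 family = family)
}

#' Spearman partial correlation
#'
#' Rank-transforms x, y and the covariates (average ranks for ties),
#' residualizes the ranked x and y on an intercept plus the ranked
#' covariates, and correlates the residuals — equivalent to the
#' recursive partial-correlation formula applied to Spearman
#' correlations. The p-value comes from the t distribution with
#' n - 2 - (number of covariates) degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional covariate data frame.
#' @return Tibble: rho, p_value, n, df, n_covariates.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  ncov <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= ncov + 2) stop("too few observations for the design",
                          call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(lapply(as.data.frame(covariates), rank))
  }
  rx <- covariate_adjust(rank(x), covariates)
  ry <- covariate_adjust(rank(y), covariates)
  if (sd(rx) < n * 1e-12 || sd(ry) < n * 1e-12) {
    stop("zero residual variance; correlation undefined", call. = FALSE)
  }
  rho <- cor(rx, ry)
  df <- n - 2L - ncov
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(-abs(tval), df)
  if (abs(rho) >= 1) p <- 0
  tibble::tibble(rho = rho, p_value = p, n = n, df = df,
                 n_covariates = ncov)
}

# Hat-matrix residualizer and per-permutation group-difference t stats for
# a subjects x edges outcome matrix (shared machinery for nbs()).
edge_t_stats <- function(res_mat, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(res_mat[g1, , drop = FALSE])
  m2 <- colMeans(res_mat[!g1, , drop = FALSE])
  v1 <- apply(res_mat[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(res_mat[!g1, , drop = FALSE], 2, stats::var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

#' Network-based statistic (NBS)
#'
#' Familywise inference over connected components of suprathreshold
#' edges. Each edge's two-sample t statistic is computed on
#' covariate-adjusted values and converted to a parametric p; edges with
#' p below `edge_alpha` form a graph whose connected components are the
#' candidate effects. Component-level corrected p-values come from a
#' permutation null of the maximum component size (edge count), using a
#' single permutation schedule shared across edges (residuals permuted,
#' Freedman-Lane style).
#'
#' @param edge_values Subjects x edges matrix of connectivity outcomes.
#' @param groups Two-level group labels.
#' @param covariates Optional covariate data frame.
#' @param edge_index Two-column matrix of node indices per edge column;
#'   defaults to the row-major upper triangle of an N-node network
#'   inferred from the edge count.
#' @param edge_alpha Primary edge threshold on the parametric p (default
#'   0.001).
#' @param comp_alpha Component-level significance level (default 0.05).
#' @param n_iter Permutations for the component null (default 1000).
#' @param seed Integer seed.
#' @return List of class `dfc_nbs`: `components` (tibble: component id,
#'   n_edges, p_corrected, significant), `edges` (tibble: edge, node_1,
#'   node_2, t, p, component), `null_max_size`, parameters.
#' @export
nbs <- function(edge_values, groups, covariates = NULL, edge_index = NULL,
                edge_alpha = 0.001, comp_alpha = 0.05, n_iter = 1000,
                seed = NULL) {
  stopifnot(is.matrix(edge_values))
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  if (length(lev) != 2 || any(table(groups) < 2)) {
    stop("two groups with >= 2 subjects each required", call. = FALSE)
  }
  n <- nrow(edge_values)
  m <- ncol(edge_values)
  if (is.null(edge_index)) {
    nn <- (1 + sqrt(1 + 8 * m)) / 2
    if (abs(nn - round(nn)) > 1e-9) {
      stop("edge count is not N(N-1)/2; supply edge_index", call. = FALSE)
    }
    nn <- round(nn)
    edge_index <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
    edge_index <- edge_index[order(edge_index[, 1], edge_index[, 2]), ,
                             drop = FALSE]
  }
  res <- apply(edge_values, 2, covariate_adjust, covariates = covariates)
  g1 <- groups == lev[1]
  ncov <- if (is.null(covariates)) 0L else NCOL(covariates)
  df <- n - 2L - ncov
  t_obs <- edge_t_stats(res, g1)
  p_obs <- 2 * pt(-abs(t_obs), df)
  supra <- p_obs < edge_alpha

  comp_of <- function(supra_edges) {
    if (!any(supra_edges)) return(list(sizes = integer(0),
                                       membership = rep(NA_integer_, m)))
    el <- edge_index[supra_edges, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(as.character(el), ncol = 2), directed = FALSE)
    cmp <- igraph::components(g)
    vnames <- igraph::V(g)$name
    memb_node <- setNames(cmp$membership, vnames)
    edge_comp <- rep(NA_integer_, m)
    edge_comp[supra_edges] <- memb_node[as.character(el[, 1])]
    sizes <- as.integer(table(edge_comp[supra_edges]))
    list(sizes = sizes, membership = edge_comp)
  }
  obs <- comp_of(supra)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      rp <- res[sample.int(n), , drop = FALSE]
      tp <- edge_t_stats(rp, g1)
      pp <- 2 * pt(-abs(tp), df)
      s <- comp_of(pp < edge_alpha)$sizes
      if (length(s) == 0) 0L else max(s)
    }, integer(1))
  })

  comp_tbl <- if (length(obs$sizes) == 0) {
    tibble::tibble(component = integer(0), n_edges = integer(0),
                   p_corrected = numeric(0), significant = logical(0))
  } else {
    tibble::tibble(
      component = seq_along(obs$sizes),
      n_edges = obs$sizes,
      p_corrected = vapply(obs$sizes, function(s) {
        (1 + sum(null_max >= s)) / (n_iter + 1)
      }, numeric(1))) |>
      dplyr::mutate(significant = .data$p_corrected < comp_alpha)
  }
  edges_tbl <- tibble::tibble(
    edge = seq_len(m), node_1 = edge_index[, 1], node_2 = edge_index[, 2],
    t = t_obs, p = p_obs, component = obs$membership)
  structure(
    list(components = comp_tbl, edges = edges_tbl, null_max_size = null_max,
         edge_alpha = edge_alpha, comp_alpha = comp_alpha, n_iter = n_iter,
         groups = lev, seed = seed),
    class = "dfc_nbs")
}

#' @export
print.dfc_nbs <- function(x, ...) {
  cat("<dfc_nbs> ", x$groups[1], " vs ", x$groups[2], ": ",
      nrow(x$components), " suprathreshold component(s)\n", sep = "")
  if (nrow(x$components)) print(x$components)
  invisible(x)
}

#' @describeIn nbs Component table.
#' @param x A `dfc_nbs`.
#' @param ... Unused.
#' @export
tidy.dfc_nbs <- function(x, ...) x$components

#' Demographic and clinical comparison utilities
#'
#' Thin wrappers over the standard tests used to describe a cohort:
#' Kruskal-Wallis for age across groups, chi-square (without continuity
#' correction) for gender proportions, and Mann-Whitney U for a clinical
#' score between two named groups.
#'
#' @param manifest Tibble with columns group, age, gender and optionally
#'   the score named by `score`.
#' @param score Optional clinical score column (e.g., "nrs").
#' @param score_groups The two groups compared on the score.
#' @return Tibble: test, statistic, df, p_value.
#' @export
demographics_tests <- function(manifest, score = NULL,
                               score_groups = c("HZ", "PHN")) {
  need <- c("group", "age", "gender")
  if (!all(need %in% names(manifest))) {
    stop("manifest must contain columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "),
         call. = FALSE)
  }
  kw <- stats::kruskal.test(manifest$age, as.factor(manifest$group))
  cs <- stats::chisq.test(table(manifest$gender, manifest$group),
                          correct = FALSE)
  out <- tibble::tibble(
    test = c("kruskal_wallis_age", "chisq_gender"),
    statistic = c(unname(kw$statistic), unname(cs$statistic)),
    df = c(unname(kw$parameter), unname(cs$parameter)),
    p_value = c(kw$p.value, cs$p.value))
  if (!is.null(score)) {
    if (!score %in% names(manifest)) {
      stop("score column '", score, "' missing", call. = FALSE)
    }
    sub <- manifest[manifest$group %in% score_groups, ]
    mw <- stats::wilcox.test(sub[[score]][sub$group == score_groups[1]],
                             sub[[score]][sub$group == score_groups[2]],
                             exact = FALSE)
    out <- dplyr::bind_rows(out, tibble::tibble(
      test = paste0("mann_whitney_", score),
      statistic = unname(mw$statistic), df = NA_real_,
      p_value = mw$p.value))
  }
  out
}

#' Pairwise covariate-adjusted group contrasts on a metric table
#'
#' Runs [permutation_test()] for every metric column and group pair, then
#' applies [fdr_bh()] within the stated family (all states x contrasts of
#' one metric kind by default).
#'
#' @param data Tibble with one row per subject: group, covariate columns,
#'   and the metric columns to test.
#' @param metrics Character vector of metric column names.
#' @param covariate_cols Covariate column names (default age, gender).
#' @param n_perm,seed Passed to [permutation_test()].
#' @param q FDR level.
#' @return Tibble: metric, group_1, group_2, statistic, p_raw, p_adj,
#'   reject.
#' @export
group_contrasts <- function(data, metrics,
                            covariate_cols = c("age", "gender"),
                            n_perm = 5000, seed = NULL, q = 0.05) {
  groups <- unique(data$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  seeds <- derive_seeds(seed, length(metrics) * length(pairs))
  i <- 0L
  res <- purrr::map_dfr(metrics, function(mt) {
    purrr::map_dfr(pairs, function(pr) {
      i <<- i + 1L
      sub <- data[data$group %in% pr, ]
      pt_ <- permutation_test(sub[[mt]], sub$group,
                              covariates = sub[covariate_cols],
                              n_perm = n_perm, seed = seeds[i])
      tibble::tibble(metric = mt, group_1 = pt_$group_1,
                     group_2 = pt_$group_2, statistic = pt_$statistic,
                     p_raw = pt_$p_value)
    })
  })
  adj <- fdr_bh(res$p_raw, q = q, family = "metric_family")
  dplyr::bind_cols(res, dplyr::select(adj, "p_adj", "reject"))
}
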