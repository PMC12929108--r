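#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults mirror the
#' standard resting-state dFC protocol: 30-TR windows stepped by 1 TR,
#' elbow selection over K = 2..8, sparsity sweep 0.10-0.40 in steps of
#' 0.01, 5,000 permutations, NBS edge alpha 0.001 / component alpha 0.05
#' / 1,000 iterations, FDR q 0.05.
#'
#' @param input Either "synthetic" (simulate the default cohort) or a
#'   path to a cohort manifest for [load_roi_tables()].
#' @param window A [window_spec()].
#' @param k Fixed number of states, or NULL to select by elbow.
#' @param k_range Candidate K values for the elbow.
#' @param n_init K-means restarts.
#' @param sparsities Sparsity sweep levels.
#' @param n_perm Permutations for group contrasts.
#' @param nbs_iter NBS permutations.
#' @param min_windows State-validity bound.
#' @param run_graph_stats Compute the nodal AUC contrast tables (the
#'   slowest stage); default TRUE.
#' @param out_dir Output directory or NULL to skip writing files.
#' @param seed Master seed; every stage seed derives from it.
#' @param ... Overrides stored verbatim (cohort generator arguments:
#'   `model`, `groups`, `n_timepoints`).
#' @return A list of class `dfc_config`.
#' @export
dfc_config <- function(input = "synthetic", window = window_spec(),
                       k = NULL, k_range = 2:8, n_init = 20,
                       sparsities = seq(0.10, 0.40, by = 0.01),
                       n_perm = 5000, nbs_iter = 1000, min_windows = 10,
                       run_graph_stats = TRUE, out_dir = NULL,
                       seed = 1L, ...) {
  structure(
    c(list(input = input, window = window, k = k, k_range = k_range,
           n_init = n_init, sparsities = sparsities, n_perm = n_perm,
           nbs_iter = nbs_iter, min_windows = min_windows,
           run_graph_stats = run_graph_stats, out_dir = out_dir,
           seed = as.integer(seed)),
      list(...)),
    class = "dfc_config")
}

#' Load ROI time-series tables from a cohort manifest
#'
#' The manifest is a delimited table with columns subject_id, group, age,
#' gender, path; each path points to a delimited file whose header row
#' holds the ROI labels. All subjects must share the same ROI set in the
#' same order, and series must be finite.
#'
#' @param manifest_path Path to the manifest file.
#' @return A list shaped like a `dfc_cohort` (manifest tibble + named
#'   series list; no ground truth).
#' @export
load_roi_tables <- function(manifest_path) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "group", "age", "gender", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest missing column(s): ",
         paste(setdiff(need, names(manifest)), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  series <- list()
  labels_ref <- NULL
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(manifest$path[i]))
    tbl <- readr::read_tsv(p, show_col_types = FALSE)
    m <- as.matrix(tbl)
    if (any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stop("non-finite value in ", manifest$subject_id[i], " at row ",
           bad[1], ", column ", colnames(m)[bad[2]], call. = FALSE)
    }
    if (is.null(labels_ref)) {
      labels_ref <- colnames(m)
    } else if (!identical(colnames(m), labels_ref)) {
      stop("ROI labels of ", manifest$subject_id[i],
           " do not match the first subject's (count/order must align)",
           call. = FALSE)
    }
    series[[manifest$subject_id[i]]] <- m
  }
  structure(list(manifest = manifest[setdiff(names(manifest), "path")],
                 series = series, truth = NULL),
            class = "dfc_cohort")
}

#' Run the full dFC state analysis
#'
#' Orchestrates simulate/load -> sliding-window Fisher-z -> pooled
#' Manhattan K-means (elbow-selected K) -> state ranking and validity ->
#' temporal metrics with covariate-adjusted permutation contrasts ->
#' per-state graph-metric sparsity sweep with AUC contrasts. Aborts with
#' a diagnostic if any state holds fewer than `min_windows` pooled
#' windows.
#'
#' @param config A [dfc_config()].
#' @return A list of class `dfc_run`: cohort, elbow, partition (ranked),
#'   validity, timelines, temporal (per-subject summary),
#'   temporal_contrasts, state_networks, graph_auc, graph_contrasts,
#'   seeds, timing.
#' @export
run_dfc_pipeline <- function(config = dfc_config()) {
  stopifnot(inherits(config, "dfc_config"))
  seeds <- derive_seeds(config$seed, 4L)
  timing <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  cohort <- if (identical(config$input, "synthetic")) {
    simulate_cohort(
      model = config$model %||% default_state_model(),
      groups = config$groups %||% default_group_specs(),
      n_timepoints = config$n_timepoints %||% 230,
      seed = seeds[1])
  } else {
    load_roi_tables(config$input)
  }
  timing["cohort"] <- lap(t0)

  t0 <- tic()
  z_by_subject <- lapply(cohort$series, windowed_z, spec = config$window)
  features <- build_window_features(z_by_subject)
  timing["windows"] <- lap(t0)

  t0 <- tic()
  if (is.null(config$k)) {
    elbow <- select_k_elbow(features, k_range = config$k_range,
                            n_init = config$n_init, seed = seeds[2])
    partition <- elbow$fits[[paste0("k", elbow$selected_k)]]
  } else {
    elbow <- NULL
    partition <- kmeans_manhattan(features, config$k,
                                  n_init = config$n_init, seed = seeds[2])
  }
  partition <- rank_states_by_strength(partition)
  validity <- validate_states(partition, config$min_windows)
  if (!all(validity$valid)) {
    stop("state-validity failure: state(s) ",
         paste(validity$state[!validity$valid], collapse = ", "),
         " hold fewer than ", config$min_windows, " pooled windows",
         call. = FALSE)
  }
  timing["clustering"] <- lap(t0)

  t0 <- tic()
  timelines <- state_timelines(partition)
  temporal <- temporal_summary(timelines, k = partition$k,
                               manifest = cohort$manifest)
  metric_cols <- c(paste0("fw_", seq_len(partition$k)),
                   paste0("mdt_", seq_len(partition$k)), "n_transitions")
  temporal_contrasts <- group_contrasts(
    temporal, metric_cols, n_perm = config$n_perm, seed = seeds[3])
  timing["temporal"] <- lap(t0)

  t0 <- tic()
  state_networks <- purrr::map_dfr(names(z_by_subject), function(id) {
    labs <- timelines$state[timelines$subject_id == id]
    purrr::map_dfr(seq_len(partition$k), function(s) {
      net <- suppressMessages(state_network(z_by_subject[[id]], labs, s))
      if (is.null(net)) return(NULL)
      tibble::tibble(subject_id = id, state = s, network = list(net))
    })
  })
  graph_auc <- NULL
  graph_contrasts <- NULL
  if (isTRUE(config$run_graph_stats)) {
    graph_auc <- purrr::map_dfr(seq_len(nrow(state_networks)), function(i) {
      sw <- graph_metric_sweep(state_networks$network[[i]],
                               sparsities = config$sparsities)
      dplyr::mutate(sw, subject_id = state_networks$subject_id[i],
                    state = state_networks$state[i])
    })
    auc_tbl <- sweep_auc(graph_auc)
    graph_contrasts <- auc_tbl |>
      dplyr::left_join(cohort$manifest, by = "subject_id") |>
      dplyr::group_by(.data$state, .data$metric, .data$node) |>
      dplyr::group_modify(function(d, key) {
        groups <- unique(d$group)
        if (length(groups) < 2) return(tibble::tibble())
        pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
        purrr::map_dfr(pairs, function(pr) {
          sub <- d[d$group %in% pr, ]
          if (min(table(sub$group)) < 2) return(tibble::tibble())
          pt_ <- permutation_test(sub$auc, sub$group,
                                  covariates = sub[c("age", "gender")],
                                  n_perm = config$n_perm, seed = seeds[4])
          tibble::tibble(group_1 = pt_$group_1, group_2 = pt_$group_2,
                         statistic = pt_$statistic, p_raw = pt_$p_value)
        })
      }) |>
      dplyr::ungroup()
    if (nrow(graph_contrasts)) {
      graph_contrasts <- graph_contrasts |>
        dplyr::group_by(.data$state, .data$metric, .data$group_1,
                        .data$group_2) |>
        dplyr::mutate(p_adj = fdr_bh(.data$p_raw)$p_adj,
                      reject = .data$p_adj < 0.05) |>
        dplyr::ungroup()
    }
  }
  timing["graphs"] <- lap(t0)

  run <- structure(
    list(config = config, cohort = cohort, elbow = elbow,
         partition = partition, validity = validity,
         timelines = timelines, temporal = temporal,
         temporal_contrasts = temporal_contrasts,
         state_networks = state_networks, graph_auc = graph_auc,
         graph_contrasts = graph_contrasts,
         seeds = seeds, timing = timing),
    class = "dfc_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.dfc_run <- function(x, ...) {
  cat("<dfc_run> ", nrow(x$cohort$manifest), " subjects, K = ",
      x$partition$k, if (!is.null(x$elbow)) " (elbow-selected)", "\n",
      sep = "")
  cat("pooled windows per state: ", paste(x$partition$sizes,
                                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn run_dfc_pipeline One-row run summary.
#' @param x A `dfc_run`.
#' @param ... Unused.
#' @export
glance.dfc_run <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$cohort$manifest),
    n_windows = length(x$partition$labels),
    selected_k = x$partition$k,
    min_state_windows = min(x$partition$sizes),
    all_states_valid = all(x$validity$valid),
    total_cost = x$partition$cost,
    seed = x$config$seed)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$timelines, file.path(dir, "state_labels.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$temporal, file.path(dir, "temporal_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$temporal_contrasts,
                   file.path(dir, "temporal_contrasts.tsv"),
                   progress = FALSE)
  cen <- run$partition$centroids
  colnames(cen) <- paste0("edge_", seq_len(ncol(cen)))
  readr::write_tsv(tibble::as_tibble(cen),
                   file.path(dir, "centroids.tsv"), progress = FALSE)
  if (!is.null(run$elbow)) {
    readr::write_tsv(run$elbow$curve, file.path(dir, "elbow_curve.tsv"),
                     progress = FALSE)
  }
  if (!is.null(run$graph_contrasts) && nrow(run$graph_contrasts)) {
    readr::write_tsv(run$graph_contrasts,
                     file.path(dir, "graph_contrasts.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(seed = run$config$seed, stage_seeds = run$seeds,
         selected_k = run$partition$k,
         state_sizes = run$partition$sizes,
         validity = all(run$validity$valid),
         total_cost = run$partition$cost,
         timing_seconds = as.list(round(run$timing, 2))),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' State occupancy and temporal-metric overview plot
#'
#' Group-wise mean fractional windows per state, the standard Figure-2
#' style presentation.
#'
#' @param object A `dfc_run`.
#' @param ... Unused.
#' @export
autoplot.dfc_run <- function(object, ...) {
  k <- object$partition$k
  long <- object$temporal |>
    tidyr::pivot_longer(dplyr::all_of(paste0("fw_", seq_len(k))),
                        names_to = "state", values_to = "fw",
                        names_prefix = "fw_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$fw,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "connectivity state", y = "fractional windows",
                  title = "State occupancy by group") +
    ggplot2::theme_minimal()
}
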