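#' Build state covariance matrices from block specifications
#'
#' Constructs one correlation-scale covariance matrix per connectivity
#' state. Each state is described by a list of node blocks with a
#' within-block correlation level; ROIs outside any block (and all
#' between-block pairs) share the `noise_floor` correlation. Diagonals are
#' 1, so the matrices are correlation matrices up to the diagonal loading
#' applied when a requested structure is not positive definite.
#'
#' @param n_rois Number of regions (columns of the simulated series), >= 4.
#' @param blocks A list with one element per state; each element is a list
#'   of blocks, each block a list with `nodes` (integer indices) and
#'   `level` (within-block correlation in (-1, 1)).
#' @param noise_floor Baseline correlation for all pairs not covered by a
#'   block (default 0).
#' @param loading_step,max_loading Diagonal loading is added in steps of
#'   `loading_step` (then renormalised to unit diagonal) until the matrix
#'   is positive definite, up to `max_loading`; failure beyond that is an
#'   error.
#'
#' @return A list of symmetric positive-definite matrices, one per state.
#' @export
#' @examples
#' covs <- make_state_covariances(6, list(
#'   list(list(nodes = 1:6, level = 0.6)),
#'   list(list(nodes = 1:3, level = 0.2))
#' ))
#' eigen(covs[[1]])$values
make_state_covariances <- function(n_rois, blocks, noise_floor = 0,
                                   loading_step = 0.01, max_loading = 0.5) {
  stopifnot(n_rois >= 4)
  lapply(blocks, function(state_blocks) {
    sigma <- matrix(noise_floor, n_rois, n_rois)
    for (b in state_blocks) {
      lv <- b$level
      if (!is.numeric(lv) || abs(lv) >= 1) {
        stop("block correlation levels must lie in (-1, 1)", call. = FALSE)
      }
      sigma[b$nodes, b$nodes] <- lv
    }
    diag(sigma) <- 1
    repair_spd(sigma, loading_step, max_loading)
  })
}

# Diagonal loading until strictly positive definite; renormalises back to
# unit diagonal after each load so the result stays a correlation matrix.
repair_spd <- function(sigma, step = 0.01, max_loading = 0.5) {
  load <- 0
  repeat {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10) return(sigma)
    load <- load + step
    if (load > max_loading + 1e-12) {
      stop("covariance not repairable by diagonal loading (min eigenvalue ",
           signif(min(ev), 3), ")", call. = FALSE)
    }
    sigma <- (sigma + diag(step, nrow(sigma))) / (1 + step)
  }
}

#' Latent Markov-switching connectivity model
#'
#' Bundles the generative model behind the synthetic cohort: a set of
#' state covariance matrices, a row-stochastic transition matrix over the
#' states, and an initial state distribution. Validity (stochasticity,
#' positive definiteness) is checked on construction.
#'
#' @param state_covariances List of N x N symmetric positive-definite
#'   matrices, one per latent state.
#' @param transition_matrix K x K row-stochastic matrix of state
#'   transition probabilities at the time-point level.
#' @param initial_distribution Length-K probability vector; defaults to
#'   the chain's stationary distribution.
#'
#' @return An object of class `latent_state_model`.
#' @export
latent_state_model <- function(state_covariances, transition_matrix,
                               initial_distribution = NULL) {
  k <- length(state_covariances)
  stopifnot(k >= 1, is.matrix(transition_matrix),
            nrow(transition_matrix) == k, ncol(transition_matrix) == k)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition_matrix rows must be probabilities summing to 1",
         call. = FALSE)
  }
  n <- nrow(state_covariances[[1]])
  for (s in state_covariances) {
    stopifnot(is.matrix(s), nrow(s) == n, ncol(s) == n)
    if (max(abs(s - t(s))) > 1e-10) {
      stop("state covariances must be symmetric", call. = FALSE)
    }
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("state covariances must be positive definite", call. = FALSE)
    }
  }
  if (is.null(initial_distribution)) {
    initial_distribution <- stationary_distribution(transition_matrix)
  }
  stopifnot(length(initial_distribution) == k)
  if (any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("initial_distribution must be a probability vector", call. = FALSE)
  }
  structure(
    list(n_states = k, n_rois = n,
         state_covariances = state_covariances,
         transition_matrix = transition_matrix,
         initial_distribution = initial_distribution,
         chol = lapply(state_covariances, chol)),
    class = "latent_state_model")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param p Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% p = pi`.
#' @export
stationary_distribution <- function(p) {
  e <- eigen(t(p))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Default three-state latent connectivity model
#'
#' The default generative model plants three connectivity states with
#' distinct spatial patterns and tiered overall strength, mirroring the
#' strong / sparse / intermediate organisation typical of resting-state
#' connectivity states: state 1 is a strongly connected modular pattern
#' (three within-module blocks at correlation 0.7, between-module
#' anticorrelation -0.2), state 2 a sparse pattern (uniform 0.05), and
#' state 3 an intermediate-strength pattern with a different module
#' layout (two blocks at 0.5, between-block -0.1). The time-point-level
#' transition matrix is reversible with stationary occupancy
#' (0.365, 0.572, 0.063) and mean dwell times of 100, 135 and 35 time
#' points, so state switches happen within a scan and windows near state
#' boundaries are genuinely mixed.
#'
#' @param n_rois Number of regions; default 30. Blocks scale with
#'   `n_rois` (thirds for state 1, halves for state 3).
#' @return A `latent_state_model`.
#' @export
default_state_model <- function(n_rois = 30) {
  third <- floor(n_rois / 3)
  half <- floor(n_rois / 2)
  b1 <- list(1:third, (third + 1):(2 * third), (2 * third + 1):n_rois)
  b3 <- list(1:half, (half + 1):n_rois)
  modular <- function(block_list, within, between) {
    s <- matrix(between, n_rois, n_rois)
    for (b in block_list) s[b, b] <- within
    diag(s) <- 1
    repair_spd(s)
  }
  covs <- list(
    modular(b1, 0.70, -0.20),
    modular(list(1:n_rois), 0.05, 0.05),
    modular(b3, 0.50, -0.10))
  # reversible chain, stationary (0.365, 0.572, 0.063),
  # mean dwells (100, 135, 35) time points
  p <- matrix(c(
    0.990000, 0.008336, 0.001664,
    0.005319, 0.992596, 0.002085,
    0.009643, 0.018929, 0.971428), 3, 3, byrow = TRUE)
  p <- p / rowSums(p)
  latent_state_model(covs, p)
}

#' Group specification for the synthetic cohort
#'
#' Describes one study group: size, optional transition-matrix override
#' (how that group moves among states), optional nodal perturbation of a
#' state's covariance (a connectivity effect localised to named nodes),
#' and covariate distributions.
#'
#' @param name Group label; must be unique within a cohort.
#' @param n_subjects Number of subjects (>= 1).
#' @param transition_matrix Optional row-stochastic override of the
#'   model's transition matrix.
#' @param nodal_perturbation Optional list with `state` (state index),
#'   `nodes` (node indices) and `delta` (additive correlation change
#'   applied to all pairs involving those nodes, SPD-repaired).
#' @param age_mean,age_sd Age distribution (years), normal clipped to
#'   30-80.
#' @param p_male Probability a subject is coded male (gender indicator 1).
#'
#' @return An object of class `dfc_group_spec`.
#' @export
group_spec <- function(name, n_subjects, transition_matrix = NULL,
                       nodal_perturbation = NULL,
                       age_mean = 58, age_sd = 10, p_male = 0.5) {
  stopifnot(is.character(name), length(name) == 1, n_subjects >= 1)
  structure(
    list(name = name, n_subjects = as.integer(n_subjects),
         transition_matrix = transition_matrix,
         nodal_perturbation = nodal_perturbation,
         age_mean = age_mean, age_sd = age_sd, p_male = p_male),
    class = "dfc_group_spec")
}

#' Default three-group cohort design
#'
#' Healthy-control, herpes-zoster and postherpetic-neuralgia analogues.
#' The PHN analogue inflates the self-transition probability of state 3
#' (longer dwell, higher occupancy there, lower in state 1) and adds a
#' nodal connectivity perturbation in state 1, mirroring the kinds of
#' group effects the method is meant to detect.
#'
#' @param n_hc,n_hz,n_phn Group sizes; the desk-scale default is 4/4/4.
#' @return List of three `dfc_group_spec` objects.
#' @export
default_group_specs <- function(n_hc = 4, n_hz = 4, n_phn = 4) {
  p_phn <- matrix(c(
    0.9800, 0.0120, 0.0080,
    0.0050, 0.9890, 0.0060,
    0.0040, 0.0060, 0.9900), 3, 3, byrow = TRUE)
  list(
    group_spec("HC", n_hc),
    group_spec("HZ", n_hz),
    group_spec("PHN", n_phn, transition_matrix = p_phn,
               nodal_perturbation = list(state = 1, nodes = 5, delta = 0.15))
  )
}

apply_group_model <- function(model, spec) {
  covs <- model$state_covariances
  pert <- spec$nodal_perturbation
  if (!is.null(pert)) {
    s <- covs[[pert$state]]
    for (nd in pert$nodes) {
      s[nd, -nd] <- s[nd, -nd] + pert$delta
      s[-nd, nd] <- s[-nd, nd] + pert$delta
    }
    s <- pmax(pmin(s, 0.99), -0.99)
    diag(s) <- 1
    covs[[pert$state]] <- repair_spd(s)
  }
  p <- if (is.null(spec$transition_matrix)) model$transition_matrix else
    spec$transition_matrix
  latent_state_model(covs, p)
}

#' Simulate one subject's ROI time series
#'
#' Samples a latent state sequence from the model's Markov chain at the
#' time-point level, then draws each time point from a zero-mean
#' multivariate normal with the covariance of the current state.
#'
#' @param model A `latent_state_model`.
#' @param n_timepoints Series length T (must cover the window width used
#'   downstream).
#' @param seed Integer seed; the draw is deterministic given the seed.
#'
#' @return A list with `series` (T x N matrix, columns named ROI_1..N)
#'   and `states` (length-T integer ground-truth state sequence).
#' @export
simulate_subject <- function(model, n_timepoints, seed = NULL) {
  stopifnot(inherits(model, "latent_state_model"), n_timepoints >= 2)
  k <- model$n_states
  n <- model$n_rois
  with_seed(seed, {
    states <- integer(n_timepoints)
    states[1] <- sample.int(k, 1, prob = model$initial_distribution)
    for (t in seq_len(n_timepoints - 1)) {
      states[t + 1] <- sample.int(k, 1,
                                  prob = model$transition_matrix[states[t], ])
    }
    z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
    series <- matrix(0, n_timepoints, n)
    for (s in unique(states)) {
      rows <- states == s
      series[rows, ] <- z[rows, , drop = FALSE] %*% model$chol[[s]]
    }
    colnames(series) <- paste0("ROI_", seq_len(n))
    list(series = series, states = states)
  })
}

#' Simulate a multi-group synthetic cohort
#'
#' Generates per-subject ROI time series under a shared latent
#' Markov-switching connectivity model, with per-group overrides of the
#' transition matrix and nodal covariance structure. Subject seeds and
#' covariates are derived deterministically from the master seed.
#'
#' @param model Baseline `latent_state_model`; default
#'   [default_state_model()].
#' @param groups List of [group_spec()] objects; default
#'   [default_group_specs()].
#' @param n_timepoints Time points per subject; default 230.
#' @param seed Master seed for the whole cohort.
#'
#' @return An object of class `dfc_cohort`: `manifest` (tibble with
#'   subject_id, group, age, gender), `series` and `truth` (named lists of
#'   per-subject T x N matrices and ground-truth state sequences),
#'   `model`, `seed`.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_timepoints = 60, seed = 1,
#'   groups = list(group_spec("A", 2), group_spec("B", 2)))
#' cohort$manifest
simulate_cohort <- function(model = default_state_model(),
                            groups = default_group_specs(),
                            n_timepoints = 230, seed = NULL) {
  stopifnot(inherits(model, "latent_state_model"))
  names_ <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(names_)) {
    stop("duplicate group names: ", paste(unique(names_[duplicated(names_)]),
                                          collapse = ", "), call. = FALSE)
  }
  sizes <- vapply(groups, function(g) g$n_subjects, integer(1))
  if (sum(sizes) < 1) stop("cohort must contain at least one subject",
                           call. = FALSE)
  n_total <- sum(sizes)
  seeds <- derive_seeds(seed, n_total + 1L)
  cov_seed <- seeds[n_total + 1L]

  manifest <- vector("list", length(groups))
  series <- list()
  truth <- list()
  idx <- 0L
  covars <- with_seed(cov_seed, {
    lapply(groups, function(g) {
      age <- pmin(pmax(stats::rnorm(g$n_subjects, g$age_mean, g$age_sd),
                       30), 80)
      gender <- stats::rbinom(g$n_subjects, 1, g$p_male)
      list(age = age, gender = gender)
    })
  })
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    gmodel <- apply_group_model(model, g)
    ids <- sprintf("%s_%02d", g$name, seq_len(g$n_subjects))
    for (si in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sub <- simulate_subject(gmodel, n_timepoints, seed = seeds[idx])
      series[[ids[si]]] <- sub$series
      truth[[ids[si]]] <- sub$states
    }
    manifest[[gi]] <- tibble::tibble(
      subject_id = ids, group = g$name,
      age = covars[[gi]]$age, gender = covars[[gi]]$gender)
  }
  structure(
    list(manifest = dplyr::bind_rows(manifest), series = series,
         truth = truth, model = model, groups = groups,
         n_timepoints = n_timepoints, seed = seed),
    class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat("<dfc_cohort> ", nrow(x$manifest), " subjects, ",
      x$model$n_rois, " ROIs x ", x$n_timepoints, " time points, ",
      x$model$n_states, " latent states\n", sep = "")
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}

#' @describeIn simulate_cohort Long tidy view of the simulated series:
#'   one row per (subject, time point, ROI).
#' @param x A `dfc_cohort`.
#' @param ... Unused.
#' @export
tidy.dfc_cohort <- function(x, ...) {
  purrr::map_dfr(names(x$series), function(id) {
    m <- x$series[[id]]
    tibble::tibble(
      subject_id = id,
      timepoint = rep(seq_len(nrow(m)), ncol(m)),
      roi = rep(colnames(m), each = nrow(m)),
      value = as.vector(m),
      state = rep(x$truth[[id]], ncol(m)))
  })
}

#' Write a cohort to delimited text files
#'
#' Emits one tab-separated time-series file per subject (header row = ROI
#' labels), a cohort manifest (`manifest.tsv` with subject_id, group, age,
#' gender, path), a ground-truth state table (`truth.tsv`), and a JSON run
#' descriptor recording the master seed. Regeneration with the same seed
#' is byte-identical.
#'
#' @param cohort A `dfc_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$manifest))
  for (i in seq_along(cohort$series)) {
    id <- names(cohort$series)[i]
    p <- file.path(dir, paste0(id, ".tsv"))
    readr::write_tsv(tibble::as_tibble(cohort$series[[id]]), p,
                     progress = FALSE)
    # manifest stores paths relative to its own directory, so a cohort
    # folder is relocatable and regeneration is byte-identical
    paths[match(id, cohort$manifest$subject_id)] <- basename(p)
  }
  manifest <- dplyr::mutate(cohort$manifest, path = paths)
  mpath <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, mpath, progress = FALSE)
  truth <- purrr::map_dfr(names(cohort$truth), function(id) {
    tibble::tibble(subject_id = id,
                   timepoint = seq_along(cohort$truth[[id]]),
                   state = cohort$truth[[id]])
  })
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed, n_subjects = nrow(cohort$manifest),
         n_rois = cohort$model$n_rois, n_states = cohort$model$n_states,
         n_timepoints = cohort$n_timepoints, manifest = "manifest.tsv"),
    file.path(dir, "descriptor.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
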