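#' Per-subject state timelines
#'
#' Restricts a pooled state partition back to each subject's ordered
#' window sequence.
#'
#' @param partition A `dfc_partition` fitted on features that carried a
#'   subject/window index.
#' @return Tibble: subject_id, window, state, ordered by window within
#'   subject.
#' @export
state_timelines <- function(partition) {
  if (is.null(partition$index)) {
    stop("partition carries no subject/window index", call. = FALSE)
  }
  dplyr::arrange(tidy(partition), .data$subject_id, .data$window)
}

check_labels <- function(labels, k) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("empty state timeline", call. = FALSE)
  if (any(labels < 1 | labels > k)) {
    stop("state labels outside 1..", k, call. = FALSE)
  }
  labels
}

#' Fractional windows
#'
#' Proportion of a subject's windows spent in each state.
#'
#' @param labels Ordered state sequence for one subject (values 1..k).
#' @param k Number of states.
#' @return Length-k proportions summing to 1.
#' @export
fractional_windows <- function(labels, k) {
  labels <- check_labels(labels, k)
  tabulate(labels, k) / length(labels)
}

#' Mean dwell time
#'
#' Mean length (in windows) of the maximal runs a subject spends in each
#' state before switching; runs truncated at the timeline boundary count.
#' States never visited contribute 0.
#'
#' @inheritParams fractional_windows
#' @return Length-k vector of mean run lengths (window units).
#' @export
mean_dwell_time <- function(labels, k) {
  labels <- check_labels(labels, k)
  r <- rle(labels)
  vapply(seq_len(k), function(s) {
    len <- r$lengths[r$values == s]
    if (length(len) == 0) 0 else mean(len)
  }, numeric(1))
}

#' Number of state transitions
#'
#' Count of window boundaries where the state changes; equals the number
#' of maximal runs minus 1.
#'
#' @param labels Ordered state sequence for one subject.
#' @return Integer count.
#' @export
n_transitions <- function(labels) {
  if (length(labels) == 0) stop("empty state timeline", call. = FALSE)
  sum(labels[-1] != labels[-length(labels)])
}

#' Per-subject temporal summary table
#'
#' The tidy deliverable of the temporal analysis: fractional windows and
#' mean dwell time for every state plus the transition count, one row per
#' subject. Dwell time is in window units; supply `tr_seconds` to add a
#' seconds conversion.
#'
#' @param timelines Tibble from [state_timelines()] (subject_id, window,
#'   state) or a `dfc_partition` with an index.
#' @param k Number of states; defaults to the maximum observed label.
#' @param manifest Optional cohort manifest to join group/covariates.
#' @param tr_seconds Optional repetition time for an MDT-in-seconds
#'   column.
#' @return Tibble: subject_id \[, group, age, gender\], fw_1..k, mdt_1..k,
#'   n_transitions.
#' @export
temporal_summary <- function(timelines, k = NULL, manifest = NULL,
                             tr_seconds = NULL) {
  if (inherits(timelines, "dfc_partition")) {
    k <- k %||% timelines$k
    timelines <- state_timelines(timelines)
  }
  k <- k %||% max(timelines$state)
  out <- timelines |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$window, .by_group = TRUE) |>
    dplyr::summarise(
      fw = list(fractional_windows(.data$state, k)),
      mdt = list(mean_dwell_time(.data$state, k)),
      n_transitions = n_transitions(.data$state),
      .groups = "drop")
  fw <- do.call(rbind, out$fw)
  mdt <- do.call(rbind, out$mdt)
  colnames(fw) <- paste0("fw_", seq_len(k))
  colnames(mdt) <- paste0("mdt_", seq_len(k))
  out <- dplyr::bind_cols(
    dplyr::select(out, "subject_id", "n_transitions"),
    tibble::as_tibble(fw), tibble::as_tibble(mdt)) |>
    dplyr::relocate("n_transitions", .after = dplyr::last_col())
  if (!is.null(tr_seconds)) {
    for (s in seq_len(k)) {
      out[[paste0("mdt_sec_", s)]] <- out[[paste0("mdt_", s)]] * tr_seconds
    }
  }
  if (!is.null(manifest)) {
    out <- dplyr::left_join(manifest, out, by = "subject_id")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
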