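# Overall-behaviour metrics per trial (display completion time, total head
# movement) and condition-level descriptive tables.

trial_summary_one <- function(frames, meta, enc = NULL, srch = NULL) {
  n <- nrow(frames)
  completion <- sum(frames$duration_s)
  if (n > 1) {
    head_move <- sum(sqrt(diff(frames$hmd_x)^2 + diff(frames$hmd_y)^2 +
                            diff(frames$hmd_z)^2))
  } else {
    head_move <- 0
  }
  n_correct <- sum(frames$event == "placement_attempt" &
                     frames$event_correct %in% TRUE)
  enc_inc <- if (!is.null(enc) && "included" %in% names(enc)) {
    enc[enc$included, ]
  } else enc
  srch_inc <- if (!is.null(srch) && "included" %in% names(srch)) {
    srch[srch$included, ]
  } else srch
  tibble::new_tibble(list(
    completion_time_s = completion,
    total_head_movement_m = head_move,
    n_correct_placements = as.integer(n_correct),
    timed_out = n_correct < N_TARGETS,
    n_encoding_periods_included = if (is.null(enc_inc)) NA_integer_
                                  else nrow(enc_inc),
    total_encoding_time_s = if (is.null(enc_inc)) NA_real_
                            else sum(enc_inc$model_viewing_time_s),
    n_searches_included = if (is.null(srch_inc)) NA_integer_
                          else nrow(srch_inc)
  ), nrow = 1L)
}

#' Per-trial overall-behaviour summary
#'
#' Display completion time (the sum of all frame durations), total head
#' movement (the summed Euclidean distance between the head-mounted-display
#' coordinates of subsequent frames), whether the trial timed out before all
#' 8 objects were placed, and -- when period tables are supplied -- the
#' number of included encoding periods, the total encoding time per display
#' (sum of included model viewing times), and the number of included
#' searches.
#'
#' @inheritParams detect_encoding_periods
#' @param encodings Optional encoding periods with exclusion flags.
#' @param searches Optional search periods with exclusion flags.
#' @return A tibble with one row per trial.
#' @export
trial_summary <- function(x, meta = NULL, encodings = NULL, searches = NULL) {
  groups <- trial_groups(x, meta)
  keyed_enc <- !is.null(encodings) &&
    length(intersect(TRIAL_KEYS, names(encodings))) == 3
  keyed_srch <- !is.null(searches) &&
    length(intersect(TRIAL_KEYS, names(searches))) == 3
  enc_key <- if (keyed_enc) do.call(paste, c(encodings[TRIAL_KEYS], sep = "."))
  srch_key <- if (keyed_srch) do.call(paste, c(searches[TRIAL_KEYS], sep = "."))
  dplyr::bind_rows(lapply(groups, function(g) {
    key <- paste(unlist(g$meta[1, TRIAL_KEYS]), collapse = ".")
    enc <- if (keyed_enc) encodings[enc_key == key, ] else encodings
    srch <- if (keyed_srch) searches[srch_key == key, ] else searches
    with_keys(trial_summary_one(g$frames, g$meta, enc, srch), g$meta)
  }))
}

#' Condition-level descriptive summary
#'
#' Aggregates a per-observation metric to participant means within condition
#' cells, then reports the grand mean (the mean of participant means, not of
#' pooled observations) and the standard error of the mean over participants.
#' When the data carry a `timed_out` column, timed-out trials are dropped
#' first (overall-behaviour analyses use completed trials only); disable via
#' `exclude_timeouts = FALSE`.
#'
#' @param data A keyed tibble of per-trial or per-period observations.
#' @param metric Name of the numeric column to summarise.
#' @param meta Trial metadata (condition columns).
#' @param by Condition columns to stratify by.
#' @param exclude_timeouts Drop rows with `timed_out == TRUE` when present.
#' @return A tibble with one row per condition cell: `n_participants`,
#'   `grand_mean`, `sem`.
#' @export
condition_summary <- function(data, metric, meta,
                              by = c("distraction", "movement_effort"),
                              exclude_timeouts = TRUE) {
  if (!metric %in% names(data)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    stop("metric `", metric, "` not found; available numeric columns: ",
         paste(setdiff(numeric_cols, TRIAL_KEYS), collapse = ", "),
         call. = FALSE)
  }
  if (exclude_timeouts && "timed_out" %in% names(data)) {
    data <- data[!data$timed_out, ]
  }
  miss <- setdiff(by, names(data))
  if (length(miss) > 0) {
    data <- dplyr::left_join(data, dplyr::distinct(meta[, c(TRIAL_KEYS, miss)]),
                             by = TRIAL_KEYS)
  }
  per_participant <- data |>
    dplyr::summarise(
      m = mean(.data[[metric]], na.rm = TRUE),
      .by = dplyr::all_of(c("participant_id", by))
    )
  out <- per_participant |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      grand_mean = mean(.data$m),
      sem = stats::sd(.data$m) / sqrt(dplyr::n()),
      .by = dplyr::all_of(by)
    )
  if (nrow(out) == 0) warning("no data for metric `", metric, "`",
                              call. = FALSE)
  out
}
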