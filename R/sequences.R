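# Working-memory usage: behavioural sequences bounded by successive included
# encoding periods, and the attributes-in-memory metric (correct pickups +
# correct placements of target objects inside each sequence).

act_extract_one <- function(frames, meta) {
  empty <- EMPTY_ACTIONS
  rows <- which(frames$event %in% c("pickup", "placement_attempt"))
  if (length(rows) == 0) return(empty)
  layout <- meta$resource_layout[[1]]
  kind <- ifelse(frames$event[rows] == "pickup", "pickup", "placement")
  correct <- frames$event_correct[rows]
  na_pick <- which(kind == "pickup" & is.na(correct))
  for (i in na_pick) {
    correct[i] <- pickup_is_correct(frames, rows[i], layout)
  }
  if (kind[1] == "placement") {
    stop("placement event at frame ", rows[1] - 1L,
         " has no preceding pickup", call. = FALSE)
  }
  tibble::new_tibble(list(
    action_ordinal = seq_along(rows),
    kind = kind,
    object = frames$event_object[rows],
    slot = frames$event_slot[rows],
    correct = as.logical(correct),
    frame = rows - 1L
  ), nrow = length(rows))
}

#' Extract interaction actions from a frame log
#'
#' One record per pickup or placement-attempt event, in frame order, with
#' correctness taken from the event (for pickups lacking a recorded
#' correctness, a non-target object counts as incorrect). `release_to_pool`
#' events close erroneous pickups without creating a record.
#'
#' @inheritParams detect_encoding_periods
#' @return A tibble of actions with 0-based frames.
#' @export
extract_actions <- function(x, meta = NULL) {
  map_trials(x, meta, act_extract_one)
}

seq_build_one <- function(enc, actions, frames) {
  empty <- EMPTY_SEQ
  enc <- enc[order(enc$start_frame), ]
  if ("included" %in% names(enc)) enc <- enc[enc$included, ]
  k <- nrow(enc)
  if (k < 1) return(empty)
  n <- nrow(frames)
  is_station <- frames$gaze_station %in% c("resource_pool", "workspace")
  cum_station <- cumsum(is_station)
  ord <- order(actions$frame)
  a_frame <- actions$frame[ord]
  a_kind <- actions$kind[ord]
  a_correct <- actions$correct[ord]

  # closed sequences between consecutive included encodings, plus one open
  # tail from the last encoding to trial end (used by the decision and error
  # extractors; the WM-usage metric keeps closed sequences only)
  m <- k
  lo <- c(enc$end_frame[-k], enc$end_frame[k])  # 0-based, exclusive
  hi <- c(enc$start_frame[-1L], n)              # 0-based, exclusive
  closed <- c(rep(TRUE, k - 1L), FALSE)
  end_ord <- c(enc$ordinal[-1L], NA_integer_)
  qualifies <- logical(m); stype <- character(m)
  n_act <- integer(m); attrs <- integer(m)
  for (i in seq_len(m)) {
    in_seq <- which(a_frame > lo[i] & a_frame < hi[i])
    qualifies[i] <- hi[i] - lo[i] > 1L &&
      (cum_station[hi[i]] - cum_station[lo[i] + 1L]) > 0  # rows lo+2..hi
    stype[i] <- if (length(in_seq) == 0) "other"
                else if (a_kind[in_seq[1]] == "pickup") "search_first"
                else "placement_first"
    n_act[i] <- length(in_seq)
    attrs[i] <- sum(a_correct[in_seq])
  }
  out <- tibble::new_tibble(list(
    seq_ordinal = seq_len(m), start_enc_ordinal = enc$ordinal,
    end_enc_ordinal = end_ord, start_frame = lo, end_frame = hi,
    closed = closed, qualifies = qualifies, sequence_type = stype,
    n_actions = n_act, attributes_used = as.integer(attrs)
  ), nrow = m)
  # an empty tail (no actions, no station gaze) carries no information
  out[out$closed | out$n_actions > 0L | out$qualifies, ]
}

#' Build working-memory usage sequences
#'
#' Consecutive included encoding periods bound each closed sequence; actions
#' whose frames lie strictly between the end of the opening encoding and the
#' start of the closing encoding are assigned to it. A sequence qualifies
#' only if the resource pool or workspace was gazed between the bounding
#' encodings. `attributes_used` counts correct pickups plus correct
#' placements of target objects. One additional open sequence (`closed =
#' FALSE`) spans from the last included encoding to trial end: the
#' working-memory metric ignores it (it never concluded with an encoding),
#' but the decision and error extractors use it so that behaviour cut off by
#' trial end is not silently censored.
#'
#' @param encodings Encoding periods with exclusion flags applied
#'   ([apply_encoding_exclusions()]); only included periods bound sequences.
#' @param actions Output of [extract_actions()].
#' @param x The frame log(s) the periods came from.
#' @param meta Trial metadata tibble for tibble input.
#' @return A tibble of sequences with type (`search_first`,
#'   `placement_first`, `other`) and attribute counts.
#' @export
build_sequences <- function(encodings, actions, x, meta = NULL) {
  groups <- trial_groups(x, meta)
  keyed <- length(intersect(TRIAL_KEYS, names(encodings))) == 3
  enc_key <- if (keyed) do.call(paste, c(encodings[TRIAL_KEYS], sep = "."))
  act_key <- if (keyed) do.call(paste, c(actions[TRIAL_KEYS], sep = "."))
  dplyr::bind_rows(lapply(groups, function(g) {
    if (keyed) {
      key <- paste(unlist(g$meta[1, TRIAL_KEYS]), collapse = ".")
      enc <- encodings[enc_key == key, ]
      act <- actions[act_key == key, ]
    } else {
      enc <- encodings
      act <- actions
    }
    with_keys(seq_build_one(enc, act, g$frames), g$meta)
  }))
}

#' Summarise working-memory usage
#'
#' Per participant and condition cell: the mean number of attributes used per
#' qualifying sequence and the probability of using exactly `k` attributes
#' (`k` capped at `max_attributes`, the last bin collecting larger counts).
#' Probabilities sum to 1 within each cell.
#'
#' @param sequences Output of [build_sequences()].
#' @param meta Trial metadata (supplies the condition columns).
#' @param by Condition columns to stratify by.
#' @param max_attributes Upper bin for the attribute distribution.
#' @return A tibble with one row per participant x cell x attribute count:
#'   columns `n_sequences`, `mean_attributes`, `attributes`, `p_attributes`.
#' @export
wm_usage_summary <- function(sequences, meta,
                             by = c("distraction", "movement_effort"),
                             max_attributes = 6L) {
  seq2 <- sequences[sequences$qualifies, ]
  if ("closed" %in% names(seq2)) seq2 <- seq2[seq2$closed, ]
  seq2 <- dplyr::left_join(
    seq2, dplyr::distinct(meta[, c(TRIAL_KEYS, by)]), by = TRIAL_KEYS
  )
  cells <- seq2 |>
    dplyr::mutate(attr_bin = pmin(.data$attributes_used, max_attributes)) |>
    dplyr::summarise(
      n_sequences = dplyr::n(),
      mean_attributes = mean(.data$attributes_used),
      n_k = list(table(factor(.data$attr_bin, levels = 0:max_attributes))),
      .by = dplyr::all_of(c("participant_id", by))
    )
  out <- cells |>
    dplyr::mutate(dist = lapply(.data$n_k, function(tab) {
      tibble::tibble(attributes = as.integer(names(tab)),
                     p_attributes = as.numeric(tab) / sum(tab))
    })) |>
    dplyr::select(-"n_k") |>
    tidyr::unnest("dist")
  if (nrow(out) == 0) warning("no qualifying sequences", call. = FALSE)
  out
}
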