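# Detect encoding periods (model-directed gaze with sub-25-frame gaps bridged)
# and visual-search periods (resource-pool gaze ending in a pickup), with the
# per-period metrics and sequential inclusion filters.

GAP_SPLIT_FRAMES <- 25L      # off-model gap that can split encoding periods
MIN_OBJECT_FRAMES <- 2L      # consecutive frames for a slot/object to count
MIN_PERIOD_S <- 0.050        # minimum period duration (50 ms)
SD_CUTOFF <- 3.5             # per-participant outlier filter

# zero-row output prototypes (built once at load time; cheap to reuse)
EMPTY_ENC <- tibble::tibble(
  ordinal = integer(), start_frame = integer(), end_frame = integer(),
  model_viewing_time_s = double(), n_targets_encoded = integer(),
  followed_by_station = logical(), first_in_display = logical()
)
EMPTY_SEARCH <- tibble::tibble(
  ordinal = integer(), start_frame = integer(), pickup_frame = integer(),
  search_time_s = double(), picked_object = integer(),
  pickup_correct = logical(), n_targets_viewed = integer(),
  n_distractors_viewed = integer(), object_viewing_times = list(),
  no_pickup = logical()
)
EMPTY_ACTIONS <- tibble::tibble(
  action_ordinal = integer(), kind = character(), object = integer(),
  slot = integer(), correct = logical(), frame = integer()
)
EMPTY_SEQ <- tibble::tibble(
  seq_ordinal = integer(), start_enc_ordinal = integer(),
  end_enc_ordinal = integer(), start_frame = integer(),
  end_frame = integer(), closed = logical(), qualifies = logical(),
  sequence_type = character(), n_actions = integer(),
  attributes_used = integer()
)
EMPTY_DECISIONS <- tibble::tibble(
  seq_ordinal = integer(), kind = character(), position = integer(),
  locked_frame = integer(), used_memory = logical(), included = logical(),
  exclusion_reason = character()
)
EMPTY_ERRORS <- tibble::tibble(
  seq_ordinal = integer(), kind = character(), position_slot = character(),
  occurred = logical(), frame = integer()
)
EMPTY_VIEWS <- tibble::tibble(
  object = integer(), viewing_time_s = double(), is_target = logical()
)

# Normalise input: a frame_log, or a keyed frames tibble plus a meta tibble,
# into a list of per-trial (frames, meta) pairs.
trial_groups <- function(x, meta = NULL) {
  if (inherits(x, "frame_log")) {
    return(list(list(frames = x$frames, meta = x$meta)))
  }
  if (inherits(x, "copy_task_sim")) {
    meta <- x$meta
    x <- x$frames
  }
  x <- tibble::as_tibble(x)
  keys <- intersect(TRIAL_KEYS, names(x))
  if (length(keys) == 0) {
    if (is.null(meta)) meta <- trial_meta()
    return(list(list(frames = x, meta = meta[1, ])))
  }
  if (is.null(meta)) {
    stop("a trial metadata tibble is required for multi-trial frame input",
         call. = FALSE)
  }
  key <- paste(x$participant_id, x$day, x$trial_id, sep = ".")
  idx <- split(seq_len(nrow(x)), factor(key, levels = unique(key)))
  meta_key <- paste(meta$participant_id, meta$day, meta$trial_id, sep = ".")
  lapply(names(idx), function(k) {
    m <- meta[match(k, meta_key), ]
    if (anyNA(m$participant_id)) {
      stop("no metadata row for trial ", k, call. = FALSE)
    }
    list(frames = x[idx[[k]], ], meta = m)
  })
}

map_trials <- function(x, meta, fn) {
  groups <- trial_groups(x, meta)
  dplyr::bind_rows(lapply(groups, function(g) {
    with_keys(fn(g$frames, g$meta), g$meta)
  }))
}

# --- encoding ---------------------------------------------------------------

enc_detect_one <- function(frames, meta) {
  empty <- EMPTY_ENC
  n <- nrow(frames)
  if (n == 0) return(empty)
  st <- frames$gaze_station
  is_model <- st == "model"
  if (!any(is_model)) return(empty)
  is_station <- st %in% c("resource_pool", "workspace")
  dur <- frames$duration_s

  r <- rle(is_model)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mi <- which(r$values)
  m_start <- starts[mi]
  m_end <- ends[mi]

  k <- length(mi)
  if (k > 1) {
    gap_from <- m_end[-k] + 1L
    gap_to <- m_start[-1] - 1L
    gap_len <- gap_to - gap_from + 1L
    cum_station <- cumsum(is_station)
    gap_has_station <- (cum_station[gap_to] -
                          cum_station[gap_from - 1L]) > 0
    split_after <- gap_len >= GAP_SPLIT_FRAMES & gap_has_station
    p_start <- m_start[c(1L, which(split_after) + 1L)]
    p_end <- m_end[c(which(split_after), k)]
  } else {
    p_start <- m_start
    p_end <- m_end
  }
  np <- length(p_start)

  cum_dur <- cumsum(dur)
  prev <- p_start - 1L
  base <- numeric(length(prev))
  base[prev > 0L] <- cum_dur[prev[prev > 0L]]
  viewing <- cum_dur[p_end] - base

  occupied <- meta$target_layout[[1]]$slot
  ent_code <- ifelse(is_model & !is.na(frames$gaze_entity),
                     frames$gaze_entity, -1L)
  n_targets <- integer(np)
  for (j in seq_len(np)) {
    r2 <- rle(ent_code[p_start[j]:p_end[j]])
    ok <- r2$values > 0 & r2$lengths >= MIN_OBJECT_FRAMES &
      r2$values %in% occupied
    n_targets[j] <- length(unique(r2$values[ok]))
  }

  cum_station_all <- cumsum(is_station)
  followed <- logical(np)
  for (j in seq_len(np)) {
    upto <- if (j < np) p_start[j + 1L] - 1L else n
    followed[j] <- p_end[j] < upto &&
      (cum_station_all[upto] - cum_station_all[p_end[j]]) > 0
  }

  tibble::new_tibble(list(
    ordinal = seq_len(np),
    start_frame = as.integer(p_start - 1L),
    end_frame = as.integer(p_end - 1L),
    model_viewing_time_s = as.numeric(viewing),
    n_targets_encoded = n_targets,
    followed_by_station = followed,
    first_in_display = seq_len(np) == 1L
  ), nrow = np)
}

#' Detect encoding periods
#'
#' An encoding period starts at a frame whose gaze intersects the model and
#' ends when gaze leaves the model for at least 25 frames (~250 ms) during
#' which the resource pool or workspace was fixated; shorter excursions, and
#' long excursions that never reach a station, are bridged into the same
#' period. Model viewing time sums all frame durations from period start to
#' end (bridged gaps included); the number of targets encoded counts distinct
#' occupied model slots fixated for at least 2 consecutive frames (~20 ms).
#'
#' @param x A `frame_log`, a `copy_task_sim`, or a frames tibble keyed by
#'   participant/day/trial.
#' @param meta Trial metadata tibble (needed for tibble input; supplies the
#'   occupied model slots).
#' @return A tibble of encoding periods with per-trial ordinals, 0-based
#'   start/end frames, metrics, and the flags the exclusion filters use.
#' @export
detect_encoding_periods <- function(x, meta = NULL) {
  map_trials(x, meta, enc_detect_one)
}

#' Apply the encoding inclusion filters
#'
#' Flags are applied sequentially and `exclusion_reason` records the first
#' matching rule: (1) periods not followed by resource-pool or workspace gaze
#' before the next period or trial end; (2) the first period of each display
#' (orientation at trial start); (3) periods shorter than 50 ms; (4) periods
#' more than 3.5 standard deviations above the participant's mean viewing
#' time, computed on raw seconds over that participant's periods surviving
#' rules 1--3, pooled across all conditions. With fewer than two surviving
#' periods for a participant the SD filter is skipped with a warning.
#'
#' @param periods Output of [detect_encoding_periods()], ideally covering all
#'   trials of each participant.
#' @return `periods` with `included` and `exclusion_reason` columns set.
#' @export
apply_encoding_exclusions <- function(periods) {
  reason <- rep("none", nrow(periods))
  reason[reason == "none" & !periods$followed_by_station] <- "not_followed_by_station"
  reason[reason == "none" & periods$first_in_display] <- "first_in_display"
  reason[reason == "none" & periods$model_viewing_time_s < MIN_PERIOD_S] <- "below_50ms"

  pid <- if ("participant_id" %in% names(periods)) periods$participant_id
         else rep("all", nrow(periods))
  for (p in unique(pid)) {
    i <- which(pid == p & reason == "none")
    if (length(i) < 2) {
      warning("fewer than 2 surviving encoding periods for participant ", p,
              "; SD filter skipped", call. = FALSE)
      next
    }
    v <- periods$model_viewing_time_s[i]
    thr <- mean(v) + SD_CUTOFF * stats::sd(v)
    reason[i[v > thr]] <- "above_3p5_sd"
  }
  periods$exclusion_reason <- reason
  periods$included <- reason == "none"
  periods
}

# --- visual search ----------------------------------------------------------

search_detect_one <- function(frames, meta, encodings = NULL) {
  empty <- EMPTY_SEARCH
  n <- nrow(frames)
  if (n == 0) return(empty)
  if (is.null(encodings)) encodings <- enc_detect_one(frames, meta)

  st <- frames$gaze_station
  is_res <- st == "resource_pool"
  dur <- frames$duration_s
  cum_dur <- cumsum(dur)
  pickups <- which(frames$event == "pickup")
  enc_start <- encodings$start_frame + 1L  # to 1-based rows
  enc_end <- encodings$end_frame + 1L

  in_enc <- rep(FALSE, n)
  for (j in seq_along(enc_start)) in_enc[enc_start[j]:enc_end[j]] <- TRUE
  open_ok <- is_res & !in_enc

  layout <- meta$resource_layout[[1]]
  ent_code <- ifelse(is_res & !is.na(frames$gaze_entity),
                     frames$gaze_entity, -1L)

  out <- list()
  anchor <- 1L
  repeat {
    cand <- which(open_ok & seq_len(n) >= anchor)
    if (length(cand) == 0) break
    f <- cand[1]
    p <- pickups[pickups >= f]
    p <- if (length(p) > 0) p[1] else NA_integer_
    e <- enc_start[enc_start > f]
    e <- if (length(e) > 0) e[1] else NA_integer_

    if (!is.na(e) && (is.na(p) || e < p)) {
      # an encoding period opens before any pickup: discard this search
      last <- e - 1L
      out[[length(out) + 1L]] <- search_metrics(
        f, last, NA_integer_, frames, cum_dur, ent_code, layout,
        no_pickup = TRUE
      )
      j <- which(enc_start == e)[1]
      anchor <- enc_end[j] + 1L
    } else if (!is.na(p)) {
      out[[length(out) + 1L]] <- search_metrics(
        f, p, p, frames, cum_dur, ent_code, layout, no_pickup = FALSE
      )
      anchor <- p + 1L
    } else {
      out[[length(out) + 1L]] <- search_metrics(
        f, n, NA_integer_, frames, cum_dur, ent_code, layout, no_pickup = TRUE
      )
      break
    }
    if (anchor > n) break
  }
  if (length(out) == 0) return(empty)
  grab <- function(name, proto) vapply(out, function(o) o[[name]], proto)
  tibble::new_tibble(list(
    ordinal = seq_along(out),
    start_frame = grab("start_frame", integer(1)),
    pickup_frame = grab("pickup_frame", integer(1)),
    search_time_s = grab("search_time_s", numeric(1)),
    picked_object = grab("picked_object", integer(1)),
    pickup_correct = grab("pickup_correct", logical(1)),
    n_targets_viewed = grab("n_targets_viewed", integer(1)),
    n_distractors_viewed = grab("n_distractors_viewed", integer(1)),
    object_viewing_times = lapply(out, function(o) o$object_viewing_times),
    no_pickup = grab("no_pickup", logical(1))
  ), nrow = length(out))
}

search_metrics <- function(from, to, pickup_row, frames, cum_dur, ent_code,
                           layout, no_pickup) {
  r <- rle(ent_code[from:to])
  ok <- r$values > 0 & r$lengths >= MIN_OBJECT_FRAMES
  if (any(ok)) {
    run_end <- cumsum(r$lengths) + from - 1L
    run_start <- run_end - r$lengths + 1L
    prev <- run_start[ok] - 1L
    base <- numeric(length(prev))
    base[prev > 0L] <- cum_dur[prev[prev > 0L]]
    span_time <- cum_dur[run_end[ok]] - base
    obj <- r$values[ok]
    per_obj <- rowsum(span_time, obj)
    obj_u <- as.integer(rownames(per_obj))
    is_tgt <- layout$is_target[match(obj_u, layout$object)]
    views <- tibble::new_tibble(
      list(object = obj_u, viewing_time_s = as.numeric(per_obj[, 1L]),
           is_target = is_tgt),
      nrow = length(obj_u)
    )
  } else {
    views <- EMPTY_VIEWS
  }
  search_time <- cum_dur[to] - if (from > 1L) cum_dur[from - 1L] else 0
  list(
    start_frame = from - 1L,
    pickup_frame = if (is.na(pickup_row)) NA_integer_ else pickup_row - 1L,
    search_time_s = as.numeric(search_time),
    picked_object = if (is.na(pickup_row)) NA_integer_
                    else frames$event_object[pickup_row],
    pickup_correct = if (is.na(pickup_row)) NA
                     else pickup_is_correct(frames, pickup_row, layout),
    n_targets_viewed = sum(is_tgt_count(views$is_target, TRUE)),
    n_distractors_viewed = sum(is_tgt_count(views$is_target, FALSE)),
    object_viewing_times = views,
    no_pickup = no_pickup
  )
}

is_tgt_count <- function(x, val) !is.na(x) & x == val

# correctness of a pickup: taken from the event when recorded, otherwise a
# non-target (distractor or replacement duplicate) counts as incorrect
pickup_is_correct <- function(frames, row, layout) {
  recorded <- frames$event_correct[row]
  if (!is.na(recorded)) return(recorded)
  obj <- frames$event_object[row]
  isTRUE(layout$is_target[match(obj, layout$object)])
}

#' Detect visual-search periods
#'
#' A search opens at the first resource-pool gaze frame after the latest of
#' trial start, the previous pickup, and the end of the preceding encoding
#' period, and closes at the next pickup event (the pickup frame is included
#' in the search). If an encoding period begins before a pickup occurs the
#' open search is discarded (`no_pickup`) and a new one opens after that
#' period. Resource-pool frames bridged into an encoding period never open a
#' search. Per-object viewing requires at least 2 consecutive frames on the
#' object; `object_viewing_times` sums all qualifying spans.
#'
#' @inheritParams detect_encoding_periods
#' @param encodings Optional pre-computed [detect_encoding_periods()] output;
#'   recomputed when missing.
#' @return A tibble of search periods with metrics and the `no_pickup` flag.
#' @export
detect_search_periods <- function(x, meta = NULL, encodings = NULL) {
  groups <- trial_groups(x, meta)
  use_enc <- !is.null(encodings)
  if (use_enc) {
    enc_key <- do.call(paste, c(encodings[intersect(TRIAL_KEYS, names(encodings))],
                                sep = "."))
  }
  dplyr::bind_rows(lapply(groups, function(g) {
    enc <- NULL
    if (use_enc) {
      key <- paste(unlist(g$meta[1, TRIAL_KEYS]), collapse = ".")
      enc <- encodings[enc_key == key, ]
    }
    with_keys(search_detect_one(g$frames, g$meta, enc), g$meta)
  }))
}

#' Apply the visual-search inclusion filters
#'
#' Sequential rules mirroring the encoding filters: searches that never ended
#' in a pickup are excluded first (`no_pickup`), then (1) searches shorter
#' than 50 ms, (2) searches that ended with a pick-up error, and (3) searches
#' more than 3.5 standard deviations above the participant's mean search time
#' (raw seconds, pooled across conditions, computed on the survivors of the
#' earlier rules).
#'
#' @param periods Output of [detect_search_periods()].
#' @return `periods` with `included` and `exclusion_reason` set.
#' @export
apply_search_exclusions <- function(periods) {
  reason <- rep("none", nrow(periods))
  reason[periods$no_pickup] <- "no_pickup"
  reason[reason == "none" & periods$search_time_s < MIN_PERIOD_S] <- "below_50ms"
  reason[reason == "none" & !periods$pickup_correct] <- "ended_in_pickup_error"

  pid <- if ("participant_id" %in% names(periods)) periods$participant_id
         else rep("all", nrow(periods))
  for (p in unique(pid)) {
    i <- which(pid == p & reason == "none")
    if (length(i) < 2) {
      warning("fewer than 2 surviving search periods for participant ", p,
              "; SD filter skipped", call. = FALSE)
      next
    }
    v <- periods$search_time_s[i]
    thr <- mean(v) + SD_CUTOFF * stats::sd(v)
    reason[i[v > thr]] <- "above_3p5_sd"
  }
  periods$exclusion_reason <- reason
  periods$included <- reason == "none"
  periods
}
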