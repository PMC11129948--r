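# Frame-log data model: per-frame gaze/position/interaction records sampled at
# a nominal 90 Hz, plus per-trial metadata (conditions and layouts).

GAZE_STATIONS <- c("model", "resource_pool", "workspace", "other", "none")
FRAME_EVENTS  <- c("none", "pickup", "placement_attempt", "release_to_pool")

FRAME_COLUMNS <- c(
  "frame_index", "duration_s", "gaze_station", "gaze_entity",
  "hmd_x", "hmd_y", "hmd_z", "ctrl_x", "ctrl_y", "ctrl_z",
  "event", "event_object", "event_slot", "event_correct", "held_object"
)

TRIAL_KEYS <- c("participant_id", "day", "trial_id")

N_MODEL_SLOTS <- 18L
N_TARGETS <- 8L
N_RESOURCE_OBJECTS <- 24L

#' Construct per-trial metadata
#'
#' One row of trial metadata: identifiers, the two experimental conditions
#' (distraction of the resource pool and movement effort between model and
#' workspace), the trial timer, and the two layouts that give every object an
#' identity and every target a model slot.
#'
#' @param participant_id Participant identifier (character).
#' @param day Testing day, 1 or 2.
#' @param session Session within day, 1 or 2.
#' @param block Block number within session.
#' @param trial_id Trial identifier, unique within participant and day.
#' @param distraction `"high"` (distractors fully opaque) or `"low"`
#'   (distractors semi-transparent).
#' @param movement_effort `"deg0"` (model directly above the workspace) or
#'   `"deg90"` (model rotated 90 degrees away).
#' @param direction `"left"` or `"right"`: which way the resource pool lies.
#' @param timer_limit_s Trial timeout in seconds (default 45).
#' @param target_layout Tibble with columns `object` (resource object id) and
#'   `slot` (model slot id, 1--18); exactly 8 rows with distinct slots.
#' @param resource_layout Tibble with columns `object` and `is_target`;
#'   exactly 24 rows of which 8 are targets.
#' @return A one-row tibble with list-columns `target_layout` and
#'   `resource_layout`.
#' @export
trial_meta <- function(participant_id = "p01", day = 1L, session = 1L,
                       block = 1L, trial_id = 1L,
                       distraction = c("high", "low"),
                       movement_effort = c("deg0", "deg90"),
                       direction = c("right", "left"),
                       timer_limit_s = 45,
                       target_layout = NULL,
                       resource_layout = NULL) {
  distraction <- match.arg(distraction)
  movement_effort <- match.arg(movement_effort)
  direction <- match.arg(direction)
  if (is.null(resource_layout)) {
    resource_layout <- tibble::tibble(
      object = seq_len(N_RESOURCE_OBJECTS),
      is_target = c(rep(TRUE, N_TARGETS), rep(FALSE, N_RESOURCE_OBJECTS - N_TARGETS))
    )
  }
  if (is.null(target_layout)) {
    target_layout <- tibble::tibble(
      object = resource_layout$object[resource_layout$is_target],
      slot = seq_len(N_TARGETS) * 2L
    )
  }
  stopifnot(timer_limit_s > 0)
  check_layouts(target_layout, resource_layout)
  tibble::tibble(
    participant_id = as.character(participant_id),
    day = as.integer(day), session = as.integer(session),
    block = as.integer(block), trial_id = as.integer(trial_id),
    distraction = distraction, movement_effort = movement_effort,
    direction = direction, timer_limit_s = as.numeric(timer_limit_s),
    target_layout = list(tibble::as_tibble(target_layout)),
    resource_layout = list(tibble::as_tibble(resource_layout))
  )
}

check_layouts <- function(target_layout, resource_layout) {
  if (nrow(target_layout) != N_TARGETS) {
    stop("target_layout must have exactly ", N_TARGETS, " rows", call. = FALSE)
  }
  if (anyDuplicated(target_layout$slot)) {
    stop("target slots must be distinct", call. = FALSE)
  }
  if (!all(target_layout$slot %in% seq_len(N_MODEL_SLOTS))) {
    stop("target slots must lie in 1..", N_MODEL_SLOTS, call. = FALSE)
  }
  if (nrow(resource_layout) != N_RESOURCE_OBJECTS) {
    stop("resource_layout must have exactly ", N_RESOURCE_OBJECTS, " rows", call. = FALSE)
  }
  if (sum(!resource_layout$is_target) != N_RESOURCE_OBJECTS - N_TARGETS) {
    stop("resource_layout must contain exactly ",
         N_RESOURCE_OBJECTS - N_TARGETS, " distractors", call. = FALSE)
  }
  if (!setequal(target_layout$object,
                resource_layout$object[resource_layout$is_target])) {
    stop("target_layout objects must equal the resource_layout targets", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a frame log
#'
#' Bundle a frames tibble with its trial metadata into a `frame_log`. Frame
#' intervals are half-open `[t, t + duration_s)` and `frame_index` is 0-based.
#'
#' @param frames Tibble with the columns listed in [empty_frames()].
#' @param meta One-row tibble from [trial_meta()].
#' @param validate If `TRUE` (default), error when [validate_frame_log()]
#'   reports violations.
#' @return An object of class `frame_log`: a list with elements `meta` and
#'   `frames`.
#' @export
frame_log <- function(frames, meta = trial_meta(), validate = TRUE) {
  frames <- tibble::as_tibble(frames)
  missing <- setdiff(FRAME_COLUMNS, names(frames))
  if (length(missing) > 0) {
    stop("frames is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(frames), FRAME_COLUMNS)
  frames <- frames[, c(FRAME_COLUMNS, extra)]
  log <- structure(list(meta = meta, frames = frames), class = "frame_log")
  if (validate) {
    v <- validate_frame_log(log)
    if (nrow(v) > 0) {
      stop("invalid frame log: ", v$rule[1], " at frame ", v$frame_index[1],
           " (", nrow(v), " violation(s) in total)", call. = FALSE)
    }
  }
  log
}

#' Empty frames tibble
#'
#' A zero-row tibble with the frame-log columns and their types: gaze AOI
#' (station and optional entity), head-mounted-display and controller
#' positions in metres, and the interaction event fields.
#'
#' @return A zero-row tibble.
#' @export
empty_frames <- function() {
  tibble::tibble(
    frame_index = integer(), duration_s = double(),
    gaze_station = character(), gaze_entity = integer(),
    hmd_x = double(), hmd_y = double(), hmd_z = double(),
    ctrl_x = double(), ctrl_y = double(), ctrl_z = double(),
    event = character(), event_object = integer(), event_slot = integer(),
    event_correct = logical(), held_object = integer()
  )
}

#' Validate a frame log
#'
#' Checks every type invariant of the frame-log data model and returns the
#' violations as data rather than raising: positive frame durations,
#' consecutive 0-based frame indices, station/entity consistency, event-field
#' consistency (an event object is present iff an event occurred, pickups
#' cannot happen while already holding an object, placements require a held
#' object on the preceding frame), and the trial-timer bound on cumulative
#' duration.
#'
#' @param log A `frame_log`.
#' @return A tibble with columns `frame_index`, `rule`, and `message`; empty
#'   iff the log is valid.
#' @export
validate_frame_log <- function(log) {
  f <- log$frames
  meta <- log$meta
  bad <- list()
  flag <- function(idx, rule, msg) {
    tibble::tibble(frame_index = as.integer(idx), rule = rule, message = msg)
  }
  n <- nrow(f)
  if (n == 0) {
    return(flag(integer(), character(), character()))
  }

  if (any(f$duration_s <= 0, na.rm = TRUE) || anyNA(f$duration_s)) {
    i <- which(is.na(f$duration_s) | f$duration_s <= 0)
    bad <- c(bad, list(flag(f$frame_index[i], "nonpositive duration",
                            "duration_s must be > 0")))
  }
  expect_idx <- seq_len(n) - 1L
  if (!identical(as.integer(f$frame_index), expect_idx)) {
    i <- which(as.integer(f$frame_index) != expect_idx)[1]
    bad <- c(bad, list(flag(f$frame_index[i], "non-monotone frame_index",
                            sprintf("expected %d at row %d", expect_idx[i], i))))
  }
  if (any(!f$gaze_station %in% GAZE_STATIONS)) {
    i <- which(!f$gaze_station %in% GAZE_STATIONS)
    bad <- c(bad, list(flag(f$frame_index[i], "unknown gaze_station",
                            "gaze_station outside the station enum")))
  }
  if (any(!f$event %in% FRAME_EVENTS)) {
    i <- which(!f$event %in% FRAME_EVENTS)
    bad <- c(bad, list(flag(f$frame_index[i], "unknown event",
                            "event outside the event enum")))
  }

  # station/entity consistency
  ent <- f$gaze_entity
  max_ent <- c(model = N_MODEL_SLOTS, resource_pool = N_RESOURCE_OBJECTS,
               workspace = N_MODEL_SLOTS)
  has_ent <- !is.na(ent)
  station_ok <- ifelse(
    f$gaze_station %in% names(max_ent),
    !has_ent | (ent >= 1L & ent <= max_ent[f$gaze_station]),
    !has_ent
  )
  if (any(!station_ok)) {
    i <- which(!station_ok)
    bad <- c(bad, list(flag(f$frame_index[i], "station/entity mismatch",
                            "gaze_entity inconsistent with gaze_station")))
  }

  # event-field consistency
  ev <- f$event != "none"
  if (any(ev != !is.na(f$event_object))) {
    i <- which(ev != !is.na(f$event_object))
    bad <- c(bad, list(flag(f$frame_index[i], "event_object mismatch",
                            "event_object must be present iff event != none")))
  }
  held_before <- c(NA_integer_, f$held_object[-n])
  i <- which(f$event == "pickup" & !is.na(held_before))
  if (length(i) > 0) {
    bad <- c(bad, list(flag(f$frame_index[i], "pickup while holding",
                            "pickup event while held_object already set")))
  }
  i <- which(f$event == "placement_attempt" & is.na(held_before))
  if (length(i) > 0) {
    bad <- c(bad, list(flag(f$frame_index[i], "placement without held object",
                            "placement_attempt requires held_object on the preceding frame")))
  }
  i <- which(f$event == "placement_attempt" &
               (is.na(f$event_slot) | is.na(f$event_correct)))
  if (length(i) > 0) {
    bad <- c(bad, list(flag(f$frame_index[i], "incomplete placement event",
                            "placement_attempt requires event_slot and event_correct")))
  }

  total <- sum(f$duration_s)
  limit <- meta$timer_limit_s[1] + f$duration_s[n]
  if (is.finite(total) && total > limit + 1e-9) {
    bad <- c(bad, list(flag(f$frame_index[n], "timer overrun",
                            sprintf("cumulative duration %.4f s exceeds timer limit", total))))
  }

  if (length(bad) == 0) flag(integer(), character(), character())
  else dplyr::arrange(dplyr::bind_rows(bad), .data$frame_index)
}

#' Write a frame log to CSV
#'
#' One row per frame, comma-separated, UTF-8, with the canonical column order
#' and the empty string as the null token for optional fields. Numeric fields
#' are serialised with shortest round-trip precision so that
#' `read_frame_log()` reproduces the log exactly. Trial metadata is written
#' separately via [write_trial_meta()].
#'
#' @param log A validated `frame_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(log, path) {
  v <- validate_frame_log(log)
  if (nrow(v) > 0) {
    stop("refusing to write an invalid frame log (", v$rule[1],
         " at frame ", v$frame_index[1], ")", call. = FALSE)
  }
  readr::write_csv(log$frames[, FRAME_COLUMNS], path, na = "")
  invisible(path)
}

frame_col_types <- function() {
  readr::cols(
    frame_index = readr::col_integer(), duration_s = readr::col_double(),
    gaze_station = readr::col_character(), gaze_entity = readr::col_integer(),
    hmd_x = readr::col_double(), hmd_y = readr::col_double(),
    hmd_z = readr::col_double(), ctrl_x = readr::col_double(),
    ctrl_y = readr::col_double(), ctrl_z = readr::col_double(),
    event = readr::col_character(), event_object = readr::col_integer(),
    event_slot = readr::col_integer(), event_correct = readr::col_logical(),
    held_object = readr::col_integer(), .default = readr::col_character()
  )
}

#' Read a frame log from CSV
#'
#' Reads a file written by [write_frame_log()], restores column types, and
#' validates the result. Unknown extra columns are preserved as character
#' annotations.
#'
#' @param path File path.
#' @param meta One-row metadata tibble for the trial (default: a generic
#'   [trial_meta()]).
#' @param validate Validate after reading (default `TRUE`).
#' @return A `frame_log`.
#' @export
read_frame_log <- function(path, meta = trial_meta(), validate = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(FRAME_COLUMNS, header)
  if (length(missing) > 0) {
    stop("frame CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frames <- readr::read_csv(path, col_types = frame_col_types(), na = "",
                            show_col_types = FALSE)
  attr(frames, "spec") <- NULL
  attr(frames, "problems") <- NULL
  frames$gaze_station[is.na(frames$gaze_station)] <- "none"
  frames$event[is.na(frames$event)] <- "none"
  frame_log(frames, meta, validate = validate)
}

#' Write trial metadata to CSV
#'
#' One row per trial; the target and resource layouts are JSON-encoded into
#' single columns so the file stays flat.
#'
#' @param meta Tibble of one or more [trial_meta()] rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_meta <- function(meta, path) {
  flat <- meta
  flat$target_layout <- vapply(
    meta$target_layout,
    function(x) as.character(jsonlite::toJSON(x, digits = NA)), character(1)
  )
  flat$resource_layout <- vapply(
    meta$resource_layout,
    function(x) as.character(jsonlite::toJSON(x, digits = NA)), character(1)
  )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' Read trial metadata from CSV
#'
#' @param path File written by [write_trial_meta()].
#' @return Tibble of trial metadata with layout list-columns restored.
#' @export
read_trial_meta <- function(path) {
  flat <- readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(), day = readr::col_integer(),
      session = readr::col_integer(), block = readr::col_integer(),
      trial_id = readr::col_integer(), distraction = readr::col_character(),
      movement_effort = readr::col_character(),
      direction = readr::col_character(), timer_limit_s = readr::col_double(),
      target_layout = readr::col_character(),
      resource_layout = readr::col_character()
    )
  )
  attr(flat, "spec") <- NULL
  attr(flat, "problems") <- NULL
  flat$target_layout <- lapply(flat$target_layout, function(s) {
    tibble::as_tibble(jsonlite::fromJSON(s))
  })
  flat$resource_layout <- lapply(flat$resource_layout, function(s) {
    tibble::as_tibble(jsonlite::fromJSON(s))
  })
  flat
}

#' @export
print.frame_log <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<frame_log> participant %s day %d trial %d: %d frames (%.2f s), %s distraction, %s\n",
    m$participant_id, m$day, m$trial_id, nrow(x$frames),
    sum(x$frames$duration_s), m$distraction, m$movement_effort
  ))
  invisible(x)
}

#' Tidy a frame log into one tibble
#'
#' @param x A `frame_log`.
#' @param ... Unused.
#' @return The frames tibble with the trial key columns prepended.
#' @method tidy frame_log
#' @export
tidy.frame_log <- function(x, ...) {
  dplyr::bind_cols(
    x$meta[rep(1, nrow(x$frames)), TRIAL_KEYS],
    x$frames
  )
}

#' One-row summary of a frame log
#'
#' @param x A `frame_log`.
#' @param ... Unused.
#' @return A one-row tibble with frame count, duration, and event counts.
#' @method glance frame_log
#' @export
glance.frame_log <- function(x, ...) {
  f <- x$frames
  tibble::tibble(
    n_frames = nrow(f),
    duration_s = sum(f$duration_s),
    n_pickups = sum(f$event == "pickup"),
    n_placements = sum(f$event == "placement_attempt"),
    n_correct_placements = sum(f$event == "placement_attempt" & f$event_correct,
                               na.rm = TRUE)
  )
}

# Attach trial keys from a meta row to a per-trial tibble.
with_keys <- function(tbl, meta) {
  n <- nrow(tbl)
  tibble::new_tibble(
    c(list(participant_id = rep.int(meta$participant_id[[1]], n),
           day = rep.int(meta$day[[1]], n),
           trial_id = rep.int(meta$trial_id[[1]], n)),
      as.list(tbl)),
    nrow = n
  )
}
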