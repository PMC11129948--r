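# Sensorimnemonic decisions: after every correct target pickup (location-
# related) and every correct placement (identity-related) the participant
# either acts from memory or re-fixates the model first. Decisions are
# position-indexed within their sequence and pass the inclusion filters
# before probabilities are estimated. Errors are position-indexed likewise.

dec_extract_one <- function(sequences, searches, actions, frames,
                            encodings = NULL) {
  empty <- EMPTY_DECISIONS
  if (nrow(sequences) == 0 || nrow(actions) == 0) return(empty)
  n <- nrow(frames)
  model_frames <- which(frames$gaze_station == "model") - 1L  # 0-based
  release_frames <- which(frames$event == "release_to_pool") - 1L
  ord <- order(actions$frame)
  a_frame <- actions$frame[ord]
  a_kind <- actions$kind[ord]
  a_correct <- actions$correct[ord]
  na <- length(a_frame)

  sq_start <- sequences$start_frame
  sq_end <- sequences$end_frame
  sq_type <- sequences$sequence_type
  sq_ord <- sequences$seq_ordinal
  enc_ok <- if (!is.null(encodings) && "included" %in% names(encodings)) {
    encodings$included[match(sequences$start_enc_ordinal, encodings$ordinal)]
  } else rep(TRUE, nrow(sequences))
  srch_pickup <- searches$pickup_frame
  srch_included <- if ("included" %in% names(searches)) searches$included
                   else rep(FALSE, nrow(searches))

  o_seq <- integer(0); o_kind <- character(0); o_pos <- integer(0)
  o_lock <- integer(0); o_mem <- logical(0); o_reason <- character(0)

  for (i in seq_along(sq_start)) {
    in_seq <- which(a_frame > sq_start[i] & a_frame < sq_end[i])
    if (length(in_seq) == 0) next
    correct_rows <- in_seq[a_correct[in_seq]]
    if (length(correct_rows) == 0) next

    seq_reason <- "none"
    if (sq_type[i] != "search_first") {
      seq_reason <- "non_search_first_sequence"
    } else if (!isTRUE(enc_ok[i])) {
      seq_reason <- "bad_initial_encoding"
    } else {
      m <- which(srch_pickup == a_frame[in_seq[1]])
      if (length(m) == 0 || !isTRUE(srch_included[m[1]])) {
        seq_reason <- "unmatched_or_bad_search"
      }
    }

    pos <- 0L
    for (j in correct_rows) {
      pos <- pos + 1L
      af <- a_frame[j]
      kind <- if (a_kind[j] == "pickup") "location_related" else "identity_related"
      locked <- af + 1L
      has_next <- j < na
      if (has_next) {
        nxt_frame <- a_frame[j + 1L]
        used_memory <- !any(model_frames > af & model_frames < nxt_frame)
      } else {
        used_memory <- if (any(model_frames > af)) FALSE else NA
      }

      reason <- seq_reason
      if (reason == "none") {
        before <- in_seq[in_seq < j]
        disrupted <- any(!a_correct[before]) ||
          any(release_frames > sq_start[i] & release_frames < af)
        if (disrupted) {
          reason <- "disrupted"
        } else if (isTRUE(used_memory) && has_next && !a_correct[j + 1L]) {
          reason <- "memory_then_error"
        } else if ((!has_next && is.na(used_memory)) || locked >= n) {
          reason <- "no_following_action"
        }
      }
      o_seq <- c(o_seq, sq_ord[i]); o_kind <- c(o_kind, kind)
      o_pos <- c(o_pos, pos); o_lock <- c(o_lock, locked)
      o_mem <- c(o_mem, used_memory); o_reason <- c(o_reason, reason)
    }
  }
  if (length(o_seq) == 0) return(empty)
  tibble::new_tibble(list(
    seq_ordinal = o_seq, kind = o_kind, position = o_pos,
    locked_frame = o_lock, used_memory = o_mem,
    included = o_reason == "none", exclusion_reason = o_reason
  ), nrow = length(o_seq))
}

#' Extract sensorimnemonic decisions
#'
#' Location-related decisions are locked to the frame after a correct target
#' pickup; identity-related decisions to the frame after a correct placement.
#' `used_memory` is true iff the next pickup/placement occurs with no
#' intervening model fixation. Inclusion filters, applied in order: the
#' sequence must have started with a search and pickup (`search_first`); the
#' search preceding its first decision must be matchable and included; the
#' run-up to the decision must not have been disrupted by an error needing
#' correction; a memory decision must not be followed by a mistake; and the
#' decision must be followed by an encoding or another action.
#'
#' @param sequences Output of [build_sequences()].
#' @param searches Search periods with exclusion flags
#'   ([apply_search_exclusions()]).
#' @param actions Output of [extract_actions()].
#' @param x The frame log(s).
#' @param meta Trial metadata for tibble input.
#' @param encodings Optional encoding periods with exclusion flags, used to
#'   verify that each sequence's initial encoding was included (sequences
#'   built from included periods satisfy this by construction).
#' @return A tibble of decisions with position, `used_memory`, and inclusion
#'   flags.
#' @export
extract_decisions <- function(sequences, searches, actions, x, meta = NULL,
                              encodings = NULL) {
  groups <- trial_groups(x, meta)
  keyed <- length(intersect(TRIAL_KEYS, names(sequences))) == 3
  seq_key <- if (keyed) do.call(paste, c(sequences[TRIAL_KEYS], sep = "."))
  srch_key <- if (keyed) do.call(paste, c(searches[TRIAL_KEYS], sep = "."))
  act_key <- if (keyed) do.call(paste, c(actions[TRIAL_KEYS], sep = "."))
  enc_key <- if (keyed && !is.null(encodings)) {
    do.call(paste, c(encodings[TRIAL_KEYS], sep = "."))
  }
  dplyr::bind_rows(lapply(groups, function(g) {
    if (keyed) {
      key <- paste(unlist(g$meta[1, TRIAL_KEYS]), collapse = ".")
      sq <- sequences[seq_key == key, ]
      sr <- searches[srch_key == key, ]
      ac <- actions[act_key == key, ]
      en <- if (is.null(encodings)) NULL else encodings[enc_key == key, ]
    } else {
      sq <- sequences; sr <- searches; ac <- actions; en <- encodings
    }
    with_keys(dec_extract_one(sq, sr, ac, g$frames, en), g$meta)
  }))
}

#' Probability of relying on memory
#'
#' The proportion of included sensorimnemonic decisions in which memory was
#' used, by decision kind, position within the sequence, and condition.
#' Positions beyond `all_effort_up_to` are restricted to the high
#' movement-effort condition (`deg90`), where longer memory-guided sequences
#' occur often enough to estimate.
#'
#' @param decisions Output of [extract_decisions()].
#' @param meta Trial metadata (condition columns).
#' @param by Condition columns to stratify by.
#' @param positions Decision positions to report.
#' @param all_effort_up_to Positions above this value keep only `deg90`
#'   trials; set to `Inf` to keep all conditions at all positions.
#' @return A tibble with `kind`, `position`, the `by` columns, `n_decisions`,
#'   and `p_memory`.
#' @export
p_memory_table <- function(decisions, meta, by = "distraction",
                           positions = 1:3, all_effort_up_to = 1) {
  cols <- unique(c(by, "movement_effort"))
  d <- decisions[decisions$included, ]
  d <- dplyr::left_join(d, dplyr::distinct(meta[, c(TRIAL_KEYS, cols)]),
                        by = TRIAL_KEYS)
  d <- d[d$position %in% positions, ]
  d <- d[d$position <= all_effort_up_to | d$movement_effort == "deg90", ]
  out <- d |>
    dplyr::summarise(
      n_decisions = dplyr::n(),
      p_memory = mean(.data$used_memory),
      .by = dplyr::all_of(c("kind", "position", by))
    ) |>
    dplyr::arrange(.data$position, .data$kind)
  if (nrow(out) == 0) warning("no included decisions in the requested cells",
                              call. = FALSE)
  out
}

err_extract_one <- function(sequences, actions, target_objects) {
  empty <- EMPTY_ERRORS
  if (nrow(sequences) == 0 || nrow(actions) == 0) return(empty)
  ord <- order(actions$frame)
  a_frame <- actions$frame[ord]
  a_kind <- actions$kind[ord]
  a_object <- actions$object[ord]
  a_correct <- actions$correct[ord]

  o_seq <- integer(0); o_kind <- character(0); o_slot <- character(0)
  o_occ <- logical(0); o_frame <- integer(0)
  push <- function(seq_ord, kind, slot, occurred, frame) {
    o_seq <<- c(o_seq, seq_ord); o_kind <<- c(o_kind, kind)
    o_slot <<- c(o_slot, slot); o_occ <<- c(o_occ, occurred)
    o_frame <<- c(o_frame, frame)
  }
  for (i in seq_len(nrow(sequences))) {
    if (sequences$sequence_type[i] != "search_first") next
    in_seq <- which(a_frame > sequences$start_frame[i] &
                      a_frame < sequences$end_frame[i])
    n_pick <- 0L; n_place <- 0L
    for (j in in_seq) {
      if (a_kind[j] == "pickup") {
        n_pick <- n_pick + 1L
        if (n_pick <= 2L) {
          push(sequences$seq_ordinal[i], "identity",
               c("first_pickup", "second_pickup")[n_pick],
               !a_correct[j], a_frame[j])
        }
      } else {
        # attempted placements of non-targets are not error opportunities
        if (!a_object[j] %in% target_objects) {
          if (!a_correct[j]) break
          next
        }
        n_place <- n_place + 1L
        if (n_place <= 2L) {
          push(sequences$seq_ordinal[i], "location",
               c("first_placement", "second_placement")[n_place],
               !a_correct[j], a_frame[j])
        }
      }
      if (!a_correct[j]) break  # sequence truncated after its first error
    }
  }
  if (length(o_seq) == 0) return(empty)
  tibble::new_tibble(
    list(seq_ordinal = o_seq, kind = o_kind, position_slot = o_slot,
         occurred = o_occ, frame = o_frame),
    nrow = length(o_seq)
  )
}

#' Extract position-indexed identity and location errors
#'
#' Within each search-first sequence, one opportunity record is emitted per
#' first/second pickup (identity errors: grabbing a distractor or a
#' replacement duplicate) and first/second placement of a target (location
#' errors: a wrong-slot placement attempt), walking the actions in order and
#' stopping after the first error so later errors in the same sequence stay
#' out of the rates. Unlike decisions, error sequences are kept irrespective
#' of what follows each action.
#'
#' @param sequences Output of [build_sequences()].
#' @param actions Output of [extract_actions()].
#' @param meta Trial metadata (supplies the target objects per trial).
#' @return A tibble of error opportunities with `occurred` flags.
#' @export
extract_errors <- function(sequences, actions, meta) {
  keyed <- length(intersect(TRIAL_KEYS, names(sequences))) == 3
  if (!keyed) {
    targets <- meta$target_layout[[1]]$object
    return(err_extract_one(sequences, actions, targets))
  }
  seq_key <- do.call(paste, c(sequences[TRIAL_KEYS], sep = "."))
  act_key <- do.call(paste, c(actions[TRIAL_KEYS], sep = "."))
  meta_key <- do.call(paste, c(meta[TRIAL_KEYS], sep = "."))
  dplyr::bind_rows(lapply(unique(seq_key), function(key) {
    m <- meta[match(key, meta_key), ]
    res <- err_extract_one(sequences[seq_key == key, ],
                           actions[act_key == key, ],
                           m$target_layout[[1]]$object)
    with_keys(res, m)
  }))
}

#' Error rates by kind, position, and condition
#'
#' The percentage of incorrect pickups/placements out of all pickup/placement
#' opportunities, per position slot within the behavioural sequence.
#'
#' @param errors Output of [extract_errors()].
#' @param meta Trial metadata (condition columns).
#' @param by Condition columns to stratify by.
#' @return A tibble with `kind`, `position_slot`, the `by` columns,
#'   `n_opportunities`, `n_errors`, and `error_rate_pct` in `[0, 100]`.
#' @export
error_rate_table <- function(errors, meta, by = "distraction") {
  e <- dplyr::left_join(errors, dplyr::distinct(meta[, c(TRIAL_KEYS, by)]),
                        by = TRIAL_KEYS)
  slot_order <- c("first_pickup", "first_placement",
                  "second_pickup", "second_placement")
  e |>
    dplyr::summarise(
      n_opportunities = dplyr::n(),
      n_errors = sum(.data$occurred),
      error_rate_pct = 100 * mean(.data$occurred),
      .by = dplyr::all_of(c("kind", "position_slot", by))
    ) |>
    dplyr::arrange(match(.data$position_slot, slot_order))
}
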