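# Generative task agent: emits frame logs of the object-copying task plus
# ground-truth annotations of every encoding visit, search, sensorimnemonic
# decision and action, so downstream detectors can be validated by recovery.

#' Agent policy for the task simulator
#'
#' The policy collects the behavioural parameters of the generative agent:
#' how many targets it encodes per model visit, how long it dwells on model
#' slots and resource objects, which distractors it inspects, the probability
#' of relying on memory at each sensorimnemonic decision, error rates, and
#' locomotion geometry/speed. All dwell parameters are in seconds; the frame
#' rate is nominally 90 Hz.
#'
#' @param n_encode_dist Named list with elements `deg0` and `deg90`, each a
#'   probability vector over encoding 1..8 targets per model visit.
#' @param encode_dwell_s `c(mean, jitter)` of gaze dwell per encoded model
#'   slot; dwells are drawn uniformly from `mean +- jitter`.
#' @param orient_dwell_s Duration of the initial orientation viewing of the
#'   model at trial start.
#' @param inter_slot_gap_frames Integer support of off-model gaze gaps
#'   (gaze `"none"`) between slot dwells inside one model visit; kept below
#'   25 frames by default so the gap-bridging rule merges them.
#' @param p_inspect_distractor Named vector `c(high = , low = )`: probability
#'   that each distractor is fixated during one search, by distraction
#'   condition.
#' @param p_inspect_target Probability that a non-sought target is fixated
#'   during a search.
#' @param inspect_dwell_s List with `target = c(mean, jitter)` and
#'   `distractor = list(high = c(mean, jitter), low = c(mean, jitter))`.
#' @param place_dwell_s `c(mean, jitter)` of workspace-slot gaze before a
#'   placement attempt.
#' @param p_memory Tibble with columns `kind` (`"location"`/`"identity"`),
#'   `position` (decision index within a sequence), `distraction`,
#'   `movement_effort`, `p`: probability of relying on memory. Positions
#'   beyond the largest tabulated position reuse the last row.
#' @param p_identity_error Tibble `position` (pickup index within sequence,
#'   capped at 2), `distraction`, `p`: probability a pickup selects a
#'   non-target.
#' @param p_location_error Tibble `position`, `distraction`, `p`: probability
#'   a placement attempt targets a wrong slot.
#' @param locomotion_speed_m_s Head translation speed between stations.
#' @param station_geometry List with elements `deg0` and `deg90`, each a list
#'   of 3-vectors `model`, `resource`, `workspace` (metres, room frame with
#'   origin at the room centre) for the rightward direction; leftward trials
#'   mirror the x axis.
#' @param frame_rate_hz Frames per second (default 90).
#' @return An object of class `agent_policy` (a list).
#' @export
agent_policy <- function(n_encode_dist = list(
                           deg0 = c(0.65, 0.30, 0.05, rep(0, 5)),
                           deg90 = c(0.20, 0.45, 0.25, 0.10, rep(0, 4))
                         ),
                         encode_dwell_s = c(mean = 0.35, jitter = 0.10),
                         orient_dwell_s = 0.6,
                         inter_slot_gap_frames = 0:5,
                         p_inspect_distractor = c(high = 0.28, low = 0.15),
                         p_inspect_target = 0.08,
                         inspect_dwell_s = list(
                           target = c(mean = 0.30, jitter = 0.08),
                           distractor = list(high = c(mean = 0.18, jitter = 0.06),
                                             low = c(mean = 0.12, jitter = 0.04))
                         ),
                         place_dwell_s = c(mean = 0.35, jitter = 0.06),
                         p_memory = default_p_memory(),
                         p_identity_error = default_p_identity_error(),
                         p_location_error = default_p_location_error(),
                         locomotion_speed_m_s = 1.5,
                         station_geometry = default_station_geometry(),
                         frame_rate_hz = 90) {
  stopifnot(frame_rate_hz > 0, locomotion_speed_m_s >= 0)
  stopifnot(all(p_memory$p >= 0 & p_memory$p <= 1))
  stopifnot(all(p_identity_error$p >= 0 & p_identity_error$p <= 1))
  stopifnot(all(p_location_error$p >= 0 & p_location_error$p <= 1))
  stopifnot(all(inter_slot_gap_frames >= 0))
  structure(
    list(
      n_encode_dist = n_encode_dist, encode_dwell_s = encode_dwell_s,
      orient_dwell_s = orient_dwell_s,
      inter_slot_gap_frames = as.integer(inter_slot_gap_frames),
      p_inspect_distractor = p_inspect_distractor,
      p_inspect_target = p_inspect_target,
      inspect_dwell_s = inspect_dwell_s, place_dwell_s = place_dwell_s,
      p_memory = tibble::as_tibble(p_memory),
      p_identity_error = tibble::as_tibble(p_identity_error),
      p_location_error = tibble::as_tibble(p_location_error),
      locomotion_speed_m_s = locomotion_speed_m_s,
      station_geometry = station_geometry, frame_rate_hz = frame_rate_hz
    ),
    class = "agent_policy"
  )
}

#' Default memory-reliance probabilities
#'
#' Memory reliance rises with movement effort (re-encoding is costlier when
#' the model is rotated away) and, for identity-related decisions, falls
#' under high distraction; location-related decisions are unaffected by
#' distraction. Values are tabulated for decision positions 1--6 within a
#' sequence.
#'
#' @return A tibble with columns `kind`, `position`, `distraction`,
#'   `movement_effort`, `p`.
#' @export
default_p_memory <- function() {
  base <- list(
    location = list(deg90 = c(0.85, 0.80, 0.55, 0.50, 0.35, 0.30),
                    deg0  = c(0.50, 0.45, 0.20, 0.18, 0.10, 0.10)),
    identity = list(deg90 = c(0.55, 0.50, 0.35, 0.35, 0.20, 0.20),
                    deg0  = c(0.20, 0.18, 0.08, 0.08, 0.05, 0.05))
  )
  # distraction lowers identity-related memory use multiplicatively
  identity_high_factor <- 0.84
  grid <- tidyr::expand_grid(
    kind = c("location", "identity"), position = 1:6,
    distraction = c("high", "low"), movement_effort = c("deg0", "deg90")
  )
  grid$p <- unname(mapply(function(kind, pos, dis, eff) {
    p <- base[[kind]][[eff]][pos]
    if (kind == "identity" && dis == "high") p <- p * identity_high_factor
    p
  }, grid$kind, grid$position, grid$distraction, grid$movement_effort))
  grid
}

#' Default identity-error probabilities
#'
#' Picking a non-target is more likely under high distraction and later in a
#' sequence (memory-guided pickups).
#'
#' @return A tibble with columns `position`, `distraction`, `p`.
#' @export
default_p_identity_error <- function() {
  tidyr::expand_grid(position = 1:2, distraction = c("high", "low")) |>
    dplyr::mutate(p = dplyr::case_when(
      position == 1 & distraction == "high" ~ 0.045,
      position == 1 & distraction == "low" ~ 0.020,
      position == 2 & distraction == "high" ~ 0.060,
      TRUE ~ 0.030
    ))
}

#' Default location-error probabilities
#'
#' Wrong-slot placements are not increased by distraction (the manipulation
#' targets identity information); second placements err slightly more often
#' under low distraction.
#'
#' @return A tibble with columns `position`, `distraction`, `p`.
#' @export
default_p_location_error <- function() {
  tidyr::expand_grid(position = 1:2, distraction = c("high", "low")) |>
    dplyr::mutate(p = dplyr::case_when(
      position == 1 & distraction == "high" ~ 0.030,
      position == 1 & distraction == "low" ~ 0.035,
      position == 2 & distraction == "high" ~ 0.035,
      TRUE ~ 0.050
    ))
}

#' Default station geometry
#'
#' Stations sit on a 0.6 m radius around the room centre: the workspace ahead,
#' the resource pool 90 degrees to the right, and the model either directly
#' above the workspace (`deg0`, no translation needed) or 90 degrees to the
#' left (`deg90`). Head height is fixed at 1.6 m.
#'
#' @return A list with elements `deg0` and `deg90`.
#' @export
default_station_geometry <- function() {
  list(
    deg0 = list(model = c(0, 1.6, 0.6), resource = c(0.6, 1.6, 0),
                workspace = c(0, 1.6, 0.6)),
    deg90 = list(model = c(-0.6, 1.6, 0), resource = c(0.6, 1.6, 0),
                 workspace = c(0, 1.6, 0.6))
  )
}

# uniform draw from an explicit support vector (safe for length-1 supports)
resample1 <- function(x) x[sample.int(length(x), 1L)]

# dwell length in frames from a (mean, jitter) spec, at least 3 frames
dwell_frames <- function(spec, fps) {
  s <- stats::runif(1, spec[[1]] - spec[[2]], spec[[1]] + spec[[2]])
  max(3L, as.integer(round(s * fps)))
}

lookup_prob <- function(tbl, position, distraction, kind = NULL,
                        movement_effort = NULL) {
  sub <- tbl
  if (!is.null(kind)) sub <- sub[sub$kind == kind, ]
  if (!is.null(movement_effort)) sub <- sub[sub$movement_effort == movement_effort, ]
  sub <- sub[sub$distraction == distraction, ]
  if (nrow(sub) == 0) stop("no probability entry for this condition", call. = FALSE)
  pos <- min(position, max(sub$position))
  unname(sub$p[match(pos, sub$position)])
}

# --- segment tape ------------------------------------------------------------

# A tape accumulates gaze/event segments; expansion turns them into uniform
# 1/fps frames with piecewise-linear head paths.
new_tape <- function(fps, start_pos) {
  cap <- 256L
  station <- character(cap); entity <- rep(NA_integer_, cap)
  nfr <- integer(cap)
  tx <- numeric(cap); ty <- numeric(cap); tz <- numeric(cap)
  ev <- rep(NA_character_, cap); ev_obj <- rep(NA_integer_, cap)
  ev_slot <- rep(NA_integer_, cap); ev_corr <- rep(NA, cap)
  n_seg <- 0L
  cur <- start_pos
  n_frames <- 0L
  path_m <- 0

  grow <- function() {
    cap2 <- cap * 2L
    length(station) <<- cap2; length(entity) <<- cap2; length(nfr) <<- cap2
    length(tx) <<- cap2; length(ty) <<- cap2; length(tz) <<- cap2
    length(ev) <<- cap2; length(ev_obj) <<- cap2; length(ev_slot) <<- cap2
    length(ev_corr) <<- cap2
    cap <<- cap2
  }

  emit <- function(st, en, n, to = NULL, event = NA_character_,
                   event_object = NA_integer_, event_slot = NA_integer_,
                   event_correct = NA) {
    n <- as.integer(n)
    if (n <= 0) return(invisible(NULL))
    if (n_seg + 1L > cap) grow()
    n_seg <<- n_seg + 1L
    station[n_seg] <<- st; entity[n_seg] <<- as.integer(en); nfr[n_seg] <<- n
    if (is.null(to)) to <- cur
    tx[n_seg] <<- to[1]; ty[n_seg] <<- to[2]; tz[n_seg] <<- to[3]
    path_m <<- path_m + sqrt(sum((to - cur)^2))
    cur <<- to
    ev[n_seg] <<- event; ev_obj[n_seg] <<- as.integer(event_object)
    ev_slot[n_seg] <<- as.integer(event_slot); ev_corr[n_seg] <<- event_correct
    n_frames <<- n_frames + n
    invisible(NULL)
  }

  walk_to <- function(target, speed, gaze = "other") {
    d <- sqrt(sum((target - cur)^2))
    if (d < 1e-12) return(invisible(NULL))
    if (speed <= 0) {
      stop("locomotion_speed_m_s must be > 0 to travel between distinct stations",
           call. = FALSE)
    }
    emit(gaze, NA_integer_, max(1L, as.integer(ceiling(d / speed * fps))),
         to = target)
  }

  expand <- function(limit_frames = NULL) {
    idx <- seq_len(n_seg)
    n <- nfr[idx]
    total <- sum(n)
    st <- rep(station[idx], n)
    en <- rep(entity[idx], n)
    # head path: frame j of a segment sits at from + (j/n) * (to - from)
    frac <- sequence(n) / rep(n, n)
    from_x <- c(start_pos[1], tx[idx][-n_seg]); from_y <- c(start_pos[2], ty[idx][-n_seg])
    from_z <- c(start_pos[3], tz[idx][-n_seg])
    hx <- rep(from_x, n) + frac * rep(tx[idx] - from_x, n)
    hy <- rep(from_y, n) + frac * rep(ty[idx] - from_y, n)
    hz <- rep(from_z, n) + frac * rep(tz[idx] - from_z, n)
    event <- rep("none", total)
    event_object <- rep(NA_integer_, total)
    event_slot <- rep(NA_integer_, total)
    event_correct <- rep(NA, total)
    last_frame <- cumsum(n)
    has_ev <- which(!is.na(ev[idx]))
    event[last_frame[has_ev]] <- ev[idx][has_ev]
    event_object[last_frame[has_ev]] <- ev_obj[idx][has_ev]
    event_slot[last_frame[has_ev]] <- ev_slot[idx][has_ev]
    event_correct[last_frame[has_ev]] <- ev_corr[idx][has_ev]

    if (!is.null(limit_frames) && total > limit_frames) {
      keep <- seq_len(limit_frames)
      st <- st[keep]; en <- en[keep]; hx <- hx[keep]; hy <- hy[keep]; hz <- hz[keep]
      event <- event[keep]; event_object <- event_object[keep]
      event_slot <- event_slot[keep]; event_correct <- event_correct[keep]
      total <- limit_frames
    }

    # held object follows pickup / correct placement / release events
    held <- rep(NA_integer_, total)
    pick <- which(event == "pickup")
    drop_f <- which((event == "placement_attempt" & event_correct %in% TRUE) |
                      event == "release_to_pool")
    if (length(pick) > 0) {
      bounds <- vapply(pick, function(p) {
        nxt <- drop_f[drop_f >= p]
        if (length(nxt) == 0) total else nxt[1]
      }, integer(1))
      for (k in seq_along(pick)) {
        held[seq(pick[k], bounds[k])] <- event_object[pick[k]]
      }
    }

    tibble::new_tibble(list(
      frame_index = seq_len(total) - 1L, duration_s = rep(1 / fps, total),
      gaze_station = st, gaze_entity = en,
      hmd_x = hx, hmd_y = hy, hmd_z = hz,
      ctrl_x = hx + 0.10, ctrl_y = hy - 0.45, ctrl_z = hz + 0.15,
      event = event, event_object = event_object, event_slot = event_slot,
      event_correct = event_correct, held_object = held
    ), nrow = total)
  }

  # path length of the first `limit_frames` frames, closed form over segments
  path_length <- function(limit_frames = NULL) {
    if (is.null(limit_frames) || n_frames <= limit_frames) return(path_m)
    idx <- seq_len(n_seg)
    from_x <- c(start_pos[1], tx[idx][-n_seg]); from_y <- c(start_pos[2], ty[idx][-n_seg])
    from_z <- c(start_pos[3], tz[idx][-n_seg])
    leg <- sqrt((tx[idx] - from_x)^2 + (ty[idx] - from_y)^2 + (tz[idx] - from_z)^2)
    ends <- cumsum(nfr[idx])
    starts <- ends - nfr[idx] + 1L
    kept <- pmin(pmax(limit_frames - starts + 1L, 0L), nfr[idx])
    sum(leg * kept / nfr[idx])
  }

  list(emit = emit, walk_to = walk_to, expand = expand,
       frames_so_far = function() n_frames, path_length = path_length)
}

# --- single-trial simulation -------------------------------------------------

#' Simulate one trial of the object-copying task
#'
#' The agent orients on the model, then loops: encode a batch of targets,
#' walk to the resource pool, search (fixating distractors according to the
#' inspection model) and pick up the sought target, and at each
#' sensorimnemonic decision either act from memory or re-fixate the model
#' first. Erroneous pickups are returned to the pool and erroneous placements
#' corrected before the task continues; the trial ends at 8 correct
#' placements or at the trial timer.
#'
#' @param policy An [agent_policy()].
#' @param meta A one-row [trial_meta()] tibble.
#' @param seed Integer seed; identical `(policy, meta, seed)` give
#'   byte-identical output.
#' @return A list with elements `log` (a `frame_log`) and `truth` (a list of
#'   ground-truth tibbles: `encodings`, `searches`, `decisions`, `actions`,
#'   `trial`).
#' @export
simulate_trial <- function(policy, meta, seed = 1L) {
  stopifnot(inherits(policy, "agent_policy"))
  set.seed(as.integer(seed))
  fps <- policy$frame_rate_hz
  effort <- meta$movement_effort[1]
  dis <- meta$distraction[1]
  limit_frames <- as.integer(round(meta$timer_limit_s[1] * fps))

  geom <- policy$station_geometry[[effort]]
  if (meta$direction[1] == "left") {
    geom <- lapply(geom, function(p) c(-p[1], p[2], p[3]))
  }
  speed <- policy$locomotion_speed_m_s

  targets <- meta$target_layout[[1]]
  resource <- meta$resource_layout[[1]]
  distractors <- resource$object[!resource$is_target]
  plan <- targets[sample.int(nrow(targets)), ]  # copy order

  tape <- new_tape(fps, start_pos = c(0, 1.6, 0))

  # ground-truth accumulators (parallel vectors)
  tv <- new.env(parent = emptyenv())
  tv$enc_start <- integer(0); tv$enc_end <- integer(0); tv$enc_slots <- list()
  tv$sr_start <- integer(0); tv$sr_pick <- integer(0); tv$sr_obj <- list()
  tv$dc_kind <- character(0); tv$dc_pos <- integer(0)
  tv$dc_mem <- logical(0); tv$dc_lock <- integer(0)
  tv$ac_kind <- character(0); tv$ac_obj <- integer(0)
  tv$ac_slot <- integer(0); tv$ac_corr <- logical(0); tv$ac_frame <- integer(0)

  placed <- 0L
  pos <- 0L          # decision position within current sequence
  n_pick_seq <- 0L   # pickup index within current sequence
  n_place_seq <- 0L

  encode_visit <- function(first = FALSE) {
    start_f <- tape$frames_so_far()
    if (first) {
      tape$emit("model", NA_integer_, max(3L, round(policy$orient_dwell_s * fps)))
      tape$walk_to(geom$model, speed, gaze = "model")
    } else {
      tape$walk_to(geom$model, speed)
      start_f <- tape$frames_so_far()
    }
    k <- sample.int(8L, 1L, prob = policy$n_encode_dist[[effort]])
    k <- max(1L, min(k, 8L - placed))
    slots <- plan$slot[seq(placed + 1L, placed + k)]
    for (i in seq_len(k)) {
      tape$emit("model", slots[i], dwell_frames(policy$encode_dwell_s, fps))
      if (i < k) {
        g <- resample1(policy$inter_slot_gap_frames)
        if (g > 0) tape$emit("none", NA_integer_, g)
      }
    }
    tv$enc_start <- c(tv$enc_start, start_f)
    tv$enc_end <- c(tv$enc_end, tape$frames_so_far() - 1L)
    tv$enc_slots <- c(tv$enc_slots, list(as.integer(slots)))
    pos <<- 0L; n_pick_seq <<- 0L; n_place_seq <<- 0L
    invisible(NULL)
  }

  inspect_some <- function(exclude_obj) {
    looked <- integer(0)
    cand_d <- distractors[stats::runif(length(distractors)) <
                            policy$p_inspect_distractor[[dis]]]
    other_t <- setdiff(targets$object, exclude_obj)
    cand_t <- other_t[stats::runif(length(other_t)) < policy$p_inspect_target]
    cand <- c(cand_d, cand_t)
    if (length(cand) > 0) cand <- cand[sample.int(length(cand))]
    for (obj in cand) {
      spec <- if (obj %in% distractors) policy$inspect_dwell_s$distractor[[dis]]
              else policy$inspect_dwell_s$target
      tape$emit("resource_pool", obj, dwell_frames(spec, fps))
      looked <- c(looked, obj)
    }
    looked
  }

  pickup_object <- function(obj, correct) {
    tape$emit("resource_pool", obj, dwell_frames(policy$inspect_dwell_s$target, fps),
              event = "pickup", event_object = obj, event_correct = correct)
    f <- tape$frames_so_far() - 1L
    tv$ac_kind <- c(tv$ac_kind, "pickup"); tv$ac_obj <- c(tv$ac_obj, obj)
    tv$ac_slot <- c(tv$ac_slot, NA_integer_)
    tv$ac_corr <- c(tv$ac_corr, correct); tv$ac_frame <- c(tv$ac_frame, f)
    f
  }

  search_and_pickup <- function() {
    sought <- plan$object[placed + 1L]
    tape$walk_to(geom$resource, speed)
    n_pick_seq <<- n_pick_seq + 1L
    start_f <- tape$frames_so_far()
    looked <- inspect_some(sought)
    p_err <- lookup_prob(policy$p_identity_error, min(n_pick_seq, 2L), dis)
    if (stats::runif(1) < p_err) {
      # identity error: grab a distractor or a replacement duplicate
      already <- plan$object[seq_len(placed)]
      wrong <- if (placed > 0 && stats::runif(1) < 0.3) resample1(already)
               else resample1(distractors)
      f <- pickup_object(wrong, correct = FALSE)
      tv$sr_start <- c(tv$sr_start, start_f); tv$sr_pick <- c(tv$sr_pick, f)
      tv$sr_obj <- c(tv$sr_obj, list(unique(c(looked, wrong))))
      # all other objects disappear until the mistake is resolved; gaze follows
      # the held object, not the pool, so the next search opens afterwards
      tape$emit("other", NA_integer_, dwell_frames(c(0.30, 0.08), fps),
                event = "release_to_pool", event_object = wrong)
      # a fresh search opens for the sought target
      n_pick_seq <<- n_pick_seq + 1L
      start_f <- tape$frames_so_far()
      looked <- inspect_some(sought)
    }
    f <- pickup_object(sought, correct = TRUE)
    tv$sr_start <- c(tv$sr_start, start_f); tv$sr_pick <- c(tv$sr_pick, f)
    tv$sr_obj <- c(tv$sr_obj, list(unique(c(looked, sought))))
    f
  }

  place_object <- function() {
    obj <- plan$object[placed + 1L]
    slot <- plan$slot[placed + 1L]
    tape$walk_to(geom$workspace, speed)
    n_place_seq <<- n_place_seq + 1L
    p_err <- lookup_prob(policy$p_location_error, min(n_place_seq, 2L), dis)
    if (stats::runif(1) < p_err) {
      wrong_slot <- resample1(setdiff(seq_len(N_MODEL_SLOTS), slot))
      tape$emit("workspace", wrong_slot, dwell_frames(policy$place_dwell_s, fps),
                event = "placement_attempt", event_object = obj,
                event_slot = wrong_slot, event_correct = FALSE)
      tv$ac_kind <- c(tv$ac_kind, "placement"); tv$ac_obj <- c(tv$ac_obj, obj)
      tv$ac_slot <- c(tv$ac_slot, wrong_slot)
      tv$ac_corr <- c(tv$ac_corr, FALSE)
      tv$ac_frame <- c(tv$ac_frame, tape$frames_so_far() - 1L)
    }
    tape$emit("workspace", slot, dwell_frames(policy$place_dwell_s, fps),
              event = "placement_attempt", event_object = obj,
              event_slot = slot, event_correct = TRUE)
    f <- tape$frames_so_far() - 1L
    tv$ac_kind <- c(tv$ac_kind, "placement"); tv$ac_obj <- c(tv$ac_obj, obj)
    tv$ac_slot <- c(tv$ac_slot, slot)
    tv$ac_corr <- c(tv$ac_corr, TRUE); tv$ac_frame <- c(tv$ac_frame, f)
    placed <<- placed + 1L
    f
  }

  draw_decision <- function(kind, action_frame) {
    pos <<- pos + 1L
    p <- lookup_prob(policy$p_memory, pos, dis, kind = kind,
                     movement_effort = effort)
    m <- stats::runif(1) < p
    tv$dc_kind <- c(tv$dc_kind, kind); tv$dc_pos <- c(tv$dc_pos, pos)
    tv$dc_mem <- c(tv$dc_mem, m); tv$dc_lock <- c(tv$dc_lock, action_frame + 1L)
    m
  }

  encode_visit(first = TRUE)
  while (placed < 8L && tape$frames_so_far() < limit_frames) {
    f <- search_and_pickup()
    use_mem <- draw_decision("location", f)
    if (!use_mem) encode_visit()
    f <- place_object()
    if (placed >= 8L || tape$frames_so_far() >= limit_frames) break
    use_mem <- draw_decision("identity", f)
    if (!use_mem) encode_visit()
  }

  frames <- tape$expand(limit_frames)
  n <- nrow(frames)
  log <- frame_log(frames, meta, validate = FALSE)

  keep <- tv$enc_start < n
  enc <- tibble::new_tibble(
    list(start_frame = tv$enc_start[keep],
         end_frame = pmin(tv$enc_end[keep], n - 1L),
         slots = tv$enc_slots[keep]),
    nrow = sum(keep)
  )
  keep <- tv$sr_pick < n
  srch <- tibble::new_tibble(
    list(start_frame = tv$sr_start[keep], pickup_frame = tv$sr_pick[keep],
         objects = tv$sr_obj[keep]),
    nrow = sum(keep)
  )
  keep <- tv$dc_lock < n
  dec <- tibble::new_tibble(
    list(kind = tv$dc_kind[keep], position = tv$dc_pos[keep],
         used_memory = tv$dc_mem[keep], locked_frame = tv$dc_lock[keep]),
    nrow = sum(keep)
  )
  keep <- tv$ac_frame < n
  act <- tibble::new_tibble(
    list(kind = tv$ac_kind[keep], object = tv$ac_obj[keep],
         slot = tv$ac_slot[keep], correct = tv$ac_corr[keep],
         frame = tv$ac_frame[keep]),
    nrow = sum(keep)
  )

  n_correct_placed <- sum(act$kind == "placement" & act$correct)
  trial <- tibble::new_tibble(list(
    duration_s = n / fps,
    n_frames = n,
    n_correct_placements = as.integer(n_correct_placed),
    timed_out = n_correct_placed < 8L,
    path_length_m = tape$path_length(limit_frames)
  ), nrow = 1L)

  list(log = log,
       truth = list(encodings = enc, searches = srch, decisions = dec,
                    actions = act, trial = trial))
}

# --- experiment-level simulation ---------------------------------------------

#' Experiment design specification
#'
#' The default design mirrors the study protocol: 2 testing days of 2 sessions,
#' 4 blocks per session (one per condition combination), 14 displays per block
#' split into two 7-display sub-blocks of opposite movement direction --
#' 112 displays per day and 224 per participant, 28 per condition.
#'
#' @param participants Character vector of participant ids.
#' @param days Number of testing days.
#' @param sessions_per_day Sessions per day.
#' @param blocks_per_session Blocks per session; each block takes one of the
#'   four condition combinations.
#' @param displays_per_block Displays per block (split into two sub-blocks).
#' @param timer_limit_s Trial timeout in seconds.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(participants = "p01", days = 2L,
                              sessions_per_day = 2L, blocks_per_session = 4L,
                              displays_per_block = 14L, timer_limit_s = 45) {
  if (days <= 0 || sessions_per_day <= 0 || blocks_per_session <= 0 ||
      displays_per_block <= 0) {
    stop("design counts must be positive", call. = FALSE)
  }
  structure(
    list(participants = as.character(participants), days = as.integer(days),
         sessions_per_day = as.integer(sessions_per_day),
         blocks_per_session = as.integer(blocks_per_session),
         displays_per_block = as.integer(displays_per_block),
         timer_limit_s = timer_limit_s),
    class = "experiment_design"
  )
}

random_layouts <- function(seen) {
  repeat {
    target_objects <- sort(sample.int(N_RESOURCE_OBJECTS, N_TARGETS))
    slots <- sort(sample.int(N_MODEL_SLOTS, N_TARGETS))
    key <- paste(c(target_objects, slots), collapse = ",")
    if (!key %in% seen) break
  }
  resource_layout <- tibble::tibble(
    object = seq_len(N_RESOURCE_OBJECTS),
    is_target = seq_len(N_RESOURCE_OBJECTS) %in% target_objects
  )
  target_layout <- tibble::tibble(
    object = target_objects,
    slot = sample(slots)  # random slot assignment among the chosen slots
  )
  list(target_layout = target_layout, resource_layout = resource_layout,
       key = key)
}

#' Simulate a full experiment
#'
#' Emits one trial per design cell with pseudo-randomised target layouts that
#' never repeat within a participant. Per-trial seeds are derived
#' deterministically from the master seed, so the same seed reproduces the
#' dataset exactly.
#'
#' @param policy An [agent_policy()].
#' @param design An [experiment_design()].
#' @param seed Integer master seed.
#' @return An object of class `copy_task_sim`: a list with `frames` (all
#'   frames, keyed by participant/day/trial), `meta` (trial metadata), and
#'   `truth` (keyed ground-truth tibbles `encodings`, `searches`, `decisions`,
#'   `actions`, `trials`).
#' @export
simulate_experiment <- function(policy, design = experiment_design(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(as.integer(seed))
  combos <- tidyr::expand_grid(distraction = c("high", "low"),
                               movement_effort = c("deg0", "deg90"))

  metas <- list()
  for (p in design$participants) {
    seen <- character(0)
    for (d in seq_len(design$days)) {
      trial_counter <- 0L
      for (s in seq_len(design$sessions_per_day)) {
        block_order <- sample.int(nrow(combos))
        if (design$blocks_per_session != nrow(combos)) {
          block_order <- rep_len(block_order, design$blocks_per_session)
        }
        for (b in seq_len(design$blocks_per_session)) {
          cond <- combos[block_order[b], ]
          half <- design$displays_per_block %/% 2L
          dirs <- sample(c("left", "right"))
          dir_seq <- c(rep(dirs[1], half),
                       rep(dirs[2], design$displays_per_block - half))
          for (t in seq_len(design$displays_per_block)) {
            trial_counter <- trial_counter + 1L
            lay <- random_layouts(seen)
            seen <- c(seen, lay$key)
            metas[[length(metas) + 1L]] <- trial_meta(
              participant_id = p, day = d, session = s, block = b,
              trial_id = trial_counter,
              distraction = cond$distraction,
              movement_effort = cond$movement_effort,
              direction = dir_seq[t], timer_limit_s = design$timer_limit_s,
              target_layout = lay$target_layout,
              resource_layout = lay$resource_layout
            )
          }
        }
      }
    }
  }
  meta <- dplyr::bind_rows(metas)
  simulate_trials(policy, meta, seed = seed)
}

#' Simulate the trials described by a metadata table
#'
#' Runs [simulate_trial()] once per row of `meta`, deriving each trial's seed
#' deterministically from the master seed and the row index, and binds the
#' frame logs and ground truth into one keyed dataset.
#'
#' @param policy An [agent_policy()].
#' @param meta Tibble of [trial_meta()] rows.
#' @param seed Integer master seed.
#' @return A `copy_task_sim` (see [simulate_experiment()]).
#' @export
simulate_trials <- function(policy, meta, seed = 1L) {
  base_seed <- as.integer(seed)
  n <- nrow(meta)
  frames_l <- vector("list", n)
  enc_l <- vector("list", n); srch_l <- vector("list", n)
  dec_l <- vector("list", n); act_l <- vector("list", n)
  tri_l <- vector("list", n)
  for (i in seq_len(n)) {
    m <- meta[i, ]
    trial_seed <- (abs(base_seed) %% 100000L) * 20011L + i * 7L
    out <- simulate_trial(policy, m, seed = trial_seed %% 2147483647L)
    frames_l[[i]] <- with_keys(out$log$frames, m)
    enc_l[[i]] <- with_keys(out$truth$encodings, m)
    srch_l[[i]] <- with_keys(out$truth$searches, m)
    dec_l[[i]] <- with_keys(out$truth$decisions, m)
    act_l[[i]] <- with_keys(out$truth$actions, m)
    tri_l[[i]] <- with_keys(out$truth$trial, m)
  }
  structure(
    list(
      frames = dplyr::bind_rows(frames_l),
      meta = meta,
      truth = list(
        encodings = dplyr::bind_rows(enc_l),
        searches = dplyr::bind_rows(srch_l),
        decisions = dplyr::bind_rows(dec_l),
        actions = dplyr::bind_rows(act_l),
        trials = dplyr::bind_rows(tri_l)
      )
    ),
    class = "copy_task_sim"
  )
}

#' Random trial metadata for simulation studies
#'
#' Builds `n` trials of one condition cell with freshly randomised,
#' non-repeating target/resource layouts and alternating movement directions
#' -- a convenience for parameter-recovery experiments that do not need the
#' full block structure of [experiment_design()].
#'
#' @param n Number of trials.
#' @param distraction,movement_effort Condition of every trial.
#' @param seed Integer seed for the layout randomisation.
#' @param participant_id Participant id assigned to all trials.
#' @param timer_limit_s Trial timeout in seconds.
#' @return A tibble of `n` [trial_meta()] rows.
#' @export
random_trial_meta <- function(n, distraction = "high",
                              movement_effort = "deg90", seed = 1L,
                              participant_id = "p01", timer_limit_s = 45) {
  set.seed(as.integer(seed))
  seen <- character(0)
  out <- vector("list", n)
  dirs <- rep(c("right", "left"), length.out = n)
  for (i in seq_len(n)) {
    lay <- random_layouts(seen)
    seen <- c(seen, lay$key)
    out[[i]] <- trial_meta(
      participant_id = participant_id, day = 1L, session = 1L, block = 1L,
      trial_id = i, distraction = distraction,
      movement_effort = movement_effort, direction = dirs[i],
      timer_limit_s = timer_limit_s, target_layout = lay$target_layout,
      resource_layout = lay$resource_layout
    )
  }
  dplyr::bind_rows(out)
}

#' @export
print.copy_task_sim <- function(x, ...) {
  cat(sprintf(
    "<copy_task_sim> %d trials, %d participants, %d frames; %d timed out\n",
    nrow(x$meta), length(unique(x$meta$participant_id)), nrow(x$frames),
    sum(x$truth$trials$timed_out)
  ))
  invisible(x)
}

# --- scripted fixture logs ---------------------------------------------------

#' Build a frame log from a hand-written gaze/event script
#'
#' Deterministic fixture builder: each script row contributes `n` uniform
#' 1/90 s frames of the given gaze, with an optional interaction event on the
#' last frame. The head stays at the room centre. Intended for constructing
#' exact edge cases (gap lengths, sub-threshold fixations) for the detectors.
#'
#' @param script Tibble (or data frame) with columns `station`, `n`, and
#'   optionally `entity`, `event`, `event_object`, `event_slot`,
#'   `event_correct`.
#' @param meta A [trial_meta()] row.
#' @param validate Validate the resulting log (default `TRUE`).
#' @return A `frame_log`; an empty script gives an empty log.
#' @export
script_log <- function(script, meta = trial_meta(), validate = TRUE) {
  script <- tibble::as_tibble(script)
  if (nrow(script) == 0) {
    return(frame_log(empty_frames(), meta, validate = FALSE))
  }
  if (!all(c("station", "n") %in% names(script))) {
    stop("script needs at least `station` and `n` columns", call. = FALSE)
  }
  for (col in c("entity", "event_object", "event_slot")) {
    if (is.null(script[[col]])) script[[col]] <- NA_integer_
  }
  if (is.null(script$event)) script$event <- NA_character_
  if (is.null(script$event_correct)) script$event_correct <- NA
  if (any(!script$station %in% GAZE_STATIONS)) {
    stop("unknown station in script: ",
         paste(unique(setdiff(script$station, GAZE_STATIONS)), collapse = ", "),
         call. = FALSE)
  }
  max_ent <- c(model = N_MODEL_SLOTS, resource_pool = N_RESOURCE_OBJECTS,
               workspace = N_MODEL_SLOTS)
  bad <- !is.na(script$entity) &
    (!script$station %in% names(max_ent) |
       script$entity < 1 | script$entity > max_ent[script$station])
  if (any(bad)) stop("script references an unknown entity", call. = FALSE)

  fps <- 90
  tape <- new_tape(fps, start_pos = c(0, 1.6, 0))
  for (i in seq_len(nrow(script))) {
    tape$emit(script$station[i], script$entity[i], script$n[i],
              event = if (is.na(script$event[i])) NA_character_ else script$event[i],
              event_object = script$event_object[i],
              event_slot = script$event_slot[i],
              event_correct = script$event_correct[i])
  }
  frame_log(tape$expand(), meta, validate = validate)
}

# convenience for tests and examples: script rows from compact vectors
script_row <- function(station, n, entity = NA, event = NA,
                       event_object = NA, event_slot = NA, event_correct = NA) {
  tibble::tibble(station = station, n = as.integer(n),
                 entity = as.integer(entity), event = as.character(event),
                 event_object = as.integer(event_object),
                 event_slot = as.integer(event_slot),
                 event_correct = event_correct)
}
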