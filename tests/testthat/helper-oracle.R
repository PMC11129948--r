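# Independent per-frame reference implementations of the period detectors.
# Deliberately naive (frame-by-frame state machines, O(n^2) allowed): these
# serve as the oracle the vectorised detectors are checked against.

oracle_encoding <- function(frames, occupied_slots) {
  st <- frames$gaze_station
  dur <- frames$duration_s
  ent <- frames$gaze_entity
  n <- length(st)
  starts <- integer(0); ends <- integer(0)

  i <- 1L
  while (i <= n) {
    if (st[i] != "model") { i <- i + 1L; next }
    start <- i
    end <- i
    j <- i + 1L
    while (j <= n) {
      if (st[j] == "model") { end <- j; j <- j + 1L; next }
      # off-model run: find where model gaze resumes
      k <- j
      while (k <= n && st[k] != "model") k <- k + 1L
      if (k > n) break
      gap_len <- k - j
      station_in_gap <- FALSE
      for (t in j:(k - 1L)) {
        if (st[t] %in% c("resource_pool", "workspace")) station_in_gap <- TRUE
      }
      if (gap_len >= 25L && station_in_gap) break
      end <- k
      j <- k + 1L
    }
    starts <- c(starts, start); ends <- c(ends, end)
    i <- end + 1L
    while (i <= n && st[i] != "model") i <- i + 1L
  }

  np <- length(starts)
  res <- vector("list", np)
  for (p in seq_len(np)) {
    viewing <- 0
    for (t in starts[p]:ends[p]) viewing <- viewing + dur[t]
    # distinct occupied slots fixated >= 2 consecutive frames
    seen <- integer(0)
    run_ent <- NA_integer_; run_len <- 0L
    for (t in starts[p]:ends[p]) {
      cur <- if (st[t] == "model" && !is.na(ent[t])) ent[t] else NA_integer_
      if (!is.na(cur) && !is.na(run_ent) && cur == run_ent) {
        run_len <- run_len + 1L
      } else {
        run_ent <- cur; run_len <- if (is.na(cur)) 0L else 1L
      }
      if (!is.na(cur) && run_len >= 2L && cur %in% occupied_slots) {
        seen <- union(seen, cur)
      }
    }
    upto <- if (p < np) starts[p + 1L] - 1L else n
    followed <- FALSE
    if (ends[p] < upto) {
      for (t in (ends[p] + 1L):upto) {
        if (st[t] %in% c("resource_pool", "workspace")) followed <- TRUE
      }
    }
    res[[p]] <- data.frame(
      ordinal = p, start_frame = starts[p] - 1L, end_frame = ends[p] - 1L,
      model_viewing_time_s = viewing, n_targets_encoded = length(seen),
      followed_by_station = followed, first_in_display = p == 1L
    )
  }
  if (np == 0) {
    return(data.frame(ordinal = integer(), start_frame = integer(),
                      end_frame = integer(), model_viewing_time_s = double(),
                      n_targets_encoded = integer(),
                      followed_by_station = logical(),
                      first_in_display = logical()))
  }
  do.call(rbind, res)
}

oracle_search <- function(frames, enc, layout) {
  st <- frames$gaze_station
  dur <- frames$duration_s
  ent <- frames$gaze_entity
  ev <- frames$event
  n <- length(st)
  in_enc <- rep(FALSE, n)
  enc_start_at <- rep(FALSE, n)
  if (nrow(enc) > 0) {
    for (p in seq_len(nrow(enc))) {
      in_enc[(enc$start_frame[p] + 1L):(enc$end_frame[p] + 1L)] <- TRUE
      enc_start_at[enc$start_frame[p] + 1L] <- TRUE
    }
  }

  out <- list()
  anchor <- 1L
  while (anchor <= n) {
    f <- NA_integer_
    for (t in anchor:n) {
      if (st[t] == "resource_pool" && !in_enc[t]) { f <- t; break }
    }
    if (is.na(f)) break
    close_t <- NA_integer_; no_pickup <- FALSE; next_anchor <- NA_integer_
    for (t in f:n) {
      if (ev[t] == "pickup") { close_t <- t; next_anchor <- t + 1L; break }
      if (enc_start_at[t] && t > f) {
        close_t <- t - 1L; no_pickup <- TRUE
        p <- which(enc$start_frame + 1L == t)[1]
        next_anchor <- enc$end_frame[p] + 2L
        break
      }
    }
    if (is.na(close_t)) { close_t <- n; no_pickup <- TRUE; next_anchor <- n + 1L }

    stime <- 0
    for (t in f:close_t) stime <- stime + dur[t]
    # per-object qualifying spans
    times <- numeric(0); objs <- integer(0)
    run_obj <- NA_integer_; run_len <- 0L; run_time <- 0
    flush <- function() {
      if (!is.na(run_obj) && run_len >= 2L) {
        k <- match(run_obj, objs)
        if (is.na(k)) { objs <<- c(objs, run_obj); times <<- c(times, run_time) }
        else times[k] <<- times[k] + run_time
      }
    }
    for (t in f:close_t) {
      cur <- if (st[t] == "resource_pool" && !is.na(ent[t])) ent[t] else NA_integer_
      if (!is.na(cur) && !is.na(run_obj) && cur == run_obj) {
        run_len <- run_len + 1L; run_time <- run_time + dur[t]
      } else {
        flush()
        run_obj <- cur; run_len <- if (is.na(cur)) 0L else 1L
        run_time <- if (is.na(cur)) 0 else dur[t]
      }
    }
    flush()
    ord <- order(objs)
    objs <- objs[ord]; times <- times[ord]
    is_tgt <- layout$is_target[match(objs, layout$object)]
    pickup_frame <- if (no_pickup) NA_integer_ else close_t - 1L
    picked <- if (no_pickup) NA_integer_ else frames$event_object[close_t]
    correct <- if (no_pickup) NA else frames$event_correct[close_t]
    if (!no_pickup && is.na(correct)) {
      correct <- isTRUE(layout$is_target[match(picked, layout$object)])
    }
    out[[length(out) + 1L]] <- list(
      start_frame = f - 1L, pickup_frame = pickup_frame,
      search_time_s = stime, picked_object = picked, pickup_correct = correct,
      n_targets_viewed = sum(is_tgt, na.rm = TRUE),
      n_distractors_viewed = sum(!is_tgt, na.rm = TRUE),
      objects = objs, viewing_times = times, no_pickup = no_pickup
    )
    anchor <- next_anchor
  }
  out
}

# analytic distribution of attributes per completed search-first sequence:
# 1 attribute for the opening pickup, then survival through alternating
# location/identity memory decisions
oracle_attr_dist <- function(p_mem_tbl, distraction, movement_effort,
                             kmax = 12L) {
  p_at <- function(kind, pos) {
    sub <- p_mem_tbl[p_mem_tbl$kind == kind &
                       p_mem_tbl$distraction == distraction &
                       p_mem_tbl$movement_effort == movement_effort, ]
    pos <- min(pos, max(sub$position))
    sub$p[match(pos, sub$position)]
  }
  probs <- numeric(kmax)
  surv <- 1
  for (k in seq_len(kmax)) {
    # after the k-th attribute the decision at position k decides continuation
    kind <- if (k %% 2L == 1L) "location" else "identity"
    p_cont <- p_at(kind, k)
    probs[k] <- surv * (1 - p_cont)
    surv <- surv * p_cont
  }
  probs / sum(probs)
}
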