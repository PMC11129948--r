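# Sensorimnemonic decision extraction, inclusion filters, memory-probability
# tables, and position-indexed errors.

# full trial scaffold: orientation period, then scripted behaviour, then a
# closing encoding so the last sequence is bounded
dec_script <- function(...) {
  dplyr::bind_rows(
    script_row("model", 40),
    script_row("resource_pool", 30, entity = 1),
    script_row("model", 30),
    ...,
    script_row("model", 30),
    script_row("resource_pool", 30, entity = 2)
  )
}

pickup_seg <- function(obj, n = 30, correct = TRUE) {
  script_row("resource_pool", n, entity = obj, event = "pickup",
             event_object = obj, event_correct = correct)
}
place_seg <- function(obj, slot, n = 30, correct = TRUE) {
  script_row("workspace", n, entity = slot, event = "placement_attempt",
             event_object = obj, event_slot = slot, event_correct = correct)
}

analyze_script <- function(...) {
  suppressWarnings(analyze_copy_task(script_log(dec_script(...))))
}

test_that("memory versus sampling is read off the intervening model gaze", {
  # place directly after pickup: location decision relies on memory
  an <- analyze_script(pickup_seg(1), place_seg(1, 2))
  d <- an$decisions
  expect_identical(d$kind, c("location_related", "identity_related"))
  expect_identical(d$position, 1:2)
  expect_identical(d$used_memory, c(TRUE, FALSE))
  expect_true(d$included[1])
  # the identity decision is followed by the closing encoding, not an action
  expect_true(d$included[2])

  # model re-fixation between pickup and placement: no memory used, and the
  # re-fixation ends the sequence, so the placement opens a new one
  an2 <- analyze_script(pickup_seg(1), script_row("model", 30),
                        place_seg(1, 2))
  d2 <- an2$decisions
  expect_identical(d2$used_memory[1], FALSE)
  expect_identical(d2$position, c(1L, 1L))
  expect_identical(d2$seq_ordinal, 1:2)
})

test_that("memory decisions followed by a mistake are excluded", {
  an <- analyze_script(pickup_seg(1), place_seg(1, 5, correct = FALSE),
                       place_seg(1, 2))
  d <- an$decisions
  expect_identical(d$exclusion_reason[1], "memory_then_error")
  # the decision after the corrected placement sits in a disrupted run-up
  expect_identical(d$exclusion_reason[2], "disrupted")
})

test_that("error run-ups mark later decisions as disrupted", {
  # the error happens after a clean opening search, so the search filter
  # passes and the disruption rule is what fires
  an <- analyze_script(
    pickup_seg(1), place_seg(1, 2),
    pickup_seg(9, correct = FALSE),
    script_row("other", 20, event = "release_to_pool", event_object = 9),
    pickup_seg(2), place_seg(2, 4)
  )
  d <- an$decisions
  # the identity decision before the bad pickup was a memory decision that
  # ended in a mistake; everything after the error is disrupted
  expect_identical(d$exclusion_reason,
                   c("none", "memory_then_error", "disrupted", "disrupted"))
  # positions index correct actions only
  expect_identical(d$position, 1:4)
})

test_that("placement-first sequences are extracted but excluded", {
  # location decision not from memory: the placement lands after the next
  # encoding, opening a placement-first sequence
  an <- analyze_script(
    pickup_seg(1), script_row("model", 30), place_seg(1, 2),
    script_row("resource_pool", 5, entity = 3),
    pickup_seg(2), place_seg(2, 4)
  )
  d <- an$decisions
  expect_identical(d$kind[1], "location_related")
  expect_false(d$used_memory[1])
  seq2 <- d[d$seq_ordinal == 2, ]
  expect_identical(seq2$kind[1], "identity_related")
  expect_identical(seq2$position[1], 1L)
  expect_identical(unique(seq2$exclusion_reason), "non_search_first_sequence")
})

test_that("decisions need a matchable included search", {
  # make the opening search end in a pickup error: its sequence's decisions
  # are excluded via the search filter chain
  an <- analyze_script(
    pickup_seg(9, correct = FALSE),
    script_row("other", 20, event = "release_to_pool", event_object = 9),
    pickup_seg(1), place_seg(1, 2)
  )
  # force the stronger check: first action's search must be included
  dec <- extract_decisions(an$sequences, an$searches, an$actions,
                           script_log(dec_script(
                             pickup_seg(9, correct = FALSE),
                             script_row("other", 20, event = "release_to_pool",
                                        event_object = 9),
                             pickup_seg(1), place_seg(1, 2)
                           )))
  expect_true(all(!dec$included))
})

test_that("p_memory_table partitions included decisions into cells", {
  pol <- error_free_policy()
  meta <- dplyr::bind_rows(
    random_trial_meta(6, "high", "deg90", seed = 1),
    random_trial_meta(6, "low", "deg90", seed = 2) |>
      dplyr::mutate(trial_id = trial_id + 6L)
  )
  sim <- simulate_trials(pol, meta, seed = 3)
  an <- analyze_copy_task(sim)
  tbl <- p_memory_table(an$decisions, sim$meta, positions = 1:6,
                        all_effort_up_to = Inf)
  expect_true(all(tbl$p_memory >= 0 & tbl$p_memory <= 1))
  expect_identical(sum(tbl$n_decisions), sum(an$decisions$included))

  # degenerate: memory certain at positions 1-2, never used at position 3
  det <- default_p_memory()
  det$p <- ifelse(det$position <= 2, 1, 0)
  sim2 <- simulate_trials(error_free_policy(p_memory = det),
                          random_trial_meta(4, "high", "deg90", seed = 7),
                          seed = 5)
  an2 <- analyze_copy_task(sim2)
  tbl2 <- p_memory_table(an2$decisions, sim2$meta, positions = 1:3,
                         all_effort_up_to = Inf)
  expect_true(all(tbl2$p_memory[tbl2$position <= 2] == 1))
  expect_true(all(tbl2$p_memory[tbl2$position == 3] == 0))
  expect_identical(sort(unique(an2$sequences$attributes_used[
    an2$sequences$qualifies & an2$sequences$sequence_type == "search_first"])),
    3L)
})

test_that("re-running extraction on its own output changes nothing", {
  sim <- simulate_experiment(
    agent_policy(), experiment_design(days = 1, sessions_per_day = 1,
                                      displays_per_block = 2), seed = 41
  )
  an <- analyze_copy_task(sim)
  again <- extract_decisions(an$sequences, an$searches, an$actions,
                             sim$frames, sim$meta)
  expect_equal(again, an$decisions)
})

test_that("non-memory decisions imply a model fixation before the next action", {
  sim <- simulate_experiment(
    agent_policy(), experiment_design(days = 1, sessions_per_day = 1,
                                      displays_per_block = 2), seed = 43
  )
  an <- analyze_copy_task(sim)
  d <- an$decisions[an$decisions$included & !an$decisions$used_memory, ]
  frames <- sim$frames
  for (i in seq_len(nrow(d))) {
    f <- frames[frames$participant_id == d$participant_id[i] &
                  frames$day == d$day[i] & frames$trial_id == d$trial_id[i], ]
    nxt <- f$frame_index[f$event %in% c("pickup", "placement_attempt") &
                           f$frame_index >= d$locked_frame[i]]
    upto <- if (length(nxt) > 0) nxt[1] else nrow(f)
    window <- f$gaze_station[(d$locked_frame[i] + 1):upto]
    expect_true(any(window == "model"))
  }
})

test_that("errors truncate sequences and index by position slot", {
  # identity error on the first pickup: one record, nothing after
  an <- analyze_script(
    pickup_seg(9, correct = FALSE),
    script_row("other", 20, event = "release_to_pool", event_object = 9),
    pickup_seg(1), place_seg(1, 2)
  )
  e <- an$errors
  expect_identical(nrow(e), 1L)
  expect_identical(e$kind, "identity")
  expect_identical(e$position_slot, "first_pickup")
  expect_true(e$occurred)

  # error-free two-object memory sequence: four opportunities, none occurred
  an2 <- analyze_script(pickup_seg(1), place_seg(1, 2),
                        pickup_seg(2), place_seg(2, 4))
  e2 <- an2$errors
  expect_identical(nrow(e2), 4L)
  expect_identical(e2$position_slot,
                   c("first_pickup", "first_placement",
                     "second_pickup", "second_placement"))
  expect_true(all(!e2$occurred))

  # location error on the first placement truncates the rest
  an3 <- analyze_script(pickup_seg(1), place_seg(1, 5, correct = FALSE),
                        place_seg(1, 2), pickup_seg(2), place_seg(2, 4))
  e3 <- an3$errors
  expect_identical(e3$position_slot, c("first_pickup", "first_placement"))
  expect_identical(e3$occurred, c(FALSE, TRUE))
})

test_that("error rates are exact opportunity ratios", {
  an <- analyze_script(pickup_seg(1), place_seg(1, 2),
                       pickup_seg(2), place_seg(2, 4))
  tbl <- error_rate_table(an$errors, an$meta)
  expect_true(all(tbl$error_rate_pct == 0))
  expect_identical(tbl$n_opportunities, rep(1L, 4))
  expect_true(all(tbl$error_rate_pct ==
                    100 * tbl$n_errors / tbl$n_opportunities))
})
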