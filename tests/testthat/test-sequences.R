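# Action extraction, sequence construction, and the WM-usage metric.

# script with three encoding periods; the middle pair bounds one sequence
two_enc_script <- function(between) {
  dplyr::bind_rows(
    script_row("model", 40),                       # first period (excluded)
    script_row("resource_pool", 30, entity = 1),
    script_row("model", 30),                       # sequence start
    between,
    script_row("model", 30),                       # sequence end
    script_row("resource_pool", 30, entity = 2)
  )
}

test_that("a minimal one-object memory sequence uses two attributes", {
  between <- dplyr::bind_rows(
    script_row("resource_pool", 30, entity = 1, event = "pickup",
               event_object = 1, event_correct = TRUE),
    script_row("workspace", 30, entity = 2, event = "placement_attempt",
               event_object = 1, event_slot = 2, event_correct = TRUE)
  )
  an <- suppressWarnings(analyze_copy_task(script_log(two_enc_script(between))))
  sq <- an$sequences[an$sequences$qualifies & an$sequences$closed, ]
  expect_identical(nrow(sq), 1L)
  expect_identical(sq$attributes_used, 2L)
  expect_identical(sq$sequence_type, "search_first")
})

test_that("back-to-back encodings with no station gaze do not qualify", {
  log <- script_log(dplyr::bind_rows(
    script_row("model", 40), script_row("resource_pool", 30, entity = 1),
    script_row("model", 30),
    script_row("none", 40),    # long gap, but never a station
    script_row("other", 40),
    script_row("model", 30), script_row("resource_pool", 30, entity = 2)
  ))
  an <- suppressWarnings(analyze_copy_task(log))
  # the none/other gap is bridged, so both model spans form one period; with
  # an explicit station-free boundary the sequence must not qualify
  enc <- tibble::tibble(
    ordinal = 1:2, start_frame = c(40L, 140L), end_frame = c(69L, 169L),
    included = TRUE
  )
  sq <- seq_build_one(enc, an$actions, log$frames)
  expect_identical(nrow(sq[sq$closed, ]), 1L)
  expect_false(sq$qualifies[sq$closed])
})

test_that("incorrect actions are recorded but contribute no attributes", {
  between <- dplyr::bind_rows(
    script_row("resource_pool", 30, entity = 1, event = "pickup",
               event_object = 1, event_correct = TRUE),
    script_row("workspace", 20, entity = 5, event = "placement_attempt",
               event_object = 1, event_slot = 5, event_correct = FALSE),
    script_row("workspace", 20, entity = 2, event = "placement_attempt",
               event_object = 1, event_slot = 2, event_correct = TRUE)
  )
  log <- script_log(two_enc_script(between))
  act <- extract_actions(log)
  expect_identical(act$kind, c("pickup", "placement", "placement"))
  expect_identical(act$correct, c(TRUE, FALSE, TRUE))
  an <- suppressWarnings(analyze_copy_task(log))
  sq <- an$sequences[an$sequences$qualifies & an$sequences$closed, ]
  expect_identical(sq$attributes_used, 2L)  # failed attempt adds nothing
  expect_identical(sq$n_actions, 3L)
})

test_that("release events close erroneous pickups without an action record", {
  between <- dplyr::bind_rows(
    script_row("resource_pool", 20, entity = 9, event = "pickup",
               event_object = 9, event_correct = FALSE),
    script_row("other", 20, event = "release_to_pool", event_object = 9),
    script_row("resource_pool", 20, entity = 1, event = "pickup",
               event_object = 1, event_correct = TRUE),
    script_row("workspace", 20, entity = 2, event = "placement_attempt",
               event_object = 1, event_slot = 2, event_correct = TRUE)
  )
  act <- extract_actions(script_log(two_enc_script(between)))
  expect_identical(nrow(act), 3L)  # release creates no record
  expect_identical(sum(act$kind == "pickup"), 2L)
})

test_that("pickup correctness falls back to the resource layout", {
  between <- dplyr::bind_rows(
    script_row("resource_pool", 20, entity = 9, event = "pickup",
               event_object = 9),  # object 9 is a distractor, no flag recorded
    script_row("other", 20, event = "release_to_pool", event_object = 9)
  )
  act <- extract_actions(script_log(two_enc_script(between)))
  expect_false(act$correct[1])
})

test_that("a placement with no preceding pickup is a validation error", {
  f <- script_log(script_row("workspace", 5, entity = 1))$frames
  f$event[4] <- "placement_attempt"
  f$event_object[4] <- 1L; f$event_slot[4] <- 1L; f$event_correct[4] <- TRUE
  f$held_object[3:4] <- 1L  # fake holding so the log itself validates
  log <- frame_log(f, trial_meta(), validate = FALSE)
  expect_error(extract_actions(log), "no preceding pickup")
})

test_that("sequence attributes are conserved against the action stream", {
  sim <- simulate_experiment(
    agent_policy(), experiment_design(days = 1, sessions_per_day = 1,
                                      displays_per_block = 3), seed = 17
  )
  an <- analyze_copy_task(sim)
  for (key in unique(paste(an$trials$participant_id, an$trials$day,
                           an$trials$trial_id))) {
    parts <- strsplit(key, " ")[[1]]
    sq <- an$sequences[an$sequences$participant_id == parts[1] &
                         an$sequences$day == parts[2] &
                         an$sequences$trial_id == parts[3] &
                         an$sequences$closed, ]
    act <- an$actions[an$actions$participant_id == parts[1] &
                        an$actions$day == parts[2] &
                        an$actions$trial_id == parts[3], ]
    if (nrow(sq) == 0) next
    lo <- min(sq$start_frame); hi <- max(sq$end_frame)
    expected <- sum(act$correct & act$frame > lo & act$frame < hi)
    expect_identical(sum(sq$attributes_used), as.integer(expected))
  }
})

test_that("wm_usage_summary gives per-cell distributions that sum to one", {
  sim <- simulate_experiment(
    agent_policy(), experiment_design(days = 1, sessions_per_day = 1,
                                      displays_per_block = 3), seed = 23
  )
  an <- analyze_copy_task(sim)
  wm <- wm_usage_summary(an$sequences, sim$meta)
  sums <- dplyr::summarise(wm, s = sum(p_attributes),
                           .by = c(participant_id, distraction,
                                   movement_effort))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(wm$mean_attributes >= 1))

  # degenerate: every sequence one attribute
  out <- simulate_trial(no_memory_policy(),
                        trial_meta(movement_effort = "deg0"), seed = 2)
  an1 <- analyze_copy_task(out$log)
  wm1 <- wm_usage_summary(an1$sequences, out$log$meta)
  expect_true(all(wm1$mean_attributes == 1))
  expect_identical(wm1$p_attributes[wm1$attributes == 1], 1)
})

test_that("attribute distribution matches the Markov-chain oracle", {
  # error-free agent; only the first three sequences per trial enter, since
  # the sequence in progress at trial end is censored (see methods vignette)
  pol <- error_free_policy()
  meta <- random_trial_meta(220, distraction = "low",
                            movement_effort = "deg90", seed = 5)
  res <- run_chunked(pol, meta, seed = 29)
  sq <- res$sequences[res$sequences$qualifies & res$sequences$closed &
                        res$sequences$sequence_type == "search_first" &
                        res$sequences$seq_ordinal <= 3, ]
  ana <- oracle_attr_dist(default_p_memory(), "low", "deg90")
  n <- nrow(sq)
  expect_gt(n, 300)
  for (k in 1:4) {
    p_hat <- mean(sq$attributes_used == k)
    expect_true(within_3se(p_hat, ana[k], n),
                info = paste("attribute count", k))
  }
})
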