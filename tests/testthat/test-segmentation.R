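# Encoding/search detection: gap bridging and splitting, the 2-consecutive-
# frame object rule, and the sequential exclusion filters.

enc_of <- function(script) {
  detect_encoding_periods(script_log(dplyr::bind_rows(script)))
}

test_that("sub-25-frame gaps are bridged into one encoding period", {
  enc <- enc_of(list(
    script_row("model", 30), script_row("none", 24),
    script_row("model", 30), script_row("resource_pool", 10, entity = 3)
  ))
  expect_identical(nrow(enc), 1L)
  expect_identical(enc$start_frame, 0L)
  expect_identical(enc$end_frame, 83L)
  expect_equal(enc$model_viewing_time_s, 84 / 90, tolerance = 1e-12)

  # a 24-frame *station* gap is still bridged (both tests must hold to split)
  enc2 <- enc_of(list(
    script_row("model", 30), script_row("resource_pool", 24, entity = 5),
    script_row("model", 30), script_row("workspace", 10)
  ))
  expect_identical(nrow(enc2), 1L)
  expect_identical(enc2$end_frame, 83L)
})

test_that("a >= 25-frame gap with a station visit splits encoding periods", {
  enc <- enc_of(list(
    script_row("model", 30), script_row("resource_pool", 26, entity = 5),
    script_row("model", 30), script_row("resource_pool", 10, entity = 2,
                                        event = "pickup", event_object = 2,
                                        event_correct = TRUE)
  ))
  expect_identical(nrow(enc), 2L)
  expect_identical(enc$start_frame, c(0L, 56L))
  expect_identical(enc$end_frame, c(29L, 85L))
  expect_equal(enc$model_viewing_time_s, c(30, 30) / 90, tolerance = 1e-12)

  # a long gap with no station gaze never splits
  enc2 <- enc_of(list(
    script_row("model", 30), script_row("none", 60), script_row("model", 30),
    script_row("workspace", 10)
  ))
  expect_identical(nrow(enc2), 1L)
  expect_identical(enc2$end_frame, 119L)
})

test_that("encoded targets need >= 2 consecutive frames on an occupied slot", {
  # default layout occupies slots 2,4,...,16; slot 3 is empty
  enc <- enc_of(list(
    script_row("model", 3, entity = 2), script_row("model", 3, entity = 4),
    script_row("model", 1, entity = 6), script_row("model", 5, entity = 3),
    script_row("resource_pool", 30, entity = 1)
  ))
  expect_identical(nrow(enc), 1L)
  expect_identical(enc$n_targets_encoded, 2L)  # slot 6: 1 frame; slot 3: empty

  # an interrupted dwell does not accumulate across the interruption
  enc2 <- enc_of(list(
    script_row("model", 1, entity = 2), script_row("model", 1, entity = 4),
    script_row("model", 1, entity = 2), script_row("resource_pool", 30)
  ))
  expect_identical(enc2$n_targets_encoded, 0L)
})

test_that("encoding exclusions apply sequentially with recorded reasons", {
  # period 2 below 50 ms, period 4 not followed by a station
  log <- script_log(dplyr::bind_rows(
    script_row("model", 30), script_row("resource_pool", 30, entity = 1),
    script_row("model", 4), script_row("workspace", 30),
    script_row("model", 30), script_row("resource_pool", 30, entity = 2),
    script_row("model", 30), script_row("none", 30)
  ))
  enc <- suppressWarnings(apply_encoding_exclusions(detect_encoding_periods(log)))
  expect_identical(enc$exclusion_reason,
                   c("first_in_display", "below_50ms", "none",
                     "not_followed_by_station"))
  expect_identical(enc$included, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("the 3.5 SD filter removes outliers on surviving raw seconds", {
  times <- c(rep(0.5, 99), 10)
  periods <- tibble::tibble(
    participant_id = "p01", day = 1L, trial_id = seq_along(times),
    ordinal = 2L, start_frame = 100L, end_frame = 150L,
    model_viewing_time_s = times, n_targets_encoded = 1L,
    followed_by_station = TRUE, first_in_display = FALSE
  )
  out <- apply_encoding_exclusions(periods)
  expect_true(10 > mean(times) + 3.5 * sd(times))  # the constructed premise
  expect_identical(out$exclusion_reason[100], "above_3p5_sd")
  expect_identical(sum(out$included), 99L)

  # the threshold uses survivors only: a <50 ms period is not in the pool
  times2 <- c(rep(0.5, 99), 10, 0.01)
  periods2 <- periods[c(seq_along(times), 1), ]
  periods2$trial_id <- seq_along(times2)
  periods2$model_viewing_time_s <- times2
  out2 <- apply_encoding_exclusions(periods2)
  expect_identical(out2$exclusion_reason[101], "below_50ms")
  expect_identical(out2$exclusion_reason[100], "above_3p5_sd")

  # degenerate: identical values, SD = 0, nothing excluded
  periods3 <- periods
  periods3$model_viewing_time_s <- rep(0.5, 100)
  expect_identical(sum(apply_encoding_exclusions(periods3)$included), 100L)

  # fewer than 2 survivors: filter skipped with a warning
  expect_warning(apply_encoding_exclusions(periods[1, ]), "SD filter skipped")
})

test_that("a trial whose only period is its first has zero included periods", {
  log <- script_log(dplyr::bind_rows(
    script_row("model", 40), script_row("resource_pool", 40, entity = 1)
  ))
  enc <- suppressWarnings(apply_encoding_exclusions(detect_encoding_periods(log)))
  expect_identical(nrow(enc), 1L)
  expect_identical(sum(enc$included), 0L)
  expect_identical(enc$exclusion_reason, "first_in_display")
})

test_that("search periods span first resource gaze to pickup, counting objects", {
  log <- script_log(dplyr::bind_rows(
    script_row("model", 30),
    script_row("resource_pool", 5, entity = 3),
    script_row("resource_pool", 1, entity = 7),
    script_row("resource_pool", 4, entity = 5, event = "pickup",
               event_object = 5, event_correct = TRUE)
  ))
  srch <- detect_search_periods(log)
  expect_identical(nrow(srch), 1L)
  expect_identical(srch$start_frame, 30L)
  expect_identical(srch$pickup_frame, 39L)
  expect_equal(srch$search_time_s, 10 / 90, tolerance = 1e-12)
  expect_identical(sort(srch$object_viewing_times[[1]]$object), c(3L, 5L))
  expect_equal(srch$object_viewing_times[[1]]$viewing_time_s[
    srch$object_viewing_times[[1]]$object == 3], 5 / 90, tolerance = 1e-12)
  # objects 3 and 5 are targets in the default layout
  expect_identical(srch$n_targets_viewed, 2L)
  expect_identical(srch$n_distractors_viewed, 0L)
})

test_that("an encoding period discards the open search as no_pickup", {
  log <- script_log(dplyr::bind_rows(
    script_row("model", 30),
    script_row("resource_pool", 30, entity = 9),
    script_row("model", 30),
    script_row("resource_pool", 10, entity = 2, event = "pickup",
               event_object = 2, event_correct = TRUE)
  ))
  srch <- suppressWarnings(apply_search_exclusions(detect_search_periods(log)))
  expect_identical(nrow(srch), 2L)
  expect_identical(srch$no_pickup, c(TRUE, FALSE))
  expect_identical(srch$exclusion_reason, c("no_pickup", "none"))
  expect_identical(srch$start_frame, c(30L, 90L))
})

test_that("search exclusions: 50 ms, pickup error, and 3.5 SD", {
  log <- script_log(dplyr::bind_rows(
    script_row("model", 30),
    script_row("resource_pool", 3, entity = 2, event = "pickup",
               event_object = 2, event_correct = TRUE),
    script_row("workspace", 30, entity = 4, event = "placement_attempt",
               event_object = 2, event_slot = 4, event_correct = TRUE),
    script_row("resource_pool", 30, entity = 9, event = "pickup",
               event_object = 9, event_correct = FALSE)
  ))
  srch <- suppressWarnings(apply_search_exclusions(detect_search_periods(log)))
  expect_identical(srch$exclusion_reason,
                   c("below_50ms", "ended_in_pickup_error"))

  durs <- c(rep(1, 50), 20)
  searches <- tibble::tibble(
    participant_id = "p01", day = 1L, trial_id = seq_along(durs),
    ordinal = 1L, start_frame = 0L, pickup_frame = 100L,
    search_time_s = durs, picked_object = 2L, pickup_correct = TRUE,
    n_targets_viewed = 1L, n_distractors_viewed = 0L,
    object_viewing_times = rep(list(tibble::tibble()), length(durs)),
    no_pickup = FALSE
  )
  out <- apply_search_exclusions(searches)
  expect_identical(out$exclusion_reason[51], "above_3p5_sd")
  expect_identical(sum(out$included), 50L)

  # identical durations: degenerate SD excludes nothing
  searches$search_time_s <- rep(1, length(durs))
  expect_identical(sum(apply_search_exclusions(searches)$included), 51L)
})

test_that("empty logs yield empty period tables", {
  log <- script_log(empty_frames()[, 0])
  expect_identical(nrow(detect_encoding_periods(log)), 0L)
  expect_identical(nrow(detect_search_periods(log)), 0L)
})
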