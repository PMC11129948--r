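# End-to-end convenience wrapper: frames + metadata in, every derived table
# out.

#' Run the full decomposition pipeline
#'
#' Detects encoding and search periods, applies the inclusion filters,
#' extracts actions, builds working-memory usage sequences, extracts
#' sensorimnemonic decisions and position-indexed errors, and summarises each
#' trial. The result bundles every table so downstream summaries
#' ([wm_usage_summary()], [p_memory_table()], [error_rate_table()],
#' [condition_summary()]) can be computed directly.
#'
#' @param x A `copy_task_sim`, a `frame_log`, or a keyed frames tibble.
#' @param meta Trial metadata tibble (taken from `x` when it is a
#'   `copy_task_sim`).
#' @return An object of class `copy_task_analysis`: a list of tibbles
#'   `encodings`, `searches`, `actions`, `sequences`, `decisions`, `errors`,
#'   `trials`, plus the `meta` used.
#' @export
analyze_copy_task <- function(x, meta = NULL) {
  if (inherits(x, "copy_task_sim")) {
    meta <- x$meta
    frames <- x$frames
  } else if (inherits(x, "frame_log")) {
    meta <- x$meta
    frames <- x
  } else {
    frames <- x
    if (is.null(meta)) stop("meta is required for frames-tibble input",
                            call. = FALSE)
  }

  groups <- trial_groups(frames, meta)
  ng <- length(groups)

  # pass 1: per-trial detection (exclusion filters need all trials at once)
  enc_l <- vector("list", ng); srch_l <- vector("list", ng)
  act_l <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- groups[[i]]
    enc_l[[i]] <- enc_detect_one(g$frames, g$meta)
    srch_l[[i]] <- search_detect_one(g$frames, g$meta, enc_l[[i]])
    act_l[[i]] <- act_extract_one(g$frames, g$meta)
  }
  enc <- apply_encoding_exclusions(
    dplyr::bind_rows(lapply(seq_len(ng), function(i) {
      with_keys(enc_l[[i]], groups[[i]]$meta)
    }))
  )
  srch <- apply_search_exclusions(
    dplyr::bind_rows(lapply(seq_len(ng), function(i) {
      with_keys(srch_l[[i]], groups[[i]]$meta)
    }))
  )

  # pass 2: sequences, decisions, errors, trial summaries on flagged periods
  enc_split <- split(seq_len(nrow(enc)),
                     factor(paste(enc$participant_id, enc$day, enc$trial_id,
                                  sep = "."),
                            levels = vapply(groups, function(g) {
                              paste(g$meta$participant_id, g$meta$day,
                                    g$meta$trial_id, sep = ".")
                            }, character(1))))
  srch_split <- split(seq_len(nrow(srch)),
                      factor(paste(srch$participant_id, srch$day,
                                   srch$trial_id, sep = "."),
                             levels = names(enc_split)))
  seq_l <- vector("list", ng); dec_l <- vector("list", ng)
  err_l <- vector("list", ng); tri_l <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- groups[[i]]
    enc_i <- enc[enc_split[[i]], ]
    srch_i <- srch[srch_split[[i]], ]
    sq <- seq_build_one(enc_i, act_l[[i]], g$frames)
    seq_l[[i]] <- with_keys(sq, g$meta)
    dec_l[[i]] <- with_keys(
      dec_extract_one(sq, srch_i, act_l[[i]], g$frames), g$meta
    )
    err_l[[i]] <- with_keys(
      err_extract_one(sq, act_l[[i]], g$meta$target_layout[[1]]$object),
      g$meta
    )
    tri_l[[i]] <- with_keys(
      trial_summary_one(g$frames, g$meta, enc_i, srch_i), g$meta
    )
    act_l[[i]] <- with_keys(act_l[[i]], g$meta)
  }
  act <- dplyr::bind_rows(act_l)
  seqs <- dplyr::bind_rows(seq_l)
  dec <- dplyr::bind_rows(dec_l)
  err <- dplyr::bind_rows(err_l)
  trials <- dplyr::bind_rows(tri_l)

  structure(
    list(encodings = enc, searches = srch, actions = act, sequences = seqs,
         decisions = dec, errors = err, trials = trials, meta = meta),
    class = "copy_task_analysis"
  )
}

#' @export
print.copy_task_analysis <- function(x, ...) {
  cat(sprintf(
    paste0("<copy_task_analysis> %d trials: %d encoding periods (%d included), ",
           "%d searches (%d included),\n  %d sequences, %d decisions ",
           "(%d included), %d error opportunities\n"),
    nrow(x$trials), nrow(x$encodings), sum(x$encodings$included),
    nrow(x$searches), sum(x$searches$included), nrow(x$sequences),
    nrow(x$decisions), sum(x$decisions$included), nrow(x$errors)
  ))
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `copy_task_analysis`.
#' @param table Which table to return.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy copy_task_analysis
#' @export
tidy.copy_task_analysis <- function(x, table = c("trials", "encodings",
                                                 "searches", "actions",
                                                 "sequences", "decisions",
                                                 "errors"), ...) {
  x[[match.arg(table)]]
}

#' One-row overview of a pipeline result
#'
#' @param x A `copy_task_analysis`.
#' @param ... Unused.
#' @return A one-row tibble of table sizes and headline means.
#' @method glance copy_task_analysis
#' @export
glance.copy_task_analysis <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trials),
    n_timed_out = sum(x$trials$timed_out),
    n_encoding_periods = nrow(x$encodings),
    n_encoding_included = sum(x$encodings$included),
    n_searches = nrow(x$searches),
    n_searches_included = sum(x$searches$included),
    n_sequences = nrow(x$sequences),
    mean_attributes = mean(x$sequences$attributes_used[x$sequences$qualifies]),
    n_decisions_included = sum(x$decisions$included),
    p_memory_overall = mean(x$decisions$used_memory[x$decisions$included])
  )
}
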