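# Shared simulation utilities for the test suite.

# a policy with behavioural parameters jittered around the defaults, used for
# randomised oracle-equivalence runs
random_policy <- function(seed) {
  set.seed(seed)
  p_mem <- default_p_memory()
  p_mem$p <- pmin(0.95, pmax(0.02, p_mem$p * stats::runif(1, 0.5, 1.4)))
  p_id <- default_p_identity_error()
  p_id$p <- p_id$p * stats::runif(1, 0, 2.5)
  p_loc <- default_p_location_error()
  p_loc$p <- p_loc$p * stats::runif(1, 0, 2.5)
  agent_policy(
    encode_dwell_s = c(mean = stats::runif(1, 0.2, 0.6),
                       jitter = stats::runif(1, 0.02, 0.15)),
    orient_dwell_s = stats::runif(1, 0.3, 1.0),
    inter_slot_gap_frames = 0:sample(c(3L, 8L, 20L, 30L), 1),
    p_inspect_distractor = c(high = stats::runif(1, 0.1, 0.5),
                             low = stats::runif(1, 0.05, 0.3)),
    p_inspect_target = stats::runif(1, 0, 0.2),
    inspect_dwell_s = list(
      target = c(mean = stats::runif(1, 0.2, 0.45), jitter = 0.08),
      distractor = list(high = c(mean = stats::runif(1, 0.1, 0.3), jitter = 0.05),
                        low = c(mean = stats::runif(1, 0.08, 0.2), jitter = 0.04))
    ),
    p_memory = p_mem, p_identity_error = p_id, p_location_error = p_loc,
    locomotion_speed_m_s = stats::runif(1, 1.0, 2.0)
  )
}

# error-free variant of the default policy (clean parameter recovery)
error_free_policy <- function(p_memory = default_p_memory()) {
  p_id <- default_p_identity_error(); p_id$p <- 0
  p_loc <- default_p_location_error(); p_loc$p <- 0
  agent_policy(p_memory = p_memory, p_identity_error = p_id,
               p_location_error = p_loc)
}

# policy in which memory is never used: every action follows a model visit
no_memory_policy <- function() {
  p_mem <- default_p_memory(); p_mem$p <- 0
  error_free_policy(p_memory = p_mem)
}

# simulate a trial set in chunks, keeping only the derived tables (frames are
# discarded per chunk to bound memory)
run_chunked <- function(policy, meta, seed, chunk_size = 250L) {
  n <- nrow(meta)
  starts <- seq(1L, n, by = chunk_size)
  acc <- list(decisions = list(), errors = list(), sequences = list(),
              trials = list(), truth_decisions = list(),
              truth_trials = list())
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunk_size - 1L, n)
    sim <- simulate_trials(policy, meta[idx, ], seed = seed + ci * 1009L)
    an <- analyze_copy_task(sim)
    acc$decisions[[ci]] <- an$decisions
    acc$errors[[ci]] <- an$errors
    acc$sequences[[ci]] <- an$sequences
    acc$trials[[ci]] <- an$trials
    acc$truth_decisions[[ci]] <- sim$truth$decisions
    acc$truth_trials[[ci]] <- sim$truth$trials
  }
  lapply(acc, dplyr::bind_rows)
}

# three-SE binomial check helper
within_3se <- function(p_hat, p_true, n) {
  se <- sqrt(p_true * (1 - p_true) / n)
  abs(p_hat - p_true) <= 3 * se + 1e-12
}
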