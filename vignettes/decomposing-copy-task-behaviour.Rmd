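---
title: "Decomposing object-copying behaviour: detectors, agent model, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing object-copying behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copytask)
library(dplyr)
```

## The measurement problem

In an immersive object-copying task a participant reproduces a model
arrangement of 8 objects by taking targets from a resource pool (8 targets
among 16 distractors) and placing them into a workspace grid, under a 45 s
timer. Nothing constrains *how*: the participant decides when to study the
model, how many object identities and locations to hold in mind, and when to
fall back on re-inspection. The scientific content of the task therefore
lives in a decomposition of the continuous 90 Hz gaze/interaction stream
into discrete, interpretable units — encoding periods, searches,
working-memory (WM) usage sequences, sensorimnemonic decisions, and errors.
This package implements that decomposition as a tested pipeline, plus a
generative agent whose ground truth lets every stage be validated by
parameter recovery rather than by eye.

## Data model

A *frame log* is one trial: a metadata row (conditions, timer, target and
resource layouts) plus one row per frame with a gaze station
(`model`, `resource_pool`, `workspace`, `other`, `none`), an optional gaze
entity (model slot 1–18, resource object 1–24, workspace slot 1–18), head
and controller positions in metres, and the interaction event fields.
Frame intervals are half-open `[t, t + duration_s)`; `frame_index` is
0-based. Validation (`validate_frame_log()`) is total — it reports
violations as data (rule + frame index) rather than raising — and covers
positive durations, consecutive indices, station/entity consistency, event
completeness, pickup-while-holding, placements without a held object, and
the timer bound. On disk a log is a flat CSV with the empty string as the
null token, written at shortest round-trip precision so write→read is the
identity and repeated writes are byte-identical.

## Detector semantics

**Encoding periods.** A period opens at a model-gaze frame. Successive
model-gaze runs merge into the same period unless the off-model gap both
(a) lasts at least 25 frames (~250 ms) *and* (b) contains resource-pool or
workspace gaze. Two consequences are intentional and fixture-tested:

- long stretches of `none`/`other` gaze never split a period (the
  participant never redirected to a task station);
- short (< 25-frame) station excursions are bridged *into* the period, so a
  period's span can contain a few non-model frames. Model viewing time sums
  **all** frame durations from period start to end, bridged gaps included —
  the literal "from start to end" reading. The alternative
  (model-frames-only) would change viewing times by the bridged-gap
  fraction, which is well under 1% under realistic gaze streams.

The number of targets encoded counts distinct *occupied* model slots fixated
for at least 2 consecutive frames (~20 ms); a dwell interrupted by any other
gaze does not accumulate across the interruption.

**Exclusion filters** run in a fixed order, and `exclusion_reason` records
the first rule that fired: (1) periods not followed by resource-pool or
workspace gaze before the next period or trial end; (2) the first period of
every display (the model faces the participant at trial start, so the first
look is orientation, not task encoding); (3) periods under 50 ms; (4)
periods more than 3.5 SD above the participant's mean viewing time. The SD
threshold is computed on raw seconds, per participant, pooled across all
conditions and days, using only the survivors of rules 1–3; with fewer than
two survivors it is skipped with a warning. Applying the order-sensitive
filters sequentially matters: a first-in-display period that is also under
50 ms is recorded as `first_in_display`.

**Search periods.** A search opens at the first resource-pool gaze frame
after the latest of trial start, the previous pickup, and the preceding
encoding period, and closes at the next pickup event (the pickup frame is
inside the search). Two boundary rules needed a decision the task
description leaves open:

- resource-pool frames bridged into an encoding period never open a search
  (they are, by the encoding definition, part of an encoding episode);
- if an encoding period *starts* before any pickup, the open search is
  discarded (`no_pickup`) and the next search opens after that period. A
  frame carrying both a pickup event and model gaze is processed
  event-first: pickups close searches.

Per-object viewing times sum the ≥ 2-consecutive-frame spans per object;
search exclusions run as `no_pickup` → under 50 ms → ended in a pickup
error → 3.5 SD (same per-participant convention as encoding).

**Sequences and WM usage.** Consecutive *included* encoding periods bound a
sequence; an excluded period (say, a 40 ms glance) does not split one.
Actions strictly between the end of the opening and the start of the closing
encoding belong to the sequence; `attributes_used` counts correct pickups
plus correct placements (a failed attempt adds nothing but stays in the
action list). A sequence qualifies for WM analyses only if the resource pool
or workspace was gazed between its bounding encodings, and its type is set
by its first action (`search_first` / `placement_first` / `other`).

One subtlety is worth spelling out because it measurably matters. The run of
behaviour in progress when the trial ends has no closing encoding. For the
WM-usage *metric* that run is correctly discarded — the metric is defined
between encodings. But decisions live on action boundaries, and discarding
the trailing run censors it in a length-biased way (longer, more
memory-guided runs are more likely to contain the trial's last object): in
simulation this depressed recovered memory probabilities by 3–4 binomial
SEs at 2,000 decisions per cell. `build_sequences()` therefore emits one
additional *open* sequence per trial (`closed = FALSE`) spanning from the
last included encoding to trial end. The WM summary ignores it; the decision
and error extractors use it. With the open tail in place, recovery of the
generative probabilities is unbiased (|z| < 1 at n ≈ 2,900).

**Sensorimnemonic decisions.** Location-related decisions are locked to the
frame after a correct target pickup, identity-related decisions to the frame
after a correct placement; `used_memory` is true iff no model-gaze frame
occurs before the next pickup/placement. "Re-fixating the model" is
operationalised as *any* model-gaze frame, not a qualifying encoding period
— re-fixation is a weaker event than encoding, and requiring a full
qualifying period would reclassify brief glances as memory use. Positions
restart at 1 in every sequence, and a non-memory decision's model re-fixation
ends the sequence, so the deferred action opens the next one
(`placement_first` sequences arise exactly this way).

Inclusion filters, in order: the sequence must be `search_first`; its
initial encoding must be included; the search ending at its first pickup
must be matchable and included; the run-up to the decision must be free of
errors and returns-to-pool (`disrupted`); a memory decision must not be
followed by a mistake (`memory_then_error`); and the decision must be
followed by an encoding or another action (`no_following_action` otherwise,
e.g. at trial end). `p_memory_table()` restricts positions ≥ 2 to the high
movement-effort condition by default, where multi-attribute sequences are
frequent enough to estimate.

**Errors.** Error extraction uses the same search-first base but keeps
erroneous sequences: one opportunity record per first/second pickup
(identity) and first/second placement of a target (location), walking the
actions in order and stopping after the first error so later errors in the
same disrupted run stay out of the rates. Placement attempts of non-targets
are not location-error opportunities.

**Overall behaviour.** Completion time is the sum of frame durations; total
head movement is the sum of Euclidean distances between successive HMD
positions, unsmoothed (a `--smooth`-style option was considered and
rejected: the simulator produces noiseless piecewise-linear paths, and on
real data smoothing is a preprocessing choice that belongs upstream).
Condition summaries average participant means, not pooled observations, and
drop timed-out trials by default.

## The generative agent

`simulate_trial()` plays the task as a loop over the grammar: orient on the
model, encode a batch of targets (batch size from `n_encode_dist`, dwell
per slot from `encode_dwell_s`, short `none`-gaze gaps between slots), walk
to the pool, search (each distractor inspected with probability
`p_inspect_distractor[distraction]`, dwells by role and condition), pick up
the sought target, then at each decision consult
`p_memory(kind, position, conditions)`: act from memory, or walk back and
re-encode first. Identity errors grab a distractor or an already-placed
duplicate, which must be returned (`release_to_pool`) before the task
continues; location errors place at a wrong slot and are corrected
immediately. The trial ends at 8 correct placements or at the timer, with
frames truncated exactly at the limit.

Heads move on piecewise-linear paths between station positions at
`locomotion_speed_m_s`, with each walk leg divided into whole frames — so
the frame-wise Euclidean sum equals the scripted path length in closed form
(to 1e-9 relative; this is the oracle for the head-movement metric).
Identical `(policy, meta, seed)` give byte-identical output; experiment
seeds derive per-trial seeds arithmetically (all below 2^31).

Defaults were chosen once, as a realistic operating point, and are not
fitted to any dataset:

- *Task constants* (8 targets, 18 slots, 24 pool objects, 45 s timer,
  90 Hz, 2 days × 2 sessions × 4 blocks × 14 displays with 7+7 sub-block
  directions) are fixed by the protocol.
- *Geometry*: stations on a 0.6 m radius around the room centre, head
  height 1.6 m; the model sits above the workspace (`deg0`, no translation)
  or 90° away (`deg90`). Locomotion 1.5 m/s. These give per-trial head paths
  of roughly 14–22 m and completion times of 24–35 s with rare timeouts,
  matching the scale of a task in which ~1.5% of trials time out.
- *Gaze dwells*: 0.35 ± 0.10 s per encoded slot; search inspections
  0.30 ± 0.08 s on targets, 0.18/0.12 s on distractors under high/low
  distraction; placements 0.35 ± 0.06 s. The placement dwell is kept at or
  above 26 frames deliberately: a sub-25-frame workspace excursion between
  two model looks is — correctly, per the gap rule — bridged into one
  encoding period, and an agent that swallowed placements that way would
  misrepresent the task grammar it is meant to emulate.
- *Memory probabilities* fall with position, rise with movement effort, and
  (for identity-related decisions only) fall under high distraction —
  producing the qualitative pattern the task is designed to expose: mean
  attributes ≈ 1.5 at low effort vs ≈ 2.3 at high effort, ~30%
  placement-first sequences at high effort, and a small distraction decrement
  on identity decisions.
- *Error rates* of 2–6% by position and condition, higher for identity
  errors under high distraction, location errors flat-to-reversed.

`script_log()` builds fully deterministic logs from hand-written
gaze/event scripts and is how the edge-case fixtures (exact gap lengths,
sub-threshold fixations, constructed outlier sets) are made.

## Validation strategy, and what it does and does not show

- **Oracle equivalence.** A deliberately naive per-frame reference
  implementation of both detectors (frame-by-frame state machines, no
  vectorisation, written independently of the production code) is compared
  field-for-field on 1,000 simulated trials with randomly jittered policies.
- **Parameter recovery.** Included decisions recover the generative
  `p_memory` within 3 binomial SEs at ≥ 2,000 decisions per
  kind × position × condition cell (error-free agent — with errors on, the
  `memory_then_error` filter removes a slice of memory decisions and biases
  the estimand itself by ~p·p_err, a property of the filter, not the
  estimator); error rates recover their generative probabilities on the
  error-prone agent; the sign of a moderate distraction effect on the second
  identity-related decision (0.50 vs 0.30) is recovered in ≥ 95 of 100
  replicate experiments of 24 trials per condition.
- **Analytic cross-checks.** The attribute distribution of completed
  search-first sequences matches a closed-form alternating-survival
  calculation from `p_memory`; the comparison uses each trial's first three
  sequences, because the final sequence is censored by task completion in a
  length-biased way. Conservation (attributes vs. the action stream), the
  closed-form head path, distribution normalisation, and byte-level
  determinism are asserted exactly.

Problem sizes in the shipped tests — 1,000 oracle trials at a 15 s timer,
2,000 recovery trials per condition, 100 sign-recovery replicates — were
chosen as the smallest sets at which the binomial tolerances above are
meaningful.

What passing these tests shows: the pipeline implements its stated
semantics exactly, and its estimators are unbiased for data that follow the
task grammar. What it does not show: robustness to properties of real
eye-tracking data that the agent deliberately does not emulate — saccade
kinematics and gaze noise (the input here is already an AOI stream; the
gap-bridging and 2-frame rules exist to absorb exactly such noise, but
their real-world operating characteristics cannot be measured on synthetic
AOI streams), calibration drift, tracker dropout, idiosyncratic behaviours
beyond the modelled error-and-correct cycle, and learning across trials
(the agent treats trials as exchangeable given the policy).

## Numerical conventions

Durations are exact multiples of 1/90 s; all thresholds are applied in the
stated units (25 frames, 2 frames, 0.050 s, 3.5 SD on raw seconds) with
strict inequalities for the "less than 50 ms" and "more than 3.5 SD" rules.
Sums use compensated-enough double accumulation (cumulative sums over at
most ~4,000 frames; round-trip error is below 1e-12 of a trial duration).
Ties are deterministic: an event frame that also shows model gaze is
processed event-first. Degenerate inputs are defined: empty logs give empty
tables everywhere; an SD filter over identical values excludes nothing; a
trial whose only encoding period is its first yields no included periods
and no sequences.

## Known limitations

- The CSV dialect is package-defined; adapters for specific VR engines'
  raw exports are out of scope.
- Inferential statistics (mixed models, contrasts, Bayes factors) are
  intentionally not included; the tables are tidy inputs for `lme4` and
  friends.
- The agent's decision process is memoryless given position and condition;
  it cannot emulate strategic drift within a session.
- Direction (left/right sub-blocks) mirrors the geometry but no metric
  depends on it, matching the absence of direction analyses in this task
  family.
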