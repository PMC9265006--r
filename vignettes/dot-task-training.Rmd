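---
title: "Dot-task training: the model behind the simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dot-task training: the model behind the simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dottask)
```

## The procedure

`dottask` models a shaping protocol for teaching touchscreen-naive subjects
a two-item numerical sequencing skill. Training advances on a fixed
calendar, not on a performance criterion: ten One Dot sessions with the
target shrinking from 550 px ("almost as large as the screen") to 100 px,
five Two Dot sessions, then eighty Two Number Dot sessions, the final 55 of
which interleave forced-choice trials (only the "1" dot shown) at 25% of
trials. Sessions last 10 minutes with no set trial count; a session-start
chime marks the first trial's onset. Correct responses earn a chime, a
green LED, and one food pellet; sequencing errors earn a buzzer and red
LED, with no pellet. The whole schedule is data, not code: see
`build_training_curriculum()` and the JSON round trip in
`default_config()` / `read_config()`.

Each trial is a small state machine (`run_trial()`): touches that miss
every visible dot are logged and ignored — stimuli on screen are always
touchable, and background touching carries no penalty; hitting a dot hides
it; the task rule decides when the trial resolves. Forced-choice trials
admit no error path, which is exactly why they are excluded from
performance scoring.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| screen | 1024 × 768 | px | Typical 4:3 panel; the native resolution is unrecorded, and this is the smallest common geometry admitting the 550-px dot with room to move. |
| `iti_s` | 3.0 | s | The protocol states only a "brief" inter-trial delay. 3 s, with the 1-s ideal touch latency, makes the engine's ceiling exactly the reported maximum usage rate of 15 trials/min, so the pair is chosen jointly and treated as fixed. |
| ideal `latency_s` | 1.0 | s | Time to find and touch a dot for a fluent subject (see above). |
| `max_trial_duration_s` | 60 | s | A response timeout the animals never needed but a simulation does; unresolved trials end as `aborted`, with no feedback. |
| `duration_s` | 600 | s | The 10-minute session. |
| `min_gap_px` | 0 | px | Dots are only required not to overlap. |
| `forced_fraction` | 0.25 | — | The stated forced-choice proportion in the final 55 sessions. |
| `chance_level` | 0.5 | — | A uniform pick between two ordered dots. |
| `block_size_sessions` | 5 | sessions | Performance is pooled per five-session block. |
| `alpha` | 0.05 | — | Above-chance flag threshold; no multiple-testing correction is applied across blocks, so flags are per-block statements only. |

## Numerical and procedural choices

* **Coordinates** are 0-based pixels, origin top-left, y downward; centers
  sit on the integer lattice, distances are floating point. The feasible
  center band is `radius <= center <= dimension - radius` per axis.
* **Hit boundary is inclusive** (distance ≤ radius). Pixel-scale ties are
  biologically meaningless but must be deterministic.
* **Placement** is rejection sampling, uniform over the joint feasible
  (non-overlapping) region, with a 10,000-attempt budget; infeasible
  geometry raises a configuration error, an exhausted budget a placement
  error. Note the *joint* distribution is uniform: the per-dot marginals of
  a pair are very slightly edge-biased because central positions collide
  more often. At the default 100-px dots the effect is far below what a
  10⁴-draw chi-square on a 4 × 4 grid of the feasible box can resolve.
* **Clock granularity** is 1 ms. Every touch and every trial consumes at
  least one tick, so degenerate zero-latency/zero-ITI configurations remain
  finite: throughput is then bounded by `duration / 0.001`.
* **Session cutoff**: no trial starts at or after 600 s; a trial in flight
  completes and is logged. Hard-aborting it would bias latency statistics.
* **Forced-trial interleaving**: only the 25% figure is stated. A Bernoulli
  scheme would allow long forced droughts and runs, so flags are balanced
  in windows of four — one forced trial per window, uniform position. The
  percentage is then exact at any multiple of four
  (`generate_trial_sequence()`); a known-length sequence finishes a partial
  window with independent Bernoulli(0.25) draws, while the session runner,
  which cannot know the trial count in advance, simply truncates its last
  pre-drawn window (the marginal forced probability of every trial is 0.25
  either way).
* **Error handling in the sequencing task**: touching "2" first ends the
  trial immediately as incorrect; there is no correction trial and no
  time-out penalty (the simplest reading of the protocol).
* **Performance testing** uses the exact binomial tail (summed point
  probabilities, no normal approximation), one-sided "greater" by default
  because the scientific claim is "above chance"; two-sided is a config
  switch. Trials are pooled within a block, not averaged per session,
  mirroring a single test per block. Blocks with zero choice trials report
  missing values, never zeros.

## The simulated subjects

The protocol constrains no individual learning model, so the agents are the
package's synthetic-data generators, from fully deterministic to minimally
cognitive:

* `ideal_agent()` — touches the required dot after a fixed latency; the
  throughput and determinism oracle.
* `stimulus_directed_random_agent()` — uniform pick among visible dots,
  uniform landing point within the chosen dot; the exact chance-level
  oracle (accuracy 1/2 on choice trials).
* `random_location_agent()` — uniform screen touches; per-touch hit
  probability equals the dot's area fraction, the engagement-noise model.
* `rescorla_wagner_agent()` — the minimal two-action learner: softmax
  choice between "touch-1-first" (value *v*) and "touch-2-first" (value
  *w*), update `value ← value + α(r − value)`. Forced trials reward and
  update *v* only. Defaults α = 0.1, β = 5, v₀ = w₀ = 0.5: a naive subject
  with no initial preference. Stochastic agents draw latency as mean ±
  uniform jitter (1.0 ± 0.5 s) — latencies are recorded but not analyzed,
  so the simplest model suffices.

All randomness flows through R's global RNG, seeded once per session, so a
seed plus an agent reproduces a session log bit for bit.

### What a green test does and does not establish

The generator emulates the *contingencies* of the task — timing, feedback,
forced-choice scaffolding, chance levels — not animal behavior. Real
sessions have multiple subjects sharing one screen, motivational drift,
satiation, and side biases; none are modeled. Green property tests
establish that the engine implements the stated protocol and that the
analyses recover known ground truth from simulated logs; they say nothing
about how any animal group would perform.

Two Monte-Carlo subtleties in the learning-dynamics checks are worth
recording. First, block-accuracy monotonicity is asserted on the learner's
*expected* accuracy (the mean softmax probability of the correct action)
rather than realized accuracy: within every replicate *v* only rises and
*w* only falls, so expected accuracy increases strictly by construction,
whereas realized late-block differences (~10⁻⁴ once the agent has
converged) sit below Monte-Carlo resolution at any desk-scale replicate
count — a strict inequality on realized means would be a coin flip, i.e. an
uninformative test of the real property. Second, forced-trial scaffolding
is compared at matched *choice*-trial counts (forced trials added on top).
At matched total counts forced trials merely substitute for choice trials
that are equally informative under the symmetric update rule, and no
acceleration exists to detect; the matched-choice design tests the actual
claim — that interleaving unfailable trials speeds learning relative to the
same amount of choice experience.

## Data formats

Trial logs are flat CSV (schema in `trial_log_columns()`, times at
millisecond precision), feedback events are JSONL, session metadata a JSON
sidecar; `write_session()` emits all three and `validate_session_dir()`
re-reads them with full invariant checking (reward iff correct, forced
implies correct, monotone timestamps), pinpointing the offending line and
field on failure. Write-then-read is the identity on records.

## Known limitations

* Single simulated "group" per run; no dominance, monopolization, or
  multi-subject access modeling.
* No adaptive stage advancement (the protocol advanced on the calendar).
* The Rescorla–Wagner agent is a stand-in: published group accuracies are
  figure-only and are deliberately not used as fitting targets.
* Hardware (pellet dispenser, LEDs, audio) is abstracted to feedback
  events consumed by logging sinks.
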