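# dottask

A headless, fully testable engine for operant touchscreen **dot tasks** of
the kind used to train touchscreen-naive primate groups for enrichment and
cognition research. The package re-creates the task software as a simulation
harness: the discrete-trial state machines, the shaping curriculum, session
timing and reward events, durable trial logs, and the standard engagement
and performance analyses — exercised end to end by simulated subjects
instead of animals.

## Who this is for

Researchers and engineers who need a reference implementation of a
touchscreen training protocol that can be driven, perturbed, and verified
entirely in software: to prototype analyses before animal data exist, to
validate logging pipelines, or to study how training-schedule choices
(forced-choice scaffolding, inter-trial intervals, dot-size ladders)
interact with subject learning dynamics.

## The protocol

Three tasks, advanced on a fixed 95-session calendar (one 10-minute session
per day, no set trial count):

| Sessions | Task | Details |
|---|---|---|
| 1–10 | **One Dot** | touch a single dot; diameter shrinks 550 → 400 → 200 → 100 px over 3/2/2/3 sessions |
| 11–15 | **Two Dot** | touch two non-overlapping dots, either order |
| 16–40 | **Two Number Dot** | dots labeled "1" and "2"; touch in numeric order |
| 41–95 | **Two Number Dot** | as above, with 25% *forced-choice* trials (only the "1" dot shown) |

Correct responses trigger a chime, green LED, and a food pellet; touching
"2" before "1" triggers a buzzer and red LED with no pellet. Forced-choice
trials cannot be failed and are excluded from performance scoring.

Engagement is summarized as **trials per minute** (completed trials divided
by session minutes; the ceiling under default timing is 15). Performance on
the sequencing task pools *choice* trials over blocks of five sessions and
tests each block's accuracy against the 0.5 chance level with an **exact
binomial test** (upper tail, summed point probabilities):

p = Σ_{k = n_correct}^{n} C(n, k) · 0.5ⁿ

Simulated subjects include an ideal responder, uniform-random and
stimulus-directed touchers (the chance-level oracle), and a
**Rescorla–Wagner softmax learner**: it picks "touch-1-first" with
probability `P = exp(βv) / (exp(βv) + exp(βw))` and updates the chosen
action's value by `value ← value + α(r − value)`, `r ∈ {0, 1}`.

## Worked example

```r
library(dottask)

cur <- build_training_curriculum()
cur
#> <dot_curriculum> 95 sessions
#>   sessions  1- 3  one_dot         dot 550 px  forced 0%
#>   sessions  4- 5  one_dot         dot 400 px  forced 0%
#>   sessions  6- 7  one_dot         dot 200 px  forced 0%
#>   sessions  8-10  one_dot         dot 100 px  forced 0%
#>   sessions 11-15  two_dot         dot 100 px  forced 0%
#>   sessions 16-40  two_number_dot  dot 100 px  forced 0%
#>   sessions 41-95  two_number_dot  dot 100 px  forced 25%

# an ideal subject saturates the engagement ceiling
log <- run_session(session_spec(10, stage_for_session(cur, 10), seed = 1),
                   ideal_agent())
trials_per_minute(log)
#> [1] 15

# a learning subject on the forced-choice phase
ag <- rescorla_wagner_agent(alpha = 0.1, beta = 5)
logs <- run_session_queue(curriculum_session_specs(cur, 41:45, base_seed = 9),
                          ag)
block_performance(logs)
#>   block_index session_start session_end n_sessions partial n_choice_trials
#> 1           1            41          45          5   FALSE             480
#>   n_correct proportion_correct       p_value above_chance
#> 1       469          0.9770833 2.281562e-123         TRUE
```

The learner completes 480 choice trials over the five-session block, gets
97.7% of them right, and the exact binomial test flags the block as far
above the 0.5 chance level — the per-block summary a training study reports.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/dottask.R simulate --agent rw --sessions 41..45 --seed 9 --out logs/
Rscript inst/cli/dottask.R analyze logs/ --out report.json
Rscript inst/cli/dottask.R validate logs/
Rscript inst/cli/dottask.R curriculum
```

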