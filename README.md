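# rehabplan

Automatic planning of computerized cognitive rehabilitation for
acquired-brain-injury (ABI) patients.

After an ABI, treatment is delivered as ~60 one-hour sessions of
parameterizable computerized tasks, each designed for one of 11
cognitive subfunctions (attention: sustained/selective/divided;
memory: visual/verbal/working; executive: scheduling/inhibition/
flexibility/sequencing/categorization). Choosing the tasks and their
difficulty for every session by hand is costly and
therapist-dependent. `rehabplan` is for rehabilitation informatics
researchers and clinical decision-support developers who want that
planning loop as reproducible, testable code.

## What it computes

* **Cognitive profiles** — test items are z-scored against
  age/education-stratified norms, averaged per subfunction and banded
  to an integer impairment level IL ∈ {0..4} (0 = normality,
  4 = very severe).
* **Patient stratification** — a seeded EM Gaussian mixture
  (diagonal covariances) over the 11-dimensional profiles;
  the component count can be chosen automatically by 10-fold
  cross-validated held-out log-likelihood. `fit_em()` returns a
  classed model with `print`/`summary`/`coef`/`predict`/`simulate`/
  `logLik` methods.
* **Task suitability** — per patient, every catalog task gets a usage
  score *U* (cluster execution quartiles, 0–4), an improvement score
  *I* (PRE→POST gains of similar patients, 0–4), and a clinical score
  *IL&CC* = Σₛ ILₛ·CCₛ over the 11 subfunctions, combined as

  ```
  GSS = U·ku + I·ki + IL&CC·kc        (defaults ku = ki = kc = 1)
  ```

  and the ranked catalog splits into suitability quartiles SQ1–SQ4.
* **Session assembly** — blocks of ten 60-minute sessions drawing
  tasks cyclically 3×SQ1, 2×SQ2, 2×SQ3, 1×SQ4; each task's parameter
  space is enumerated into difficulty quartiles DQ1–DQ4 by summed
  value weights, and the configuration is drawn from
  `DQ = clamp(4 − IL, 1, 4)` on the task's designated subfunction.
* **Adaptation** — executions score 0–100 and classify as
  infra-therapeutic (< 65), therapeutic (65–85) or supra-therapeutic
  (> 85). Between blocks, the mean execution result per subfunction
  (MERS) revises the impairment level (+1 / −1 / −2 for
  infra/therapeutic/supra, clamped); out-of-range executions can be
  re-queued one difficulty quartile easier or harder.
* **Closed-loop simulation** — synthetic archetype-based cohorts and
  a latent-ability logistic response model
  (`E[score] = 100·logistic(γ(θ − d) + log 3)`, learning on
  therapeutic executions) exercise the full plan→execute→adapt loop
  and compare the PRE-only planner (v1) against the MERS-adaptive one
  (v2).

## Worked example

```r
library(rehabplan)

catalog <- read_task_catalog(system.file("extdata", "tasks_synthetic.json",
                                         package = "rehabplan"))
p <- cognitive_profile(c(3, 2, 3, 2, 1, 3, 1, 0, 1, 2, 0),
                       patient_id = "P001")

scores <- score_tasks(catalog, p)
head(scores[order(-scores$GSS), ], 5)
#>            task_id U I ILCC GSS SQ
#>         s05_n_back 0 0   24  24  1
#>     s02_dual_track 0 0   22  22  1
#>              bingo 0 0   19  19  1
#>  s01_visual_search 0 0   19  19  2
#>  s03_picture_pairs 0 0   16  16  2
```

With no execution history the usage and improvement criteria are 0 and
the ranking is driven by the clinical score: the working-memory n-back
task tops the list because this patient's worst levels (sustained
attention 3, working memory 3) meet its strongest clinical criteria.
The Bingo task scores IL&CC = 3·4 + 2·2 + 3·1 = 19.

```r
plan <- assemble_block(scores, catalog, p, version = "v2", seed = 7)
plan
#> Rehabilitation block plan (v2): 10 sessions, 66 task assignments
plan$sessions[[1]][, c("task_id", "sq", "dq", "duration")]
#>            task_id sq dq duration
#>     s02_dual_track  1  1        9
#>              bingo  1  1       10
#>         s05_n_back  1  1        8
#>    s09_story_order  2  2        7
#>  s03_picture_pairs  2  2        7
#>     s06_errand_plan  3  3       12
```

The first session opens with the 3/2/2/1 quartile cycle (three SQ1
tasks, then SQ2, …) and stops before exceeding 60 minutes; with no
history yet, difficulty comes from the PRE levels (impairment 3 on
sustained attention → DQ1, the easiest quartile, for the Bingo).

```r
cohort <- generate_cohort(cohort_config(n = 6, seed = 1))
run <- run_closed_loop(cohort, catalog, version = "v2", n_blocks = 2,
                       seed = 1)
run
#> Closed-loop simulated treatment (planner v2)
#>   patients: 6  executions: 794
#>   range fractions: infra 0.311 / therapeutic 0.385 / supra 0.304
#>   patients improved: 66.7%
```

A command-line interface over the same functions ships in
`inst/cli/rehabplan` (subcommands `cluster`, `score`, `plan`,
`simulate`, `evaluate`).

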