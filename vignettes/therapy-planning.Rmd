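---
title: "Adaptive therapy planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive therapy planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabplan)
```

## The problem

Computerized cognitive rehabilitation after acquired brain injury (ABI)
delivers treatments as roughly 60 one-hour sessions of parameterizable
tasks, each task designed for one of 11 cognitive subfunctions grouped
under attention, memory and executive functions. Assembling those
sessions by hand — which tasks, at which difficulty — is expensive and
depends heavily on therapist experience. `rehabplan` implements an
automatic planner: it profiles patients, groups similar patients,
rates every catalog task for the patient at hand, assembles sessions
from the resulting ranking, and adapts task difficulty to the patient's
running performance. A closed-loop simulator generates synthetic
cohorts and execution responses so the whole pipeline can be exercised
and compared end to end without clinical data.

## Impairment profiles

A patient's cognitive profile rates each subfunction on an integer
scale from 0 (normality) to 4 (very severe impairment). Raw test
scores are first converted to z-scores against normative data
stratified by age band and education level, averaged per subfunction,
and banded:

* z > −1 → 0, then one severity level per further standard deviation,
  capped at 4 for z ≤ −4.

The banding thresholds are a package choice: 1-SD clinical severity
bands are the standard convention that spans the 0–4 scale, and they
make the banding monotone and total. Function-level aggregates are the
arithmetic mean of a function's subfunctions rounded half-up — the
simplest order-preserving summary; function-level values are only
consumed by the improvement criterion. Because normalization tables
are proprietary, cohorts may equally supply pre-banded 0–4 vectors
(`read_cohort(..., scale = "level")`), which bypass normalization.

A patient counts as *improved* between the PRE and POST assessment
when at least one function-level value strictly decreases and none
increases.

## Patient stratification

`fit_em()` fits a Gaussian mixture with diagonal covariances to the
11-dimensional profiles by expectation–maximization and returns a
classed model object with the usual methods (`print`, `summary`,
`coef`, `predict`, `simulate`, `logLik`). Profiles are stored as
integers but treated as real-valued — a mixture density needs
continuous support. Numerical choices that matter:

* **Initialization** is k-means (5 restarts) from the user seed;
  identical seed and data give bit-identical fits. Degenerate inputs
  (fewer distinct rows than components) fall back to jittered sampled
  rows rather than failing.
* **Variance floor 0.1.** Profiles live on an integer lattice with
  spacing 1. With a much smaller floor a component can collapse onto a
  single severity level (SD ≈ 0.03 gives densities above 12 at the
  lattice point), which inflates held-out likelihood and drives
  component selection toward spurious splits. A floor of 0.1
  (SD ≈ 0.32, a third of a level) blocks the degeneracy while staying
  well below realistic between-patient spread.
* **Automatic component count** by 10-fold cross-validated held-out
  log-likelihood: K grows while the mean held-out log-likelihood
  improves *by more than a 1% relative margin*. A bare "improves at
  all" rule keeps finding per-observation gains of order 0.01–0.03
  from the residual lattice structure long after the real cluster
  structure (gains of order 10) is captured; the margin makes the rule
  stop at the substantive clusters.
* **Convergence**: relative log-likelihood change below `tol`
  (default 1e-8) or `max_iter` (500); hitting the cap flags the model
  (`converged = FALSE`) instead of raising, so a planner run never
  dies on a hard dataset.

Whenever a new patient enters treatment, `refit_with_patient()`
re-estimates the mixture over all profiles including the newcomer and
returns the newcomer's posterior — the stratification always reflects
every patient known to the system.

## Task scoring

For one patient, every task in the catalog receives four criteria:

* **Usage score U (0–4):** execution counts of the task among the
  patient's cluster, ranked and split into quartiles; 4 for the most
  used quartile, 1 for the least, 0 for never-used tasks.
* **Improvement score I (0–4):** over cluster patients who executed
  the task, the mean PRE−POST drop on the task's designated
  subfunction, plus (at weight `w_other = 0.5`) the mean function-level
  drop on the two functions the task was not designed for, clamped to
  [0, 4]. The exact functional form is a package choice — the concept
  (designated-subfunction improvement, collateral improvement weighted
  by adjustable coefficients) fixes the structure but not the formula;
  clamping keeps the criterion commensurable with the other 0–4
  scores.
* **Clinical score IL&CC (≥ 0):** the dot product of the patient's
  11 impairment levels with the task's clinical-criteria vector. Only
  subfunction-level terms enter, matching the worked numerical example
  the score is defined by.
* **Global suitability:** `GSS = U·ku + I·ki + IL&CC·kc` with
  defaults `ku = ki = kc = 1`. The coefficients exist so clinicians
  can reweight the criteria; no published values exist, so equal
  weights are the neutral default, all config-overridable.

Ranked by descending GSS (ties by ascending task id), tasks split into
four contiguous suitability quartiles SQ1–SQ4, as equal as possible
with earlier quartiles taking the remainder — a 95-task catalog splits
24/24/24/23. In the usage score, tied execution counts promote to the
best group any of them occupies, which keeps the score independent of
the input order and favors inclusion in better quartiles.

## Session assembly and difficulty adaptation

Sessions draw tasks cyclically 3×SQ1, 2×SQ2, 2×SQ3, 1×SQ4 —
uniformly without replacement within a session (no task twice in one
session), with replacement across sessions — and a session closes when
the next drawn task would exceed the 60-minute cap. An exhausted
quartile falls through to the next non-empty one and is counted in the
plan object. The cycle position carries across sessions, so 80 emitted
draws contain exactly 30/20/20/10 tasks per quartile.

Each task's parameter space is enumerated into configurations; the sum
of per-value difficulty weights (0 = easiest value) orders them, ties
resolved lexicographically, into difficulty quartiles DQ1 (easiest) to
DQ4 (hardest), again near-equal with the remainder to the front. The
patient's impairment level `a` on the task's designated subfunction
selects the target quartile `DQ = clamp(4 − a, 1, 4)` — the mapping is
a package choice; it is monotone, spans all quartiles, and sends the
severest impairment to the easiest quartile. For tasks with fewer than
four distinct configurations the nearest non-empty quartile is used,
preferring the easier side.

Between 10-session blocks, version 2 of the planner revises the
impairment level per subfunction from the mean execution result for
that subfunction (MERS): below 65 adds one level (easier tasks),
65–85 subtracts one, above 85 subtracts two, clamped to 0–4. Version 1
(kept behind the `version` flag for comparison) plans the whole
treatment upfront from the PRE profile alone. Execution scores 65–85
count as therapeutic, below 65 infra-therapeutic, above 85
supra-therapeutic; both boundary scores are therapeutic so the three
ranges partition [0, 100]. Out-of-range executions can be re-queued
into the next session with room, one difficulty quartile easier
(infra) or harder (supra) — the one-quartile step is the smallest
responsive change, and re-queuing extends the target session within
the duration cap rather than replacing a scheduled task.

## The synthetic cohort and response model

`generate_cohort()` draws each patient from one of a few archetype
profiles plus independent Gaussian noise, clamped and rounded to the
0–4 lattice, keeping the generating archetype as hidden truth. The
default archetypes — attention-dominant mild (levels ≈ 0.5–1.5),
moderate global (≈ 2), severe global (≈ 3–3.5), SD 0.5 — describe the
mild/moderate/severe strata a clinician would expect in an ABI
cohort; they are fixed defaults, not tuning knobs.

`simulate_execution()` gives each patient a latent ability per
subfunction, θ = (4 − impairment)/4 ∈ [0, 1]. A configuration at
normalized difficulty d (total weight over the task's maximum) scores

> E[score] = 100 · logistic(γ·(θ − d) + log 3)

plus Gaussian noise, clamped to [0, 100]. The offset log 3 makes a
perfectly matched difficulty (θ = d) score 75 in expectation — the
middle of the therapeutic band, encoding the premise that well-matched
difficulty is therapeutic by construction. After a therapeutic-range
execution θ on the designated subfunction grows by δ (learning happens
where training is effective); defaults γ = 6, noise SD = 8 points,
δ = 0.02. The POST profile is the inverse banding of the final θ.

What the simulator deliberately does *not* model: therapist manual
planning beyond a random baseline, fatigue or day-to-day variability,
transfer between subfunctions, and the clinical outcome percentages
reported for real cohorts. Passing closed-loop tests therefore shows
that the planner steers difficulty in the right direction under the
stated response model — not that clinical effect sizes are reproduced.

## Problem sizes and determinism

Every stochastic step flows from explicit integer seeds (cohort
generation, EM initialization and fold assignment, task and
configuration draws, execution noise), and identical seeds reproduce
entire closed-loop logs bit for bit. The shipped tests exercise
clustering recovery at 100–200 patients, quartile assignments against
brute-force oracles on a thousand random instances, and the v1-vs-v2
closed-loop comparison over 20 paired replicates of 6-patient,
2-block treatments on a 24-task catalog — sizes chosen to pin the
statistical behavior while keeping a full suite run under a minute.

## Known limitations

* The z→0–4 banding, the improvement-score formula, the
  impairment→DQ mapping and the GSS coefficients are declared package
  choices where no published values exist; all are config-overridable.
* EM uses diagonal covariances; strongly correlated impairment
  dimensions are summarized, not modeled.
* Automatic K via cross-validation refits the mixture 10·K times;
  for cohorts in the tens of thousands a fixed K is the practical
  route.
* The v1 planner recomputes suitability quartiles once upfront, not
  mid-treatment; the v2 planner re-plans difficulty but not
  suitability between blocks.
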