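#' Configuration for a synthetic patient cohort
#'
#' Synthetic cohorts emulate the clustered structure of impairment
#' profiles seen in acquired-brain-injury populations: each patient is
#' drawn from one of a few archetype profiles with independent Gaussian
#' noise, then clamped and rounded to the integer 0-4 scale. The default
#' archetypes describe a mildly impaired, a moderate mixed and a severely
#' impaired group.
#'
#' @param n number of patients.
#' @param archetypes list of archetype definitions, each a list with
#'   `mean` (numeric(11) in \[0, 4\]) and `sd` (> 0).
#' @param seed integer seed.
#' @param age_range min/max patient age in years.
#' @param education_levels labels sampled uniformly per patient.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n = 100L,
                          archetypes = default_archetypes(),
                          seed = 1L,
                          age_range = c(18, 70),
                          education_levels = c("primary", "secondary",
                                               "higher")) {
  for (a in archetypes) {
    if (length(a$mean) != 11L || any(a$mean < 0 | a$mean > 4))
      stop("archetype means must be 11 values in [0, 4]")
    if (a$sd <= 0) stop("archetype SD must be positive")
  }
  structure(list(n = as.integer(n), archetypes = archetypes,
                 seed = as.integer(seed), age_range = age_range,
                 education_levels = education_levels),
            class = "cohort_config")
}

#' Default cohort archetypes
#'
#' Three clinical archetypes: attention-dominant mild impairment,
#' moderate mixed impairment, and severe global impairment, with
#' within-archetype SD 0.5.
#' @return list of archetypes for [cohort_config()].
#' @export
default_archetypes <- function() {
  list(
    list(mean = c(1.5, 1.5, 1.5, 0.5, 0.5, 1.0, 0.5, 0.5, 0.5, 0.5, 0.5),
         sd = 0.5),
    list(mean = c(2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0, 2.0),
         sd = 0.5),
    list(mean = c(3.5, 3.0, 3.5, 3.0, 3.0, 3.5, 3.0, 3.0, 3.0, 3.0, 3.0),
         sd = 0.5)
  )
}

#' Generate a synthetic cohort of PRE profiles
#'
#' @param config a [cohort_config()].
#' @return data.frame with `patient_id`, `archetype` (the hidden
#'   generating label), `age`, `education` and one integer 0-4 column per
#'   subfunction; attribute `"profiles"` holds the corresponding list of
#'   [cognitive_profile()] objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sfn <- subfunction_names()
  n <- config$n
  arch <- sample.int(length(config$archetypes), n, replace = TRUE)
  m <- matrix(0L, n, 11L, dimnames = list(NULL, sfn))
  for (i in seq_len(n)) {
    a <- config$archetypes[[arch[i]]]
    v <- stats::rnorm(11L, a$mean, a$sd)
    m[i, ] <- as.integer(round(clamp(v, 0, 4)))
  }
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  edu <- sample(config$education_levels, n, replace = TRUE)
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    archetype = arch, age = age, education = edu,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m))
  attr(out, "profiles") <- lapply(seq_len(n), function(i)
    cognitive_profile(m[i, ], patient_id = out$patient_id[i]))
  out
}

#' Extract cognitive profiles from a cohort table
#' @param cohort data.frame from [generate_cohort()] or [read_cohort()].
#' @return list of [cognitive_profile()] objects.
#' @export
cohort_profiles <- function(cohort) {
  pr <- attr(cohort, "profiles")
  if (!is.null(pr)) return(pr)
  sfn <- subfunction_names()
  lapply(seq_len(nrow(cohort)), function(i)
    cognitive_profile(unlist(cohort[i, sfn]),
                      patient_id = cohort$patient_id[i]))
}

#' Patient response model for simulated task executions
#'
#' Each patient carries a latent ability per subfunction,
#' `theta = (4 - impairment) / 4` in \[0, 1\]. Executing a task at
#' normalized difficulty `d` (total configuration weight over the task's
#' maximum weight) yields an expected score
#' `100 * logistic(gamma * (theta - d) + offset)` plus Gaussian noise,
#' clamped to \[0, 100\]. The offset `log(3)` makes a perfectly matched
#' difficulty (`theta == d`) score 75 in expectation, the middle of the
#' therapeutic band. After a therapeutic-range execution the ability on
#' the task's designated subfunction grows by the learning increment
#' `delta` (capped at 1) — training in the therapeutic band is what
#' drives improvement.
#'
#' @param gamma slope of the logistic response (> 0).
#' @param noise_sd SD of the Gaussian score noise, in score points.
#' @param delta learning increment applied to theta after a
#'   therapeutic-range execution.
#' @param offset logistic offset; default `log(3)` centers matched
#'   difficulty on an expected score of 75.
#' @return an object of class `response_model`.
#' @export
response_model <- function(gamma = 6, noise_sd = 8, delta = 0.02,
                           offset = log(3)) {
  stopifnot(gamma > 0, noise_sd >= 0, delta >= 0)
  structure(list(gamma = gamma, noise_sd = noise_sd, delta = delta,
                 offset = offset), class = "response_model")
}

# latent abilities from a PRE profile
theta_from_profile <- function(profile) {
  (4 - profile$subfunctions) / 4
}

# inverse banding: abilities back to an integer impairment profile
profile_from_theta <- function(theta, patient_id = NA_character_) {
  cognitive_profile(as.integer(round(clamp(4 * (1 - theta), 0, 4))),
                    patient_id = patient_id)
}

#' Simulate one task execution
#'
#' @param theta named numeric(11) of current latent abilities.
#' @param task the task definition.
#' @param config named parameter values (as from [select_difficulty()]
#'   `$values` or a serialized string).
#' @param response a [response_model()].
#' @param dmodel optional precomputed [build_difficulty_model()] for the
#'   task (built on the fly if missing).
#' @return list with `score`, `range`, `d` (normalized difficulty) and
#'   `theta` (abilities after any learning update).
#' @export
simulate_execution <- function(theta, task, config, response,
                               dmodel = NULL) {
  if (is.null(dmodel)) dmodel <- build_difficulty_model(task)
  if (is.character(config)) config <- deserialize_config(config)
  w <- 0
  for (p in task$parameters) {
    vi <- match(as.character(config[[p$name]]), as.character(p$values))
    if (is.na(vi))
      stop("configuration value for '", p$name,
           "' outside the parameter space of task '", task$task_id, "'")
    w <- w + p$weights[vi]
  }
  d <- if (dmodel$max_weight > 0) w / dmodel$max_weight else 0
  th <- theta[[task$subfunction]]
  expected <- 100 * stats::plogis(response$gamma * (th - d) + response$offset)
  score <- clamp(expected + stats::rnorm(1L, 0, response$noise_sd), 0, 100)
  rng <- classify_range(score)
  if (rng == "therapeutic")
    theta[[task$subfunction]] <- min(1, th + response$delta)
  list(score = score, range = rng, d = d, theta = theta)
}

#' Run a closed-loop simulated treatment for a cohort
#'
#' Alternates session planning and simulated execution: for every
#' patient, blocks of sessions are planned from the scored catalog (with
#' running usage statistics feeding the usage score) and each scheduled
#' task is executed under the response model, updating latent abilities
#' after therapeutic-range executions. Version `"v1"` plans the whole
#' treatment upfront from the PRE profile only; `"v2"` re-plans every
#' block using the patient's mean execution result per subfunction.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param catalog task definition list.
#' @param version `"v1"` or `"v2"`.
#' @param n_blocks number of 10-session blocks per patient.
#' @param response a [response_model()].
#' @param seed integer seed for planning and execution noise.
#' @param block_size sessions per block.
#' @param session_minutes session length cap.
#' @param coeff a [rehab_coefficients()].
#' @return An object of class `rehab_run`: list with `log` (execution
#'   data.frame: `patient_id`, `task_id`, `session`, `config`, `score`,
#'   `range`), `pre` and `post` profile lists, `summary` (see
#'   [summarize_outcomes()]), `version` and `seed`.
#' @export
run_closed_loop <- function(cohort, catalog, version = c("v2", "v1"),
                            n_blocks = 6L, response = response_model(),
                            seed = 1L, block_size = 10L,
                            session_minutes = 60,
                            coeff = rehab_coefficients()) {
  version <- match.arg(version)
  profiles <- cohort_profiles(cohort)
  n <- length(profiles)
  ids <- task_ids(catalog)
  dmodels <- stats::setNames(lapply(catalog, build_difficulty_model), ids)
  designated <- stats::setNames(
    vapply(catalog, function(t) t$subfunction, character(1)), ids)
  logs <- list()
  post <- vector("list", n)
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    theta <- theta_from_profile(p)
    scores <- score_tasks(catalog, p, coeff = coeff)
    recs <- list()
    session0 <- 0L
    plan_v1 <- if (version == "v1")
      assemble_block(scores, catalog, p, mers = NULL, version = "v1",
                     block_size = n_blocks * block_size,
                     session_minutes = session_minutes,
                     seed = seed + 13L * i)
    for (b in seq_len(if (version == "v1") 1L else n_blocks)) {
      plan <- if (version == "v1") plan_v1
        else assemble_block(scores, catalog, p,
                            mers = compute_mers(
                              do.call(rbind, c(recs, list(NULL))) %||%
                                data.frame(task_id = character(0),
                                           score = numeric(0)),
                              designated),
                            version = "v2", block_size = block_size,
                            session_minutes = session_minutes,
                            seed = seed + 13L * i + 1000L * b)
      set.seed(seed + 13L * i + 1000L * b + 500000L)
      flat <- as.data.frame(plan)
      for (r in seq_len(nrow(flat))) {
        tid <- flat$task_id[r]
        task <- catalog[[match(tid, ids)]]
        ex <- simulate_execution(theta, task, flat$config[r], response,
                                 dmodel = dmodels[[tid]])
        theta <- ex$theta
        recs[[length(recs) + 1L]] <- data.frame(
          patient_id = p$patient_id, task_id = tid,
          session = session0 + flat$session[r], config = flat$config[r],
          score = ex$score, range = ex$range, stringsAsFactors = FALSE)
      }
      session0 <- session0 + length(plan$sessions)
    }
    logs[[i]] <- do.call(rbind, recs)
    post[[i]] <- profile_from_theta(theta, patient_id = p$patient_id)
  }
  log <- do.call(rbind, logs)
  structure(
    list(log = log, pre = profiles, post = post,
         summary = summarize_outcomes(log, profiles, post),
         version = version, seed = as.integer(seed)),
    class = "rehab_run"
  )
}

#' @export
print.rehab_run <- function(x, ...) {
  cat("Closed-loop simulated treatment (planner ", x$version, ")\n",
      sep = "")
  cat("  patients:", length(x$pre), " executions:", nrow(x$log), "\n")
  s <- x$summary
  cat(sprintf("  range fractions: infra %.3f / therapeutic %.3f / supra %.3f\n",
              s$fractions["infra"], s$fractions["therapeutic"],
              s$fractions["supra"]))
  cat(sprintf("  patients improved: %.1f%%\n", 100 * s$improvement_rate))
  invisible(x)
}

#' @export
plot.rehab_run <- function(x, ...) {
  rng <- factor(x$log$range, levels = c("infra", "therapeutic", "supra"))
  blk <- (x$log$session - 1) %/% 10 + 1
  tab <- prop.table(table(blk, rng), margin = 1)
  graphics::matplot(as.numeric(rownames(tab)), tab, type = "b",
                    pch = 19, lty = 1,
                    xlab = "session block", ylab = "fraction of executions",
                    main = paste("Execution ranges by block,", x$version),
                    ...)
  graphics::legend("topright", legend = colnames(tab), col = 1:3, pch = 19)
  invisible(tab)
}

#' Summarize execution ranges and patient improvement
#'
#' @param log execution log with a `range` column.
#' @param pre,post aligned lists of PRE and POST [cognitive_profile()]s.
#' @return list with `fractions` (named numeric over
#'   infra/therapeutic/supra, summing to 1), `n_executions` and
#'   `improvement_rate` (fraction of patients satisfying [improved()];
#'   `NA` when no profiles are given).
#' @export
summarize_outcomes <- function(log, pre = NULL, post = NULL) {
  log <- as.data.frame(log)
  if (nrow(log) == 0L) stop("cannot summarize an empty execution log")
  fr <- prop.table(table(factor(log$range,
                                levels = c("infra", "therapeutic",
                                           "supra"))))
  fr <- stats::setNames(as.numeric(fr), names(fr))
  rate <- NA_real_
  if (!is.null(pre) && !is.null(post)) {
    stopifnot(length(pre) == length(post))
    rate <- mean(mapply(improved, pre, post))
  }
  list(fractions = fr, n_executions = nrow(log), improvement_rate = rate)
}

#' Generate a synthetic task catalog
#'
#' Builds a catalog of rehabilitation task definitions with the
#' structure of the ABI catalog: each task targets one of the 11
#' subfunctions, carries a clinical-criteria vector concentrated on its
#' designated subfunction (and, more weakly, its siblings within the same
#' cognitive function), 2-3 difficulty parameters whose easiest value has
#' weight 0, and a nominal duration of 5-12 minutes.
#'
#' @param n number of tasks (default 95, the size of the ABI catalog).
#' @param seed integer seed.
#' @return list of task definitions as from [read_task_catalog()].
#' @export
generate_task_catalog <- function(n = 95L, seed = 1L) {
  set.seed(seed)
  tx <- rehab_taxonomy()
  sfn <- names(tx$subfunctions)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    des <- sfn[(i - 1L) %% 11L + 1L]
    cc <- stats::setNames(rep(0L, 11L), sfn)
    cc[des] <- sample(3:4, 1L)
    sibs <- setdiff(sfn[tx$subfunctions == tx$subfunctions[[des]]], des)
    for (s in sibs) cc[s] <- sample(0:2, 1L)
    npar <- sample(2:3, 1L)
    pars <- lapply(seq_len(npar), function(j) {
      nv <- sample(2:5, 1L)
      list(name = paste0("param", j),
           values = as.character(seq_len(nv)),
           weights = 0:(nv - 1L))
    })
    out[[i]] <- list(
      task_id = sprintf("T%03d", i),
      name = paste0("task ", i, " (", des, ")"),
      subfunction = des, cc = cc,
      parameters = pars,
      duration = sample(5:12, 1L))
  }
  out
}
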