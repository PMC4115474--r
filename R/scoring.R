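#' Scoring coefficients for the global suitability score
#'
#' The four task-rating criteria are combined as a weighted sum
#' `GSS = U*ku + I*ki + ILCC*kc`; the improvement criterion itself weighs
#' the designated-subfunction gain against gains on the other two
#' functions via `w_primary` and `w_other`. The weights exist so
#' clinicians can tilt the ranking toward the criteria they trust most;
#' the defaults weigh the three criteria equally and count collateral
#' improvement at half the designated one.
#'
#' @param ku,ki,kc non-negative weights of the usage, improvement and
#'   clinical scores (not all zero).
#' @param w_primary,w_other non-negative weights inside the improvement
#'   score.
#' @return an object of class `rehab_coefficients`.
#' @export
rehab_coefficients <- function(ku = 1, ki = 1, kc = 1,
                               w_primary = 1, w_other = 0.5) {
  vals <- c(ku = ku, ki = ki, kc = kc,
            w_primary = w_primary, w_other = w_other)
  if (any(vals < 0)) stop("coefficients must be non-negative")
  if (ku == 0 && ki == 0 && kc == 0)
    stop("at least one of ku, ki, kc must be positive")
  structure(as.list(vals), class = "rehab_coefficients")
}

# split n ranked items into 4 contiguous groups as equal as possible,
# earlier (better) groups taking the remainder; returns the 4 sizes
quartile_sizes <- function(n) {
  base <- n %/% 4L
  base + as.integer(seq_len(4L) <= n %% 4L)
}

#' Usage score: how often the patient's cluster used each task
#'
#' Tasks never executed by the cluster score 0. Used tasks are ranked by
#' descending execution count and split into four contiguous groups, as
#' equal as possible with earlier groups taking the remainder; the most
#' used group scores 4 down to 1 for the least used. Tasks with equal
#' counts all receive the best score any of them occupies.
#'
#' @param tasks character vector of task ids (the catalog), or a list of
#'   task definitions from [read_task_catalog()].
#' @param cluster_log execution log restricted to the patient's cluster:
#'   a data.frame with at least a `task_id` column (one row per
#'   execution), or an empty/NULL log.
#' @return named integer vector, a 0-4 score per task id.
#' @export
usage_score <- function(tasks, cluster_log = NULL) {
  ids <- task_ids(tasks)
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  if (!is.null(cluster_log) && nrow(as.data.frame(cluster_log)) > 0) {
    tab <- table(factor(as.character(cluster_log$task_id), levels = ids))
    counts[names(tab)] <- as.integer(tab)
  }
  score <- stats::setNames(rep(0L, length(ids)), ids)
  used <- names(counts)[counts > 0L]
  if (length(used) == 0L) return(score)
  used <- used[order(-counts[used], used)]
  grp <- rep.int(1:4, quartile_sizes(length(used)))
  # ties on count: promote to the best occupied group
  for (cnt in unique(counts[used]))
    grp[counts[used] == cnt] <- min(grp[counts[used] == cnt])
  score[used] <- 5L - grp
  score
}

#' Task identifiers of a catalog
#' @param tasks a list of task definitions, or already a character vector
#'   of ids (returned unchanged).
#' @return character vector of task ids.
#' @export
task_ids <- function(tasks) {
  if (is.character(tasks)) return(tasks)
  vapply(tasks, function(t) t$task_id, character(1))
}

#' Improvement score: PRE to POST gains of similar patients on the task
#'
#' Over the patients of the cluster who executed the task, the mean
#' PRE minus POST drop in impairment on the task's designated subfunction
#' (`delta_primary`) is combined with the mean function-level drop on the
#' two cognitive functions the task was not designed for (`delta_other`):
#' `I = clamp(w_primary * delta_primary + w_other * delta_other, 0, 4)`.
#' Zero when no cluster patient executed the task.
#'
#' @param task a task definition (needs `task_id` and `subfunction`).
#' @param cluster_outcomes list of outcomes for the cluster's patients;
#'   each element a list with `pre` and `post` ([cognitive_profile()])
#'   and `tasks`, the character ids of tasks that patient executed.
#' @param coeff a [rehab_coefficients()] object.
#' @return numeric score in \[0, 4\].
#' @export
improvement_score <- function(task, cluster_outcomes,
                              coeff = rehab_coefficients()) {
  tx <- rehab_taxonomy()
  des <- task$subfunction
  fun <- tx$subfunctions[[des]]
  others <- setdiff(tx$functions, fun)
  dp <- numeric(0); do_ <- numeric(0)
  for (o in cluster_outcomes) {
    if (!task$task_id %in% o$tasks) next
    dp <- c(dp, o$pre$subfunctions[[des]] - o$post$subfunctions[[des]])
    do_ <- c(do_, mean(o$pre$functions[others] - o$post$functions[others]))
  }
  if (length(dp) == 0L) return(0)
  unname(clamp(coeff$w_primary * mean(dp) + coeff$w_other * mean(do_), 0, 4))
}

#' Clinical score: impairment level crossed with clinical criteria
#'
#' The sum over the 11 subfunctions of the patient's impairment level
#' times the task's clinical-criteria value, i.e. the dot product of the
#' two vectors. Rewards tasks rated suitable for exactly the subfunctions
#' where the patient is most impaired.
#'
#' @param profile the patient's [cognitive_profile()].
#' @param task a task definition with a `cc` vector (0-4 per subfunction).
#' @return integer score (>= 0).
#' @examples
#' p <- cognitive_profile(c(3, 2, 3, 2, 1, 3, 1, 0, 1, 2, 0))
#' bingo_cc <- c(4, 2, 1, rep(0, 8))
#' t <- list(task_id = "bingo", subfunction = "sustained", cc = bingo_cc)
#' clinical_score(p, t)   # 12 + 4 + 3 = 19
#' @export
clinical_score <- function(profile, task) {
  cc <- task$cc
  if (length(cc) != 11L) stop("clinical-criteria vector must have length 11")
  if (!is.null(names(cc))) cc <- cc[subfunction_names()]
  as.integer(sum(profile$subfunctions * cc))
}

#' Global suitability score
#'
#' Weighted sum of the usage, improvement and clinical scores:
#' `GSS = U*ku + I*ki + ILCC*kc`.
#'
#' @param U usage score (0-4).
#' @param I improvement score (0-4).
#' @param ILCC clinical score (>= 0).
#' @param coeff a [rehab_coefficients()].
#' @return numeric.
#' @export
global_suitability <- function(U, I, ILCC, coeff = rehab_coefficients()) {
  U * coeff$ku + I * coeff$ki + ILCC * coeff$kc
}

#' Split scored tasks into suitability quartiles
#'
#' Tasks are ordered by descending global suitability score (ties broken
#' by ascending task id) and split into four contiguous groups, as equal
#' as possible with earlier groups taking the remainder: SQ1 holds the
#' most suitable tasks down to SQ4 the least suitable.
#'
#' @param scores a data.frame with columns `task_id` and `GSS` (one row
#'   per catalog task).
#' @return the input data.frame with an integer `SQ` column (1-4) added,
#'   in the original row order.
#' @export
suitability_quartiles <- function(scores) {
  scores <- as.data.frame(scores)
  n <- nrow(scores)
  if (n == 0L) stop("cannot build suitability quartiles from an empty list")
  ord <- order(-scores$GSS, as.character(scores$task_id))
  sq <- integer(n)
  sq[ord] <- rep.int(1:4, quartile_sizes(n))
  scores$SQ <- sq
  scores
}

#' Rate a full task catalog for one patient
#'
#' Computes the four criteria and the global suitability score for every
#' task in the catalog, then assigns suitability quartiles.
#'
#' @param catalog list of task definitions ([read_task_catalog()]).
#' @param profile the patient's [cognitive_profile()].
#' @param cluster_log execution log of the patient's cluster (see
#'   [usage_score()]); `NULL` when no history exists.
#' @param cluster_outcomes PRE/POST outcomes of the cluster (see
#'   [improvement_score()]); `NULL` when no history exists.
#' @param coeff a [rehab_coefficients()].
#' @return data.frame with one row per task: `task_id`, `U`, `I`, `ILCC`,
#'   `GSS`, `SQ`.
#' @export
score_tasks <- function(catalog, profile, cluster_log = NULL,
                        cluster_outcomes = NULL,
                        coeff = rehab_coefficients()) {
  U <- usage_score(catalog, cluster_log)
  I <- vapply(catalog, function(t) {
    if (is.null(cluster_outcomes)) 0
    else improvement_score(t, cluster_outcomes, coeff)
  }, numeric(1))
  ILCC <- vapply(catalog, clinical_score, integer(1), profile = profile)
  out <- data.frame(task_id = task_ids(catalog), U = unname(U),
                    I = unname(I), ILCC = ILCC,
                    stringsAsFactors = FALSE)
  out$GSS <- global_suitability(out$U, out$I, out$ILCC, coeff)
  suitability_quartiles(out)
}
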