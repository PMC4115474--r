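#' Classify an execution score into a therapeutic range
#'
#' A task execution scoring between 65 and 85 (inclusive) sits in the
#' therapeutic range, where difficulty matches capacity and treatment is
#' most effective. Below 65 is infra-therapeutic (too hard, risks
#' frustration); above 85 supra-therapeutic (too easy, insufficient
#' activation). The boundary scores are counted as therapeutic so the
#' three ranges partition \[0, 100\].
#'
#' @param score numeric vector of execution scores in \[0, 100\].
#' @param low,high therapeutic band limits (defaults 65 and 85).
#' @return character vector in `c("infra", "therapeutic", "supra")`.
#' @examples
#' classify_range(c(64, 65, 70, 85, 86))
#' @export
classify_range <- function(score, low = 65, high = 85) {
  if (any(is.na(score)) || any(score < 0 | score > 100))
    stop("execution scores must lie in [0, 100]")
  ifelse(score < low, "infra", ifelse(score <= high, "therapeutic", "supra"))
}

#' Enumerate a task's difficulty configurations and quartiles
#'
#' Every combination of the task's parameter values is a configuration;
#' its total difficulty weight is the sum of the per-value weights (0 =
#' easiest value of each parameter). Configurations are sorted by
#' ascending total weight (ties by the parameter values' lexicographic
#' order) and split into four contiguous near-equal difficulty quartiles,
#' DQ1 (easiest) to DQ4 (hardest), earlier quartiles taking the
#' remainder.
#'
#' @param task a task definition with a `parameters` list; each parameter
#'   has `name`, `values` and integer `weights` (same length as values,
#'   minimum 0).
#' @return An object of class `difficulty_model`: list with `task_id`,
#'   `configs` (data.frame: one column per parameter holding the value
#'   index, plus `weight` and `dq`), `values` (the per-parameter value
#'   lists) and `max_weight`.
#' @export
build_difficulty_model <- function(task) {
  pars <- task$parameters
  if (length(pars) < 1L) stop("task '", task$task_id, "' has no parameters")
  idx <- lapply(pars, function(p) seq_along(p$values))
  names(idx) <- vapply(pars, function(p) p$name, character(1))
  grid <- rev(expand.grid(rev(idx), KEEP.OUT.ATTRS = FALSE))
  w <- rep(0L, nrow(grid))
  for (j in seq_along(pars))
    w <- w + as.integer(pars[[j]]$weights[grid[[j]]])
  ord <- do.call(order, c(list(w), as.list(grid)))
  grid <- grid[ord, , drop = FALSE]
  w <- w[ord]
  dq <- rep.int(1:4, quartile_sizes(nrow(grid)))
  configs <- cbind(grid, weight = w, dq = dq)
  rownames(configs) <- NULL
  structure(
    list(task_id = task$task_id, configs = configs,
         values = stats::setNames(lapply(pars, function(p) p$values),
                                  names(idx)),
         max_weight = sum(vapply(pars, function(p) max(p$weights),
                                 numeric(1)))),
    class = "difficulty_model"
  )
}

#' @export
print.difficulty_model <- function(x, ...) {
  cat("Difficulty model for task", x$task_id, "-",
      nrow(x$configs), "configurations, DQ sizes",
      paste(tabulate(x$configs$dq, 4L), collapse = "/"), "\n")
  invisible(x)
}

#' Resolve a difficulty-model row into concrete parameter values
#' @param model a [build_difficulty_model()] object.
#' @param row a one-row slice of `model$configs`.
#' @return named list of parameter values.
#' @export
config_values <- function(model, row) {
  pn <- names(model$values)
  stats::setNames(
    lapply(seq_along(pn), function(j) model$values[[j]][[row[[pn[j]]]]]),
    pn)
}

#' Mean execution result per subfunction (MERS)
#'
#' The running average score of every already-executed task, grouped by
#' the subfunction each task was designed for. Subfunctions with no
#' executions yet are `NA`.
#'
#' @param log execution log data.frame with `task_id` and `score`.
#' @param catalog list of task definitions (for the task to subfunction
#'   mapping), or a named character vector task_id -> subfunction.
#' @return named numeric(11): mean score per subfunction, `NA` where
#'   nothing was executed.
#' @export
compute_mers <- function(log, catalog) {
  des <- if (is.character(catalog)) catalog
         else stats::setNames(
           vapply(catalog, function(t) t$subfunction, character(1)),
           task_ids(catalog))
  sfn <- subfunction_names()
  mers <- stats::setNames(rep(NA_real_, length(sfn)), sfn)
  log <- as.data.frame(log)
  if (nrow(log) == 0L) return(mers)
  if (any(log$score < 0 | log$score > 100))
    stop("execution scores must lie in [0, 100]")
  sf <- des[as.character(log$task_id)]
  agg <- tapply(log$score, factor(sf, levels = sfn), mean)
  mers[!is.na(agg)] <- agg[!is.na(agg)]
  mers
}

#' Adjust a PRE impairment level by running performance
#'
#' Between 10-session blocks the planner revises each subfunction's
#' impairment level using the mean execution result for that subfunction
#' (MERS): infra-therapeutic performance (MERS < 65) adds one level
#' (easier tasks needed); therapeutic performance subtracts one (the
#' patient is progressing); supra-therapeutic (MERS > 85) subtracts two
#' (tasks are too easy). The result is clamped to the 0-4 scale, and the
#' PRE value is kept unchanged where no execution history exists.
#'
#' @param pre_value integer PRE impairment level(s) in 0..4.
#' @param mers numeric MERS value(s) in \[0, 100\], or `NA` when the
#'   subfunction has no executions.
#' @return integer impairment level(s) in 0..4.
#' @examples
#' adjusted_impairment(3, c(NA, 50, 70, 90))   # 3 4 2 1
#' @export
adjusted_impairment <- function(pre_value, mers) {
  if (any(pre_value < 0 | pre_value > 4))
    stop("PRE impairment levels must lie in 0..4")
  delta <- ifelse(is.na(mers), 0L,
           ifelse(mers < 65, 1L, ifelse(mers <= 85, -1L, -2L)))
  as.integer(clamp(pre_value + delta, 0L, 4L))
}

#' Select a task configuration for a given impairment level
#'
#' The (adjusted) impairment level on the task's designated subfunction
#' maps to a target difficulty quartile as `DQ = clamp(4 - level, 1, 4)`:
#' the most impaired patients get the easiest quartile and unimpaired
#' patients the hardest. A configuration is drawn uniformly from the
#' target quartile (falling to the nearest non-empty quartile, easier
#' side first, for tasks with fewer than four distinct configurations).
#'
#' @param task the task definition.
#' @param model its [build_difficulty_model()].
#' @param adj_impairment integer 0..4.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return list with `values` (named parameter values), `dq`, `weight`
#'   and `row` (index into `model$configs`).
#' @export
select_difficulty <- function(task, model, adj_impairment, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- clamp(4L - as.integer(adj_impairment), 1L, 4L)
  present <- sort(unique(model$configs$dq))
  if (!target %in% present)
    target <- present[which.min(abs(present - target) +
                                  0.1 * (present > target))]
  rows <- which(model$configs$dq == target)
  # always consume exactly one draw so parallel planning runs that differ
  # only in the target quartile keep their RNG streams aligned
  row <- rows[sample.int(length(rows), 1L)]
  cfg <- model$configs[row, , drop = FALSE]
  list(values = config_values(model, cfg), dq = cfg$dq,
       weight = cfg$weight, row = row)
}

#' Assemble a block of rehabilitation sessions
#'
#' Tasks are drawn cyclically from the suitability quartiles in the order
#' 3 x SQ1, 2 x SQ2, 2 x SQ3, 1 x SQ4 (rewarding the most suitable tasks
#' without abandoning the rest), uniformly without replacement within a
#' session and with replacement across sessions. A session closes when
#' the next drawn task would exceed the session length. Each scheduled
#' task gets a difficulty configuration from the patient's impairment on
#' the task's designated subfunction: version `"v1"` uses the raw PRE
#' level for the whole treatment, version `"v2"` first adjusts it by the
#' patient's running performance ([adjusted_impairment()] with the
#' supplied MERS state).
#'
#' @param scores scored catalog with suitability quartiles, from
#'   [score_tasks()] (columns `task_id`, `SQ`).
#' @param catalog the task definition list.
#' @param profile the patient's [cognitive_profile()].
#' @param mers named MERS vector from [compute_mers()] (ignored under
#'   `"v1"`; `NULL` means no history).
#' @param version `"v1"` (PRE only) or `"v2"` (PRE adjusted by MERS).
#' @param block_size number of sessions in the block (default 10).
#' @param session_minutes session length cap in minutes (default 60).
#' @param seed integer seed driving all draws.
#' @return An object of class `block_plan`: list with `sessions` (list of
#'   data.frames: `position`, `task_id`, `sq`, `dq`, `duration`, `config`
#'   serialized as `name=value;...`), `version`, `draw_quartiles`
#'   (requested vs used quartile per emitted entry) and `fallthroughs`.
#' @export
assemble_block <- function(scores, catalog, profile, mers = NULL,
                           version = c("v2", "v1"), block_size = 10L,
                           session_minutes = 60, seed = 1L) {
  version <- match.arg(version)
  if (nrow(scores) == 0L) stop("empty scored catalog")
  set.seed(seed)
  cat_by_id <- stats::setNames(catalog, task_ids(catalog))
  dmodels <- lapply(cat_by_id, build_difficulty_model)
  durations <- vapply(cat_by_id, function(t) t$duration, numeric(1))
  sq_of <- stats::setNames(scores$SQ, as.character(scores$task_id))
  if (is.null(mers))
    mers <- stats::setNames(rep(NA_real_, 11L), subfunction_names())

  cycle <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L)
  pos <- 0L
  sessions <- vector("list", block_size)
  draw_log <- list()
  fallthroughs <- 0L
  for (s in seq_len(block_size)) {
    dur <- 0
    rows <- list()
    in_session <- character(0)
    repeat {
      q_ask <- cycle[pos %% 8L + 1L]
      q_use <- NA_integer_
      avail <- NULL
      for (off in 0:3) {           # fall through to the next non-empty SQ
        q <- (q_ask - 1L + off) %% 4L + 1L
        cand <- names(sq_of)[sq_of == q & !names(sq_of) %in% in_session]
        if (length(cand)) { q_use <- q; avail <- cand; break }
      }
      if (is.na(q_use)) break     # whole catalog already in this session
      tid <- avail[sample.int(length(avail), 1L)]
      if (dur + durations[[tid]] > session_minutes) break
      if (q_use != q_ask) fallthroughs <- fallthroughs + 1L
      task <- cat_by_id[[tid]]
      pre_v <- profile$subfunctions[[task$subfunction]]
      adj <- if (version == "v1") pre_v
             else adjusted_impairment(pre_v, mers[[task$subfunction]])
      cfg <- select_difficulty(task, dmodels[[tid]], adj)
      rows[[length(rows) + 1L]] <- data.frame(
        position = length(rows) + 1L, task_id = tid, sq = q_use,
        dq = cfg$dq, duration = durations[[tid]],
        config = serialize_config(cfg$values),
        stringsAsFactors = FALSE)
      draw_log[[length(draw_log) + 1L]] <-
        c(asked = q_ask, used = q_use)
      in_session <- c(in_session, tid)
      dur <- dur + durations[[tid]]
      pos <- pos + 1L
    }
    sessions[[s]] <- if (length(rows)) do.call(rbind, rows)
                     else data.frame(position = integer(0),
                                     task_id = character(0),
                                     sq = integer(0), dq = integer(0),
                                     duration = numeric(0),
                                     config = character(0))
  }
  structure(
    list(sessions = sessions, version = version,
         session_minutes = session_minutes, seed = seed,
         draw_quartiles = if (length(draw_log)) do.call(rbind, draw_log)
                          else matrix(integer(0), 0, 2),
         fallthroughs = fallthroughs),
    class = "block_plan"
  )
}

#' @export
print.block_plan <- function(x, ...) {
  n_entries <- sum(vapply(x$sessions, nrow, integer(1)))
  cat("Rehabilitation block plan (", x$version, "): ",
      length(x$sessions), " sessions, ", n_entries, " task assignments\n",
      sep = "")
  if (x$fallthroughs > 0L)
    cat("  quartile fall-throughs:", x$fallthroughs, "\n")
  invisible(x)
}

#' @export
as.data.frame.block_plan <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$sessions), function(s) {
    df <- x$sessions[[s]]
    if (nrow(df) == 0L) return(NULL)
    cbind(session = s, df)
  }))
  if (is.null(out))
    out <- data.frame(session = integer(0), position = integer(0),
                      task_id = character(0), sq = integer(0),
                      dq = integer(0), duration = numeric(0),
                      config = character(0))
  rownames(out) <- NULL
  out
}

#' Serialize / parse a task configuration
#'
#' Configurations travel through plan and log CSVs as
#' `name=value;name=value` strings.
#' @param values named list of parameter values.
#' @return `serialize_config`: a single string; `deserialize_config`:
#'   a named list of character values.
#' @export
serialize_config <- function(values) {
  paste(vapply(names(values),
               function(n) paste0(n, "=", values[[n]]), character(1)),
        collapse = ";")
}

#' @rdname serialize_config
#' @param s a serialized configuration string.
#' @export
deserialize_config <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[2]),
                  vapply(parts, function(p) p[1], character(1)))
}

#' Re-launch an out-of-range task execution
#'
#' When an execution falls outside the therapeutic range the task is
#' queued again in the next session with room for it, one difficulty
#' quartile easier after an infra-therapeutic score and one harder after
#' a supra-therapeutic score (clamped to DQ1..DQ4). Therapeutic
#' executions leave the plan unchanged.
#'
#' @param record one execution: list or one-row data.frame with
#'   `task_id`, `session` (index in the block), `score`, `config`
#'   (serialized configuration).
#' @param model the task's [build_difficulty_model()].
#' @param block the current `block_plan`.
#' @param catalog task definitions (for the duration of the task).
#' @param step difficulty quartile step size (default 1).
#' @param seed optional seed for the draw within the new quartile.
#' @return the updated `block_plan` (invisibly unchanged when no open
#'   session can take the task).
#' @export
relaunch <- function(record, model, block, catalog, step = 1L,
                     seed = NULL) {
  rng <- classify_range(record$score)
  if (rng == "therapeutic") return(block)
  cur_dq <- config_dq(model, deserialize_config(record$config))
  new_dq <- clamp(cur_dq + if (rng == "infra") -step else step, 1L, 4L)
  present <- sort(unique(model$configs$dq))
  if (!new_dq %in% present)
    new_dq <- present[which.min(abs(present - new_dq))]
  if (!is.null(seed)) set.seed(seed)
  rows <- which(model$configs$dq == new_dq)
  row <- rows[sample.int(length(rows), 1L)]
  cfg <- model$configs[row, , drop = FALSE]
  dur <- catalog_duration(catalog, record$task_id)
  for (s in seq(from = record$session + 1L, length.out =
                  max(0L, length(block$sessions) - record$session))) {
    df <- block$sessions[[s]]
    if (record$task_id %in% df$task_id) next
    if (sum(df$duration) + dur > block$session_minutes) next
    block$sessions[[s]] <- rbind(df, data.frame(
      position = nrow(df) + 1L, task_id = record$task_id,
      sq = NA_integer_, dq = cfg$dq, duration = dur,
      config = serialize_config(config_values(model, cfg)),
      stringsAsFactors = FALSE))
    return(block)
  }
  message("relaunch: no open session can take task ", record$task_id)
  block
}

# find the DQ of a concrete configuration (values matched as characters)
config_dq <- function(model, values) {
  pn <- names(model$values)
  row_idx <- rep(TRUE, nrow(model$configs))
  for (p in pn) {
    vi <- match(as.character(values[[p]]),
                as.character(unlist(model$values[[p]])))
    if (is.na(vi)) stop("configuration value for '", p,
                        "' not in the task's parameter space")
    row_idx <- row_idx & model$configs[[p]] == vi
  }
  r <- which(row_idx)
  if (length(r) != 1L) stop("configuration does not identify a unique row")
  model$configs$dq[r]
}

catalog_duration <- function(catalog, task_id) {
  for (t in catalog) if (t$task_id == task_id) return(t$duration)
  stop("task '", task_id, "' not in catalog")
}
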