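#' Read a task catalog from JSON
#'
#' The catalog is a JSON array of task objects with fields `task_id`,
#' `name`, `subfunction` (one of the 11 taxonomy subfunctions), `cc`
#' (11 clinical-criteria integers 0-4, taxonomy order), `parameters`
#' (array of objects with `name`, `values`, `weights`) and `duration`
#' (minutes). All task invariants are validated on read: the designated
#' subfunction's clinical-criteria value must be positive, every
#' parameter needs at least one value, per-value weights are
#' non-negative integers and the easiest value of each parameter has
#' weight 0.
#'
#' @param path path to the JSON file.
#' @return list of task definition lists.
#' @export
read_task_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0L) stop("task catalog is empty")
  lapply(raw, validate_task)
}

#' Validate one task definition
#' @param t a task definition list.
#' @return the validated task (with `cc` named and coerced to integer).
#' @export
validate_task <- function(t) {
  id <- t$task_id
  if (is.null(id) || !nzchar(id)) stop("task with missing task_id")
  sfn <- subfunction_names()
  if (is.null(t$subfunction) || !t$subfunction %in% sfn)
    stop("task '", id, "': field subfunction must be one of the 11 ",
         "taxonomy subfunctions")
  cc <- unlist(t$cc)
  if (length(cc) != 11L)
    stop("task '", id, "': field cc must have 11 values")
  if (is.null(names(cc)) || !setequal(names(cc), sfn)) {
    names(cc) <- sfn
  } else {
    cc <- cc[sfn]
  }
  if (any(cc != as.integer(cc)) || any(cc < 0L | cc > 4L))
    stop("task '", id, "': field cc values must be integers in 0..4")
  if (cc[[t$subfunction]] == 0L)
    stop("task '", id, "': field cc must be positive for the ",
         "designated subfunction")
  if (length(t$parameters) < 1L)
    stop("task '", id, "': field parameters must list at least one ",
         "parameter")
  t$parameters <- lapply(t$parameters, function(p) {
    if (is.null(p$name)) stop("task '", id, "': parameter without a name")
    vals <- unlist(p$values)
    w <- unlist(p$weights)
    if (length(vals) < 1L)
      stop("task '", id, "': field parameters/", p$name,
           " needs at least one value")
    if (length(w) != length(vals))
      stop("task '", id, "': field parameters/", p$name,
           " weights and values differ in length")
    if (any(w != as.integer(w)) || any(w < 0))
      stop("task '", id, "': field parameters/", p$name,
           " weights must be non-negative integers")
    if (min(w) != 0L)
      stop("task '", id, "': field parameters/", p$name,
           " must give weight 0 to its easiest value")
    list(name = p$name, values = vals, weights = as.integer(w))
  })
  dur <- t$duration
  if (is.null(dur) || !is.numeric(dur) || dur <= 0)
    stop("task '", id, "': field duration must be a positive number ",
         "of minutes")
  list(task_id = id, name = t$name %||% id, subfunction = t$subfunction,
       cc = stats::setNames(as.integer(cc), sfn),
       parameters = t$parameters, duration = as.numeric(dur))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a task catalog to JSON
#' @param catalog list of task definitions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_task_catalog <- function(catalog, path) {
  out <- lapply(catalog, function(t) {
    t$cc <- as.list(t$cc)
    t
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read or write a patient cohort CSV
#'
#' One row per patient-assessment: `patient_id`, `timepoint` (`PRE` or
#' `POST`), `age`, `education`, then one column per subfunction in
#' taxonomy order. The `scale` argument declares whether the subfunction
#' columns hold integer 0-4 impairment levels (`"level"`, the default)
#' or z-scores (`"z"`, banded on read with [band_impairment()]); cohorts
#' with pre-banded levels bypass normalization entirely.
#'
#' @param path CSV file path.
#' @param scale `"level"` or `"z"`.
#' @return data.frame with the columns above, subfunction columns always
#'   integer 0-4.
#' @export
read_cohort <- function(path, scale = c("level", "z")) {
  scale <- match.arg(scale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "age", "education",
            subfunction_names())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  for (s in subfunction_names()) {
    v <- df[[s]]
    if (scale == "z") v <- band_impairment(v)
    if (any(v != as.integer(v)) || any(v < 0L | v > 4L))
      stop("cohort column '", s, "' holds values outside 0..4")
    df[[s]] <- as.integer(v)
  }
  df
}

#' @rdname read_cohort
#' @param cohort cohort data.frame (as from [generate_cohort()], with a
#'   `timepoint` column added if absent — defaults to `PRE`).
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  if (is.null(df$timepoint)) df$timepoint <- "PRE"
  keep <- c("patient_id", "timepoint", "age", "education",
            subfunction_names())
  extra <- setdiff(keep, names(df))
  if (length(extra))
    stop("cohort table is missing column(s): ", paste(extra, collapse = ", "))
  utils::write.csv(df[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write an execution log CSV
#'
#' Columns `patient_id`, `task_id`, `session`, `config` (serialized as
#' `name=value;...`), `score`, `range`. On read, scores must lie in
#' \[0, 100\] and the stored range must equal the range recomputed from
#' the score; violations raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @return data.frame of execution records.
#' @export
read_execution_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "task_id", "session", "config", "score", "range")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("execution log is missing column(s): ",
         paste(miss, collapse = ", "))
  df$score <- as.numeric(df$score)
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 100)
  if (length(bad))
    stop("execution log row ", bad[1], ": score ", df$score[bad[1]],
         " outside [0, 100]")
  recomputed <- classify_range(df$score)
  bad <- which(recomputed != df$range)
  if (length(bad))
    stop("execution log row ", bad[1], ": range '", df$range[bad[1]],
         "' inconsistent with score ", df$score[bad[1]],
         " (expected '", recomputed[bad[1]], "')")
  df
}

#' @rdname read_execution_log
#' @param log execution log data.frame.
#' @export
write_execution_log <- function(log, path) {
  keep <- c("patient_id", "task_id", "session", "config", "score", "range")
  utils::write.csv(as.data.frame(log)[keep], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a normative map from JSON
#'
#' The normative map supplies, per neuropsychological test item, the
#' subfunction it measures and the normative mean and SD stratified by
#' age band (e.g. `"16-35"`, `"56+"`) and education level. It is a
#' configuration input: the clinical normalization tables themselves are
#' proprietary, so deployments supply their own.
#'
#' @param path JSON file keyed by item id.
#' @return named list usable by [normalize_assessment()].
#' @export
read_normative_map <- function(path) {
  norms <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (id in names(norms)) {
    e <- norms[[id]]
    if (is.null(e$subfunction) || is.null(e$norms))
      stop("normative entry for item '", id,
           "' needs 'subfunction' and 'norms'")
    for (band in names(e$norms))
      for (ed in names(e$norms[[band]])) {
        st <- e$norms[[band]][[ed]]
        if (is.null(st$sd) || st$sd <= 0)
          stop("non-positive normative SD for item '", id, "', band '",
               band, "', education '", ed, "'")
      }
  }
  norms
}

#' Read a run configuration
#'
#' JSON file holding the tunable settings of a planning run; missing
#' keys fall back to the package defaults. Validated keys:
#' `therapeutic_low` < `therapeutic_high`, both in (0, 100).
#'
#' @param path JSON file path, or `NULL` for all defaults.
#' @return a named list with `coefficients` (a [rehab_coefficients()]),
#'   `therapeutic_low`, `therapeutic_high`, `session_minutes`,
#'   `block_size`, `version`, `seed`, `relaunch_step`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(ku = 1, ki = 1, kc = 1, w_primary = 1, w_other = 0.5,
              therapeutic_low = 65, therapeutic_high = 85,
              session_minutes = 60, block_size = 10L, version = "v2",
              seed = 1L, relaunch_step = 1L)
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  if (!(cfg$therapeutic_low > 0 && cfg$therapeutic_high < 100 &&
        cfg$therapeutic_low < cfg$therapeutic_high))
    stop("therapeutic_low must be < therapeutic_high, both in (0, 100)")
  list(coefficients = rehab_coefficients(cfg$ku, cfg$ki, cfg$kc,
                                         cfg$w_primary, cfg$w_other),
       therapeutic_low = cfg$therapeutic_low,
       therapeutic_high = cfg$therapeutic_high,
       session_minutes = cfg$session_minutes,
       block_size = as.integer(cfg$block_size),
       version = cfg$version, seed = as.integer(cfg$seed),
       relaunch_step = as.integer(cfg$relaunch_step))
}
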