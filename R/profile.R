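#' Construct a cognitive impairment profile
#'
#' A cognitive profile rates each of the 11 subfunctions on an integer
#' 0 (normality) to 4 (very severe impairment) scale, plus an aggregate
#' impairment level per cognitive function (mean of its subfunctions,
#' rounded half-up).
#'
#' @param subfunctions numeric(11), integer values in 0..4, either named by
#'   subfunction or given in the canonical taxonomy order.
#' @param patient_id optional identifier carried along with the profile.
#' @return An object of class `cognitive_profile`: a list with integer
#'   vectors `subfunctions` (length 11) and `functions` (length 3), and
#'   `patient_id`.
#' @examples
#' p <- cognitive_profile(c(3, 2, 3, 2, 1, 3, 1, 0, 1, 2, 0))
#' p$functions
#' @export
cognitive_profile <- function(subfunctions, patient_id = NA_character_) {
  tx <- rehab_taxonomy()
  sfn <- names(tx$subfunctions)
  if (length(subfunctions) != 11L)
    stop("a cognitive profile needs 11 subfunction values, got ",
         length(subfunctions))
  if (is.null(names(subfunctions))) {
    names(subfunctions) <- sfn
  } else {
    if (!setequal(names(subfunctions), sfn))
      stop("subfunction names do not match the taxonomy")
    subfunctions <- subfunctions[sfn]
  }
  v <- as.integer(round(subfunctions))
  if (any(is.na(v)) || any(v < 0L | v > 4L) ||
      any(abs(subfunctions - v) > 1e-8))
    stop("impairment levels must be integers in 0..4")
  names(v) <- sfn
  fv <- vapply(tx$functions, function(f) {
    as.integer(round_half_up(mean(v[tx$subfunctions == f])))
  }, integer(1))
  structure(
    list(subfunctions = v, functions = fv,
         patient_id = as.character(patient_id)),
    class = "cognitive_profile"
  )
}

#' @export
print.cognitive_profile <- function(x, ...) {
  cat("Cognitive impairment profile",
      if (!is.na(x$patient_id)) paste0("(patient ", x$patient_id, ")"), "\n")
  print(x$subfunctions)
  cat("Function-level aggregates:\n")
  print(x$functions)
  invisible(x)
}

#' Map z-scores to 0-4 impairment levels
#'
#' Standard 1-SD severity bands: z above -1 is within normal limits (0);
#' each further standard deviation below the normative mean adds one
#' severity level, capped at 4 (z of -4 or lower).
#'
#' @param z numeric vector of z-scores (negative = below the norm).
#' @return integer vector of impairment levels in 0..4.
#' @examples
#' band_impairment(c(0, -1, -2.5, -7))   # 0 1 2 4
#' @export
band_impairment <- function(z) {
  ifelse(z > -1, 0L, pmin(4L, as.integer(floor(-z))))
}

#' Normalize a raw neuropsychological assessment into a cognitive profile
#'
#' Each test item is converted to a z-score against normative data
#' stratified by the patient's age band and education level; item z-scores
#' are averaged per subfunction and banded into the 0-4 impairment scale
#' with [band_impairment()].
#'
#' @param raw a list with `patient_id`, `age` (years, > 0), `education`
#'   (level label matching the normative map), and `items`: a data.frame
#'   with columns `item` (id) and `score` (raw test score).
#' @param norms a normative map as returned by [read_normative_map()]:
#'   a named list keyed by item id, each entry holding `subfunction` and
#'   `norms[[age_band]][[education]] = list(mean, sd)`.
#' @param taxonomy the cognitive taxonomy (default [rehab_taxonomy()]).
#' @return A [cognitive_profile()].
#' @export
normalize_assessment <- function(raw, norms, taxonomy = rehab_taxonomy()) {
  stopifnot(is.list(raw), !is.null(raw$items))
  if (is.null(raw$age) || raw$age <= 0) stop("patient age must be positive")
  items <- raw$items
  sfn <- names(taxonomy$subfunctions)
  zs <- stats::setNames(rep(list(numeric(0)), length(sfn)), sfn)
  for (i in seq_len(nrow(items))) {
    id <- as.character(items$item[i])
    entry <- norms[[id]]
    if (is.null(entry))
      stop("no normative entry for item '", id, "'")
    sf <- entry$subfunction
    if (!sf %in% sfn)
      stop("item '", id, "' maps to unknown subfunction '", sf, "'")
    stratum <- .find_stratum(entry$norms, raw$age, raw$education, id)
    if (stratum$sd <= 0)
      stop("non-positive normative SD for item '", id, "'")
    z <- (items$score[i] - stratum$mean) / stratum$sd
    zs[[sf]] <- c(zs[[sf]], z)
  }
  empty <- sfn[vapply(zs, length, integer(1)) == 0L]
  if (length(empty))
    stop("no assessment items for subfunction(s): ",
         paste(empty, collapse = ", "))
  lev <- vapply(zs, function(v) band_impairment(mean(v)), integer(1))
  cognitive_profile(lev, patient_id = raw$patient_id)
}

# locate the (age band x education) normative stratum for an item
.find_stratum <- function(bands, age, education, item_id) {
  for (bn in names(bands)) {
    rng <- .parse_age_band(bn)
    if (age >= rng[1] && age <= rng[2]) {
      ed <- bands[[bn]][[as.character(education)]]
      if (is.null(ed))
        stop("no normative stratum for item '", item_id,
             "', age band '", bn, "', education '", education, "'")
      return(ed)
    }
  }
  stop("no normative age band covers age ", age, " for item '", item_id, "'")
}

# "16-35" -> c(16, 35); "56+" -> c(56, Inf)
.parse_age_band <- function(s) {
  if (grepl("\\+$", s)) return(c(as.numeric(sub("\\+$", "", s)), Inf))
  parts <- as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
  if (length(parts) != 2 || any(is.na(parts)))
    stop("malformed age band '", s, "'")
  parts
}

#' Did a patient improve between PRE and POST assessment?
#'
#' Improvement of cognitive capacities requires that at least one of the
#' three function-level impairment values strictly decreases from PRE to
#' POST while none of the others increases.
#'
#' @param pre,post `cognitive_profile` objects over the same taxonomy.
#' @return `TRUE` or `FALSE`.
#' @examples
#' pre  <- cognitive_profile(rep(2, 11))
#' post <- cognitive_profile(c(rep(1, 3), rep(2, 8)))
#' improved(pre, post)
#' @export
improved <- function(pre, post) {
  stopifnot(inherits(pre, "cognitive_profile"),
            inherits(post, "cognitive_profile"))
  if (!identical(names(pre$functions), names(post$functions)))
    stop("profiles are over different taxonomies")
  any(post$functions < pre$functions) && !any(post$functions > pre$functions)
}
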