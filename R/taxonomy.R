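#' Cognitive taxonomy for acquired brain injury
#'
#' The fixed taxonomy used throughout the package: 3 cognitive functions
#' (attention, memory, executive) covering 11 treatable subfunctions.
#' Every rehabilitation task is designed for exactly one subfunction, and
#' patient impairment profiles are rated per subfunction on a 0 (normality)
#' to 4 (very severe impairment) scale.
#'
#' @return A list with components:
#'   \item{functions}{character(3), the function names in canonical order.}
#'   \item{subfunctions}{named character(11); names are the subfunction
#'     identifiers in canonical order, values the parent function of each.}
#' @examples
#' tx <- rehab_taxonomy()
#' tx$subfunctions["sustained"]   # parent function of sustained attention
#' @export
rehab_taxonomy <- function() {
  list(
    functions = c("attention", "memory", "executive"),
    subfunctions = c(
      sustained      = "attention",
      selective      = "attention",
      divided        = "attention",
      visual         = "memory",
      verbal         = "memory",
      working        = "memory",
      scheduling     = "executive",
      inhibition     = "executive",
      flexibility    = "executive",
      sequencing     = "executive",
      categorization = "executive"
    )
  )
}

#' Subfunction names in canonical order
#' @return character(11)
#' @export
subfunction_names <- function() names(rehab_taxonomy()$subfunctions)

# round half away from zero upward (2.5 -> 3), unlike round()'s banker's rule
round_half_up <- function(x) floor(x + 0.5)

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
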