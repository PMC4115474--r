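#' Fit a Gaussian mixture over cognitive profiles by expectation-maximization
#'
#' Groups patients with similar 11-dimensional impairment profiles using a
#' diagonal-covariance Gaussian mixture fitted by EM. Profiles are stored as
#' integers but treated as real-valued here, since the mixture density needs
#' continuous support. With `k = NULL` the number of components is chosen
#' automatically by 10-fold cross-validated held-out log-likelihood,
#' increasing K while the mean held-out log-likelihood improves by more
#' than a 1% relative margin (a bare any-improvement rule overfits the
#' residual lattice structure of integer-valued profiles).
#'
#' @param profiles a list of [cognitive_profile()] objects, or a numeric
#'   matrix with one row per patient and 11 columns.
#' @param k integer number of mixture components, or `NULL` (default) for
#'   automatic selection.
#' @param seed integer seed controlling initialization and fold assignment;
#'   identical seed and data give bit-identical fits.
#' @param tol convergence tolerance on the relative change in
#'   log-likelihood between EM iterations.
#' @param max_iter maximum EM iterations; hitting it flags the model as
#'   non-converged rather than raising an error.
#' @param var_floor lower bound applied to every per-coordinate variance.
#'   Besides keeping 11-dimensional fits stable at small sample sizes,
#'   the floor matters because impairment profiles live on an integer
#'   lattice: a floor well below the lattice spacing lets a component
#'   collapse onto a single severity level and inflate the likelihood,
#'   which drives automatic component selection toward spurious splits.
#'   The default 0.1 (SD about 0.32, a third of a severity level) blocks
#'   that failure mode.
#' @param k_max largest K considered during automatic selection.
#' @return An object of class `em_mix` with components `k`, `weights`,
#'   `means` (K x 11), `variances` (K x 11), `log_likelihood`,
#'   `loglik_trace`, `converged`, `posterior` (n x K), `cluster` (hard
#'   assignment per training profile), `seed`, `n`, and (for automatic
#'   selection) `cv`, a data.frame of per-K held-out log-likelihood.
#' @seealso [assign_cluster()], [refit_with_patient()],
#'   [predict.em_mix()], [simulate.em_mix()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(55, 1, .3), 5), matrix(rnorm(55, 3, .3), 5))
#' fit <- fit_em(x, k = 2, seed = 1)
#' fit$cluster
#' @export
fit_em <- function(profiles, k = NULL, seed = 1L, tol = 1e-8,
                   max_iter = 500L, var_floor = 0.1, k_max = 8L) {
  x <- profiles_to_matrix(profiles)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 profiles to cluster")
  cv <- NULL
  if (is.null(k)) {
    sel <- .select_k_cv(x, seed = seed, tol = tol, max_iter = max_iter,
                        var_floor = var_floor, k_max = k_max)
    k <- sel$k
    cv <- sel$cv
  } else {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > n) stop("fewer profiles (", n, ") than components (", k, ")")
  }
  fit <- .em_run(x, k, seed = seed, tol = tol, max_iter = max_iter,
                 var_floor = var_floor)
  fit$cv <- cv
  fit$seed <- as.integer(seed)
  fit
}

#' Coerce profiles to the n x 11 matrix the mixture works on
#' @param profiles list of `cognitive_profile` or a numeric matrix.
#' @return numeric matrix, columns named by subfunction.
#' @export
profiles_to_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (ncol(profiles) != 11L) stop("profile matrix must have 11 columns")
    colnames(profiles) <- subfunction_names()
    return(profiles)
  }
  if (is.list(profiles) &&
      all(vapply(profiles, inherits, logical(1), "cognitive_profile"))) {
    m <- do.call(rbind, lapply(profiles, function(p) p$subfunctions))
    colnames(m) <- subfunction_names()
    return(m)
  }
  stop("profiles must be a matrix or a list of cognitive_profile objects")
}

# one full EM run at fixed k; deterministic given (x, k, seed)
.em_run <- function(x, k, seed, tol, max_iter, var_floor) {
  n <- nrow(x); d <- ncol(x)
  set.seed(seed)
  if (k == 1L) {
    means <- matrix(colMeans(x), 1L)
  } else {
    km <- tryCatch(
      stats::kmeans(x, centers = k, nstart = 5L, iter.max = 50L),
      error = function(e) NULL)
    means <- if (is.null(km)) {
      # degenerate data (fewer distinct rows than k): jittered sampled rows
      x[sample.int(n, k, replace = TRUE), , drop = FALSE] +
        matrix(stats::rnorm(k * d, 0, 1e-3), k, d)
    } else km$centers
  }
  vars <- matrix(pmax(rep(apply(x, 2, stats::var), each = k), var_floor), k, d)
  vars[is.na(vars)] <- var_floor
  w <- rep(1 / k, k)

  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    e <- .e_step(x, w, means, vars)
    resp <- e$resp
    trace <- c(trace, e$loglik)
    if (is.finite(loglik) &&
        abs(e$loglik - loglik) < tol * (abs(loglik) + tol)) {
      loglik <- e$loglik
      converged <- TRUE
      break
    }
    loglik <- e$loglik
    # M-step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    means <- t(resp) %*% x / nk
    second <- t(resp) %*% (x^2) / nk
    vars <- pmax(second - means^2, var_floor)
  }
  cl <- max.col(resp, ties.method = "first")
  structure(
    list(k = k, weights = as.numeric(w), means = unname(means),
         variances = unname(vars), log_likelihood = loglik,
         loglik_trace = trace, converged = converged,
         posterior = unname(resp), cluster = cl, n = n, cv = NULL,
         seed = NA_integer_),
    class = "em_mix"
  )
}

# responsibilities and total log-likelihood under current parameters
.e_step <- function(x, w, means, vars) {
  n <- nrow(x); k <- length(w)
  lp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lp[, j] <- log(w[j]) +
      colSums(stats::dnorm(t(x), mean = means[j, ],
                           sd = sqrt(vars[j, ]), log = TRUE))
  }
  m <- apply(lp, 1, max)
  lse <- m + log(rowSums(exp(lp - m)))
  list(resp = exp(lp - lse), loglik = sum(lse))
}

# held-out log-likelihood of x under a fitted model
.heldout_loglik <- function(fit, x) {
  .e_step(x, fit$weights, fit$means, fit$variances)$loglik
}

# automatic K: grow K while 10-fold CV mean held-out log-likelihood improves
# by more than a 1% relative margin (bare improvement overfits the residual
# lattice structure of integer profiles with arbitrarily small gains)
.select_k_cv <- function(x, seed, tol, max_iter, var_floor,
                         k_max = 8L, folds = 10L, min_rel_gain = 0.01) {
  n <- nrow(x)
  folds <- min(folds, n)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  best_k <- 1L
  best_cv <- -Inf
  rows <- list()
  for (k in seq_len(k_max)) {
    ll <- 0
    ok <- TRUE
    for (f in seq_len(folds)) {
      train <- x[fold_id != f, , drop = FALSE]
      test <- x[fold_id == f, , drop = FALSE]
      if (nrow(train) < k || nrow(test) == 0L) { ok <- FALSE; break }
      fit <- .em_run(train, k, seed = seed + 1000L * k + f,
                     tol = tol, max_iter = max_iter, var_floor = var_floor)
      ll <- ll + .heldout_loglik(fit, test)
    }
    if (!ok) break
    cvk <- ll / n
    rows[[k]] <- data.frame(k = k, cv_loglik = cvk)
    margin <- if (is.finite(best_cv)) min_rel_gain * abs(best_cv) else 0
    if (cvk > best_cv + margin) {
      best_cv <- cvk
      best_k <- k
    } else {
      break   # the extra component brings no substantive improvement
    }
  }
  list(k = best_k, cv = do.call(rbind, rows))
}

#' @export
print.em_mix <- function(x, ...) {
  cat("Gaussian mixture over cognitive profiles (EM",
      if (!x$converged) ", NOT converged" else "", ")\n", sep = "")
  cat("  components:", x$k, " patients:", x$n,
      " log-likelihood:", format(x$log_likelihood, digits = 6), "\n")
  cat("  mixture weights:", format(x$weights, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.em_mix <- function(object, ...) {
  cat("Gaussian mixture fit by EM\n")
  cat("Components:", object$k, "  patients:", object$n,
      "  converged:", object$converged,
      "  iterations:", length(object$loglik_trace), "\n")
  cat("Log-likelihood:", format(object$log_likelihood, digits = 8), "\n")
  if (!is.null(object$cv)) {
    cat("\nCross-validated component selection:\n")
    print(object$cv, row.names = FALSE)
  }
  cat("\nComponent means (impairment level per subfunction):\n")
  m <- coef(object)
  print(round(m, 2))
  cat("\nCluster sizes:", tabulate(object$cluster, object$k), "\n")
  invisible(object)
}

#' @export
coef.em_mix <- function(object, ...) {
  m <- object$means
  dimnames(m) <- list(paste0("cluster", seq_len(object$k)),
                      subfunction_names())
  m
}

#' @export
logLik.em_mix <- function(object, ...) {
  p <- object$k * (1 + 2 * ncol(object$means)) - 1
  structure(object$log_likelihood, df = p, nobs = object$n,
            class = "logLik")
}

#' Posterior cluster membership for new profiles
#'
#' @param object a fitted `em_mix` model.
#' @param newdata profiles as in [fit_em()].
#' @param ... unused.
#' @return A data.frame with `cluster` (hard assignment, argmax of the
#'   posterior) and one `p<k>` column per component holding the
#'   responsibilities (each row sums to 1).
#' @export
predict.em_mix <- function(object, newdata, ...) {
  x <- profiles_to_matrix(newdata)
  if (ncol(x) != ncol(object$means))
    stop("profile dimension does not match the fitted model")
  e <- .e_step(x, object$weights, object$means, object$variances)
  post <- e$resp
  out <- data.frame(cluster = max.col(post, ties.method = "first"))
  colnames(post) <- paste0("p", seq_len(object$k))
  cbind(out, as.data.frame(post))
}

#' Draw synthetic profiles from a fitted mixture
#'
#' @param object a fitted `em_mix` model.
#' @param nsim number of profiles to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return numeric matrix `nsim` x 11 of (continuous) profile draws.
#' @export
simulate.em_mix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
  d <- ncol(object$means)
  out <- object$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(nsim * d), nsim, d) *
      sqrt(object$variances[comp, , drop = FALSE])
  colnames(out) <- subfunction_names()
  out
}

#' Assign one patient to a cluster
#'
#' Responsibilities are proportional to mixture weight times component
#' density at the profile, normalized to sum to 1; the hard assignment is
#' the argmax.
#'
#' @param model a fitted `em_mix`.
#' @param profile a [cognitive_profile()] or numeric(11).
#' @return A list with `patient_id`, `cluster` (1-based index) and
#'   `posterior` (numeric(K)).
#' @export
assign_cluster <- function(model, profile) {
  pid <- NA_character_
  if (inherits(profile, "cognitive_profile")) {
    pid <- profile$patient_id
    v <- profile$subfunctions
  } else {
    v <- as.numeric(profile)
  }
  if (length(v) != ncol(model$means))
    stop("profile dimension does not match the fitted model")
  pr <- predict(model, matrix(v, 1L))
  list(patient_id = pid, cluster = pr$cluster[1],
       posterior = as.numeric(pr[1, -1]))
}

#' Refit the mixture when a new patient enters treatment
#'
#' The clusters are recomputed over all known patients plus the newcomer
#' (mirroring the dynamic refit performed whenever a patient starts
#' treatment), and the newcomer's assignment under the refitted model is
#' returned.
#'
#' @param profiles existing profiles (list or matrix, as [fit_em()]).
#' @param new_profile the new patient's [cognitive_profile()].
#' @param seed integer seed.
#' @param k fixed component count or `NULL` for automatic selection.
#' @param ... passed on to [fit_em()].
#' @return list(model = `em_mix`, assignment = see [assign_cluster()]).
#' @export
refit_with_patient <- function(profiles, new_profile, seed = 1L,
                               k = NULL, ...) {
  x <- profiles_to_matrix(profiles)
  v <- if (inherits(new_profile, "cognitive_profile"))
    new_profile$subfunctions else as.numeric(new_profile)
  x2 <- rbind(x, v)
  model <- fit_em(x2, k = k, seed = seed, ...)
  list(model = model, assignment = assign_cluster(model, new_profile))
}

#' Serialize a fitted mixture to JSON
#' @param model an `em_mix` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(k = model$k, weights = model$weights,
              means = model$means, variances = model$variances,
              log_likelihood = model$log_likelihood,
              converged = model$converged, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized mixture model
#' @param path JSON file written by [write_cluster_model()].
#' @return an `em_mix` object (without training posteriors).
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(k = as.integer(obj$k), weights = as.numeric(obj$weights),
         means = matrix(as.numeric(obj$means), nrow = obj$k),
         variances = matrix(as.numeric(obj$variances), nrow = obj$k),
         log_likelihood = obj$log_likelihood,
         loglik_trace = numeric(0), converged = isTRUE(obj$converged),
         posterior = NULL, cluster = NULL, n = NA_integer_, cv = NULL,
         seed = as.integer(obj$seed)),
    class = "em_mix"
  )
}
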