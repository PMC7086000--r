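#' Pearson correlation between predicted and measured atrophy, seed points
#' excluded
#'
#' To avoid the spurious correlation a seed region would contribute merely by
#' being both seeded and atrophied, the data points corresponding to the seed
#' regions are excluded from every correlation between measured and predicted
#' atrophy. This makes the fit a test of the model's predictive power over the
#' *rest* of the brain, not a restatement of where the atrophy is.
#'
#' @param predicted length-N numeric vector of model-predicted atrophy.
#' @param measured length-N numeric vector of measured atrophy (`y` of
#'   [zscore_atrophy()]).
#' @param seeds seed set: logical length-N vector, 0/1 length-N vector, or
#'   integer vector of seed indices.
#' @return Pearson correlation over the non-seed regions, or `NA_real_` when
#'   either restricted vector has (numerically) zero variance; callers treat
#'   `NA` as non-improvement.
#' @export
correlation_excluding_seeds <- function(predicted, measured, seeds) {
  n <- length(predicted)
  if (length(measured) != n) stop("predicted and measured lengths differ")
  keep <- !as_seed_logical(seeds, n)
  if (sum(keep) < 3L) stop("need at least 3 non-seed regions")
  p <- predicted[keep]
  m <- measured[keep]
  if (is_degenerate_sd(p) || is_degenerate_sd(m)) return(NA_real_)
  stats::cor(p, m)
}

# Normalize a seed specification to a logical mask of length n.
as_seed_logical <- function(seeds, n) {
  if (is.logical(seeds)) {
    if (length(seeds) != n) stop("logical seed vector has wrong length")
    return(seeds)
  }
  seeds <- as.numeric(seeds)
  if (length(seeds) == n && all(seeds %in% c(0, 1))) return(seeds == 1)
  idx <- as.integer(seeds)
  if (length(idx) == 0L || any(idx < 1L | idx > n)) {
    stop("seed indices out of range")
  }
  mask <- logical(n)
  mask[idx] <- TRUE
  mask
}

#' Screen every region as a single injury epicenter candidate
#'
#' Correlates a patient's measured atrophy with the diffusion prediction of
#' every single-region seed at every time point (seed region excluded from
#' each correlation), giving an N x T correlation matrix. For each candidate
#' seed, `R` is the highest correlation across time and `t_best` the time at
#' which it occurs. Undefined correlations (zero variance of the restricted
#' prediction, e.g. at t = 0 where the prediction is a degenerate indicator)
#' are recorded as 0 and flagged.
#'
#' @param profiles list of per-seed `"ndm_diffusion"` profiles from
#'   [all_seed_profiles()].
#' @param atrophy an `"ndm_atrophy"` for one patient.
#' @return An object of class `"ndm_seed_screen"`: list with
#'   `correlation_matrix` (N x T), `defined` (logical N x T), `R` (length-N),
#'   `t_best` (length-N time values), `t_index` (length-N grid positions,
#'   1-based), `timepoints`.
#' @export
screen_single_seeds <- function(profiles, atrophy) {
  stopifnot(inherits(atrophy, "ndm_atrophy"))
  y <- atrophy$y
  n <- length(profiles)
  if (n == 0L || nrow(profiles[[1L]]$values) != length(y)) {
    stop("profiles do not match the atrophy map")
  }
  if (is_degenerate_sd(y)) {
    stop("measured atrophy is constant across regions; no inference possible")
  }
  timepoints <- profiles[[1L]]$timepoints
  tt <- length(timepoints)
  cm <- matrix(0, n, tt)
  defined <- matrix(TRUE, n, tt)
  for (i in seq_len(n)) {
    vals <- profiles[[i]]$values
    for (j in seq_len(tt)) {
      r <- correlation_excluding_seeds(vals[, j], y, i)
      if (is.na(r)) {
        defined[i, j] <- FALSE
        r <- 0
      }
      cm[i, j] <- r
    }
  }
  rn <- rownames(profiles[[1L]]$values)
  dimnames(cm) <- dimnames(defined) <- list(rn, paste0("t", timepoints))
  t_index <- apply(cm, 1L, which.max)          # ties -> earlier time
  structure(list(correlation_matrix = cm,
                 defined = defined,
                 R = stats::setNames(cm[cbind(seq_len(n), t_index)], rn),
                 t_best = stats::setNames(timepoints[t_index], rn),
                 t_index = stats::setNames(t_index, rn),
                 timepoints = timepoints),
            class = "ndm_seed_screen")
}

#' @export
print.ndm_seed_screen <- function(x, ...) {
  best <- which.max(x$R)
  cat(sprintf("Seed screen: %d candidates x %d times; best %s (R = %.3f at t = %g)\n",
              nrow(x$correlation_matrix), ncol(x$correlation_matrix),
              rownames(x$correlation_matrix)[best], x$R[best], x$t_best[best]))
  invisible(x)
}

#' Initial epicenter configuration from a single-seed screen
#'
#' Applies three filtering rules in order to the screened correlations `R`:
#' (1) `R[i]` is set to 0 for every region whose best time lies on either end
#' of the time grid (the grid did not bracket its optimum); (2) `R[i]` is set
#' to 0 if `R[i] < 0` and `R[i]` is below the median of the (rule-1-filtered)
#' `R` vector; (3) every region with `R[i] > 0` becomes a member of the
#' initial configuration.
#'
#' @param screen an `"ndm_seed_screen"`.
#' @return Named integer 0/1 vector of length N.
#' @export
initial_configuration <- function(screen) {
  stopifnot(inherits(screen, "ndm_seed_screen"))
  R <- screen$R
  tt <- length(screen$timepoints)
  R[screen$t_index %in% c(1L, tt)] <- 0
  med <- stats::median(R)
  R[R < 0 & R < med] <- 0
  config <- as.integer(R > 0)
  names(config) <- rownames(screen$correlation_matrix)
  config
}

# Fit one seed set: predicted atrophy at every interior time point and the
# seed-excluded correlation at each; returns the arg-max time (ties -> the
# earlier time), treating undefined correlations as -Inf.
seed_set_fit <- function(lap, seed_idx, y, alpha, timepoints) {
  tt <- length(timepoints)
  if (tt < 3L) stop("need at least 3 time points to have an interior optimum")
  interior <- 2:(tt - 1L)
  Q <- lap$eigenvectors
  coef <- colSums(Q[seed_idx, , drop = FALSE])   # t(Q) %*% indicator(seed_idx)
  decay <- exp(-alpha * outer(lap$eigenvalues, timepoints[interior]))
  pred <- Q %*% (decay * coef)
  r <- vapply(seq_along(interior), function(j) {
    correlation_excluding_seeds(pred[, j], y, seed_idx)
  }, numeric(1))
  r[is.na(r)] <- -Inf
  if (all(!is.finite(r))) {
    stop("no valid interior time point for this seed set")
  }
  jbest <- which.max(r)                          # ties -> earlier time
  list(t_max = timepoints[interior[jbest]],
       t_index = interior[jbest],
       r_best = r[jbest],
       r_interior = r,
       predicted = pred[, jbest])
}

#' Best-fitting diffusion time for a fixed seed set
#'
#' Simulates the network diffusion model from the given seed set (initial
#' condition 1 at each seed) and finds the interior time point at which the
#' seed-excluded correlation between predicted and measured atrophy peaks:
#' `t_max = argmax_t R(f_t, y)`. The first and last grid points are excluded,
#' mirroring the screening rule — a boundary optimum means the grid did not
#' bracket the best fit. Ties resolve to the earlier time.
#'
#' @param lap an `"ndm_laplacian"`.
#' @param seeds seed set (see [correlation_excluding_seeds()] for accepted
#'   forms), non-empty.
#' @param atrophy an `"ndm_atrophy"`.
#' @param alpha diffusion coefficient.
#' @param timepoints time grid (default `0:19`).
#' @return List with `t_max` (time value), `t_index` (grid position),
#'   `r_best`, `r_interior` (correlation at each interior time), and
#'   `predicted` (length-N predicted atrophy at `t_max`).
#' @export
find_tmax <- function(lap, seeds, atrophy, alpha = 0.25, timepoints = 0:19) {
  stopifnot(inherits(lap, "ndm_laplacian"), inherits(atrophy, "ndm_atrophy"))
  n <- nrow(lap$H)
  seed_idx <- which(as_seed_logical(seeds, n))
  if (length(seed_idx) == 0L) stop("seed set must be non-empty")
  seed_set_fit(lap, seed_idx, atrophy$y, alpha, timepoints)
}

#' Infer a patient's injury epicenters by greedy seed-combination search
#'
#' Starting from the candidate pool given by [initial_configuration()] (or,
#' when that pool is empty, the single best-screening region), the search
#' begins at the pool member with the highest single-seed correlation and
#' repeatedly adds the pool member whose inclusion most increases the
#' seed-excluded correlation at the best interior time, re-fitting `t_max`
#' for every trial set. When no addition improves the fit, an optional single
#' backward pass removes any member whose removal does not decrease the
#' correlation. The procedure is deterministic: correlation ties resolve to
#' the earlier time, candidate-gain ties to the lower region index.
#'
#' @param lap an `"ndm_laplacian"`.
#' @param screen an `"ndm_seed_screen"` for this patient.
#' @param atrophy the patient's `"ndm_atrophy"`.
#' @param alpha diffusion coefficient.
#' @param timepoints time grid.
#' @param prune run the backward pruning pass (default `TRUE`).
#' @param pool optional integer vector of candidate region indices overriding
#'   the initial configuration (e.g. to cap the search space).
#' @return An object of class `"ndm_epicenter_result"`: list with `seeds`
#'   (named 0/1 vector), `seed_idx`, `seed_names`, `t_max`, `t_index`,
#'   `r_best`, `r_squared`, `predicted`, `search_trace` (data.frame logging
#'   every candidate set evaluated), `alpha`, `timepoints`.
#' @export
optimize_seed_combination <- function(lap, screen, atrophy, alpha = 0.25,
                                      timepoints = 0:19, prune = TRUE,
                                      pool = NULL) {
  stopifnot(inherits(lap, "ndm_laplacian"), inherits(screen, "ndm_seed_screen"))
  n <- nrow(lap$H)
  y <- atrophy$y
  if (is.null(pool)) {
    pool <- unname(which(initial_configuration(screen) == 1L))
    if (length(pool) == 0L) pool <- unname(which.max(screen$R))
  } else {
    pool <- sort(unique(as.integer(pool)))
    if (any(pool < 1L | pool > n)) stop("pool indices out of range")
  }
  rn <- lap$parcellation$region_name

  trace <- list()
  log_step <- function(action, set, fit) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L,
      action = action,
      n_seeds = length(set),
      seeds = paste(rn[sort(set)], collapse = "+"),
      t_max = fit$t_max,
      r = fit$r_best,
      stringsAsFactors = FALSE)
  }

  start <- pool[which.max(screen$R[pool])]       # ties -> lower region index
  current <- start
  fit <- seed_set_fit(lap, current, y, alpha, timepoints)
  log_step("start", current, fit)

  repeat {
    cands <- setdiff(pool, current)
    if (length(cands) == 0L || length(current) >= n - 3L) break
    fits <- lapply(cands, function(j) {
      seed_set_fit(lap, sort(c(current, j)), y, alpha, timepoints)
    })
    rs <- vapply(fits, `[[`, numeric(1), "r_best")
    k <- which.max(rs)                           # ties -> lower region index
    if (rs[k] > fit$r_best) {
      current <- sort(c(current, cands[k]))
      fit <- fits[[k]]
      log_step("add", current, fit)
    } else break
  }

  if (prune && length(current) > 1L) {
    for (m in sort(current)) {
      if (length(current) == 1L) break
      fit_wo <- seed_set_fit(lap, setdiff(current, m), y, alpha, timepoints)
      if (fit_wo$r_best >= fit$r_best) {
        current <- setdiff(current, m)
        fit <- fit_wo
        log_step("drop", current, fit)
      }
    }
  }

  fit <- seed_set_fit(lap, current, y, alpha, timepoints)  # final re-evaluation
  seeds <- integer(n)
  seeds[current] <- 1L
  names(seeds) <- rn
  structure(list(seeds = seeds,
                 seed_idx = current,
                 seed_names = rn[current],
                 t_max = fit$t_max,
                 t_index = fit$t_index,
                 r_best = fit$r_best,
                 r_squared = fit$r_best^2,
                 predicted = stats::setNames(fit$predicted, rn),
                 search_trace = do.call(rbind, trace),
                 alpha = alpha,
                 timepoints = timepoints),
            class = "ndm_epicenter_result")
}

#' @export
print.ndm_epicenter_result <- function(x, ...) {
  cat(sprintf("Injury epicenters: %s\n  t_max = %g, R = %.3f, R^2 = %.3f (%d candidate sets evaluated)\n",
              paste(x$seed_names, collapse = ", "), x$t_max, x$r_best,
              x$r_squared, nrow(x$search_trace)))
  invisible(x)
}

#' One-call epicenter inference for a single patient
#'
#' Convenience wrapper: screens all single seeds, forms the initial
#' configuration, and runs the greedy combination search.
#'
#' @inheritParams optimize_seed_combination
#' @param profiles optional precomputed [all_seed_profiles()] list (reused
#'   across patients of a cohort); computed on the fly when `NULL`.
#' @return An `"ndm_epicenter_result"` (with the screen attached as attribute
#'   `"screen"`).
#' @export
infer_epicenters <- function(lap, atrophy, alpha = 0.25, timepoints = 0:19,
                             prune = TRUE, profiles = NULL) {
  if (is.null(profiles)) profiles <- all_seed_profiles(lap, alpha, timepoints)
  screen <- screen_single_seeds(profiles, atrophy)
  res <- optimize_seed_combination(lap, screen, atrophy, alpha, timepoints,
                                   prune = prune)
  attr(res, "screen") <- screen
  res
}
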