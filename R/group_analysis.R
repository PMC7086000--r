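#' Stack per-patient predicted atrophy maps into a patients x regions matrix
#'
#' @param results list of `"ndm_epicenter_result"` objects.
#' @param patient_ids optional character vector of row names.
#' @return P x N numeric matrix of each patient's predicted atrophy at their
#'   `t_max`.
#' @export
predicted_atrophy_matrix <- function(results, patient_ids = NULL) {
  stopifnot(length(results) >= 1L)
  m <- t(vapply(results, `[[`, numeric(length(results[[1L]]$predicted)),
                "predicted"))
  rownames(m) <- patient_ids %||% names(results) %||%
    paste0("patient_", seq_along(results))
  m
}

#' Principal components of predicted atrophy maps
#'
#' Identifies common orthogonal spatial patterns across patients: the
#' patients-x-regions matrix is column mean-centered and decomposed by
#' singular value decomposition (equivalently, eigendecomposition of the
#' covariance matrix over regions). Component signs are fixed so that each
#' component's largest-magnitude loading is positive, making outputs
#' reproducible.
#'
#' @param x P x N numeric matrix (patients x regions), P >= 2.
#' @param k number of components to return (default `min(5, P - 1, N)`).
#' @return An object of class `"ndm_pca"`: list with `components` (k x N
#'   orthonormal loadings), `explained_variance_fraction` (over all
#'   `min(P - 1, N)` components; sums to 1), `scores` (P x k), `center`
#'   (length-N column means), `k`.
#' @export
pca_predicted_maps <- function(x, k = NULL) {
  x <- as.matrix(x)
  p <- nrow(x)
  n <- ncol(x)
  if (p < 2L) stop("need at least 2 patients for PCA")
  m <- min(p - 1L, n)
  k <- as.integer(k %||% min(5L, m))
  if (k < 1L || k > m) stop("k must be between 1 and min(P - 1, N)")
  if (!any(apply(x, 2L, stats::sd) > 0)) stop("constant matrix: zero total variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev[seq_len(m)]^2
  frac <- ev / sum(ev)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                 # largest-|loading| entry positive
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(components = t(load),
                 explained_variance_fraction = frac,
                 scores = scores,
                 center = pc$center,
                 k = k),
            class = "ndm_pca")
}

#' @export
print.ndm_pca <- function(x, ...) {
  f <- x$explained_variance_fraction[seq_len(x$k)]
  cat(sprintf("PCA of predicted atrophy maps: first %d components explain %s%% (total %.0f%%)\n",
              x$k, paste(sprintf("%.0f", 100 * f), collapse = "/"),
              100 * sum(f)))
  invisible(x)
}

#' Write PCA loadings as a delimited table
#'
#' Components x regions, tab-separated, with region names — the layout used
#' downstream for anatomical surface maps.
#'
#' @param pca an `"ndm_pca"`.
#' @param path output path.
#' @param region_names optional column names.
#' @export
write_pca_loadings <- function(pca, path, region_names = NULL) {
  m <- pca$components
  rownames(m) <- paste0("PC", seq_len(nrow(m)))
  if (!is.null(region_names)) colnames(m) <- region_names
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Partial correlation controlling for one covariate
#'
#' Residualizes `x` and `y` on the covariate (least squares with intercept)
#' and correlates the residuals; the two-sided p-value comes from the t
#' distribution with `n - 3` degrees of freedom. Equivalent to the closed
#' form `(r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))`.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param covariate numeric vector to control for; must not be constant.
#' @param covariate_name label stored in the result.
#' @return An object of class `"ndm_association"`: list with `r`, `p_value`,
#'   `n`, `df`, `covariates`.
#' @export
partial_correlation <- function(x, y, covariate, covariate_name = "covariate") {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) stop("input lengths differ")
  if (n < 4L) stop("need at least 4 observations for a partial correlation")
  if (is_degenerate_sd(covariate)) stop("covariate is constant")
  design <- cbind(1, covariate)
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (is_degenerate_sd(rx) || is_degenerate_sd(ry)) {
    stop("zero residual variance after removing the covariate")
  }
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tstat <- r * sqrt(df / (1 - r^2))
  structure(list(r = r,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 n = n, df = df,
                 covariates = covariate_name),
            class = "ndm_association")
}

#' Plain Pearson correlation as an association record
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return An `"ndm_association"` with `df = n - 2` and no covariates.
#' @export
plain_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("input lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  if (is_degenerate_sd(x) || is_degenerate_sd(y)) {
    stop("correlation undefined: an input is constant")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = n, df = unname(ct$parameter),
                 covariates = character(0)),
            class = "ndm_association")
}

#' @export
print.ndm_association <- function(x, ...) {
  ctrl <- if (length(x$covariates)) {
    sprintf(" controlling for %s", paste(x$covariates, collapse = ", "))
  } else ""
  cat(sprintf("Association%s: r = %.3f, p = %.4g (n = %d, df = %d)\n",
              ctrl, x$r, x$p_value, x$n, x$df))
  invisible(x)
}

#' Model fit versus time since injury, controlling for age
#'
#' Correlates each patient's coefficient of determination (squared best
#' seed-excluded correlation) with time since injury, partialling out age.
#'
#' @param results list of `"ndm_epicenter_result"`, one per patient.
#' @param tsi time since injury in years, aligned with `results`.
#' @param age age in years, aligned with `results`.
#' @return An `"ndm_association"`.
#' @export
fit_vs_time_since_injury <- function(results, tsi, age) {
  r2 <- vapply(results, `[[`, numeric(1), "r_squared")
  partial_correlation(r2, tsi, age, covariate_name = "age")
}

#' Model peak time versus time since injury
#'
#' Plain Pearson correlation between each patient's best-fitting diffusion
#' time `t_max` and time since injury.
#'
#' @param results list of `"ndm_epicenter_result"`.
#' @param tsi time since injury in years.
#' @return An `"ndm_association"`.
#' @export
peaktime_vs_time_since_injury <- function(results, tsi) {
  t_max <- vapply(results, `[[`, numeric(1), "t_max")
  plain_correlation(t_max, tsi)
}
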