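# Shared fixtures and independent oracles for the test suite.

# Tiny parcellation with n generic regions.
toy_parcellation <- function(n, hemi = "midline") {
  parcellation(sprintf("r%02d", seq_len(n)), hemi)
}

# Connectome from an explicit weight matrix.
toy_connectome <- function(w) {
  connectome(w, toy_parcellation(nrow(as.matrix(w))))
}

# The 2-node unit-weight graph: H = [[1, -1], [-1, 1]].
two_node_lap <- function() {
  graph_laplacian(toy_connectome(matrix(c(0, 1, 1, 0), 2)))
}

# Random connected symmetric nonnegative weight matrix (Erdos-Renyi-ish,
# dense enough to be connected with overwhelming probability).
random_weights <- function(n, density = 0.3, scale = 1) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    m <- sum(ut)
    vals <- ifelse(stats::runif(m) < density,
                   stats::rlnorm(m, log(scale), 1), 0)
    w[ut] <- vals
    w <- w + t(w)
    # connectivity via matrix powers of the pattern
    a <- (w > 0) * 1
    reach <- diag(n)
    for (i in seq_len(n)) reach <- (reach %*% (a + diag(n)) > 0) * 1
    if (all(reach > 0)) return(w)
  }
}

random_lap <- function(n, density = 0.3, ...) {
  graph_laplacian(toy_connectome(random_weights(n, density)), ...)
}

# Independent ODE oracle: explicit Euler integration of df/dt = -alpha H f.
euler_diffusion <- function(H, f0, alpha, t_end, dt = 1e-4) {
  f <- as.numeric(f0)
  for (s in seq_len(round(t_end / dt))) {
    f <- f - alpha * dt * drop(H %*% f)
  }
  f
}

# Exhaustive seed-subset search oracle: best seed-excluded correlation over
# every non-empty subset of the candidate pool.
exhaustive_best_r <- function(lap, pool, atrophy, alpha = 0.25,
                              timepoints = 0:19) {
  best <- -Inf
  for (k in seq_along(pool)) {
    for (s in utils::combn(pool, k, simplify = FALSE)) {
      fit <- find_tmax(lap, s, atrophy, alpha, timepoints)
      if (fit$r_best > best) best <- fit$r_best
    }
  }
  best
}

# Hand-built seed screen object for rule-level tests.
fake_screen <- function(R, t_best, timepoints = 0:19) {
  n <- length(R)
  cm <- matrix(0, n, length(timepoints),
               dimnames = list(sprintf("r%02d", seq_len(n)),
                               paste0("t", timepoints)))
  t_index <- match(t_best, timepoints)
  cm[cbind(seq_len(n), t_index)] <- R
  structure(list(correlation_matrix = cm,
                 defined = matrix(TRUE, n, length(timepoints)),
                 R = R, t_best = t_best, t_index = t_index,
                 timepoints = timepoints),
            class = "ndm_seed_screen")
}

# Atrophy map directly from a loss vector y (bypassing volumes).
atrophy_from_y <- function(y) {
  structure(list(z = -y, y = y), class = "ndm_atrophy")
}

# Small synthetic cohort spec with fast settings for unit tests.
test_spec <- function(...) {
  cohort_spec(n_regions = 20L, n_modules = 2L, n_controls = 8L,
              n_patients = 4L, ...)
}
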