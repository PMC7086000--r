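#' Specification of a synthetic TBI cohort
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: an 82-region parcellation,
#' 19 healthy controls, and 17 patients scanned 1-5 years after injury at
#' ages 10-17, whose atrophy pattern arises from network diffusion out of a
#' small set of true injury epicenters.
#'
#' The connectome is a weighted stochastic block model: regions are split
#' into `n_modules` communities (half the regions per hemisphere), edges are
#' sampled with probability `intra_module_density` within and
#' `inter_module_density` between communities, and edge weights are
#' log-normal (heavy right tail, like streamline counts) with mean
#' `weight_scale` and log-scale spread `weight_sdlog`.
#'
#' Volumes: each region gets a log-normal baseline volume; controls vary
#' around baseline with coefficient of variation `control_cv`. Patients lose
#' volume in proportion to the diffusion pattern from their true seeds at
#' time `true_time`, scaled so the most affected region loses `atrophy_gain`
#' control standard deviations, plus per-region Gaussian noise of `noise_sd`
#' control SDs. Expressing both in control-SD units maps them directly onto
#' z-score space.
#'
#' @param n_regions number of regions (default 82).
#' @param n_modules number of communities in the block model.
#' @param intra_module_density,inter_module_density edge probabilities in
#'   (0, 1].
#' @param weight_scale mean edge weight (streamline-count scale; the
#'   Laplacian normalization removes it).
#' @param weight_sdlog log-scale SD of edge weights.
#' @param n_controls,n_patients cohort sizes (defaults 19 and 17).
#' @param true_seeds_per_patient seed-set size per patient: a count, or a
#'   range `c(lo, hi)` sampled uniformly.
#' @param true_time diffusion time of the generating process (interior to the
#'   default analysis grid `0:19`).
#' @param atrophy_gain peak volume loss in control-SD units.
#' @param noise_sd per-region patient volume noise in control-SD units.
#' @param control_cv control between-subject volume coefficient of variation.
#' @param connectome_jitter log-scale SD of per-control multiplicative edge
#'   jitter around the template connectome.
#' @param alpha diffusion coefficient of the generating process.
#' @param rng_seed integer seed making every generated artifact reproducible.
#' @return A validated list of class `"ndm_cohort_spec"`.
#' @export
cohort_spec <- function(n_regions = 82L, n_modules = 4L,
                        intra_module_density = 0.6,
                        inter_module_density = 0.15,
                        weight_scale = 50, weight_sdlog = 1,
                        n_controls = 19L, n_patients = 17L,
                        true_seeds_per_patient = 1L,
                        true_time = 7, atrophy_gain = 3,
                        noise_sd = 0.1, control_cv = 0.05,
                        connectome_jitter = 0.1,
                        alpha = 0.25, rng_seed = 1L) {
  spec <- list(n_regions = as.integer(n_regions),
               n_modules = as.integer(n_modules),
               intra_module_density = intra_module_density,
               inter_module_density = inter_module_density,
               weight_scale = weight_scale, weight_sdlog = weight_sdlog,
               n_controls = as.integer(n_controls),
               n_patients = as.integer(n_patients),
               true_seeds_per_patient = as.integer(true_seeds_per_patient),
               true_time = true_time, atrophy_gain = atrophy_gain,
               noise_sd = noise_sd, control_cv = control_cv,
               connectome_jitter = connectome_jitter,
               alpha = alpha, rng_seed = as.integer(rng_seed))
  with(spec, {
    stopifnot(n_regions >= 2L, n_modules >= 1L, n_modules <= n_regions,
              intra_module_density > 0, intra_module_density <= 1,
              inter_module_density > 0, inter_module_density <= 1,
              weight_scale > 0, weight_sdlog >= 0,
              n_controls >= 2L, n_patients >= 1L,
              all(true_seeds_per_patient >= 1L),
              length(true_seeds_per_patient) %in% 1:2,
              true_time >= 0, atrophy_gain >= 0, noise_sd >= 0,
              control_cv >= 0, connectome_jitter >= 0, alpha >= 0)
  })
  structure(spec, class = "ndm_cohort_spec")
}

# Parcellation for a synthetic cohort: first half left, second half right.
synthetic_parcellation <- function(n_regions) {
  half <- ceiling(n_regions / 2)
  hemi <- rep(c("left", "right"), c(half, n_regions - half))
  tag <- ifelse(hemi == "left", "L", "R")
  num <- c(seq_len(half), seq_len(n_regions - half))
  parcellation(sprintf("%s_roi%02d", tag, num), hemi)
}

# Connected-components check on a weight matrix (BFS), no graph dependency.
n_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(w[v, ] > 0 & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  ncomp
}

#' Generate a synthetic structural connectome
#'
#' Weighted stochastic-block-model graph per the [cohort_spec()]: modular
#' edge structure, log-normal (right-skewed) positive weights, symmetric,
#' zero diagonal, guaranteed connected (regenerated up to `max_tries` times).
#'
#' @param spec an `"ndm_cohort_spec"`.
#' @param seed RNG seed; `NULL` continues the current RNG stream (used when
#'   called from [generate_cohort()]).
#' @param max_tries connectivity retry bound.
#' @return An `"ndm_connectome"`.
#' @export
generate_connectome <- function(spec, seed = spec$rng_seed, max_tries = 25L) {
  stopifnot(inherits(spec, "ndm_cohort_spec"))
  parc <- synthetic_parcellation(spec$n_regions)
  with_seed(seed, {
    n <- spec$n_regions
    module <- rep(seq_len(spec$n_modules), length.out = n)
    module <- sort(module)                       # contiguous blocks
    meanlog <- log(spec$weight_scale) - spec$weight_sdlog^2 / 2
    for (try in seq_len(max_tries)) {
      same <- outer(module, module, `==`)
      p <- ifelse(same, spec$intra_module_density, spec$inter_module_density)
      w <- matrix(0, n, n)
      ut <- upper.tri(w)
      edge <- stats::runif(sum(ut)) < p[ut]
      wt <- numeric(sum(ut))
      wt[edge] <- stats::rlnorm(sum(edge), meanlog, spec$weight_sdlog)
      w[ut] <- wt
      w <- w + t(w)
      if (n_components(w) == 1L) return(connectome(w, parc))
    }
    stop(sprintf("could not generate a connected graph in %d tries; %s",
                 max_tries, "increase the edge densities"))
  })
}

# Multiplicative log-normal jitter of a template connectome (per control).
jitter_connectome <- function(template, sdlog) {
  w <- template$weights
  ut <- upper.tri(w)
  w[ut] <- w[ut] * stats::rlnorm(sum(ut), 0, sdlog)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  connectome(w, template$parcellation)
}

#' Generate a control cohort volume table
#'
#' Draws one log-normal baseline volume per region, then `n_controls`
#' subjects as baseline times `1 + N(0, control_cv)` multiplicative noise.
#'
#' @param spec an `"ndm_cohort_spec"`.
#' @param conn an `"ndm_connectome"` supplying the parcellation.
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return An `"ndm_volume_table"` of `n_controls` x `n_regions` volumes.
#' @export
generate_controls <- function(spec, conn, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "ndm_cohort_spec"))
  parc <- conn$parcellation
  with_seed(seed, {
    n <- n_regions(parc)
    baseline <- stats::rlnorm(n, meanlog = log(6000), sdlog = 0.5)
    noise <- matrix(stats::rnorm(spec$n_controls * n, 0, spec$control_cv),
                    spec$n_controls, n)
    v <- sweep(1 + noise, 2L, baseline, `*`)
    volume_table(v, sprintf("control_%02d", seq_len(spec$n_controls)), parc)
  })
}

#' Generate one patient's regional volumes from known epicenters
#'
#' Inverts the analysis model: pathology `g` is the network diffusion from
#' the true seed set at `true_time`; the patient's volume in region i is
#' `mu_i - atrophy_gain * sigma_i * g_i / max(g) + sigma_i * eps_i` with
#' `eps_i ~ N(0, noise_sd)`. Because the loss is expressed in control-SD
#' units, the noise-free measured atrophy `y = -z` recovered by
#' [zscore_atrophy()] against the same control statistics is exactly
#' `atrophy_gain * g / max(g)` — a positive rescaling of the generating
#' pattern, the round-trip that anchors all recovery tests.
#'
#' @param spec an `"ndm_cohort_spec"`.
#' @param conn the `"ndm_connectome"` the pathology spreads on.
#' @param control_stats the `"ndm_control_stats"` the patient will be
#'   z-scored against.
#' @param truth list with `seeds` (region indices) and `true_time`.
#' @param seed RNG seed; `NULL` continues the current stream.
#' @param lap optional precomputed `"ndm_laplacian"` for `conn`.
#' @return Named length-N volume vector.
#' @export
generate_patient <- function(spec, conn, control_stats, truth,
                             seed = spec$rng_seed, lap = NULL) {
  stopifnot(inherits(spec, "ndm_cohort_spec"),
            inherits(control_stats, "ndm_control_stats"))
  n <- n_regions(conn$parcellation)
  if (length(truth$seeds) == 0L || any(truth$seeds < 1L | truth$seeds > n)) {
    stop("true seeds must be valid region indices")
  }
  mu <- control_stats$mu
  sigma <- control_stats$sigma
  if (any(spec$atrophy_gain * sigma >= mu)) {
    stop("atrophy_gain too large: would produce non-positive volumes")
  }
  if (is.null(lap)) lap <- graph_laplacian(conn)
  f0 <- numeric(n)
  f0[truth$seeds] <- 1
  g <- simulate_diffusion(lap, f0, alpha = spec$alpha,
                          timepoints = truth$true_time)$values[, 1L]
  g <- g / max(g)
  with_seed(seed, {
    eps <- stats::rnorm(n, 0, spec$noise_sd)
    stats::setNames(mu - spec$atrophy_gain * sigma * g + sigma * eps,
                    conn$parcellation$region_name)
  })
}

#' Generate a complete synthetic cohort
#'
#' Produces everything the pipeline consumes, with known ground truth:
#' per-control connectomes (multiplicative jitter around one template, so
#' that averaging is exercised), control and patient volume tables, true
#' seed sets, and clinical covariates (time since injury uniform on 1-5
#' years, age uniform on 10-17 years). Patients are generated against the
#' *empirical* statistics of the realized control table, so the generating
#' process is exactly the analysis model.
#'
#' Everything is reproducible from `spec$rng_seed`.
#'
#' @param spec an `"ndm_cohort_spec"`.
#' @return An object of class `"ndm_cohort"`: list with `spec`,
#'   `parcellation`, `template` (generating connectome),
#'   `control_connectomes`, `control_volumes`, `patient_volumes`,
#'   `control_stats`, `truths` (per patient: `patient_id`, `seeds`,
#'   `seed_names`, `true_time`), `covariates` (data.frame patient_id, age,
#'   tsi).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ndm_cohort_spec"))
  with_seed(spec$rng_seed, {
    template <- generate_connectome(spec, seed = NULL)
    parc <- template$parcellation
    control_connectomes <- lapply(seq_len(spec$n_controls), function(i) {
      jitter_connectome(template, spec$connectome_jitter)
    })
    names(control_connectomes) <- sprintf("control_%02d",
                                          seq_len(spec$n_controls))
    control_volumes <- generate_controls(spec, template, seed = NULL)
    control_stats <- compute_control_stats(control_volumes)
    lap <- graph_laplacian(template)

    ids <- sprintf("patient_%02d", seq_len(spec$n_patients))
    k_range <- range(spec$true_seeds_per_patient)
    truths <- lapply(seq_len(spec$n_patients), function(i) {
      k <- if (k_range[1L] == k_range[2L]) k_range[1L] else {
        sample(k_range[1L]:k_range[2L], 1L)
      }
      seeds <- sort(sample.int(spec$n_regions, k))
      list(patient_id = ids[i], seeds = seeds,
           seed_names = parc$region_name[seeds],
           true_time = spec$true_time)
    })
    pv <- t(vapply(truths, function(tr) {
      generate_patient(spec, template, control_stats, tr, seed = NULL,
                       lap = lap)
    }, numeric(spec$n_regions)))
    patient_volumes <- volume_table(pv, ids, parc)
    covariates <- data.frame(patient_id = ids,
                             age = stats::runif(spec$n_patients, 10, 17),
                             tsi = stats::runif(spec$n_patients, 1, 5),
                             stringsAsFactors = FALSE)
    structure(list(spec = spec, parcellation = parc, template = template,
                   control_connectomes = control_connectomes,
                   control_volumes = control_volumes,
                   patient_volumes = patient_volumes,
                   control_stats = control_stats,
                   truths = truths, covariates = covariates),
              class = "ndm_cohort")
  })
}

#' @export
print.ndm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d regions, %d controls, %d patients (seed %d)\n",
              x$spec$n_regions, x$spec$n_controls, x$spec$n_patients,
              x$spec$rng_seed))
  invisible(x)
}

#' Write a synthetic cohort in the pipeline's input file dialects
#'
#' Emits `parcellation.tsv`, one `connectomes/<id>.tsv` per control,
#' `volumes_controls.tsv`, `volumes_patients.tsv`, `covariates.tsv`, and a
#' machine-readable `ground_truth.json` manifest (spec echo plus per-patient
#' true seeds).
#'
#' @param cohort an `"ndm_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ndm_cohort"))
  dir.create(file.path(dir, "connectomes"), recursive = TRUE,
             showWarnings = FALSE)
  parc <- cohort$parcellation
  utils::write.table(
    data.frame(region_name = parc$region_name, hemisphere = parc$hemisphere),
    file.path(dir, "parcellation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$control_connectomes)) {
    write_connectome(cohort$control_connectomes[[id]],
                     file.path(dir, "connectomes", paste0(id, ".tsv")))
  }
  write_volume_table(cohort$control_volumes,
                     file.path(dir, "volumes_controls.tsv"))
  write_volume_table(cohort$patient_volumes,
                     file.path(dir, "volumes_patients.tsv"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(spec = unclass(cohort$spec),
                   n_control_connectomes = length(cohort$control_connectomes),
                   truths = lapply(cohort$truths, function(tr) {
                     tr[c("patient_id", "seeds", "seed_names", "true_time")]
                   }))
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
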