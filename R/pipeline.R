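#' Build a resolved pipeline configuration
#'
#' Central bag of settings for the three pipeline stages. The defaults
#' reproduce the analysis' fixed constants: diffusion coefficient
#' `alpha = 0.25`, the 20-point time grid `t = 0..19`, max-weight-scaled
#' Laplacian, backward pruning on, and 5 reported principal components.
#'
#' @param data_dir directory of cohort input files (the dialect written by
#'   [write_cohort()]).
#' @param out_dir directory for stage outputs.
#' @param alpha diffusion coefficient.
#' @param timepoints diffusion time grid.
#' @param normalization Laplacian normalization (see [graph_laplacian()]).
#' @param prune backward pruning pass in the seed search.
#' @param n_components principal components to report.
#' @param seed RNG seed for the simulate stage.
#' @param cohort named list of [cohort_spec()] overrides for the simulate
#'   stage.
#' @param verbose print per-patient progress.
#' @return A list of class `"ndm_config"`.
#' @export
pipeline_config <- function(data_dir = "results/cohort",
                            out_dir = "results",
                            alpha = 0.25, timepoints = 0:19,
                            normalization = "max-weight-scaled",
                            prune = TRUE, n_components = 5L,
                            seed = 1L, cohort = list(),
                            verbose = FALSE) {
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 alpha = alpha, timepoints = timepoints,
                 normalization = normalization, prune = prune,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed), cohort = cohort,
                 verbose = isTRUE(verbose)),
            class = "ndm_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys in the file override the [pipeline_config()] defaults; unknown keys
#' are an error.
#'
#' @param path YAML file.
#' @return An `"ndm_config"`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

# Write the fully resolved configuration beside the stage outputs.
echo_config <- function(config, out_dir, stage) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config),
                   file.path(out_dir, paste0("config_", stage, ".yaml")))
}

require_file <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

#' Stage 1: simulate a synthetic cohort to disk
#'
#' Generates a [generate_cohort()] bundle from `config$seed` and
#' `config$cohort` overrides and writes it under `config$data_dir` in the
#' file dialects the infer stage reads back.
#'
#' @param config an `"ndm_config"`.
#' @return The `"ndm_cohort"`, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "ndm_config"))
  spec <- do.call(cohort_spec,
                  utils::modifyList(list(rng_seed = config$seed),
                                    config$cohort))
  cohort <- generate_cohort(spec)
  write_cohort(cohort, config$data_dir)
  echo_config(config, config$data_dir, "simulate")
  if (config$verbose) {
    message(sprintf("simulated cohort: %d controls, %d patients -> %s",
                    spec$n_controls, spec$n_patients, config$data_dir))
  }
  invisible(cohort)
}

#' Stage 2: infer injury epicenters for every patient
#'
#' Reads the cohort files under `config$data_dir`, averages the control
#' connectomes into the healthy template, builds the Laplacian, z-scores
#' each patient against the control cohort, and runs single-seed screening
#' plus the greedy combination search per patient. Writes per-patient JSON
#' records, a summary table, and the predicted atrophy maps at each
#' patient's `t_max`.
#'
#' @param config an `"ndm_config"`.
#' @return Invisibly, a list with `results` (named list of
#'   `"ndm_epicenter_result"`), `summary` (data.frame), `lap`, `stats`.
#' @export
run_infer <- function(config) {
  stopifnot(inherits(config, "ndm_config"))
  dd <- config$data_dir
  parc <- read_parcellation(require_file(file.path(dd, "parcellation.tsv"),
                                         "parcellation"))
  conn_files <- sort(list.files(file.path(dd, "connectomes"),
                                full.names = TRUE))
  if (length(conn_files) == 0L) {
    stop("no connectome files under ", file.path(dd, "connectomes"))
  }
  conns <- lapply(conn_files, read_connectome, parc = parc)
  lap <- graph_laplacian(average_connectomes(conns),
                         normalization = config$normalization)
  controls <- read_volume_table(
    require_file(file.path(dd, "volumes_controls.tsv"), "control volume"),
    parc)
  patients <- read_volume_table(
    require_file(file.path(dd, "volumes_patients.tsv"), "patient volume"),
    parc)
  stats <- compute_control_stats(controls)
  profiles <- all_seed_profiles(lap, config$alpha, config$timepoints)

  out <- file.path(config$out_dir, "inference")
  dir.create(file.path(out, "patients"), recursive = TRUE,
             showWarnings = FALSE)
  results <- list()
  for (id in patients$subjects) {
    res <- tryCatch(
      infer_epicenters(lap, zscore_atrophy(patients$volumes[id, ], stats),
                       config$alpha, config$timepoints,
                       prune = config$prune, profiles = profiles),
      error = function(e) stop("patient ", id, ": ", conditionMessage(e),
                               call. = FALSE))
    results[[id]] <- res
    if (config$verbose) {
      message(sprintf("%s: %d seeds (%s), t_max = %g, R = %.3f",
                      id, length(res$seed_idx),
                      paste(res$seed_names, collapse = "+"),
                      res$t_max, res$r_best))
    }
    rec <- res[c("seed_idx", "seed_names", "t_max", "r_best", "r_squared")]
    rec$predicted <- unname(res$predicted)
    jsonlite::write_json(rec,
                         file.path(out, "patients", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = 12)
  }
  summary <- data.frame(
    patient_id = names(results),
    n_seeds = vapply(results, function(r) length(r$seed_idx), integer(1)),
    seeds = vapply(results, function(r) paste(r$seed_names, collapse = "+"),
                   character(1)),
    t_max = vapply(results, `[[`, numeric(1), "t_max"),
    r_best = vapply(results, `[[`, numeric(1), "r_best"),
    r_squared = vapply(results, `[[`, numeric(1), "r_squared"),
    row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(summary, file.path(out, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pm <- predicted_atrophy_matrix(results)
  utils::write.table(pm, file.path(out, "predicted_maps.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  echo_config(config, out, "infer")
  invisible(list(results = results, summary = summary, lap = lap,
                 stats = stats))
}

#' Stage 3: group-level patterns and clinical associations
#'
#' Reads the inference outputs plus the cohort covariates, runs PCA on the
#' predicted atrophy maps, and computes the two clinical associations:
#' model fit (R^2) versus time since injury controlling for age, and peak
#' time versus time since injury. Writes PCA loadings, the explained-
#' variance table, and the association records.
#'
#' @param config an `"ndm_config"`.
#' @return Invisibly, a list with `pca`, `fit_vs_tsi`, `peaktime_vs_tsi`.
#' @export
run_group <- function(config) {
  stopifnot(inherits(config, "ndm_config"))
  inf <- file.path(config$out_dir, "inference")
  summary <- utils::read.table(
    require_file(file.path(inf, "summary.tsv"), "inference summary"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (nrow(summary) < 4L) {
    stop("need at least 4 patients for the association analyses")
  }
  pm <- as.matrix(utils::read.table(file.path(inf, "predicted_maps.tsv"),
                                    sep = "\t", header = TRUE,
                                    row.names = 1L, check.names = FALSE))
  cov <- utils::read.table(
    require_file(file.path(config$data_dir, "covariates.tsv"), "covariate"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  cov <- cov[match(summary$patient_id, cov$patient_id), ]
  if (anyNA(cov$patient_id)) stop("covariates missing for some patients")

  out <- file.path(config$out_dir, "group")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  k <- min(config$n_components, nrow(pm) - 1L, ncol(pm))
  pca <- pca_predicted_maps(pm, k = k)
  write_pca_loadings(pca, file.path(out, "pca_loadings.tsv"),
                     region_names = colnames(pm))
  ev <- data.frame(component = seq_along(pca$explained_variance_fraction),
                   explained_variance_fraction =
                     pca$explained_variance_fraction)
  utils::write.table(ev, file.path(out, "explained_variance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  results <- lapply(seq_len(nrow(summary)), function(i) {
    list(r_squared = summary$r_squared[i], t_max = summary$t_max[i])
  })
  fit_assoc <- fit_vs_time_since_injury(results, cov$tsi, cov$age)
  peak_assoc <- tryCatch(peaktime_vs_time_since_injury(results, cov$tsi),
                         error = function(e) {
                           structure(list(r = NA_real_, p_value = NA_real_,
                                          n = nrow(summary),
                                          df = NA_integer_,
                                          covariates = character(0),
                                          note = conditionMessage(e)),
                                     class = "ndm_association")
                         })
  assoc <- list(
    fit_vs_tsi = fit_assoc[c("r", "p_value", "n", "df", "covariates")],
    peaktime_vs_tsi = peak_assoc[intersect(names(peak_assoc),
                                           c("r", "p_value", "n", "df",
                                             "covariates", "note"))])
  jsonlite::write_json(assoc, file.path(out, "associations.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  echo_config(config, out, "group")
  if (config$verbose) {
    message(sprintf("PC1-%d explain %.0f%% of variance; fit~TSI r = %.2f (p = %.3g)",
                    k, 100 * sum(pca$explained_variance_fraction[seq_len(k)]),
                    fit_assoc$r, fit_assoc$p_value))
  }
  invisible(list(pca = pca, fit_vs_tsi = fit_assoc,
                 peaktime_vs_tsi = peak_assoc))
}
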