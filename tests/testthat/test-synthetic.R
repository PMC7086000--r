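test_that("connectome generation is deterministic and respects the spec", {
  spec <- test_spec(rng_seed = 101)
  a <- generate_connectome(spec)
  b <- generate_connectome(spec)
  expect_identical(a$weights, b$weights)
  expect_equal(a$weights, t(a$weights))
  expect_true(all(diag(a$weights) == 0))
  expect_true(all(a$weights >= 0))

  # degenerate densities: complete graph with constant weights
  flat <- cohort_spec(n_regions = 6, n_modules = 1,
                      intra_module_density = 1, inter_module_density = 1,
                      weight_scale = 2, weight_sdlog = 0,
                      n_controls = 2, n_patients = 1, rng_seed = 1)
  cn <- generate_connectome(flat)
  off <- cn$weights[upper.tri(cn$weights)]
  expect_true(all(abs(off - 2) < 1e-12))

  expect_false(identical(
    generate_connectome(test_spec(rng_seed = 1))$weights,
    generate_connectome(test_spec(rng_seed = 2))$weights))
})

test_that("edge weights average to the nominal scale", {
  spec <- cohort_spec(n_regions = 60, n_modules = 1,
                      intra_module_density = 1, inter_module_density = 1,
                      weight_scale = 40, weight_sdlog = 1,
                      n_controls = 2, n_patients = 1, rng_seed = 71)
  cn <- generate_connectome(spec)
  w <- cn$weights[upper.tri(cn$weights)]    # 1770 sampled edges
  expect_lt(abs(mean(w) - 40) / 40, 0.05)
})

test_that("control volume tables have the nominal shape and noise level", {
  spec <- test_spec(rng_seed = 73)
  cn <- generate_connectome(spec)
  ct <- generate_controls(spec, cn)
  expect_equal(dim(ct$volumes), c(8L, 20L))
  expect_true(all(ct$volumes > 0))

  # zero control variability: all subjects equal the baseline
  spec0 <- test_spec(rng_seed = 73, control_cv = 0)
  ct0 <- generate_controls(spec0, cn)
  expect_equal(apply(ct0$volumes, 2, stats::sd),
               stats::setNames(rep(0, 20), colnames(ct0$volumes)))

  # empirical per-region SD matches control_cv * baseline on a large draw
  specN <- cohort_spec(n_regions = 15, n_modules = 1,
                       intra_module_density = 1, inter_module_density = 1,
                       n_controls = 2000, n_patients = 1,
                       control_cv = 0.07, rng_seed = 75)
  cnN <- generate_connectome(specN)
  ctN <- generate_controls(specN, cnN)
  sd_emp <- apply(ctN$volumes, 2, stats::sd)
  baseline <- colMeans(ctN$volumes)
  expect_true(all(abs(sd_emp / (0.07 * baseline) - 1) < 0.08))
})

test_that("noise-free patients round-trip to a rescaling of the pathology", {
  spec <- test_spec(rng_seed = 77, noise_sd = 0)
  cn <- generate_connectome(spec)
  ct <- generate_controls(spec, cn)
  stats <- compute_control_stats(ct)
  truth <- list(seeds = c(3L, 9L), true_time = 7)
  x <- generate_patient(spec, cn, stats, truth)
  y <- zscore_atrophy(x, stats)$y
  lap <- graph_laplacian(cn)
  g <- simulate_diffusion(lap, replace(numeric(20), truth$seeds, 1),
                          0.25, 7)$values[, 1]
  g <- g / max(g)
  expect_equal(unname(y), unname(spec$atrophy_gain * g), tolerance = 1e-10)
  expect_equal(stats::cor(y, g), 1, tolerance = 1e-12)

  # null patient: no atrophy, no noise
  spec00 <- test_spec(rng_seed = 77, noise_sd = 0, atrophy_gain = 0)
  x0 <- generate_patient(spec00, cn, stats, truth)
  expect_equal(unname(zscore_atrophy(x0, stats)$y), rep(0, 20))

  # same truth and seed give identical draws
  specN <- test_spec(rng_seed = 79, noise_sd = 0.2)
  expect_identical(generate_patient(specN, cn, stats, truth),
                   generate_patient(specN, cn, stats, truth))

  big <- test_spec(atrophy_gain = 1e6)
  expect_error(generate_patient(big, cn, stats, truth), "non-positive")
  expect_error(generate_patient(spec, cn, stats,
                                list(seeds = 99L, true_time = 7)),
               "valid region")
})

test_that("cohorts bundle every pipeline input reproducibly", {
  spec <- test_spec(rng_seed = 83)
  cohort <- generate_cohort(spec)
  expect_length(cohort$control_connectomes, 8L)
  expect_equal(dim(cohort$control_volumes$volumes), c(8L, 20L))
  expect_equal(dim(cohort$patient_volumes$volumes), c(4L, 20L))
  expect_length(cohort$truths, 4L)
  expect_true(all(vapply(cohort$truths,
                         function(tr) length(tr$seeds) >= 1L, logical(1))))
  expect_equal(nrow(cohort$covariates), 4L)
  expect_true(all(cohort$covariates$tsi >= 1 & cohort$covariates$tsi <= 5))
  expect_true(all(cohort$covariates$age >= 10 & cohort$covariates$age <= 17))

  cohort2 <- generate_cohort(spec)
  expect_identical(cohort$patient_volumes$volumes,
                   cohort2$patient_volumes$volumes)
  expect_identical(lapply(cohort$truths, `[[`, "seeds"),
                   lapply(cohort2$truths, `[[`, "seeds"))

  # seed-set size range is respected
  spec_r <- test_spec(rng_seed = 85, true_seeds_per_patient = c(1L, 3L))
  sizes <- lengths(lapply(generate_cohort(spec_r)$truths, `[[`, "seeds"))
  expect_true(all(sizes >= 1 & sizes <= 3))
})

test_that("cohort files round-trip bit-identically through the io layer", {
  spec <- test_spec(rng_seed = 87)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"))
  expect_equal(parc$region_name, cohort$parcellation$region_name)
  cn <- read_connectome(file.path(dir, "connectomes", "control_01.tsv"), parc)
  expect_equal(cn$weights, cohort$control_connectomes[[1]]$weights,
               tolerance = 1e-12)
  cv <- read_volume_table(file.path(dir, "volumes_controls.tsv"), parc)
  expect_equal(cv$volumes, cohort$control_volumes$volumes, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$spec$n_patients, 4L)
  expect_length(manifest$truths$patient_id, 4L)
})

test_that("inference recovers true seeds across a noisy synthetic cohort", {
  spec <- cohort_spec(n_regions = 30, n_modules = 2, n_controls = 12,
                      n_patients = 8, noise_sd = 0.1, rng_seed = 89)
  cohort <- generate_cohort(spec)
  lap <- graph_laplacian(average_connectomes(cohort$control_connectomes))
  stats <- compute_control_stats(cohort$control_volumes)
  profiles <- all_seed_profiles(lap)
  hits <- vapply(seq_len(spec$n_patients), function(i) {
    id <- cohort$truths[[i]]$patient_id
    atr <- zscore_atrophy(cohort$patient_volumes$volumes[id, ], stats)
    res <- infer_epicenters(lap, atr, profiles = profiles)
    all(cohort$truths[[i]]$seeds %in% res$seed_idx)
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})
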