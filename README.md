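# ndmtbi

Network-diffusion modeling of neurodegeneration after traumatic brain
injury (TBI).

After a moderate-to-severe TBI, gray-matter atrophy keeps progressing for
years and appears at sites remote from — but connected to — the original
injury. `ndmtbi` treats this secondary degeneration as passive spread of
pathology along the structural connectome and inverts the model per
patient: it finds the small set of regions (*injury epicenters*) whose
seeding best predicts the patient's measured atrophy everywhere else.

The core model is the network diffusion model (NDM)

```
f(t) = exp(-α H t) f(0)
```

where `H = D − W` is the graph Laplacian of the (control-average)
connectome, `α = 0.25` the diffusion coefficient, and `t = 0..19` the time
grid. Per patient, the pipeline

1. z-scores regional volumes against the control cohort
   (`z = (X − μ)/σ`), taking `y = −z` as measured atrophy;
2. screens all 82 single-region seeds over all time points, correlating
   predicted with measured atrophy while **excluding each seed's own data
   point** (anti-circularity);
3. filters the screened correlations into a candidate pool and runs a
   deterministic greedy seed-combination search, re-fitting the best time
   `t_max = argmax_t R(f_t, y)` for every trial set;
4. aggregates patients: PCA of the predicted atrophy maps (spatial
   components), model fit vs. time since injury controlling for age, and
   peak time vs. time since injury.

Because patient MRI cannot ship with the package, a first-class synthetic
cohort generator produces connectomes (weighted stochastic block model),
control volume tables, and forward-simulated patients with known
epicenters in exactly the file formats the pipeline reads — every stage is
testable end to end, with ground truth. See the methods vignette
(`vignettes/network-diffusion-epicenters.Rmd`) for the model, parameter
meanings, and design decisions.

## Worked example

```r
library(ndmtbi)

spec   <- cohort_spec(rng_seed = 1)               # 82 regions, 19 controls, 17 patients
cohort <- generate_cohort(spec)
lap    <- graph_laplacian(average_connectomes(cohort$control_connectomes))
stats  <- compute_control_stats(cohort$control_volumes)

atr <- zscore_atrophy(cohort$patient_volumes$volumes["patient_01", ], stats)
res <- infer_epicenters(lap, atr)
res
#> Injury epicenters: L_roi13
#>   t_max = 7, R = 0.953, R^2 = 0.908 (1 candidate sets evaluated)

cohort$truths[[1]]$seed_names                      # the generating truth
#> [1] "L_roi13"
```

The printed result says patient 1's atrophy is best explained by seeding
region `L_roi13` and diffusing to `t = 7`: the seed-excluded Pearson
correlation between predicted and measured atrophy peaks there at
R = 0.953 (R² = 0.908) — and the inferred epicenter matches the region the
synthetic patient was actually generated from, at the generating time.

## Analysis workflow

The full study pipeline is three numbered drivers over the package
functions, writing under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # synthetic cohort -> results/cohort/
Rscript analysis/02_infer.R               # per-patient epicenters -> results/inference/
Rscript analysis/03_group.R               # PCA + associations -> results/group/
```

With the default seed this reports a mean per-patient R of 0.905 (range
0.78–0.97), median `t_max` = 7 (the generating time), 17/17 true epicenters
recovered, and five principal components explaining 65% of the variance in
the predicted atrophy maps.

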