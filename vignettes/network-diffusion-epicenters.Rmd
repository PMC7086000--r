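---
title: "Inferring injury epicenters with network diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring injury epicenters with network diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a moderate-to-severe traumatic brain injury (TBI) the brain does not
simply carry a static lesion: deafferentation and degenerative processes
continue for years, and the resulting gray-matter atrophy appears at sites
remote from — but connected to — the original injury. `ndmtbi` models this
secondary degeneration as *passive diffusion of pathology along the
structural connectome* and inverts the model: given one cross-sectional
atrophy map per patient, it asks which small set of regions ("injury
epicenters"), seeded into the diffusion model, best predicts the observed
atrophy everywhere else.

## The network diffusion model

The substrate is a weighted undirected graph whose 82 nodes are gray-matter
regions (Desikan-Killiany scale) and whose edge weights summarize
white-matter connectivity (streamline counts). Pathology concentration
$f(t)$ evolves by the linear heat equation on the graph,

$$f(t) = e^{-\alpha H t}\, f(0),$$

where $H = D - W$ is the graph Laplacian (degree matrix minus adjacency)
and $\alpha$ the diffusion coefficient. The model is run at $\alpha = 0.25$
over the integer grid $t = 0, \dots, 19$; the time unit is arbitrary, so no
physical-time calibration is attempted.

Because $H$ is symmetric positive semidefinite and small, the propagator is
computed once per time grid by symmetric eigendecomposition
($H = Q \Lambda Q^\top \Rightarrow e^{-\alpha H t} = Q e^{-\alpha \Lambda t}
Q^\top$) and shared across all 82 single-seed simulations. The propagator is
doubly stochastic, so total pathology is conserved and every trajectory
relaxes toward the uniform vector on a connected graph; tiny negative
entries from round-off (magnitude below $10^{-10}$) are clamped to zero.

**Weight scale.** Raw streamline counts reach the thousands, which would
make the combinatorial Laplacian relax essentially instantly on the stated
$(\alpha, t)$ grid — every seed would look identical from $t = 1$ onward.
The default normalization therefore divides $W$ by its largest entry before
forming $D - W$ ("max-weight-scaled"), putting the spectral range near 1 so
the 20-step trajectory actually sweeps from the seeded state to near
mixing. The operator form is unchanged, only the unit of $t$; the
combinatorial Laplacian on raw weights remains selectable. The control
connectomes are averaged element-wise into a single healthy template before
the Laplacian is built, and no thresholding or binarization is applied.

## Measured atrophy

Each patient's regional volume $X_i$ is z-scored against the control
cohort, $z_i = (X_i - \mu_i)/\sigma_i$, with $\mu_i, \sigma_i$ the control
sample mean and sample SD (denominator $n-1$ — material with only 19
controls). Volume *loss* gives negative $z$, while diffusion predictions
are positive, so all correlations use the loss-oriented map $y = -z$:
a positive correlation then literally means "the model predicts the loss
pattern". Volumes are taken as prepared; no intracranial-volume or age
adjustment is applied inside the package — if desired it belongs upstream
of the volume table.

## Epicenter inference

Inference proceeds in three deterministic stages per patient.

**1. Single-seed screening.** Every region in turn is seeded with unit
pathology and the model's prediction at each of the 20 time points is
correlated with $y$, *excluding the seed region's own data point*. This
yields an $82 \times 20$ correlation matrix; per seed, $R_i$ is the best
correlation over time and $t_i$ its arg max. Seed exclusion is the
anti-circularity rule used everywhere in the package: a seed can never gain
credit for being atrophied itself, only for predicting atrophy elsewhere.
At $t = 0$ the restricted prediction is identically zero, so the
correlation is undefined; undefined correlations are recorded as 0 and
flagged, and are treated as non-improvements everywhere.

**2. Initial configuration.** Three filtering rules, applied in order:
(i) $R_i \leftarrow 0$ whenever $t_i$ sits on either end of the grid — a
boundary optimum means the grid did not bracket the best fit; (ii) with the
median computed over the rule-(i)-filtered vector, $R_i \leftarrow 0$ if
$R_i < 0$ *and* $R_i < \mathrm{median}(R)$ — the conjunction is implemented
literally even though it is redundant whenever the median is nonnegative;
(iii) every region with $R_i > 0$ enters the candidate pool.

**3. Greedy combination search.** The published description of the
combination step — a simple iterative technique prioritizing seeds of
higher predictive value — leaves the exact procedure open, so the package
fixes it as *greedy forward selection with a single backward pruning pass*:
start from the pool member with the highest $R_i$; repeatedly re-fit
$t_{\max}$ for every one-seed extension and accept the extension that most
increases the seed-excluded correlation, stopping when none improves it;
then try removing each member once, keeping any removal that does not
decrease the fit (the pruning pass is a switch, default on). Ties resolve
to the earlier time point and the lower region index, so results are fully
deterministic. The fit of a seed set is always evaluated at interior time
points only, mirroring rule (i). The final $(t_{\max}, R)$ is re-computed
from scratch from the returned seed set, and the full search trace is kept
so the monotonicity of the forward path can be asserted on every run.

The per-patient correlation reported everywhere (including the group
analyses) is the seed-excluded one; including the seed points would
reintroduce exactly the circularity the exclusion rule removes.

## Group-level analysis

The 17 predicted atrophy maps (each patient's prediction at their own
$t_{\max}$) are stacked patients-by-regions, column mean-centered, and
decomposed by SVD — regions are the variables, so components are spatial
maps. Sign is fixed by making each component's largest-magnitude loading
positive; the first 5 components are reported by default. Explained-variance
fractions are computed over all $\min(P-1, N)$ components and sum to 1.

Two clinical associations are computed: model fit ($R^2$) against time
since injury controlling for age — a partial correlation implemented by
double residualization (equivalent to the closed form; $p$ from the $t$
distribution with $n-3$ df) — and peak time $t_{\max}$ against time since
injury as a plain Pearson correlation ($n-2$ df). The significance level is
0.05 and no multiplicity correction is applied to these two exploratory
tests.

## The synthetic cohort generator

Patient MRI data cannot ship with the package, so the generator produces
cohorts in exactly the file dialects the pipeline reads, with known ground
truth. Its defaults are the study conditions: 82 regions, 19 controls, 17
patients, ages 10-17, 1-5 years post injury.

| parameter | default | meaning |
|---|---|---|
| `n_regions` | 82 | parcellation size |
| `n_modules` | 4 | communities of the stochastic block model |
| `intra_module_density` / `inter_module_density` | 0.6 / 0.15 | edge probabilities |
| `weight_scale` | 50 | mean edge weight (streamline-count scale) |
| `weight_sdlog` | 1 | log-normal weight spread (heavy right tail) |
| `connectome_jitter` | 0.1 | per-control log-normal edge jitter |
| `n_controls` / `n_patients` | 19 / 17 | cohort sizes |
| `control_cv` | 0.05 | control volume coefficient of variation |
| `true_seeds_per_patient` | 1 | ground-truth epicenter count (or range) |
| `true_time` | 7 | generating diffusion time (interior to the grid) |
| `atrophy_gain` | 3 | peak volume loss, in control SDs |
| `noise_sd` | 0.1 | patient volume noise, in control SDs |

Design notes, in the order they mattered:

* **Modular, heavy-tailed connectomes.** Brain networks are modular and
  streamline-count distributions are strongly right-skewed; with log-normal
  weights the max-scaled Laplacian lands in a spectral range (roughly 0-3)
  where the $t = 0..19$ grid at $\alpha = 0.25$ spans seeding to near-mixing,
  as it must for $t_{\max}$ to be informative. A 5% control volume CV is a
  realistic between-subject spread for regional gray-matter volumes.
* **Atrophy in control-SD units.** A patient's volume in region $i$ is
  $\mu_i - g\,\sigma_i\,\tilde p_i + \sigma_i \varepsilon_i$, where
  $\tilde p$ is the diffusion pattern from the true seeds scaled to peak 1,
  $g$ = `atrophy_gain`, and $\varepsilon_i \sim N(0, \texttt{noise\_sd})$.
  Expressing the loss in units of the *same* control statistics used for
  z-scoring makes the round trip exact: at `noise_sd = 0` the recovered
  $y$ is exactly $g\,\tilde p$, so the generating process is precisely the
  analysis model and noise-free pipeline runs must (and do) recover the
  true seeds with $R \to 1$ and $t_{\max}$ = `true_time`. This is the
  module's core oracle. Scaling the loss by $\mu_i$ instead (fractional
  volume loss) would break exactness whenever the empirical $\mu/\sigma$
  ratio varies across regions, conflating generator artifacts with
  inference error. A peak loss of 3 SD matches the severity of
  moderate-to-severe TBI atrophy.
* **Separate control and patient noise.** Control variability
  (`control_cv`) must stay positive for z-scoring to exist, so the patient
  noise knob (`noise_sd`) is a separate parameter; "noise-free" always
  means noise-free *patients*.
* **Jittered control connectomes.** Each control's connectome is the
  template with multiplicative log-normal edge noise, so the averaging step
  is exercised and the analysis Laplacian differs slightly from the
  generating one — a mild, realistic model mismatch.

What the generator does **not** emulate: real tractography topology and its
distance-dependent biases, spatially correlated volume noise, intracranial
volume and age effects, lesion masks, and multifocal contusive injury
beyond multi-seed ground truths. Passing recovery tests therefore show the
*inference machinery* is correct and well-calibrated under its own model
class — they cannot show that real TBI degeneration follows linear network
diffusion.

## Numerical choices

* Matrix exponentials via symmetric eigendecomposition (no Padé/squaring):
  one decomposition serves all seeds and times at $N \approx 82$.
* Kernel/profile entries in $(-10^{-10}, 0)$ are clamped to 0; eigenvalues
  are floored at 0.
* Connectome asymmetry up to $10^{-6}$ (relative) is symmetrized by
  averaging; anything larger is a data error, not noise.
* Zero-variance detection uses a scale-aware threshold
  (`sd <= eps^0.75 * max(1, max|x|)`).
* Disconnected graphs warn rather than fail — diffusion remains defined per
  component — and the zero eigenvalue multiplicity equals the component
  count.
* The block-model generator retries up to 25 draws to obtain a connected
  graph, inside one seeded RNG stream, so outputs stay reproducible.

## Validation scale

The shipped tests validate diffusion against closed forms on 2-node graphs
and an explicit-Euler ODE oracle (step $10^{-4}$) on 82-node graphs; the
greedy search against exhaustive subset enumeration on 20-node graphs with
4-candidate pools; seed recovery on a 50-patient, 82-region cohort at
`noise_sd = 0.1` (requiring ≥ 90% recovery and median $t_{\max}$ within 2
of the generating time); PCA and partial correlations against independent
closed-form oracles; and byte-identical end-to-end reruns under a fixed
seed. These sizes were chosen so the whole suite exercises the full design
scale while running in well under a minute.

## Known limitations

* The model is linear and passive: no reaction term, no directionality, no
  per-patient $\alpha$ fitting (the coefficient is fixed by design).
* Greedy selection does not guarantee the global subset optimum; the
  exhaustive comparison bounds its gap only at small pool sizes, and large
  candidate pools can in principle overfit by accumulating seeds.
* $t_{\max}$ is a grid index with arbitrary units; comparisons across
  connectome normalizations are not meaningful.
* The two clinical association tests are exploratory and uncorrected.
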