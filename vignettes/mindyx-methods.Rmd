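---
title: "Modeling joint rest and task brain dynamics with mindyx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling joint rest and task brain dynamics with mindyx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindyx)
```

## The model

`mindyx` treats parcellated fMRI as observations of a discrete-time nonlinear
dynamical system over `n` brain regions. The hidden neural state
$x_t \in \mathbb{R}^n$ evolves as

$$x_{t+1} = x_t + W\,\psi_\alpha(x_t) - D \odot x_t + B u_t + \varepsilon_w,$$

and the measured BOLD signal is $y = h * x + \varepsilon_v$, a causal
convolution of the state with a hemodynamic response function plus Gaussian
observation noise. One model step corresponds to one repetition time (TR,
0.72 s in the layouts emulated here).

The ingredients, and what they mean:

* `W` — the *effective connectivity*: a directed, signed coupling matrix,
  parameterized as a sparse matrix plus a low-rank product,
  `W = Ws + W1 %*% t(W2)`. The sparse part carries interpretable
  region-to-region edges; the rank-`k` part absorbs diffuse global structure
  at far fewer parameters than a dense matrix.
* $\psi_\alpha$ — an elementwise sigmoid,
  $\psi_\alpha(x) = \sqrt{\alpha^2 + (bx + 1/2)^2} - \sqrt{\alpha^2 + (bx - 1/2)^2}$
  with fixed $b = 20/3$. It is odd, strictly increasing and bounded in
  $(-1, 1)$. Small $\alpha$ gives a step-like regional response, large
  $\alpha$ a flat one; the slope at the origin is $b/\sqrt{\alpha^2 + 1/4}$.
  Fitted values of $\alpha$ concentrate around 5.
* `D` — nonnegative per-region decay rates (local leak/inhibition).
* `B u_t` — the task drive. `u_t` is a per-volume indicator vector built
  from block designs: a one-hot code during condition blocks and the zero
  vector during rest and block intervals, so rest is literally the
  zero-input regime of the same system.
* $\varepsilon_w$, $\varepsilon_v$ — process and observation noise, zero-mean
  Gaussian and independent across regions.

The scientific payoff is not the one-step fit itself but the *attractor
landscape* of the fitted map: its stable equilibria and limit cycles under
each constant input, how task input reshapes them (bifurcation), and where
observed states sit relative to population-level attractor motifs.

## Deconvolution

Fitting happens in neural-state space, so BOLD runs are first deconvolved
with `wiener_deconvolve()`:

$$X(f) = \frac{H^*(f)\, Y(f)}{|H(f)|^2 + 1/\mathrm{snr}},$$

the minimum mean-squared-error inverse filter under a flat signal-to-noise
prior, default `snr = 50` (the assumed ratio of neural-signal variance to
observation-noise variance, applied uniformly across frequency bands). The
HRF defaults to the canonical double gamma (peak 6 s, undershoot 16 s, unit
dispersions, undershoot ratio 1/6, 32 s support, unit peak).

Numerical conventions, chosen where the procedure is underdetermined:

* Each run is filtered whole, zero-padded to the next power of two.
* Each parcel series is de-meaned before the FFT; the removed mean is
  restored *through the filter's DC response* rather than verbatim, so a
  constant offset is treated consistently with every other frequency (a raw
  restore would inflate the neural estimate by the HRF's DC gain, about 6.6
  at TR = 0.72 s).
* The filter is acausal: within roughly one kernel length (~45 volumes) of
  the run boundaries it lacks the future or past samples it needs, and the
  estimate there is untrustworthy. Fidelity checks in the test suite
  therefore evaluate interior volumes.

What deconvolution cannot do: $|H(f)|$ is tiny above ~0.15 Hz, so any neural
variance up there is multiplied by nearly zero in the BOLD and cannot be
recovered at any SNR. Deconvolved series are intrinsically smoother than the
true state. The consequences for fitting are discussed below.

## Preparation of measured runs

`normalize_run()` linearly detrends each parcel and standardizes it; task
runs can be standardized by the mean and standard deviation of their block
intervals so that interval volumes look like resting data.
`regress_confounds()` removes nuisance series (e.g. white-matter principal
components) by per-parcel OLS. `scrub_interpolate()` replaces
high-framewise-displacement volumes (conventional thresholds: 0.2 mm rest,
0.9 mm task) by linear interpolation between clean neighbors, copying the
nearest clean value at run edges, and reports the flagged fraction so callers
can apply an exclusion rule (e.g. more than 1/3 flagged). Framewise
displacement is an input; the package does not compute it from motion
parameters.

## Fitting

`fit_mindyx()` minimizes

$$J = \tfrac{1}{2}\|x_{t+1} - \hat x_{t+1}\|_2^2
  + \lambda_1 \|W_s\|_{1,1} + \lambda_2 \mathrm{Tr}|W_s|
  + \lambda_3 (\|W_1\|_{1,1} + \|W_2\|_{1,1}),$$

with $(\lambda_1, \lambda_2, \lambda_3) = (0.075, 0.2, 0.05)$. The extra
diagonal penalty on `Ws` suppresses its redundancy with the decay term. The
squared error is averaged over each minibatch (scale-stable across batch
sizes); penalties are added once per batch.

Training draws minibatches of 300 transition triplets $(x_t, u_t, x_{t+1})$
uniformly across all runs (pairs never span a run boundary) and performs
5000 NADAM updates by default. Choices the protocol leaves open, fixed here:

* Optimizer hyperparameters: learning rate 2e-3, $\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon =$ 1e-8; all exposed in `fit_config()`.
* Initialization: weight matrices from N(0, 0.01); $\alpha = 5$ (its typical
  fitted value), `D = 0.5`.
* The l1 terms are handled by proximal soft-thresholding of `Ws`, `W1`, `W2`
  after each NADAM step — stabler than subgradients and the reason fitted
  `Ws` contains exact zeros.
* $\alpha$ and `D` are projected to $\ge$ 1e-6 after every update.
* The rank defaults to `min(72, n - 1)` so small problems stay well posed.

After gradient descent, `global_rescale()` corrects the systematic shrinkage
that l1 regularization leaves on the fitted terms: three scalars
$(p_W, p_D, p_B)$ are fit by ordinary least squares (no intercept, matching
the one-step prediction form) and folded into `W`, `D`, `B`. A term absent
from the training data — such as `B u` when only rest runs are supplied — is
left at factor 1 and flagged rather than estimated from a degenerate
regressor.

Model comparison baselines (`fit_baseline()`): VARX(1,1)
($x_{t+1} = A x_t + B u_t + \varepsilon$, l1 on `A` via glmnet over the grid
$\lambda \in \{0, 0.001, 0.005, 0.01, 0.05\}$ with 0.01 the conventional
choice), ARX(1,1) (diagonal decay only), and a static GLM
($x_t = \mu + \beta u_t + \varepsilon$). `crossval_r2()` scores any
dynamical model by one-step $R^2$ on held-out runs, per parcel and pooled.

## Simulation and noise calibration

`simulate_noise_free()` iterates the deterministic map (used for attractor
probing); `simulate_noise_driven()` adds independent Gaussian process noise
per parcel each step, runs a 1000-step zero-input warm-up to reach the
stationary regime, then applies the task design. The process-noise variance
for a fitted model is taken from the model's own mean squared one-step
prediction error per parcel (`fit_mindyx()` reports it as `noise_sd`),
i.e. the unexplained variability is treated as the intrinsic noise.
`generate_bold()` closes the loop with the observation model: causal HRF
convolution plus observation noise at `var(x)/snr` per parcel. A divergence
guard flags trajectories exceeding $10^6$ in magnitude — fitted models are
empirically bounded, but synthetic ones need not be.

## Attractor identification

`find_attractors()` probes one constant input with 120 standard-normal
initial conditions, 1600 noise-free steps each:

* *Equilibrium*: every per-parcel change over the last 10 steps below 1e-6;
  the final state is the candidate. Candidates are grouped by single-linkage
  clustering at Euclidean distance 0.1; group centroids are the reported
  equilibria, with basin counts.
* *Limit cycle*: a non-converged trajectory that entered and later left the
  radius-0.5 ball around its final state. The period is the interval between
  the last two entries into that ball — for a closed orbit this is exactly
  one revolution, whereas measuring from the final entry to the end of the
  simulation would return only the width of the terminal neighborhood
  crossing. Duplicate cycles are merged when their symmetric mean
  minimum point-to-orbit distance falls below 0.5 (the same scale as the
  detection radius; the deduplication threshold is otherwise unspecified in
  the protocol this follows).
* Unresolved trajectories are extended by doubling up to 25,600 steps; if any
  remain unresolved (or diverged), the set carries `unclassified_flag`
  instead of being silently dropped.

Stability is established by convergence of forward simulation, not by
Jacobian eigenvalues (a Jacobian check, `verify_equilibria()`, exists for
diagnostics). Topology is then classified: *oscillatory* if at least one
stable limit cycle exists (regardless of equilibria), else *multistable*
with two or more equilibria, else *monostable*; `bifurcation_flag()` marks a
model whose class differs between two inputs (e.g. rest vs. a task
condition).

## Motifs, occupancy and features

Equilibria pooled across a population of models are clustered on the unit
sphere with spherical K-means (`kmeans_cosine()`): cosine distance compares
activation *patterns* irrespective of amplitude. The number of motifs is
chosen by clustering instability (`select_k_by_instability()`): for each K,
points are repeatedly split into random halves, each half clustered, all
points assigned to both solutions, the labelings aligned by exact
maximum-agreement matching (assignment problem solved by dynamic programming
over label subsets), and the mean disagreement recorded; the selected K is
the smallest local minimum of this curve over K = 2..10. The left comparison
of the local-minimum rule is non-strict: with cleanly separated clusters the
instability can be exactly zero for several K (merging the two closest
bundles is itself deterministic), and a tie plateau should resolve to its
largest K — equally stable, finer structure. With no interior local minimum
the global minimum is used.

Per subject, `label_volumes()` assigns each observed volume to the motif of
highest cosine similarity (ties to the lowest index; zero-norm volumes
dropped), giving *occupancy* fractions that sum to one, and
`occupancy_and_distances()` also returns the mean Euclidean distance from
every volume to each motif centroid — by default over all volumes of the
condition, with a `volumes` argument to restrict to in-block volumes, since
the convention is ambiguous. Distances live in the same deconvolved,
standardized state space the model was fit in. `build_feature_table()`
assembles the behavioral predictors: the bifurcation indicator, K - 1
occupancy columns (one dropped as collinear: occupancies sum to one), and K
distance columns, optionally plus rest-condition distances.
`fit_behavior_model()` and `behavior_model_specs()` run the standard OLS
model family (bifurcation-only, occupancy, distance, additive, interaction)
with closed-form fit statistics and nested-F comparisons.

## The synthetic generator

`make_ground_truth()` and `synthesize_session()` exist so that every stage is
testable against a known truth without access to restricted neuroimaging
data. The default layout mirrors a working-memory session at desk scale:
n = 15 parcels, rank k = 5, two rest runs of 1000 volumes, one task run of
400 volumes at TR = 0.72 s with four 25 s blocks per condition (`cond_1`,
`cond_2`, emulating 0-back/2-back-like blocks), observation SNR 50.

Design choices, fixed once:

* **Near-critical coupling.** The background connectivity is scaled so the
  linearization at the origin has spectral radius 0.9. This produces the
  slow, approximately unit-variance fluctuations characteristic of resting
  fMRI, concentrates state variance inside the hemodynamic passband, and
  gives true weights large enough that the l1 penalties (calibrated for
  standardized, strongly coupled data) do not annihilate them.
* **Process noise** `process_sd = 0.3`, giving held-out one-step $R^2$
  around 0.7 at the default layout — the same order as empirical fits.
* **Regimes.** Multistable: two parcels get supercritical self-excitation
  (self-gain 1.6 times their decay), each contributing a pair of stable
  states. Oscillatory: a parcel pair gets a rotational block whose
  linearization is an unstable spiral (growth 1.15, ~40-step rotation);
  activation saturation bounds it into a limit cycle. Monostable: the
  near-critical background alone. Every draw is verified post hoc with
  `find_attractors()` and redrawn up to five times; the regime is a property
  of the realized model, not an assumption.
* **Task drive.** `B` carries a planted half-positive/half-negative parcel
  split (task-positive vs. task-negative regions), condition 2 stronger than
  condition 1.

What the generator does *not* emulate: head motion, physiological noise
spectra, regional HRF variability, multi-band artifacts, or session-level
nonstationarity. Passing tests show the pipeline's operations are correct
and mutually consistent under the stated generative model — not that real
data satisfy that model.

## What end-to-end tests can and cannot show

Two limitations surfaced by the synthetic truth are worth stating plainly.

First, fitting through the observation path (HRF convolution, then Wiener
deconvolution) cannot recover the generating parameters with high fidelity
when the process noise is white: most of that noise's variance lies above
the hemodynamic passband, is destroyed by the measurement, and the
deconvolved series is consequently markedly smoother (more autocorrelated)
than the true state. Parameter recovery is therefore validated at the
neural level (the suite requires off-diagonal `W` correlation with truth of
at least 0.8 at n = 15), while the observation path is validated at the
level it supports: topology recovery and recreation of FC and GLM
statistics.

Second, the same smoothing biases the fitted one-step map toward higher
effective gain: models fit to deconvolved data from a *monostable*
near-critical truth come back with a supercritical linearization and a
multistable landscape, while multistable truths are recovered faithfully. This mirrors the empirical
observation that models fit to real resting data are never monostable, and
it means absence of monostability in fitted models should not by itself be
read as evidence about the underlying system. The suite therefore checks the
full deconvolution path on multistable truths and the monostable regime on
neural-level fits.

## Problem sizes and runtime

All simulation-based tests run at the desk-scale defaults (n = 15 parcels,
sessions of 2400 volumes, 1500–2000 minibatches, 5 seeds where a claim is
about seed stability; 120 starts by 1600 steps for attractor probing; 20
seeds by 25 resamples for motif-selection stability). At these sizes a full
fit takes on the order of a second and the entire suite a few minutes on one
CPU; `scripts/acceptance.R` re-runs the headline analyses in about half a
minute. All randomness flows from explicit seeds; identical seeds reproduce
archives, trajectories and attractor sets bit for bit.

## Known limitations

* The canonical HRF parameterization is a convention; regional and
  individual HRF variability is not modeled.
* Whether deconvolution should be applied per run or to concatenated runs is
  unspecified upstream; the package filters per run.
* The instability index follows the half-split/exact-matching construction
  described above; other instability formulations exist and may select
  different K on ambiguous data.
* Continuous-time variants, region-specific `b`, hierarchical fitting,
  chaos diagnostics and bifurcation-diagram continuation are out of scope.
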