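---
title: "The stochastic-variational posture model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stochastic-variational posture model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical model, the design
choices behind it, and what the accompanying simulations do and do not
demonstrate. It is written for a reader who wants to understand or modify the
method, not just run it.

## 1. The pipeline

A camera-based fall monitor produces one bounding box per frame around the
tracked person. The package models everything downstream of the detector:

1. **Centroid features** (`extract_centroids()`): each box becomes its
   centroid, normalized by the frame dimensions (so a 1.6 m webcam and a
   3.1 m surveillance camera share a scale), in image convention (origin
   top-left, y downward). Speeds are backward differences times the frame
   rate; the first sample of a stream has speed zero. No smoothing is
   applied: the windowed pooling below is the smoother.
2. **Windows** (`make_windows()`): sliding 21-frame windows
   (BBox(t)…BBox(t+20)), anchored and labeled at their first frame, default
   stride 1. Windows spanning a recording gap larger than two frame periods
   are dropped rather than interpolated.
3. **Attention block** (`attention_forward()`): per time point, a gate
   `c(t) = 4*softmax(W f(t) + b)` re-weights the four channels of
   `f(t) = (x, y, vx, vy)`; the gated feature is `c(t) ⊙ f(t) + f(t)`
   (a residual add); the window is mean-pooled and projected 4 → 2. The
   softmax is rescaled by 4 so the all-equal gate multiplies every channel by
   exactly 1, making "no attention" the identity. Gating is per time point
   only; there is no cross-time attention, because the pooled window already
   mixes time and the 2-D maps downstream need a fixed-dimensional summary.
4. **Mixture** (`svi_fit()`): a K-component Gaussian mixture over the 2-D
   features with variational distributions on all parameters, trained by
   stochastic variational inference (below).
5. **Maps and alarms**: posterior responsibilities classify points into
   cluster regions named from labeled training data; `likelihood_map()` /
   `region_map()` render the probabilistic maps; `alarm_state_machine()`
   turns streamed classifications into staged warnings.

## 2. The variational mixture

Per cluster k the mean carries `μ_k ~ Normal(N1_k, diag(N2_k))`, the
precision `Σ_k⁻¹ ~ Wishart(W1_k, W2_k)` and the weights jointly
`α ~ Dirichlet(D)`. The priors are `Normal(0, 1)` per mean coordinate,
`Wishart(3, I/3)` (prior mean precision = identity; 3 degrees of freedom is
the smallest integer choice valid in two dimensions), and a symmetric
Dirichlet. The Dirichlet concentration is `2/K` per component by default — a
weakly informative choice — with the literal alternative `2K` selectable via
`prior_spec(dirichlet_interpretation = "2K")`.

The training objective is the negative Monte-Carlo evidence lower bound

```
loss = −[ (1/L) Σ_l  mean_batch ln p(s | z_l)  −  w_KLD · KLD(q(z) ‖ p(z)) ]
```

with `L` reparameterized draws `z_l` of the full parameter set per mini-batch
(one draw shared across the batch, not one per point). `svi_loss()` exposes
this quantity with `w_KLD = 1`, the plain batch formula, which satisfies
`loss ≥ −(1/L) Σ_l mean ln p` because a KLD is nonnegative. For *training*,
the two terms must live on the same per-sample scale — otherwise the prior,
which enters once, overwhelms a batch-mean likelihood and shrinks every
cluster toward the prior — so `svi_fit()` uses `w_KLD = 1/n` with `n` the
training-set size (equivalently: the mini-batch estimates the full-data
log-likelihood `n × mean_batch`). This is the standard stochastic-variational
scaling; `svi_config(kld_weight=)` overrides it.

**Reparameterized draws** (`sample_gmm_params()`): means by the
location-scale transform `N1 + sqrt(N2)·ε`; precisions by the Bartlett
decomposition with inverse-CDF chi-square diagonals (`qchisq(u, ν)` is smooth
in ν for fixed u, so the draw is pathwise differentiable in every variational
parameter once the underlying `(ε, u)` are held fixed); weights by normalized
inverse-CDF Gamma draws. Draws are deterministic given a seed.

**Diagonal covariance mode.** A Wishart with a diagonal scale matrix does not
produce diagonal draws, so the diagonal family is the Wishart's diagonal
analogue: independent `Gamma(ν/2, scale 2·w_i)` precisions per axis — exactly
the marginal of the Wishart diagonal, with the same mean `ν·W2` — and the
precision KLD becomes a sum of closed-form Gamma KLDs (the Wishart KLD
restricted to that family). `expected_gmm()`, which summarizes the state as a
point mixture (`μ = N1`, `Σ = (W1·W2)⁻¹`, `α = D/ΣD`), is exact in both
modes.

**Closed-form KLDs** (`kld_variational_prior()`): Gaussian-to-Gaussian for
the means, Wishart-to-Wishart (full) or Gamma-to-Gamma (diagonal) for the
precisions, Dirichlet-to-Dirichlet for the weights. The test suite checks
each term against numerical quadrature and checks nonnegativity over random
states.

## 3. The training core

No automatic differentiation is used: the gradient of the loss is computed
pathwise by forward finite differences in compiled code, with the
mini-batch and the reparameterization noise held fixed while each
unconstrained parameter is perturbed (common random numbers). Constraints are
structural, never projected post hoc: log for the mean variances, a shifted
log for the Wishart degrees of freedom (ν = dim−1 + e^θ), lower-Cholesky
factors with log diagonals for the Wishart scales, and a numerically stable
softplus for the Dirichlet concentrations.

The optimizer is gradient descent with momentum 0.9 and step size 1e-2,
augmented with per-coordinate RMS scaling (Adam, β₂ = 0.999). The scaling is
not cosmetic: posture clusters have within-cluster variances around 1e-5 in
normalized units (a resting subject moves by detector jitter only), which
makes the precision parameters orders of magnitude stiffer than the means;
unscaled momentum descent diverges on such data at any useful step size.

Joint training of the attention block required three further choices, each
adopted after the unconstrained version demonstrably failed:

* **The projection is frozen by default**
  (`svi_config(train_projection = FALSE)`), at a template that passes
  vertical position and vertical speed — the canonical fall-discriminative
  kinematics — through to the feature plane. An unconstrained projection is
  scale-degenerate (shrinking it inflates the density of the projected
  features at no cost), and even constrained to orthonormal it tends to
  *rotate* the rare, heavy-tailed fall direction out of the plane, because an
  unsupervised Gaussian likelihood prefers channels without heavy tails. The
  gates and bias — the attention weights proper — remain fully trained.
  `train_projection = TRUE` restores the fully learned projection.
* **Orthonormality penalty** `10·‖PᵀP − I‖²_F` whenever the projection is
  trained, removing the scale degeneracy; channel weighting is the gates'
  job.
* **A small ridge** `0.5·(‖W‖² + ‖b‖²)` anchors the gate map at the identity
  unless the data pay for a deviation, preventing slow diffusion along
  directions the mixture likelihood is indifferent to.

**Initialization.** k-means (5 restarts) on the initial features sets `N1`;
each cluster's sample covariance (plus a relative ridge of 1e-4 of the total
feature variance) sets `W2` through `W1·W2 = Σ̂_k⁻¹`; and the concentrations
start at posterior-like values, `W1_k = n_k`, `D_k = n_k`, and
`N2_k = diag(Σ̂_k)/n_k` (the sampling variance of a cluster mean). Diffuse
concentrations (ν ≈ 10) make each sampled precision fluctuate by ~45%,
which early in training smears the components and collapses small clusters;
the posterior-like start gives the sampler the noise level the data actually
support and leaves gradient descent to polish, not rescue, the state.

**Cluster naming** (`assign_cluster_labels()`): after unsupervised training,
each cluster takes the majority ground-truth label of the training points it
claims (hard assignment), ties resolved toward the more severe label under
the fixed order normal < transition < falling.

**Training-set balance.** A full protocol session is ~93% normal frames; an
unsupervised K = 3 mixture on such data spends its components on the dominant
mass (splitting walking from spinning) rather than on the brief descent.
`fit_posture_model(balance = "match")` therefore subsamples normal-labeled
windows down to the non-normal count before training — labels steer only the
composition of the training set, never the loss. The published per-point
counts of the protocol this emulates are similarly non-normal-dominated.
`balance = "none"` disables it.

**Optional empirical-Bayes mode.** `svi_config(prior_refresh_every = k)`
copies the variational summary into the prior every k steps (the prior then
tracks the accumulated data); it is off by default and not used by any
shipped analysis.

## 4. Alarms

`classify_point()` assigns the region of the maximum-responsibility cluster
when that responsibility reaches the threshold (default 0.5), else
"uncertain"; ties go to the lowest cluster index. The state machine requires
`persistence` (default 3) consecutive consistent classifications to change
state — escalation and de-escalation alike — and "uncertain" points neither
advance nor reset the run. Both defaults are configurable; 3 samples at
60 FPS adds 50 ms of latency, negligible against the ~0.7 s descent. Events
are dated by the window anchor; note a window anchored at t summarizes frames
t…t+20, so a real-time deployment incurs a third of a second of look-ahead
latency on top of the persistence filter.

`lead_time(n, fps) = n/fps` converts a centroid-point count into seconds:
the 40-point transit of the transition region at 60 FPS spans 0.667 s, which
is the scale of early warning the staged alarm provides.

## 5. Maps and normalization

Maps live on the min-max normalized unit square. `normalize_features()` fits
the per-axis transform on training points only and returns a record that
re-applies it to new points; normalized tibbles carry a flag so accidental
double normalization errors out. Min-max scaling is affine, so
`transform_gmm()` maps the fitted mixture into normalized coordinates
*exactly* (means like points, covariances by the diagonal scaling on both
sides) — maps are rendered from the transformed mixture rather than refitted.
`likelihood_map()` evaluates the mixture density at cell centers (default
resolution 200×200); `region_map()` tags each cell by posterior argmax;
`covariance_ellipses()` eigendecomposes each covariance into center,
semi-axes (`n_std·√λ`) and rotation. Region maps are partitions by
construction, and as resolution grows the density mass inside each region
converges to the component weight for well-separated clusters (tested at
128 vs 512).

## 6. The session simulator

`simulate_session()` emulates the monitoring protocol: a short approach walk
(constant-velocity centroid with a 2 px gait bob), ~30 s of in-place spinning
(stationary centroid with small oscillation, box width oscillating with the
rotation), a fall whose centroid descends along a smoothstep over 0.7 s
(≈ 40 frames at 60 FPS — it accelerates, then decelerates into the mattress,
so the annotated `impact_time` is the instant the centroid comes to rest),
then prone rest. Boxes are perspective-scaled by a pinhole model with the
camera (height 1.6 m or 3.1 m, ~3 m from the subject) aimed at the standing
centroid; subject heights are drawn from Normal(1.586 m, sd 0.143 m);
independent Gaussian jitter of `noise_sd` pixels (default 1 px on a 640×480
frame, typical of a stable detector) perturbs every corner. Frames are
labeled normal, transition (the 40 pre-impact frames) or falling (impact
onward). `simulate_cohort()` draws a cohort and emits both camera geometries
per subject.

What the simulator does *not* reproduce: detector dropouts and identity
switches, occlusion, lens distortion, non-fall confounders (sitting, bending,
picking objects up), multi-person scenes, and the biomechanical variety of
real falls. Passing the end-to-end tests therefore shows that the inference
machinery recovers the structure this template encodes under jitter and
geometry changes — it is a statement about the method, not a clinical
validation on real falls.

## 7. Problem sizes and numerical choices

The shipped analyses use: 2 000–5 000 points for cluster recovery and the
EM-agreement check; 2 000 training / 1 000 held-out points for the
covariance-mode and component-count comparisons (1 200 steps); cohorts of 3–4
subjects × 2 cameras (≈ 2 400 balanced windows, 1 200–1 500 steps) with 12
held-out sessions for the end-to-end alarm study. Defaults elsewhere:
L = 10 Monte-Carlo draws, batch 64, 2 000 steps.

Numerics worth knowing: mixture log-densities always go through log-sum-exp;
responsibilities are computed in the log domain and normalize to 1 within
1e-12; softplus and its inverse switch to the identity above 30 to avoid
overflow at posterior-scale concentrations; degenerate inputs error eagerly
with specific messages ("stream too short", "degenerate axis", "training
diverged at step …"); and all randomness flows from explicit seeds —
identical seeds give bit-identical training traces, and the variational state
round-trips through JSON bit-exactly (17 significant digits).

## 8. Known limitations

* The attention block is a per-time-point gate; sequence-to-sequence
  attention across the window is out of scope.
* The feature plane is 2-D by design (it is what the probabilistic maps
  display); richer projections would need the map machinery generalized.
* Unsupervised joint feature learning remains delicate: the shipped defaults
  (frozen projection, gate ridge) trade some adaptivity for robustness, and
  `train_projection = TRUE` should be used with care on imbalanced data.
* The alarm's look-ahead window means streamed decisions lag the anchor time
  by 20 frames; latency-critical deployments should weigh shorter windows.
* K is fixed by the user (2 or 3 in the intended use); there is no automatic
  component selection.
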