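# fallgmm

Probabilistic human-posture classification and staged fall alarms from
bounding-box trajectories.

Camera-based fall monitoring systems run an object detector on each video
frame and obtain, per frame, a bounding box around the person. `fallgmm`
implements everything downstream of the detector: it turns the time-stamped
box stream into centroid kinematics, learns a probabilistic map of posture
states with a stochastic-variational Gaussian mixture, and raises staged
warnings — an instability warning when the trajectory enters the transition
region of the map and a fall alarm when it enters the falling region — early
enough that the fall alarm typically precedes the impact itself. It is aimed
at researchers in biomedical monitoring and human-movement analysis who want
a transparent, statistically grounded alternative to end-to-end black-box
classifiers.

## The model

**Features.** Each detected box at frame *t* is reduced to its normalized
centroid and backward-difference speed, f(t) = (x(t), y(t), vx(t), vy(t)).
A self-attention gate re-weights these four channels at every time point of a
21-frame window (BBox(t) … BBox(t+20)):

    c(t) = 4 · softmax(W f(t) + b),      o(t) = c(t) ⊙ f(t) + f(t)

(⊙ is the Hadamard product; the rescaled softmax makes the all-equal gate an
identity multiplier, and the residual keeps the raw signal). The gated
features are mean-pooled over the window and projected to a 2-D feature
vector s — the point that is plotted on the posture maps.

**Mixture.** The feature vectors follow a K-component Gaussian mixture

    p(s | z) = Σₖ αₖ N(s | μₖ, Σₖ),    K ∈ {2, 3}

whose parameters carry variational distributions: μₖ ~ Normal(N1, N2),
Σₖ⁻¹ ~ Wishart(W1, W2), α ~ Dirichlet(D), with priors Normal(0, 1),
Wishart(3, I/3) and a symmetric Dirichlet. Training maximizes a Monte-Carlo
evidence lower bound: with L reparameterized draws of the mixture parameters,

    loss = −[ (1/L) Σₗ ln p(s | zₗ) − KLD(q(z) ‖ p(z)) ]

is minimized by mini-batch gradient descent that updates the attention gates
and the variational parameters N1, N2, W1, W2, D jointly (pathwise
finite-difference gradients in compiled code). Posterior responsibilities
p(z | s) classify each point; clusters are named normal / transition /
falling by majority vote of labeled training windows; and a persistence-
filtered state machine turns the streaming classifications into Warning1
(transition region) and Warning2 (falling region) events.

Because no public recordings of the protocol exist, the package ships a
kinematic session simulator (walk → ~30 s in-place spinning → fall onto a
mattress, 60 FPS, two camera heights of 1.6 m and 3.1 m, detector jitter)
that generates labeled streams for every test.

## Worked example

```r
library(fallgmm)

cohort <- simulate_cohort(n_subjects = 3, seed = 1)
fit <- fit_posture_model(cohort, K = 3, covariance_mode = "full",
                         config = svi_config(steps = 1500), seed = 2)
fit
#> Stochastic-variational Gaussian mixture
#>   K = 3, covariance: full, n = 2400, steps = 1500
#>   final loss: -1.77648
#>   regions: normal, transition, falling

tidy(fit)
#> # A tibble: 3 × 8
#>   cluster weight mean_s1 mean_s2  var_s1  var_s2   cov_s1_s2 region
#>     <int>  <dbl>   <dbl>   <dbl>   <dbl>   <dbl>       <dbl> <chr>
#> 1       1 0.498     1.07 0.00522 0.00172 0.00293  0.00000459 normal
#> 2       2 0.0682    1.28 0.476   0.0235  0.0387  -0.00524    transition
#> 3       3 0.434     1.39 0.00748 0.00468 0.00371  0.0000588  falling
```

The three mixture components recover the three posture regimes: the normal
cluster (low vertical speed, standing height), the transition cluster
(elevated downward speed during the pre-impact descent) and the falling
cluster (prone height, zero speed). Streaming a held-out fall session through
the model:

```r
session <- simulate_session(session_spec(seed = 99, camera_height = 3.1))
pred <- predict_session(fit, session)
mean(pred$region == pred$label)
#> [1] 0.9913119

alarm_state_machine(pred, fit)
#>      state  t_enter trigger_index     p_normal p_transition    p_falling
#> 1 warning1 34.91667          2096 6.192281e-02   0.93804950 2.768774e-05
#> 2 warning2 35.55000          2134 9.266898e-12   0.03530291 9.646971e-01
session$impact_time
#> [1] 35.7
```

Warning1 fires 0.78 s and Warning2 0.15 s *before* the annotated impact —
the staged early-alarm behavior the method is built for. The transit of the
transition region spans about 40 centroid points at 60 FPS:

```r
lead_time(40, 60)
#> [1] 0.6666667
```

`autoplot()` methods draw the training-loss trace of a fit and the
likelihood/region maps from `likelihood_map()` and `region_map()`;
`covariance_ellipses()` returns the per-cluster uncertainty ellipses drawn on
such maps. A thin command-line dispatcher over the same functions lives at
`inst/cli/fallgmm.R` with subcommands `simulate`, `fit`, `map`, `alarm`
(exit status 0/1/2 encodes the highest warning reached) and `evaluate`.

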