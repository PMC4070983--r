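---
title: "Models and methods behind palmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind palmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(palmkit)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. Nothing here states a
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The measurement model

A PALM movie is a stack of camera frames in which a sparse, changing subset
of photoactivatable fluorophores is emitting. `palmkit` models one emitter
in one frame as a pixel-integrated 2D Gaussian point-spread function:
pixel (i, j) receives `N · [Φ((x_hi−x)/s) − Φ((x_lo−x)/s)] · [...]` photons
in expectation, on top of a uniform background `b` photons/pixel, and the
recorded count is Poisson. Coordinates are continuous nanometres, origin at
the image top-left, pixel centres at half-integer multiples of the pixel
size; every exported table is in nm.

Defaults: pixel size 125 nm (a 500 nm distance spans exactly 4 pixels at
this sampling), frame time 50 ms, PSF σ 130 nm — consistent with a
high-NA TIRF objective at red fluorescent-protein emission wavelengths.
Camera gain, offset and read noise are configurable but default to a
photon-counting ideal (gain 1, offset 0, no read noise): the analysis
chain's claims do not depend on camera digitisation, and no published
calibration was available to emulate, so the defaults are declared rather
than inferred.

## 2. Localization and its precision

`fit_spot()` maximises the Poisson likelihood of the integrated-Gaussian +
background model over an 11×11-pixel window (L-BFGS-B; position, photons,
background and PSF width free; non-converged fits are dropped). Candidates
closer than one window are both discarded — sparse activation is assumed,
and multi-emitter fitting is out of scope. MLE under Poisson noise, rather
than weighted least squares, is used precisely so that the reported
precision can be the Mortensen MLE formula

$$\sigma_{loc}^2 = \frac{s_a^2}{N}\left(\frac{16}{9} +
\frac{8\pi s_a^2\, b}{N a^2}\right),\qquad s_a^2 = s^2 + a^2/12 .$$

The tests exercise the self-consistency this implies: the empirical RMSE of
the fitter on rendered spots must track the formula within 15% across a
grid of photon counts and backgrounds, and photon estimates must be
unbiased within 3 standard errors at 200–2000 photons. One operating point
deserves mention: at 600 photons, σ 130 nm and 125 nm pixels the formula
reaches 18 nm at a background of ≈182 photons/pixel
(`invert_precision_background(18, 600)`), which is the condition the
acceptance script re-measures.

Fiducial markers (bright, stationary beads) are identified purely
behaviourally: any localization cluster persisting within a one-pixel
radius in more than 90% of frames is flagged. Drift is the smoothed
(10-frame moving average) mean displacement of fiducials from their
first-frame positions, subtracted from every localization. A consequence
worth knowing: a *simulated* static, always-on emitter is
indistinguishable from a fiducial and will be flagged as one — tests that
need a trackable static emitter give it a finite on-time.

## 3. Blink correction and the dark-state lifetime

Photoactivatable fluorescent proteins re-enter dark states reversibly
(mean lifetime `T_off`) before bleaching, so a naive count of localization
bursts overcounts molecules. `group_blinks()` merges, greedily in frame
order, any localization that lies within `r_group` of an open molecule's
running precision-weighted mean position and within an allowed dark period
`T_d` of its last appearance; ties go to the nearest molecule. Greedy
frame-order grouping is deterministic and order-stable, which the
reproducibility guarantees rely on. The default
`r_group = 3 × median precision` captures ≈98.9% of re-localizations of a
static molecule per localization (Rayleigh tail at 3σ); the residual ~1%
splitting is visible in the tests and is why molecule counts sit slightly
above truth at finite `T_d`.

`estimate_toff()` implements the molecule-count-curve estimator: compute
`N(T_d)` on a grid (default 0–1.05 s in 0.15 s steps) and fit
`N(T_d)/N(0) = A·exp(−T_d/T_off) + C` to the first 7 points by
Levenberg–Marquardt nonlinear least squares. Two design points:

* the additive offset `C` absorbs the persistent-molecule plateau; without
  it the fitted lifetime is biased upward;
* only the first ~1 s of the grid is fitted because at larger `T_d` the
  curve's slower second decay — different molecules at the same position
  being merged — contaminates the blinking signal. Pooled normalisation to
  `N(0)` is used throughout.

The simulator draws dark durations as continuous exponentials rounded *up*
to whole frames. This choice preserves the exponential survival exactly at
grid times (`ceil(X/Δt) > k ⟺ X > kΔt`), so the estimator sees an
uncorrupted exponential; the frame-measured mean dark time is accordingly
`Δt/(1 − e^{−Δt/T_off})` ≈ `T_off + Δt/2`, which the tests assert instead
of the continuous mean. Photophysics is simulated on the frame grid;
sub-frame on/off switching and motion blur are not modelled.

## 4. Nanocluster statistics

`ripley_k()` estimates `K(r) = |A|/(n(n−1)) Σ_i Σ_{j≠i} w_ij 1[d_ij ≤ r]`
with isotropic edge-correction weights (inverse fraction of the circle of
radius `d_ij` centred on point *i* inside the window). The closed-form
corner-aware weight is valid while the circle crosses at most one corner,
hence the hard precondition `r_max ≤ ¼ × shorter window side`. A naive
double-loop oracle in the test suite must agree to 10⁻⁹ on every random
≤25-point instance.

Envelopes come from Monte Carlo CSR simulations at the observed `n`.
Pointwise quantile envelopes are provided for plotting, but any *decision*
uses either (a) the rank-based Monte Carlo test at one pre-chosen radius
(`ripley_test()`, exact type-I control by the rank argument — the tests
verify ≈5% at α = 0.05 over 100 seeded repeats), or (b) for
`apparent_cluster_size()`, a Besag-style global bound, the (1−α) quantile
of each simulation's *maximum* of `H(r)` over the grid. The global bound
matters: `H(r)` is strongly autocorrelated in `r`, and selecting the argmax
of `H` then comparing to a pointwise envelope would flag a large fraction
of genuinely random patterns.

The apparent cluster scale is *defined* here as the argmax of `H(r)` above
the global bound. It is a length scale, not a physical diameter: for
point-like clusters it is dominated by the localization precision, and the
tests assert exactly that behaviour (the peak grows monotonically as the
blur goes 5 → 18 → 40 nm) rather than any absolute value.

Simulation-aided DBSCAN: `min_pts` is fixed at 2 so dimers are detectable;
`eps` is the 1st percentile of nearest-neighbour distances pooled over CSR
simulations at the observed density — a distance this small rarely occurs
by chance, so pairs this close are evidence of genuine aggregation. The
percentile, not an absolute distance, is the tunable: it adapts `eps`
automatically to density (the tests check the `0.5/√λ` CSR law at the 50th
percentile and the monotone density response). Cluster analysis always
runs on blink-corrected molecules, never raw localizations — otherwise
every blinking molecule is itself a "cluster".

## 5. Trajectory linking

Per consecutive frame pair, assignments minimise total displacement by an
exact Hungarian solve on an augmented cost matrix in which every link
farther than `max_disp` is forbidden and leaving a localization unmatched
costs `max_disp` — so a feasible link is always preferred over two track
ends, and the 500 nm gate is hard (asserted on every output). A greedy
nearest-neighbour matcher is available behind a flag and must coincide
with the optimal one at low density (tested). There is no gap closing: one
dark frame terminates a track, and tracks need at least two frames.

The gate's diffusion-constant equivalent is stored as
`max_disp²/(4Δt) = 1.25 µm²/s` at 500 nm and 50 ms. A commonly quoted
figure for the same gate is 1.39 µm²/s, which is not arithmetically
consistent with this conversion (it would need an effective interval of
~45 ms); the convention behind it is unrecoverable, so `palmkit` stores
the computed value and lets the 500 nm gate, not any `D` value, govern
behaviour.

## 6. The diffusion-state HMM

Step magnitudes of 2D Brownian motion in state `k` are Rayleigh with
per-axis variance `v_k = 2 D_k Δt + 2σ_loc²`. The HMM over these emissions
is fitted by Baum–Welch EM: scaled forward–backward in C++ (tracks
independent, sufficient statistics pooled), closed-form M-step
(`v_k` = state-weighted mean of `r²/2`, transition rows from expected
counts), 10 seeded restarts by default initialised by k-means on `log r²`
(jittered after the first), convergence at Δloglik < 10⁻⁸ or 500
iterations, states reported sorted by ascending `D`. Monotonicity of the
log-likelihood is asserted on every fit, and forward–backward must equal
exhaustive path enumeration to 10⁻⁹ on short tracks. Magnitudes, not
displacement vectors, are modelled; `σ_loc` defaults to 0, with the
static-noise term available when the tracking precision is known.

Model size is chosen by BIC, `−2·loglik + k·log(n_steps)` with
`k = K + K(K−1) + (K−1)` free parameters. BIC here stands in for the
variational evidence used by variational-Bayes treatments of the same
model: both penalise complexity, and the package's claims (the number of
states and their rate constants on simulated data) are testable under
either criterion. This is a deliberate divergence, documented rather than
hidden; a full variational posterior over model size is out of scope.

Simulated trajectories for the recovery tests use three states at 0.44,
0.08 and 0.02 µm²/s. Transition probabilities of the motivating
experiment are not published as numbers, so simulations default to a
moderately sticky chain (`trans_ii = 0.9`, off-diagonals equal) — sticky
enough for dwell structure, mobile enough that ~10⁴ steps sample all
transitions.

## 7. What the generators emulate — and what they do not

The synthetic engine reproduces the statistical structure the analysis
assumes: geometric photoactivation, exponential on/dark periods,
irreversible bleaching, ~600 photons per on-frame, Poisson pixel noise,
Gaussian PSF, stage drift, bright fiducials; CSR or Thomas-like clustered
point patterns with 2–3-member clusters; Markov-switching Brownian
trajectories observed with static localization noise. It does **not**
emulate: sub-frame blinking or motion blur, TIRF evanescent-depth
intensity variation, 3D PSFs, EM-gain excess noise, fluorophore
orientation effects, heterogeneous backgrounds, or misfolded/immature
fluorophores. Passing tests therefore demonstrate estimator correctness
under the stated model, not robustness to every pathology of real data.

## 8. Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to make the statistical
tolerances meaningful on a single CPU: 3200 blinking emitters over 4000
frames for lifetime recovery (the tolerance band 0.21–0.31 s is then many
standard errors wide), 500 rendered spots for photon/precision statistics
(SE ≈ 4 photons), ~10⁴ steps from 600 tracks for three-state HMM recovery,
100 seeded repeats for the type-I rate. Degenerate inputs are handled
explicitly: a blink-free movie yields a flat `N(T_d)` curve and a flagged
degenerate fit; an HMM state that empties restarts the fit (all restarts
collapsing is an error); equal-`D` states are collapsed by BIC; grouping
ties break to the nearest molecule; all generators take explicit seeds and
every stochastic test states its seed.

## 9. Known limitations

* Blink grouping at finite `T_d` leaves a predictable molecule overcount
  (`≈ e^{−T_d/T_off}` of dark periods split); counting applications should
  read `N(T_d)` curves, not single counts.
* The 3σ grouping radius trades a ~1% split rate against merging of
  near-neighbours; both artifacts appear as nanoscale "clusters" in
  downstream statistics, which is intrinsic to localization microscopy and
  the reason cluster claims here are calibrated against CSR simulations.
* The apparent cluster scale conflates true extent with resolution; it is
  reported as a scale, never as a physical size.
* Tracking assumes sparse activation; at high density optimal matching
  degrades gracefully but identity errors are unavoidable in principle.
* At high background (~180 photons/pixel) the five-parameter Poisson MLE
  carries a small finite-sample photon bias (~+1.4% at 600 photons in an
  11×11 window, measured on 2000 simulated spots), driven by the weak
  identifiability between total intensity, PSF width and background.
  Position estimates are unaffected; photon-based stoichiometry at high
  background should budget for it.
* The HMM ignores localization-noise correlation between consecutive
  steps (the same noisy endpoint enters two displacements), which slightly
  biases fast-state estimates when `σ_loc` is large relative to step size.
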