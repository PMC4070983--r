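# palmkit

Tools for analysing photoactivated localization microscopy (PALM) data, and
for simulating every input the analysis needs — so the whole chain can be
validated end to end without microscope data.

PALM builds super-resolution images by sparsely photoactivating single
fluorophores (here, PAmCherry1-like photoactivatable fluorescent proteins,
including split/BiFC variants that report protein–protein interactions),
localizing each one to tens of nanometres, and accumulating localizations
over thousands of frames. Two analysis chains sit on top of the raw
localizations:

* **static PALM** — drift correction, blink correction and molecular
  counting, nanocluster statistics, image rendering; used to ask whether
  membrane protein complexes (e.g. Ras/Raf) organise into nanoclusters and
  how many molecules each cluster holds;
* **smt-PALM** (single-molecule tracking) — frame-to-frame linking of live-cell
  localizations into trajectories and inference of discrete diffusion
  states from the displacement statistics.

`palmkit` implements both chains as tidyverse-style functions (tibbles in,
tibbles out, `tidy()`/`glance()`/`autoplot()` on fitted objects), plus a
synthetic-data engine that emulates the photophysics, spatial structure and
dynamics the analysis assumes.

## The statistics at the core

**Localization and precision.** Spots are fitted frame by frame by
maximum likelihood under Poisson noise with a pixel-integrated 2D Gaussian
PSF plus uniform background. The reported precision is the Mortensen MLE
form

σ²_loc = (s² + a²/12)/N · (16/9 + 8π (s² + a²/12) b / (N a²))

with `N` photons, `b` background photons/pixel, PSF width `s` and pixel
size `a`. At `N = 600`, `s = 130` nm, `a = 125` nm this is ~18 nm once the
background reaches ~182 photons/pixel (`invert_precision_background()`).

**Blink correction and the dark-state lifetime.** A photoactivatable
fluorophore blinks: it revisits reversible dark states (mean lifetime
`T_off`) before bleaching, so one molecule produces several localization
bursts. `group_blinks()` merges bursts separated by dark periods up to an
allowed gap `T_d`; `estimate_toff()` scans `T_d`, counts molecules
`N(T_d)`, and fits `N(T_d)/N(0) = A·exp(−T_d/T_off) + C` to the first
seven grid points (up to ~1 s) — the initial fast decay is the blinking
being reconnected, and its rate estimates `T_off`.

**Nanocluster statistics.** Ripley's `K(r)` with isotropic edge
correction, `H(r) = √(K/π) − r`, pointwise and global Monte Carlo CSR
envelopes, the `H`-peak position as the apparent cluster length scale, and
simulation-aided DBSCAN: `eps` is calibrated to the 1st percentile of
nearest-neighbour distances in CSR simulations at the observed density,
`min_pts = 2`, so dimers are detectable while chance pairs are rare.

**Tracking and diffusion states.** Localizations in consecutive frames are
linked by optimal bipartite matching with a hard 500 nm (4 pixel) per-frame
gate; no gap closing; tracks need ≥ 2 frames. Step magnitudes `r` are
modelled by a hidden Markov model with Rayleigh emissions,
`log p(r|k) = log r − log v_k − r²/(2 v_k)`, `v_k = 2 D_k Δt + 2σ²_loc`
per axis, fitted by Baum–Welch EM with seeded multi-restarts; the number
of states is chosen by BIC.

## Worked example

```r
library(palmkit)

phys  <- photophysics_params(activation_rate = 0.002, mean_dark_time = 0.26,
                             bleach_prob = 0.5)
roi   <- c(0, 10000, 0, 10000)                      # 10 x 10 um, nm units
truth <- sim_cluster_pattern(roi, total_density = 4, clustered_fraction = 0.4,
                             occupancy_pmf = c(`2` = 0.6, `3` = 0.4),
                             cluster_sigma = 10, seed = 1)
blinks <- sim_photophysics(phys, nrow(truth), n_frames = 3000, seed = 2)
locs   <- sim_localizations(truth, blinks, loc_sigma = 18, seed = 3)

estimate_toff(locs)
#> <palm_toff> T_off = 0.257 s (se 0.013); fit R = 0.9994 on 7 points

mols <- group_blinks(locs, t_d = 0.26)              # 586 molecules from 1243 locs
rip  <- ripley_k(mols, seq(5, 250, by = 5), roi) |>
  add_csr_envelope(n_sims = 99, seed = 4)
apparent_cluster_size(rip)
#> [1] 65

cal <- calibrate_dbscan(mols, roi, seed = 5)
dbscan_clusters(mols, cal$eps, cal$min_pts)
#> <palm_clusters> 82 clusters (eps 20.2 nm, min_pts 2); mean occupancy 2.57; clustered fraction 0.36

trajs <- sim_trajectories(D = c(0.44, 0.08, 0.02),
                          trans = matrix(c(.9,.05,.05, .05,.9,.05, .05,.05,.9),
                                         3, byrow = TRUE),
                          n_tracks = 500, mean_track_length = 15, seed = 6)
select_model(trajs, K_range = 1:4, n_restarts = 4, seed = 7)
#> <palm_hmm> K = 3 states, 7025 steps, loglik -39697.1, BIC 79491.6
#>   D (um^2/s): 0.019, 0.0786, 0.45
#>   occupancy:  0.356, 0.376, 0.268
```

Reading the output: the dark-lifetime estimator recovers the generating
0.26 s to within its standard error; blink grouping collapses 1243
localizations to 586 molecules (402 true emitters plus the expected
residual splitting at `T_d = T_off`); the `H(r)` peak at 65 nm reflects
cluster extent convolved with the 18 nm localization precision; calibrated
DBSCAN reports 2–3 molecules per cluster (truth: mean 2.4); and BIC picks
exactly three diffusion states with rate constants within a few percent of
the generating 0.44/0.08/0.02 µm²/s.

`run_static_pipeline()` and `run_tracking_pipeline()` chain the stages
(localize → drift → group → cluster statistics → render, and localize →
drift → link → histogram → model selection) from a single `palm_config()`,
write all intermediate tables, and stamp a JSON provenance record.

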