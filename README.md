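# mot2d — multi-object tracking and trackability analysis in 2D

Quantitative behaviour, active-matter and cell-biology experiments routinely
produce two-dimensional movies of many similar moving objects — swimming
larvae, crawling cells, driven particles, robots — whose analysis starts by
extracting one trajectory per object. mot2d is an R toolkit for that step
and, just as importantly, for knowing how much to trust it. It provides:

* **Detection**: background estimation (min/max/mean over strided frames),
  optional pyramidal phase-correlation drift registration, thresholding,
  morphological filtering, 8-connected components with an area filter, and
  Moore border-following contour extraction.
* **Kinematics**: per-blob centre of mass, direction in `[0, 2π)`
  (equivalent-ellipse axis from Green's-theorem contour moments, oriented by
  projection skewness), area and perimeter.
* **Matching**: frame-to-frame identity assignment minimising the
  normalised kinematic cost
  `c_ij = dr/s_r + dα/s_α + dA/s_A + dp/s_p`, with hard thresholds making a
  pairing impossible (`c_ij = ∞`) beyond `h_r, h_α, h_A, h_p`, solved
  exactly by the Kuhn–Munkres algorithm on (possibly rectangular) cost
  matrices, plus a short-term memory keeping lost objects available for up
  to `h_t` frames.
* **Automatic parameters**: an iterative loop that tracks, pools one-frame
  increments, and re-estimates the soft normalisations by maximum
  likelihood — Rayleigh scale `s_r = sqrt(mean(dr²)/2)` for step lengths,
  Gaussian scales for signed increments — until every parameter changes by
  less than 10⁻³ relative.
* **Trackability without ground truth**: the probability `P_inc(τ)` that an
  object's displacement over timescale `τ` leaves its (static) Voronoi
  cell, computed from the geometric incursion profile `p_inc(ρ)` versus the
  reduced displacement `ρ = r√d`; its logistic fit
  `P_inc = L / (1 + (τ₀/τ)^k)` and the critical resampling factor
  `τ₁ = τ₀ (L·N_obj − 1)^(−1/k)` that separates oversampled (`τ₁ > 1`)
  from undersampled (`τ₁ < 1`) movies.
* **Evaluation**: identity-swap probability
  `P_swap = N_swap / (N_obj − n_ap)` and accuracy
  `A = (n_obj·n_img − (2·N_swap + N_undetected)) / (n_obj·n_img)` against a
  ground truth, plus a controlled trajectory degradation operator for
  robustness studies.
* **Synthetic movies**: a generator of elliptical random walkers with
  reflective walls, exact ground truth, and deterministic rendering, so the
  whole pipeline is testable without any external data.

Everything is tidyverse-native: tables in and out are tibbles, fitted
objects have `tidy()`/`glance()` methods, and every result type has an
`autoplot()`.

## Worked example

Simulate a movie, detect, auto-tune the matching cost, track, and ask both
"was it right?" (against the known ground truth) and "was it trackable?"
(without using the ground truth):

```r
library(mot2d)

cfg   <- sim_config(n_objects = 12, n_frames = 150, roi_width = 400,
                    roi_height = 400, step_sigma = 2,
                    arrangement = "hexagonal", seed = 42)
gt    <- simulate_trajectories(cfg)
movie <- render_movie(gt, cfg)

det  <- detect_objects(movie, detection_params(threshold = 80, min_area = 20),
                       background = matrix(220, 400, 400))
auto <- iterate_autoparams(det)
auto
#> <autoparam_result> converged in 5 iteration(s)
#> <match_params>
#>   soft: s_r = 2.01036 px, s_alpha = 2.07795 rad, s_A = 2.24243 px^2, s_p = Inf px
#>   hard: h_r = 10.0518, h_alpha = 3.14159, h_A = 11.2122, h_p = Inf, h_t = 10 frames

traj <- track(det, auto$params)
p_swap(traj, gt)
#> <swap_report>
#>   N_swap = 0, n_ap = 12, N_obj = 1800, N_undetected = 0
#>   P_swap = 0, accuracy = 1

trackability(traj, c(400, 400), n_angles = 120, max_frames = 5)
#> <trackability_report> N_obj = 1800, density = 7.5e-05 objects/px^2
#> <logistic_fit> L = 0.00493, k = 2.901, tau0 = 7.463 (log-RMS 0.256, n = 7)
#>   tau1 = 3.664 -> oversampled
```

Reading the output: the auto-tuned `s_r ≈ 2.01` px recovers the simulated
step scale (`step_sigma = 2`) from the images alone — the `s_alpha ≈ 2.1`
rad is large because symmetric ellipses only define their direction modulo
π. Tracking makes no identity swap (`P_swap = 0`, accuracy 1). The
trackability analysis, which never looks at the ground truth, reports
`τ₁ ≈ 3.7 > 1`: the movie is oversampled — its framerate could be reduced
almost fourfold before incursions (and hence swaps) become likely.

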