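---
title: "Tracking, trackability and automatic parameters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking, trackability and automatic parameters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mot2d)
```

mot2d tracks multiple deformable objects in two-dimensional grayscale movies
and, beyond the tracking itself, quantifies how *trackable* a movie is
without needing ground truth. This vignette describes the models and
numerical choices; the README shows a worked example.

## The tracking model

Tracking splits into detection, kinematic extraction and matching.

**Detection.** Objects are separated from a static background by
thresholding the background-minus-frame difference (or its negative,
depending on which side is lighter). The background is either supplied or
estimated as the per-pixel minimum, maximum or mean over `n` frames sampled
with stride `floor(T/n)` starting at the first frame. Binary masks can be
cleaned by standard morphological operations (erosion, dilatation, opening,
closing, gradient, top-hat, black-hat, hit-miss) with rectangular,
cross-shaped or elliptical kernels, applied in user order; grayscale
morphology is delegated to EBImage. Connected components use
**8-connectivity**, and a pixel-count area filter `[min_area, max_area]`
removes both speckle and merged (overlapping) objects. The outer contour of
each surviving component is extracted by Moore border following.
Coordinates are 0-based, x rightward, y downward, origin at the top-left
pixel centre — everywhere in the package.

**Kinematics.** Each blob is summarised by the quantities the matcher
consumes: centre of mass, direction, area (filled pixel count) and
perimeter (arc length of the pixel-centre contour polygon). Centroid and
second-order central moments are evaluated with Green's theorem as line
integrals over the blob's exact boundary — the closed polygon of exposed
pixel edges — so they agree with dense pixel-sum moments to the trivial
1/12 pixel-square term; tests assert agreement within 2%. The equivalent
ellipse's axis angle is `0.5 * atan2(2*mu11, mu20 - mu02)` in `[0, pi)`; the
full direction in `[0, 2*pi)` is fixed by the skewness of the filled pixels
projected on the major axis, choosing the orientation whose third
standardised moment is non-positive ("heavy side forward"). The convention
is arbitrary but fixed and covered by tests; a mirror-symmetric blob
(|skewness| below 1e-6) keeps the bare axis angle. Skewness uses all filled
pixels, not only the contour.

**Matching.** For states *i* (previous frames) and *j* (current frame) the
pairing cost is

$$c_{ij} = \frac{dr_{ij}}{s_r} + \frac{d\alpha_{ij}}{s_\alpha} +
  \frac{dA_{ij}}{s_A} + \frac{dp_{ij}}{s_p},$$

with `dr` the Euclidean distance, `dalpha` the circular angular difference
folded to `[0, pi]`, and `dA`, `dp` absolute area and perimeter
differences. Each term also carries a hard threshold (`h_r`, `h_alpha`,
`h_A`, `h_p`): the cost is `+Inf` as soon as any enabled increment reaches
its threshold. Setting both the soft and hard value of a term to `+Inf`
discards that kinematic parameter entirely. The candidate-by-detection cost
matrix — rectangular whenever the object count changes — is solved exactly
with the Kuhn–Munkres algorithm (a Jonker–Volgenant shortest-augmenting-path
implementation, verified against exhaustive enumeration). Forbidden
pairings are encoded for the solver as a finite sentinel exceeding the sum
of all finite entries and stripped from the result, which makes the
returned pairing the cheapest among maximum-cardinality feasible ones. Ties
are broken by the solver's deterministic row order.

Objects may vanish briefly (occlusion, detection dropouts). Unassigned
trajectories stay in a memory for up to `h_t` frames as
*pseudo-occurrences*: their frozen last state competes in the cost matrix
with unmodified thresholds (no age-dependent scaling — the simplest rule,
documented rather than guessed). A reappearance within `h_t` continues the
same identity with a real gap (no interpolation); beyond `h_t` a new
identity is created. Matching uses only past and current frames, and memory
candidates compete with active ones in a single joint matrix.

## Automatic soft parameters

The soft normalisations are the typical frame-to-frame changes of each
kinematic parameter, which are unknown before any tracking exists. The
iteration breaks the circularity: track with the current parameters, pool
the one-frame increments over all trajectories (links across gaps are
excluded — they would inflate the scales), re-estimate, repeat until every
soft parameter changes by less than `1e-3` relative (the `tolerance`
argument), or `max_iter` is hit.

Estimation is closed-form maximum likelihood rather than histogram curve
fitting — deterministic and asymptotically identical to fitting the stated
densities. Signed increments (angle, area, perimeter) get the Gaussian ML
scale about the sample mean (centring on the mean rather than zero keeps
drifting systems meaningful). Step lengths are non-negative; assuming
independent per-axis Gaussian displacements they follow the chi
distribution with 2 degrees of freedom (Rayleigh),
$f(dr) = (dr/s_r^2)\,e^{-dr^2/2s_r^2}$, whose ML scale is
`sqrt(mean(dr^2)/2)`.

Two quantities are not specified by the model and are fixed as package
defaults: during iteration the hard thresholds ride at **5x the current
soft values** (generous enough to keep the increment pool representative,
finite enough to exclude nonsense links; `h_alpha` is additionally capped
at pi, its maximal possible increment) and `h_t` is held at **10 frames**.
Default seed parameters are `s_r = 20` px, `s_alpha = 0.5` rad,
`s_A = 100` px², perimeter discarded. An increment family with strictly
zero variance (e.g. perfectly constant areas) is disabled rather than
fitted. The first iteration tracks the full movie, not a subset.

On synthetic Brownian movies the loop converges in a handful of iterations
from arbitrary starting points, to the scale obtained from ground-truth
increments within a few tenths of a percent, and the converged parameters
are near-optimal: at least three quarters of random parameter sets do no
better on swap probability.

## Trackability: the probability of incursions

An *incursion* is a displacement over a timescale `tau` that carries an
object out of its own Voronoi cell (the cell is static, computed from a
single frame). Displacements are made dimensionless as
$\rho = r\sqrt{d}$ with `d` the object density (mean visible objects per
ROI area), so `rho = 1/2` is the typical distance to a cell boundary.

The geometric profile `p_inc(rho)` is the fraction of `n_angles` uniform
directions whose endpoint at distance `rho/sqrt(d)` lands in another
object's cell, averaged over objects and over a strided sample of start
frames (cells are recomputed at each sampled frame). Because cells are
convex, the implementation computes per-direction exit distances exactly
from the nearest forward perpendicular-bisector crossing; tests cross-check
against a brute-force nearest-generator endpoint oracle. Endpoints that
leave the ROI count as non-incursions, which is why small systems with
reflective walls saturate below 1. The averaging is object-weighted, not
cell-area-weighted. `profile_inflection()` locates the inflection by
fitting a logistic sigmoid in `rho`; for dense uniform random
configurations it sits close to 1/2, and hexagonal packings (stereotyped
cells) rise more steeply than Poisson ones.

The incursion probability at timescale `tau` is the expectation of
`p_inc` under the distribution of observed reduced displacements,
evaluated as the empirical mean of the linearly interpolated profile at the
sample values (equivalent to density quadrature, without binning choices;
the profile is extrapolated flat beyond its grid). For `tau >= 1`
(integers) displacements are taken on the strided frame set; for
`tau < 1` single-frame displacements are scaled linearly by `tau`. Note
that for diffusive motion the sub-unit rule deliberately deviates from the
physical `sqrt(tau)` scaling — it is a linear interpolation convention.

`P_inc(tau)` is logistic in `log(tau)`:

$$P_{inc}(\tau) = \frac{L}{1 + (\tau_0/\tau)^k},$$

fitted by Levenberg–Marquardt least squares on `log P_inc` (zero values
carry no information on the log scale and are excluded; at least 4 positive
points are required, `L` is constrained to `(0, 1]`, initial guesses are
`L = max(P)`, `k = 2`, `tau0` at half maximum). On synthetic Brownian
movies at several densities the points collapse onto the standard sigmoid
`1/(1+e^{-x})` after the `(L, k, tau0)` transform, with linear-units RMS
below 0.01 when integer timescales are used; sub-unit points deviate
systematically for the reason above, so the collapse check excludes them.

The critical resampling factor is the timescale at which the fitted
`P_inc` reaches one incursion over the whole movie
(`1/N_obj`): $\tau_1 = \tau_0 (L N_{obj} - 1)^{-1/k}$. Movies with
`tau1 > 1` are oversampled — the framerate can be divided by `tau1` without
triggering incursions — and movies with `tau1 < 1` undersampled. When
`L * N_obj <= 1` the threshold is never reached and `tau1` is `+Inf`,
flagged.

The analysis is usable on imperfect input trajectories: degrading ground
truth by random identity swaps between Voronoi neighbours (`degrade()`, at
rate `delta` swaps per object-frame, each swap exchanging two ids from a
random frame onward) changes the fitted `(L, k, tau0)` by less than 10% up
to `delta = 1e-3` on a 50-object, 500-frame synthetic movie.

## Evaluation against ground truth

`p_swap()` matches every tracked state to the nearest ground-truth object
in its frame, accepting a match only within half the minimal ground-truth
inter-object distance of that frame — the radius that makes the assignment
unambiguous and swap counts exactly recoverable on constructed cases;
anything farther is counted undetected. `N_swap` is the number of
transitions, within a tracked trajectory, between successive matched states
whose ground-truth identity differs. One physical exchange between two
trajectories therefore counts twice (each trajectory changes once); the
convention is fixed and documented, and absolute values may differ from
per-event counting by a factor of at most 2. With `N_obj` tracked states
and `n_ap` trajectory births,

$$P_{swap} = \frac{N_{swap}}{N_{obj} - n_{ap}},$$

whose denominator is the number of transition opportunities; for a constant
object count `n` over `T` frames it reduces to `n(T-1)`. The accuracy

$$A = \frac{n_{obj} n_{img} - (2 N_{swap} + N_{undetected})}{n_{obj} n_{img}}$$

(clipped at 0) charges each swap two object-frames and each missed
detection one.

## The synthetic generator

Every result above is exercised on synthetic movies with exact ground
truth. `simulate_trajectories()` moves `n_objects` area-conserving ellipses
in a rectangle with reflective walls (specular reflection of the
overshoot): per-axis i.i.d. Gaussian steps of scale `step_sigma` — so step
lengths are exactly the chi-2-dof law the autoparameter model assumes —
and Gaussian heading increments of scale `angle_sigma` wrapped to
`[0, 2*pi)`. Initial positions are uniform or on an equal-spacing hexagonal
lattice; the lattice is the right choice when a scenario requires
well-separated objects, since uniform draws may start two objects
overlapped. With `appearance_rate > 0`, each visible object disappears
permanently with that per-frame probability and new objects (fresh ids,
never reused) enter at the same rate, exercising rectangular assignment
and birth accounting. `render_movie()` rasterises each object by the
pixel-centre-in-ellipse test with no anti-aliasing (deterministic pixel
counts), on a uniform background (intensity 220, objects 30, or the exact
8-bit inversion for inverted polarity), plus optional additive Gaussian
noise. Identical configurations give bit-identical output.

What the generator does **not** emulate: deformable or asymmetric bodies
(rendered ellipses are mirror-symmetric, so their measurable direction is
only defined modulo pi — angle increments then show occasional wrap
outliers at pi, which inflates the fitted `s_alpha` without harming the
other parameters), illumination gradients, shadows, reflections, occlusion
by 3-D overlap, or pixel-correlated noise. Passing tests on these movies
validates the algorithms and their statistical assumptions, not robustness
to such imaging artifacts.

## Numerical choices and problem sizes

* Registration (optional, off by default) implements pyramidal phase
  correlation only — coarse 4x-downsampled pass, then full resolution, with
  3-point parabolic subpixel refinement; ECC and feature-based registration
  are deliberately not provided and error informatively.
* The hexagonal lattice keeps a single lattice constant in both axes (so
  nearest-neighbour distances are exactly equal) and fills row-major when
  `n` does not tile the grid.
* `estimate_sigma_chi2` of an all-zero sample returns 0 flagged degenerate;
  a fully static movie aborts the autoparameter loop with a clear error.
* Voronoi adjacency (for `degrade()`) is decided exactly by a 1-D linear
  feasibility test on the pair's bisector; no tessellation library is used
  anywhere — incursion geometry needs only nearest-generator comparisons,
  done in closed form via bisector crossings.
* Test and acceptance problem sizes are chosen to sample each regime
  adequately at desk scale: 500-point configurations with 360 directions
  for the inflection; a 20-object, 200-frame rendered movie for the
  autoparameter study; a 10-object, 100-frame movie for the zero-swap
  pipeline; a 50-object, 500-frame ground truth (ROI 256x256, step scale
  3 px — dense and fast enough that `P_inc(tau)` traverses its sigmoid
  within the movie length) for the degradation study.

## Known limitations

* The matcher is purely kinematic; no appearance features, no velocity
  prediction, no overlap resolution. Merged blobs are removed by the area
  filter rather than split.
* Head/tail decomposition is not implemented; the corresponding output
  columns duplicate the body values.
* The area filter uses filled pixel count (not contour-moment area); exact
  numeric parity with tools that filter on a different area variant is not
  guaranteed.
* `P_inc` at a single timescale is fragile under tracking errors (swaps
  put a bump of mass where `p_inc` is near 1); the timescale-resolved fit
  is the robust object, which is exactly why it is the one reported.
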