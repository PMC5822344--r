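---
title: "The contour-thrust raft model and its trajectory-analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The contour-thrust raft model and its trajectory-analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyraft)
```

## The system

Motile *E. coli* trapped at an air–liquid interface swim in circular
trajectories, and cohesive microcolonies ("rafts") of tens to thousands
of cells move as 2D rigid bodies on the interface, also along circles,
but slower and with no preferred rotation direction.  `colonyraft`
implements a minimal physical model of the raft motion together with the
trajectory-analysis pipeline used to quantify tracked swimmers and
rafts, and a synthetic-track generator so that the entire pipeline can
be exercised against known ground truth without any experimental data.

## The model

A raft of $N$ cells is a rigid disk of radius $r = \sqrt{N/\pi}$ (unit
cell area).  Only the $N_b$ bacteria on the contour thrust; each exerts
a force of fixed magnitude $f$ at an angle $\alpha_i$ drawn once,
independently and uniformly on $[0, 2\pi)$, and frozen in the
co-rotating body frame (quenched disorder).  In the overdamped limit the
equations of motion reduce to

$$ v_{cm} = \frac{|\mathbf{F}_b|}{D}, \qquad
   \omega = \frac{T_b}{G}, \qquad
   R = \frac{v_{cm}}{|\omega|}, $$

with net thrust $\mathbf{F}_b = \sum_i f(\cos\alpha_i, \sin\alpha_i)$,
net torque $T_b = \sum_i (\mathbf{r}_i \times \mathbf{f}_i)\cdot\hat z =
r f \sum_i \sin\varphi_i$, translational drag $D = d_0 N_b$ and
rotational drag $G = g_0 N_b^3$ (Stokes-type scalings for an oblate
body, implemented as equalities since only scalings are prescribed by
the physics).  Because the thrust angles co-rotate with the body, the
exact solution is uniform circular motion — `propagate()` returns it in
closed form, and also by explicit 4th-order Runge–Kutta integration as
an internal cross-check.

The central limit theorem gives the force and torque statistics: each
component of $\mathbf{F}_b$ has standard deviation $f\sqrt{N_b/2}$
(variance of $\cos\alpha$ is $1/2$ for uniform angles) and $T_b$ has
standard deviation $r f \sqrt{N_b/2}$.  `thrust_statistics()` reports
both the Monte-Carlo and the analytic values so the prefactor is
auditable.  Since $T_b$ is symmetric around zero, clockwise and
counterclockwise rafts are equally likely — the model's explanation for
the absence of a preferred rotation direction.

With $N_b = \max(3, \operatorname{round}(2\sqrt{\pi}\sqrt{N}))$ (the
perimeter of a disk of $N$ unit cells; the floor avoids degenerate
rafts), the scaling chain predicts

$$ v_{cm} \sim N^{-1/4}, \qquad \omega \sim N^{-3/4}, \qquad
   R \sim N^{+1/2}. $$

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `f` | per-bacterium thrust | 1 | force |
| `d0` | translational drag per contour cell | 1 | force·time/length |
| `g0` | rotational drag prefactor | 1 | force·length·time |
| `cb` | contour-count coefficient | $2\sqrt{\pi}$ | — |
| `cell_size` | length per cell | 1 | length |

All defaults are nondimensional by design: the exponents are unit-free,
so prefactors only shift intercepts in log–log space, never slopes.
Every stochastic constructor takes an explicit seed, and sweeps derive
one named sub-stream per raft from a master seed, so any row of a sweep
can be regenerated in isolation.

## The scaling study

`run_scaling_experiment()` sweeps $N \in \{16, 32, \dots, 4096\}$ with
2000 independent realizations per size — enough that the bootstrap
uncertainty of each exponent is a few times $10^{-3}$ while the whole
sweep takes seconds on one core.  `fit_power_law()` fits
$y = a x^b$ by ordinary least squares in $\log_{10}$ space on binned
data: when $x$ takes at most `n_bins` distinct values (the sweep case)
each distinct size is its own bin; otherwise bins are log-spaced.  The
central statistic is the **mean** for $v_{cm}$ and $|\omega|$ but the
**median** for $R$: $R = |\mathbf{F}_b| G / (|T_b| D)$ has a Gaussian
denominator centered at zero, so its population mean diverges and only
the typical (median) value obeys the $N^{1/2}$ scaling.  Exponent
uncertainty is a 95% percentile bootstrap over the raw sweep rows
(default 1000 resamples); the quoted interval always contains the point
estimate.

### Finite-size behaviour (a known limitation)

The predictions above are asymptotic in $N_b$.  Over the default grid
the smallest rafts have $N_b = 14$, and two finite-size effects
systematically steepen the fitted slopes by a few times $10^{-3}$: the
integer rounding of $N_b(N)$, and the $O(1/N_b)$ corrections to
$\mathrm{E}|\sum_i \sin\varphi_i|$ before the half-normal limit is
reached.  The speed and radius fits comfortably bracket their
predictions, but for $|\omega|$ the genuine offset is comparable to the
bootstrap interval half-width at 2000 replicates, so a strict
CI-containment check of $-0.75$ holds for some seeds and not others.
This is a property of the model at these sizes, not an estimator
artifact; we deliberately do not widen the interval or enlarge the grid
to hide it.

## Trajectory analysis

The analysis consumes delimited track tables (`track_id`, `frame`, `x`,
`y` in μm; 50 frames/s by default) in the dialect of common tracking
plugins, and applies explicit, logged rules in place of manual curation:

* **Length filter** — tracks with fewer than 70 frames (1.4 s) are
  discarded; the boundary is included (`>= 70`) and the threshold is
  configurable, since "longer than" is ambiguous at the boundary.
* **Arc segmentation** — run-and-tumble tracks are cut at cusps where
  the smoothed turning angle between successive velocity vectors
  exceeds 50°, or the instantaneous speed falls below 0.3× the track's
  median speed (a robust scalar reference; a rolling reference adds
  noise without changing the calls on our synthetic cusps).  Velocities
  are smoothed with a 3-frame centred moving average.  These defaults
  recover generated cusp locations within ±2 frames; segments shorter
  than 10 frames are dropped.
* **Circle fitting** — each arc is fitted twice: an algebraic linear
  least-squares fit (on $x^2+y^2 = 2ax + 2by + c$) initializes a
  geometric Gauss–Newton refinement of $\sum (\lVert p - c\rVert - R)^2$.
  Fits where the two radii disagree by more than 20% are rejected as
  incoherent (no univocal rotation), and `apply_R_filter()` removes
  fits with $R > 50$ μm.  Collinear input raises a degenerate-fit
  error.
* **Handedness** — the sign of the mean z-component of cross products
  of successive displacement vectors, taken over a frame lag of about a
  tenth of the segment: the turning signal grows as lag³ while the
  localization-noise term grows only as lag^1.5, which is what makes
  the call reliable at realistic noise.  Coordinates are mathematical
  (y up, CCW positive); `image_coords = TRUE` handles y-down pixel
  origins.
* **Marker-pair kinematics** — raft pose is reconstructed from two
  tracked contour bacteria: orientation is the unwrapped bearing of the
  marker-difference vector, the center is re-projected through the 2D
  rigid transform anchored at the first frame, $\omega$ is the
  least-squares slope of orientation versus time, and speed/radius come
  from the center path.  Speeds use chords spanning ~0.1 s (swimmers)
  or ~0.5 s (rafts): at 50 fps a raft moves less than the localization
  noise between consecutive frames, and lagged chords remove the
  resulting upward bias.
* **Population statistics** — Welch two-sample tests for speed and
  radius between CW/CCW subgroups and between singles and rafts, and an
  exact binomial test of the CW fraction against 1/2.  The published
  p-values name no tests; these are the standard choices for unequal
  variances and small counts.

## The synthetic generator

`gen_single_swimmers()` emulates what the analysis assumes: sequences of
exact circular arcs (per-arc speed and radius lognormal with cv 0.4
around configurable means — the published single-swimmer means 12.4 μm/s
and 24.4 μm by default), handedness fixed per swimmer (CCW with
probability 0.86), exponential run durations (rate 0.5 s⁻¹), a 5-frame
stop at each tumble followed by a uniform heading redraw, and isotropic
Gaussian localization noise (σ = 0.05 μm, typical centroid precision at
40×).  `gen_raft_marker_tracks()` attaches two markers rigidly to a raft
undergoing exact uniform circular motion, with kinematics drawn either
around the published raft means (2.31 μm/s, 17.68 μm, 49% CW) or from
contour-thrust realizations.  Distributional shapes, tumble statistics
and the noise level are conventions — the source data report none — and
are all configurable.

What passing round trips show, therefore, is that the pipeline
faithfully recovers populations *with this structure*: rigid circular
arcs, stationary tumbles, isotropic white noise.  They do not establish
robustness to features real movies have and the generator omits —
stage drift, anisotropic or frame-correlated noise, crossing tracks,
partial occlusion, gradual speed changes within a run, or rafts that
deform.  The published experimental means themselves derive from
undeposited microscopy and are used here only as calibration constants,
never as quantities the simulation could reproduce.

## Numerical notes

* The numeric propagator requires $|\omega|\,\Delta t < 0.1$ and agrees
  with the closed form to better than $10^{-6}$ of the path radius over
  four periods at $\Delta t = T/500$.
* Gauss–Newton circle refinement runs at most 100 iterations with a
  $10^{-12}$ relative step tolerance and falls back to the algebraic
  solution if a step becomes singular; point-center distances are
  floored at machine epsilon.
* `fit_power_law` pairs the arithmetic bin mean of $y$ with the
  geometric bin mean of $x$, and the bin median of $y$ with the bin
  median of $x$, so a noiseless power law is recovered exactly under
  either statistic.
* Zero torque yields `handedness = "NONE"` and an undefined radius of
  curvature (flagged, not infinite); zero mean cross product in
  handedness classification returns `NA` with a warning rather than an
  arbitrary call.
* Per-arc statistics are the default unit of analysis (each scatter
  point is one arc); per-track aggregation is available by grouping
  `arcs_table()` output on `track_id`.

## Reproducing the study

The numbered scripts under `analysis/` run the three stages
(`01_raft_scaling.R`, `02_thrust_statistics.R`,
`03_track_roundtrip.R`) and write their tables under `results/`;
`scripts/acceptance.R --seed <s> --out <path>` recomputes the three
scaling exponents from scratch.  All figures of merit quoted anywhere in
the documentation are produced by these scripts or by the test suite.
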