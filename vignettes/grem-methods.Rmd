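---
title: "The generalised random encounter model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The generalised random encounter model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grem)
```

## The estimation problem

Remote sensors — camera traps, terrestrial and marine acoustic detectors —
produce counts of encounters with unmarked animals. Turning a count `z`
into an absolute density requires a model of how often a moving animal
ends up detectable. The ideal-gas argument gives the simplest answer: if
a sensor detects everything within distance $r$ in every direction, and
animals move at speed $v$ in random directions, the sensor sweeps (in the
animals' reference frame) an area $2rv$ per unit time, so
$E[z] = 2\,r\,v\,t\,D$ and $\hat D = z / (2\,r\,v\,t)$.

Real sensors detect only within a sector of central angle $\theta$, and
many animals emit directional signals: a call (or a recognisable aspect)
that can be received only from directions within $\alpha/2$ of the
animal's heading. The generalised random encounter model (gREM) replaces
the constant swept width $2r$ with a **mean profile width** $\bar p$, the
detectable cross-section averaged over approach angles, giving

$$\hat D = \frac{z}{v\,t\,\bar p(\theta, \alpha, r)}.$$

`estimate_density()` implements this for whole tables of surveys;
because repeated encounters of one individual are themselves part of the
encounter-rate model, no individual recognition is needed.

## Geometry of the profile

For an animal travelling with heading $\gamma$, a position $q$ (relative
to the sensor) is detectable iff (a) $|q| \le r$ and $q$ lies in the
sensor sector, and (b) the bearing from the animal back to the sensor is
within $\alpha/2$ of $\gamma$. Condition (b) is equivalent to $q$ lying
in a wedge of half-angle $\alpha/2$ with apex at the sensor, centred on
the *arrival bearing* $\gamma + \pi$. The detectable set at heading
$\gamma$ is therefore the radius-$r$ sector spanned by the intersection
of two circular arcs — the sensor arc and the signal arc — and the
profile $p(\gamma)$ is the width of its shadow perpendicular to the
heading. Since every component of that set touches the apex, the shadow
is governed by the extrema of $\sin\psi$ over the arc intersection,
which `profile_width()` evaluates in closed form per angle.

Averaging over the full circle of approach directions (equivalent, by
the symmetry of the configuration, to averaging over a half-circle)
gives $\bar p$. Two independent routes are provided:

* `mean_profile_numeric()` — midpoint quadrature of `profile_width()`
  with successive grid doubling (starting at 2048 nodes) until the
  change falls below `max(tol * 2r, 1e-3 * r)`; non-convergence is an
  error. This is the oracle: it never touches the closed forms.
* `mean_profile_closed()` — the piecewise closed forms, obtained by
  integrating the piecewise-trigonometric profile analytically region by
  region (the integrands change where arc endpoints cross each other or
  the extrema of $\sin$, all of which are affine loci in
  $(\theta, \alpha)$).

The analytical derivation was carried out symbolically and collapses,
over the whole square $(\theta, \alpha) \in (0, 2\pi]^2$, to **five
distinct expressions** with straight-line boundaries $\alpha = \pi$,
$\theta = 2\pi - \alpha/2$ and $\theta + \alpha = 3\pi$ (many separately
derived sub-regions share an expression):

| region | where | $\bar p \cdot \pi / r$ |
|---|---|---|
| SW  | $\alpha \le \pi$, $\theta \le 2\pi - \alpha/2$ | $\theta \sin\frac\alpha2 - \cos\frac\alpha2 + 1$ |
| SE2 | $\alpha \le \pi$, $\theta > 2\pi - \alpha/2$ | $\theta \sin\frac\alpha2 - \cos\frac\alpha2 + \cos(\frac\alpha2 + \theta)$ |
| NW  | $\alpha > \pi$, $\theta \le 2\pi - \alpha/2$ | $\theta + 1 - \cos\frac\alpha2$ |
| NE1 | $\alpha > \pi$, $\theta + \alpha \le 3\pi$ | $\theta - \cos\frac\alpha2 + \cos(\frac\alpha2 + \theta)$ |
| NE2 | $\theta + \alpha > 3\pi$ | $\theta + 2 \sin\frac\theta2$ |

The classical anchors fall out: NE2 at $\theta = 2\pi$ is the gas model
$\bar p = 2r$; NW at $\alpha = 2\pi$ is the camera-trap REM
$\bar p = r(2+\theta)/\pi$ (for $\alpha = 2\pi$ and $\theta \le \pi$ the
detectable set is a fixed convex sector, so this also agrees with
Cauchy's mean-width formula, perimeter$/\pi$); SE2 is the worked
directional-signal submodel. Adjacent expressions agree identically on
the shared boundary lines (asserted to $10^{-9} r$ in the tests), the
closed forms match the quadrature oracle to well below $5\times10^{-3} r$
everywhere, $\bar p$ is non-decreasing in each angle, and
$\bar p(\alpha = 0) = 0$. `classify_submodel()` reports which expression
applies; labels other than `gas`, `REM` and `SE2` are internal names
chosen by compass position.

```{r}
mean_profile_closed(sensor_spec(theta = 15 * pi / 8, r = 0.01),
                    signal_spec(alpha = pi / 2))
```

### Conventions and degenerate inputs

Angles are radians throughout (the command-line interface accepts
degrees); the sensor sector is symmetric about its facing axis and the
signal cone about the heading. $\theta = 0$ or $\alpha = 0$ yield
$\bar p = 0$ exactly — a convention, since a zero-width wedge is a ray
whose crossing measure is not zero, but no physical sensor or call has
exactly zero width — and `estimate_density()` refuses such
configurations rather than dividing by zero. Points on a region boundary
may be labelled with either adjacent region; the expressions agree
there, so the estimate is unaffected.

## The validation world

The simulator reproduces the study design used to validate the
estimator: animals at density $D$ (default 70 km⁻², the expected density
of a ~1 g mammal — a deliberate upper bound) placed uniformly on a
square torus with a single sector sensor of radius $r$ (default 10 m) at
the centre, moving in discrete steps of $T$ = 15 min for $N$ = 14400
steps (150 days) at $v$ = 40 km/day (the largest terrestrial day range).
Step distances are $\mathrm{Normal}(vT, vT/10)$ truncated at zero (the
negative mass is ~$10\sigma$ out, so truncation is a formality chosen
over resampling for reproducibility). Stop–start movement keeps an
animal still for a whole step with probability $S$; correlated random
walks turn by $\mathrm{Uniform}[-A, A]$ at the start of each moving
step. Headings persist through stationary steps.

Encounters are **entries into the capture set**: along each step
segment the engine intersects, exactly, the in-disk sub-interval
(a quadratic), the sensor-sector condition and the signal-cone condition
(each cut by its wedge's boundary rays into an interval or the
complement of one), and records the first admissible point. Exact
intersection matters: subsampling segments at a fixed spatial resolution
was measured to lose the thin detection slivers of narrow signal widths
(about −11% encounters at $\theta = 2\pi/9$, $\alpha = \pi/11$ with a
$r/20$ grid), a bias larger than the effects the validation experiments
measure. After an encounter an animal is disarmed until it is next
beyond $r$ from the sensor, so one pass yields one encounter, matching
the profile derivation that asks only whether a trajectory crosses the
profile. Animals already in the capture set at the start are counted
once at time zero (the alternative — requiring a fresh entry — changes
expected counts by under 0.03 encounters at the defaults). Encounter
times are interpolated within the step from the distance travelled.

Two engine-level conveniences are deliberate deviations from a literal
re-creation and are validated in the tests: (1) a single RNG stream with
a fixed generation order (whole-run matrices) rather than per-animal
streams — base R has one generator, and the same seed still reproduces
the encounter log bit for bit; (2) the torus wrap is never applied
inside a step segment, which is sound because configurations are
required to satisfy $L/2 \gg$ step + $r$, so a wrapped image cannot
reach the central sensor.

### What the simulation does and does not emulate

The world is homogeneous: constant density, no home ranges, no
behavioural states, no attraction to or avoidance of the sensor, one
sensor per arena, perfect detection within the sector and none outside.
Passing the validation experiments therefore shows that the estimator
inverts *this* encounter process correctly and is robust to the movement
models tested; it does not show robustness to heterogeneous densities,
trigger delays, duty-cycled sensors or distance-dependent detection,
which are outside the model.

## The validation experiments

Four experiments mirror the study, each returning tidy per-replicate
results plus a summary and an `autoplot()` method:

* `submodel_accuracy_experiment()` — percentage error of $\hat D$ per
  $(\theta, \alpha)$ cell (medians, IQRs, SDs).
* `capture_count_experiment()` — runs to fixed capture totals; the
  estimate at target $n$ uses the elapsed time of the $n$-th capture;
  precision is the CV across replicates.
* `movement_model_experiment()` — accuracy under stop–start and
  turning movement. The speed handed to the estimator is the realised
  average $v(1-S)$: the gREM assumes continuous motion, and only
  movement during the survey generates encounters, so the average
  realised speed is the parameter a field worker should supply. (With
  the raw $v$ the estimate would be biased low by exactly the factor
  $1-S$, which is a statement about parameter choice, not the model.)
* `parameter_error_experiment()` — surveys simulated under true
  parameters, densities re-estimated with single parameters perturbed.
  Its deterministic counterpart, `parameter_sensitivity()`, holds the
  count at its expectation $z = D v t \bar p$ and isolates parameter
  bias from sampling noise; both signed and absolute errors are
  reported because either convention is defensible. Perturbed angles
  leaving $(0, 2\pi]$ are clipped and flagged.

### Scales

The experiments default to a desk scale: arena 1.5 km (population
157), 30 replicates, the six `spanning_cells()` (the four grid corners
plus two interior cells); `full_scale = TRUE` restores the 7.5 km,
100-replicate, 77-cell design. The capture-number experiment uses the
four corner cells as its representative submodels: the exact
representative cells of the original figures are not recoverable, and
the corners span the parameter ranges by construction.

What the desk scale does and does not preserve deserves care. The
*expected* capture count is arena-independent at fixed density,
duration and geometry — the sensor sees the same local flux — and this
invariance is asserted empirically in the tests. The *dispersion* of
the count is not preserved: it is governed by the number of
individuals, which scales with arena area. With simple movement an
animal's heading never changes, so for a narrow sensor and a narrow
signal only the small fraction of animals with favourable headings can
ever be detected; at 157 animals the smallest cell's captures come from
roughly a dozen individuals whose repeated, quasi-periodic passes
cluster. Measured at the smallest cell (θ = 2π/9, α = π/11), the
per-survey percentage error has a standard deviation of about 22% at
desk scale against about 8% (essentially the count's Poisson noise) at
full scale, while the mean stays unbiased (+0.45% ± 1.27% s.e. over 300
desk-scale surveys). Medians of 30 replicates and CVs of
run-until-capture times in that cell are therefore substantially
noisier — and the CV genuinely larger — at desk scale than the
full-scale study's headline figures; the acceptance summaries are
computed at desk scale regardless and should be read with that in
mind.

## Known limitations

* The estimator ships no variance or interval estimator for $\hat D$;
  precision must come from replication, as in the validation study.
* Group-living animals, moving sensors (the $v + v_s$ extension) and
  imperfect detection within the sector are not modelled.
* $\bar p$ enters as a point value; uncertainty in $\theta$, $\alpha$,
  $r$, $v$ propagates per `parameter_sensitivity()` but is not folded
  into the estimate.
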