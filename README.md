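# grem

Absolute animal density from remote-sensor count data via the
**generalised random encounter model (gREM)**.

Camera traps and acoustic detectors count encounters with unmarked
animals. Without individual recognition or distances, converting a count
`z` into a density needs a model of the encounter process. The ideal-gas
model handles an omnidirectional sensor and omnidirectional animals
(`D = z / (2 r v t)`); the camera-trap random encounter model (REM)
handles narrow sensors. The gREM covers the whole parameter square —
any sensor detection width θ ∈ (0, 2π] and any animal signal
directionality α ∈ (0, 2π] (echolocating bats, songbirds, cetaceans,
big cats …) — through one estimator:

```
D̂ = z / (v · t · p̄(θ, α, r))
```

where `p̄` is the **mean profile width**: the detectable cross-section
the sensor presents to an approaching animal, averaged over approach
angles. Over the (θ, α) square, `p̄` takes five closed-form expressions
with linear boundaries (α = π, θ = 2π − α/2, θ + α = 3π); the gas model
(`p̄ = 2r`) and the REM (`p̄ = r(2+θ)/π`) are the two classical corners.
The package provides:

* the closed forms and an independent numerical oracle
  (`mean_profile_closed()`, `mean_profile_numeric()`,
  `classify_submodel()`, `profile_width()`);
* the estimator and a parameter-sensitivity analysis
  (`estimate_density()`, `parameter_sensitivity()`);
* a spatially explicit agent-based simulation of animals moving past a
  sector sensor on a torus (`sim_config()`, `run_survey()`,
  `run_until_captures()`), with exact event detection along movement
  segments;
* the validation experiments: submodel accuracy, precision versus
  number of captures, robustness to movement models, and propagation of
  parameter mis-measurement (`submodel_accuracy_experiment()` and
  friends), each with tidy outputs and `autoplot()` methods;
* a command-line interface (`inst/cli/grem.R`) with `profile`,
  `estimate`, `simulate` and `exp-*` subcommands.

Units are consistent throughout: distances km, times days, speeds
km/day, angles radians (the CLI accepts degrees).

## Worked example

An acoustic sensor with a nearly full detection circle (θ = 15π/8,
r = 10 m) surveys an animal with a fairly directional call (α = π/2)
for 30 days; animals move at 40 km/day and 412 calls are captured:

```r
library(grem)

mean_profile_closed(sensor_spec(theta = 15 * pi / 8, r = 0.01),
                    signal_spec(alpha = pi / 2))
#> <grem_profile> p_bar = 0.0139483 (closed_form, submodel SE2; theta = 5.89, alpha = 1.571, r = 0.01)

estimate_density(tibble::tibble(z = c(8400, 412), t = c(150, 30), v = 40,
                                theta = c(2 * pi, 15 * pi / 8),
                                alpha = c(2 * pi, pi / 2), r = 0.01))
#> # A tibble: 2 × 9
#>       z     t     v theta alpha     r  p_bar region D_hat
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl> <chr>  <dbl>
#> 1  8400   150    40  6.28  6.28  0.01 0.02   gas     70
#> 2   412    30    40  5.89  1.57  0.01 0.0139 SE2     24.6
```

The first row is the ideal-gas special case (p̄ = 2r = 0.02 km), giving
70 animals/km²; the second uses the SE2 submodel's profile
(p̄ ≈ 0.0139 km) to turn 412 directional calls into ≈ 24.6 animals/km².

Closing the loop with the simulator: a 150-day simulated survey of the
same sensor at a true density of 70 km⁻² captures 5877 encounters, and
the estimator recovers the truth to a fraction of a percent:

```r
sv <- run_survey(sim_config(theta = 15 * pi / 8, alpha = pi / 2,
                            arena = 1.5, seed = 1))
glance(sv)$z
#> [1] 5877
estimate_density(tibble::tibble(z = sv$z, t = sv$t_total, v = 40,
                                theta = 15 * pi / 8, alpha = pi / 2,
                                r = 0.01))$D_hat
#> [1] 70.2
```

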