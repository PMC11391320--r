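# patchrecovery

How long does a disturbed coastal habitat patch — a seagrass meadow wiped
out by a flood, a reef patch lost to a heatwave — take to recover, and
which restoration action buys the most time? `patchrecovery` answers these
questions for any habitat that recovers by propagule dispersal from
connected remnant patches followed by in-place regrowth. It is written for
restoration ecologists and managers who need recovery timescales under
explicit assumptions about connectivity, recruitment and chronic stress.

## The model

Recovery time decomposes as **T = W + t_grow**:

* **W**, a stochastic colonization waiting time. The annual recolonization
  probability comes from one of two models over a binary patch network
  *Q*:
  * *uncertain dispersal* — arrival is the lottery, recruitment certain:
    `p_D = 1 − ∏_j (1 − L_max / (1 + exp(−ν(B_j − τ))))` over connected
    patches *j*;
  * *uncertain recruitment* — arrival deterministic, recruitment the
    lottery, driven by summed connected biomass *S*:
    `p_R = R_max / (1 + exp(−ν(S − τ)))`, capped at `R_max` no matter how
    many patches connect.

  The annual probability maps to a hazard `λ = −ln(1 − p)`, so W is
  exponential and T follows a translated-exponential law with closed-form
  mean and quantiles (a Monte Carlo simulator cross-checks them).
* **t_grow**, the deterministic time for logistic regrowth from the
  colonization biomass `B0` to 50% of the light-specific equilibrium
  `B_eq(ℓ) = B_max·ℓ`, with growth rate `r(ℓ) = r_max·ℓ` under chronic
  low-light stress (fraction ℓ of normal benthic light):
  `t_grow = ln[f(B_eq − B0)/(B0(1 − f))]/r(ℓ)`.

On top sit factorial scenario grids, management interventions (seeding /
planting, recruitment stabilization, light improvement) compared as *years
of recovery time saved*, multiplicative parameter-sensitivity sweeps, and a
calibrated placeholder parameter registry for two seagrass-like species.
The methods vignette (`vignettes/recovery-model.Rmd`) documents every
equation, default and design choice.

## Worked example

```r
library(patchrecovery)
reg <- generate_fixture_registry()   # placeholder parameters, all tagged

run_scenario(scenario("zostera-like", "dispersal", 1, 1), reg)
#> Scenario: zostera-like | dispersal model | 1 connected patch(es) | light 1 | management none | threshold 0.5
#>   annual recolonization probability: 0.24 (analytic mode)
#>   median 4.82 years, 75% interval [2.78, 9.87], 95% interval [2.39, 15.7]
```

One connected meadow at normal light gives the disturbed patch a 0.24
annual chance of recolonization; with the ~2.3 years of regrowth after
colonization, median recovery is 4.8 years but the 95% interval stretches
to 15.7 — recovery in one funding cycle and recovery in a decade are both
plausible. Connectivity and light stress move these numbers sharply:

```r
grid <- run_scenario_grid(reg, species = "zostera-like", model = "dispersal",
                          n_connected = c(1, 3, 10), light_fraction = c(1, 0.25))
grid[, c("n_connected", "light_fraction", "annual_probability", "median", "q025", "q975")]
#>   n_connected light_fraction annual_probability median q025   q975
#> 1           1           1.00            0.24000   4.82 2.39  15.74
#> 2           3           1.00            0.56102   3.14 2.33   6.78
#> 3          10           1.00            0.93571   2.55 2.31   3.64
#> 4           1           0.25            0.00726 101.45 9.83 512.44
#> 5           3           0.25            0.02163  38.05 7.51 175.05
#> 6          10           0.25            0.07030  15.87 6.70  56.96
```

More propagule sources shorten and, above all, *stabilize* recovery;
severe light stress (25% of normal) at low connectivity pushes the median
past a century — the regime where intervention is essential. Management
actions are compared as years saved, and ranked:

```r
base   <- run_scenario(scenario("zostera-like", "dispersal", 1, 0.25), reg)
seeded <- run_scenario(scenario("zostera-like", "dispersal", 1, 0.25, "seed"), reg)
years_saved(seeded, base)
#> [1] 95.09408

best_action(reg, "zostera-like", "recruitment", 1, 1)
#> Management action ranking (median recovery time):
#>     action statistic    years rank
#>  stabilize    median 2.297560    1
#>       seed    median 3.772330    2
#>       none    median 4.823267    3
#>      light    median 4.823267    3
#> best: stabilize
```

When recruitment is the uncertain step, stabilizing recruitment conditions
beats seeding; when dispersal is, seeding wins — the best action tracks the
constraint on recovery, and (as the sensitivity sweeps show) is robust to
the poorly known productivity parameter τ even though the recovery times
themselves are not.

## Command line

```sh
Rscript inst/cli/patchrecovery.R analytic --out-dir out            # scenario grid
Rscript inst/cli/patchrecovery.R simulate --seed 1 --reps 10000 --out-dir out
Rscript inst/cli/patchrecovery.R manage-compare --out-dir out      # years saved per action
Rscript inst/cli/patchrecovery.R sweep --parameter tau --out-dir out
Rscript inst/cli/patchrecovery.R fixtures --out-dir out            # write the placeholder registry
```

Each run writes tidy CSV results, a JSON metadata file recording the
parameter registry (with provenance tags), seed and package version, and a
log line; identical invocations produce identical result files. A YAML or
JSON `--config` file can replace the placeholder registry and default grid
(see `?load_config`).

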