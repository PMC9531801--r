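# bbcsim

Quantifies how well porous fabrics — the materials of home-made face
masks — block **ballistic respiratory droplets**: the large droplets that
fly like projectiles from an emitter's mouth to a receiver's face and
dominate short-range transmission. The package implements a frugal,
stain-based assessment pipeline end to end:

1. **Imaging** — turn scanned stain patterns into the *Ballistic Blocking
   Capacity*

   $$\mathrm{BBC} = \Bigl(1 - \frac{\langle\bar p_o\rangle}{\langle\bar
   p_{no}\rangle}\Bigr)\times 100\%, $$

   where $\langle\bar p_o\rangle$ and $\langle\bar p_{no}\rangle$ are
   mean binary-pixel fractions of the screen scans with and without the
   obstacle (100% = everything blocked, 0% = nothing blocked), plus stain
   size statistics via equivalent-disk diameters.
2. **Transport simulation** — Monte-Carlo emission of droplets moving
   under gravity and Stokes drag (closed-form trajectories with
   relaxation time $\tau = 2\rho r^2/9\eta$), interacting with a cloth
   described by a tunneling probability $p$ and a deceleration factor
   $f$; the simulated statistic (SBBC) applies the BBC formula to droplet
   volumes reaching the screen center.
3. **Calibration** — weighted least-squares fit of $(p, f)$ to BBC
   observations at several cloth positions, linear position-trend
   comparison, and an exact one-tailed Mann–Whitney test for
   source-control vs. wearer-protection comparisons.
4. **Synthetic data** — a scanner-image generator with full ground truth,
   so the whole pipeline is testable without any real scans.

It is aimed at researchers reproducing or extending frugal mask-testing
protocols, and at anyone needing a tested reference implementation of the
BBC/SBBC statistics.

## Worked example

Simulate the bench (nozzle 19 cm from the screen, 100 000 droplets from
the measured size law at 3 m/s, ±10°), hold a silk-like cloth
($p = 0.04$, $f = 0.56$) 1.5 cm from the screen, and compute the
simulated blocking:

```r
library(bbcsim)
geo  <- experiment_geometry()          # L = 19 cm, ROI band = +/- 2 cm
m    <- emission_model(seed = 11)      # mean 54.0 um, SD 52.3 um, min 7 um
free <- simulate_experiment(m, geo)
table(free$fate)
#>    hit_roi hit_screen    blocked    stalled       fell
#>       1283       3758          0      94679        280

silk <- barrier(0.175, p = 0.04, f = 0.56)
rec  <- simulate_experiment(m, geo, silk, barrier_mode = "weighted")
sbbc(rec, free)
#> [1] 96.09116
```

Only ~5% of emitted droplets can ballistically cross 19 cm at all (the
rest stall: their whole drag-limited range is shorter than the bench),
and the receiver-side cloth blocks 96.1% of the volume that would have
reached the screen center. Calibrating $(p, f)$ against blocking
observations at the four standard cloth positions:

```r
obs <- data.frame(distance_m = default_barrier_positions(geo),
                  bbc = c(100, 99.3, 97.4, 96.1), sigma = 1)
fit_pf(obs, emission_model(seed = 12), geo)
#> Cloth model fit: p = 0.039, f = 0.557 (objective 0.03738)
#>   slopes vs position: experimental -25.5, simulated -25.5 %/m (rel. diff 0.01%)
#>   note: fitted line exceeds 100% inside the data range
```

The fit recovers the generating parameters and both blocking-vs-position
trends agree to a fraction of a percent; the over-range note flags linear
extrapolations above 100%, which should not be interpreted.

## Analysis workflow

The `analysis/` drivers run the full study on synthetic data and write
their tables under `results/`:

| stage | does | writes |
|---|---|---|
| `01_simulate_configurations.R` | SBBC for free / receiver-side / source-side / both / intermediate cloth placements | `results/sbbc_configurations.csv` |
| `02_generate_synthetic_scans.R` | 15 scanner images (5 configurations × 3 replicates) with ground truth | `scratch/synthetic_scans/` |
| `03_image_analysis.R` | BBC per position, stain statistics, Mann–Whitney source-vs-receiver test | `results/bbc_estimates.csv`, `results/configuration_test.json` |
| `04_fit_cloth_model.R` | $(\hat p, \hat f)$ calibration and slope comparison | `results/fit_result.json` |

Run them in order with `Rscript analysis/01_simulate_configurations.R`
and so on; every stage prints what it found and all randomness is seeded
in the scripts.

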