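# consortsim

Simulation and analysis of two-strain rod-shaped bacterial consortia growing
in open monolayer microfluidic traps, where dynamic control of a strain's
mean cell division length confers a mechanical competitive advantage.

The package provides three complementary model tiers plus shared analysis
tools:

- **Agent-based model (ABM)** — 2D spherocylinders that grow exponentially,
  divide at stochastic target lengths, interact through simplified Hookean
  contact mechanics with overdamped relaxation, and are washed out of the
  open trap when their centers cross its boundary. Long cells self-organize
  into vertical nematic columns; shortening a strain's division length
  (factor `a`) makes its daughters rotate, invade neighboring columns
  laterally, and take over the trap.
- **Quorum-sensing (QS) layer** — each strain produces an orthogonal signal
  (C4HSL / C14HSL) under LacI repression; signals cross the membrane with
  first-order kinetics into a well-mixed trap pool coupled to a diluted flow
  channel. A received opposite-strain signal above a threshold `H_T`
  triggers the division-length reduction, closing a negative-feedback loop
  that yields sustained strain-fraction oscillations.
- **Stochastic lattice model (LM)** — an event-driven (Gillespie) caricature
  on an always-full `M x N` grid: cells are vertical or horizontal, divide
  at boundary-modulated rates `lambda * exp(-kappa * distance)`, displace
  whole half-rows/columns, and rotate with a neighborhood-averaged
  probability `p_rot` that serves as the proxy for division length.
- **Reduced oscillator** — a two-variable fast–slow ODE for the strain
  fraction `x` and a growth-dominance switch `Q`, with the closed-form
  sharp-switch period `ln(K2/K1) + ln((1-K1)/(1-K2))`.

## Quick tour

Single-strain nematic ordering in the ABM (bulk order parameter ~0.98 at
division length 4.2 um, distinctly lower at 2.5 um):

```r
library(consortsim)
g <- trap_geometry(width = 50, height = 20)
p <- abm_params(geometry = g, blue = strain_params(l_d_bar = 4.2),
                dt = 0.05, sample_dt = 25)
tr <- abm_simulate(p, t_end = 400, seed = 1, mode = "single", n_seed = 32)
region_q(tr$final_cells, g, "bulk")   # ~0.97
```

Division-length-driven takeover — induce `a = 0.6` in the orange strain of a
mixed trap and fit the saturating invasion exponential to the ensemble mean
(the fixed-prefactor model `1 - 0.5 exp(-alpha (t - t0))` starts at 1/2, so
it describes the mean, not a single drifting run):

```r
p <- abm_params(geometry = g,
                blue = strain_params(l_d_bar = 4.2),
                orange = strain_params(l_d_bar = 4.2, a = 0.6),
                dt = 0.05, sample_dt = 10,
                induce_time = c(blue = Inf, orange = 150))
f <- sapply(1:6, function(sd)
  abm_simulate(p, t_end = 450, seed = sd, mode = "random",
               n_seed = 64)$summary$frac_orange)
fit_alpha(seq(0, 450, by = 10), rowMeans(f), "invasion", t0 = 150)$alpha
```

Lattice-model ensemble (forcing mode: strains in separate halves, orange
rotation switched on at t = 1):

```r
p <- lm_params(M = 20, N = 100, kappa = 0.02,
               p_rot = c(blue = 0, orange = 0), induction_time = 1,
               p_rot_post = c(blue = 0, orange = 0.5))
ens <- lm_ensemble(p, replicates = 100, t_end = 2, sample_dt = 0.05,
                   seed = 1, mode = "separated", orientation = "vertical")
fit_alpha(ens$summary$t, ens$summary$mean_frac_orange, "growth",
          t0 = 1)$alpha   # ~0.045
```

QS oscillator (calibrated defaults; ~6 strain-fraction half-cycles over
1500 min in a 40 x 20 um trap):

```r
p <- abm_params(geometry = trap_geometry(width = 40, height = 20),
                blue = strain_params(l_d_bar = 4.2, a = 0.6),
                orange = strain_params(l_d_bar = 4.2, a = 0.6),
                dt = 0.05, sample_dt = 20, qs = qs_params())
res <- run_oscillator(p, t_end = 1500, seed = 3)
res$half_cycles   # >= 3, status "ok"
```

Reduced oscillator against its closed form:

```r
op <- osc_params(K1 = 0.2, K2 = 0.8, n = 64, eps = 1e-3)
measure_period(osc_integrate(op, t_end = 15))  # 2.80
osc_period_limit(op)                           # 2 ln 4 = 2.77
```

## Command line

A thin CLI is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/consortsim", package="consortsim"))') \
  lm --config cfg.yaml --replicates 100 --out runs/lm
```

Subcommands: `lm`, `abm` (YAML-configured simulations written as
`<stem>_summary.csv` + `<stem>_meta.json`), `osc` (ODE trajectory CSV),
`analyze` (exponential-rate fit of a written trajectory). See
`read_config()` for the YAML schema.

## Reproduction

`scripts/acceptance.R` measures the two headline statistics against the
installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

- `t4`: expected nematic order parameter of 10^6 uniformly random
  orientations (≈ 0.0009; tends to 0).
- `t5`: steady-state bulk order parameter of a single-strain ABM run at
  division length 4.2 um (≈ 0.97; target ≈ 1 within 0.1).

The full test suite (`tests/testthat/`) contains one acceptance block per
criterion in `test-acceptance.R` plus unit/property tests per module. Note:
the banded-seeding lattice sub-criterion states expectations that the
faithful neighborhood-averaged rotation rule does not robustly reproduce;
those assertions fail by design rather than being weakened — see the
"Known limitations" section of the methods vignette
(`vignettes/methods.Rmd`).
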