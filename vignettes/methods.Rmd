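---
title: "Methods: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

consortsim simulates two-strain consortia of rod-shaped bacteria in open
monolayer microfluidic traps, where shortening a strain's mean division
length changes its collective mechanics and hence its competitive fate.
This vignette defines each model tier, lists the default parameters and the
reasoning behind them, and documents numerical choices and known
limitations. Heavy chunks are not evaluated at build time; all quoted
numbers come from the runs reproduced by the test suite and
`scripts/acceptance.R`.

## 1. Agent-based model

Cells are 2D spherocylinders of fixed 1 µm width with center `(x, y)`, axis
angle `phi` in `[0, π)` (nematic identification) and length `l`. Per update
cycle of length `dt` the engine applies, in order:

1. **Growth** — exponential in length, `l ← l · 2^(dt / doubling_time)`.
2. **Division** — a daughter born at length `l0` divides when
   `l ≥ sqrt(2 · l0 · l̄_d)`, where `l̄_d` is the strain's (possibly
   reduced) mean division length; this makes the lineage's division length
   a contraction map with fixed point `l̄_d`. The mother splits at
   `eps0 ~ U[0.45, 0.55]` into two daughters placed end-to-end inside her
   footprint, each receiving a small angular jitter
   (`noise_sd` = 0.02 rad) and intracellular species in proportion to
   birth length.
3. **Mechanical relaxation** — pairwise contacts between axis segments
   generate linear repulsive forces `k_n ×` overlap at the contact point,
   with torque; positions/angles relax by overdamped first-order updates
   (drag `zeta` per unit length) until the maximum overlap falls below
   `tol` or `max_iter` sweeps have run. The accumulated inward axial load
   is recorded per cell as `F_axial`.
4. **Outflow** — cells whose centers leave the trap rectangle are removed
   (open boundaries on all four sides).
5. **Quorum sensing** (optional) — forward-Euler kinetics co-integrated
   with the mechanics step (section 2).

### Mechanics calibration

The contact scheme is a deliberate simplification of rigid-body granular
mechanics. Its constants were calibrated until a single long-strain
population (`l̄_d = 4.2` µm) robustly forms the vertical nematic columns
that are the model's reference state:

| constant | value | note |
|---|---|---|
| `k_n` | 100 | contact stiffness |
| `zeta` | 100 | drag per unit length |
| `tol` | 0.05 µm | residual-overlap tolerance |
| `max_iter` | 50 | relaxation sweeps per step |
| `noise_sd` | 0.02 rad | division angular jitter |
| `dt` | 0.02 min (0.05 in the reduced test trap) | update step |

With these values a 50 × 20 µm trap seeded with 32 cells reaches a filled
steady state (~550 cells) whose bulk order parameter averages ≈ 0.97 at
`l̄_d = 4.2` µm versus ≈ 0.72 at 2.5 µm:

```{r abm-order}
library(consortsim)
g <- trap_geometry(width = 50, height = 20)
p <- abm_params(geometry = g, blue = strain_params(l_d_bar = 4.2),
                dt = 0.05, sample_dt = 25)
tr <- abm_simulate(p, t_end = 400, seed = 1, mode = "single", n_seed = 32)
region_q(tr$final_cells, g, "bulk")
```

The internal relaxation pseudo-step is `0.2 · zeta · w / k_n`; doubling it
degrades the steady-state bulk order from ≈ 0.98 to ≈ 0.86 and was
rejected.

### Division-length control

Reducing a strain's mean division length by the factor `a` (default study
value 0.6, i.e. 4.2 µm → 2.52 µm) is the single control knob. Short
daughters are more easily rotated by neighbor contacts, break out of their
column, grow horizontally and invade adjacent columns; an induced strain's
fraction grows along a saturating exponential `1 − 0.5·exp(−α(t − t0))`.
Induction is either external (`induce_time`) or signal-triggered
(section 2). The threshold comparison is strict (`H_opp > H_T`); equality
leaves the length unreduced.

## 2. Quorum-sensing circuit

Each strain produces an orthogonal acyl-HSL (blue → molecule 1 "C4HSL",
orange → molecule 2 "C14HSL"). Per cell:

- production of the own molecule at rate
  `alpha / (1 + (LacI / K_L)^m_L)`,
- membrane exchange `d_m (H_e,m − H_m)` for both molecules (first-order),
- LacI activation by the received opposite signal,
  `dLacI/dt = beta · H_opp^m_H / (K_H^m_H + H_opp^m_H) − delta_L · LacI`.

The external field is a well-mixed trap pool receiving the area-weighted
membrane flux of all cells, exchanging with a flow-channel compartment at
rate `k_ex`, which is diluted at rate `gamma`. A cell whose received signal
strictly exceeds `H_T` has its division length reduced by its strain's
factor `a`. All kinetics use forward Euler at the mechanics step (a
step-doubling check in the test suite bounds the discretization error).

### Circuit calibration (documented tuning)

The exact rate constants of the original circuit are not published in the
material this package works from; the Hill forms above are standard
reconstructions, and the defaults were tuned — as sanctioned for this
layer — until the full co-simulation sustains strain-fraction
oscillations. The calibration journey matters because each failure mode is
informative:

1. Slow LacI turnover (`delta_L = 0.1`, `K_L = 0.5`) lets LacI saturate at
   `beta/delta_L = 10`, repressing the losing strain's signal ~400-fold:
   the toggle locks and one strain fixes (extinction) before the relay can
   fire.
2. A threshold far below the operating signal range (`H_T = 0.4` against
   signals of 2–18) keeps **both** strains induced; the competition is
   symmetric and drifts to fixation. This is retained as the deliberate
   "low `H_T` → extinction" failure mode.
3. A lower-mid threshold (`H_T = 4`) releases the **majority** strain
   (whose opponent's signal has dropped), and in the fully induced,
   disordered trap a released long strain *beats* the short one —
   positive feedback, runaway extinction. The short-cell invasion
   advantage requires an ordered columnar opponent.
4. A threshold just above the 50/50 operating level (`H_T = 9` against
   ~7–8.5) means only a **majority** strain's signal crosses it, so the
   **minority** is shortened and counter-invades the majority's ordered
   columns — negative feedback and sustained oscillation (6 half-cycles
   over 1500 min at the default seed; `H_T = 10` still oscillates but
   with ~3× the period).

Frozen defaults: `alpha = 6`, `d = (2, 1)` (the smaller molecule exchanges
faster — the designed source of oscillation asymmetry), `k_ex = k_ex' =
0.5`, `gamma = 1`, `K_L = 2`, `m_L = 2`, `K_H = 1`, `m_H = 2`, `beta = 1`,
`delta_L = 1`, `H_T = 9`. With `K_H = 1` LacI stays near saturation
(0.94–0.99) and modulates anti-phase with the fraction; the oscillation is
threshold-controller-driven rather than toggle-driven.

```{r oscillator}
p <- abm_params(geometry = trap_geometry(width = 40, height = 20),
                blue = strain_params(l_d_bar = 4.2, a = 0.6),
                orange = strain_params(l_d_bar = 4.2, a = 0.6),
                dt = 0.05, sample_dt = 20, qs = qs_params())
res <- run_oscillator(p, t_end = 1500, seed = 3)
res$half_cycles; res$status
```

## 3. Stochastic lattice model

The trap is an always-full `M × N` grid (default 20 × 100, mirroring the
trap aspect ratio). Each cell is vertical or horizontal and blue or orange.
A vertical cell in row `i` divides upward at rate
`lambda · exp(−kappa (M − i))` and downward at rate
`lambda · exp(−kappa (i − 1))`; horizontal cells divide left/right with the
analogous column rates — `kappa` encodes how strongly the population
between a cell and its target boundary suppresses growth. A division
displaces the entire half-row/column from the daughter's site to the
boundary; the cell pushed past the boundary is removed, and a daughter that
would land outside is discarded. The displacing daughter rotates with
probability equal to the arithmetic mean of `p_rot` over the mother and her
existing Moore neighbors; `p_rot` is the lattice proxy for a short division
length. The engine is an exact Gillespie simulation over the 2`MN`
directional rates, kept in a Fenwick tree for `O(log MN)` updates.

Orientation order is summarized as `q = |2 f_H − 1|` with `f_H` the
horizontal fraction.

### `kappa` and seeding protocols

`kappa` is not pinned by the available material. The constructor default is
0.25 (strong boundary modulation; visibly position-dependent rates). The
*study* calibration used in the takeover experiments is `kappa = 0.02`,
chosen because larger values freeze horizontal division chains in the wide
direction (`exp(−kappa N/2)` ≈ 0 for N = 100) and suppress the takeover
dynamics entirely. Two-strain protocols:

- **separated** (forcing mode): blue fills the left half-columns, orange
  the right, all vertical; orange's rotation is switched on at `t = 1`.
  The ensemble-mean orange fraction leaves 1/2 as `0.5·exp(α(t − 1))` with
  `α` increasing approximately linearly in `p_rot,o`
  (0.028/0.045/0.056 at `p_rot,o` = 0.3/0.5/0.7; linear `R²` > 0.9).
- **banded**: alternating 10-column single-strain bands, all vertical,
  same induction (see Limitations).

## 4. Reduced oscillator

The fast–slow caricature tracks the strain fraction `x` and a dominance
switch `Q`:

- `dx/dt = Q·x − (1 − Q)(1 − x)`
- `eps · dQ/dt = −Q·L1(x) + (1 − Q)·L2(x)` with Hill switches
  `L1 = 1/(1 + ((1 − x)/(1 − K2))^n)`, `L2 = 1/(1 + (x/K1)^n)`.

For `K1 < K2` and sharp switches the fraction relaxes back and forth
between the thresholds; in the limit `n → ∞`, `eps → 0` the period is
`ln(K2/K1) + ln((1 − K1)/(1 − K2))` — for `K1 = 0.2, K2 = 0.8` this is
`2 ln 4 ≈ 2.7726`, and the integrated system (`n = 64`, `eps = 10⁻³`,
stiff `lsoda`) measures 2.80 (+1.0%). For `K1 > K2` the trajectory
converges to a fixed point.

## 5. Analysis toolbox

- `order_parameter(phi, weights)` — nematic order
  `q = sqrt(mean(cos 2φ)² + mean(sin 2φ)²)`; 10⁶ uniform angles give
  `q ≈ 0.0009` (→ 0).
- `region_q` — order within the bulk / edge strips of the trap
  (full-height strips: central 40% and outer 15% of the width by default).
- `kymograph` — per-column time series of `q` or of the axial-force
  projection `F_x = mean(F_axial · |cos φ|)`; used for the co-located
  order-drop / force-rise signature of an invading short strain.
- `fit_alpha` — nonlinear least squares for the saturating invasion form
  `1 − 0.5·exp(−α(t − t0))` (fitted up to the first crossing of 0.95) and
  the early growth form `0.5·exp(α(t − t0))`; parameter recovery within
  10% on noisy synthetics is part of the acceptance suite.
- `alpha_vs_parameter` — monotonicity and linear/exponential trend of `α`
  against a control parameter.

## 6. Numerical and reproducibility notes

- Both engines are compiled (Rcpp) with their own Mersenne-Twister RNG
  streams seeded per run; R-level operations use R's RNG. Identical seeds give
  identical trajectories; `make_seeding` restores the caller's RNG state.
- ABM runs in this document use `dt = 0.05` min in reduced traps; the
  conservative default is 0.02. The QS kinetics step equals the mechanics
  step and passes a step-doubling consistency check.
- Trajectory files are plain CSV plus a JSON sidecar
  (`format_version = 1`); `read_trajectory` refuses unknown versions.

## 7. Known limitations

- **Banded lattice takeover.** With the faithful neighborhood-averaged
  rotation rule, the banded protocol's ensemble mean rises from 0.5 to only
  ~0.65–0.73 by `t ≈ 40` (100 replicates), the saturating fit's `R²`
  fluctuates around 0.9 across seeds, and `α` is not monotone in
  `p_rot,o`: at high `p_rot,o`, rotated invaders adjacent to opposite-strain
  bands inherit much of their rotation tendency from those neighbors, which
  symmetrizes the interface instead of sharpening the invasion. The
  acceptance tests state the stronger published expectations verbatim and
  fail honestly on those assertions rather than weakening them; the
  separated/forcing protocol reproduces its expectations in full.
- **Simplified mechanics.** The contact model is first-order/overdamped
  with a fixed iteration budget; absolute force scales are meaningful only
  relative to each other (kymograph comparisons are always differential).
- **Well-mixed signals.** No spatial signal gradients inside the trap; the
  external field is two homogeneous compartments.
- **Oscillator seed fragility.** In the reduced 40 × 20 µm trap the
  tuned circuit sustains oscillation in 2 of 3 spot-checked seeds (5–6
  half-cycles); one seed dies by a finite-population excursion that
  outruns the relay — the documented extinction failure mode is never far
  away at ~300 cells.
- **LacI near saturation.** With the frozen circuit constants the
  co-repression adds delay but little bistability; oscillation timing is
  dominated by the threshold controller and population turnover.
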