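---
title: "Ion permeation analysis under terahertz driving: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion permeation analysis under terahertz driving: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzchannel)
options(thzchannel.verbose = FALSE)
```

## The system and the questions

A potassium-channel selectivity filter (SF) is a single-file stack of
carbonyl-lined binding sites — S4, S3, S2, S1 plus the flanking cavity site
Scav and external site S0 — through which dehydrated K⁺ moves under a
membrane voltage. Two conduction modes are distinguished: *soft knock-on*,
in which permeating ions are always separated by co-permeating waters, and
*direct knock-on*, in which adjacent ions make unscreened Coulomb contact.
A midinfrared field tuned to the carbonyl stretch band near 51.87 THz
(where bulk water absorbs little) excites the S1 coordination cage, and the
resulting structural stabilisation lowers the S1 barrier and speeds
conduction.

This package provides the *analysis* of such trajectories — occupancy
states, permeation counting, mechanism classification, potential of mean
force (PMF), IR spectra, pore geometry — together with a reduced-scale
Langevin simulator that generates trajectories with the same statistical
structure, so every analysis step can be validated against exact or
analytic ground truth.

## The channel simulator

`simulate_channel()` propagates ions and waters on the pore axis with
overdamped (Euler–Maruyama) Langevin dynamics:

$$ z_{t+\Delta t} = z_t + \frac{D}{k_BT} F(z_t, t)\,\Delta t
   + \sqrt{2D\Delta t}\,\xi, \qquad D = \frac{k_BT}{m\gamma}. $$

Forces on an ion are (i) the gradient of a multi-well binding landscape,
(ii) a constant membrane-voltage field, (iii) the oscillating field
$qE_0\cos(2\pi f t + \phi)$, and (iv) screened Coulomb repulsion
$\frac{q_iq_j}{4\pi\varepsilon_0\varepsilon_r r}e^{-r/\lambda_D}$ from the
other ions. Waters feel the landscape at reduced strength
(`water_scale`, default 0.5) and the single-file exclusion, but carry no
monopole charge, so they ignore both fields — the minimal mechanism that
lets soft and direct knock-on coexist. A particle leaving one end of the
box re-enters at the other, the single-compartment image of the
double-membrane periodic setup used in computational electrophysiology.

Key parameter defaults (`run_config()`):

| parameter | default | unit | why |
|---|---|---|---|
| `dt_fs` | 10 | fs | resolves the default landscape's gentlest features; rate studies with steep crests use 2 fs (below) |
| `temperature` | 300 | K | thermal reference; landscape energies are kT at 300 K (absolute 2.494 kJ/mol, so cooling sharpens wells) |
| `friction` | 5 | 1/ps | gives D(K⁺) ≈ 0.013 nm²/ps; only sets the time scale in the overdamped regime |
| `membrane_voltage` | 50 | mV | small outward drive; dropped uniformly across the box (constant-field method) |
| `epsilon_r`, `debye_nm` | 2, 0.8 | —, nm | screened Coulomb inside the filter |
| `d_min` | 0.24 | nm | single-file exclusion; the Coulomb force saturates below it (finite-size core) |
| `charge_imbalance_dq` | 4 | e | metadata only: the charge imbalance the voltage emulates |

Two design points deserve emphasis.

**The voltage is a constant field over the whole box, not a pore-local
tilt.** Besides matching the constant-electric-field method, a field-free
exit reservoir would add a barrier-independent diffusive series resistance;
in a barrier-rate experiment that extra term suppresses the Arrhenius
response the analysis is designed to measure.

**The landscape is a piecewise-cosine chain with exact extrema.** Wells sit
at `-depth` kT, barrier tops at `+barrier` kT relative to the flat
reservoirs, with C¹ cosine segments between, so depths and barrier heights
are exact by construction. Two optional refinements exist for
barrier-controlled rate studies: `barrier_halfwidth` puts a flat plateau at
each crest and `well_halfwidth` a flat floor at each well. The reason is a
Kramers prefactor effect: a fixed-width smooth crest's curvature scales
with its height, so *lowering* a barrier also *widens* it and part of the
expected $e^{\Delta B/k_BT}$ rate gain is lost to the prefactor. With flat
crests and floors, shifting a barrier rescales its crest Boltzmann weight
exactly and the hop rates follow the pure Arrhenius law.

## Resonant coupling to the carbonyl oscillator

The carbonyl stretch is modelled as one classical damped driven oscillator
(`carbonyl_oscillator()`): natural frequency 51.87 THz, damping
γ = 6 ps⁻¹ (Lorentzian FWHM ≈ 0.95 THz, consistent with a fingerprint band
narrower than 2 THz), reduced mass 6.86 amu, unit effective charge. Driven
at field frequency $f$ its steady-state amplitude is the Lorentzian

$$ A(f) = \frac{q_\mathrm{eff}E_0/m}{\sqrt{(\omega_0^2-\omega^2)^2 +
\gamma^2\omega^2}}, $$

integrated with `deSolve::ode` (lsoda) and checked against this closed form
to 1%. Its mean steady-state energy $\langle E\rangle$ (in kT) lowers the
S2→S1 barrier top by $\kappa\langle E\rangle$ (`modulated_barrier()`).
The oscillator relaxes within picoseconds, far faster than barrier hopping,
so the coupling is treated as quasi-static: the oscillator is integrated
first, then the particle dynamics run on the modulated landscape. κ is a
free calibration constant (no quantitative excitation–barrier link is
available); the defaults give ≈1.2 kT excitation at resonance with E₀ =
0.4 V/nm and near-zero a few THz away, which orders conditions as
no-field ≈ 50 THz < 53 THz < 51.87 THz, the qualitative pattern the
comparative experiment probes. The simulator does not attempt atomistic
side-chain dynamics; the causal chain is barrier-mediated by construction.

## Analysis conventions

* **Occupancy codes** span S1→S4 (leftmost = S1), alphabet `{K, W, 0}`;
  S0/Scav are reported separately. If two particles land in one interval
  the one nearer the interval centre wins and the tie is logged. The census
  is frame-weighted (time-averaged); the per-event view lives in the
  mechanism census.
* **Site intervals are half-open** `[z_lo, z_hi)`, so boundary coordinates
  assign deterministically.
* **Permeation events** use a two-plane committor rule: an outward event
  must enter from the intracellular reservoir, visit at least one binding
  site, and reach the extracellular reservoir without re-touching the entry
  reservoir. This is immune to rapid recrossing noise at a single plane,
  and the recycling jump (which skips the binding sites) can never fake an
  event. Reported current is net outward, $I = (N_{out}-N_{in})e/T$.
* **Mechanism classification** is per event: *soft* iff every frame of the
  transit window with ≥2 filter ions keeps a water between each adjacent
  ion pair; *direct* if any such frame has an adjacent pair with no
  intervening water. A vacancy between two ions counts as direct — nothing
  screens the Coulomb interaction — a declared choice the tests pin down.
  Windows with at most one filter ion stay unassigned and are excluded from
  the percentages (reported half-up to 2 decimals).
* **PMF** is equilibrium Boltzmann inversion on a uniform grid (default
  Δz = 0.02 nm), minimum referenced to zero; empty bins are flagged `NA`,
  never interpolated. Profiles from driven runs are labelled quasi-PMF in
  their output metadata. Barriers are `max(W)` between two well minima
  minus the donor minimum, reported for both hop directions.
* **IR spectra** use one fixed estimator: the ω²-weighted one-sided power
  spectrum of the mean-removed, Hann-windowed dipole (by Wiener–Khinchin,
  the ω-weighted Fourier transform of the windowed dipole autocorrelation).
  No quantum correction is applied. Zero-padding extends to the next
  2-3-5-smooth length ≥ `pad_factor`·N so the FFT stays fast for awkward
  trace lengths; peak frequencies are refined by a quadratic fit through
  the three bins around each maximum and widths by linear interpolation at
  half height.
* **Pore radius** is `r = l/2 − r_o` with `r_o = 1.52` Å by default (van
  der Waals oxygen; configurable since the formula's radius is not uniquely
  standardised). With four oxygens, ids (1,2) and (3,4) are the diagonal
  pairs and their distances are averaged. "Vibration amplitude" is the
  post-discard standard deviation of `l`.

## The barrier-rate (Arrhenius) experiment

The headline statistical experiment compares two otherwise identical runs
in which every inter-site barrier top is lowered by ln(1.8) ≈ 0.588 kT in
the second; barrier-controlled hopping predicts a 1.8-fold current gain.
`arrhenius_current_ratio()` fixes the study conditions:

* five wells (S4…S0) at 0.5 nm spacing, 2.5 kT deep;
* 3 kT flat-topped crests (plateau half-width 0.12 nm, floors 0.08 nm);
* 150 mV constant-field drive, one ion, dt = 2 fs, frames every ps;
* 4 seeds × 750 ns per condition in the acceptance script (the test suite
  uses 2 × 250 ns), first 2 ns discarded.

These conditions were chosen *before* the stochastic runs by validating the
design against an independent mean-first-passage-time (MFPT) oracle — the
1-D Smoluchowski double integral
$T = D^{-1}\int e^{U(y)}\int^y e^{-U(x)}dx\,dy$ — as the test suite does.
Two numerical effects matter and are documented here because they shape the
defaults. First, at finite barrier heights the diffusive ratio falls a few
percent short of the pure $e^{0.588} = 1.8$ limit; flat crests and floors
remove the dominant (prefactor) part of that shortfall. Second,
Euler–Maruyama sampling carries an O(Δt·D·V″) occupancy bias concentrated
at the steep cosine tapers; a dt sweep against the oracle fixes dt = 2 fs
for this landscape, while the flat crests and floors, where the rate is
actually decided, are bias-free. The suite asserts the simulated ratio
within two counting standard errors of the oracle prediction.

## What the generator does and does not emulate

The simulator reproduces the *statistical structure* the analysis assumes:
multi-site hopping with Boltzmann occupancies, voltage-driven net flux,
single-file order, ion–ion knock-on, water co-permeation, and a resonant,
barrier-mediated field effect. It does **not** emulate: 3-D pore geometry
or coordination chemistry, explicit solvent, lipids, polarisation,
absolute currents or absolute barrier heights of any real channel, or
atomistic origins of the carbonyl band. Passing tests therefore validate
the analysis pipeline and the qualitative physics of barrier-mediated
conduction — not quantitative agreement with any experimental or all-atom
system. The printed mechanism percentages are reproduced through scripted
trajectories whose ground truth is known exactly; they are classifier
fixtures, not predictions of the simulator.

## Degenerate inputs and numerical guards

Trajectories must have a uniform time grid (1 ppm tolerance) and no
coordinate gaps; species come from `{K, W, O, CL}`. The integrator aborts
when a deterministic step would exceed half the smallest site width,
advising a smaller dt. The oscillator integrator requires
dt ≤ 1/(20 f₀) and the underdamped regime γ/2 < 2πf₀. Spectra require ≥64
uniformly spaced finite samples. `census()` and `mechanism_census()` refuse
empty inputs; `site_barriers()` refuses sites with no sampled bins. The
screened-Coulomb force saturates below `d_min` so contacts cannot blow up
the integrator. All randomness flows from the config seed through R's RNG;
identical configs give bit-identical trajectories.

## Problem sizes

The test suite runs equilibrium validations at 10–20 ns (2–4 × 10⁶ steps),
the rate study at 2 × 250 ns, and everything else at sub-second scale; the
acceptance script's rate study uses 4 × 750 ns per condition. These sizes
give a few hundred to ~1400 permeation events, enough for the two-standard-
error criteria the suite applies.
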