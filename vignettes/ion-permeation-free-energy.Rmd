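---
title: "Nonequilibrium and equilibrium free-energy analysis of multi-ion permeation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonequilibrium and equilibrium free-energy analysis of multi-ion permeation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpmf)
```

## The problem

Bacterial voltage-gated sodium channels conduct Na⁺ readily in both
directions but pass K⁺ only outward: inward K⁺ current appears only at
large negative membrane potentials. Equilibrium free-energy landscapes
alone do not explain this — on the two-ion potential of mean force (PMF) a
pair of K⁺ ions has low-barrier pathways through the selectivity filter in
both directions. The explanation requires a nonequilibrium ingredient: under
a modest inward driving force, two K⁺ ions are pressed side by side into a
"pass-by" configuration near the filter entrance and wedge there, and
breaking this block costs several kcal/mol of work, equivalent to membrane
potentials of roughly −70 to −145 mV across three elementary charges.

`ionpmf` implements the full analysis chain at desk scale:

1. a Brownian (overdamped Langevin) simulator on analytic model landscapes
   that stands in for all-atom molecular dynamics,
2. the step-wise pulling protocol with harmonic restraints and its work
   ledger,
3. Jarzynski ("useful work") free-energy profiles with per-ion components,
4. umbrella sampling with 1D/2D WHAM reconstruction of unperturbed PMFs,
   with minima and bottleneck-path extraction,
5. pair-coordinate occupancy analytics (axial histograms, z₁–z₂ density,
   block detection, shared-solvent counting, directional asymmetry), and
6. the unit conversions connecting work to membrane potentials and forces.

Throughout, units are Å, kcal/mol and ps; k_B = 0.0019872 kcal/mol/K, so
k_BT = 0.5962 kcal/mol at the default 300 K. The axial coordinate z
increases in the inward direction and the filter spans z = −15 Å (entrance)
to −5 Å (cavity side).

## The model landscapes

A `landscape_spec()` has four energy terms: axial Gaussians U₀(z) (wells
and barriers), harmonic lateral confinement toward the pore axis, a
screened ion–ion repulsion V(r) = A·exp(−r/ℓ)/r soft-core clamped below
r = 1 Å, and pair *coordination* features — Gaussians in the pair's mean z
and z-separation that act only when two ions sit near the same z. The
coordination terms are the synthetic stand-in for what the filter's
glutamate/serine network does to a K⁺ pair: they carve "pass-by" minima
into the otherwise repulsive same-z diagonal of the two-ion surface.

Two presets are calibrated by topology, not by value:

* **Na-like** — three axial wells ~3 Å apart and no coordination terms. The
  two-ion surface has only off-diagonal ("knock-on") minima; the diagonal
  is a ridge.
* **K-like** — weak axial structure, a low entrance barrier, and a same-z
  architecture: the global pass-by minimum **X** in the middle of the
  filter (z ≈ −11.75), the shallower, narrower entrance-side minimum **Y**
  (z ≈ −13.25), a same-z ridge on the cavity side of X, and a same-z wall
  at the cavity mouth. Single ions travel through ordinary wells; only
  pre-formed pairs feel X (its same-z tolerance is small), which is what
  makes the block history-dependent: an inward pair, queued up at the
  entrance and funnelled through Y, lands in X and is held there by the
  driving force, while outward ions arrive single file and pass the same
  region without pairing.

```{r topology}
g <- pair_surface(preset_landscape("K-like"))
find_stationary_points(g, min_depth = 0.4)
```

The calibration targets were: exactly two same-z minima with X global and
deeper than Y; knock-on channels alongside; and barriers out of X toward
the pathways of a few k_BT, so a pass-by pair at equilibrium is mobile and
only an applied force holds the block in place. Values on these surfaces
are the package's own and are not comparable to any all-atom result; only
the topology and the qualitative asymmetry are.

## The simulator

Dynamics are inertialess Euler–Maruyama: each coordinate advances by
(D/k_BT)·F·dt plus a Gaussian kick of variance 2·D·dt. The default
D = 0.2 Å²/ps is of the order of bulk ion diffusivity; no in-filter value
is known, so D is an effective parameter and times are "simulator time".
One consequence is a time mapping for the protocols: the all-atom
relaxation times of 0.5 ns (fast) and 3 ns (slow) per pulling step become
50 and 300 ps here (one global factor of 0.1), which keeps each relaxation
window hundreds of in-well correlation times (k_BT/(k·D) ≈ 0.3–1 ps) long
— the regime the original protocol is designed for.

The integrator is stable only if k·D·dt/k_BT < 0.1 for the stiffest
curvature k in play; running functions check the bound and refuse to start
otherwise. The K-like preset's coordination terms reach ~130 kcal/mol/Å²,
hence the 2 fs default in `preset_sim_config()` (and 1.5 fs under umbrella
bias). Validation is statistical: a harmonic trap reproduces the
Ornstein–Uhlenbeck stationary variance k_BT/k within 5%, and unbiased
sampling on bounded landscapes reproduces U₀ through −k_BT·log(histogram)
to better than 0.1 kcal/mol at 10⁶ frames.

Randomness is counter-based: every replica or window derives its stream
from the master seed via `seed_stream()`, so results are independent of
execution order and bit-reproducible.

## Step-wise pulling and the Jarzynski estimator

`run_pulling()` advances the axial restraint centre λ in discrete
increments (±1 Å by default), relaxes for τ between switches, and records
the instantaneous-switching work ΔW = Σᵢ ½k[(zᵢ−λ')² − (zᵢ−λ)²] at frozen
coordinates — the standard step-wise Jarzynski protocol. The soft spring
k = 0.6 kcal/mol/Å² probes forces of membrane-potential magnitude
(0.5–1 kcal/mol/Å ≈ 0.035–0.07 nN); with 2 Å of lateral play the lateral
restraint costs only ~2 k_BT.

`jarzynski_profile()` applies ΔF = −k_BT·log⟨exp(−W/k_BT)⟩ (overflow-safe
log-sum-exp) to the cumulative work at each λ; per-point uncertainties use
the width/count formula [σ²_W/Q + σ⁴_W(k_BT)⁻²/2(Q−1)]^½. Two estimator
routes exist:

* **cumulative** (default) — Jarzynski's equality on the cumulative work;
  right for soft springs and few, well-separated steps;
* **stepwise** — per-switch estimates accumulated by `profile_from_steps()`
  with quadrature uncertainties; right in the stiff-spring limit, where the
  per-switch distributions stay narrow while the cumulative one grows
  without bound. The stiff-spring equivalence check (k = 20, Δλ = 0.2)
  uses this route and agrees with the umbrella/WHAM PMF to < 0.3 kcal/mol
  RMSE.

Per-ion components use the exponential weights of the *total* work applied
to each ion's cumulative work, with the remaining fluctuation gap (the
difference between the weighted mean total and the Jarzynski estimate)
shared equally among ions. This makes components sum to the total exactly
at every λ — the property the decomposition is used for — at the cost of
spreading the entropic correction uniformly; an independent per-ion
estimator is available via `per_ion_profiles(method = "independent")` but
does not sum to the total.

Uncertainty propagation across steps ignores step-to-step correlations
(quadrature), which overstates errors of *differences* of profile points;
`asymmetry_summary()` therefore bootstraps whole replicas when given
`pull_run` objects.

## Umbrella sampling and WHAM

`generate_windows()` tiles one or two axial coordinates (spacing 0.5 Å,
k_umb = 10 kcal/mol/Å², grid bin 0.5 Å by default — conventional,
overlap-safe values; a warning fires when the bias width drops below half
the spacing). `wham_solve()` iterates the standard self-consistent
equations to tol = 10⁻⁷ kcal/mol on the window free energies (cap 10⁵
iterations, non-convergence flagged, never silently accepted). Unsampled
bins are masked, never extrapolated; the PMF is offset so its sampled
minimum is zero. The solution is invariant to window order, to uniform
count doubling and to constant shifts of the bias (gauge invariance) —
all tested.

Minima extraction (`find_stationary_points()`) keeps strict 8-neighbour
minima whose topographic prominence (computed by a union-find sweep in
order of increasing energy) exceeds `min_depth`; grid-boundary bins are
excluded by default because truncation manufactures spurious edge minima.
Pathways (`minimum_energy_path()`) are bottleneck-optimal (minimax) paths
on the 8-connected grid, with ties broken by path length then node order so
results are deterministic; the reported barrier is the lowest saddle the
pair must cross, verified against exhaustive enumeration on small grids and
against analytic saddles.

## Occupancy analytics and the block

`pair_density()` bins a designated ion pair on (z₁, z₂); `detect_block()`
looks for a contiguous stretch of the same-z band (|z₁−z₂| ≤ 1 Å,
consistent with `classify_pair_configuration()`) holding at least
θ_occ = 0.2 of all aligned frames. θ_occ is an artifact parameter — no
quantitative threshold defines a "blocking area" in the literature — and
0.2 was fixed once as "a fifth of the protocol spent wedged", before the
acceptance runs. Occupancy is measured against *all* frames of the run, so
a protocol that spends most of its time outside the filter cannot fire by
concentration alone. `separation_and_solvent()` counts solvent points
inside the lens-shaped overlap of the two spheres of radius r₁₂ centred on
the ions (the intersection reading of "shared" solvent — a union reading
would count solvent near either ion, which is not what screening between
the ions means), averaging per pulling step over the final 2.5/3 of each
relaxation window.

`asymmetry_summary()` reports, for matched inward/outward runs, the maximum
cumulative work over the filter span and the block-escape work: the rise
from the profile minimum inside the block region (λ ∈ [−15, −10]) to the
highest point before the next local minimum, with the search confined to
the filter span — work done far outside the filter reflects bulk
extraction against the restraint, not the block. Escape-difference
uncertainties come from a replica bootstrap (default 200 resamples).

```{r asymmetry, eval = FALSE}
cfg <- preset_sim_config(seed = 5)
KL  <- preset_landscape("K-like")
ki  <- run_pulling(KL, preset_pull("inward",  n_replicas = 20, seed = 201),
                   cfg, species = "K-like")
ko  <- run_pulling(KL, preset_pull("outward", n_replicas = 20, seed = 202),
                   cfg, species = "K-like")
detect_block(pair_density(ki$trajectory))   # fires
detect_block(pair_density(ko$trajectory))   # does not
asymmetry_summary(ki, ko)
```

On the shipped presets this reproduces the qualitative headline: the
detector fires for K-like inward pulling only (occupancy ≈ 0.26 vs ≈ 0.17
outward, against the 0.2 threshold, stable across seeds), never for
Na-like, and the inward block-escape work exceeds the outward value by
far more than twice its bootstrap uncertainty, at roughly 6–11 kcal/mol —
the same scale the conversion functions translate to ~90–160 mV across
three charges.

## What the synthetic data can and cannot show

The generator emulates: diffusive multi-ion motion on species-dependent
axial landscapes, screened inter-ion repulsion, pass-by stabilisation for
K-like pairs, harmonic stepped restraints, and uniform solvent for
shared-water counting. It does not contain explicit water, protein degrees
of freedom, electrostatics beyond the screened pair term, or any membrane;
its landscape *values* are inventions calibrated only for topology. Tests
passing here therefore validate the estimators, the protocol bookkeeping,
the WHAM solver and the detection logic — they do not validate any
particular channel's energetics, and the kcal/mol numbers printed by the
pulling runs are properties of the presets, not predictions for NavAb.

## Numerical choices and limitations

* Problem sizes: the shipped checks use 19–23 step protocols with 12–80
  replicas, 19 umbrella windows × 2×10⁴ frames in 1D and 169 windows ×
  3×10³ frames in 2D — sizes chosen so the whole validation suite runs on
  one CPU in minutes while leaving comfortable statistical margins.
* The soft-core clamp makes pair energies finite at contact; force is zero
  below 1 Å, so two ions can in principle swap through each other — at
  realistic repulsion amplitudes this is rare and harmless on the pair
  coordinates analysed.
* Euler–Maruyama has O(dt) bias; at the enforced stability margin the
  equilibrium variance error stays below ~2%.
* The Jarzynski estimator is biased low-tail-dominated; for wide work
  distributions (σ_W ≫ k_BT) its Q-sample estimate is biased upward, which
  is why the stiff-spring check uses the stepwise route and why reported
  uncertainties carry the σ⁴ term.
* WHAM assumes uncorrelated samples; frames are recorded several in-well
  relaxation times apart to keep the effective sample count honest.
* Only the stepped protocol is implemented (no continuous steering), only
  Jarzynski (no bidirectional Crooks/BAR), PMFs up to 2D, and 1–3 ions.
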