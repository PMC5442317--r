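---
title: "A motor-free model of mitotic spindle assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A motor-free model of mitotic spindle assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spindlesim` simulates the earliest stage of mitosis in a fission-yeast-like
closed nucleus with **no molecular motors**: two spindle pole bodies (SPBs)
embedded in a fixed spherical nuclear envelope (NE) nucleate rigid, dynamic
microtubules (MTs); passive crosslinkers of the PRC1/Ase1 family bind
antiparallel MT pairs, and crosslinks near an MT plus end locally stabilize
its dynamic instability, standing in for the rescue factor (CLASP/Cls1
family) that Ase1 recruits. The question the model addresses is whether this
combination — crosslinking, local stabilization, and polymerization forces —
suffices to establish a bipolar spindle from two side-by-side poles.

This vignette documents the model, its parameters and units, the numerical
scheme, the synthetic-data surface used by the test suite, and the design
choices made where the problem was genuinely open. It states no empirical
result that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## Model components

### Geometry and mobility

The NE is a sphere of fixed diameter (2.75 µm). Each SPB is a thin disk
(0.18 µm) inserted in the envelope; it translates on the sphere and spins
about its normal with measured-scale diffusivities, driven by tether
reactions, disk–disk repulsion, and thermal noise. Positions are integrated
by an unconstrained tangent-plane step followed by radial re-projection
(error O(dt)); the invariant `|position| = R` holds to 10⁻⁹ µm at every
frame.

Each SPB carries 14 nucleation sites in a sunflower layout on the disk. An
MT is a rigid rod: its minus end is tethered to its site by a harmonic
spring, and the site acts as a *hinge with orientation stiffness*
(`nucleation_stiffness`, pN µm/rad) pulling the rod axis toward the site
normal; site normals fan outward on a cone (`nucleation_cone`). A freely
pivoting minus end is the limiting case `nucleation_stiffness = 0`; the
reference uses a soft hinge (0.1 pN µm), which in our hands is required to
suppress a spurious attractor in which MTs point *away* from the pole pair
and crosslink tail-to-tail (see *Design choices*).

Rod mobility is slender-body theory (parallel, perpendicular and rotational
drag with logarithmic end corrections), so rotational diffusion is correct
for any length; drag coefficients are cached and refreshed when the length
drifts by >2%.

### Dynamic instability and forces on growing tips

Plus ends switch between growth and shrinkage with four parameters
(v_g, v_s, f_c, f_r), one Bernoulli draw per MT per step with probability
1 − exp(−f·dt). The reference values

| quantity | value |
|---|---|
| growth speed v_g | 0.064 µm/s |
| shrinking speed v_s | 0.1 µm/s |
| catastrophe frequency f_c | 0.132 s⁻¹ |
| rescue frequency f_r | 0.05 s⁻¹ |

are chosen so the unstabilized bounded-growth mean length
v_g·v_s/(f_c·v_s − f_r·v_g) equals **0.64 µm** exactly. Shrinkage below one
tubulin subunit (8/13 nm) renucleates the MT at the floor in the growing
state. We deliberately use a one-subunit floor rather than a mesoscopic one:
a large reflecting floor shifts the stationary mean length above the closed
form, breaking the only quantitative calibration anchor the model has.

A growing tip under axial compressive load F polymerizes at the
multi-filament Brownian-ratchet speed

v(F) = v_g (α e^(−β) − 1)/(α − 1),  α = e^(F_s σ/kT), β = F σ/kT,

with N = 13 protofilaments, per-event increment σ = 8/13 nm, and stall scale
F_s (5 pN). The normalization constant v₊ = v_g α/(α−1) is fixed by the
requirement v(0) = v_g; the law stalls exactly at F = F_s. Loaded tips also
catastrophe more often: f_c is multiplied by v_g/v(F) (capped at 20×), the
standard stalled-tip catastrophe coupling. Without it, MTs pinned against
the envelope persist indefinitely and jam the nucleus.

### Envelope wall force

A tip protruding a distance L past the envelope deforms the membrane and is
pushed radially inward. The published force law for membrane-tube extension
comes in two regimes, which we blend into a single expression with the
correct boundary behaviour:

- linear (point-load response of a tense membrane):
  F_lin(L) = F_w L / (2 R_tube (ln(2√2 R_tube/r_mt) − γ)), γ = 0.5772…;
- membrane-tube (non-monotonic approach to the asymptotic force):
  F_nm(L) = F_w (1 + a e^(−cL/b) cos(cL/b)), a = 0.5416, c = 4.038,
  b = √2 R_tube.

The non-monotonic term carries the boundary factor 1 − e^(−L/λ) (λ = 1 µm, a
config key; the decay scale of this factor is not fixed by the sources we
reconstruct from). The linear term grows without bound, so a literal sum of
the two regimes has no asymptote; it therefore carries a complementary
short-range weight e^(−L/b). The combination satisfies F(0) = 0 exactly,
F → F_w, continuity everywhere, and monotone approach beyond the decay of
the oscillatory term. The force acts only on plus tips, always radially
inward; its axial component enters the ratchet law.

### Crosslinkers

Crosslinkers have zero, one or two heads bound. Kinetics are built to be
consistent with the filament-pair partition function so that, on frozen
filaments, the equilibrium occupancy and attachment-position density follow
the Boltzmann distribution of the spring energy E = ½k(|d| − r₀)²:

- free → one-bound: rate k₁ × (MT arc length within the capture radius of
  the crosslinker), landing uniform on that arc;
- one-bound → two-bound: rate k₂ × ∫ e^(−E(y)/kT) dy over each *antiparallel*
  partner (midpoint rule, 0.01 µm bins, window bounded by a 20 kT energy
  cutoff), landing drawn from the Boltzmann density;
- unbinding: constant per-head rates, optionally Bell-accelerated
  (e^(F x_c/kT)); detailed balance then gives the two-bound density
  ∝ e^(−E/kT).

Bound heads diffuse along the lattice; doubly bound heads feel the axial
spring force and are integrated with a locally linearized
Ornstein–Uhlenbeck update that is unconditionally stable for stiff springs.
Heads that step past a lattice end are clamped there by default
(`end_release = FALSE`); crosslinkers stranded by a shrinking plus end
always fall off. Crosslinkers never interact with each other.

An MT whose plus end has a crosslink head within the stabilization length
s = 0.1 µm is *stabilized*: f_c/s_fc, f_r·s_fr, v_g·s_vg, v_s/s_vs. The
scaling is binary (multiple crosslinks do not stack) and only the plus end
counts. Reference factors: s_vg = 1.5, s_vs = 8, s_fc = 8, s_fr = 15 — the
regime where rescue is stabilized at least 10-fold and shrinkage slowed at
least 5-fold. After scaling, the reference set is in the unbounded-growth
regime (f_c v_s < f_r v_g): engaged MTs elongate rather than hover at
0.64 µm.

### Bipolarity classification

The interpolar fraction (IF) is the fraction of MTs engaged in at least one
crosslink with an MT from the opposite pole (count-based definition; a
length-weighted variant is recorded alongside). A run is a successful
bipolar spindle if the IF rises above 0.2 and stays above it until the end
of the run for at least 2 min, tolerating dips below threshold of at most
12 s each; dips do not reset the 2-min clock. The formation start time is
the first crossing of the qualifying epoch. Late-time SPB separation is the
mean pole–pole distance over the last 30 s.

## Reference parameter table (non-printed values)

Values not fixed by the problem statement were set once at fission-yeast
scale and, where unavoidable, calibrated so the model reproduces the
headline phenomenology (assembly with stabilization, loss without). They
are all config keys.

| key | value | note |
|---|---|---|
| envelope_diameter | 2.75 µm | fission-yeast nucleus |
| spb_diameter | 0.18 µm | |
| spb_diffusion_coefficient | 1.5×10⁻³ µm²/s | MBC-scale pole mobility |
| mt_diameter | 25 nm | |
| tether_spring_constant | 100 pN/µm | |
| nucleation_stiffness / cone | 0.1 pN µm / 0.8 | see Design choices |
| viscosity | 1 pN s/µm² | effective nucleoplasm |
| crosslinker number | 160 | |
| spring_constant / rest_length | 207 pN/µm / 53 nm | Ase1 scale |
| one_head_on_rate / off | 800 µm⁻¹s⁻¹ / 1 s⁻¹ | |
| two_head_on_rate_scale / off | 3000 µm⁻¹s⁻¹ / 0.08 s⁻¹ | |
| bound / free diffusion | 0.1 / 1.0 µm²/s | lattice / nucleoplasm |
| bell_parameter | 1 nm | force-dependent unbinding |
| antiparallel_threshold | −0.5 | see Design choices |
| stall_scale F_s | 5 pN | |
| tube_radius R_tube | 50 nm | |
| asymptotic_force F_w | 7.6 pN | mid-range of the 0–14.8 pN sweep |
| kT | 4.11 pN nm | ≈25 °C convention |

## Numerics

- **Timestep.** The nominal timestep is 5×10⁻⁵ s. Whole-spindle simulations
  in the test suite and the examples use a documented coarse profile,
  dt = 2×10⁻³ s: a convergence check on the bipolarity outcome showed the
  classifier statistics is preserved at this step, while a 5×10⁻³ s step is
  not acceptable (the engagement state degrades). Stiff per-step elements —
  crosslink head motion — use the locally exact OU update, and rod/SPB
  deterministic displacements are trust-region capped (5 nm, 0.05 rad per
  step) so steric and spring stresses can never blow up; cap counts are
  reported per run.
- **Sterics.** WCA repulsion (σ = MT diameter, cutoff 2^(1/6)σ, ε = 1 kT,
  force capped below 0.6σ) between rod closest points; exactly coincident
  rods are separated deterministically along a fixed axis. Pair distances
  are recomputed lazily using an accumulated-displacement bound, which is
  exact: a pair is never skipped when it could be within the cutoff.
- **Kinetic sub-stepping.** Free-crosslinker diffusion/binding every 10
  steps, pair-binding sweeps every 5 steps (config keys); at most one
  transition per crosslinker per sweep, with a runtime warning when
  rate × effective step exceeds 0.1.
- **Quadrature.** The pair partition integral uses 0.01 µm midpoint bins
  (config key); halving the bin changes the weights by well under 1%.
- **Reproducibility.** A dedicated counter-free xoshiro256** stream with a
  ziggurat normal sampler; every run is bitwise reproducible from
  (parameters, seed); scan replicate seeds are drawn up-front from the
  master seed so results are independent of scheduling order.

## What the synthetic fixtures emulate

The test suite never consumes external data; `make_fixture()` builds the
states the oracles need: frozen antiparallel/parallel MT pairs for the
statistical-mechanics checks (filaments immobile, only crosslinker kinetics
run), single-MT ensembles for mean-length and waiting-time statistics,
engineered IF time series for the classifier, and randomized crosslinked
states for force/torque closure. These fixtures validate *mechanisms* —
equilibrium distributions, conservation laws, boundary rules. They cannot
validate what real spindles do: there is no imaging noise, no chromatin, no
kinetochores, no NE shape change, and the "experiment" the whole-spindle
runs are compared against is a published description, not raw data.

## Design choices made where the problem was open

1. **Nucleation hinge and cone.** With freely pivoting minus ends, the
   model possesses a spurious attractor: MTs from the two adjacent poles
   flip outward and crosslink tail-to-tail around the pole pair, gluing the
   poles and registering IF > 0.2 *independently of stabilization*. A soft
   orientation hinge (0.1 pN µm) with an outward cone (spread 0.8) biases
   fans inward and weakens this state.
2. **Alignment threshold −0.5.** A strict hemisphere rule (dot < 0) admits
   near-perpendicular X-crossings; their crosslinks arrest pole separation
   without contributing to a bundle. The crosslinker's two MT-binding
   interfaces require rough antiparallel alignment, so the reference
   restricts crosslinking to pairs within 120° of antiparallel. The
   `is_antiparallel()` API keeps the hemisphere rule as its default
   threshold.
3. **Bell unbinding (x_c = 1 nm).** With force-independent unbinding,
   crosslinks bound in transiently strained geometries accumulate static
   network stress that pulls the poles together; force-dependent unbinding
   releases it. Force-dependent binding kinetics are part of the model
   class this package implements.
4. **Polymerization pushing on the pole.** MTs sterically repel the
   *opposite* SPB disk, and the contact loads the plus tip through the
   ratchet law. In a motor-free model this is the only mechanism that
   converts polymerization into pole–pole force at short range.
5. **Boundary-only ratchet load.** The force entering the growth law is the
   envelope/pole load on the tip, not crosslinker tension (config-fixed
   choice).
6. **One-bound heads are tracers** (no force on their MT), and the capture
   radius for first-head binding equals the crosslinker rest length.

## Known limitations

- The frozen reference set robustly produces *persistent interpolar
  engagement* between the two poles, but pole separation remains short
  (typically ≤ 1 µm rather than spanning the nucleus); the model as
  implemented under-produces the outward force needed for full bipolar
  elongation. Consequently, trend claims that are expressed through
  late-time pole separation (wall-force and crosslinker-number dependence
  of spindle length) are only partially reproduced, and the
  stabilization-knockout contrast is regime-dependent: across randomly
  sampled parameter space the knockout abolishes assembly essentially
  completely, but at the finely balanced reference point itself roughly a
  third of knockout runs still cross the IF criterion through crosslinking
  alone, and the stabilized reference succeeds in roughly two thirds of
  runs rather than nearly always. The honest state of each check is in the
  test suite.
- Problem sizes in the suite are desk-scale by design: the reference
  behaviour check uses 10 seeds per condition, random-sampling scans use
  tens of parameter sets with a few replicates each, and sweeps use 2–3
  values per parameter with 3–4 replicates; the full-scale study (hundreds
  of parameter sets × 12 replicates, 24-point sweeps × 32 replicates) is a
  cluster-scale reproduction run through the same `scan`/`sweep` surface.
- Rigid rods: no MT flexibility, no hydrodynamic coupling, no kinetochores
  or chromatin mechanics, no NE deformation beyond the local force law —
  all deliberate scope boundaries of the model class.
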