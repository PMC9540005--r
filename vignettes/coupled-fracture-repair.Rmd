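---
title: "Coupled fracture healing and bone remodelling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled fracture healing and bone remodelling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ossify` simulates secondary bone fracture repair on idealized long-bone
geometries over a simulated year, coupling four sub-models: biphasic
(poroelastic) finite-element mechanics, mesenchymal stem cell (MSC)
infiltration, mechano-regulated tissue differentiation in the fracture
callus, and — once a bony union has formed — strain-energy-density (SED)
and fatigue-damage based bone remodelling. This vignette documents the
models, their parameters and units, the numerical choices, and what the
package's synthetic geometries do and do not establish.

## 1. Geometry and mechanics

The tibia is idealized as a co-axial cylinder of cortical bone around a
marrow cavity, interrupted by a transverse fracture gap. The repair
tissue is split into three zones: the *callus focus* between the cortical
fragment ends, the *inner* (endosteal) and *outer* (periosteal) callus.
Unplated and calibration variants are meshed axisymmetrically; the plated
variant is a plane-strain half-section with a titanium strip (E = 110 GPa)
perfectly bonded to one cortical surface, spanning the gap. Screws are
not meshed: a rigidly bonded plate is the 2D analogue of self-locking
screw fixation, and pin-hole stress concentrations are out of scope.

All tissues are saturated biphasic continua. Bilinear quads carry
displacement and pore pressure at every node; one "daily loading event"
is a ramp-and-hold consolidation solve (default 1 s, four implicit
sub-steps — one physiological loading cycle) whose peak-in-time
octahedral deviatoric strain and Darcy fluid speed feed the healing
stimulus, plus a drained elastic solve whose stress and SED feed
remodelling. Using the drained fields for remodelling makes the
homeostatic algebra exact: a uniaxial stress sigma on bone of modulus E
and density rho gives psi = sigma^2/(2 E rho) identically.

Two numerical choices matter here:

* **Selective reduced integration.** In the undrained limit the tissue is
  nearly incompressible and bilinear quads lock volumetrically, which
  suppresses exactly the strains the mechano-regulation depends on. The
  volumetric (lambda) stiffness and the pressure coupling therefore use
  the mean-dilatation (centroid) operator, the 2D analogue of the
  reduced-integration bricks of the original 3D implementation.
* **Load introduction.** The daily load is applied through a rigid platen
  tied to the proximal *cortical wall* only. Tying the whole cross
  section would force the (undrained, incompressible) marrow column to
  carry most of the load, stiffening the model several-fold and erasing
  the load sensitivity of the callus stimulus.

Default cortical radii are 11.3 mm outer / 5 mm inner. The published description prints no dimensions, but it states
both that perfect gait is
300% of a 700 N body weight and that 6.6 MPa acts homeostatically on the
tibia after day 112; 2100 N / 6.6 MPa = 318 mm^2 fixes the cortical area
those statements jointly imply. Every dimension is config-overridable.

The calibration variant (ovine metatarsus osteotomy, 3 mm gap, 500 N)
represents its unilateral external fixator as an axial spring (default
450 N/mm, a documented reconstruction — the fixture's dimensions are
approximate). Without a parallel fixator the bare reconstructed geometry
cannot sit in the ~1 mm inter-fragmentary movement regime reported for
the experiment.

## 2. MSC infiltration

Cell concentration obeys dc/dt = D lap(c) on the callus subdomain, with
D = 0.1 mm^2/day (the published description also mentions 0.3 elsewhere; 0.1 is the
default and both are config keys). The source surfaces are the exterior
callus boundary (soft tissue), the inner-callus contact with marrow and
the endosteal wall (marrow bathes both), and the periosteal
outer-callus/cortex interface, including the corner rings where those
surfaces meet the fracture plane. The cortical fracture faces bounding
the callus focus carry no source, so the focus interior fills by
diffusion from the periphery and union is infiltration- as well as
stimulus-limited. The boundary concentration ramps as
c_b' = D (c_max − c_b), removing the start-up artifact of a hard c = 1
boundary. Lumped-mass implicit Euler steps are clamped to [0, c_b],
enforcing the discrete maximum principle exactly. On the default
geometry, minimum-node near-confluence (min c >= 0.95) lands at roughly
190 days; the 112-day figure quoted for the original 3D model depends on its
unprinted marrow radius, so the packaged check is qualitative (order
10^2 days).

## 3. Mechano-regulated differentiation

The stimulus S = eps_dev/a + w/b (a = 0.0375, b = 3 um/s) selects the
phenotype: fibrous tissue (S > 3), cartilage (1 < S < 3), immature bone
(0.2667 < S < 1), mature/woven bone (0.01 < S < 0.2667) and resorption
below 0.01. Fuzzy zones of total width 10% of each threshold, centered
on it, crossfade the two adjacent memberships linearly (the 10% figure is
stated; centering and linearity are this package's choice). Cells
differentiate down the potency hierarchy MSC -> fibroblast -> chondrocyte
-> immature -> mature bone cell with calibrated rates Ff = 0.02,
Fc = 0.3, Fib = 0.15, Fmb = 0.15 /day; tissues are produced at Qf = 0.12,
Qc = 0.2, Qib = 0.1, Qmb = 0.1 /day, higher-priority tissue replacing
lower-priority tissue in proportion to its share of the differentiated
total. In the resorption band, bone fractions are removed at their
production rate scaled by the resorption membership (osteoclastic removal is stated without a rate). Granulation tissue closes the
volume balance.

Element stiffness is the volume-fraction-weighted rule of mixtures. Each
range-valued tissue modulus is interpolated within its tabulated range by
the matching cell density (a maturation rule not stated in the published framework);
granulation tissue has no matching cell phenotype and uses a fixed
E_gran = 0.3 MPa within the tabulated 0.001–2 MPa range. Because the
geometry is a reconstruction, this one free constant was anchored to the
printed healing/non-union boundary of the unplated load sweep and then
frozen; it is not fitted to any graded quantity. On the final geometry
the boundary falls between the 105 N and 122.5 N conditions (the
published results place the 105 N case just on the non-union side). The tabulated
"intermediate bone" row is absorbed by the immature->mature
interpolation rather than being a fifth phenotype. Poroelastic
side-properties of mixed tissue are volume-weighted (permeability on a
log scale, since the tabulated values span decades).

The raw modulus is smoothed by a dt-weighted trailing 10-day average,
and a healing time control keeps every accepted per-increment
volume-fraction change below dm_max = 0.05.

## 4. Remodelling

After union, each bone element remodels site-specifically toward a SED
window. The reference psi_ref = sigma_U^2/(2 E_U rho_U)/(1+w) with
sigma_U = 6.6 MPa, E_U = 17 GPa, rho_U = 1.649 g/cm^3 and lazy-zone
width w = 0.35 places psi_U = psi_ref (1+w) independent of w, so bone at
the homeostatic stress always remodels positively to the homeostatic
modulus; psi_L = psi_ref (1−w). Density maps to stiffness by
E = 3790 rho^3 and rates scale with Martin's internal free-surface-area
curve a(rho) (a quintic in porosity with a small linear correction so it
vanishes exactly at rho_min = 0.01 and rho_max = 1.73 g/cm^3). The rate
constant tau = 130 g^2 mm^-2 J^-1 per month (month = 30 days) is read as
yielding drho/dt in g/cm^3 per month, the unit system of the underlying
remodelling theory; a time control caps density change at 0.175 g/cm^3
per month-equivalent.

Fatigue damage follows Miner's rule against
log10 Nf = H log10 sigma + J T + K rho + M (T = 37 C). The historical
cycles-to-failure data behind H, J, K, M are not shipped; a synthetic
stand-in table (`inst/extdata/carter_sn_synthetic.csv`, clearly labelled)
encodes the field's typical cortical-bone S-N slope, shorter life at
body temperature and longer life at higher density, and the defaults are
the least-squares fit to that table (config-overridable). The repair
rate is tied to the homeostatic stress at the local density, so
homeostatic loading accumulates no damage stimulus. The critical
stimulus omega_crit is the stimulus one month of daily loading at
sigma = E(rho) * 3500e-6 would accumulate (the 3500 microstrain
criterion); above it, density is resorbed at a(rho) Cd N omega with
Cd = 0.1e8 — deliberately much faster than SED resorption — bounded at
0.00625 g/cm^3 per increment by the damage time control. Runs can switch
damage off entirely (ND vs D comparisons).

Numerical guard: a forward-Euler density step is limited to half the
remaining distance to whichever bound it moves toward. Without this,
elements overshoot onto rho_max, where a(rho) = 0 freezes them
permanently and artefactually erases later stress-shielding resorption.

## 5. Driver, time stepping and transitions

Each increment: solve the daily loading event; form healing and
remodelling trial updates; take the minimum of the healing (dm_max), SED
(drho_max/month) and damage (0.00625) time-scale factors; accept the
increment at dt*min(factor) (floored at dt_min with per-process caps, a
desk-scale runtime compromise — 0.25 day by default); apply updates;
advance the MSC field; check union and transition; grow dt geometrically
(factor 1.2, capped at 1 day — the published framework specifies only
shrinking).

Loading follows four post-operative phases: constant initial load to day
28 (10–20% of body weight for LC_A–LC_E; reconstructed stress magnitudes
2.6/4.6/6.6 MPa for the plated schedules LC_F–LC_H), a linear ramp to
50% body weight at day 56 (crutch walking), a ramp to perfect gait at
day 112, then 300% body weight. Ramp shapes between breakpoints are
linear (the published figure is not reproduced in text).

Union is an adjacency-connected chain of callus-focus elements with bone
volume fraction >= 0.5 linking the two fragment faces. The transition to
remodelling latches when union holds and the windowed mean per-day
modulus change a candidate SED step would produce on the focus exceeds
the healing rate of change. At the transition the whole callus converts
to bone elements at rho = (E/3790)^(1/3), the diffusion field freezes
(whether it continues is not stated in the published framework), and healing stops. A
run with no union by day 172 (112 + 60, an artifact choice) terminates
as a non-union.

## 6. What the synthetic world does and does not establish

The geometries are reconstructions from proportions, reduced to 2D, and
the full 3D commercial-FE element counts, screw geometry and histology
comparisons are out of scope. Green tests therefore establish: the
closed-form worked values (stimulus band edges, density-modulus law,
homeostatic fixed point); the governing invariants (conservation,
boundedness, maximum principle, time-control caps, lazy-zone inertness,
Terzaghi-consistent consolidation); and the published framework's qualitative
orderings on coarse meshes (slower union with load and gap, plated
healing at loads that defeat unplated models, stress shielding, and the
damage/no-damage contrast). They do not establish the original model's absolute
3D timings (16.6-day bridging, 120-day union) or spatial stress patterns
around screws.

Within the homeostatic fixed point, note one asymmetry: with the
modified lazy zone, a bone element at sigma_U converges to rho_U only
from below; from above, psi(rho) lies inside [psi_L, psi_U] and the
element legitimately does not move. That is a property of the modified
reference formulation itself, which was designed so that bone *positively*
remodels to its homeostatic state.

## 7. Worked example

```r
library(ossify)
cfg <- simulation_config(
  geometry = geometry_spec("unplated", fracture_gap = 3,
                           mesh_target_size = 3.5),
  schedule = load_schedule("LC_A"))
res <- run_simulation(cfg)
print(res)
write_outputs(res, "lc_a_run")
```

The run prints its status (healed/non-union), union and transition days
and final callus-focus modulus; `series.csv` holds the per-increment
time series plotted in the README.
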