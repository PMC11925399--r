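---
title: "Models and methods: active nematic shells with strain-gated morphogen feedback"
author: "nematoshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nematoshell)
```

## The scientific problem

Regenerating epithelial spheroids of *Hydra* are bilayered shells around
an incompressible fluid lumen, carrying supracellular actomyosin fibers
(myonemes) whose mod-pi orientation field is a unit nematic.  On a closed
genus-0 surface the fiber field must carry topological defects of total
charge +2; a +1 aster marks the future head organizer, a pair of +1/2
defects the future foot.  Transient global fiber contractions focus
mechanical strain at these defect sites, and the focused strain is
hypothesized to gate local morphogen production, which in turn aligns
fibers along morphogen gradients and stabilizes the +1 aster — a closed
mechanochemical feedback loop.  `nematoshell` implements this model and
the quantitative analyses needed to study it, entirely on synthetic
inputs.

## Mechanics: a vertex model on a closed curved surface

Cells are polygons sharing vertices; the shell is a closed 2-manifold
(`validate_shell()` enforces closure, Euler characteristic 2, outward
winding, vertex degree >= 3).  Per cell, the center is the vertex mean,
the area the sum of fan-triangle areas, and the normal the normalized
area-weighted mean of fan-triangle normals (equal to the polygon vector
area because the center is the vertex mean).  The energy is

    E = sum_c K/2 (A_c - A0)^2  +  sum_b Lambda L_b
      + sum_c Gamma/2 P_c^2     +  sum_b beta/2 theta_b^2

with `theta_b` the angle between the unit normals of the two cells
sharing bond `b`.  The quadratic (small-angle) bending form was chosen
over `1 - cos(theta)`; at the dihedral angles arising here (< 0.4 rad on
relaxed spheroids) the two differ by under 2%.  Vertices follow
overdamped dynamics `gamma dR/dt = -dE/dR + F_active - mu dV/dR`; all
gradients are exact analytic expressions (finite-difference checked to
1e-5 in the test suite).

**Lumen incompressibility.** The Lagrange multiplier is computed by
projection, `mu = (F.G)/(G.G)` with `G = dV/dR`, which zeroes the
instantaneous volume rate; the residual O(dt^2) drift is removed after
every Euler substep by an exact radial rescaling about the centroid.
The relative volume drift over entire runs stays below 1e-6 (typically
1e-12).

**Active stress.** Each cell carries a unit nematic `q_c` (Frobenius
norm 1, stored as an angle in the cell's orthonormal tangent frame).
Global contractions enter through a virtual-work active energy
`E_act = zeta/2 sum_c sum_v r_v . Q_c r_v` (with `r_v` the vertex offsets
from the cell center and `Q_c` the 3D-embedded tensor), whose exact
gradient at fixed nematic is the active force.  With `zeta > 0` a cell
contracts along its fiber axis and extends perpendicular to it; the
stress is traceless, so single-cell areas change only at second order in
`zeta`.  Any discretization with these two properties satisfies the
model contract; this one was chosen because its gradient is exact and
cheap.

**Time stepping.** Explicit Euler with the empirical stability bound
`dt <= 0.1 gamma / (K A0 + Gamma + beta/A0)`; during strong pulses the
bound tightens by `|zeta|` and the integrator sub-steps automatically.
A Richardson-style step-halving test confirms convergence.

**T1 transitions.** A bond shorter than `L_th` collapses to a vertex;
each fourfold vertex is tested against its two threefold resolutions by
placing a trial bond of length `2 L_th` and comparing energies; the
larger energy decrease wins, ties (and non-improving resolutions) stay
merged.  Higher-fold vertices are supported but left merged.  Cells
persist through T1s, so all per-cell fields carry over unchanged.

## Reference parameters and the negative Poisson ratio

The reference set (model units: lengths in sqrt(A0), energies in K A0^2,
times in gamma/(K A0)) is

    K = 1, A0 = 1, Lambda = -0.1, Gamma = 0.25, beta = 2,
    gamma = 1, L_th = 0.05.

It was fixed, once, by three requirements: (i) the flat periodic
network must have a *negative* 2D Poisson ratio, so the shell sustains
the large isotropic strains observed at defect cores without cell
rearrangements; (ii) a relaxed spheroid must be smooth (no buckling);
(iii) a single calibrated contraction pulse must reach a core log
strain of ln 2 without any bond collapsing.  `measure_poisson_ratio()`
evaluates (i) on the periodic honeycomb's single-cell unit: the rest
state is found by energy minimization, a small strain `eps_xx` is
imposed, the remaining degrees of freedom relax, and
`nu = -eps_yy/eps_xx`.  Negative `nu` (about -0.12 here, stable under
strain halving) arises in the perimeter-dominated regime where cells sit
below their preferred area: a uniaxial stretch lets them regain area by
expanding in both directions.  Softer bending moduli (beta below ~1)
wrinkle under calibrated pulses and collapse bonds; a positive bond
tension actively shortens bonds; both were rejected during the
parameter search, which is why `Lambda < 0` (adhesion) and `beta = 2`.

## Nematic field

Each cell's fiber angle lives in a tangent frame that is transported by
the minimal rotation between successive cell normals, so the nematic is
convected and co-rotated with the tissue.  Neighbor alignment uses the
average neighbor tensor: each neighbor tensor is transported into the
cell's tangent plane and arithmetically averaged (not renormalized).
Gradient coupling adds `alpha * T(grad phi)` with
`T = g g^T - |g|^2/2 I`, the traceless-symmetric outer product — blind
to the gradient's polarity, as a nematic must be.  The unit-norm
constraint (the Lagrange multiplier of the continuous equations) is
realized as project-then-renormalize, equivalent to first order in the
step; because the renormalized angle is stored, `|q| = 1` holds exactly
at all times.  Whether the neighbor term is written `<q>/tau_q` or
`(<q> - q)/tau_q` is immaterial under this scheme — the difference is
parallel to `q` and removed by the projection — which is why the scheme
was chosen.

**Defect detection with exact charge accounting.** For every vertex the
ordered ring of incident cells is traversed; each step contributes the
transported angle difference wrapped to (-pi/2, pi/2], and the loop's
holonomy (the net frame rotation of the composed minimal-rotation
transports, equal to the spherical area swept by the cell normals) is
added.  The resulting vertex winding is an exact half-integer up to
float noise, and because every directed cell-pair contribution cancels
against its reverse at the bond's other endpoint while the holonomies
tile the Gauss map, the vertex charges sum to exactly +2 on any closed
genus-0 shell — for arbitrary fields, including i.i.d. random angles.
Charged vertices within 1.25 cell diameters are merged (a discrete +1
aster spreads its winding over two adjacent vertices).

## Morphogen field

Molecule counts `N_c` per cell; concentration `phi_c = N_c / A_c`.
Fluxes are `D L_cc' (phi_c' - phi_c)` per shared bond (exactly
conservative and variance-dissipating), degradation is `-r_minus N_c`,
and production is gated by the cell area strain
`eps_c = (A_c - A_c0)/A_c0` measured against the *t = 0* areas, through
`r_plus * f(eps)` with `f = (1 + tanh(w (eps - eps_th)/eps_th))/2` and
`w = 10`.  The bare `tanh/2` form is negative below threshold and
saturates at 1/2, contradicting the stated saturation at `r_plus`; the
shifted form satisfies both limits and is the default
(`sigmoid_convention = "raw"` keeps the bare form for sensitivity
checks).  `r_plus = 1` without loss of generality.  Gradients are
estimated per cell by tangent-plane least squares over the neighbor
center offsets (exact on linear fields; collinear neighborhoods fall
back to the minimum-norm solution).  Explicit Euler with the stability
bound `dt <= 0.2 min(A)/(D max(P))`, checked before every step.
Production reads the instantaneous strain; the pulse width and period
set the effective duty cycle.

## Scenarios and calibration

`event_scenario()` builds a relaxed spheroid with a frozen nematic
pattern; `run_single_event()` drives one Gaussian pulse
(`zeta(t) = zeta_M exp(-(t - t_k)^2 / (2 dT^2))`) with nematic and
morphogen frozen — the paper-level timescale separation (events take
minutes, fiber reorganization hours) implemented by scheduling, not by
separate physics.  `calibrate_zeta()` bisects `zeta_M` until the mean
core (graph distance <= 1 from the +1 focus) log area strain at the
event peak matches ln 2 within 0.05; numerical blow-up marks the
instability onset and caps the bracket.  On the 300-cell reference
scenario the calibrated amplitude is about 1.05 and no T1 fires.  At
200 cells the core response plateaus near 0.6 before a snap-through,
which is why the reference event scenario uses 300 cells (inside the
stated 200-300 range).

`run_regeneration()` starts from the `fragment` pattern (an ordered
axial band spanning ~2/3 of the circumference plus a disordered region
of net charge +2: two caps and a two-cell-row bridge, together 1/3 of
the area) with zero morphogen, and interleaves mechanics (every step),
morphogen and nematic updates (every 5 mechanics steps, sub-stepped to
their own stability bounds) over a pulse train.  Outcomes are
classified by `classify_outcome()`: morphogen peaks are local maxima of
the 1-ring-smoothed concentration at >= 2x the global mean; an
organizer is a +1 defect (or a +1/2 pair within 2 cells) with a peak
within graph distance 2; categories are `single_organizer`,
`two_organizers`, `four_half` (exactly four +1/2, no organizer), and
`other`.

**Feedback defaults.** `tau_q = 2`, `alpha = 5`, `D = 0.2`,
`r_minus = 0.1`, `eps_th = 0.45`, pulse period 30, width 3, 20 pulses,
200 cells.  These were chosen once so that the qualitative phase
structure of the model is realized: production localizes to the strain
foci (calibrated core strains reach area strains ~0.6-1.0, ordered-band
strains are negative, so `eps_th = 0.45` gates cleanly); the screening
length `sqrt(D/r_minus)` is about 1.3 cell diameters, keeping peaks
discrete; and `alpha |grad phi|^2` at a peak competes with the neighbor
alignment rate `1/tau_q`, which is what stabilizes asters.  With these
defaults different seeds yield one organizer, two organizers, or
occasionally four +1/2 — the same outcome variability the model is
meant to exhibit — while `r_plus = 0`, `alpha = 0`, or
`eps_th -> infinity` reproducibly give four +1/2 defects and no +1.
The pulse period (30 instead of the leisurely 100 one might picture for
~1/h contractions against hour-scale fiber reorganization) is a
deliberate compression to keep full runs at desk scale; what matters
for the phase structure is the ratio of alignment, degradation and
duty-cycle timescales, which is preserved.

## Synthetic data: what it does and does not emulate

The mesh generator (seeded random directions, spherical Voronoi via the
convex-hull Delaunay duality, Lloyd relaxation) produces closed
spheroids with ~10% area dispersion and 5-7-gon disorder — a reasonable
stand-in for epithelial packing, but with no pre-existing cell-shape
anisotropy, no bilayer, and no lumen pressure history.  Nematic
initializations reproduce the observed *patterns* (fragment,
late-defect, four-half) via conformal stereographic pullback of planar
multi-defect fields, so charges are exact by construction; the fine
structure of real fiber disorder is not modeled.  Fiber-intensity
rasters are periodic textures (stripes, aster spokes) or
line-segment renderings (half-integer motifs) with known per-pixel
orientation; they emulate fibrous contrast, not microscope optics.  A
green test on these inputs establishes the correctness of the
algorithms and the internal consistency of the model — not biological
fidelity.

## Orientation imaging

Structure-tensor orientation (gradients after 1 px pre-smoothing,
box-averaged over ~6 um), doubled-angle Gaussian smoothing (sigma 4 um),
coherence (windowed mean of `|cos(theta - theta_ij)|` over ~15 um,
referenced to the raw center orientation — computed before smoothing;
an i.i.d. field gives 2/pi and the 0.88 threshold separates ordered
from disordered regions), and the order parameter
`S = |<e^{2 i theta}>|` over ~25 um, which is 1 for parallel alignment
and minimal at defect cores.  2D defects are plaquette windings of the
doubled angle, clustered within 12 px (a smoothed +1 aster splits into
two half-integer winding cores about 2-3 sigma apart) and excluding an
8 px border.  Under noise at SNR 3 the *summed* charge near a
ground-truth defect is recovered in >= 95% of seeds; sub-cluster
localization inside the smoothing scale is not claimed.

## Numerical choices and degenerate inputs

Angle wrapping uses round-to-nearest (ties are measure-zero);
`find_peak_frame` resolves ties to the earliest frame; the twofold
event boundary is assigned to "small" (strictly greater than twofold is
"large"); a zero-gradient pixel has undefined orientation and is `NA`;
a degenerate (zero-area) cell or triangle raises or is excluded with a
flag; antipodal normals make the minimal rotation undefined and raise.
The shape tensor uses the left polar (Hencky) log-stretch of the
reference-to-actual triangle map, so the reference triangle's
orientation is immaterial; reported magnitudes are under this
convention and are not claimed to match any particular color scale.

## Known limitations

No rupture or fracture (holes are not simulated), no endodermal layer,
no osmotic inflation cycles, no cell division or death, no remeshing,
no open surfaces, deterministic mean-field morphogen dynamics only, and
no claim that the reduced pulse protocol reproduces printed parameter
values — the reference set is a stated world that satisfies the model's
qualitative structure and the package's quantitative acceptance
criteria.
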