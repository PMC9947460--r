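---
title: "An axisymmetric finite-element model of orbital fat swelling and the eye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An axisymmetric finite-element model of orbital fat swelling and the eye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Spaceflight-Associated Neuro-ocular Syndrome (SANS) groups several ocular
findings in people exposed to microgravity: optic disc edema, choroidal
folds, flattening of the posterior globe, axial-length shortening, and a
hyperopic shift. `orbitfem` implements a biomechanical account of these
signs: the cephalad fluid shift of microgravity raises the water content of
the retrobulbar orbital fat; the swelling fat, confined by the rigid orbital
bone, pushes the globe forward and presses on its posterior surface. The
package computes the resulting equilibrium of the eye-orbit system by an
axisymmetric, geometrically nonlinear finite-element model and reports the
clinically measurable consequences: proptosis, axial-length change,
peripapillary arc-length change (a proxy for choroidal fold risk), and the
change of the posterior radius of curvature (ROC).

# Model at a glance

* **Domains** (meridian half-plane, axis of symmetry = optical axis):
  ocular coats (one shell for cornea+sclera), vitreous, orbital fat, optic
  axon bundle, dural sheath. The orbital bone is rigid and enters only as a
  fixed boundary.
* **Materials**: incompressible, isotropic neo-Hookean solids with
  multiplicative hygroscopic swelling, `F = F_e (1 + eps_H) I`,
  `J_H = (1 + eps_H)^3`. Moduli: coats 1.5 MPa, vitreous 6.5 Pa, fat 700 Pa.
  The nerve tissues carry no published values here; the sheath uses the
  scleral modulus (it is continuous with the sclera) and the axon bundle
  30 kPa, a literature-order value for neural tissue. Shear moduli are
  `E/3` (incompressible limit).
* **Loads**: IOP generated by vitreous swelling from an inversely identified
  zero-stress configuration; ICP as a follower traction on the roof of the
  sub-arachnoid space; extraocular-muscle (EOM) tension as a ring load obeying
  the passive rectus stretching law
  `F_EOM = 4M(-0.29 w + 4.79 e^{w/4.57} - 3.01)` mN; an optic-nerve spring
  engaged only beyond 6 mm of slack (never reached); frictionless sliding
  contact between the eye/nerve and the fat.
* **Staging**: A — coordinate search for the zero-stress eye (radii +
  vitreous swelling); B — reload to the residually stressed, pressurised
  eye; C — seat in the orbit and ramp the muscle multiplier to its final
  value (terrestrial state); D — increment fat swelling (and, for the
  sensitivity grid, ICP). All biometrics are D relative to C.

```r
library(orbitfem)
pr <- run_protocol("baseline")   # the full study, ~3 min on one CPU
print(pr$biometrics)
```

# Geometry reconstruction

The study prints twelve scalars; the remaining shape had to be
reconstructed, and three choices deserve record:

**Shell thickness.** The inner surface is the ellipse `(R_Eq, R_P)`, the
outer the ellipse `(R_Eq + h_Eq, R_P + h_P)`. The thickness then blends
smoothly and monotonically from 1.0 mm at the poles to 0.5 mm at the
equator without any extra blending rule.

**Globe placement.** The quoted optic-nerve slack formula,
`slack = ON length - orbit length - AL/2`, treats the apex-to-centre
distance as `L_O - AL/2`; the globe centre therefore sits at the orbital
rim plane, with the posterior hemisphere inside the orbit. This placement
is also the only one we found self-consistent: the fat then forms a
retrobulbar cup wetting the posterior hemisphere only (which produces the
reported globe *flattening*; placements that let fat wrap anterior of the
equator squeeze the equator and *elongate* the globe), its escape aperture
is the narrow equator–rim annulus (which produces mm-scale proptosis; the
retrobulbar volume of about 10 mL yields a volumetric bound of about 4.3 mm
at 7% swelling, matching the reported 4.66 mm), and a +10% equatorial
radius still fits the orbit.

**Orbit wall.** Two straight segments from the printed scalars: apex
`(R_Do, 0)` to the widest point at depth `L_OM` behind the rim, then to the
rim `(R_OM, L_O)`. The interior widening factor (`orbit_bulge`, default
1.10) reflects that the bony orbit is widest a short distance behind its
rim; a straight apex-to-rim cone would touch the globe.

**ICP application.** A 270 um outer-scleral annulus (the specification's
default reading) gives an axial resultant of ~3.7 mN at 13.6 cmH2O, three
times the quoted ~1.17 mN. The projected annulus of the sub-arachnoid space
itself, `pi (R_Di^2 - R_A^2)`, reproduces the quoted value to 1%, and ICP
physically resides in that space; the default (`icp_band = "sas_roof"`)
therefore loads the scleral flange face over the sub-arachnoid gap, with the
outer-annulus variant available. With this choice the terrestrial force
balance lands on the reported values (F_EOM 7.25 vs 7.36 mN, F_ICP 1.16 vs
1.17 mN, F_fat 6.1 vs 5.6 mN).

# Numerical formulation

* **Discretisation.** Lagrange triangles on structured, feature-aligned
  grids; conforming where tissues are tied, independent meshes for the fat
  with node-to-surface contact. The eye uses *quartic* elements by default:
  the globe's flattening mode is bending-dominated ovalization of a thin
  pressurised shell, and quadratic triangles lock it membranously (we
  measured several-fold understated posterior compliance at coarse quadratic
  resolution). The fat uses quadratic elements: its response is volumetric
  and contact-driven, and moderate order is far more robust under the
  several-millimetre sliding it undergoes.
* **Incompressibility.** Mixed displacement–pressure (perturbed Lagrangian)
  with element-wise constant pressure, condensed exactly within every Newton
  step. Solid elements constrain the quadrature mean dilatation; fluid-like
  elements (vitreous, fat) constrain the element volume computed *exactly*
  from the boundary integral `V = 2*pi*closed_int (r^2/2) dz` (polynomial in the
  edge parameter, so edge Gauss rules are exact and interior faces cancel).
  The exact form matters: with quadrature-approximated volumes the
  near-inviscid vitreous can "swell" into integration error and never
  pressurise the globe.
* **Contact.** Slave nodes on the fat boundary against the deformed
  quadratic/quartic master edges of the sclera and sheath, with smooth
  closest-point projection (continuous normals), a C1 quadratic activation
  band of 20 um, and a tangent-ray extension behind the nerve foot (the
  nerve continues into the optic canal). Penalty 1e7 Pa/mm; physical contact
  pressures (<= a few kPa) keep penetrations below a micrometre; no
  tangential force is ever transferred.
* **Solver.** Damped Newton on the condensed system: trust-region-style cap
  (0.25 mm) on displacement increments, backtracking only on element
  inversion, restart-from-best on divergence, and load continuation with
  automatic bisection. The residual tolerance is 1e-8 relative with an
  absolute floor of 8 uN, three orders below the millinewton load scale.
* **Zero-stress search.** Cyclic coordinate updates: radius mismatches feed
  back additively (the inflation displacement depends only weakly on the
  zero-stress radii); the vitreous strain is updated by a secant step on the
  achieved IOP; warm-started re-evaluation. Converges in 3–5 evaluations to
  sub-micrometre mismatch and 0.01 mmHg.

# Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| target IOP | 15 mmHg | unpublished in the source; predictions at 10 mmHg differ by <1%, so the choice is immaterial and reported rather than tuned |
| terrestrial ICP | 13.6 cmH2O | mid-normal, as quoted |
| EOM insertion | 60 deg polar angle | anatomic rectus insertion (~6.9 mm behind the limbus); pure axial pull at a point ring |
| muscle multiplier M | 1 (passive); 2.25 (active study) | ramped from 0 in stage C |
| fat swelling | 0 to 0.070 strain | the baseline schedule |
| contact penalty, band | 1e7 Pa/mm, 20 um | penetration < 1 um at physical pressures |
| orbit_bulge | 1.10 | interior wall widening |

# What the generator emulates, and what it does not

The preset/anatomy module is the synthetic-case generator: every study case
is built from the printed parameter set with exactly one perturbation
(±10% anatomy, scleral modulus 0.25–5 MPa, ICP 0–20 cmH2O, muscle
multiplier up to 2.25). It reproduces the geometry, staging and loading of
the source study. It does *not* represent: three-dimensional orbital
anatomy (no rectus muscle bellies, no asymmetric wall), eyelids or the
anterior orbital septum, tissue anisotropy or viscoelasticity, vascular or
axoplasmic physiology. Passing tests therefore validate the mechanical
account on the axisymmetric idealisation, not subject-specific prediction.

# Numerical choices, degeneracies, limitations

* Two thin fat wedges are excised from the fat domain (a 3 mm chord across
  the concave sheath–globe attachment corner; the 3 mm apex wedge): both
  corners trap incompressible fat between converging contact faces as the
  globe advances ~5 mm, which a fixed Lagrangian mesh cannot follow
  (remeshing is out of scope). Together they hold ~1% of the fat volume.
* The near-inviscid tissues make the tangent nearly singular in isochoric
  rearrangement modes; the solver's increment cap and damping schedule
  exist for them.
* At full swelling the fat sliding past the equator partially separates and
  its unloaded surface can wrinkle (soft solids under tangential
  compression do); the coarse fat surface resolution keeps those modes out
  of the basin the continuation follows.
* In this reconstruction a doubling of the fat shear modulus
  (0.7 to 1.5 kPa) changes the axial-length response by tens of percent
  (the stiffer fat transmits more of its push to the posterior cap), whereas
  the source reports no effect over that range; the proptosis response is
  insensitive (~3%). The discrepancy is recorded rather than tuned away.
* Where our reconstruction still under-predicts the source numbers —
  axial-length change about one-third low, peripapillary arc shortening and
  posterior-ROC change substantially smaller — the shortfall is localized
  at the peripapillary flange, whose stiffness here is set by the assumed
  sheath/bundle moduli and the reconstructed nerve-head geometry that the
  source does not print. The global force balance, proptosis, the signs and
  the monotone trends of all four biometrics, and the ICP/stiffness/anatomy
  sensitivity orderings all reproduce.
* The sweep drivers run on one CPU in minutes: the baseline table uses the
  quartic-eye/quadratic-fat meshes (~4000 nodes, 139 s in our runs); the
  property and sensitivity sweeps use quadratic everywhere (~2300 nodes,
  tens of seconds per case) since they compare directions and ratios, not
  absolute flattening magnitudes.
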