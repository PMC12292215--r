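---
title: "Methods: geometry, surrogate and optimization choices in tpmsdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, surrogate and optimization choices in tpmsdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tpmsdesign)
```

This vignette records how the package models shell-type TPMS implant
lattices, why its defaults are what they are, and what its synthetic data
can and cannot tell you about real specimens.

## The geometric model

A lattice design is seven numbers plus a surface family: per-axis unit
cell sizes $L_x, L_y, L_z$ (mm), shell thickness $t$ (mm), a rotation
$\theta$ about the X axis, and the height $H$ and diameter $D$ of a
cylindrical envelope. The mid-surface is the zero level set of the
family's standard trigonometric approximation (gyroid
$\sin X\cos Y + \sin Y\cos Z + \sin Z\cos X$; Schwarz-Diamond and Split-P
in their common published forms — see `?tpms_surfaces`), with coordinates
phase-scaled by $2\pi/L_i$ and rotated before evaluation.

Two modelling decisions matter here:

* **Metric thickness.** The shell solid is
  $|\varphi(p)|/\lVert\nabla\varphi(p)\rVert \le t/2$, a first-order
  distance approximation with central-difference gradients, rather than
  the raw field band $|\varphi| \le c$. A field band has no length units:
  its width varies with the local gradient, so it cannot honor a
  thickness prescribed in millimetres. Where the gradient degenerates
  (isolated critical points), the test falls back to the bounded band
  $|\varphi| \le (t/2)\,\bar k$ with $\bar k$ the mean phase scale
  $2\pi/L$, so no division by zero can occur.
* **Clipping.** The cylinder axis is Z, the base at $z = 0$. Surface
  extraction triangulates the pointwise minimum of the shell band and the
  envelope's signed distances, so reported surface areas *include* the
  cylindrical and planar cut faces. Whether a commercial kernel counts
  those faces is generally undocumented; including them is the
  unambiguous choice and is stated here so users can subtract the
  envelope term if needed.

Discretization uses voxel sampling at cell centers for volumes and
marching tetrahedra (six tetrahedra per cube around the main diagonal) at
grid nodes for surfaces. Marching tetrahedra was chosen over classic
marching cubes because its case analysis is derivable in a few lines —
no 256-entry lookup table to transcribe and trust — at the cost of more,
thinner triangles; areas converge identically. The test suite pins both
estimators to closed forms: sphere and box isosurface areas within 2 %,
relative density stable within 1 % under voxel halving, and
RD + porosity = 100 exactly.

Default voxel spacing is 0.05 mm — at most $t/4$ for the thinnest 0.2 mm
shell in the default design space. `voxelize()` refuses spacings above
$t/2$ and warns above $t/4$. Tests and examples use small envelopes
(H ≤ 8 mm, D ≤ 5 mm) so grids stay in the $10^5$–$10^6$ cell range;
a `max_cells` budget (default $2.5\times10^7$) turns runaway grids into
an error carrying a suggested spacing. Degenerate designs (thickness not
below the cell size) are representable only through the explicit
`full_solid` override, which tests use to pin RD = 100 exactly.

## Design space, size classes, and encoding

The default factor levels are three families × cell sizes {3, 4} mm per
axis × thickness {0.2, 0.3, 0.4} mm × rotation {0, 30, 60}° × heights
{8, 10, 15, 20} mm × diameters {5, 10, 15, 20} mm: 3456 designs, of which
3024 survive the squat-column stability filter $H/D \le 2$ (slender
compression specimens fail by buckling rather than material response).
The size classes are geometric: small ($H \le 8$ and $D \le 8$ mm), large
($H > 15$ or $D > 15$ mm), medium as the complement. Defining medium as
the complement — rather than by its own inequalities — guarantees the
classes partition the space; with the default levels this yields
216/1512/1296 designs (72/504/432 per family).

Features for modelling are the seven numerics, z-scored with statistics
fitted on the training table, plus a three-column one-hot for the family
(10 features total). The fitted scaler is stored in the surrogate and
re-applied to every prediction, so optimization and attribution operate
in natural units throughout.

## Mechanical metrics and the synthetic response generator

Engineering stress uses the envelope cross-section $\pi(D/2)^2$ — the
cellular-solids convention, which keeps lattice stress commensurate with
RD. Energy absorption is the trapezoidal integral of stress over strain
up to 0.5, so MPa × (—) gives MJ/m³; a curve ending early is integrated
to its end and flagged rather than extrapolated. The modulus is fitted
over the 10–40 % of ultimate stress window (deterministic, robust to
plateau onset), yield by the 0.2 %-offset construction with a flagged
first-local-maximum fallback, plateau stress as the mean over
$\varepsilon \in [0.2, 0.4]$ (the usual cellular-solids window). All
windows are configurable arguments. The Johnson–Cook failure strain is
implemented as a pure formula with the compression-calibrated Ti6Al4V
constants as defaults; no damage-evolution solver exists in this package,
and the reference elastic constants (including the mass-scaled density a
commercial explicit solver would use) are carried only as metadata in
`material_metadata()`.

The synthetic generator stands in for a finite-element campaign:

* **Descriptors** at dataset scale come from an analytic thin-sheet
  model: $RD \approx c_{\text{type}}\, t / L_g$ (with $c_{\text{type}}$
  the family's specific mid-surface area per unit cell — 3.0966 for the
  gyroid, 3.8378 for Schwarz-D, 4.2 for Split-P — and $L_g$ the
  geometric-mean cell size), a small boundary-truncation and rotation
  modifier, and $SA/VR \approx 2/t + 4/D + 2/H$ (two sheet faces plus
  envelope cut faces). The model was calibrated once against the
  package's own voxel/isosurface pipeline, which showed the plain $2/t$
  sheet term accurate to a few percent with no curvature correction
  needed; the test suite keeps the two paths within 15 % of each other on
  a reference design.
* **Strength** follows a Gibson–Ashby power law
  $U = k_{\text{type}}\, \sigma_0 (RD/100)^{1.5}$ with
  $\sigma_0 = 1000$ MPa (the order of Ti6Al4V yield) and family
  multipliers {gyroid 1.0, diamond 1.1, split_p 0.85}; exponent 1.5 is
  the bending-dominated cellular-solids value. Small documented
  modifiers — $1 + 0.05\sin 2\theta$ for rotation and
  $1 - 0.04(H/D - 1)$ for slenderness — keep every design variable
  mechanically relevant.
* **Energy absorption** integrates an idealized elastic–plateau curve
  with plateau stress $0.85\,U$ and modulus
  $10^5 (RD/100)^2$ MPa to $\varepsilon = 0.5$, giving
  $EA = 0.85\,U(0.5 - \varepsilon_y/2)$.
* **Noise** is multiplicative lognormal with unit mean and coefficient
  of variation 0.02 (independent draws for U and EA), matching the
  near-deterministic scatter of a converged simulation campaign; the
  generator is bit-reproducible given its seed.

With the default design space these choices put median U near 100–150
MPa and median EA near 50 MJ/m³, relative densities spanning roughly
15–50 % — the ranges a Ti6Al4V shell-lattice campaign reports. What the
generator deliberately does **not** emulate: densification upturn beyond
$\varepsilon = 0.5$, local buckling and contact, print-induced defects,
or any coupling between rotation and anisotropic load paths beyond the
small harmonic. Consequently, green tests here demonstrate that the
pipeline recovers *this* response surface; they do not validate the
surrogate's accuracy on laboratory data.

## The surrogate

The network is a 10 → 128 → 64 → 32 → 4 ReLU perceptron with linear
output, trained by Adam (learning rate 0.001, batch 32, 150 epochs, MSE)
on z-scored targets so the four outputs — percentages, 1/mm, MPa, MJ/m³ —
contribute comparably to the loss. Hidden activation, epochs and batch
size are configurable; there is no early stopping or cross-validation by
default (the held-out split is the accuracy report). Initialization is
Glorot-uniform: in capacity tests on small noiseless problems it
generalizes markedly better than He initialization here, and it matches
the convention of the mainstream deep-learning frameworks this
architecture mirrors. A small L2 weight penalty (10⁻⁴, the conventional
default of standard MLP implementations) damps late-training loss spikes
near interpolation; set `weight_decay = 0` to disable. Training, data
splitting (train size $\lfloor 0.8 n \rfloor$) and hence the entire loss
history are deterministic functions of the configured seed. The
acceptance suite requires held-out $R^2 \ge 0.97$ on all four targets for
the 3024-row study dataset and a validation loss that tracks training
loss (no divergence).

## NSGA-II

The optimizer is the canonical elitist NSGA-II: fast non-dominated
sorting, crowding distance with infinite boundary values and
range-normalized interior gaps, binary tournaments on (rank, crowding),
bounded simulated binary crossover (distribution index 15, pair
probability 0.9, per-variable mixing probability 0.5, per-variable child
swap with probability 0.5), and polynomial mutation (index 20,
per-variable probability $1/n$). The bounded SBX form — the spread
distribution truncated against the variable bounds, as in the reference
C implementation — is used rather than unbounded SBX with clipping; in
convergence experiments during development the bounded-with-swap form
converged roughly an order of magnitude faster on the 30-variable ZDT1
benchmark, and the unit tests pin that behavior (mean vertical distance
to the analytic front below 0.35 at 50 generations and below 0.05 at 120
generations, population 100). Users wanting tighter fronts on hard
problems should raise `generations`; the per-group lattice problem is
7-dimensional and converges much faster than ZDT1.

Three objectives — predicted U, EA and SA/VR — are maximized per
implant-size group, with box bounds taken from the group's observed
variable ranges (a degenerate single-valued bound is widened by 10⁻⁶).
The categorical surface family is *not* encoded into the real-valued
chromosome: SBX on a one-hot or integer code has no meaningful metric.
Instead the optimizer runs once per family (seed offset by the family
index), merges the three fronts, and keeps the non-dominated union.
Relative density is attached to every front member by the surrogate and
then filtered to the inclusive 20–40 % band — a post-hoc filter, not a
fourth objective or penalty, so the front itself remains purely
mechanical/geometric and the bookkeeping (front size, retained size) is
reported separately per group.

## Sensitivity and attribution

OFAT curves vary one feature over its observed range (categoricals are
enumerated) with the others at training means. Shapley values use the
interventional expectation: a coalition's value is the mean prediction
over a fixed-seed background sample with coalition features pinned to
the instance. The exact estimator enumerates all $2^p$ coalitions
(capped at $p \le 13$; the design problem has 8 features counting the
family as one) and satisfies efficiency by construction; the permutation
sampler is unbiased, seeded, and reports Monte-Carlo standard errors.
Tests verify the additive closed form
$\phi_i = w_i(x_i - \bar x_i^{\text{bg}})$ to $10^{-9}$, the dummy and
symmetry axioms, and exact/sampled agreement within three standard
errors. Group summaries subsample designs (default 25–30) and rank
features by mean $|\phi|$; on the synthetic system thickness ranks first
for ultimate stress, which is a property of the generator's
$U \propto (c\,t/L_g)^{1.5}$ structure — thickness spans a factor 2 while
cell sizes span only 4/3 — and a useful sanity anchor, not a claim about
laboratory lattices.

## Problem sizes

The shipped tests and the acceptance script use: geometry oracles on
$\sim 10^5$–$1.8\times10^6$ cell grids (sphere at $r/50$, lattice
convergence at 0.1 vs 0.05 mm); the full 3024-row study dataset with one
150-epoch training; NSGA-II at population 100 for 50 generations per
family per group; and exact Shapley attributions for 25 designs over a
60-row background. These sizes keep a full run in the low tens of
minutes on a single CPU while exercising every stage at study scale.

## Known limitations

* Absolute RD/SA values from a commercial implicit-modelling kernel will
  differ (Split-P coefficient conventions, cut-face accounting,
  meshing); the package pins *relative* behavior (convergence,
  monotonicity, closed forms) instead.
* The surrogate and fronts are only as faithful as the response surface
  they are trained on; with the synthetic generator they demonstrate
  pipeline correctness, not predictive validity for Ti6Al4V prints.
* The energy-absorption unit is strictly volumetric (MJ/m³). Reports
  that quote lattice EA in "MJ" without a volume reference cannot be
  compared number-for-number without knowing that convention.
* NSGA-II handles only box bounds; manufacturing constraints (minimum
  printable wall, overhang angles) must be imposed on the design space
  or as a post-filter.
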