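---
title: "Methods: dimerization free-energy surfaces by well-tempered metadynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimerization free-energy surfaces by well-tempered metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerfes)
```

## The problem

Two small planar aromatic molecules in solution associate through
pi-stacking. The quantity of interest is the dimerization free-energy
surface (FES) — the free energy as a function of a few collective variables
(CVs) describing the mutual arrangement of the two rings — and, from it, the
depth and location of the binding well in the first interaction shell
(contact distances of roughly 0.4–0.7 nm), the second, partially
solvent-separated shell (0.8–1.1 nm), and whether the bound pair prefers a
perpendicular ("T-shaped", plane-normal angle near 90°) or a parallel
("stacked", near 0°) arrangement. `dimerfes` implements the complete
computational chain for this question at desk scale: rigid-molecule models,
nonbonded energetics, biased sampling, FES reconstruction, reweighting,
corrections, and error analysis.

## Collective variables

Three CVs describe a rigid dimer:

* **COG distance** `dist`: the Euclidean distance between the ring-atom
  centres of geometry, under the minimum-image convention in a cubic box.
* **Inter-ring torsion** `torsion`: the signed dihedral over the four points
  (anchor atom of A, COG of A, COG of B, anchor atom of B), in (−π, π]. The
  anchor is a configurable ring atom (atom 1 by default); together with the
  COGs it tracks the relative in-plane rotation of the two rings.
* **Plane-normal angle** `nangle`: the angle between the best-fit plane
  normals of the two rings, folded to [0°, 90°] because a plane normal has
  no preferred sign. 0° is stacked, 90° is T-shaped.

The normals are computed as the smallest principal direction of the centred
ring coordinates rather than from a three-atom cross product; for exactly
planar rings the two coincide (this equivalence is a test), but the best-fit
form is robust to numerically imperfect planarity. The torsion's sign
convention is the standard atan2 dihedral; exchanging the two molecule
labels flips its sign, and all CVs are invariant under global rotation and
translation.

## Energetics

The molecules are rigid bodies, so the bonded terms of a conventional force
field vanish identically and only the intermolecular nonbonded energy
remains: a 12-6 Lennard-Jones term plus a Coulomb term for every
intermolecular atom pair. Electrostatics use the constant-shifted reaction
field: for charges $q_i, q_j$ at distance $r \le r_c$,

$$V = f\,q_i q_j\left[\frac{1}{r} + k_{rf} r^2 - c_{rf}\right],\qquad
k_{rf} = \frac{\epsilon_{rf}-1}{(2\epsilon_{rf}+1)\,r_c^3},\qquad
c_{rf} = \frac{1}{r_c} + k_{rf} r_c^2,$$

with $f = 138.935458$ kJ mol⁻¹ nm e⁻², which is continuous (zero) at the
cutoff. Defaults: cutoff 1.4 nm for both terms, $\epsilon_{rf} = 54$
(water-like screening), 300 K. The LJ term is plainly truncated at the same
cutoff with no dispersion correction — the simplest defensible choice for a
desk-scale sampler, and a knob rather than a claim. Lorentz–Berthelot
combination rules are the default with geometric (OPLS-style) rules as an
option, since published force fields differ on exactly this point. A
one-sided harmonic wall, $\tfrac{1}{2}k(r-r_0)^2$ beyond $r_0 = 2$ nm with
$k = 200$ kJ mol⁻¹ nm⁻², keeps the dimer from drifting beyond the second
interaction shell.

There is no explicit solvent anywhere in this package. The reaction-field
dielectric provides mean-field screening only; solvation-shell structure —
in particular water-mediated second-shell minima — cannot and does not
emerge from this model.

## Samplers

Explicit-solvent molecular dynamics is replaced by two seeded desk-scale
samplers:

* **Rigid-body Metropolis Monte Carlo** (`mc_sample`): moves cycle through
  translation and rotation of each molecule in turn; acceptance follows
  $\min(1, e^{-\Delta U/k_BT})$ on $U = E_\text{dimer} + E_\text{wall} +
  V_\text{bias}$. Move sizes are tuned during a discarded burn-in to a
  30–50% acceptance window and then frozen, because continued adaptation
  would violate detailed balance. The initial state stacks the molecules
  1 nm apart with seed-derived random orientations.
* **Overdamped Langevin dynamics** (`langevin_cv_sample`): Euler–Maruyama
  integration $x \leftarrow x - \eta\,\nabla U + \sqrt{2 k_B T\,\eta}\,\xi$
  with $\eta = dt/\gamma_f$, reflective bounds, for analytic CV-space
  potentials with known free energies. This is the validation channel: the
  metadynamics engine is checked against potentials whose FES is known in
  closed form, independent of any molecular detail.

Both samplers are bit-reproducible for a given seed and restore the
caller's RNG state.

## Well-tempered metadynamics

Gaussians of initial height $w_0 = 1$ kJ/mol and widths 0.05 nm (distance)
and 0.2 rad (torsion) are deposited every 500 steps on the sampled CV
position. Heights decay with the accumulated bias $V$ as

$$w = w_0\, e^{-V(s)/((\gamma-1)k_BT)},\qquad \gamma = 5,$$

and the converged FES estimate is $F(s) = -\frac{\gamma}{\gamma-1}V(s) + C$
(prefactor −1.25 at $\gamma = 5$). The bias lives on a grid (0.01 nm ×
0.05 rad by default; distance non-periodic over [0, 2.2] nm with the wall
guarding the upper edge, torsion periodic), evaluated by bilinear
interpolation, with each Gaussian truncated at 6σ (truncation error below
$10^{-8}$ of a hill). Grid storage makes bias evaluation O(1) per step; its
cost is a discretization error of order $\Delta x^2/8\sigma^2$ (≈1% of the
local bias at the default resolution) at off-node points, which bounds how
tightly the interpolated bias can be compared with an explicit hill sum.
Hills are written in a PLUMED-style HILLS dialect, CV trajectories in a
COLVAR dialect, so external tooling can consume both.

## Reweighting

Projections onto CVs that were *not* biased (here the plane-normal angle)
use frame weights

$$w_t \propto e^{\beta[V(s_t, t) - c(t)]},\qquad
c(t) = \frac{1}{\beta}\ln
\frac{\sum_s e^{\beta\gamma V(s,t)/(\gamma-1)}}
     {\sum_s e^{\beta V(s,t)/(\gamma-1)}},$$

with $V(s_t,t)$ the instantaneous bias recorded with each frame and $c(t)$
evaluated on the bias grid rebuilt at the frame's deposition epoch
(time-dependent-offset reweighting). A simpler final-bias variant,
$w_t \propto e^{\beta V_\text{final}(s_t)}$, is provided as an alternative
(`variant = "final_bias"`); both are standard, and the choice is exposed
rather than fixed. With zero bias the weights are exactly uniform and the
estimator reduces bit-for-bit to a plain histogram, which is a test.

Weighted histograms use bins centred on the FES grid nodes, so reweighted
and bias-derived surfaces live on identical supports and can be compared
node by node.

## Corrections and binding extraction

Two post-processing steps give the radial profile its physical gauge:

* **Entropic (Jacobian) correction**: in $n$ dimensions the volume element
  grows as $r^{n-1}$, adding a spurious $-(n-1)RT\ln r$ slope to the raw
  radial free energy; `entropic_correction` adds $(n-1)RT\ln r$ back
  ($n = 3$ by default). Its physical content is tested literally: a
  non-interacting dimer's corrected radial profile must be flat.
* **Zero shift**: profiles are translated so the mean over the nearly flat
  window [1.6, 1.8] nm (operationalizing "around 1.7 nm") is zero. The
  operation is idempotent and removes any additive gauge exactly.

`extract_binding` then reports the deepest point within the first
(0.4–0.7 nm) and second (0.8–1.1 nm) shells and labels the binding mode
from the plane-normal angle at the first-shell minimum: ≥60° T-shaped,
≤30° stacked, otherwise mixed. The thresholds operationalize the field's
qualitative language and are configurable. `compare_profiles` tabulates
first-shell depths across runs and flags pairs differing by more than
$k_BT$ (2.494 kJ/mol at 300 K) — differences below thermal energy are
treated as indistinguishable.

## Error analysis

`block_fes_error` partitions a trajectory into contiguous blocks, forms the
weighted FES per block, and reports the weighted standard error across
blocks per node (blocks weighted by their total weight; the two-block,
equal-weight case reduces to the textbook $d/2$). The "average error" is
the unweighted mean over nodes populated in every block; nodes missing from
any block are excluded, so strongly correlated short blocks can leave the
average undefined — the convergence verdict then uses the largest
informative sizes. `convergence_curve` repeats this over increasing block
sizes: a flat curve (slope below 0.05 kJ/mol per doubling over the largest
three sizes) is read as converged, a rising curve as residual correlation.
An AR(1) fixture with $\phi = 0.99$ (correlation time ≈ 100 samples)
produces the rising case; white noise the flat, converged case.

The bias-derived FES needs its own error bar: the instantaneous
well-tempered estimate keeps oscillating around the converged profile with
an amplitude set by the decaying hill height, which block analysis of the
trajectory cannot see. `fes_bias_error` therefore rebuilds the cumulative
bias at checkpoints over the tail of the hill sequence and reports the
per-node spread of the aligned FES estimates. Consistency between the
reweighted and bias-derived surfaces is judged against the combined error.

## The synthetic-data layer

`make_ring_template` builds linear acene-like fused-ring molecules (1 ring
= 6 atoms up to 4 rings = 18 atoms, benzene-like C–C bond 0.14 nm), exactly
planar, hydrogens omitted, with merged carbon-like united-atom parameters
(σ = 0.355 nm, ε = 0.29 kJ/mol, q = 0) unless a topology file supplies real
ones. The three-ring template plus configuration stands in for compact
fused systems such as pyrene without being atom-for-atom pyrene: the
pipeline, not the chemistry, is under test. `make_ideal_gas_dimer` zeroes ε
and q to give the exactly solvable non-interacting reference.
`make_double_well` ($U = h(s^2-1)^2$), `make_harmonic`, and `make_flat`
supply analytic potentials whose free energies come from independent
quadrature; `make_ar1_series` supplies correlated series with known
correlation time; `make_dip_fes` builds FES grids with wells at known
positions. Every oracle is deliberately naive code sharing no kernels with
the main path.

What passing these tests shows — and what it does not: the engine
reproduces known free energies on analytic potentials, exact identities
(tempering law, Jacobian correction, estimator equivalences) hold, and the
statistical machinery behaves as theory requires. It does not show that the
desk-scale molecular runs reproduce explicit-solvent results: LJ-only rings
in implicit screening bind stacked and a few kJ/mol deeper than solvated
benzene, and second-shell structure from ordered water is absent by
construction.

## Numerical choices and problem sizes

* Langevin double-well validation: $h = 10$ kJ/mol, effective step
  $\eta = 5\times10^{-4}$ (stable against the maximal curvature $8h$), hill
  width 0.1 (about half the thermal width of a well), grid [−1.75, 1.75]
  with 141 nodes, 6×10⁵ steps (1200 hills) — enough for the final hill
  height to fall below 0.1 kJ/mol and the recovered minima/barrier to sit
  within 1 kJ/mol of the quadrature values across seeds.
* Ideal-gas MC: 10⁶ moves, translation cap 1 nm (acceptance stays high for
  a non-interacting pair, and large moves decorrelate the distance quickly);
  radial bins of 0.05 nm keep the rarely visited small-$r$ bins populated.
* Desk-scale dimer metadynamics: 2×10⁵ moves, default hill parameters;
  reweighted onto 0.05 nm × 5° bins.
* Degenerate inputs: coincident COGs make the torsion undefined (error);
  collinear ring atoms make the plane normal undefined (error); atom pairs
  closer than 10⁻⁶ nm are rejected as overlapping, and the MC sampler
  treats such proposals as infinite-energy rejections.
* Tie-breaks: shell minima take the first grid node attaining the minimum;
  a perfectly flat first shell is labelled "mixed" with a warning.

## Design decisions that were genuinely open

* The reweighting reference in the field is ambiguous between several
  standard algorithms; both the time-dependent-offset and final-bias
  variants are implemented, with the former as default and an internal
  consistency test between the reweighted and bias-derived surfaces.
* The torsion's anchor atom is not dictated by anything physical; it
  defaults to atom 1 and is stored in the topology format.
* Fused-ring growth is linear (acene-like); compact topologies are
  approximated, not reproduced.
* Monte Carlo replaces molecular dynamics below the metadynamics layer:
  the bias engine and every analysis step are agnostic to how the chain was
  generated, and MC needs no forces, thermostat, or constraint algorithm.
  Production length has no ns equivalent here; convergence is judged by the
  block-error curve instead.

## Known limitations

Implicit solvent only (no hydration structure, no water-mediated minima);
rigid bodies (no internal flexibility, no bonded terms); two molecules only;
1- or 2-D bias grids; no kinetics — metadynamics timescales are not
physical; the desk-scale well depths are model observables, not predictions
of solvated binding free energies.
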