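# dimerfes

Dimerization free-energy surfaces (FES) of small planar aromatic molecules
by well-tempered metadynamics, at desk scale.

## What this package is for

How strongly do two aromatic rings bind, at what distance, and in which
mutual orientation — stacked (parallel planes) or T-shaped (perpendicular)?
`dimerfes` implements the full computational chain used to answer this with
biased sampling:

* rigid planar molecule models (generated acene-like rings, or a plain-text
  topology with per-atom Lennard-Jones and charge parameters),
* nonbonded energetics: truncated 12-6 LJ plus reaction-field Coulomb
  (cutoff 1.4 nm, ε_rf = 54, 300 K) and a harmonic upper wall
  (k = 200 kJ mol⁻¹ nm⁻² beyond 2 nm),
* the three stacking collective variables: COG distance, inter-ring torsion
  (anchor–COG–COG–anchor dihedral), and the plane-normal angle,
* seeded rigid-body Metropolis Monte Carlo and overdamped Langevin samplers
  (the desk-scale stand-in for solvated molecular dynamics),
* a well-tempered metadynamics engine: Gaussians of initial height
  w₀ = 1 kJ/mol and widths (0.05 nm, 0.2 rad) deposited every 500 steps,
  bias factor γ = 5, heights decaying as
  `w = w₀ exp(−V/((γ−1) k_B T))`, FES = −γ/(γ−1) · V,
* FES post-processing: reweighting onto unbiased CVs with the
  time-dependent offset `c(t)`, the entropic (Jacobian) correction
  `(n−1) R T ln r`, zero-shifting at the flat tail (~1.7 nm), first/second
  interaction-shell minima (0.4–0.7 and 0.8–1.1 nm) with stacked/T-shaped
  mode labels, and profile comparison flagging differences beyond
  k_BT = 2.494 kJ/mol,
* block-analysis error estimation with a flatness-equals-convergence
  diagnostic,
* PLUMED-style HILLS / COLVAR / fes.dat text I/O throughout.

## Worked example

A benzene-like dimer, 2×10⁵ MC moves of well-tempered metadynamics on
(distance, torsion), reweighted onto (distance, plane-normal angle):

```r
library(dimerfes)

t1 <- make_ring_template(1)          # 6-atom hexagon, C-C 0.14 nm
t1
#> molecule_template 'benzene_like': 6 atoms, 6 ring atoms, anchor 1, net charge 0 e

g    <- bias_grid()                  # dist x torsion, gamma = 5, w0 = 1
traj <- mc_sample(t1, t1, n_steps = 2e5, seed = 42, metad = g,
                  record_stride = 2L)
nrow(traj$hills)                     # 400 hills deposited

w    <- reweight_weights(traj, traj$hills, traj$grid)
axes <- list(grid_axis("dist", 0.25, 2.2, spacing = 0.05),
             grid_axis("nangle", 0, pi/2, n = 19L))
fes  <- reweight_to_cv(traj, axes, weights = w)
fes  <- zero_shift(entropic_correction(fes))
extract_binding(fes)
#> binding summary: first shell min -4.718 kJ/mol at 0.60 nm / 75 deg;
#>   second shell min -2.787 kJ/mol at 0.80 nm; mode: T-shaped

convergence_curve(traj, axes, block_sizes = c(5000, 10000, 20000, 50000),
                  weights = w)
#>  block_size avg_error
#>        5000 0.2392525
#>       10000 0.2603491
#>       20000 0.2715381
#>       50000 0.2791641
#> slope over largest blocks: 0.007981 kJ/mol per doubling -> converged
```

Reading the output: the contact well sits at 0.60 nm, 4.7 kJ/mol below the
dissociated tail, at a 75° plane-normal angle (T-shaped); the second-shell
well at 0.80 nm is shallower; the block-error curve is flat at
~0.27 kJ/mol per node, so the run is converged at that precision. These are
observables of the desk-scale model (LJ-only rings, implicit screening) —
not predictions for solvated benzene.

The same chain is available as a config-driven pipeline
(`pipeline_generate`, `pipeline_run`, `pipeline_analyze`,
`pipeline_compare`, YAML configs, outputs stamped with a config hash) and
as a shell wrapper in `inst/scripts/dimerfes`.

## Vignette

`vignettes/dimerfes-methods.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, the reweighting and error
estimators, what the synthetic generators emulate (and what passing tests
does and does not show about real solvated systems), and the numerical
choices.
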