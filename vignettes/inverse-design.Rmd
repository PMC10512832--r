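---
title: "Inverse design of anisotropic TPMS bone scaffolds"
author: "tpmsdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse design of anisotropic TPMS bone scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A bone implant that is much stiffer than the bone around it shields the bone
from load and drives resorption. Scaffolds built from triply periodic minimal
surfaces (TPMS) are attractive implant lattices — smooth, fully
interconnected, high specific surface — but the usual design workflow is
forward-only: pick a family and a porosity, compute the stiffness, repeat.
Real bone is anisotropic: its compressive stiffness differs along the three
anatomical axes. This package implements the reverse workflow: given a target
partial stiffness matrix, find the TPMS structure that realizes it.

Anisotropy is introduced through the *arrangement counts*. A cube of edge
$L$ holds $m \times n \times l$ unit cells along $x, y, z$; unequal counts
stretch the unit cell differently in each direction, so the homogenized
stiffness becomes direction-dependent while the part envelope stays fixed.
A design point is $X = (c, \varphi, t, m, n, l)$: family label
$c \in \{1,2,3,4\}$ (Gyroid, Primitive, Octo/I-WP, Diamond), porosity
$\varphi$, level-set threshold $t$, and the three counts.

The pipeline has four stages:

1. **Geometry.** The solid phase is the region $U(x,y,z) \ge 0$ of an
   implicit level-set function, e.g. for the Primitive family
   $U = \cos\frac{2\pi m x}{L} + \cos\frac{2\pi n y}{L} +
   \cos\frac{2\pi l z}{L} - t$. The threshold $t$ is calibrated to the
   requested porosity by bisection.
2. **Forward model.** The effective Voigt stiffness matrix
   $C \in \mathbb{R}^{6\times6}$ is computed by voxel finite-element
   homogenization: one trilinear hexahedron per solid voxel, displacement
   driven compression and shear load cases, entries from face reactions.
3. **Surrogate.** Two small feed-forward networks (BPNN1, BPNN2) learn
   $X \mapsto C_{11}$ and $X \mapsto C_{44}$ from an FE-labelled sample of the
   design space.
4. **Inverse search.** A regenerative genetic algorithm (RGA) minimizes the
   sum of absolute mismatches between surrogate-predicted directional moduli
   and the target entries; the winner is re-verified by FE.

## The regeneration trick

Single-output networks are more accurate than multi-output ones at fixed
size, but a target usually involves moduli in several directions. The RGA
therefore evaluates each individual together with two axis-permuted siblings,
$(m,n,l) \to (n,m,l)$ and $(l,n,m)$. Relabelling axes maps the structure onto
itself (up to a mirror, for the chiral Gyroid), so the sibling's canonical
moduli are the original's moduli in the permuted directions:

| probe | BPNN1 reads | BPNN2 reads |
|-------|-------------|-------------|
| $(m,n,l)$ | $C_{11}$ | $C_{44}$ |
| $(n,m,l)$ | $C_{22}$ | $C_{55}$ |
| $(l,n,m)$ | $C_{33}$ | $C_{66}$ |

The canonical labels are compression along $x$ ($C_{11}$) and shear in the
$yz$ plane ($C_{44}$). This pairing is forced by the sibling set: the two
transpositions move the $y$- and $z$-counts into the $x$ slot, which
permutes $\{C_{11}, C_{22}, C_{33}\}$ and simultaneously permutes
$\{C_{44}, C_{55}, C_{66}\}$ — the $yz$ plane is the one not involving $x$,
so it follows the same cycle. A canonical $xy$-shear label would leave
$C_{55}$ unreachable from these two siblings. Mirrors do not change the
diagonal stiffness entries, so the identity holds exactly for all four
families; this is verified against the FE model in the test suite.

Because the multiset of level-set values on a cubic cell-centred grid is
exactly invariant under axis permutation (coordinate relabellings and
reflections map the grid onto itself), the calibrated threshold depends only
on the *sorted* counts: siblings reuse the parent's $t$, and the calibration
cache is keyed on sorted $(m,n,l)$.

## Sign convention and porosity calibration

The solid phase is $\{U \ge 0\}$, so raising $t$ shrinks the solid set and
raises the porosity. This orientation is fixed by the reference design point
for the Gyroid at 67% porosity with counts $(7,8,3)$, whose threshold is
$t \approx +0.52$; the package reproduces that value. Calibration bisects on
$t$ with a porosity tolerance of 0.002; the level-set field is sampled once
per calibration, so each bisection step is a thresholding pass.

## FE homogenization choices

* **Elements.** 8-node trilinear hexahedra, $2^3$ Gauss points, isotropic
  constituent ($E = 10$ GPa, $\nu = 0.30$ by default; 100 GPa for dense-bone
  variants). One element per solid voxel.
* **Boundary conditions.** The default mode prescribes the affine field
  $u = G\,x$ on every solid node of the outer box (kinematic uniform boundary
  conditions), with $G = \varepsilon\, e_a \otimes e_a$ for compression and
  $G = \gamma\, e_b \otimes e_a$ for shear. Reaction stresses on the box
  faces are then literally stiffness-matrix columns, which is what makes the
  off-diagonals $C_{12}, C_{13}, C_{23}$ well defined; it also keeps the
  constrained DOF set identical across all six load cases, so a single
  sparse Cholesky factorization serves them all. A `"free"` mode (bottom
  face fixed, top face driven, side faces traction-free) is available for
  apparent-modulus studies; it is softer and cannot measure off-diagonals.
* **Displacement.** 0.1 mm on the 10 mm cube, i.e. 1% nominal strain. The
  entries are strain-independent (linearity is tested), so the magnitude is
  conventional.
* **Connectivity.** Solid voxels not face-connected to the largest component
  are removed before assembly: floating islands carry no load and would make
  the system singular. If the remaining solid does not span the loading axis
  the geometry is rejected with an error naming the axis.
* **Exactness anchor.** On a fully solid grid the affine load cases are
  exactly representable, so the homogenized matrix equals the isotropic
  closed form $C_{11} = E(1-\nu)/((1+\nu)(1-2\nu))$,
  $C_{12} = E\nu/((1+\nu)(1-2\nu))$, $C_{44} = E/(2(1+\nu))$ to machine
  precision; the test suite asserts 13.4615, 5.7692, 3.8462 GPa for the
  default material.
* **Solver.** Supernodal sparse Cholesky (CHOLMOD through the Matrix
  package) on the free-DOF block.

## Resolution: why the working grid is 29³

The full protocol labels 8000 design points at a fine resolution; this
package's *desk preset* — the configuration used by its own tests and
reported statistics — labels 400 points at $R = 29$ voxels per edge, which
keeps a complete pipeline run in the tens of minutes on one CPU.

The choice of 29 rather than a rounder number is deliberate. With counts up
to 8, a commensurate grid (e.g. $R = 24$, a multiple of 3, 4, 6 and 8)
samples every unit cell at the *same* few phases of the trigonometric level
set. At three voxels per period the sampled cosine peaks at 0.5 instead of
1.0, so the thin necks that connect the solid network fall between voxel
centres *coherently* — every neck in the structure disappears at once. In a
survey across the design space roughly a quarter of all structures lost
their load path at $R = 24$, although every one of them is connected in the
continuum (verified at $R = 61$). A resolution coprime to the counts breaks
the resonance: phases drift from cell to cell, the structure is sampled
quasi-continuously, and the failure rate drops by an order of magnitude.
$R = 29$ (prime) is the smallest such grid that also keeps the residual
failure rate in the low percent.

The residual infeasible points are handled in two places: the sampler
resamples design points whose voxelization has no spanning load path (they
are not representable at desk fidelity, so they can be neither labelled nor
verified), and the GA returns the best individual in its final elite pool
whose geometry is realizable — the surrogate alone cannot tell a broken load
path. Both filters are no-ops at fine resolutions.

## Surrogate training

Architecture: input 6, two tanh hidden layers of 48 neurons, linear output —
the architecture selected by grid search on the full protocol; the package's
`architecture_search()` reproduces the comparison on the desk preset.
Training minimizes MSE on standardized inputs and labels with full-batch
Adam (learning rate 0.01, up to 3000 epochs). 15% of the training split is
held out for early stopping (patience 300 epochs, best-weights restore),
which in practice terminates well before the epoch cap and keeps the
test/train MSE ratio small — `train_bpnn()` fails a run whose ratio exceeds
3 by default, while the pipeline wrapper records the ratio and warns instead
(a long run should finish and report rather than die on a noisy guard); the
protocol tests assert the ratio. Training is full-batch and therefore deterministic for
a fixed seed. The family label $c$ enters as an integer feature, keeping the
printed six-dimensional input; a one-hot encoding was considered and
rejected to preserve that contract (the networks have no difficulty with the
four-level integer).

The threshold $t$ is an input even though it is a function of
$(c, m, n, l, \varphi)$; it is kept because the redundancy is harmless and
the six-feature input is part of the model's definition.

## The regenerative GA

Chromosome $(c, \varphi, m, n, l)$ — $t$ is *derived* by calibration, never
evolved, so inconsistent $(\varphi, t)$ pairs cannot arise. Defaults:

* population 4000, truncated to the 2000 best after each parent+offspring
  merge (desk preset scales both down tenfold to 400/200);
* variation participation decreases linearly with fitness rank, from 0.9 for
  the worst to 0.2 for the best — the elite are mostly preserved, strugglers
  are recombined;
* one-point crossover with probability 0.8 per pair; integer counts step
  $\pm 1$ (per-gene probability 0.3) clipped to 3..8; porosity takes a
  Gaussian step (sd 0.02, probability 0.5) clipped to [0.50, 0.75]; the
  family label resamples uniformly with probability 0.1;
* termination when the best fitness has not improved for 20 consecutive
  generations (a hard cap of 500 generations is a safety net);
* primary and secondary entries enter the fitness with equal weight; the
  primary/secondary distinction selects *which* entries are targeted, and a
  per-role weighting can be configured if shear matching should dominate.

Fitness is $\sum_e |\hat{C}_e - C_e^{\mathrm{target}}|$ over the targeted
entries, with predictions from the three regeneration probes. Verification
entries never enter the fitness. The regeneration siblings act as fitness
probes only — they describe the same physical structure, so admitting them
as individuals would triple the population without adding information.

At termination the run log keeps every distinct chromosome within 5% of the
best fitness: near-degenerate alternatives are common and genuinely useful —
when several structures satisfy the same mechanical target, the one with the
most favourable porosity for nutrient transport can be chosen.

## Closed-loop validation

Real targets (CT-derived bone matrices) are not distributable with the
package, so validation is closed-loop: a hidden design point is sampled, its
FE matrix provides the target entries, the GA searches without ever seeing
the hidden point, and the winner is FE-verified against the target. Because
the target is attainable by construction, the verified relative error
percentage (REP) measures the pipeline's own error — surrogate bias plus
search slack. The package's protocol runs five replicate seeds and reports
the mean and maximum REP over all binding entries; with three compressive
targets the mean stays within a few percent, with six targets the secondary
(shear) entries contribute the largest REP because their magnitudes are
small. These statistics are recomputed, not asserted from stored numbers, by
`scripts/acceptance.R` and the protocol-level tests.

Verification resolution defaults to the labelling resolution (strict
closed loop, the quantity the replicate statistics report). Verifying at
$2R$ instead exposes the surrogate's resolution bias on top of its
interpolation error; that mode is available
(`closed_loop_design(verify_R = 2 * R)`) but is not part of the reported
statistics, where target and verification are deliberately computed at the
same fidelity. Entries with near-zero targets are excluded from mean REP
(their absolute error is still reported), mirroring standard practice of
omitting items close to zero from relative-error summaries.

## What the synthetic protocol does and does not show

The closed-loop fixture emulates the *structure* of the real task — an
anisotropic partial stiffness target with primary/secondary/verification
roles, in the stiffness range the design space can reach. It does not emulate
real bone targets: a CT-derived matrix need not be attainable by any TPMS
configuration, in which case the residual fitness measures the distance to
the design space's boundary rather than pipeline error. Passing the
closed-loop checks therefore demonstrates that the method recovers targets
the space can express; it does not bound the error for arbitrary bone data.
Desk-scale numbers also carry the coarse-grid bias discussed above: labels at
$R = 29$ differ from fine-grid values by a few percent, consistently across
the dataset, which cancels in the closed loop but would not cancel against an
externally supplied target.

## Known limitations

* Sheet/shell TPMS variants (double-threshold $|U| \le t$) and graded
  porosity are out of scope.
* Homogenization uses kinematic uniform boundary conditions, not periodic
  ones; KUBC slightly overestimates the stiffness of a periodic medium. The
  bias is consistent across the pipeline and cancels in closed-loop
  statistics.
* The shear block off-diagonals and the normal-shear coupling terms are not
  measured (they vanish for orthotropic arrangements up to discretization
  noise).
* The surrogate extrapolates poorly outside the sampled design box; predict
  flags such queries.
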