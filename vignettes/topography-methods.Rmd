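---
title: "Characterizing conical intersections: models, parameters and design choices"
author: "citopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing conical intersections: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citopo)
```

## The two-state model and its assumptions

Everything in this package happens on an analytic two-state diabatic
Hamiltonian over an $n$-dimensional coordinate space $q$ (Bohr):

$$
H(q) = \begin{pmatrix}
e_X + (s+g)\cdot q + \tfrac12 q^{T} Q_{11} q & h\cdot q + \tfrac12 q^{T} Q_{12} q\\
h\cdot q + \tfrac12 q^{T} Q_{12} q & e_X + (s-g)\cdot q + \tfrac12 q^{T} Q_{22} q
\end{pmatrix}
$$

with adiabatic surfaces $E_\pm = m \pm \sqrt{d^2 + c^2}$ where $m, d, c$
are the mean, half-difference and off-diagonal elements. The two states
are degenerate at the origin for *any* choice of the linear vectors and
quadratic terms, which is what makes the model useful: the crossing point,
its branching space and its topography are all known in closed form, so
every downstream operation can be validated against an exact answer.

The assumptions are those of a first-order (linear-coupling) description:
the degeneracy is lifted linearly in the branching plane
$\mathrm{span}\{g, h\}$, the seam is locally flat (optionally curved by
the quadratic terms), and only two states participate. Three-state
degeneracies, curved-seam (second-order) effects and any real
electronic-structure content are out of scope.

Internal units are Hartree and Bohr throughout; molecular geometries for
the structural module are in Angstrom, with the single conversion constant
pinned in `units_bohr_per_angstrom()`.

## Topography parameters and the P/B classification

At the crossing, after rotating the degenerate pair to the canonical gauge
(`extract_branching_vectors()`: $g \perp h$, $|g| \ge |h|$), the first-order
double cone is fully described by four numbers:

* **pitch** $\delta_{gh} = \sqrt{(g^2+h^2)/2}$ (Hartree/Bohr) — overall
  steepness; default-free, it is whatever the surfaces give.
* **asymmetry** $\Delta_{gh} = (g^2-h^2)/(g^2+h^2) \in [0,1)$ — ellipticity
  of the cone cross-section.
* **relative tilt** $\sigma$ and **tilt heading** $\theta_s$ — the mean
  gradient resolved in the branching plane, in units of the pitch.

and two classification discriminants,

$$
P = \frac{\sigma^2\,(1-\Delta_{gh}\cos 2\theta_s)}{1-\Delta_{gh}^2},
\qquad
B = \frac{(\sigma_x^2(1+\Delta_{gh}))^{1/3} + (\sigma_y^2(1-\Delta_{gh}))^{1/3}}
         {(2\Delta_{gh})^{2/3}}.
$$

$P$ is exactly the squared maximum, over branching-plane directions, of the
ratio between the tilt slope and the cone slope: $P<1$ means the lower
sheet falls away from the apex in every direction (peaked), $P>1$ that it
rises somewhere (sloped). $B$ compares the tilt against the asymmetry that
holds two separate descent valleys along $\pm g$ open: $B<1$ keeps both
valleys (bifurcating), $B>1$ merges them into one (single path). Before
adopting these closed forms we verified them against direct numerical
inspection of the lower sheet on thousands of random cones; the package
keeps that check alive in `brute_force_classify()` and its tests, which
scan a small circle around the apex and count descent directions and local
minima without ever touching the formulas.

Numerical conventions worth knowing:

* $\theta_s \in [0, 2\pi)$ measured from the canonical $g$ axis; when
  $\sigma = 0$ the heading is physically undefined and set to 0.
* A circular cone ($\Delta_{gh} = 0$) makes $B$ degenerate: an untilted
  circular cone reports $B = 0$ with a `"circular"` flag, a tilted one
  $B = \infty$ (single path — the correct limit).
* $\Delta_{gh} \to 1$ ($|h| \to 0$) makes the intersection seam-degenerate;
  the parameters are still returned but flagged, with a warning, because
  silently dropping such points would bias quadrant tables.
* Classification boundary tolerance $\varepsilon = 0.02$ (configurable):
  members with $|P-1| \le \varepsilon$ or $|B-1| \le \varepsilon$ carry
  boundary flags, mirroring how borderline intersections are discussed in
  practice rather than hard-assigned.

The classification is invariant under molecular-frame rotations and under
the state-mixing gauge: mixing the two degenerate states by an angle
$\beta$ rotates the raw $(g, h)$ pair by $2\beta$, and the
canonicalization angle $\tfrac14\mathrm{atan2}(2g\cdot h, g^2-h^2)$ undoes
exactly that. The tests exercise both invariances at $10^{-10}$ relative
tolerance.

### Two derivative routes

`characterize_model()` recovers the topography either from the model's
analytic gradients or purely by finite differences of the adiabatic
surfaces. The gap itself is not differentiable at the apex, but the
squared half-gap is, and its Hessian $2(gg^{T}+hh^{T})$ yields the
canonical vectors by eigendecomposition. Because $P$ and $B$ depend only
on $\sigma_x^2$ and $\sigma_y^2$, the cone — and hence the heading — is
only defined up to reflections of the branching axes on this route, so
the finite-difference heading is reported folded into $[0, \pi/2]$. The
round-trip build → characterize is tested at $10^{-8}$ relative error on
the analytic route and $10^{-4}$ on the finite-difference route, over 200
random specifications (pitch 0.5–2 Ha/Bohr, asymmetry 0–0.95, tilt 0–2).

## The synthetic generator: what it emulates, and what it does not

Real studies of CI topography sensitivity re-optimize one intersection
under many electronic-structure treatments (e.g. shrinking CASSCF active
spaces) and obtain one $(P, B)$ point per treatment. The raw inputs of
such a study are multiconfigurational wavefunctions, which are far outside
desk scale, so the generator replaces them with the minimal stand-in: a
base model with prescribed topography plus an ensemble of perturbed copies
(`perturb_model()`). The perturbation is independent Gaussian jitter on
every linear coefficient (and quadratic term), with standard deviation
`jitter_scale` times the norm of the vector being jittered; a zero vector
(the mean gradient of an untilted base) is jittered relative to the pitch
instead, so symmetric bases still explore tilt. No published generative
model exists for how a level-of-theory change perturbs the local
Hamiltonian; Gaussian jitter is an explicit modelling choice, not a claim
about CASSCF behavior. Consequences to keep in mind:

* real active-space changes are systematic and correlated, not isotropic
  noise — the ensembles here probe *robustness of the analysis chain*, not
  the statistics of real nucleobase intersections;
* the perturbation preserves the crossing at the origin exactly, whereas
  real re-optimizations move the geometry; the structural module exists
  precisely because that geometric drift is analyzed separately in
  practice (RMSD below ~0.2 Å between re-optimized CI structures is the
  scale of interest);
* passing ensembles therefore demonstrate internal consistency and
  determinism, nothing about real molecules.

The default `jitter_scale` in the shipped study configurations is 0.02
(2 % of each coupling vector), chosen once as the scale that produces
clearly visible scatter in the $(P, B)$ plane without routinely crossing
quadrant boundaries for base models placed well inside a quadrant — the
regime in which an outlier analysis is meaningful at all. Ensemble member
1 is always the unperturbed base, so every ensemble contains its own
reference.

Seeds are explicit arguments everywhere, there is no hidden global random
state (`.Random.seed` is saved and restored around every internal draw),
and per-member seeds derive deterministically from the system seed, so
studies are reproducible byte-for-byte.

## Locating minimum-energy crossing points

Two independent algorithms are implemented, and their agreement (within
$10^{-3}$ Bohr on random models; typically $10^{-6}$) is itself one of the
package's standing checks.

**Penalty method** (`optimize_penalty()`): minimize
$\bar E(q) + w\,\Delta E^2/(\Delta E + \alpha)$, the mean energy plus a
smoothed gap penalty. Defaults: smoothing $\alpha = 0.02$ Ha, initial
weight $w = 5$, geometric escalation $\times 2$ whenever a stage ends with
the gap above `gap_tol`. The penalty derivative vanishes as the gap closes,
so the objective stays $C^1$ through the seam. Each stage is minimized
with BFGS using analytic gradients; plain steepest descent with a halving
line search was tried first and stalls badly on tilted cones, where the
penalty surface is a stiff valley across the seam and nearly flat along
it — the classic setting in which first-order descent zigzags. The choice
of inner minimizer is an implementation detail behind the same contract.

**Branching-plane projection** (`optimize_projection()`): alternate
degeneracy *restoration* — Newton steps on the gap along its gradient —
with *seam sliding* — the mean-energy gradient projected orthogonal to the
current branching plane, with a backtracking line search on the mean
energy. Below a gap of $10^{-8}$ Ha the derivative-coupling construction
is replaced by the degenerate-pair vectors, avoiding the $1/\Delta E$
blow-up.

Shared defaults: `gap_tol` $10^{-6}$ Ha, `step_tol` $10^{-6}$ Bohr,
`max_iter` 500. These are common-practice optimizer numerics, are
config-overridable, and make no claim to match any particular
quantum-chemistry code. A result is `converged` only if the final gap and
step are below their tolerances; iteration exhaustion returns an
unconverged result with the full trace, never an exception, so ensemble
runs complete and report their failures. In models with more dimensions
than the branching plane, coordinates outside the plane receive a small
positive diagonal quadratic term (0.05 Ha/Bohr², configurable) by
default, so the seam is bound and the minimum-energy point well defined.

## Structural comparison

`superpose_rmsd()` implements Kabsch least-squares alignment via SVD with
the determinant correction, so only proper rotations are used and
enantiomers keep a nonzero RMSD. Superposition is unweighted and all-atom
by default — published CI-structure comparisons rarely state their
protocol, so the neutral default is used and an `atom_mask` allows
heavy-atom-only fits. Atom correspondence is by file order; no graph
matching (the intended use compares conformers of one molecule).
Collinear or otherwise rank-deficient point sets return a flagged result
(the RMSD is still optimal, the rotation just is not unique) instead of
raising, so batch reports complete. The implementation is checked against
a hierarchically refined quaternion-grid search — pure direct search over
rotation space, sharing no code with Kabsch — to $10^{-9}$ Å, and against
`bio3d::rmsd()` as an external reference.

Dihedrals follow the signed IUPAC convention in $(-180, 180]$ degrees
(cross-checked against `bio3d::torsion.xyz()`), and
`ensemble_structure_report()` associates per-member RMSD with the change
in one tracked dihedral using the Spearman *rank* correlation: the
expected relationship is monotone, not linear, so a linear coefficient
would overstate precision. When the ensemble shows no variation the
correlation is reported as not applicable rather than `NaN`. Dihedral
atom indices are 1-based in R functions and 0-based on the command line
(stated in both places).

## Orchestration and the outlier rule

`run_study()` chains the whole pipeline per configured system and ensemble
member, recording optimizer provenance (method, tolerances, seed) in every
record. The outlier definition is the minimal operational one: a member
whose quadrant differs from its system's modal quadrant; a tie for the
mode flags the system and makes no outlier call. The rule is invariant to
record order and tested as such. Unconverged members are recorded and
logged, never dropped, so record counts always reconcile.

Outputs are plain text with stable formatting (CSV written at 17
significant digits, versioned JSON), which makes byte-identical repeated
runs a testable contract rather than an aspiration.

## Problem sizes and limitations

The standing property checks run 200-model round-trips, 200-model
classification cross-validation, 50 optimizer pairs, 50+50 invariance
rotations, 20 superposition pairs and a 5×8 ensemble study; together they
complete in well under a minute on one CPU, which keeps the full suite
cheap enough to run on every change.

Known limitations, all deliberate: first-order topography only (no
curved-seam or higher-order characterization), two electronic states only,
Gaussian jitter as the stand-in for level-of-theory variation, no
permutation- or symmetry-corrected RMSD, and no electronic-structure
computation of any kind — the package characterizes surfaces it is given
or builds, it does not produce them.

```{r example}
m <- build_model(topography_spec(pitch = 1.2, asymmetry = 0.6,
                                 tilt_magnitude = 0.5, tilt_heading = 0.7),
                 n_dim = 3)
res <- optimize_projection(m, c(0.7, -0.7, 0.3))
tp <- compute_topography(extract_branching_vectors(
  adiabatic_eval(m, res$q_star, degeneracy_tol = 1e-5)))
tp
classify(tp)
brute_force_classify(m)
```
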