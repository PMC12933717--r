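---
title: "Adaptive equilibrium refinement of molecular geometries: models, parameters and numerical choices"
author: "aefm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive equilibrium refinement of molecular geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aefm)
```

## The problem

Fast transition-state (TS) generators — semiempirical tight-binding
methods, machine-learned surrogates — produce geometries that are close
to, but systematically noisier than, high-fidelity references. `aefm`
implements a structure-only refinement scheme: a neural map
$\phi_\theta$ is trained to send degraded geometries directly to their
high-fidelity counterparts, and at inference the map is *iterated to a
fixed point*, $x^{k+1} = \phi_\theta(x^k)$, starting from the
low-fidelity guess. The refined structure is the equilibrium of the
learned flow. No energies, forces or quantum chemistry enter anywhere:
the method sees only element symbols and Cartesian coordinates in
&Aring;ngstr&ouml;m.

## The training prior and its calibration

The source distribution the model learns to undo is an isotropic
Gaussian corruption of the reference $x_1$:

$$x_0 = x_1 + \sigma \epsilon, \qquad \epsilon \sim \mathcal N(0, I).$$

The single parameter $\sigma$ is matched to the low-fidelity method the
model will face at inference. Because the expected *per-atom* squared
displacement of the corruption is exactly $3\sigma^2$ (three independent
coordinates per atom; see `expected_corruption_msd()`), equating it with
the observed deviation of low-fidelity structures from their references
gives

$$\sigma = \left( \operatorname{mean}_{\text{pairs}}
   \frac{\lVert x_1 - x_1^w \rVert^2}{3\,N} \right)^{1/2},$$

implemented in `calibrate_sigma()`. Two deliberate choices:

* The deviation is measured **in the frame as given, without
  alignment**. The low-fidelity source is expected to live in the
  reference frame; any systematic drift it has is part of the error the
  prior must cover.
* The formula is the root of the *mean squared* per-atom deviation (the
  exact moment-matching condition), not the mean of per-pair RMSDs.
  The two differ by Jensen's inequality; the moment-matched form makes
  the round-trip `calibrate_sigma(corrupt(., sigma))` $\to \sigma$ exact
  in expectation, which the test suite exploits.

Training samples are drawn on the optimal-transport interpolation path
between the corruption and the reference,

$$x_t = (1-t)\,x_0 + t\,x_1 + \sigma_{FM}\,\epsilon',
  \qquad t \sim U(0, 1),$$

with small path noise $\sigma_{FM} = 0.05$. The interpolation variable
$t$ is *not* given to the network: the model must infer how degraded its
input is from the geometry alone. This is what makes the scheme adaptive
— at inference, inputs of very different quality are all handled by the
same time-free map, which corrects a nearly-clean structure gently and a
badly degraded one aggressively. The uniform law for $t$ is the standard
choice where nothing else is specified.

## The objective

The loss combines direct endpoint prediction with a bond-consistency
term:

$$L = \underbrace{\tfrac{1}{N}\lVert x_1 - \phi_\theta(x_t)\rVert^2}_{L_{AEFM}}
    + w_b \underbrace{\frac{1}{|B(x_1)|}\sum_{(i,j)\in B(x_1)}
      \bigl[d_{ij}(\phi_\theta(x_t)) - d_{ij}(x_1)\bigr]^2}_{L_b},$$

with $w_b = 1$. The neighbour set $B(x_1) = \{(i,j):
\lVert x_{1,i} - x_{1,j}\rVert < r_{cut}\}$ uses $r_{cut} = 2$ &Aring;
— long enough to cover equilibrium H/C/N/O bonds plus the stretched
bonds typical of TS geometries. Crucially, $B$ is computed **once from
the reference** and the same index pairs are measured on the prediction
(`bond_loss()` enforces this by provenance-checking the bond set): the
penalty follows specific chemical contacts, it does not chase whatever
pairs happen to be close in the prediction. A small positional error can
coexist with chemically fatal bond distortions; this term targets
exactly that failure mode.

Per-atom averaging (rather than per-structure sums) makes small and
large molecules weigh comparably within a batch.

## Inference: fixed-point iteration with Anderson acceleration

`fixed_point_refine()` starts from the low-fidelity structure and
iterates the model. Two modes:

* **plain**: $x^{k+1} = \phi_\theta(x^k)$;
* **anderson** (default): keep the last $m+1$ iterates $x^i$ and
  residuals $g(x^i) = \phi_\theta(x^i) - x^i$, solve
  $\min_\alpha \lVert \sum_i \alpha_i g(x^i) \rVert^2$ subject to
  $\sum_i \alpha_i = 1$, and step to
  $\beta \sum_i \alpha_i \phi_\theta(x^i) +
  (1-\beta)\sum_i \alpha_i x^i$.

Defaults are $\beta = 1$, $m = 5$, and the iteration stops when the RMSD
between successive iterates falls at or below 0.01 &Aring; (computed
*without* alignment — both iterates live in the model's working frame),
with a hard cap of 100 iterations. Numerical choices:

* The sum-to-one constraint is eliminated by the difference formulation
  ($\alpha_h = 1 - \sum_{i<h}\theta_i$, normal equations in the residual
  differences) with Tikhonov regularization $10^{-8}$; a singular system
  falls back to a plain step and flags it.
* Early iterations use however much history exists (standard Anderson
  warm-up). With a single stored point and $\beta = 1$ the update *is*
  the plain update, which the tests assert bit-for-bit.
* An alternative stopping metric `stop_metric = "norm_over_n"`
  ($\lVert x^{k+1}-x^k\rVert / N \le$ tol) is provided as a config
  switch, since the normalization of the stopping rule admits two
  readings; the RMSD reading is the default because it is the stated
  intent and has units of &Aring; per atom.

### Convergence diagnostics

Local convergence of the iteration is governed by the spectral radius
$\rho(J_\phi)$ of the model's Jacobian at the iterate: $\rho < 1$ means
contraction. `spectral_radius()` estimates it from Jacobian-vector
products only (central finite differences, step $10^{-4}$), building an
Arnoldi/Krylov subspace and diagonalizing the small Hessenberg matrix.
This handles the complex leading eigenvalue pairs that defeat naive
power iteration, is exact (to solver precision) once the Krylov space is
exhausted, and detects invariant-subspace breakdown — so the identity
map reports exactly 1. Diagnostics are opt-in
(`solver_config(diagnostics = TRUE)`) because one estimate per iterate
is far more expensive than the iteration itself; they are analysis, not
inference.

## The reference backbone

The package deliberately separates the *training/inference framework*
from the *network architecture*. Any coordinate-to-coordinate map with
the right symmetries can be plugged in through the refiner interface
(`as_refiner()` wraps a bare function; `predict()` is the contract). The
shipped reference net is a small equivariant message-passing network
chosen so that CPU training in minutes is realistic:

* per pair: a Gaussian radial basis of the interatomic distance (16
  functions up to 4 &Aring;), a one-hot element-pair type, and two
  symmetric functions of smooth coordination counts
  $c_i = \sum_k \kappa(d_{ik})$ (cosine kernel, 2 &Aring; cutoff) —
  the coordination features let the net distinguish a bonded pair from
  an incidental contact at the same distance;
* a one-hidden-layer scalar network (width 64, tanh) maps these
  invariants to a pair weight $w_{ij}$, damped by a smooth cosine
  envelope so remote pairs cannot act;
* coordinates update as $x_i \leftarrow x_i + \sum_j w_{ij}(x_j - x_i)$,
  repeated over 4 layers with separate parameters.

Because every learned quantity is an invariant scalar and coordinates
move only along difference vectors, the map is SE(3)- and
permutation-equivariant *by construction*, and the antisymmetric updates
preserve the centroid exactly — translation equivariance needs no
explicit centering. `equivariance_report()` measures worst-case
deviations over random group elements and is used as a release gate
(all below $10^{-4}$ &Aring;).

The output weights of every layer start at zero, so the untrained map is
exactly the identity: fixed-point inference is well-posed from epoch 0,
and training only ever bends the map away from neutrality. Gradients are
computed by hand-derived backpropagation through the full geometry
(distances, basis, coordination counts, envelope); a finite-difference
oracle in the test suite verifies them to $10^{-4}$ relative error.

Element types outside the training vocabulary warn and fall back to the
first type rather than failing — refinement of a molecule with one
exotic atom degrades gracefully instead of aborting.

## Training loop

`train_refiner()` uses adaptive-moment gradient descent (learning rate
$5\times10^{-3}$, cosine decay to 5%, batch size 16, 200 epochs by
default), drawing fresh corruptions and interpolation times per
structure per epoch. These optimizer settings are the package's own
choice for the reference net at desk scale; nothing about them
transfers from large-scale backbones, so they are plain config. A 10%
validation split (fixed by seed) tracks the aligned RMSD of
single-application denoising per epoch. Two guards worth noting:

* a non-finite loss aborts with the offending epoch (divergence is an
  error, not a warning);
* an *effectively zero* gradient skips the optimizer step entirely.
  Adaptive-moment methods rescale gradients by their running magnitude,
  so float-rounding noise would otherwise be amplified into full-size
  parameter updates — visible in the degenerate $\sigma = \sigma_{FM} =
  0$ setting, where training must be a provable no-op.

Training from `RefinementPair` lists calibrates $\sigma$ automatically;
`use_pairs = TRUE` optionally trains on the actual low-fidelity
geometries instead of Gaussian corruptions. The default is the
corruption prior: it is what makes the learned map robust to inputs of
heterogeneous quality.

## The synthetic benchmark and what it can show

`generate_templates()` grows random tree-connected H/C/N/O geometries:
each new atom bonds to a uniformly chosen existing atom at a distance
drawn from a per-element-pair table (means 0.95–1.5 &Aring;, spread
0.05 &Aring;), rejection-sampled so no nonbonded pair comes closer than
0.8 &Aring;. `make_benchmark()` corrupts them at a known $\sigma$ and
writes XYZ files plus a JSON Lines manifest recording the truth. The
standard study conditions used by the tests and the acceptance script
are 400 training templates of 4–12 atoms, $\sigma = 0.15$ &Aring;, 100
held-out structures, default solver settings.

The generator reproduces the *statistical skeleton* the method assumes
— tight bond-length distributions, a steric exclusion floor, known
isotropic corruption — and nothing else. Real molecules also carry
angular and torsional regularities, conjugation, element-specific
valence patterns; random trees have none of these (bond directions are
uniform on the sphere). That difference matters for what the tests can
demonstrate. A denoiser can only remove noise along directions the
clean-structure prior constrains. For a random tree of $N$ atoms, the
bonded distances constrain roughly $N - 1$ of the $3N - 6$
alignment-free degrees of freedom; the remaining directions
(essentially all angles and torsions) are unconstrained, and the noise
on them is irreducible. The achievable aligned-RMSD reduction factor on
this benchmark is therefore bounded near
$\sqrt{(2N-5)/(3N-6)} \approx 0.7\!-\!0.8$ for $N$ in 4–12 — *no*
refiner, learned or oracle, can halve the RMSD of these structures.
Passing tests on this benchmark consequently demonstrate calibration
correctness, solver convergence behaviour, symmetry compliance, and the
directional effect of the bond-consistency loss on bond-length
distributions — not the large RMSD reductions that structured chemical
data admit. The test suite states the RMSD-halving expectation at face
value and it fails on this benchmark, by the argument above; the
convergence-rate and iteration-count expectations pass.

The bond-length distribution comparison (`bond_distribution_report()`,
Wasserstein-1 distance of bonded-pair distances against the reference
pool) is the more informative lens here, and shows the expected
behaviour: refinement sharpens bonded distances substantially, and
training with the bond term does at least as well as training without
it, on the same seed and epochs.

## The 2D saddle toy

`muller_brown_fixture()` builds the classic two-dimensional four-term
exponential surface, locates its first-order saddle numerically (Newton
on the analytic gradient from a standard start; the fixture *verifies*
gradient norm $< 10^{-6}$ and exactly one negative Hessian eigenvalue
rather than hard-coding the point), and draws corrupted samples around
it. The toy runs through a dedicated dense-network pathway
(`train_mlp2d()`, a tiny residual tanh network on raw 2D coordinates)
rather than the 3D equivariant net: a 2D potential has no rotational
symmetry to respect, and forcing the equivariant machinery onto it
would only blur the demonstration. Since all training targets coincide
at the saddle, the learned equilibrium map contracts the whole
neighbourhood onto it, and fixed-point refinement recovers the saddle
from fresh corrupted points to within a percent of their initial
deviation — the clearest possible picture of the method's mechanics.

## Evaluation conventions

* Reported RMSDs between distinct structures use Kabsch superposition
  with reflections excluded (mirror images are chemically distinct) and
  no atom-permutation matching; degenerate cases (single atom,
  collinear) return the identity rotation.
* "Improved" means a strict decrease. Energy-based metrics activate only
  when an analytic energy callable is supplied (the 2D toy); quantum
  chemistry is out of scope.
* Bonded/nonbonded classification uses covalent radii plus a
  0.4 &Aring; margin by default and is injectable
  (`covalent_bonded_rule`), so alternative threshold tables can be
  dropped in without touching the report code.
* `improvement_vs_threshold()` restricts statistics to records below an
  initial-quality threshold and reports explicit `NA` for empty
  subsets, never silent zeros.
* Pair enumeration is canonical everywhere (i < j, lexicographic), so
  losses, pools and reports are deterministic.

## Problem sizes and runtimes

The shipped tests and the acceptance script train the reference net on
400 templates for 200 epochs (about 3 minutes on one CPU core), refine
100 held-out structures (seconds), train the ablation variant once
more, and run the 2D toy (seconds). These sizes are the package's
standard desk-scale study conditions; all of them are plain parameters,
and scaling any of them up is a config change, not a code change.

## Known limitations

* The reference net is intentionally small; its fixed points carry a
  visible bias on hard inputs (iterating a weak denoiser drifts slightly
  along unconstrained directions). The framework is
  backbone-agnostic precisely so a stronger equivariant network can be
  plugged in where that bias matters.
* The corruption model is isotropic and element-independent; real
  low-fidelity errors are neither. `calibrate_sigma()` matches the
  second moment only.
* No atom-permutation matching in RMSD: structures whose atom order
  differs must be reconciled upstream.
* The XYZ reader accepts the common dialects (plain and extended
  comment-line metadata, extra columns ignored) but is not a general
  trajectory-format library.
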