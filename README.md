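# aefm — adaptive equilibrium flow matching for molecular geometry refinement

`aefm` refines noisy or low-fidelity molecular geometries — typically
approximate transition-state (TS) guesses from semiempirical methods or
ML generators — toward high-fidelity references, using only element
symbols and Cartesian coordinates (Å). It is aimed at computational
chemists who want a cheap structure-only correction step between a fast
TS generator and expensive quantum-chemical refinement.

## The method

A time-independent network φ<sub>θ</sub> is trained to map degraded
geometries directly to their references. The training prior is an
isotropic Gaussian corruption *x*₀ = *x*₁ + σε whose scale is calibrated
from observed low-fidelity/reference deviations via the per-atom
moment identity E[‖σε‖²/N] = 3σ²:

σ = ( mean over pairs of ‖x₁ − x₁ʷ‖² / (3N) )<sup>1/2</sup>

Inputs are sampled on the interpolation path
*x*<sub>t</sub> = (1−t)·x₀ + t·x₁ + σ<sub>FM</sub>·ε′ with t ~ U(0,1)
and σ<sub>FM</sub> = 0.05, **without** passing t to the network — the
model infers input quality from geometry alone, which is what lets a
single map handle inputs of heterogeneous quality. The loss is

L = L<sub>AEFM</sub> + w<sub>b</sub>·L<sub>b</sub>,  w<sub>b</sub> = 1

where L<sub>AEFM</sub> = ‖x₁ − φ<sub>θ</sub>(x<sub>t</sub>)‖²/N is the
endpoint-prediction term and L<sub>b</sub> penalizes squared deviations
of pair distances over the reference neighbour set
B(x₁) = {(i,j) : ‖x₁ᵢ − x₁ⱼ‖ < 2 Å} (the same reference-derived pairs
are measured on the prediction). At inference the structure is refined
by fixed-point iteration x<sup>k+1</sup> = φ<sub>θ</sub>(x<sup>k</sup>)
from the low-fidelity guess, with Anderson acceleration (β = 1, history
m = 5), stopping when the RMSD between successive iterates ≤ 0.01 Å
(cap 100 iterations). Spectral-radius diagnostics of the model Jacobian
(Arnoldi on Jacobian-vector products) certify local contraction.

The shipped backbone is a small SE(3)- and permutation-equivariant
message-passing network (invariant pair features → scalar pair weights
→ updates along difference vectors) with identity initialization and
hand-derived gradients; any backbone satisfying the refiner contract
can be plugged in.

## Worked example

```r
library(aefm)

## 1. simulate a benchmark: 120 reference geometries + corrupted copies
templates <- generate_templates(template_spec(120, atoms_min = 4, atoms_max = 12, seed = 1))
manifest  <- make_benchmark(templates, sigma_true = 0.15, dir = "bench", seed = 2)
pairs     <- load_pairs(manifest)

## 2. calibrate the corruption scale from the pairs
print(calibrate_sigma(pairs, provenance = manifest))

## 3. train the reference equivariant refiner (short demo run)
fit <- train_refiner(pairs, train_config(epochs = 60, seed = 3))
print(tail(fit$history, 2))

## 4. refine fresh corrupted structures by Anderson-accelerated fixed point
holdout <- generate_templates(template_spec(30, atoms_min = 4, atoms_max = 12, seed = 9))
set.seed(10)
lows  <- lapply(holdout, corrupt, sigma = 0.15)
batch <- refine_batch(fit$model, lows, solver_config())
print(batch)

## 5. evaluate
report <- summarize_refinement(lows, lapply(batch$results, `[[`, "refined"),
                               holdout, fp_results = batch$results)
print(report)
cat(sprintf("bonded-distance W1 to reference pool: %.4f -> %.4f Angstrom\n",
            report$aggregates$w1$initial_bonded,
            report$aggregates$w1$refined_bonded))
```

Output (about 20 s on one CPU core):

```
<aefm_prior_calibration: sigma = 0.15035 A from 120 pairs (per-atom MSD 0.06782 A^2)>
   epoch      total       aefm       bond  val_rmsd
59    59 0.04510818 0.02954137 0.01556681 0.2040247
60    60 0.04597933 0.02901994 0.01695938 0.1857731
<aefm_refine_batch: 30 structures, 100.0% converged, median 9.5 iterations>
<aefm_refinement_report: 30 structures
  RMSD (A)   mean 0.2202 -> 0.3040 | median 0.2226 -> 0.2820
  improved in RMSD: 16.7%>
bonded-distance W1 to reference pool: 0.0648 -> 0.0255 Angstrom
```

Reading the numbers: the calibration recovers the true corruption scale
(0.150 vs 0.15); every held-out structure reaches a fixed point in a
median of ~10 iterations; and refinement sharpens the bonded-distance
distribution by 2.5× (Wasserstein-1 against the reference pool,
0.065 → 0.026 Å) even though the aligned RMSD does not improve on this
toy benchmark. That last contrast is expected: the synthetic templates
have random bond angles and torsions, so bonded distances are the only
geometry a denoiser can learn to fix — see the methods vignette
(`vignettes/adaptive-equilibrium-refinement.Rmd`) for the quantitative
argument and for everything tunable.

A thin command-line front end over the same functions ships as
`inst/cli/aefm.R` with subcommands `simulate`, `calibrate`, `train`,
`refine`, `evaluate`.

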