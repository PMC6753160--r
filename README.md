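# rdcalign

Alignment-tensor analysis of amide residual dipolar couplings (RDCs) in R.

RDCs measured under weak alignment report on the orientation of each N–H
bond relative to the molecule's alignment frame, making them a
distance-independent probe of domain structure and inter-domain motion —
including in systems where only a mobile domain of a very large complex is
NMR-visible (the motivating case is the flexibly tethered C-terminal domain
of a ribosomal stalk protein). `rdcalign` is aimed at NMR spectroscopists
and structural bioinformaticians who need a scriptable, testable version of
the standard order-matrix workflow.

The core model is the Saupe order matrix **S** (traceless, symmetric,
3×3): the coupling of unit bond vector *b* is

    D = Dmax · bᵀ S b

which is linear in the five independent components of **S**, so the tensor
is fitted to measured couplings by SVD least squares. On top of this the
package provides:

* **Measurement** — couplings and uncertainties from isotropic/anisotropic
  peak lists (HSQC/TROSY or IPAP), with σ_ν = LW/(2·SN) position errors,
  quadrature propagation, and the standard dataset filters
  (S² < 0.85 flexibility, conformational exchange, overlap, σ_D > 5 Hz).
* **Fitting & validation** — `svd_fit()` with Q factor
  rms(D_calc − D_obs)/rms(D_obs), rmsd, condition-number diagnostics, and
  principal-frame parameters (Da, rhombicity R ∈ [0, 2/3], z-y-z Euler
  angles, generalized degree of order).
* **Uncertainty** — Monte-Carlo propagation of per-record coupling noise
  and cone-style structural noise (`mc_tensor_uncertainty()`), validated
  against the analytic pseudoinverse covariance.
* **Comparison** — irreducible 5-vectors, the 5D inter-tensor angle (equal
  to the Frobenius-inner-product angle by construction), and
  Sanson-Flamsteed projections of principal axes.
* **Refinement** — simulated-annealing rigid-body refinement of
  secondary-structure-element orientations against soft square-well RDC
  restraints with a floating tensor orientation and fixed Da/R.
* **Propagation** — the inter-domain order parameter
  S² = GDO(indirect)/GDO(direct) and forward simulation of alignment
  propagation through linker-rotation ensembles (uniform or
  exp(κ·cos ω)-concentrated).
* **Synthetic data** — ideal helix/strand/two-helix structures, simulated
  RDC datasets and peak lists with known ground truth, used throughout the
  tests for parameter recovery.

See the methods vignette (`vignettes/rdc-analysis.Rmd`) for the model
details, conventions and design decisions.

## Worked example

Simulate a realistic dataset (two-helix fixture, Da = 10 Hz, R = 0.3,
1.8 Hz coupling noise), fit the tensor, and quantify its uncertainty:

```r
library(rdcalign)

truth <- tensor_from_parameters(10, 0.3, c(20, 30, 40))
st    <- make_structure(fixture_spec("two_helix", n_residues = 12))
vec   <- extract_nh_vectors(st)
ds    <- simulate_rdcs(st, truth, noise = 1.8, seed = 42)

fit <- svd_fit(ds, vec)
fit
#> rdc_fit: n = 22, Q = 0.1813, rmsd = 1.814 Hz, Da = 14.488 Hz, R = 0.013
#>   euler (zyz): 88.1 23.5 28.7 deg; GDO = 0.00134; cond = 7.59

mc <- mc_tensor_uncertainty(ds, vec,
        mc_spec(n_iterations = 500, structural_noise_angle = 5, seed = 1),
        reference = truth)
mc$summary[mc$summary$parameter %in% c("Da", "magnitude", "angle5d"), 1:3]
#>  parameter     mean       sd
#>         Da 12.99958 2.840576
#>  magnitude  0.00122 0.000216
#>    angle5d 22.11924 8.385534
```

At this noise level a 22-residue fit is honest but imprecise: the fitted
Da (14.5 Hz) and the 5D angle to the generating tensor (19.8°) sit well
inside the Monte-Carlo distributions (Da 13.0 ± 2.8 Hz, angle 22 ± 8°),
which is exactly what the uncertainty machinery is for. With `noise = 0`
the same pipeline returns the generating tensor to 1e-10 and Q < 1e-10.

The inter-domain order parameter from a measured magnitude pair —
directly aligned domain (2.5 ± 0.2)×10⁻³, indirectly aligned domain
(3.5 ± 1.3)×10⁻⁴:

```r
order_parameter(2.5e-3, 0.2e-3, 3.5e-4, 1.3e-4)
#> order parameter S2 = 0.14 +/- 0.05 (indirect 0.00035 / direct 0.0025)
```

A thin command-line front end covering simulate/fit/compare/mc/refine/
propagate is installed at `system.file("exec", "rdcalign", package =
"rdcalign")`.

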