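---
title: "Alignment-tensor analysis of residual dipolar couplings with rdcalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-tensor analysis of residual dipolar couplings with rdcalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcalign)
```

# Scope

`rdcalign` implements a complete analysis chain for amide residual dipolar
couplings (RDCs) measured on weakly aligned proteins, including very large
complexes where a mobile domain is the only NMR-visible part:

1. coupling extraction from isotropic/anisotropic peak lists
   (HSQC/TROSY pairs or IPAP doublets) with uncertainty propagation and
   dataset-quality filtering;
2. Saupe alignment-tensor fitting by SVD least squares, with Q-factor and
   rmsd validation;
3. Monte-Carlo propagation of coupling noise and structural noise into
   tensor-parameter uncertainties;
4. tensor comparison (irreducible 5-vectors, 5D angles, Sanson-Flamsteed
   axis projections);
5. rigid-body refinement of secondary-structure-element orientations
   against RDC restraints;
6. inter-domain alignment propagation: a tensor-magnitude order parameter
   and forward simulation through linker-rotation ensembles.

A synthetic-data generator provides every input with known ground truth, so
all of the above is validated by parameter recovery rather than against
irreproducible experimental tables.

# The model

Under weak alignment, the RDC of an amide bond vector is

$$ D_i = D_{\max}\, \mathbf{b}_i^{\mathsf T} \mathbf{S}\, \mathbf{b}_i, $$

where $\mathbf{b}_i$ is the unit N--H internuclear vector in the reference
(PDB) frame, $\mathbf{S}$ is the traceless symmetric $3\times3$ Saupe order
matrix, and $D_{\max}$ is the dipolar interaction constant. The package
stores the pair $(\mathbf{S}, D_{\max})$ as an `alignment_tensor`. The
default $D_{\max} = 21.7$ kHz corresponds to an N--H distance of 1.04 Å;
every dimensionless result (Q factors, rhombicity, orientations, 5D angles,
order parameters) is invariant to this constant, which only fixes the scale
of the unitless Saupe components (typically $10^{-4}$--$10^{-3}$ in phage
or tag alignment).

In the principal axis frame, with eigenvalues ordered
$|A_{zz}| \ge |A_{yy}| \ge |A_{xx}|$, the derived parameters are the axial
component $D_a = D_{\max} A_{zz}/2$ (Hz), the rhombicity
$R = \tfrac{2}{3}(A_{xx}-A_{yy})/A_{zz} \in [0, 2/3]$, the z-y-z Euler
angles of the rotation from the reference frame into the principal frame,
and the generalized degree of order
$\mathrm{GDO} = \sqrt{\tfrac{2}{3}\sum_{kl} S_{kl}^2}$, a
rotation-invariant magnitude.

## Coupling measurement

Peak positions are consumed in Hz. Each position carries the uncertainty
$\sigma_\nu = \mathrm{LW}/(2\,\mathrm{SN})$ from the linewidth and
signal-to-noise ratio of the peak. Splittings are

* HSQC/TROSY: $2(\nu_{\mathrm{TROSY}} - \nu_{\mathrm{HSQC}})$ — the
  decoupled peak sits at the multiplet centre, the TROSY peak at one
  component — with $\sigma = 2\sqrt{\sigma^2_{\mathrm{HSQC}} +
  \sigma^2_{\mathrm{TROSY}}}$;
* IPAP: $\nu_{\mathrm{down}} - \nu_{\mathrm{up}}$ with quadrature error.

The coupling is the anisotropic-minus-isotropic splitting difference, again
with quadrature propagation; with constant SN and LW the HSQC/TROSY route
therefore yields $\sigma_D = 4\sigma_\nu$. The simulated TROSY component is
displaced by $+(J+D)/2$ from the decoupled position with $^1J_{\mathrm{NH}}
= -93$ Hz by default; the displacement sign is a single generator
convention, and all round-trip tests fix it consistently. Only frequency
differences enter any result, so the absolute peak positions and the value
of $J$ cancel.

Dataset-quality filters mark records excluded when the residue is locally
flexible (order parameter $S^2 < 0.85$), in conformational exchange, when
the resonance is overlapped, or when $\sigma_D > 5$ Hz. Both thresholds are
strict inequalities, so boundary records ($S^2 = 0.85$, $\sigma_D = 5$ Hz)
are retained. When several rules match the recorded reason follows the
priority flexible > exchange > overlap > large uncertainty; overlap is an
input flag from the peak list, not detected computationally. The RMS
uncertainty $\langle\sigma_D^2\rangle^{1/2}$ is always recomputed over the
surviving records.

## Tensor fitting and validation

Since $D_i$ is linear in the five independent Saupe components, fitting is
a linear least-squares problem solved by singular-value decomposition of
the $n\times5$ direction-cosine design matrix. At least five usable
records are required and the condition number is checked (default
threshold $10^8$); coplanar or parallel bond-vector geometries are reported
as rank deficiency rather than silently extrapolated. The fit is
unweighted by default, matching the common order-matrix convention;
$1/\sigma_D$ row weighting is available but off so that Q factors keep
their usual meaning.

The quality of agreement is
$Q = \mathrm{rms}(D_{\mathrm{calc}} - D_{\mathrm{obs}})/
\mathrm{rms}(D_{\mathrm{obs}})$; the alternative normalisation by
$\sqrt{2 D_a^2 (4 + 3R^2)/5}$ is provided as an option because published Q
values use both conventions. Fit and scoring selections are independent:
you can fit on all residues and score only secondary-structure elements,
or restrict both with `select_sse_vectors()`.

Euler angles carry a four-fold degeneracy (the proper sign flips of the
principal axes). The canonical representative has $\beta \in [0^\circ,
90^\circ]$ with ties broken by smallest $\alpha$, then $\gamma$;
`equivalent_frames()` enumerates all four representatives so orientations
can be compared modulo the degeneracy.

## Monte-Carlo uncertainties

`mc_tensor_uncertainty()` repeats a perturb-and-refit cycle: every included
coupling receives independent Gaussian noise with its own $\sigma_D$, and
every bond vector is rotated about a uniformly random perpendicular axis by
an angle drawn from a half-normal distribution (default s.d. $5^\circ$).
The cone-style reorientation is this package's structural-noise model; its
magnitude is an assumption to be reported with any derived uncertainty, and
it is validated against its own analytic properties (half-normal mean
displacement) and, for the coupling channel, against the delta-method
covariance $({A}^{\mathsf T}{A})^{-1}{A}^{\mathsf T}\Sigma
{A}({A}^{\mathsf T}{A})^{-1}$ from the design-matrix pseudoinverse
(`analytic_saupe_sd()`), which the empirical spreads match to within a few
percent at 1000 iterations. The two noise channels are drawn independently
per iteration; no residue-residue correlation is imposed. Each iteration's
random stream is derived deterministically from (seed, iteration), so runs
are exactly reproducible and individual iterations can be replayed.

Euler-angle samples are degeneracy-resolved toward the unperturbed point
estimate before being summarised with circular means and circular standard
deviations; non-circular parameters get means, s.d.s and central 68%/95%
intervals. Note that near-degenerate eigenvalue spectra make $D_a$ and $R$
heavy-tailed under large noise (the eigenvalue ordering can swap); the
Saupe components themselves remain well-behaved, which is why calibration
checks are phrased on the components.

## Rigid-body refinement

The refinement optimises only the orientation of each secondary-structure
element — one proper rotation about the element's C$\alpha$ centroid — plus
a global rotation of the tensor frame, holding $D_a$ and $R$ fixed at
values supplied in the configuration (typically those of the template
best-fit tensor). Translations are excluded because RDCs are insensitive
to them. The target is a soft square-well energy,

$$ E = k \sum_i \max(0, |D_{\mathrm{calc},i} - D_{\mathrm{obs},i}| -
\sigma_{D,i})^2, $$

zero whenever a residual is within its experimental uncertainty and
quadratic (with continuous first derivative) outside. Minimisation is
Metropolis simulated annealing — geometric cooling, default 50 temperature
steps of 200 moves with the initial temperature calibrated so that about
half of the initial uphill moves are accepted — followed by a greedy quench
of 3000 moves with geometrically shrinking step sizes. Because the well
bottoms are flat, the quench breaks ties by the plain sum of squared
residuals; this removes the slack the wells would otherwise leave (about
$\pm1$--$2^\circ$ on a 10$^\circ$ recovery problem) without changing the
reported energy model.

Two consequences of this deliberately minimal parameterisation deserve
emphasis:

* **Gauge freedom.** The couplings are invariant under a common rotation
  applied to all elements and the tensor frame, so per-element rotations
  are only defined relative to a reference. The reported solution is
  re-expressed in the gauge where the element carrying the most restraints
  (ties: first in the definition) has zero net rotation; its reorientation
  relative to the alignment frame is carried by the floating tensor
  orientation. Relative rotations between elements are gauge-invariant.
* **No covalent bookkeeping.** Loops and linkers keep their template
  coordinates and element junctions are not re-closed; the largest
  displacement of a junction backbone atom is reported as the
  `junction_max_shift` diagnostic instead of being repaired. The refined
  coordinates are therefore an orientation model, not a stereochemically
  continuous structure.

With zero included restraints the template is returned unchanged. Runs are
deterministic for a given seed, and the best-so-far energy trace is
non-increasing by construction.

## Tensor comparison

The five independent Saupe components are mapped to the irreducible
5-vector
$\left(\sqrt{3/2}\,S_{zz},\ (S_{xx}-S_{yy})/\sqrt{2},\ \sqrt2\,S_{xy},\
\sqrt2\,S_{xz},\ \sqrt2\,S_{yz}\right)$, scaled so that the Euclidean inner
product of two 5-vectors equals the Frobenius inner product of the Saupe
matrices. The 5D angle between two alignments is then identical to
$\arccos\langle \mathbf S_1, \mathbf S_2\rangle_F /(\|\mathbf S_1\|_F
\|\mathbf S_2\|_F)$ — there is no residual normalisation convention to
choose, and magnitude differences cancel by construction. Principal axes
are plotted via the equal-area sinusoidal (Sanson-Flamsteed) projection
$x = \lambda\cos\varphi,\ y = \varphi$; axes are unsigned, so each is
replaced by its antipodal representative with non-negative $z$ (ties:
non-negative $y$, then $x$), and axially symmetric tensors are flagged as
degenerate rather than given arbitrary transverse axes.

## Alignment propagation and the inter-domain order parameter

When only one domain of a flexibly linked system is aligned directly (for
example by a paramagnetic tag), any alignment observed in the other domain
must have propagated through the linker. The effective tensor in the
mobile domain's frame is the ensemble average
$\mathbf S_{\mathrm{eff}} = \sum_c w_c\, \mathbf R_c^{\mathsf T}
\mathbf S\, \mathbf R_c$ over conformer rotations $\mathbf R_c$. The
inter-domain order parameter is the magnitude ratio

$$ S^2 = \frac{\mathrm{GDO}(\text{indirect})}{\mathrm{GDO}(\text{direct})}, $$

1 for a rigid linker and 0 for a fully flexible one, with a first-order
(delta-method) uncertainty from the two magnitude s.d.s. The ratio
definition (not a squared ratio) matches how such order parameters are
quoted from experimental magnitude pairs; with magnitudes
$(2.5\pm0.2)\times10^{-3}$ (direct) and $(3.5\pm1.3)\times10^{-4}$
(indirect) it gives $S^2 = 0.14 \pm 0.05$.

Two ensemble generators are provided. `"random"` samples rotations
uniformly on the rotation group (quaternion method) — the fully flexible
reference, for which the propagated tensor vanishes as $n^{-1/2}$.
`"concentrated"` draws rotation axes uniformly and angles
$\omega \in [0, \pi]$ with density $\propto \exp(\kappa\cos\omega)$, a
single-parameter surrogate for a partially coupled linker: $\kappa = 0$
gives angle-uniform disorder, $\kappa \to \infty$ the rigid limit, and the
predicted $S^2$ is strictly increasing in $\kappa$, so any experimental
$S^2$ can be matched by one $\kappa$. This family makes no claim to
represent the real linker's conformational distribution — it exists to
span the flexible-to-rigid axis with known ground truth. Composition of
two ensembles (`compose_ensembles()`) models propagation through two
sequential linkers without asserting anything about their coupling.

# The synthetic-data generator

`make_structure()` builds ideal poly-alanine geometry by internal
coordinates: helices with $\varphi = -57^\circ, \psi = -47^\circ$, strands
with $\varphi = -135^\circ, \psi = 135^\circ$, standard bond lengths and
angles, amide protons in the peptide plane, and no proton on the first
residue of a segment. The two-helix fixture places a second helix rotated
75° and translated away from the first, giving bond-vector sets whose
design matrices are well-conditioned (condition number ~8) — a single
helix's near-parallel N--H bundle is deliberately poor RDC geometry, which
the rank-deficiency error path also exercises.

`simulate_rdcs()` adds Gaussian noise to back-calculated couplings;
`simulate_peak_lists()` inverts the measurement module, emitting the four
peak lists with linewidths drawn from $\mathcal N(11, 2^2)$ Hz truncated
positive and configurable signal-to-noise. Defaults emulate a realistic
weak-alignment regime — couplings up to ±30 Hz for $D_a = 10$ Hz,
coupling noise 1.8 Hz, $^{15}$N linewidths 11 ± 2 Hz — so recovery tests
run at honest signal-to-noise rather than in an idealised limit.

What the generator does *not* emulate: real chemical-shift dispersion and
peak overlap (overlap is an input flag), local dynamics (order-parameter
maps are supplied by the caller), residue-type geometry variation,
anisotropic linewidths, or spectral artefacts. Passing recovery tests
therefore demonstrate the correctness of the computations, not robustness
to every pathology of experimental spectra.

# Numerical choices and degenerate inputs

* Tensor constructors symmetrise and re-project the trace after checking
  the input is symmetric/traceless to 1e-8 relative, so stored invariants
  hold exactly.
* `svd_fit()` errors below 5 usable records and above condition number
  1e8, naming the degenerate geometry.
* Zero tensors: parameters report zero magnitude with flagged undefined
  orientation; 5D angles to a zero tensor are an error.
* Axially symmetric tensors: transverse axes flagged degenerate in
  projections; rotations about the symmetry axis give a 5D angle of 0.
* Euler extraction at the gimbal singularity ($\beta = 0$ or $180^\circ$)
  puts the whole in-plane rotation into $\alpha$.
* Monte-Carlo fit failures are counted; more than 10% failing iterations
  aborts the run.
* Per-iteration seeds are `(seed + 1000003 * iteration) mod (2^31 - 19)`,
  keeping every derived seed a valid 32-bit integer.
* The concentrated-angle sampler inverts the CDF on a 4096-point grid,
  narrowed to the mass-carrying interval for large $\kappa$ so the rigid
  limit stays accurate.

# Problem sizes used in the tests

The shipped test-suite and acceptance-script sizes were chosen so the full
cycle is a desk-scale computation: fixtures of 12–26 residues per element
(22–50 bond vectors), 500–1000 Monte-Carlo iterations for calibration
checks, 120 replicate experiments for interval-coverage checks, $10^4$–$10^5$
conformers for ensemble limits, and the default annealing schedule
(50 × 200 moves + 3000 quench steps) for refinement recovery. All are
configuration parameters, and all scale linearly or better.

# Known limitations

* Single alignment medium and a single coupling type (N--H); no joint
  multi-medium fits and no steric/electrostatic alignment prediction.
* The refinement's chain is not covalently re-closed at element junctions
  (reported, not repaired), and element translations are fixed.
* Per-element refinement rotations are conventionally gauged (see above);
  only relative orientations are data-determined when the tensor floats.
* $D_a$/$R$ uncertainties from Monte Carlo become asymmetric near
  eigenvalue degeneracy; prefer the component-level summaries there.
* The concentrated-rotation linker family is a surrogate, not a physical
  linker model; conclusions drawn from it should be stated in terms of the
  flexible-to-rigid axis it parameterises.
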